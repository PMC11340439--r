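# Equivariant network building blocks on the autodiff tape: irreps-wise
# linear maps, weighted tensor products with edge spherical harmonics,
# gated feed-forward blocks, equivariant layer normalisation and the
# graph self-attention layer.

# ---- irreps-wise linear ----------------------------------------------

# Linear map between irreps layouts. Mixes multiplicities within each
# (l, parity) type; types absent from the input map to zeros. Weights
# are N(0,1)-initialised and the op scales by 1/sqrt(fan_in).
linear_plan <- function(ir_in, ir_out) {
  blocks <- list()
  for (b3 in seq_len(nrow(ir_out))) {
    l <- ir_out$l[b3]; p <- ir_out$parity[b3]
    d <- 2L * l + 1L
    matches <- which(ir_in$l == l & ir_in$parity == p)
    in_cols <- integer(0)
    m_in <- 0L
    for (b1 in matches) {
      in_cols <- c(in_cols, irreps_block_cols(ir_in, b1))
      m_in <- m_in + ir_in$mult[b1]
    }
    lab <- sprintf("%d%s", l, if (p == 1L) "e" else "o")
    blocks[[length(blocks) + 1L]] <- list(
      l = l, d = d, m_in = m_in, m_out = ir_out$mult[b3],
      in_cols = in_cols, scalar = (l == 0L), label = lab)
  }
  list(ir_in = ir_in, ir_out = ir_out, blocks = blocks)
}

linear_param_shapes <- function(plan, prefix, bias = TRUE) {
  shapes <- list()
  for (blk in plan$blocks) {
    if (blk$m_in > 0) {
      shapes[[paste0(prefix, ".", blk$label, ".W")]] <-
        c(blk$m_out, blk$m_in)
    }
    if (bias && blk$scalar) {
      shapes[[paste0(prefix, ".", blk$label, ".b")]] <- c(1L, blk$m_out)
    }
  }
  shapes
}

# custom op: contract multiplicities of one block
ad_block_linear <- function(tp, x, w, cols, m_in, m_out, d) {
  X <- ad_value(tp, x)
  W <- ad_value(tp, w)
  E <- nrow(X)
  sc <- 1 / sqrt(m_in)
  Xc <- X[, cols, drop = FALSE]
  Xm <- matrix(Xc, E * d, m_in)   # (row, comp) x mult
  Ym <- (Xm %*% t(W)) * sc
  val <- matrix(Ym, E, m_out * d)
  nc_x <- ncol(X)
  tape_node(tp, val, c(x, w), function(g) {
    Gm <- matrix(g, E * d, m_out)
    dXc <- (Gm %*% W) * sc
    dX <- matrix(0, E, nc_x)
    dX[, cols] <- matrix(dXc, E, m_in * d)
    dW <- crossprod(Gm, Xm) * sc
    list(dX, dW)
  })
}

irreps_linear <- function(tp, x, plan, pids, prefix, bias = TRUE) {
  E <- nrow(ad_value(tp, x))
  outs <- integer(0)
  for (blk in plan$blocks) {
    if (blk$m_in == 0) {
      oid <- ad_const(tp, matrix(0, E, blk$m_out * blk$d))
    } else {
      w <- pids[[paste0(prefix, ".", blk$label, ".W")]]
      oid <- ad_block_linear(tp, x, w, blk$in_cols, blk$m_in,
                             blk$m_out, blk$d)
      if (bias && blk$scalar) {
        b <- pids[[paste0(prefix, ".", blk$label, ".b")]]
        oid <- ad_add_bias(tp, oid, b)
      }
    }
    outs <- c(outs, oid)
  }
  if (length(outs) == 1L) outs else do.call(ad_cbind, c(list(tp), outs))
}

# ---- weighted tensor product with spherical harmonics ----------------

# Enumerate coupling paths x-block (l1,p1) x sh-order l2 -> output
# (l3, natural parity), depthwise ("uvu": the output inherits the input
# multiplicity; one learned weight per path and copy, supplied per
# edge by a scalar network). Outputs are concatenated path by path; an
# irreps linear afterwards mixes them into the target layout.
tp_plan <- function(ir_in, l_max_sh, l_max_out) {
  paths <- list()
  w_off <- 0L
  out_off <- 0L
  out_rows <- list()
  for (b1 in seq_len(nrow(ir_in))) {
    l1 <- ir_in$l[b1]; p1 <- ir_in$parity[b1]; m <- ir_in$mult[b1]
    for (l2 in 0:l_max_sh) {
      p3 <- p1 * (-1L)^l2
      for (l3 in abs(l1 - l2):min(l1 + l2, l_max_out)) {
        if (p3 != (-1L)^l3) next
        ent <- coupling_entries(l1, l2, l3)
        if (is.null(ent)) next
        paths[[length(paths) + 1L]] <- list(
          b1 = b1, l1 = l1, l2 = l2, l3 = l3, mult = m,
          in_cols = irreps_block_cols(ir_in, b1),
          sh_cols = (l2^2 + 1):((l2 + 1)^2),
          w_cols = w_off + seq_len(m),
          out_off = out_off,
          entries = ent)
        w_off <- w_off + m
        out_rows[[length(out_rows) + 1L]] <-
          data.frame(mult = m, l = l3, parity = p3)
        out_off <- out_off + m * (2L * l3 + 1L)
      }
    }
  }
  if (length(paths) == 0) stop("tensor product has no allowed paths")
  list(paths = paths, n_weights = w_off,
       ir_out = irreps(do.call(rbind, out_rows)),
       dim_out = out_off)
}

# custom op: out[, u, m3] += c * w[, u] * x[, u, m1] * sh[, m2]
ad_tp <- function(tp, x, w, sh, plan) {
  X <- ad_value(tp, x)
  W <- ad_value(tp, w)
  SH <- ad_value(tp, sh)
  E <- nrow(X)
  out <- matrix(0, E, plan$dim_out)
  for (p in plan$paths) {
    d1 <- 2L * p$l1 + 1L; d3 <- 2L * p$l3 + 1L
    Wp <- W[, p$w_cols, drop = FALSE]
    for (r in seq_len(nrow(p$entries))) {
      e <- p$entries[r, ]
      s <- e$c * SH[, p$sh_cols[e$m2]]
      xc <- p$in_cols[(seq_len(p$mult) - 1L) * d1 + e$m1]
      oc <- p$out_off + (seq_len(p$mult) - 1L) * d3 + e$m3
      out[, oc] <- out[, oc] + X[, xc, drop = FALSE] * Wp * s
    }
  }
  nc_x <- ncol(X); nc_w <- ncol(W)
  tape_node(tp, out, c(x, w), function(g) {
    dX <- matrix(0, E, nc_x)
    dW <- matrix(0, E, nc_w)
    for (p in plan$paths) {
      d1 <- 2L * p$l1 + 1L; d3 <- 2L * p$l3 + 1L
      Wp <- W[, p$w_cols, drop = FALSE]
      for (r in seq_len(nrow(p$entries))) {
        e <- p$entries[r, ]
        s <- e$c * SH[, p$sh_cols[e$m2]]
        xc <- p$in_cols[(seq_len(p$mult) - 1L) * d1 + e$m1]
        oc <- p$out_off + (seq_len(p$mult) - 1L) * d3 + e$m3
        Gc <- g[, oc, drop = FALSE]
        dX[, xc] <- dX[, xc] + Gc * Wp * s
        dW[, p$w_cols] <- dW[, p$w_cols] +
          Gc * X[, xc, drop = FALSE] * s
      }
    }
    list(dX, dW)
  })
}

# ---- equivariant layer norm ------------------------------------------

# scalar block: per-row standardisation (population variance) with
# learned gain and bias
ad_lnorm_scalar <- function(tp, x, gain, bias, eps = 1e-6) {
  X <- ad_value(tp, x)
  Gn <- as.vector(ad_value(tp, gain))
  Bs <- as.vector(ad_value(tp, bias))
  C <- ncol(X)
  mu <- rowMeans(X)
  va <- rowMeans(X^2) - mu^2
  sd_ <- sqrt(va + eps)
  Y0 <- (X - mu) / sd_
  val <- sweep(sweep(Y0, 2, Gn, "*"), 2, Bs, "+")
  tape_node(tp, val, c(x, gain, bias), function(g) {
    Gp <- sweep(g, 2, Gn, "*")
    t1 <- rowMeans(Gp)
    t2 <- rowMeans(Gp * Y0)
    dX <- (Gp - t1 - Y0 * t2) / sd_
    list(dX, colSums(g * Y0), colSums(g))
  })
}

# l > 0 block: rescale by the root-mean-square of the per-copy norms;
# one learned gain per copy, direction preserved
ad_rmsnorm_block <- function(tp, x, gain, m, d, eps = 1e-12) {
  X <- ad_value(tp, x)
  Gn <- as.vector(ad_value(tp, gain))
  sq <- X^2
  ssum <- matrix(0, nrow(X), m)
  for (u in seq_len(m)) {
    ssum[, u] <- rowSums(sq[, (u - 1L) * d + seq_len(d), drop = FALSE])
  }
  r <- sqrt(rowMeans(ssum) + eps)
  gx <- rep(Gn, each = d)
  val <- sweep(X / r, 2, gx, "*")
  tape_node(tp, val, c(x, gain), function(g) {
    Gp <- sweep(g, 2, gx, "*")
    inner <- rowSums(Gp * X)
    dX <- Gp / r - X * (inner / (m * r^3))
    dg_full <- colSums(g * X / r)
    dgain <- rowsum(dg_full, group = rep(seq_len(m), each = d))
    list(dX, matrix(dgain, nrow = 1))
  })
}

eq_layer_norm <- function(tp, x, layout, pids, prefix) {
  outs <- integer(0)
  for (b in seq_len(nrow(layout))) {
    cols <- irreps_block_cols(layout, b)
    xb <- ad_cols(tp, x, cols)
    lab <- sprintf("%d%s", layout$l[b],
                   if (layout$parity[b] == 1L) "e" else "o")
    if (layout$l[b] == 0L) {
      oid <- ad_lnorm_scalar(tp, xb,
                             pids[[paste0(prefix, ".", lab, ".gain")]],
                             pids[[paste0(prefix, ".", lab, ".bias")]])
    } else {
      oid <- ad_rmsnorm_block(tp, xb,
                              pids[[paste0(prefix, ".", lab, ".gain")]],
                              layout$mult[b], 2L * layout$l[b] + 1L)
    }
    outs <- c(outs, oid)
  }
  if (length(outs) == 1L) outs else do.call(ad_cbind, c(list(tp), outs))
}

lnorm_param_shapes <- function(layout, prefix) {
  shapes <- list()
  for (b in seq_len(nrow(layout))) {
    lab <- sprintf("%d%s", layout$l[b],
                   if (layout$parity[b] == 1L) "e" else "o")
    shapes[[paste0(prefix, ".", lab, ".gain")]] <- c(1L, layout$mult[b])
    if (layout$l[b] == 0L) {
      shapes[[paste0(prefix, ".", lab, ".bias")]] <- c(1L, layout$mult[b])
    }
  }
  shapes
}

# ---- gated feed-forward ----------------------------------------------

# multiply the d components of each copy by its gate column
ad_gate_block <- function(tp, x, g, m, d) {
  X <- ad_value(tp, x)
  Gt <- ad_value(tp, g)
  idx <- rep(seq_len(m), each = d)
  val <- X * Gt[, idx, drop = FALSE]
  tape_node(tp, val, c(x, g), function(gr) {
    dX <- gr * Gt[, idx, drop = FALSE]
    dG_full <- gr * X
    dG <- matrix(0, nrow(X), m)
    for (u in seq_len(m)) {
      dG[, u] <- rowSums(dG_full[, (u - 1L) * d + seq_len(d),
                                 drop = FALSE])
    }
    list(dX, dG)
  })
}

# equivariant NN of the update step: Linear -> (SiLU scalars, sigmoid
# gates on the l>0 copies) -> Linear
ffn_plans <- function(hidden) {
  h0_rows <- which(hidden$l == 0L)
  stopifnot(length(h0_rows) == 1L)
  h0 <- hidden$mult[h0_rows]
  hi <- hidden[hidden$l > 0L, , drop = FALSE]
  ng <- sum(hi$mult)
  mid_rows <- rbind(
    data.frame(mult = h0 + ng, l = 0L, parity = 1L),
    data.frame(mult = hi$mult, l = hi$l, parity = hi$parity))
  ir_mid <- irreps(mid_rows)
  post_rows <- rbind(
    data.frame(mult = h0, l = 0L, parity = 1L),
    data.frame(mult = hi$mult, l = hi$l, parity = hi$parity))
  ir_post <- irreps(post_rows)
  list(lin1 = linear_plan(hidden, ir_mid),
       lin2 = linear_plan(ir_post, hidden),
       h0 = h0, gates = hi$mult, gate_d = 2L * hi$l + 1L,
       ir_mid = ir_mid)
}

ffn_forward <- function(tp, x, fp, pids, prefix) {
  mid <- irreps_linear(tp, x, fp$lin1, pids, paste0(prefix, ".lin1"))
  h0 <- fp$h0
  ng <- sum(fp$gates)
  s <- ad_silu(tp, ad_cols(tp, mid, seq_len(h0)))
  parts <- list(s)
  if (ng > 0) {
    gates <- ad_sigmoid(tp, ad_cols(tp, mid, h0 + seq_len(ng)))
    goff <- 0L
    coff <- h0 + ng
    for (k in seq_along(fp$gates)) {
      m <- fp$gates[k]; d <- fp$gate_d[k]
      xb <- ad_cols(tp, mid, coff + seq_len(m * d))
      gb <- ad_cols(tp, gates, goff + seq_len(m))
      parts[[length(parts) + 1L]] <- ad_gate_block(tp, xb, gb, m, d)
      goff <- goff + m
      coff <- coff + m * d
    }
  }
  post <- if (length(parts) == 1L) parts[[1]]
          else do.call(ad_cbind, c(list(tp), parts))
  irreps_linear(tp, post, fp$lin2, pids, paste0(prefix, ".lin2"))
}

# ---- scalar MLP (edge-weight networks, readout heads) ----------------

mlp2_shapes <- function(d_in, d_hid, d_out, prefix) {
  shapes <- list()
  shapes[[paste0(prefix, ".W1")]] <- c(d_in, d_hid)
  shapes[[paste0(prefix, ".b1")]] <- c(1L, d_hid)
  shapes[[paste0(prefix, ".W2")]] <- c(d_hid, d_out)
  shapes[[paste0(prefix, ".b2")]] <- c(1L, d_out)
  shapes
}

mlp2_forward <- function(tp, x, pids, prefix) {
  h <- ad_add_bias(tp, ad_mm(tp, x, pids[[paste0(prefix, ".W1")]]),
                   pids[[paste0(prefix, ".b1")]])
  h <- ad_silu(tp, h)
  ad_add_bias(tp, ad_mm(tp, h, pids[[paste0(prefix, ".W2")]]),
              pids[[paste0(prefix, ".b2")]])
}

# ---- attention layer -------------------------------------------------

# One E(3)-equivariant self-attention layer. Queries come from the
# receiving node; keys and values are tensor products of the sending
# node's features with the edge harmonics, weighted by scalar networks
# of the invariant edge embedding. The attention logit is the invariant
# channel of q (x) k summed over copies (a scaled dot product); softmax
# is taken over the incoming edges of each node. Nodes without
# neighbours aggregate the zero tensor.
attn_layer_forward <- function(tp, x, lp, pids, prefix, ctx) {
  q <- irreps_linear(tp, x, lp$q, pids, paste0(prefix, ".q"))
  xg <- ad_gather(tp, x, ctx$edge_src)
  wk <- mlp2_forward(tp, ctx$es, pids, paste0(prefix, ".nnk"))
  wv <- mlp2_forward(tp, ctx$es, pids, paste0(prefix, ".nnv"))
  kt <- ad_tp(tp, xg, wk, ctx$sh, lp$tp)
  vt <- ad_tp(tp, xg, wv, ctx$sh, lp$tp)
  k <- irreps_linear(tp, kt, lp$klin, pids, paste0(prefix, ".klin"),
                     bias = FALSE)
  v <- irreps_linear(tp, vt, lp$vlin, pids, paste0(prefix, ".vlin"),
                     bias = FALSE)
  qg <- ad_gather(tp, q, ctx$edge_dst)
  logit <- ad_scale(tp, ad_rowsum(tp, ad_mul(tp, qg, k)),
                    1 / sqrt(lp$hidden_dim))
  alpha <- ad_segment_softmax(tp, logit, ctx$edge_dst)
  msg <- ad_scale_rows(tp, v, alpha)
  agg <- ad_scatter_sum(tp, msg, ctx$edge_dst, ctx$n_nodes)
  ff <- ffn_forward(tp, agg, lp$ffn, pids, paste0(prefix, ".ffn"))
  resid <- if (is.null(lp$shortcut)) x else
    irreps_linear(tp, x, lp$shortcut, pids, paste0(prefix, ".shortcut"))
  h <- ad_add(tp, ff, resid)
  out <- eq_layer_norm(tp, h, lp$hidden, pids, paste0(prefix, ".ln"))
  list(out = out, alpha = alpha)
}
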
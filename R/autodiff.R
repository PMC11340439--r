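# Minimal reverse-mode automatic differentiation on a tape of matrix
# operations. Values are numeric matrices (or vectors/scalars); each
# tape node stores its value, parent ids and a vector-Jacobian-product
# closure. Gradients are only propagated to nodes flagged needs_grad
# (parameters and their descendants).

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- list()  # name -> id
  tp
}

tape_node <- function(tp, value, parents = integer(0), vjp = NULL,
                      needs_grad = NA) {
  if (is.na(needs_grad)) {
    needs_grad <- length(parents) > 0 &&
      any(vapply(parents, function(p)
        tp$nodes[[p]]$needs_grad, logical(1)))
  }
  id <- tp$n + 1L
  if (id > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[id]] <- list(value = value, parents = parents, vjp = vjp,
                         needs_grad = needs_grad)
  tp$n <- id
  id
}

ad_value <- function(tp, id) {
  # force id before touching tp$nodes: evaluating a nested op call in
  # the id promise may append to the tape
  force(id)
  tp$nodes[[id]]$value
}

ad_const <- function(tp, x) tape_node(tp, x, needs_grad = FALSE)

ad_param <- function(tp, x, name) {
  id <- tape_node(tp, x, needs_grad = TRUE)
  tp$params[[name]] <- id
  id
}

# Backward pass from a scalar loss node. Returns a named list of
# gradients for all registered parameters.
tape_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    node <- tp$nodes[[id]]
    g <- grads[[id]]
    if (is.null(g) || !node$needs_grad || is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (!tp$nodes[[p]]$needs_grad || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]]
                    else grads[[p]] + pg[[k]]
    }
    grads[[id]] <- NULL  # free memory early
  }
  out <- lapply(tp$params, function(pid) {
    g <- grads[[pid]]
    if (is.null(g)) {
      v <- tp$nodes[[pid]]$value
      g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else 0 * v
    }
    g
  })
  out
}

# ---- primitive operations --------------------------------------------

ad_mm <- function(tp, a, b) {
  A <- ad_value(tp, a); B <- ad_value(tp, b)
  tape_node(tp, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ad_add <- function(tp, a, b) {
  tape_node(tp, ad_value(tp, a) + ad_value(tp, b), c(a, b),
            function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  tape_node(tp, ad_value(tp, a) - ad_value(tp, b), c(a, b),
            function(g) list(g, -g))
}

# matrix + row vector (bias), broadcast over rows
ad_add_bias <- function(tp, a, b) {
  A <- ad_value(tp, a); bb <- as.vector(ad_value(tp, b))
  tape_node(tp, sweep(A, 2, bb, "+"), c(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1))
  })
}

ad_mul <- function(tp, a, b) {
  A <- ad_value(tp, a); B <- ad_value(tp, b)
  tape_node(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(tp, a, s) {
  tape_node(tp, ad_value(tp, a) * s, a, function(g) list(g * s))
}

ad_silu <- function(tp, a) {
  X <- ad_value(tp, a)
  sig <- 1 / (1 + exp(-X))
  tape_node(tp, X * sig, a, function(g) {
    list(g * sig * (1 + X * (1 - sig)))
  })
}

ad_sigmoid <- function(tp, a) {
  X <- ad_value(tp, a)
  sig <- 1 / (1 + exp(-X))
  tape_node(tp, sig, a, function(g) list(g * sig * (1 - sig)))
}

# rows of a indexed by idx (embedding lookup / per-edge gather)
ad_gather <- function(tp, a, idx) {
  A <- ad_value(tp, a)
  nr <- nrow(A)
  tape_node(tp, A[idx, , drop = FALSE], a, function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(A))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# sum rows of a into n groups given by idx (message aggregation)
ad_scatter_sum <- function(tp, a, idx, n) {
  A <- ad_value(tp, a)
  acc <- rowsum(A, group = idx)
  val <- matrix(0, n, ncol(A))
  val[as.integer(rownames(acc)), ] <- acc
  tape_node(tp, val, a, function(g) list(g[idx, , drop = FALSE]))
}

ad_cbind <- function(tp, ...) {
  ids <- c(...)
  vals <- lapply(ids, function(i) ad_value(tp, i))
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tape_node(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k)
      g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_cols <- function(tp, a, cols) {
  A <- ad_value(tp, a)
  nc <- ncol(A)
  tape_node(tp, A[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

ad_rowsum <- function(tp, a) {
  A <- ad_value(tp, a)
  tape_node(tp, matrix(rowSums(A), ncol = 1), a, function(g) {
    list(matrix(g, nrow(A), ncol(A)))
  })
}

# rows of a scaled by column vector s (n x 1 node)
ad_scale_rows <- function(tp, a, s) {
  A <- ad_value(tp, a); S <- as.vector(ad_value(tp, s))
  tape_node(tp, A * S, c(a, s), function(g) {
    list(g * S, matrix(rowSums(g * A), ncol = 1))
  })
}

# numerically stable softmax within segments (attention over incoming
# edges of each node); seg is an integer grouping vector over rows
ad_segment_softmax <- function(tp, a, seg) {
  X <- as.vector(ad_value(tp, a))
  mx <- tapply(X, seg, max)[as.character(seg)]
  ex <- exp(X - mx)
  tot <- tapply(ex, seg, sum)[as.character(seg)]
  alpha <- ex / tot
  tape_node(tp, matrix(alpha, ncol = 1), a, function(g) {
    g <- as.vector(g)
    dot <- tapply(alpha * g, seg, sum)[as.character(seg)]
    list(matrix(alpha * (g - dot), ncol = 1))
  })
}

# mean absolute error over masked entries; pred and target are n x 1
ad_mae_masked <- function(tp, pred, target, mask) {
  P <- as.vector(ad_value(tp, pred))
  Tg <- as.vector(ad_value(tp, target))
  m <- as.logical(mask)
  n_eff <- sum(m)
  if (n_eff == 0) stop("no supervised entries under the mask")
  r <- (P - Tg) * m
  tape_node(tp, sum(abs(r)) / n_eff, c(pred, target), function(g) {
    d <- matrix(g * sign(r) / n_eff, ncol = 1)
    list(d, -d)
  })
}

# weighted sum of two scalar nodes
ad_axpy <- function(tp, a, b, wa = 1, wb = 1) {
  tape_node(tp, wa * ad_value(tp, a) + wb * ad_value(tp, b), c(a, b),
            function(g) list(g * wa, g * wb))
}
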
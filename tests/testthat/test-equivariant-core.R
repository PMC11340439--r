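# The equivariant attention network: embeddings, attention weights,
# layer norm, readout, and the E(3) behaviour of the whole stack.

test_that("node embeddings concatenate the two tables at the configured width", {
  cfg <- eqshift_config()  # reference architecture
  par <- eqshift_init(cfg, seed = 2)
  expect_equal(ncol(par[["emb.elem"]]) + ncol(par[["emb.h"]]), 128L)
  mol <- fixture_mol()
  g <- build_graph(mol, fixture_ensemble()$conformers[[1]])
  tp <- eqshift:::tape_new()
  e <- eqshift:::ad_const(tp, par[["emb.elem"]])
  h <- eqshift:::ad_const(tp, par[["emb.h"]])
  x0 <- eqshift:::ad_cbind(tp,
                           eqshift:::ad_gather(tp, e, g$node_element_idx),
                           eqshift:::ad_gather(tp, h, g$node_hcount_idx))
  X <- eqshift:::ad_value(tp, x0)
  expect_equal(ncol(X), 128L)
  # same (element, hcount) -> identical embedding rows
  same <- which(g$node_element_idx == g$node_element_idx[1] &
                  g$node_hcount_idx == g$node_hcount_idx[1])
  if (length(same) > 1) {
    expect_equal(X[same[1], ], X[same[2], ])
  }
  # same element, different hcount -> rows differ for generic tables
  diffh <- which(g$node_element_idx == g$node_element_idx[1] &
                   g$node_hcount_idx != g$node_hcount_idx[1])
  if (length(diffh) > 0) {
    expect_false(isTRUE(all.equal(X[same[1], ], X[diffh[1], ])))
  }
  # out-of-vocabulary index is an error, not a silent NA row
  expect_error(eqshift:::ad_gather(tp, e, 999L), "subscript")
})

test_that("edge embeddings have the configured width and are direction symmetric", {
  cfg <- eqshift_config()
  par <- eqshift_init(cfg, seed = 2)
  expect_equal(ncol(par[["emb.bond"]]) + 1L, 32L)
  # same bond type at distances 1.5 vs 2.5 differs only in the
  # distance slot
  e15 <- c(par[["emb.bond"]][2, ], 1.5)
  e25 <- c(par[["emb.bond"]][2, ], 2.5)
  expect_equal(which(e15 != e25), 32L)
})

test_that("attention weights form a distribution and obey symmetry", {
  set.seed(61)
  mol <- fixture_mol("OCC(O)CO", id = "attnmol")
  g <- build_graph(mol, fixture_ensemble("OCC(O)CO", 4, 2,
                                         3)$conformers[[1]])
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 9)
  plans <- eqshift:::model_plans(cfg)
  fw <- eqshift:::forward_network(par, cfg, plans, g,
                                  keep_layers = TRUE)
  for (aid in fw$alphas) {
    alpha <- as.vector(eqshift:::ad_value(fw$tape, aid))
    expect_true(all(alpha >= 0))
    sums <- as.vector(tapply(alpha, g$edge_dst, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-6)
  }
  # single neighbour -> weight exactly 1
  pairmol <- fake_molecule("pair2", n_atoms = 2L)
  gp <- build_graph(pairmol, matrix(c(0, 0, 0, 1.4, 0, 0), 2, 3,
                                    byrow = TRUE))
  fwp <- eqshift:::forward_network(par, cfg, plans, gp,
                                   keep_layers = TRUE)
  expect_equal(as.vector(eqshift:::ad_value(fwp$tape, fwp$alphas[1])),
               c(1, 1))
  # two equivalent neighbours -> 0.5 / 0.5 (identical element, hcount,
  # bond type and distance on both sides)
  trimol <- fake_molecule("chain3", n_atoms = 3L)
  gt <- build_graph(trimol, matrix(c(-1.4, 0, 0, 0, 0, 0, 1.4, 0, 0),
                                   3, 3, byrow = TRUE))
  fwt <- eqshift:::forward_network(par, cfg, plans, gt,
                                   keep_layers = TRUE)
  at <- as.vector(eqshift:::ad_value(fwt$tape, fwt$alphas[1]))
  centre_in <- which(gt$edge_dst == 2L)
  expect_equal(at[centre_in], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("attention logits softmax matches an independent dense oracle", {
  set.seed(63)
  mol <- fake_molecule("tri", n_atoms = 3L)
  g <- build_graph(mol, matrix(rnorm(9), 3, 3))
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 13)
  plans <- eqshift:::model_plans(cfg)
  fw <- eqshift:::forward_network(par, cfg, plans, g,
                                  keep_layers = TRUE)
  # recompute the layer-1 logits independently: q . k / sqrt(dim)
  tp <- fw$tape
  alpha <- as.vector(eqshift:::ad_value(tp, fw$alphas[1]))
  # dense oracle from the stored logit node (parent of the softmax):
  logit_node <- tp$nodes[[fw$alphas[1]]]$parents[1]
  logits <- as.vector(eqshift:::ad_value(tp, logit_node))
  oracle <- unlist(lapply(split(seq_along(logits), g$edge_dst),
                          function(ix) {
    z <- logits[ix]
    exp(z - max(z)) / sum(exp(z - max(z)))
  }), use.names = FALSE)
  ord <- order(g$edge_dst)
  expect_equal(alpha[ord], oracle, tolerance = 1e-6)
})

test_that("equivariant layer norm: hand arithmetic and zero guard", {
  tp <- eqshift:::tape_new()
  x <- eqshift:::ad_const(tp, matrix(c(2, 4), 1, 2))
  gain <- eqshift:::ad_const(tp, matrix(1, 1, 2))
  bias <- eqshift:::ad_const(tp, matrix(0, 1, 2))
  y <- eqshift:::ad_lnorm_scalar(tp, x, gain, bias, eps = 0)
  expect_equal(as.vector(eqshift:::ad_value(tp, y)), c(-1, 1))
  # all-zero l>0 block stays zero
  z <- eqshift:::ad_const(tp, matrix(0, 2, 6))
  vg <- eqshift:::ad_const(tp, matrix(1, 1, 2))
  yz <- eqshift:::ad_rmsnorm_block(tp, z, vg, m = 2L, d = 3L)
  expect_true(all(eqshift:::ad_value(tp, yz) == 0))
  # direction of an l>0 copy is preserved up to a positive scale
  set.seed(67)
  v <- matrix(rnorm(6), 1, 6)
  xv <- eqshift:::ad_const(tp, v)
  yv <- eqshift:::ad_value(tp, eqshift:::ad_rmsnorm_block(
    tp, xv, vg, m = 2L, d = 3L))
  for (u in 1:2) {
    a <- v[1, (u - 1) * 3 + 1:3]; b <- yv[1, (u - 1) * 3 + 1:3]
    cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
})

test_that("readout MLP reproduces a hand-computed SiLU composition", {
  silu <- function(x) x / (1 + exp(-x))
  tp <- eqshift:::tape_new()
  x <- eqshift:::ad_const(tp, matrix(1.0, 1, 1))
  pids <- list("h.W1" = eqshift:::ad_const(tp, matrix(0.7, 1, 1)),
               "h.b1" = eqshift:::ad_const(tp, matrix(0.1, 1, 1)),
               "h.W2" = eqshift:::ad_const(tp, matrix(-1.3, 1, 1)),
               "h.b2" = eqshift:::ad_const(tp, matrix(0.25, 1, 1)))
  y <- eqshift:::mlp2_forward(tp, x, pids, "h")
  expect_equal(as.vector(eqshift:::ad_value(tp, y)),
               -1.3 * silu(0.7 * 1.0 + 0.1) + 0.25, tolerance = 1e-7)
  # zero weights -> zero output before denormalisation
  pz <- lapply(pids, function(i) i)
  tp2 <- eqshift:::tape_new()
  pz <- list("h.W1" = eqshift:::ad_const(tp2, matrix(0, 1, 1)),
             "h.b1" = eqshift:::ad_const(tp2, matrix(0, 1, 1)),
             "h.W2" = eqshift:::ad_const(tp2, matrix(0, 1, 1)),
             "h.b2" = eqshift:::ad_const(tp2, matrix(0, 1, 1)))
  y0 <- eqshift:::mlp2_forward(tp2, eqshift:::ad_const(
    tp2, matrix(2.5, 1, 1)), pz, "h")
  expect_equal(as.vector(eqshift:::ad_value(tp2, y0)), 0)
})

test_that("predictions are E(3) invariant and hidden features equivariant", {
  set.seed(71)
  mol <- fixture_mol()
  coords <- fixture_ensemble()$conformers[[1]]$coords
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 21)
  plans <- eqshift:::model_plans(cfg)
  g <- build_graph(mol, coords)
  fw <- eqshift:::forward_network(par, cfg, plans, g,
                                  keep_layers = TRUE)
  base <- cbind(eqshift:::ad_value(fw$tape, fw$c13),
                eqshift:::ad_value(fw$tape, fw$h1))
  hidden <- plans$hidden
  for (rep in 1:3) {
    R <- random_rotation()
    tvec <- rnorm(3, sd = 5)
    gr <- build_graph(mol, sweep(coords %*% t(R), 2, tvec, "+"))
    fr <- eqshift:::forward_network(par, cfg, plans, gr,
                                    keep_layers = TRUE)
    out <- cbind(eqshift:::ad_value(fr$tape, fr$c13),
                 eqshift:::ad_value(fr$tape, fr$h1))
    expect_lt(max(abs(out - base)), 1e-4)
    # per-layer equivariance: rotated features equal Wigner-rotated
    # features of the unrotated pass
    D <- eqshift:::wigner_d_layout(hidden, R)
    for (k in seq_along(fw$layers)) {
      Xk <- eqshift:::ad_value(fw$tape, fw$layers[k])
      Xr <- eqshift:::ad_value(fr$tape, fr$layers[k])
      err <- max(abs(Xr - Xk %*% t(D))) / max(abs(Xk))
      expect_lt(err, 1e-4)
    }
  }
  # mirror image: invariant output
  gm <- build_graph(mol, coords %*% diag(c(-1, 1, 1)))
  fm <- eqshift:::forward_network(par, cfg, plans, gm)
  outm <- cbind(eqshift:::ad_value(fm$tape, fm$c13),
                eqshift:::ad_value(fm$tape, fm$h1))
  expect_lt(max(abs(outm - base)), 1e-4)
})

test_that("relabelling atoms permutes the per-node outputs identically", {
  set.seed(73)
  mol <- fixture_mol("OCC(O)CO", id = "permmol")
  coords <- fixture_ensemble("OCC(O)CO", 4, 2, 3)$conformers[[1]]$coords
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 23)
  plans <- eqshift:::model_plans(cfg)
  pr <- eqshift:::predict_normalised(par, cfg, plans,
                                     build_graph(mol, coords))
  perm <- sample(nrow(mol$atoms))
  inv <- order(perm)
  pm <- mol
  pm$atoms <- mol$atoms[perm, ]
  pm$atoms$index <- seq_len(nrow(mol$atoms)) - 1L
  remap <- function(old) inv[old + 1L] - 1L
  pm$bonds$i <- remap(mol$bonds$i)
  pm$bonds$j <- remap(mol$bonds$j)
  pr2 <- eqshift:::predict_normalised(par, cfg, plans,
                                      build_graph(pm, coords[perm, ]))
  expect_equal(pr2, pr[perm, ], tolerance = 1e-10)
})

test_that("scalar-only hidden layout depends on geometry only through distances", {
  # two different embeddings in space with identical distance matrices:
  # a chiral point set and its mirror image
  set.seed(79)
  mol <- fake_molecule("inv4", n_atoms = 4L)
  coords <- matrix(rnorm(12, sd = 1.2), 4, 3)
  mirror <- coords %*% diag(c(-1, 1, 1))
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(mirror)),
               tolerance = 1e-12)
  cfg0 <- eqshift_config(n_layers = 2L, node_emb_dim = 16L,
                         edge_emb_dim = 8L, hidden = "14x0e",
                         readout_scalars = 16L, readout_hidden = 24L,
                         nn_hidden = 12L)
  par0 <- eqshift_init(cfg0, seed = 31)
  plans0 <- eqshift:::model_plans(cfg0)
  p1 <- eqshift:::predict_normalised(par0, cfg0, plans0,
                                     build_graph(mol, coords))
  p2 <- eqshift:::predict_normalised(par0, cfg0, plans0,
                                     build_graph(mol, mirror))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("isolated nodes aggregate the zero tensor instead of NaN", {
  mol <- fake_molecule("iso", n_atoms = 2L)
  mol$bonds <- mol$bonds[0, ]
  g <- build_graph(mol, matrix(c(0, 0, 0, 50, 0, 0), 2, 3,
                               byrow = TRUE))
  expect_equal(length(g$edge_src), 0L)
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 33)
  pr <- eqshift:::predict_normalised(par, cfg,
                                     eqshift:::model_plans(cfg), g)
  expect_true(all(is.finite(pr)))
})
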
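# Reverse-mode tape: every primitive's vector-Jacobian product is
# checked against central finite differences through a scalar readout.

fd_check <- function(build, params, eps = 1e-6, tol = 1e-5) {
  # build(tp, param_ids) must return a scalar loss node
  tp <- tape_new()
  pids <- lapply(names(params), function(nm)
    eqshift:::ad_param(tp, params[[nm]], nm))
  names(pids) <- names(params)
  loss <- build(tp, pids)
  grads <- eqshift:::tape_backward(tp, loss)
  loss_at <- function(pp) {
    tp2 <- tape_new()
    pid2 <- lapply(names(pp), function(nm)
      eqshift:::ad_param(tp2, pp[[nm]], nm))
    names(pid2) <- names(pp)
    eqshift:::ad_value(tp2, build(tp2, pid2))
  }
  for (nm in names(params)) {
    for (ix in seq_len(min(4L, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][ix] <- p2[[nm]][ix] + eps
      p3 <- params; p3[[nm]][ix] <- p3[[nm]][ix] - eps
      num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      expect_equal(grads[[nm]][ix], num, tolerance = tol,
                   label = sprintf("grad %s[%d]", nm, ix))
    }
  }
}

ad_sum_all <- function(tp, r) {
  V <- eqshift:::ad_value(tp, r)
  eqshift:::tape_node(tp, sum(V), r, function(g)
    list(matrix(g, nrow(V), ncol(V))))
}

test_that("matrix, bias, gather/scatter and activation gradients are exact", {
  set.seed(31)
  params <- list(W = matrix(rnorm(12), 4, 3), b = matrix(rnorm(3), 1, 3),
                 X = matrix(rnorm(20), 5, 4))
  idx <- c(2L, 1L, 2L, 5L, 3L, 4L)
  fd_check(function(tp, p) {
    h <- eqshift:::ad_add_bias(tp, eqshift:::ad_mm(tp, p$X, p$W), p$b)
    h <- eqshift:::ad_silu(tp, h)
    g <- eqshift:::ad_gather(tp, h, idx)
    s <- eqshift:::ad_scatter_sum(tp, g, c(1L, 1L, 2L, 3L, 3L, 3L), 4L)
    sq <- eqshift:::ad_mul(tp, s, s)
    ad_sum_all(tp, eqshift:::ad_rowsum(tp, eqshift:::ad_sigmoid(tp, sq)))
  }, params)
})

test_that("segment softmax matches a dense softmax oracle and its gradient", {
  set.seed(37)
  seg <- c(1L, 1L, 1L, 2L, 2L, 3L)
  x <- matrix(rnorm(6), ncol = 1)
  tp <- tape_new()
  xid <- eqshift:::ad_param(tp, x, "x")
  a <- eqshift:::ad_segment_softmax(tp, xid, seg)
  av <- as.vector(eqshift:::ad_value(tp, a))
  dense <- unlist(lapply(split(as.vector(x), seg), function(v)
    exp(v - max(v)) / sum(exp(v - max(v)))), use.names = FALSE)
  expect_equal(av, dense, tolerance = 1e-12)
  expect_equal(as.vector(tapply(av, seg, sum)), c(1, 1, 1),
               tolerance = 1e-12)
  # gradient through a weighted sum
  w <- rnorm(6)
  params <- list(x = x)
  fd_check(function(tp, p) {
    a <- eqshift:::ad_segment_softmax(tp, p$x, seg)
    eqshift:::tape_node(tp, sum(eqshift:::ad_value(tp, a) * w), a,
                        function(g) list(matrix(g * w, ncol = 1)))
  }, params)
})

test_that("block-linear, tensor-product, layer-norm and gate gradients are exact", {
  set.seed(41)
  ir <- irreps("3x0e+2x1o+1x2e")
  tpl <- eqshift:::tp_plan(ir, l_max_sh = 2L, l_max_out = 2L)
  E <- 4L
  sh <- sh_real(matrix(rnorm(E * 3), E, 3) |>
                  (\(m) m / sqrt(rowSums(m^2)))(), 2)
  params <- list(
    X = matrix(rnorm(E * eqshift:::irreps_dim(ir)), E),
    W = matrix(rnorm(E * tpl$n_weights), E),
    L = matrix(rnorm(2 * 3), 2, 3),          # block linear 3 -> 2 scalars
    gain = matrix(runif(2, 0.5, 1.5), 1, 2),
    bias = matrix(rnorm(2) / 4, 1, 2),
    vgain = matrix(runif(2, 0.5, 1.5), 1, 2),
    gate = matrix(rnorm(E * 2), E, 2))
  to_scalar <- function(tp, r) {
    eqshift:::tape_node(tp, sum(eqshift:::ad_value(tp, r)^2), r,
                        function(g) list(2 * g * eqshift:::ad_value(tp, r)))
  }
  fd_check(function(tp, p) {
    shc <- eqshift:::ad_const(tp, sh)
    y <- eqshift:::ad_tp(tp, p$X, p$W, shc, tpl)
    to_scalar(tp, y)
  }, params["X"] |> c(params["W"]), tol = 1e-4)
  fd_check(function(tp, p) {
    y <- eqshift:::ad_block_linear(tp, p$X, p$L, cols = 1:3, m_in = 3L,
                                   m_out = 2L, d = 1L)
    y <- eqshift:::ad_lnorm_scalar(tp, y, p$gain, p$bias)
    to_scalar(tp, y)
  }, params[c("X", "L", "gain", "bias")], tol = 1e-4)
  fd_check(function(tp, p) {
    vb <- eqshift:::ad_cols(tp, p$X, 4:9)  # the 2x1o block
    y <- eqshift:::ad_rmsnorm_block(tp, vb, p$vgain, m = 2L, d = 3L)
    y <- eqshift:::ad_gate_block(tp, y, eqshift:::ad_sigmoid(tp, p$gate),
                                 m = 2L, d = 3L)
    to_scalar(tp, y)
  }, params[c("X", "vgain", "gate")], tol = 1e-4)
})

test_that("full network gradient agrees with finite differences", {
  set.seed(43)
  mol <- fixture_mol("OCC(O)CO", id = "fdmol")
  coords <- fixture_ensemble("OCC(O)CO", n_generate = 4, n_keep = 2,
                             seed = 3)$conformers[[1]]$coords
  tg <- data.frame(atom_index = c(1L, 0L), nucleus = c("C13", "H1"),
                   shift_ppm = c(72, 3.6))
  g <- build_graph(mol, coords, targets = tg)
  cfg <- tiny_config()
  par <- eqshift_init(cfg, seed = 5)
  plans <- eqshift:::model_plans(cfg)
  ns <- list(c13 = c(mean = 70, sd = 5), h1 = c(mean = 3, sd = 1))
  fw <- eqshift:::forward_network(par, cfg, plans, g, trainable = TRUE)
  loss <- eqshift:::batch_loss(fw, g, ns)
  grads <- eqshift:::tape_backward(fw$tape, loss)
  loss_at <- function(p) {
    fw2 <- eqshift:::forward_network(p, cfg, plans, g)
    eqshift:::ad_value(fw2$tape,
                       eqshift:::batch_loss(fw2, g, ns))
  }
  eps <- 1e-5
  set.seed(44)
  for (nm in sample(names(par), 12L)) {
    ix <- sample(length(par[[nm]]), 1L)
    p2 <- par; p2[[nm]][ix] <- p2[[nm]][ix] + eps
    p3 <- par; p3[[nm]][ix] <- p3[[nm]][ix] - eps
    num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
    expect_equal(grads[[nm]][ix], num, tolerance = 2e-4,
                 label = sprintf("network grad %s[%d]", nm, ix))
  }
})
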
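# Model configuration, parameter initialisation, the end-to-end forward
# pass, and the fitted-model S3 class.

#' Configure the equivariant shift-prediction network
#'
#' Default architecture: seven attention layers,
#' 128-dimensional invariant node embedding (element and attached-H
#' tables concatenated), 32-dimensional invariant edge embedding (bond
#' category embedding with the raw distance appended), hidden geometric
#' tensors of 64 scalars + 32 vectors (l=1, odd) + 8 l=2 (even)
#' tensors, spherical harmonics up to l=2 on edge directions, and a
#' readout that maps the final invariant block to 128 scalars followed
#' by a two-layer MLP (hidden width 384) per nucleus.
#'
#' @param n_layers number of attention layers K.
#' @param node_emb_dim invariant node embedding width (even).
#' @param edge_emb_dim invariant edge embedding width.
#' @param hidden hidden irreps layout string, e.g. `"64x0e+32x1o+8x2e"`.
#'   Setting this to scalars only (e.g. `"104x0e"`) gives the invariant
#'   ablation in which geometry enters through distances alone.
#' @param l_max_sh maximum spherical-harmonic order on edges.
#' @param readout_scalars width of the invariant readout vector.
#' @param readout_hidden hidden width of the per-nucleus readout MLP.
#' @param nn_hidden hidden width of the edge-weight networks NN_k, NN_v.
#' @param r_cut edge cutoff radius in Angstrom.
#' @param element_vocab elements with their own embedding row; anything
#'   else shares an "other" row.
#' @param hcount_cap attached-hydrogen counts are capped at this value
#'   for the embedding lookup.
#' @param radial_n 0 feeds the raw distance as the edge scalar
#'   (default); a positive value switches to that many Gaussian radial
#'   basis functions spread over (0, r_cut].
#' @return an `eqshift_config` list.
#' @export
eqshift_config <- function(n_layers = 7L, node_emb_dim = 128L,
                           edge_emb_dim = 32L,
                           hidden = "64x0e+32x1o+8x2e",
                           l_max_sh = 2L, readout_scalars = 128L,
                           readout_hidden = 384L, nn_hidden = 64L,
                           r_cut = 6.0,
                           element_vocab = ELEMENT_VOCAB_DEFAULT,
                           hcount_cap = HCOUNT_CAP_DEFAULT,
                           radial_n = 0L) {
  stopifnot(n_layers >= 1, node_emb_dim %% 2 == 0, edge_emb_dim >= 2,
            l_max_sh %in% 0:2, radial_n >= 0)
  hid <- irreps(hidden)
  if (!any(hid$l == 0L & hid$parity == 1L)) {
    stop("hidden layout must contain a scalar (0e) block for readout")
  }
  n_dist <- max(1L, radial_n)
  if (edge_emb_dim <= n_dist) stop("edge_emb_dim too small")
  structure(list(
    n_layers = as.integer(n_layers),
    node_emb_dim = as.integer(node_emb_dim),
    edge_emb_dim = as.integer(edge_emb_dim),
    hidden = hidden, l_max_sh = as.integer(l_max_sh),
    readout_scalars = as.integer(readout_scalars),
    readout_hidden = as.integer(readout_hidden),
    nn_hidden = as.integer(nn_hidden),
    r_cut = r_cut, element_vocab = element_vocab,
    hcount_cap = as.integer(hcount_cap),
    radial_n = as.integer(radial_n)
  ), class = "eqshift_config")
}

#' @export
print.eqshift_config <- function(x, ...) {
  cat(sprintf(
    "<eqshift config: %d layers, hidden %s, node emb %d, edge emb %d, r_cut %.1f A>\n",
    x$n_layers, x$hidden, x$node_emb_dim, x$edge_emb_dim, x$r_cut))
  invisible(x)
}

# Precompute the coupling paths and linear-map plans for a config.
model_plans <- function(config) {
  hidden <- irreps(config$hidden)
  ir_in <- irreps(sprintf("%dx0e", config$node_emb_dim))
  l_out <- max(hidden$l)
  mk_layer <- function(ir_x, shortcut) {
    tpp <- tp_plan(ir_x, config$l_max_sh, l_out)
    list(q = linear_plan(ir_x, hidden),
         tp = tpp,
         klin = linear_plan(tpp$ir_out, hidden),
         vlin = linear_plan(tpp$ir_out, hidden),
         ffn = ffn_plans(hidden),
         shortcut = if (shortcut) linear_plan(ir_x, hidden) else NULL,
         hidden = hidden,
         hidden_dim = irreps_dim(hidden))
  }
  layers <- vector("list", config$n_layers)
  layers[[1]] <- mk_layer(ir_in, shortcut = TRUE)
  if (config$n_layers >= 2) {
    rest <- mk_layer(hidden, shortcut = FALSE)
    for (k in 2:config$n_layers) layers[[k]] <- rest
  }
  trunk <- linear_plan(hidden,
                       irreps(sprintf("%dx0e", config$readout_scalars)))
  list(hidden = hidden, ir_in = ir_in, layers = layers, trunk = trunk)
}

model_param_shapes <- function(config, plans) {
  nd <- config$node_emb_dim %/% 2L
  n_dist <- max(1L, config$radial_n)
  shapes <- list(
    "emb.elem" = c(length(config$element_vocab) + 1L, nd),
    "emb.h" = c(config$hcount_cap + 1L, nd),
    "emb.bond" = c(4L, config$edge_emb_dim - n_dist)
  )
  for (k in seq_len(config$n_layers)) {
    lp <- plans$layers[[k]]
    pre <- sprintf("L%d", k)
    shapes <- c(
      shapes,
      linear_param_shapes(lp$q, paste0(pre, ".q")),
      mlp2_shapes(config$edge_emb_dim, config$nn_hidden,
                  lp$tp$n_weights, paste0(pre, ".nnk")),
      mlp2_shapes(config$edge_emb_dim, config$nn_hidden,
                  lp$tp$n_weights, paste0(pre, ".nnv")),
      linear_param_shapes(lp$klin, paste0(pre, ".klin"), bias = FALSE),
      linear_param_shapes(lp$vlin, paste0(pre, ".vlin"), bias = FALSE),
      linear_param_shapes(lp$ffn$lin1, paste0(pre, ".ffn.lin1")),
      linear_param_shapes(lp$ffn$lin2, paste0(pre, ".ffn.lin2")),
      lnorm_param_shapes(lp$hidden, paste0(pre, ".ln"))
    )
    if (!is.null(lp$shortcut)) {
      shapes <- c(shapes,
                  linear_param_shapes(lp$shortcut,
                                      paste0(pre, ".shortcut")))
    }
  }
  shapes <- c(
    shapes,
    linear_param_shapes(plans$trunk, "readout.trunk"),
    mlp2_shapes(config$readout_scalars, config$readout_hidden, 1L,
                "readout.c13"),
    mlp2_shapes(config$readout_scalars, config$readout_hidden, 1L,
                "readout.h1")
  )
  shapes
}

#' Initialise model parameters
#'
#' @param config an `eqshift_config`.
#' @param seed RNG seed; the same seed reproduces the same parameters.
#' @return named list of parameter matrices.
#' @export
eqshift_init <- function(config, seed = 1L) {
  plans <- model_plans(config)
  shapes <- model_param_shapes(config, plans)
  set.seed(seed)
  params <- list()
  for (nm in names(shapes)) {
    dm <- shapes[[nm]]
    params[[nm]] <- if (grepl("\\.(b|bias|b1|b2)$", nm)) {
      matrix(0, dm[1], dm[2])
    } else if (grepl("\\.gain$", nm)) {
      matrix(1, dm[1], dm[2])
    } else if (grepl("\\.(W1|W2)$", nm)) {
      matrix(stats::rnorm(prod(dm), sd = 1 / sqrt(dm[1])), dm[1], dm[2])
    } else {
      matrix(stats::rnorm(prod(dm)), dm[1], dm[2])
    }
  }
  params
}

# Gaussian radial basis over (0, r_cut]
radial_features <- function(d, config) {
  if (config$radial_n == 0L) return(matrix(d, ncol = 1))
  centers <- seq(0, config$r_cut, length.out = config$radial_n)
  width <- (centers[2] - centers[1])
  exp(-outer(d, centers, "-")^2 / (2 * width^2))
}

# Full forward pass on a (batched) graph sample. Returns the tape and
# the node ids of interest so callers can attach a loss (training), run
# backward, or just read predictions and per-layer features.
forward_network <- function(params, config, plans, batch,
                            trainable = FALSE, keep_layers = FALSE) {
  tp <- tape_new()
  pids <- list()
  for (nm in names(params)) {
    pids[[nm]] <- if (trainable) ad_param(tp, params[[nm]], nm)
                  else ad_const(tp, params[[nm]])
  }
  x <- ad_cbind(
    tp,
    ad_gather(tp, pids[["emb.elem"]], batch$node_element_idx),
    ad_gather(tp, pids[["emb.h"]], batch$node_hcount_idx))
  es <- ad_cbind(
    tp,
    ad_gather(tp, pids[["emb.bond"]], batch$edge_bond_idx),
    ad_const(tp, radial_features(batch$edge_distance, config)))
  ctx <- list(
    edge_src = batch$edge_src, edge_dst = batch$edge_dst,
    n_nodes = batch$n_nodes, es = es,
    sh = ad_const(tp, sh_real(batch$edge_unit_vec, config$l_max_sh)))
  layer_ids <- integer(0)
  alphas <- integer(0)
  for (k in seq_len(config$n_layers)) {
    res <- attn_layer_forward(tp, x, plans$layers[[k]], pids,
                              sprintf("L%d", k), ctx)
    x <- res$out
    if (keep_layers) {
      layer_ids <- c(layer_ids, x)
      alphas <- c(alphas, res$alpha)
    }
  }
  trunk <- irreps_linear(tp, x, plans$trunk, pids, "readout.trunk")
  c13 <- mlp2_forward(tp, trunk, pids, "readout.c13")
  h1 <- mlp2_forward(tp, trunk, pids, "readout.h1")
  list(tape = tp, pids = pids, c13 = c13, h1 = h1,
       layers = layer_ids, alphas = alphas, final = x)
}

# Raw (normalised-unit) predictions for a batch: n x 2 matrix.
predict_normalised <- function(params, config, plans, batch) {
  fw <- forward_network(params, config, plans, batch)
  cbind(c13 = as.vector(ad_value(fw$tape, fw$c13)),
        h1 = as.vector(ad_value(fw$tape, fw$h1)))
}

# ---- fitted model object ---------------------------------------------

new_eqshift_model <- function(config, params, norm_stats, history = NULL,
                              seed = NA_integer_, provenance = list()) {
  structure(list(config = config, params = params,
                 norm_stats = norm_stats, history = history,
                 seed = seed, provenance = provenance),
            class = "eqshift_model")
}

#' @export
print.eqshift_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<eqshift model: %d layers, hidden %s, %s parameters>\n",
              x$config$n_layers, x$config$hidden,
              format(np, big.mark = ",")))
  if (!is.null(x$norm_stats)) {
    cat(sprintf("  target scaling: C13 %.2f +/- %.2f ppm, H1 %.3f +/- %.3f ppm\n",
                x$norm_stats$c13["mean"], x$norm_stats$c13["sd"],
                x$norm_stats$h1["mean"], x$norm_stats$h1["sd"]))
  }
  invisible(x)
}

#' @export
summary.eqshift_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epochs; final train MAE %.4f (normalised)\n",
                nrow(h), h$train_mae[nrow(h)]))
    if ("lr" %in% names(h)) {
      cat(sprintf("  learning rate %g -> %g\n", h$lr[1], h$lr[nrow(h)]))
    }
  }
  invisible(object)
}

#' @export
coef.eqshift_model <- function(object, ...) {
  unlist(object$params, use.names = TRUE)
}

#' Save a fitted model to a single JSON artifact
#'
#' Stores the configuration, all parameter matrices, the per-nucleus
#' target normalisation statistics and provenance (seed, package
#' version) in one plain-text file.
#'
#' @param model an `eqshift_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_eqshift_model <- function(model, path) {
  obj <- list(
    format = "eqshift_model_v1",
    config = unclass(model$config),
    norm_stats = lapply(model$norm_stats, as.list),
    seed = model$seed,
    provenance = model$provenance,
    param_names = names(model$params),
    param_dims = lapply(model$params, dim),
    param_values = lapply(model$params, as.vector)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_eqshift_model()]
#'
#' @param path artifact path.
#' @return an `eqshift_model`. Errors if the artifact's stored layout
#'   does not reproduce consistent parameter shapes.
#' @export
load_eqshift_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "eqshift_model_v1")) {
    stop("not an eqshift model artifact: ", path)
  }
  cfg <- do.call(eqshift_config, obj$config[names(obj$config) %in%
    names(formals(eqshift_config))])
  params <- list()
  for (k in seq_along(obj$param_names)) {
    nm <- obj$param_names[k]
    dm <- obj$param_dims[[nm]]
    params[[nm]] <- matrix(as.numeric(obj$param_values[[nm]]),
                           dm[1], dm[2])
  }
  expected <- model_param_shapes(cfg, model_plans(cfg))
  if (!identical(sort(names(expected)), sort(names(params)))) {
    stop("model artifact parameters do not match its configuration")
  }
  for (nm in names(expected)) {
    if (!all(dim(params[[nm]]) == expected[[nm]])) {
      stop("parameter ", nm, " has the wrong shape in ", path)
    }
  }
  ns <- obj$norm_stats
  norm_stats <- list(c13 = unlist(ns$c13), h1 = unlist(ns$h1))
  new_eqshift_model(cfg, params, norm_stats,
                    history = obj$history, seed = obj$seed,
                    provenance = obj$provenance)
}
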
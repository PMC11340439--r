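# Ensemble prediction with uncertainty, and MAE/RMSE evaluation
# stratified by nucleus and saccharide class. All standard deviations
# are population (1/N) estimates.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Predict chemical shifts over a conformer ensemble
#'
#' Runs one forward pass per conformer (batched), groups the per-node
#' predictions over conformers, and reports the ensemble mean as the
#' prediction with the population standard deviation as an uncertainty
#' estimate. C13 predictions are emitted for every carbon and H1
#' predictions for every heavy atom with at least one attached
#' hydrogen.
#'
#' @param model an `eqshift_model`.
#' @param mol an `eqshift_molecule`.
#' @param ensemble a non-empty `eqshift_ensemble` for the molecule.
#' @return data frame with columns `molecule_id`, `atom_index`,
#'   `nucleus`, `pred_mean_ppm`, `pred_std_ppm`, `n_conformers`, plus a
#'   list column `per_conformer_ppm`.
#' @export
predict_ensemble <- function(model, mol, ensemble) {
  if (length(ensemble$conformers) == 0) {
    stop("empty conformer ensemble for ", mol$molecule_id)
  }
  cfg <- model$config
  plans <- model_plans(cfg)
  samples <- lapply(ensemble$conformers, function(cf)
    build_graph(mol, cf, r_cut = cfg$r_cut,
                element_vocab = cfg$element_vocab,
                hcount_cap = cfg$hcount_cap))
  batch <- assemble_batch(samples)
  pr <- predict_normalised(model$params, cfg, plans, batch)
  ns <- model$norm_stats
  n <- n_heavy(mol)
  nconf <- length(samples)
  # rows of pr are conformer-major: conformer c occupies rows
  # (c-1)*n + 1 .. c*n
  c13 <- matrix(pr[, "c13"], nrow = n) * ns$c13["sd"] + ns$c13["mean"]
  h1 <- matrix(pr[, "h1"], nrow = n) * ns$h1["sd"] + ns$h1["mean"]
  atoms_c <- which(mol$atoms$element == "C")
  atoms_h <- which(mol$atoms$attached_h_count >= 1L)
  ai <- c(atoms_c, atoms_h)
  nuc <- c(rep("C13", length(atoms_c)), rep("H1", length(atoms_h)))
  per_conf <- c(lapply(atoms_c, function(a) unname(c13[a, ])),
                lapply(atoms_h, function(a) unname(h1[a, ])))
  out <- data.frame(
    molecule_id = rep(mol$molecule_id, length(ai)),
    atom_index = ai - 1L,
    nucleus = nuc,
    pred_mean_ppm = vapply(per_conf, mean, numeric(1)),
    pred_std_ppm = vapply(per_conf, pop_sd, numeric(1)),
    n_conformers = rep(nconf, length(ai)),
    stringsAsFactors = FALSE)
  out$per_conformer_ppm <- per_conf
  out
}

#' Predict shifts for one or more molecules
#'
#' Convenience wrapper around [predict_ensemble()]. Ensembles may be
#' supplied; otherwise they are generated with a fixed per-molecule
#' seed derived from `seed`, so repeated evaluation reuses identical
#' geometries.
#'
#' @param object an `eqshift_model`.
#' @param molecules an `eqshift_molecule` or list of them.
#' @param ensembles optional named list of ensembles keyed by
#'   molecule_id.
#' @param n_conformers ensemble size when generating (candidates are
#'   2 x this).
#' @param seed base seed for generated ensembles.
#' @param ... unused.
#' @return row-bound prediction data frame (see [predict_ensemble()]).
#' @export
predict.eqshift_model <- function(object, molecules, ensembles = NULL,
                                  n_conformers = 100L, seed = 1L, ...) {
  if (inherits(molecules, "eqshift_molecule")) {
    molecules <- list(molecules)
  }
  if (is.null(ensembles)) {
    seeds <- seed + seq_along(molecules) - 1L
    ensembles <- generate_ensembles(molecules,
                                    n_generate = 2L * n_conformers,
                                    n_keep = n_conformers,
                                    seeds = seeds)
  }
  out <- lapply(molecules, function(m)
    predict_ensemble(object, m, ensembles[[m$molecule_id]]))
  do.call(rbind, out)
}

#' Evaluate predictions against a shift dataset
#'
#' @param preds prediction data frame covering every truth key.
#' @param truth an `eqshift_dataset`.
#' @return an `eqshift_metrics` data frame with one row per
#'   (nucleus, saccharide class): `mae_ppm`, `rmse_ppm`, `n_shifts`.
#'   The pooled signed errors and their population standard deviation
#'   are attached as attributes `errors` and `error_sd`.
#' @export
evaluate_predictions <- function(preds, truth) {
  sh <- truth$shifts
  pkey <- paste(preds$molecule_id, preds$atom_index, preds$nucleus)
  tkey <- paste(sh$molecule_id, sh$atom_index, sh$nucleus)
  hit <- match(tkey, pkey)
  if (anyNA(hit)) {
    stop("missing predictions for truth keys: ",
         paste(utils::head(tkey[is.na(hit)], 10L), collapse = "; "))
  }
  delta <- preds$pred_mean_ppm[hit] - sh$shift_ppm
  cls <- vapply(sh$molecule_id, function(id)
    truth$molecules[[id]]$saccharide_class, character(1))
  cells <- expand.grid(saccharide_class =
                         intersect(SACCHARIDE_CLASSES, unique(cls)),
                       nucleus = NUCLEI, stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sel <- cls == cells$saccharide_class[r] &
      sh$nucleus == cells$nucleus[r]
    data.frame(nucleus = cells$nucleus[r],
               saccharide_class = cells$saccharide_class[r],
               mae_ppm = if (any(sel)) mean(abs(delta[sel])) else NA_real_,
               rmse_ppm = if (any(sel)) sqrt(mean(delta[sel]^2))
                          else NA_real_,
               n_shifts = sum(sel),
               stringsAsFactors = FALSE)
  }))
  res <- res[res$n_shifts > 0, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, errors = unname(delta), error_sd = pop_sd(delta),
            class = c("eqshift_metrics", "data.frame"))
}

#' @export
print.eqshift_metrics <- function(x, ...) {
  cat("shift prediction accuracy (population-sd conventions)\n")
  print.data.frame(x, digits = 4)
  cat(sprintf("pooled error sd: %.4f ppm over %d shifts\n",
              attr(x, "error_sd"), sum(x$n_shifts)))
  invisible(x)
}

#' Aggregate metric reports across folds
#'
#' @param reports list of `eqshift_metrics` with identical cell sets.
#' @return data frame with per-cell mean and population standard
#'   deviation of MAE and RMSE across reports, plus formatted
#'   `"mean (sd)"` columns, cells ordered (mono, di, tri, other) within
#'   (C13, H1).
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  key <- function(r) paste(r$nucleus, r$saccharide_class)
  k0 <- sort(key(reports[[1]]))
  for (r in reports) {
    if (!identical(sort(key(r)), k0)) {
      stop("reports have inconsistent (nucleus, class) cells")
    }
  }
  cells <- reports[[1]][, c("nucleus", "saccharide_class")]
  ord <- order(match(cells$nucleus, NUCLEI),
               match(cells$saccharide_class, SACCHARIDE_CLASSES))
  cells <- cells[ord, , drop = FALSE]
  stat <- function(col) {
    vapply(seq_len(nrow(cells)), function(i) {
      vals <- vapply(reports, function(r) {
        sel <- r$nucleus == cells$nucleus[i] &
          r$saccharide_class == cells$saccharide_class[i]
        r[[col]][sel]
      }, numeric(1))
      c(mean(vals), pop_sd(vals))
    }, numeric(2))
  }
  mm <- stat("mae_ppm"); rr <- stat("rmse_ppm")
  out <- data.frame(
    nucleus = cells$nucleus, saccharide_class = cells$saccharide_class,
    mae_mean = mm[1, ], mae_sd = mm[2, ],
    rmse_mean = rr[1, ], rmse_sd = rr[2, ],
    mae = sprintf("%.2f (%.2f)", mm[1, ], mm[2, ]),
    rmse = sprintf("%.2f (%.2f)", rr[1, ], rr[2, ]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ensemble-mean error versus mean per-conformer error
#'
#' For a molecule with known shifts, computes the MAE of the
#' ensemble-mean prediction and the mean over conformers of the
#' per-conformer MAE. The former never exceeds the latter (triangle
#' inequality), which is what licenses training on the expanded
#' conformer set.
#'
#' @param model an `eqshift_model`.
#' @param mol an `eqshift_molecule`.
#' @param ensemble its conformer ensemble.
#' @param truth an `eqshift_dataset` containing the molecule's shifts.
#' @return list with `mae_ensemble_mean`, `mean_per_conformer_mae` and
#'   `n_shifts`.
#' @export
ensemble_mae_inequality <- function(model, mol, ensemble, truth) {
  preds <- predict_ensemble(model, mol, ensemble)
  sh <- truth$shifts[truth$shifts$molecule_id == mol$molecule_id, ,
                     drop = FALSE]
  if (nrow(sh) == 0) stop("no truth shifts for ", mol$molecule_id)
  pkey <- paste(preds$atom_index, preds$nucleus)
  hit <- match(paste(sh$atom_index, sh$nucleus), pkey)
  if (anyNA(hit)) stop("predictions do not cover the truth shifts")
  per_conf <- do.call(rbind, preds$per_conformer_ppm[hit])
  mean_pred <- preds$pred_mean_ppm[hit]
  mae_mean <- mean(abs(mean_pred - sh$shift_ppm))
  per_conf_mae <- mean(colMeans(abs(per_conf - sh$shift_ppm)))
  list(mae_ensemble_mean = mae_mean,
       mean_per_conformer_mae = per_conf_mae,
       n_shifts = nrow(sh))
}
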
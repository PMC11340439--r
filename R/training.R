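# Training: masked mean-absolute-error objective, conformer-ensemble
# dataset expansion, Adam with the two learning-rate schedules
# (plateau for single-conformer training, fixed three-epoch decay for
# ensemble training), stratified cross-validation folds and
# structure-exclusion splits.

#' Masked mean absolute error
#'
#' `(1/N) * sum(|target - pred|)` over entries where `mask` is true,
#' with N the number of masked-true entries.
#'
#' @param pred,target numeric vectors of equal length.
#' @param mask logical vector; defaults to all true.
#' @return the masked MAE; error if no entry is masked true.
#' @export
mae_loss <- function(pred, target, mask = rep(TRUE, length(pred))) {
  stopifnot(length(pred) == length(target),
            length(mask) == length(pred))
  n <- sum(mask)
  if (n == 0) stop("no supervised entries in mask")
  sum(abs(pred[mask] - target[mask])) / n
}

#' Expand a shift dataset over conformer ensembles
#'
#' Emits one graph sample per (molecule, conformer) pair, every sample
#' carrying the molecule's full shift targets — the ensemble
#' augmentation under which minimising per-sample error bounds the
#' error of the ensemble-mean prediction from above.
#'
#' @param dataset an `eqshift_dataset`.
#' @param ensembles named list of `eqshift_ensemble`, one per molecule.
#' @param r_cut,element_vocab,hcount_cap featurisation settings (see
#'   [build_graph()]).
#' @return list of `eqshift_graph` samples, length
#'   `sum(ensemble sizes)`.
#' @export
expand_with_conformers <- function(dataset, ensembles, r_cut = 6.0,
                                   element_vocab = ELEMENT_VOCAB_DEFAULT,
                                   hcount_cap = HCOUNT_CAP_DEFAULT) {
  out <- list()
  for (id in names(dataset$molecules)) {
    ens <- ensembles[[id]]
    if (is.null(ens)) stop("no conformer ensemble for molecule ", id)
    mol <- dataset$molecules[[id]]
    tg <- dataset$shifts[dataset$shifts$molecule_id == id, , drop = FALSE]
    for (cf in ens$conformers) {
      out[[length(out) + 1L]] <- build_graph(
        mol, cf, targets = tg, r_cut = r_cut,
        element_vocab = element_vocab, hcount_cap = hcount_cap)
    }
  }
  out
}

#' Training configuration
#'
#' @param lr initial Adam learning rate (default 3e-4).
#' @param batch_size graph samples per gradient step (default 32).
#' @param mode `"ensemble"`: a fixed number of epochs (default 3) over
#'   the expanded conformer set with the learning rate divided by 10
#'   each new epoch, no validation split. `"single_conformer"`: train
#'   with a plateau schedule — 5 percent of molecules held out for
#'   validation, learning rate multiplied by `plateau_factor` when the
#'   validation masked MAE has not improved for `plateau_patience`
#'   epochs.
#' @param epochs number of epochs (defaults: 3 for ensemble mode, 60
#'   otherwise).
#' @param plateau_patience,plateau_factor,val_fraction plateau-schedule
#'   settings (defaults 20, 0.1, 0.05).
#' @param seed RNG seed controlling shuffling and the validation split.
#' @return an `eqshift_train_config` list.
#' @export
eqshift_train_config <- function(lr = 3e-4, batch_size = 32L,
                                 mode = c("ensemble",
                                          "single_conformer"),
                                 epochs = NULL, plateau_patience = 20L,
                                 plateau_factor = 0.1,
                                 val_fraction = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(epochs)) epochs <- if (mode == "ensemble") 3L else 60L
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1,
            val_fraction > 0, val_fraction < 0.5)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 mode = mode, epochs = as.integer(epochs),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "eqshift_train_config")
}

# Per-nucleus z-scoring statistics over the training samples (population
# standard deviation; degenerate spreads fall back to sd 1).
norm_stats_from_samples <- function(samples) {
  tc <- unlist(lapply(samples, function(s) s$target_c13[s$mask_c13]))
  th <- unlist(lapply(samples, function(s) s$target_h1[s$mask_h1]))
  pop_sd <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s < 1e-8) 1 else s
  }
  list(
    c13 = c(mean = if (length(tc)) mean(tc) else 0,
            sd = if (length(tc)) pop_sd(tc) else 1),
    h1 = c(mean = if (length(th)) mean(th) else 0,
           sd = if (length(th)) pop_sd(th) else 1)
  )
}

# Attach the combined masked-MAE loss (normalised units, both nuclei
# pooled by their target counts) to a forward pass.
batch_loss <- function(fw, batch, norm_stats) {
  tp <- fw$tape
  nc <- sum(batch$mask_c13)
  nh <- sum(batch$mask_h1)
  if (nc + nh == 0) stop("batch contains no supervised nuclei")
  zc <- (batch$target_c13 - norm_stats$c13["mean"]) /
    norm_stats$c13["sd"]
  zh <- (batch$target_h1 - norm_stats$h1["mean"]) / norm_stats$h1["sd"]
  zc[is.na(zc)] <- 0; zh[is.na(zh)] <- 0
  terms <- list(); weights <- numeric(0)
  if (nc > 0) {
    terms <- c(terms, ad_mae_masked(tp, fw$c13,
                                    ad_const(tp, matrix(zc, ncol = 1)),
                                    batch$mask_c13))
    weights <- c(weights, nc / (nc + nh))
  }
  if (nh > 0) {
    terms <- c(terms, ad_mae_masked(tp, fw$h1,
                                    ad_const(tp, matrix(zh, ncol = 1)),
                                    batch$mask_h1))
    weights <- c(weights, nh / (nc + nh))
  }
  if (length(terms) == 1L) {
    if (weights[1] == 1) terms[[1]]
    else ad_scale(tp, terms[[1]], weights[1])
  } else {
    ad_axpy(tp, terms[[1]], terms[[2]], weights[1], weights[2])
  }
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Masked MAE of a sample set under given params (normalised units).
eval_samples_mae <- function(params, config, plans, samples,
                             norm_stats, batch_size = 64L) {
  tot <- 0; n <- 0
  for (chunk in split(samples,
                      ceiling(seq_along(samples) / batch_size))) {
    b <- assemble_batch(chunk)
    pr <- predict_normalised(params, config, plans, b)
    if (any(b$mask_c13)) {
      zc <- (b$target_c13 - norm_stats$c13["mean"]) / norm_stats$c13["sd"]
      tot <- tot + sum(abs(pr[b$mask_c13, "c13"] - zc[b$mask_c13]))
      n <- n + sum(b$mask_c13)
    }
    if (any(b$mask_h1)) {
      zh <- (b$target_h1 - norm_stats$h1["mean"]) / norm_stats$h1["sd"]
      tot <- tot + sum(abs(pr[b$mask_h1, "h1"] - zh[b$mask_h1]))
      n <- n + sum(b$mask_h1)
    }
  }
  tot / n
}

#' Fit the equivariant shift model
#'
#' Trains with Adam on the masked MAE of both nuclei jointly (one
#' network, two readout heads), targets z-scored per nucleus with
#' statistics taken from the training samples and stored in the
#' returned model. In `"ensemble"` mode an epoch is one pass over the
#' expanded (molecule x conformer) sample list and the learning rate is
#' divided by 10 at each new epoch; in `"single_conformer"` mode a
#' molecule-level validation split drives a reduce-on-plateau schedule.
#'
#' @param samples list of `eqshift_graph` training samples (see
#'   [expand_with_conformers()]).
#' @param config an `eqshift_config`.
#' @param train_config an `eqshift_train_config`.
#' @param init_params optional warm-start parameter list.
#' @param verbose print per-epoch progress?
#' @return an `eqshift_model` with a per-epoch `history` data frame.
#' @export
eqshift_fit <- function(samples, config = eqshift_config(),
                        train_config = eqshift_train_config(),
                        init_params = NULL, verbose = FALSE) {
  if (length(samples) == 0) stop("no training samples")
  tc <- train_config
  plans <- model_plans(config)
  set.seed(tc$seed)
  params <- if (is.null(init_params)) {
    eqshift_init(config, seed = tc$seed)
  } else {
    init_params
  }
  # validation split at molecule level (single-conformer mode only)
  val_samples <- list()
  train_samples <- samples
  if (tc$mode == "single_conformer") {
    mols <- unique(vapply(samples, `[[`, character(1), "molecule_id"))
    n_val <- max(1L, round(tc$val_fraction * length(mols)))
    val_mols <- sample(mols, n_val)
    in_val <- vapply(samples, function(s)
      s$molecule_id %in% val_mols, logical(1))
    val_samples <- samples[in_val]
    train_samples <- samples[!in_val]
    if (length(train_samples) == 0) stop("validation split ate all data")
  }
  norm_stats <- norm_stats_from_samples(train_samples)
  state <- adam_new(params)
  lr <- tc$lr
  best_val <- Inf
  stale <- 0L
  hist <- list()
  for (epoch in seq_len(tc$epochs)) {
    if (tc$mode == "ensemble" && epoch > 1) lr <- lr * 0.1
    ord <- sample(seq_along(train_samples))
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      b <- assemble_batch(train_samples[bi])
      fw <- forward_network(params, config, plans, b, trainable = TRUE)
      loss <- batch_loss(fw, b, norm_stats)
      lv <- ad_value(fw$tape, loss)
      if (!is.finite(lv)) {
        stop(sprintf(
          "training diverged (non-finite loss at epoch %d); last finite train MAE %.4f",
          epoch, if (ep_n > 0) ep_loss / ep_n else NA_real_))
      }
      grads <- tape_backward(fw$tape, loss)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + lv * length(bi)
      ep_n <- ep_n + length(bi)
    }
    train_mae <- ep_loss / ep_n
    val_mae <- NA_real_
    if (length(val_samples) > 0) {
      val_mae <- eval_samples_mae(params, config, plans, val_samples,
                                  norm_stats)
      if (val_mae < best_val - 1e-6) {
        best_val <- val_mae
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= tc$plateau_patience) {
          lr <- lr * tc$plateau_factor
          stale <- 0L
        }
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_mae = train_mae,
                                val_mae = val_mae)
    if (verbose) {
      message(sprintf("epoch %d: lr %.2e train %.4f val %s", epoch, lr,
                      train_mae,
                      if (is.na(val_mae)) "-" else sprintf("%.4f",
                                                           val_mae)))
    }
  }
  new_eqshift_model(config, params, norm_stats,
                    history = do.call(rbind, hist), seed = tc$seed,
                    provenance = list(
                      package_version =
                        as.character(utils::packageVersion("eqshift")),
                      mode = tc$mode,
                      n_samples = length(samples)))
}

# ---- cross-validation and exclusion splits ---------------------------

#' Stratified k-fold cross-validation plan
#'
#' Molecules are partitioned into k folds stratified by saccharide
#' class: within each class molecules are dealt out so every fold gets
#' the class's base share, with remainders assigned to the currently
#' smallest folds. Per-fold class counts therefore differ from exact
#' proportionality by at most one molecule.
#'
#' @param dataset an `eqshift_dataset`.
#' @param k number of folds (default 10; must be at least 2 and no
#'   larger than the smallest class).
#' @param seed RNG seed; the plan is reproducible under it.
#' @return an `eqshift_folds` object: `k`, `assignments` (named integer
#'   vector molecule_id -> fold) and `strata`.
#' @export
make_cv_folds <- function(dataset, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2 (k = 1 leaves no held-out data)")
  ids <- names(dataset$molecules)
  cls <- vapply(dataset$molecules, `[[`, character(1),
                "saccharide_class")
  classes <- intersect(SACCHARIDE_CLASSES, unique(cls))
  for (cl in classes) {
    if (sum(cls == cl) < k) {
      stop(sprintf("class '%s' has %d molecules, fewer than k = %d",
                   cl, sum(cls == cl), k))
    }
  }
  set.seed(seed)
  assignments <- integer(length(ids))
  names(assignments) <- ids
  fold_totals <- integer(k)
  for (cl in classes) {
    members <- sample(ids[cls == cl])
    nc <- length(members)
    base <- nc %/% k
    extra <- nc %% k
    counts <- rep(base, k)
    if (extra > 0) {
      recv <- order(fold_totals, seq_len(k))[seq_len(extra)]
      counts[recv] <- counts[recv] + 1L
    }
    fold_of <- rep(seq_len(k), times = counts)
    assignments[members] <- fold_of
    fold_totals <- fold_totals + counts
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 strata = cls, seed = seed),
            class = "eqshift_folds")
}

#' @export
print.eqshift_folds <- function(x, ...) {
  cat(sprintf("<%d-fold stratified plan over %d molecules>\n", x$k,
              length(x$assignments)))
  print(table(fold = x$assignments, class = x$strata))
  invisible(x)
}

#' Structure-exclusion train/test split
#'
#' Molecules satisfying `predicate` form the test set; the complement
#' trains. Used to probe extrapolation to deliberately held-out
#' structural motifs.
#'
#' @param dataset an `eqshift_dataset`.
#' @param predicate function taking an `eqshift_molecule`, returning
#'   `TRUE` for molecules to exclude from training.
#' @return list with `train` and `test` (character vectors of molecule
#'   ids) and `n_removed`.
#' @export
make_exclusion_split <- function(dataset, predicate) {
  flags <- vapply(dataset$molecules, function(m)
    isTRUE(predicate(m)), logical(1))
  if (!any(flags)) stop("predicate excludes no molecules: empty test set")
  if (all(flags)) stop("predicate excludes every molecule: empty train set")
  list(train = names(dataset$molecules)[!flags],
       test = names(dataset$molecules)[flags],
       n_removed = sum(flags))
}
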
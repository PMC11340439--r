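#' @importClassesFrom ChemmineR SDF SDFset
#' @importFrom methods new
NULL

# Conformer ensembles: distance-geometry embedding (ETKDGv3 through the
# RDKit bridge), greedy diversity filtering on aligned heavy-atom RMSD,
# and MMFF94 energy ranking. Energies are evaluated with explicit
# hydrogens (the force field requires them); coordinates are stored for
# heavy atoms only, matching the model's graph representation.

new_conformer <- function(molecule_id, coords, energy) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, all(is.finite(coords)))
  structure(list(molecule_id = molecule_id, coords = coords,
                 energy_kcal_mol = energy),
            class = "eqshift_conformer")
}

new_ensemble <- function(molecule_id, conformers, params) {
  structure(list(molecule_id = molecule_id, conformers = conformers,
                 params = params),
            class = "eqshift_ensemble")
}

#' @export
print.eqshift_ensemble <- function(x, ...) {
  en <- vapply(x$conformers, `[[`, numeric(1), "energy_kcal_mol")
  cat(sprintf("<conformer ensemble %s: %d conformers", x$molecule_id,
              length(x$conformers)))
  if (length(en) > 0) {
    cat(sprintf(", MMFF94 energy %.2f..%.2f kcal/mol", min(en), max(en)))
  }
  cat(">\n")
  invisible(x)
}

#' Heavy-atom RMSD between two conformers
#'
#' With `align = TRUE` (the default) the minimal RMSD over rigid
#' superposition is returned, using the Kabsch algorithm restricted to
#' proper rotations (no reflection), so mirror-image conformers are not
#' treated as identical. Otherwise the raw coordinate RMSD is returned.
#'
#' @param a,b conformers of the same molecule (same atom order), or bare
#'   n x 3 coordinate matrices.
#' @param align superimpose before measuring?
#' @return RMSD in Angstrom.
#' @export
rmsd_heavy <- function(a, b, align = TRUE) {
  A <- if (is.matrix(a)) a else a$coords
  B <- if (is.matrix(b)) b else b$coords
  if (!all(dim(A) == dim(B))) stop("coordinate shape mismatch")
  if (align) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    s <- svd(crossprod(B, A))  # H = B^T A
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    B <- B %*% R
  }
  sqrt(mean(rowSums((A - B)^2)))
}

# Greedy diversity filter + energy ranking on explicit candidates.
# Candidates are processed in MMFF94-energy-ascending order; a candidate
# is kept only if its aligned heavy-atom RMSD to every kept candidate
# exceeds rmsd_min. The first min(n_keep, survivors) survivors (already
# the lowest-energy ones) are retained.
ensemble_from_candidates <- function(molecule_id, coords_list, energies,
                                     n_keep, rmsd_min, params = list()) {
  stopifnot(length(coords_list) == length(energies))
  ord <- order(energies)
  kept <- list()
  kept_energy <- numeric(0)
  for (idx in ord) {
    cand <- coords_list[[idx]]
    diverse <- TRUE
    for (k in kept) {
      if (rmsd_heavy(cand, k, align = TRUE) <= rmsd_min) {
        diverse <- FALSE
        break
      }
    }
    if (diverse) {
      kept[[length(kept) + 1L]] <- cand
      kept_energy <- c(kept_energy, energies[idx])
      if (length(kept) >= n_keep) break
    }
  }
  if (length(kept) < n_keep) {
    warning(sprintf(
      "molecule %s: only %d of the requested %d diverse conformers exist",
      molecule_id, length(kept), n_keep))
  }
  confs <- Map(function(cc, e) new_conformer(molecule_id, cc, e),
               kept, kept_energy)
  new_ensemble(molecule_id, confs,
               utils::modifyList(list(n_keep = n_keep,
                                      rmsd_min_angstrom = rmsd_min),
                                 params))
}

#' Generate a diverse low-energy conformer ensemble
#'
#' Embeds `n_generate` candidate conformers with ETKDGv3 (seeded),
#' evaluates their MMFF94 potential energies with explicit hydrogens,
#' then keeps a diverse subset: candidates are visited in
#' energy-ascending order and retained only if their aligned heavy-atom
#' RMSD to every already-retained candidate exceeds `rmsd_min`; the
#' lowest-energy `n_keep` survivors form the ensemble.
#'
#' @param mol an `eqshift_molecule`.
#' @param n_generate number of distance-geometry candidates (default
#'   200).
#' @param n_keep ensemble size cap (default 100).
#' @param rmsd_min diversity threshold in Angstrom (default 0.01).
#' @param seed integer RNG seed for the embedding.
#' @return an `eqshift_ensemble`.
#' @export
generate_ensemble <- function(mol, n_generate = 200L, n_keep = 100L,
                              rmsd_min = 0.01, seed = 1L) {
  generate_ensembles(list(mol), n_generate = n_generate, n_keep = n_keep,
                     rmsd_min = rmsd_min, seeds = seed)[[1]]
}

#' Generate conformer ensembles for many molecules in one call
#'
#' @param mols list of `eqshift_molecule` records.
#' @param seeds one integer seed per molecule (recycled if length 1).
#' @inheritParams generate_ensemble
#' @return named list of `eqshift_ensemble`, one per molecule.
#' @export
generate_ensembles <- function(mols, n_generate = 200L, n_keep = 100L,
                               rmsd_min = 0.01, seeds = 1L) {
  if (length(seeds) == 1L) seeds <- rep(seeds, length(mols))
  stopifnot(length(seeds) == length(mols))
  for (m in mols) {
    if (n_heavy(m) < 2) {
      stop("molecule ", m$molecule_id,
           " has fewer than 2 heavy atoms; cannot embed in 3D")
    }
  }
  smiles <- vapply(mols, `[[`, character(1), "smiles")
  raw <- bridge_embed(smiles, n_confs = n_generate, seeds = seeds)
  out <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    if (nrow(raw[[k]]$coords[[1]]) != n_heavy(mols[[k]])) {
      stop("embedding atom count mismatch for ", mols[[k]]$molecule_id)
    }
    out[[k]] <- ensemble_from_candidates(
      mols[[k]]$molecule_id, raw[[k]]$coords, raw[[k]]$energies,
      n_keep = n_keep, rmsd_min = rmsd_min,
      params = list(n_generate = n_generate, seed = seeds[k]))
  }
  names(out) <- vapply(mols, `[[`, character(1), "molecule_id")
  out
}

# Post-hoc check of the ensemble invariants: pairwise aligned RMSD above
# the threshold, and energies sorted within the retained set.
check_ensemble_invariants <- function(ensemble) {
  confs <- ensemble$conformers
  nc <- length(confs)
  rmsd_min <- ensemble$params$rmsd_min_angstrom
  if (nc >= 2) {
    for (i in seq_len(nc - 1)) {
      for (j in seq(i + 1, nc)) {
        r <- rmsd_heavy(confs[[i]], confs[[j]], align = TRUE)
        if (r <= rmsd_min) {
          stop(sprintf("conformers %d and %d closer than %.4g A (%.4g)",
                       i, j, rmsd_min, r))
        }
      }
    }
  }
  en <- vapply(confs, `[[`, numeric(1), "energy_kcal_mol")
  if (is.unsorted(en)) stop("retained energies are not ascending")
  invisible(TRUE)
}

# ---- SDF input/output (ChemmineR) ------------------------------------

V2000_BOND_CODE <- c(single = 1, double = 2, other = 4)

#' Write a conformer ensemble to a multi-record SDF (V2000)
#'
#' One record per conformer (heavy atoms only); the MMFF94 energy is
#' stored in the `energy_kcal_mol` SD tag with 8 significant digits.
#'
#' @param ensemble an `eqshift_ensemble`.
#' @param mol the matching `eqshift_molecule` (supplies elements/bonds).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf_ensemble <- function(ensemble, mol, path) {
  confs <- ensemble$conformers
  if (length(confs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  n <- n_heavy(mol)
  nb <- nrow(mol$bonds)
  sdfs <- vector("list", length(confs))
  for (k in seq_along(confs)) {
    ab <- cbind(confs[[k]]$coords, matrix(0, n, 12))
    rownames(ab) <- paste(mol$atoms$element, seq_len(n), sep = "_")
    colnames(ab) <- paste0("C", seq_len(ncol(ab)))
    if (nb > 0) {
      bb <- cbind(mol$bonds$i + 1L, mol$bonds$j + 1L,
                  V2000_BOND_CODE[mol$bonds$category],
                  matrix(0, nb, 4))
    } else {
      bb <- matrix(0, 0, 7)
    }
    rownames(bb) <- if (nb > 0) as.character(seq_len(nb)) else character(0)
    colnames(bb) <- paste0("C", seq_len(7))
    hdr <- c(
      Molecule_Name = sprintf("%s_conf%03d", ensemble$molecule_id, k),
      Source = "  eqshift", Comment = "",
      Counts_Line = sprintf(
        "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    sdfs[[k]] <- methods::new(
      "SDF", header = hdr, atomblock = ab, bondblock = bb,
      datablock = c(energy_kcal_mol =
                      sprintf("%.8g", confs[[k]]$energy_kcal_mol)))
  }
  sset <- methods::new("SDFset", SDF = sdfs,
                       ID = vapply(sdfs, function(s)
                         unname(ChemmineR::header(s)[1]), character(1)))
  ChemmineR::write.SDF(sset, file = path, cid = TRUE)
  invisible(path)
}

#' Read a conformer ensemble from an SDF file
#'
#' @param path SDF file path.
#' @param molecule_id id to stamp on the conformers (default: file base
#'   name).
#' @return an `eqshift_ensemble` (params carry only what the file
#'   stores).
#' @export
read_sdf_ensemble <- function(path,
                              molecule_id =
                                sub("\\.sdf$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\$\\$\\$\\$", txt))) {
    return(new_ensemble(molecule_id, list(), list()))
  }
  sset <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e)
                     stop("malformed SDF '", path, "': ",
                          conditionMessage(e)))
  confs <- vector("list", length(sset))
  for (k in seq_along(sset)) {
    sdf <- sset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0) {
      stop("malformed SDF record ", k, " in ", path)
    }
    coords <- unname(ab[, 1:3, drop = FALSE])
    db <- ChemmineR::datablock(sdf)
    en <- suppressWarnings(as.numeric(db[["energy_kcal_mol"]]))
    if (length(en) == 0 || is.na(en)) en <- NA_real_
    confs[[k]] <- new_conformer(molecule_id, coords, en)
  }
  new_ensemble(molecule_id, confs, list())
}
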
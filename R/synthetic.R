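# Synthetic fixtures: a catalogue of small stereochemically rich
# polyol/ether/acetyl molecules, and an exactly E(3)-invariant
# synthetic "chemical shift" oracle with the statistical shape of a
# carbohydrate shift table. The oracle supervises end-to-end recovery
# tests of the network without any external data.

# Fixed catalogue. Pseudo saccharide classes are assigned by size
# (mono <= 8 heavy atoms, di 9-13, tri >= 14) in proportions echoing a
# mono/di/tri carbohydrate collection (about 29/41/29 percent).
TOY_CATALOGUE <- data.frame(
  smiles = c(
    # mono: 5-8 heavy atoms
    "OCC(O)CO",
    "OC[C@H](O)[C@@H](O)CO",
    "OC[C@@H](O)[C@H](O)CO",
    "CO[C@@H]1CCCO1",
    "C[C@H](O)C(=O)O",
    # di: 9-13 heavy atoms
    "OC[C@H](O)[C@@H](O)[C@H](O)CO",
    "OC[C@H]1OC[C@@H](O)[C@H]1O",
    "CC(=O)OC[C@H](O)CO",
    "CO[C@@H]1OC[C@H](O)[C@H](O)C1",
    "OC[C@H](O)[C@@H](O)[C@H](O)[C@@H](O)CO",
    "OC[C@H]1O[C@H](O)[C@H](O)[C@@H](O)[C@@H]1O",
    "CO[C@@H]1O[C@H](CO)[C@@H](O)[C@H](O)[C@H]1O",
    # tri: 14-20 heavy atoms
    "CC(=O)OC[C@H]1OC[C@@H](O)[C@H](O)[C@H]1O",
    "CC(=O)OC[C@H]1O[C@@H](OC)[C@H](O)[C@@H](O)[C@@H]1O",
    "CC(=O)O[C@H]1CO[C@@H](OC)[C@H](O)[C@H]1OC(C)=O",
    "OC[C@H]1O[C@@H](OCC(O)CO)[C@H](O)[C@@H](O)[C@@H]1O",
    "CO[C@@H]1O[C@H](COC(C)=O)[C@@H](O)[C@H](O)[C@H]1OC"
  ),
  saccharide_class = c(rep("mono", 5), rep("di", 7), rep("tri", 5)),
  stringsAsFactors = FALSE
)

#' Deterministically sample toy molecules from the fixed catalogue
#'
#' @param n number of molecules.
#' @param seed RNG seed; the same seed returns the same molecules.
#' @return list of parsed `eqshift_molecule` records with unique ids
#'   `toyNNN_cKK` (KK = catalogue index) and pseudo saccharide classes.
#' @export
make_toy_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  picks <- sample.int(nrow(TOY_CATALOGUE), n, replace = TRUE)
  ids <- sprintf("toy%03d_c%02d", seq_len(n), picks)
  parse_smiles_many(TOY_CATALOGUE$smiles[picks], molecule_ids = ids,
                    saccharide_classes =
                      TOY_CATALOGUE$saccharide_class[picks])
}

#' Configuration of the synthetic shift oracle
#'
#' The oracle is
#' `delta(i) = a(element_i) + b * sum_j exp(-d_ij^2 / sigma^2)
#'  + c * sum_(j,k) cos(theta_jik) + eps`,
#' with the pair sum over all other atoms within `r_cut`, the angle sum
#' over unordered pairs of atoms bonded to i, and `eps` a Gaussian
#' perturbation drawn once per (molecule, atom) — not per conformer —
#' mimicking a single experimental value observed across many
#' geometries. It depends on coordinates only through distances and
#' angles, hence is exactly E(3)-invariant.
#'
#' @param element_offsets named baseline values per element (ppm-like).
#' @param b,sigma pair-interaction weight and Gaussian length scale
#'   (Angstrom).
#' @param c_angle bonded-angle weight: with a nonzero value the oracle
#'   carries angular information beyond pairwise distances of a single
#'   neighbourhood.
#' @param noise_sd standard deviation of the per-atom perturbation.
#' @param r_cut pair-sum cutoff in Angstrom.
#' @param seed seed entering the per-atom noise hash.
#' @return an `eqshift_oracle_config` list.
#' @export
oracle_config <- function(element_offsets = c(C = 85, O = 55, N = 35,
                                              other = 25),
                          b = 15, sigma = 1.5, c_angle = 8,
                          noise_sd = 0.3, r_cut = 6.0, seed = 1L) {
  stopifnot(sigma > 0, noise_sd >= 0)
  structure(list(element_offsets = element_offsets, b = b,
                 sigma = sigma, c_angle = c_angle,
                 noise_sd = noise_sd, r_cut = r_cut,
                 seed = as.integer(seed)),
            class = "eqshift_oracle_config")
}

# deterministic per-(molecule, atom) noise that leaves the global RNG
# stream untouched
.oracle_noise <- function(molecule_id, atom_index, cfg) {
  if (cfg$noise_sd == 0) return(0)
  h <- (sum(utf8ToInt(molecule_id)) * 131L + atom_index * 7919L +
          cfg$seed * 104729L) %% 2147483629L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(h)
  stats::rnorm(1, sd = cfg$noise_sd)
}

#' Synthetic shift oracle for one atom of one conformer
#'
#' @param mol an `eqshift_molecule`.
#' @param conf a conformer (or bare coordinate matrix) of the molecule.
#' @param atom_index 0-based heavy-atom index.
#' @param cfg an [oracle_config()].
#' @return the synthetic shift value (exactly invariant under
#'   rotations, translations and reflections of the conformer).
#' @export
oracle_shift <- function(mol, conf, atom_index, cfg = oracle_config()) {
  coords <- if (is.matrix(conf)) conf else conf$coords
  n <- n_heavy(mol)
  stopifnot(nrow(coords) == n, atom_index >= 0, atom_index < n)
  i <- atom_index + 1L
  el <- mol$atoms$element[i]
  off <- cfg$element_offsets
  a <- if (el %in% names(off)) off[[el]] else off[["other"]]
  ri <- coords[i, ]
  dv <- sweep(coords, 2, ri)
  d <- sqrt(rowSums(dv^2))
  near <- which(d > 0 & d < cfg$r_cut)
  pair <- sum(exp(-d[near]^2 / cfg$sigma^2))
  nb <- integer(0)
  if (nrow(mol$bonds) > 0) {
    nb <- c(mol$bonds$j[mol$bonds$i == atom_index],
            mol$bonds$i[mol$bonds$j == atom_index]) + 1L
  }
  ang <- 0
  if (length(nb) >= 2) {
    for (p in seq_len(length(nb) - 1L)) {
      for (q in seq(p + 1L, length(nb))) {
        u <- coords[nb[p], ] - ri
        v <- coords[nb[q], ] - ri
        ang <- ang + sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      }
    }
  }
  a + cfg$b * pair + cfg$c_angle * ang +
    .oracle_noise(mol$molecule_id, atom_index, cfg)
}

#' Generate a fully synthetic shift dataset with conformer ensembles
#'
#' Toy molecules are drawn from the catalogue, ensembles are generated
#' through the standard pipeline, and oracle targets are evaluated on
#' each molecule's lowest-energy conformer: every carbon receives a
#' C13 record and every H-bearing heavy atom an H1 record (the oracle
#' value divided by 10, mimicking the proton scale).
#'
#' @param n_mol number of molecules.
#' @param n_conf conformers kept per molecule (2x candidates
#'   generated).
#' @param cfg an [oracle_config()]; its `seed` also seeds molecule
#'   sampling and embedding.
#' @return list with `dataset` (an `eqshift_dataset`) and `ensembles`
#'   (named list of `eqshift_ensemble`).
#' @export
make_synthetic_dataset <- function(n_mol, n_conf, cfg = oracle_config()) {
  stopifnot(n_mol >= 1, n_conf >= 1)
  mols <- make_toy_molecules(n_mol, seed = cfg$seed)
  ensembles <- generate_ensembles(
    mols, n_generate = 2L * n_conf, n_keep = n_conf, rmsd_min = 0.01,
    seeds = cfg$seed + seq_len(n_mol) - 1L)
  rows <- list()
  for (m in mols) {
    ens <- ensembles[[m$molecule_id]]
    ref <- ens$conformers[[1]]  # lowest MMFF94 energy
    for (i in seq_len(n_heavy(m))) {
      val <- oracle_shift(m, ref, i - 1L, cfg)
      if (m$atoms$element[i] == "C") {
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_id = m$molecule_id, atom_index = i - 1L,
          nucleus = "C13", shift_ppm = val, stringsAsFactors = FALSE)
      }
      if (m$atoms$attached_h_count[i] >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_id = m$molecule_id, atom_index = i - 1L,
          nucleus = "H1", shift_ppm = val / 10,
          stringsAsFactors = FALSE)
      }
    }
  }
  ds <- shift_dataset(mols, do.call(rbind, rows),
                      provenance = sprintf(
                        "synthetic oracle (seed %d, b %.3g, c %.3g, noise %.3g)",
                        cfg$seed, cfg$b, cfg$c_angle, cfg$noise_sd))
  list(dataset = ds, ensembles = ensembles)
}
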
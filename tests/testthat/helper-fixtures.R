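# Shared fixtures. Everything is generated in code; molecule parses are
# memoised per session by the bridge, and ensembles built here are
# cached so independent test files do not repeat subprocess calls.

.fix <- new.env(parent = emptyenv())

# methyl alpha-D-galactopyranoside: C7H14O6, 13 heavy atoms
GALACTOSIDE_SMILES <- "CO[C@@H]1O[C@H](CO)[C@@H](O)[C@H](O)[C@H]1O"

fixture_mol <- function(smiles = GALACTOSIDE_SMILES, id = smiles,
                        class = "mono") {
  parse_smiles(smiles, molecule_id = id, saccharide_class = class)
}

fixture_ensemble <- function(smiles = GALACTOSIDE_SMILES,
                             n_generate = 8L, n_keep = 4L, seed = 7L) {
  key <- paste(smiles, n_generate, n_keep, seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_ensemble(fixture_mol(smiles),
                                     n_generate = n_generate,
                                     n_keep = n_keep, seed = seed)
  }
  .fix[[key]]
}

# small architecture used across network tests
tiny_config <- function(...) {
  eqshift_config(n_layers = 2L, node_emb_dim = 16L, edge_emb_dim = 8L,
                 hidden = "8x0e+4x1o+2x2e", readout_scalars = 16L,
                 readout_hidden = 24L, nn_hidden = 12L, ...)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# hand-built molecule records (no parser involved) for split/fold tests
fake_molecule <- function(id, class = "mono", n_atoms = 3L,
                          smiles = "CCC") {
  atoms <- data.frame(index = seq_len(n_atoms) - 1L,
                      element = rep("C", n_atoms),
                      attached_h_count = rep(2L, n_atoms),
                      stringsAsFactors = FALSE)
  bonds <- if (n_atoms >= 2) {
    data.frame(i = 0:(n_atoms - 2L), j = 1:(n_atoms - 1L),
               category = "single", stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), category = character(0))
  }
  structure(list(molecule_id = id, smiles = smiles, atoms = atoms,
                 bonds = bonds, saccharide_class = class),
            class = "eqshift_molecule")
}

fake_dataset <- function(n_mono, n_di, n_tri) {
  mols <- c(
    lapply(seq_len(n_mono), function(i)
      fake_molecule(sprintf("mono%03d", i), "mono")),
    lapply(seq_len(n_di), function(i)
      fake_molecule(sprintf("di%03d", i), "di")),
    lapply(seq_len(n_tri), function(i)
      fake_molecule(sprintf("tri%03d", i), "tri")))
  shifts <- data.frame(
    molecule_id = vapply(mols, `[[`, character(1), "molecule_id"),
    atom_index = 0L, nucleus = "C13", shift_ppm = 100,
    stringsAsFactors = FALSE)
  shift_dataset(mols, shifts, provenance = "fake")
}

# shared tiny synthetic dataset (one bridge call per session)
fixture_synth <- function() {
  if (is.null(.fix$synth)) {
    .fix$synth <- make_synthetic_dataset(10L, 2L,
                                         oracle_config(seed = 303L))
  }
  .fix$synth
}
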
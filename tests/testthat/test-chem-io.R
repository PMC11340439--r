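# Molecule parsing and shift-table IO.

test_that("SMILES parse folds hydrogens and maps bond categories", {
  m <- fixture_mol("CO", id = "methanol")
  expect_equal(nrow(m$atoms), 2L)
  expect_setequal(m$atoms$element, c("C", "O"))
  expect_equal(m$atoms$attached_h_count[m$atoms$element == "C"], 3L)
  expect_equal(m$atoms$attached_h_count[m$atoms$element == "O"], 1L)
  expect_equal(nrow(m$bonds), 1L)
  expect_equal(m$bonds$category, "single")

  f <- fixture_mol("C=O", id = "formaldehyde")
  expect_equal(f$bonds$category, "double")

  b <- fixture_mol("c1ccccc1", id = "benzene")
  expect_true(all(b$bonds$category == "other"))

  expect_error(parse_smiles("not-a-smiles((("), "not-a-smiles")
})

test_that("galactoside heavy atoms and H counts match the molecular formula", {
  m <- fixture_mol()
  # C7H14O6
  expect_equal(nrow(m$atoms), 13L)
  expect_equal(sum(m$atoms$element == "C"), 7L)
  expect_equal(sum(m$atoms$element == "O"), 6L)
  # independent H-count oracle: total valence minus bond orders.
  # standard valences C=4, O=2; bond order 1 for single here
  valence <- c(C = 4L, O = 2L)
  order_of <- c(single = 1L, double = 2L, other = 0L)
  hand <- vapply(seq_len(nrow(m$atoms)), function(i) {
    deg <- sum(order_of[m$bonds$category[m$bonds$i == i - 1L]]) +
      sum(order_of[m$bonds$category[m$bonds$j == i - 1L]])
    valence[[m$atoms$element[i]]] - deg
  }, integer(1))
  expect_equal(m$atoms$attached_h_count, hand)
  expect_equal(sum(m$atoms$attached_h_count), 14L)
})

test_that("parse round-trips preserve topology invariants", {
  for (smi in c("CO", "OCC(O)CO", GALACTOSIDE_SMILES)) {
    m <- fixture_mol(smi, id = paste0("rt_", smi))
    key <- sort(paste(m$atoms$element, m$atoms$attached_h_count))
    bondkey <- sort(paste(pmin(m$bonds$i, m$bonds$j),
                          pmax(m$bonds$i, m$bonds$j), m$bonds$category))
    m2 <- fixture_mol(smi, id = paste0("rt2_", smi))
    expect_equal(nrow(m2$atoms), nrow(m$atoms))
    expect_equal(sort(paste(m2$atoms$element,
                            m2$atoms$attached_h_count)), key)
    expect_equal(sort(paste(pmin(m2$bonds$i, m2$bonds$j),
                            pmax(m2$bonds$i, m2$bonds$j),
                            m2$bonds$category)), bondkey)
  }
})

test_that("shift dataset loads, validates and round-trips", {
  m1 <- fixture_mol("CO", id = "m1", class = "mono")
  m2 <- fixture_mol("OCC(O)CO", id = "m2", class = "mono")
  ci <- which(m1$atoms$element == "C") - 1L
  oi <- which(m1$atoms$element == "O") - 1L
  g_c <- which(m2$atoms$element == "C") - 1L
  sh <- data.frame(
    molecule_id = c("m1", "m1", "m2", "m2", "m2"),
    atom_index = c(ci, oi, g_c[1:3]),
    nucleus = c("C13", "H1", "C13", "C13", "C13"),
    shift_ppm = c(50.1, 3.4, 63.2, 72.5, 63.9),
    stringsAsFactors = FALSE)
  ds <- shift_dataset(list(m1, m2), sh, provenance = "unit test")
  expect_equal(length(ds$molecules), 2L)
  expect_equal(nrow(ds$shifts), 5L)

  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_shift_dataset(ds, path, format = fmt)
    ds2 <- load_shift_dataset(path)
    expect_equal(names(ds2$molecules), names(ds$molecules))
    expect_equal(ds2$shifts$shift_ppm, ds$shifts$shift_ppm)
    expect_equal(ds2$shifts$atom_index, ds$shifts$atom_index)
    expect_equal(ds2$shifts$nucleus, ds$shifts$nucleus)
  }
})

test_that("invalid shift records are rejected with informative errors", {
  m1 <- fixture_mol("CO", id = "m1")
  ci <- which(m1$atoms$element == "C") - 1L
  oi <- which(m1$atoms$element == "O") - 1L
  ok <- data.frame(molecule_id = "m1", atom_index = ci,
                   nucleus = "C13", shift_ppm = 50)
  # duplicate key
  expect_error(shift_dataset(list(m1), rbind(ok, ok)), "duplicate")
  # C13 on oxygen
  expect_error(shift_dataset(list(m1), data.frame(
    molecule_id = "m1", atom_index = oi, nucleus = "C13",
    shift_ppm = 50)), "non-carbon")
  # dangling atom index
  expect_error(shift_dataset(list(m1), data.frame(
    molecule_id = "m1", atom_index = 7L, nucleus = "C13",
    shift_ppm = 50)), "out of range")
  # out-of-window value
  expect_error(shift_dataset(list(m1), data.frame(
    molecule_id = "m1", atom_index = ci, nucleus = "C13",
    shift_ppm = 400)), "outside")
  # H1 on an atom with no attached hydrogens
  m3 <- fixture_mol("CC(=O)OC", id = "m3")
  noh <- which(m3$atoms$attached_h_count == 0L)[1] - 1L
  expect_error(shift_dataset(list(m3), data.frame(
    molecule_id = "m3", atom_index = noh, nucleus = "H1",
    shift_ppm = 2)), "no attached hydrogens")
  # schema error on load
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(molecule_id = "x", smiles = "CO"), bad,
                   row.names = FALSE)
  expect_error(load_shift_dataset(bad), "missing columns")
})

test_that("duplicate diastereotopic H1 rows are averaged on load", {
  # glycerol CH2-OH: two inequivalent protons reported separately
  rows <- data.frame(
    molecule_id = "gly", smiles = "OCC(O)CO",
    saccharide_class = "mono",
    atom_index = c(1L, 1L, 2L), nucleus = c("H1", "H1", "C13"),
    shift_ppm = c(3.60, 3.72, 72.9), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  expect_message(ds <- load_shift_dataset(path), "averaged")
  h1 <- ds$shifts[ds$shifts$nucleus == "H1", ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$shift_ppm, mean(c(3.60, 3.72)))
  # duplicate carbon rows remain an error
  rows2 <- rows
  rows2$nucleus <- "C13"
  rows2$atom_index <- 1L
  rows2$shift_ppm <- c(70, 71, 72)
  utils::write.csv(rows2, path, row.names = FALSE)
  expect_error(load_shift_dataset(path), "duplicate")
})

test_that("prediction tables round-trip at six decimals", {
  preds <- data.frame(
    molecule_id = c("a", "a"), atom_index = c(0L, 1L),
    nucleus = c("C13", "H1"),
    pred_mean_ppm = c(mean(c(1, 3)), 3.1234567),
    pred_std_ppm = c(sqrt(mean((c(1, 3) - 2)^2)), 0),
    n_conformers = c(2L, 2L), stringsAsFactors = FALSE)
  # population statistics of the {1, 3} ensemble
  expect_equal(preds$pred_mean_ppm[1], 2)
  expect_equal(preds$pred_std_ppm[1], 1)
  path <- tempfile(fileext = ".csv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back$pred_mean_ppm,
               round(preds$pred_mean_ppm, 6), tolerance = 1e-12)
  expect_equal(back$pred_std_ppm, round(preds$pred_std_ppm, 6),
               tolerance = 1e-12)
  # empty prediction set -> header-only file
  p2 <- tempfile(fileext = ".csv")
  write_predictions(preds[0, ], p2)
  expect_equal(nrow(read_predictions(p2)), 0L)
  expect_match(readLines(p2)[1], "molecule_id")
})
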
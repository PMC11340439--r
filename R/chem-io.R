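# Molecule and shift-table input/output.
#
# Molecules are represented over HEAVY atoms only: hydrogens are folded
# into a per-atom attached_h_count, following the network's graph
# representation. Atom indices are 0-based and frozen in the parser's
# atom order, so shift tables referencing atom_index are unambiguous.

BOND_CATEGORIES <- c("single", "double", "other")
SACCHARIDE_CLASSES <- c("mono", "di", "tri", "other")
NUCLEI <- c("C13", "H1")

#' Parse a SMILES string into a heavy-atom molecule record
#'
#' Hydrogens are folded into per-atom attached-hydrogen counts; heavy
#' atoms keep the parser's atom order (0-based indices). Bond orders are
#' mapped to the categories `single`, `double`, `other` (the last
#' absorbing aromatic, triple and any remaining order).
#'
#' @param smiles a single SMILES string.
#' @param molecule_id identifier stored on the record (defaults to the
#'   SMILES itself).
#' @param saccharide_class one of `"mono"`, `"di"`, `"tri"`, `"other"`.
#' @return an object of class `eqshift_molecule` with fields
#'   `molecule_id`, `smiles`, `atoms` (data frame: `index`, `element`,
#'   `attached_h_count`), `bonds` (data frame: `i`, `j`, `category`) and
#'   `saccharide_class`.
#' @examples
#' \dontrun{
#' mol <- parse_smiles("CO")
#' mol$atoms$attached_h_count  # 3 (CH3) and 1 (OH)
#' }
#' @export
parse_smiles <- function(smiles, molecule_id = smiles,
                         saccharide_class = "other") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  saccharide_class <- match.arg(saccharide_class, SACCHARIDE_CLASSES)
  raw <- bridge_parse(smiles)[[1]]
  new_molecule(molecule_id, smiles, raw, saccharide_class)
}

# Vectorised parse: one bridge call for many SMILES.
parse_smiles_many <- function(smiles, molecule_ids = smiles,
                              saccharide_classes =
                                rep("other", length(smiles))) {
  raws <- bridge_parse(smiles)
  Map(new_molecule, molecule_ids, smiles, raws, saccharide_classes)
}

new_molecule <- function(molecule_id, smiles, raw, saccharide_class) {
  atoms <- data.frame(
    index = seq_along(raw$atoms) - 1L,
    element = vapply(raw$atoms, `[[`, character(1), "element"),
    attached_h_count = vapply(raw$atoms, function(a)
      as.integer(a$attached_h_count), integer(1)),
    stringsAsFactors = FALSE
  )
  if (length(raw$bonds) > 0) {
    bonds <- data.frame(
      i = vapply(raw$bonds, function(b) as.integer(b$i), integer(1)),
      j = vapply(raw$bonds, function(b) as.integer(b$j), integer(1)),
      category = vapply(raw$bonds, `[[`, character(1), "category"),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        category = character(0), stringsAsFactors = FALSE)
  }
  mol <- structure(
    list(molecule_id = molecule_id, smiles = smiles, atoms = atoms,
         bonds = bonds, saccharide_class = saccharide_class),
    class = "eqshift_molecule"
  )
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  stopifnot(identical(mol$atoms$index, seq_len(n) - 1L))
  stopifnot(all(mol$atoms$attached_h_count >= 0L))
  if (nrow(mol$bonds) > 0) {
    ok <- mol$bonds$i >= 0 & mol$bonds$i < n &
      mol$bonds$j >= 0 & mol$bonds$j < n & mol$bonds$i != mol$bonds$j
    if (!all(ok)) stop("bond references invalid atom indices")
    stopifnot(all(mol$bonds$category %in% BOND_CATEGORIES))
  }
  invisible(mol)
}

#' @export
print.eqshift_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds, class %s>\n",
              x$molecule_id, nrow(x$atoms), nrow(x$bonds),
              x$saccharide_class))
  cat("  ", x$smiles, "\n", sep = "")
  invisible(x)
}

n_heavy <- function(mol) nrow(mol$atoms)

# ---- shift datasets ---------------------------------------------------

#' Construct a validated shift dataset
#'
#' @param molecules list of `eqshift_molecule` records.
#' @param shifts data frame with columns `molecule_id`, `atom_index`,
#'   `nucleus` (`"C13"` or `"H1"`), `shift_ppm`.
#' @param provenance free-text description of the data source.
#' @return an object of class `eqshift_dataset`.
#' @export
shift_dataset <- function(molecules, shifts, provenance = "") {
  names(molecules) <- vapply(molecules, `[[`, character(1), "molecule_id")
  if (anyDuplicated(names(molecules)))
    stop("duplicate molecule_id in dataset")
  shifts <- as.data.frame(shifts, stringsAsFactors = FALSE)
  shifts$atom_index <- as.integer(shifts$atom_index)
  ds <- structure(list(molecules = molecules, shifts = shifts,
                       provenance = provenance),
                  class = "eqshift_dataset")
  validate_dataset_internal(ds)
  ds
}

validate_dataset_internal <- function(ds) {
  sh <- ds$shifts
  stopifnot(all(c("molecule_id", "atom_index", "nucleus", "shift_ppm")
                %in% names(sh)))
  if (!all(sh$nucleus %in% NUCLEI))
    stop("nucleus must be one of: ", paste(NUCLEI, collapse = ", "))
  key <- paste(sh$molecule_id, sh$atom_index, sh$nucleus)
  if (anyDuplicated(key)) {
    stop("duplicate (molecule_id, atom_index, nucleus) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bad <- character(0)
  for (r in seq_len(nrow(sh))) {
    mol <- ds$molecules[[sh$molecule_id[r]]]
    if (is.null(mol)) {
      bad <- c(bad, sprintf("row %d: unknown molecule '%s'", r,
                            sh$molecule_id[r]))
      next
    }
    ai <- sh$atom_index[r]
    if (is.na(ai) || ai < 0 || ai >= n_heavy(mol)) {
      bad <- c(bad, sprintf("row %d: atom_index %s out of range for '%s'",
                            r, ai, sh$molecule_id[r]))
      next
    }
    el <- mol$atoms$element[ai + 1L]
    hc <- mol$atoms$attached_h_count[ai + 1L]
    if (sh$nucleus[r] == "C13" && el != "C") {
      bad <- c(bad, sprintf("row %d: C13 shift on non-carbon atom %d (%s)",
                            r, ai, el))
    }
    if (sh$nucleus[r] == "H1" && hc < 1) {
      bad <- c(bad, sprintf(
        "row %d: H1 shift on atom %d with no attached hydrogens", r, ai))
    }
    if (!is.finite(sh$shift_ppm[r]) || sh$shift_ppm[r] < 0 ||
        sh$shift_ppm[r] > 250) {
      bad <- c(bad, sprintf("row %d: shift %.3f ppm outside [0, 250]", r,
                            sh$shift_ppm[r]))
    }
  }
  if (length(bad) > 0) {
    stop("invalid shift records:\n  ", paste(bad, collapse = "\n  "))
  }
  invisible(ds)
}

#' @export
print.eqshift_dataset <- function(x, ...) {
  cls <- vapply(x$molecules, `[[`, character(1), "saccharide_class")
  cat(sprintf("<shift dataset: %d molecules, %d shifts>\n",
              length(x$molecules), nrow(x$shifts)))
  print(table(class = cls))
  print(table(nucleus = x$shifts$nucleus))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

dataset_schema <- c("molecule_id", "smiles", "saccharide_class",
                    "atom_index", "nucleus", "shift_ppm")

#' Load a shift dataset from CSV or JSON
#'
#' The flat schema has one row per shift: `molecule_id`, `smiles`,
#' `saccharide_class`, `atom_index` (0-based heavy-atom index in the
#' parser's atom order of `smiles`), `nucleus` (`C13`/`H1`),
#' `shift_ppm`. When a source lists several diastereotopic proton
#' values for one heavy atom (e.g. H6a/H6b of a CH2), the loader
#' averages them into the single `H1` record the model can supervise
#' and reports how many were merged; duplicate `C13` keys are
#' rejected.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default inferred from the
#'   extension.
#' @return an `eqshift_dataset`.
#' @export
load_shift_dataset <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  miss <- setdiff(dataset_schema, names(df))
  if (length(miss) > 0) {
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  }
  # diastereotopic protons: average duplicate H1 rows per heavy atom
  key <- paste(df$molecule_id, df$atom_index, df$nucleus)
  dup_h1 <- duplicated(key) & df$nucleus == "H1"
  if (any(dup_h1)) {
    merged <- unique(key[dup_h1])
    means <- tapply(df$shift_ppm, key, mean)
    df <- df[!dup_h1, , drop = FALSE]
    sel <- paste(df$molecule_id, df$atom_index, df$nucleus) %in% merged
    df$shift_ppm[sel] <-
      means[paste(df$molecule_id, df$atom_index,
                  df$nucleus)[sel]]
    message("averaged diastereotopic H1 values on ", length(merged),
            " heavy atom(s)")
  }
  first <- !duplicated(df$molecule_id)
  mols <- parse_smiles_many(df$smiles[first],
                            molecule_ids = df$molecule_id[first],
                            saccharide_classes =
                              df$saccharide_class[first])
  shift_dataset(mols,
                df[, c("molecule_id", "atom_index", "nucleus",
                       "shift_ppm")],
                provenance = path)
}

#' Write a shift dataset to CSV or JSON
#'
#' Inverse of [load_shift_dataset()]: writing then loading reproduces the
#' dataset (atom order is frozen by the stored SMILES).
#'
#' @param dataset an `eqshift_dataset`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_shift_dataset <- function(dataset, path, format = c("csv", "json")) {
  format <- match.arg(format)
  sh <- dataset$shifts
  mols <- dataset$molecules
  df <- data.frame(
    molecule_id = sh$molecule_id,
    smiles = vapply(sh$molecule_id, function(id) mols[[id]]$smiles,
                    character(1)),
    saccharide_class = vapply(sh$molecule_id, function(id)
      mols[[id]]$saccharide_class, character(1)),
    atom_index = sh$atom_index,
    nucleus = sh$nucleus,
    shift_ppm = sh$shift_ppm,
    stringsAsFactors = FALSE
  )
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, digits = NA)
  }
  invisible(path)
}

#' Print per-class molecule and shift counts with schema validation
#'
#' @param path path to a shift table (CSV or JSON).
#' @return the loaded dataset, invisibly.
#' @export
validate_shift_file <- function(path) {
  ds <- load_shift_dataset(path)
  print(ds)
  invisible(ds)
}

# ---- prediction tables ------------------------------------------------

#' Write ensemble shift predictions to CSV
#'
#' Columns: `molecule_id`, `atom_index`, `nucleus`, `pred_mean_ppm`,
#' `pred_std_ppm` (population standard deviation over the conformer
#' ensemble), `n_conformers`. Values round-trip at six decimals.
#'
#' @param preds a prediction data frame from [predict_ensemble()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  cols <- c("molecule_id", "atom_index", "nucleus", "pred_mean_ppm",
            "pred_std_ppm", "n_conformers")
  stopifnot(all(cols %in% names(preds)))
  df <- as.data.frame(preds)[, cols]
  df$pred_mean_ppm <- sprintf("%.6f", df$pred_mean_ppm)
  df$pred_std_ppm <- sprintf("%.6f", df$pred_std_ppm)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction CSV written by [write_predictions()]
#'
#' @param path CSV path.
#' @return a data frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$atom_index <- as.integer(df$atom_index)
  df
}
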
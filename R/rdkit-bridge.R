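# Subprocess bridge to RDKit (SMILES parsing, ETKDGv3 embedding, MMFF94
# energies). One python call handles a whole batch of molecules; parse
# results are memoised per session keyed by SMILES string.

.bridge_env <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "eqshift")
  if (!nzchar(path)) stop("rdkit_bridge.py not found in installed package")
  path
}

bridge_python <- function() {
  py <- Sys.getenv("EQSHIFT_PYTHON", unset = "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no 'python' interpreter found on PATH")
  py
}

bridge_call <- function(request) {
  req <- jsonlite::toJSON(request, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(bridge_python(),
                                  args = shQuote(bridge_script()),
                                  input = req, stdout = TRUE, stderr = ""))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit bridge failed (exit ", status, ")")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!is.null(res$error)) stop("RDKit bridge: ", res$error)
  res$results
}

#' Check that the RDKit bridge is available
#'
#' The package parses SMILES and embeds conformers through a `python`
#' interpreter with RDKit installed (found on the PATH, or named by the
#' `EQSHIFT_PYTHON` environment variable). This helper runs a round-trip
#' ping through that interpreter.
#'
#' @return `TRUE` invisibly if the bridge responds; otherwise an error.
#' @export
bridge_available <- function() {
  res <- bridge_call(list(op = "ping"))
  if (!identical(res, "pong")) stop("unexpected bridge response")
  invisible(TRUE)
}

# Parse a character vector of SMILES via one bridge call, with caching.
# Returns a list (one element per SMILES) of raw parse results.
bridge_parse <- function(smiles) {
  if (is.null(.bridge_env$parse_cache)) {
    .bridge_env$parse_cache <- new.env(parent = emptyenv())
  }
  cache <- .bridge_env$parse_cache
  missing <- unique(smiles[!vapply(smiles, function(s)
    !is.null(cache[[s]]), logical(1))])
  if (length(missing) > 0) {
    res <- bridge_call(list(op = "parse", smiles = as.list(missing)))
    for (k in seq_along(missing)) {
      if (!is.null(res[[k]]$error)) {
        stop("invalid SMILES input: ", res[[k]]$error)
      }
      cache[[missing[k]]] <- res[[k]]
    }
  }
  lapply(smiles, function(s) cache[[s]])
}

# Embed conformer candidates for a batch of molecules. `seeds` is one
# integer per molecule. Returns a list of list(coords = list of n x 3
# matrices, energies = numeric).
bridge_embed <- function(smiles, n_confs, seeds) {
  stopifnot(length(smiles) == length(seeds))
  mols <- Map(function(s, sd) list(smiles = s, seed = sd), smiles, seeds)
  res <- bridge_call(list(op = "embed", molecules = unname(mols),
                          n_confs = n_confs))
  lapply(seq_along(res), function(k) {
    r <- res[[k]]
    if (!is.null(r$error)) stop("conformer generation failed: ", r$error)
    coords <- lapply(r$coords, function(cf) {
      do.call(rbind, lapply(cf, as.numeric))
    })
    list(coords = coords, energies = as.numeric(unlist(r$energies)))
  })
}
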
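# Graph featurisation: radius-cutoff directed edges over heavy atoms,
# categorical node/edge indices, distances and unit direction vectors,
# and masked per-node shift targets.

ELEMENT_VOCAB_DEFAULT <- c("C", "N", "O", "S", "P", "F", "Cl")
HCOUNT_CAP_DEFAULT <- 4L

element_index <- function(elements, vocab = ELEMENT_VOCAB_DEFAULT) {
  idx <- match(elements, vocab)
  idx[is.na(idx)] <- length(vocab) + 1L
  idx
}

hcount_index <- function(hcounts, cap = HCOUNT_CAP_DEFAULT) {
  pmin(as.integer(hcounts), cap) + 1L
}

#' Build the model's graph sample from a molecule and one conformer
#'
#' Directed edges connect every bonded pair (keeping the bond category
#' whatever the distance) and every non-bonded pair closer than `r_cut`
#' (category `none`); both directions are present and self-edges never.
#' Each edge carries the Euclidean distance and the unit vector
#' `(r_i - r_j) / d_ij` pointing from the sending atom j to the
#' receiving atom i. Experimental shifts, when supplied, are scattered
#' onto the nodes with boolean masks.
#'
#' @param mol an `eqshift_molecule`.
#' @param conf a matching conformer (or bare n x 3 coordinate matrix).
#' @param targets optional data frame with columns `atom_index`,
#'   `nucleus`, `shift_ppm` for this molecule.
#' @param r_cut cutoff radius in Angstrom (default 6).
#' @param element_vocab,hcount_cap categorical vocabularies for the
#'   node embeddings.
#' @return an object of class `eqshift_graph`.
#' @export
build_graph <- function(mol, conf, targets = NULL, r_cut = 6.0,
                        element_vocab = ELEMENT_VOCAB_DEFAULT,
                        hcount_cap = HCOUNT_CAP_DEFAULT) {
  coords <- if (is.matrix(conf)) conf else conf$coords
  n <- n_heavy(mol)
  if (nrow(coords) != n) {
    stop("conformer has ", nrow(coords), " atoms but molecule has ", n)
  }
  D <- as.matrix(stats::dist(coords))
  bond_cat <- matrix(NA_character_, n, n)
  if (nrow(mol$bonds) > 0) {
    bi <- mol$bonds$i + 1L; bj <- mol$bonds$j + 1L
    bond_cat[cbind(bi, bj)] <- mol$bonds$category
    bond_cat[cbind(bj, bi)] <- mol$bonds$category
  }
  keep <- (D < r_cut | !is.na(bond_cat)) & upper.tri(D)
  pairs <- which(keep, arr.ind = TRUE)
  # both directions, deterministic order: all (dst < src) then mirrored
  dst <- unname(c(pairs[, 1], pairs[, 2]))
  src <- unname(c(pairs[, 2], pairs[, 1]))
  ord <- order(dst, src)
  dst <- dst[ord]; src <- src[ord]
  cat_chr <- bond_cat[cbind(dst, src)]
  cat_chr[is.na(cat_chr)] <- "none"
  edge_bond_idx <- match(cat_chr, c("none", BOND_CATEGORIES))
  d <- unname(D[cbind(dst, src)])
  unit <- unname(coords[dst, , drop = FALSE] -
                   coords[src, , drop = FALSE]) / d
  tc <- rep(NA_real_, n); th <- rep(NA_real_, n)
  if (!is.null(targets) && nrow(targets) > 0) {
    for (r in seq_len(nrow(targets))) {
      ai <- targets$atom_index[r] + 1L
      if (ai < 1 || ai > n) stop("target atom_index out of range")
      if (targets$nucleus[r] == "C13") tc[ai] <- targets$shift_ppm[r]
      else th[ai] <- targets$shift_ppm[r]
    }
  }
  structure(list(
    molecule_id = mol$molecule_id,
    saccharide_class = mol$saccharide_class,
    n_nodes = n,
    node_element_idx = element_index(mol$atoms$element, element_vocab),
    node_hcount_idx = hcount_index(mol$atoms$attached_h_count,
                                   hcount_cap),
    node_is_carbon = mol$atoms$element == "C",
    node_has_h = mol$atoms$attached_h_count >= 1L,
    edge_src = src, edge_dst = dst,
    edge_bond_idx = edge_bond_idx,
    edge_distance = d,
    edge_unit_vec = unit,
    target_c13 = tc, mask_c13 = !is.na(tc),
    target_h1 = th, mask_h1 = !is.na(th)
  ), class = "eqshift_graph")
}

#' @export
print.eqshift_graph <- function(x, ...) {
  cat(sprintf(
    "<graph %s: %d nodes, %d directed edges, %d C13 + %d H1 targets>\n",
    x$molecule_id, x$n_nodes, length(x$edge_src), sum(x$mask_c13),
    sum(x$mask_h1)))
  invisible(x)
}

#' Concatenate graph samples into one batched sample
#'
#' Node and edge arrays are concatenated with per-sample node offsets;
#' per-node sample ids are retained so [unbatch_graphs()] is an exact
#' inverse.
#'
#' @param samples non-empty list of `eqshift_graph` objects.
#' @return an `eqshift_graph` with extra fields `graph_id` (per node)
#'   and `sample_ids`.
#' @export
assemble_batch <- function(samples) {
  if (length(samples) == 0) stop("cannot batch an empty sample list")
  ns <- vapply(samples, `[[`, integer(1), "n_nodes")
  offs <- cumsum(c(0L, ns))[seq_along(samples)]
  comb <- function(f) unlist(lapply(samples, `[[`, f), use.names = FALSE)
  structure(list(
    molecule_id = vapply(samples, `[[`, character(1), "molecule_id"),
    saccharide_class = vapply(samples, `[[`, character(1),
                              "saccharide_class"),
    n_nodes = sum(ns),
    n_nodes_per_sample = ns,
    node_element_idx = comb("node_element_idx"),
    node_hcount_idx = comb("node_hcount_idx"),
    node_is_carbon = comb("node_is_carbon"),
    node_has_h = comb("node_has_h"),
    edge_src = unlist(Map(function(s, o) s$edge_src + o, samples, offs)),
    edge_dst = unlist(Map(function(s, o) s$edge_dst + o, samples, offs)),
    edge_bond_idx = comb("edge_bond_idx"),
    edge_distance = comb("edge_distance"),
    edge_unit_vec = do.call(rbind, lapply(samples, `[[`,
                                          "edge_unit_vec")),
    target_c13 = comb("target_c13"), mask_c13 = comb("mask_c13"),
    target_h1 = comb("target_h1"), mask_h1 = comb("mask_h1"),
    graph_id = rep(seq_along(samples), ns),
    node_offset = offs
  ), class = c("eqshift_graph_batch", "eqshift_graph"))
}

#' Split a batched sample back into its component graphs
#'
#' Reconstructs each component graph from the concatenated arrays (it
#' does not keep the inputs around), so the round trip genuinely
#' exercises the offset bookkeeping.
#'
#' @param batch an `eqshift_graph_batch` from [assemble_batch()].
#' @return list of `eqshift_graph` objects equal to the batched inputs.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "eqshift_graph_batch"))
  ns <- batch$n_nodes_per_sample
  offs <- batch$node_offset
  edge_gid <- batch$graph_id[batch$edge_dst]
  lapply(seq_along(ns), function(k) {
    nodes <- offs[k] + seq_len(ns[k])
    er <- which(edge_gid == k)
    structure(list(
      molecule_id = batch$molecule_id[k],
      saccharide_class = batch$saccharide_class[k],
      n_nodes = ns[k],
      node_element_idx = batch$node_element_idx[nodes],
      node_hcount_idx = batch$node_hcount_idx[nodes],
      node_is_carbon = batch$node_is_carbon[nodes],
      node_has_h = batch$node_has_h[nodes],
      edge_src = batch$edge_src[er] - offs[k],
      edge_dst = batch$edge_dst[er] - offs[k],
      edge_bond_idx = batch$edge_bond_idx[er],
      edge_distance = batch$edge_distance[er],
      edge_unit_vec = batch$edge_unit_vec[er, , drop = FALSE],
      target_c13 = batch$target_c13[nodes],
      mask_c13 = batch$mask_c13[nodes],
      target_h1 = batch$target_h1[nodes],
      mask_h1 = batch$mask_h1[nodes]
    ), class = "eqshift_graph")
  })
}
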
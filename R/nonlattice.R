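# Non-lattice subgraph extraction and candidate pair generation.
#
# A pair of concepts is non-lattice when it has two or more maximal common
# descendants; such fragments of the hierarchy concentrate modeling defects,
# and the hierarchically-unrelated concept pairs inside them are the
# candidate pool for missing IS-A detection.

#' Maximal common descendants of two concepts
#'
#' The common descendants of `a` and `b` (descendant-OR-self semantics: a
#' concept is a common descendant of itself and any of its ancestors),
#' filtered to the maximal ones — those not properly descended from another
#' common descendant of the pair.
#'
#' @inheritParams ancestors
#' @param a,b distinct concept ids.
#' @return Sorted character vector of concept ids.
#' @export
maximal_common_descendants <- function(ontology, a, b) {
  .check_id(ontology, c(a, b))
  if (a == b) stop("a and b must be distinct concepts")
  m <- .anc_matrix(ontology)
  common <- rownames(m)[m[, a] & m[, b]]
  .maximal_of(m, common)
}

# elements of `set` not properly descended from another element
.maximal_of <- function(anc, set) {
  if (length(set) <= 1) return(sort(set))
  sub <- anc[set, set, drop = FALSE]
  diag(sub) <- FALSE
  sort(set[!apply(sub, 1, any)])
}

# elements of `set` with no other element properly descended from them
.minimal_of <- function(anc, set) {
  if (length(set) <= 1) return(sort(set))
  sub <- anc[set, set, drop = FALSE]
  diag(sub) <- FALSE
  sort(set[!apply(sub, 2, any)])
}

#' Minimal common ancestors of a set of concepts
#'
#' The dual of [maximal_common_descendants()]: ancestors-or-self of every
#' member of `concept_set`, filtered to those with no other common ancestor
#' properly below them.
#'
#' @inheritParams ancestors
#' @param concept_set non-empty character vector of concept ids.
#' @return Sorted character vector of concept ids.
#' @export
minimal_common_ancestors <- function(ontology, concept_set) {
  if (!length(concept_set)) stop("concept_set must be non-empty")
  .check_id(ontology, concept_set)
  m <- .anc_matrix(ontology)
  keep <- rep(TRUE, ncol(m))
  for (s in concept_set) keep <- keep & m[s, ]
  .minimal_of(m, colnames(m)[keep])
}

#' Find all non-lattice pairs of an ontology
#'
#' Enumerates every unordered concept pair sharing two or more maximal
#' common descendants. A tree-shaped hierarchy has none; any pair related
#' by ancestry has exactly one maximal common descendant (the lower
#' concept) and is never non-lattice.
#'
#' @inheritParams ancestors
#' @return data.frame with columns `a`, `b` (lexicographically ordered
#'   within each row, rows sorted), one row per non-lattice pair, plus a
#'   `n_mcds` column.
#' @export
find_nonlattice_pairs <- function(ontology) {
  m <- .anc_matrix(ontology)
  ids <- rownames(m)
  empty <- data.frame(a = character(), b = character(), n_mcds = integer())
  if (length(ids) < 2 || !nrow(ontology$isa)) return(empty)
  # candidate pairs must share >= 2 common descendants at all
  d <- matrix(as.numeric(m), nrow(m))  # d[i, j]: i descendant-or-self of j
  counts <- crossprod(d)               # common-descendant counts per pair
  idx <- which(upper.tri(counts) & counts >= 2, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    a <- ids[idx[k, 1]]; b <- ids[idx[k, 2]]
    if (m[a, b] || m[b, a]) return(NULL)  # related pairs are never non-lattice
    mcds <- .maximal_of(m, ids[m[, a] & m[, b]])
    if (length(mcds) < 2) return(NULL)
    pr <- sort(c(a, b))
    data.frame(a = pr[1], b = pr[2], n_mcds = length(mcds))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the non-lattice subgraph of a non-lattice pair
#'
#' The subgraph aggregates everything "between" the pair's maximal common
#' descendants and their minimal common ancestors: nodes are the concepts
#' lying on some directed child-to-parent path from an MCD up to an MCA
#' (equivalently, descendants-or-self of some MCA that are also
#' ancestors-or-self of some MCD); edges are the IS-A edges with both
#' endpoints inside.
#'
#' @inheritParams ancestors
#' @param a,b the non-lattice pair.
#' @return Object of class `nonlattice_subgraph`: list with `pair`, `id`
#'   (canonical `"a|b"` identifier), `mcds`, `mcas`, `nodes`, `edges`.
#' @export
build_nonlattice_subgraph <- function(ontology, a, b) {
  mcds <- maximal_common_descendants(ontology, a, b)
  if (length(mcds) < 2)
    stop("(", a, ", ", b, ") is not a non-lattice pair")
  mcas <- minimal_common_ancestors(ontology, mcds)
  m <- .anc_matrix(ontology)
  ids <- rownames(m)
  below_mca <- rep(FALSE, length(ids))
  for (x in mcas) below_mca <- below_mca | m[, x]
  above_mcd <- rep(FALSE, length(ids))
  for (x in mcds) above_mcd <- above_mcd | m[x, ]
  nodes <- sort(ids[below_mca & above_mcd])
  edges <- ontology$isa[ontology$isa$child %in% nodes &
                          ontology$isa$parent %in% nodes, , drop = FALSE]
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  pr <- sort(c(a, b))
  structure(list(pair = pr, id = paste(pr, collapse = "|"),
                 mcds = mcds, mcas = mcas, nodes = nodes, edges = edges),
            class = "nonlattice_subgraph")
}

#' @export
print.nonlattice_subgraph <- function(x, ...) {
  cat(sprintf("<nonlattice_subgraph> pair (%s, %s): %d MCDs, %d MCAs, %d nodes, %d edges\n",
              x$pair[1], x$pair[2], length(x$mcds), length(x$mcas),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract all non-lattice subgraphs of an ontology
#'
#' @inheritParams ancestors
#' @return List of [build_nonlattice_subgraph()] objects, named by
#'   subgraph id.
#' @export
nonlattice_subgraphs <- function(ontology) {
  pairs <- find_nonlattice_pairs(ontology)
  out <- lapply(seq_len(nrow(pairs)), function(i)
    build_nonlattice_subgraph(ontology, pairs$a[i], pairs$b[i]))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Candidate concept pairs from non-lattice subgraphs
#'
#' Within each subgraph, every unordered node pair not linked by ancestry
#' in either direction is a candidate for a missing IS-A relation.
#' Candidates found in several subgraphs are de-duplicated, with
#' `source_subgraphs` recording provenance.
#'
#' @inheritParams ancestors
#' @param subgraphs list of subgraphs from [nonlattice_subgraphs()].
#' @return data.frame with columns `x`, `y` (lexicographically ordered,
#'   rows sorted) and list-column `source_subgraphs`.
#' @export
candidate_pairs <- function(ontology, subgraphs) {
  m <- .anc_matrix(ontology)
  xs <- ys <- ids <- list()
  for (sg in subgraphs) {
    nodes <- sg$nodes   # sorted, so row < col gives canonical pair order
    if (length(nodes) < 2) next
    rel <- m[nodes, nodes, drop = FALSE]
    rel <- rel | t(rel)
    hit <- which(upper.tri(rel) & !rel, arr.ind = TRUE)
    if (!nrow(hit)) next
    k <- length(xs) + 1
    xs[[k]] <- nodes[hit[, 1]]
    ys[[k]] <- nodes[hit[, 2]]
    ids[[k]] <- rep(sg$id, nrow(hit))
  }
  xs <- unlist(xs); ys <- unlist(ys); ids <- unlist(ids)
  if (!length(xs))
    return(data.frame(x = character(), y = character(),
                      source_subgraphs = I(list()), stringsAsFactors = FALSE))
  key <- paste(xs, ys, sep = "|")
  prov <- lapply(split(ids, key), function(v) sort(unique(v)))
  keys <- sort(names(prov))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    x = vapply(parts, `[`, "", 1),
    y = vapply(parts, `[`, "", 2),
    source_subgraphs = I(unname(prov[keys])),
    stringsAsFactors = FALSE)
}

#' Export non-lattice subgraphs
#'
#' Writes one JSON document per subgraph (`pair`, `mcds`, `mcas`, `nodes`,
#' `edges`) plus a summary TSV (`pair_a`, `pair_b`, `n_mcds`, `n_nodes`,
#' `n_edges`).
#'
#' @param subgraphs list from [nonlattice_subgraphs()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_subgraphs <- function(subgraphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sg in subgraphs) {
    jsonlite::write_json(
      list(pair = sg$pair, mcds = sg$mcds, mcas = sg$mcas,
           nodes = sg$nodes, edges = sg$edges),
      file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", sg$id), ".json")),
      pretty = TRUE)
  }
  summary <- data.frame(
    pair_a = vapply(subgraphs, function(s) s$pair[1], ""),
    pair_b = vapply(subgraphs, function(s) s$pair[2], ""),
    n_mcds = vapply(subgraphs, function(s) length(s$mcds), 0L),
    n_nodes = vapply(subgraphs, function(s) length(s$nodes), 0L),
    n_edges = vapply(subgraphs, function(s) nrow(s$edges), 0L))
  write.table(summary, file.path(dir, "subgraphs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
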
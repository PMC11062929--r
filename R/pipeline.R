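# End-to-end missing IS-A suggestion pipeline:
# non-lattice extraction -> candidate pairs -> logical + lexical screening
# (with the primitive-supertype and attribute-relation filters) ->
# cycle removal -> redundancy removal.

#' Pipeline configuration
#'
#' @param require_primitive_supertype only suggest supertypes whose
#'   definition status is primitive. In an inferred release a fully defined
#'   supertype with a more-specific subtype would already have the edge, so
#'   valid missing relations hide under primitive supertypes.
#' @param require_attribute_relation only suggest supertypes whose
#'   definition carries at least one (non-IS-A) attribute relation;
#'   IS-A-only definitions are too weak to anchor the comparison.
#' @param chain_value_subtype_allowed see [relation_more_specific()].
#' @param provider a [lexical_provider()] or a provider identifier string.
#' @param injective_group_matching see [definition_more_specific()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(require_primitive_supertype = TRUE,
                            require_attribute_relation = TRUE,
                            chain_value_subtype_allowed = FALSE,
                            provider = "rulebased",
                            injective_group_matching = FALSE) {
  if (!inherits(provider, "lexical_provider"))
    provider <- lexical_provider(provider)
  structure(list(require_primitive_supertype = require_primitive_supertype,
                 require_attribute_relation = require_attribute_relation,
                 chain_value_subtype_allowed = chain_value_subtype_allowed,
                 provider = provider,
                 injective_group_matching = injective_group_matching),
            class = "pipeline_config")
}

.empty_suggestions <- function() {
  data.frame(child = character(), parent = character(),
             child_name = character(), parent_name = character(),
             status = character(), rule_summary = character(),
             lexical_margin = integer(),
             source_subgraphs = I(list()), logical = I(list()),
             stringsAsFactors = FALSE)
}

#' Evaluate one candidate pair
#'
#' Tests both orientations of an unordered, hierarchically-unrelated
#' candidate pair. An orientation (child `X`, parent `Y`) yields a
#' suggestion iff (a) the configured supertype filters pass for `Y`
#' (primitive status; at least one attribute relation), (b) `X`'s inferred
#' definition is more specific than `Y`'s at relation-group level, and (c)
#' `X`'s enriched lexical feature set is a superset of `Y`'s.
#'
#' @inheritParams ancestors
#' @param x,y the unordered candidate pair.
#' @param config a [pipeline_config()].
#' @param source_subgraphs provenance: ids of the non-lattice subgraphs
#'   the pair was drawn from.
#' @return Suggestion data.frame with 0, 1 or 2 rows (columns `child`,
#'   `parent`, `child_name`, `parent_name`, `status`, `rule_summary`,
#'   `lexical_margin`, and list-columns `source_subgraphs`, `logical`).
#' @export
evaluate_pair <- function(ontology, x, y, config = pipeline_config(),
                          source_subgraphs = character()) {
  .check_id(ontology, c(x, y))
  m <- .anc_matrix(ontology)
  if (m[x, y] || m[y, x])
    stop("candidate pair (", x, ", ", y, ") is hierarchically related")
  out <- .empty_suggestions()
  for (dir in list(c(x, y), c(y, x))) {
    s <- .evaluate_direction(ontology, dir[1], dir[2], config, source_subgraphs)
    if (!is.null(s)) out <- rbind(out, s)
  }
  out
}

.evaluate_direction <- function(ontology, child, parent, config,
                                source_subgraphs) {
  cn <- setNames(ontology$concepts$name, ontology$concepts$id)
  if (config$require_primitive_supertype &&
      ontology$concepts$definition_status[ontology$concepts$id == parent] !=
        "primitive")
    return(NULL)
  Iy <- inferred_definition(ontology, parent)
  if (config$require_attribute_relation && !has_attribute_relation(Iy))
    return(NULL)
  Ix <- inferred_definition(ontology, child)
  ev <- definition_more_specific(
    ontology, Ix, Iy,
    chain_value_subtype_allowed = config$chain_value_subtype_allowed,
    injective_group_matching = config$injective_group_matching)
  if (!ev$holds) return(NULL)
  cs <- enriched_feature_set(ontology, child, config$provider)
  ps <- enriched_feature_set(ontology, parent, config$provider)
  if (!lexical_subsumes(cs, ps)) return(NULL)
  data.frame(child = child, parent = parent,
             child_name = unname(cn[child]), parent_name = unname(cn[parent]),
             status = "kept", rule_summary = .rule_summary(ev),
             lexical_margin = length(setdiff(cs, ps)),
             source_subgraphs = I(list(sort(source_subgraphs))),
             logical = I(list(ev)),
             stringsAsFactors = FALSE)
}

#' Remove cycle-causing suggestions
#'
#' Marks `removed_cycle` every suggestion lying on a directed cycle of the
#' graph formed by the existing IS-A edges plus the whole suggestion set:
#' mutually-suggested pairs knock each other out, and a suggestion
#' contradicting an existing path is removed.
#'
#' @inheritParams ancestors
#' @param suggestions suggestion data.frame (see [evaluate_pair()]).
#' @return The data.frame with `status` updated.
#' @export
remove_cycle_causing <- function(ontology, suggestions) {
  live <- which(suggestions$status == "kept")
  if (!length(live)) return(suggestions)
  edges <- rbind(ontology$isa[, c("child", "parent")],
                 data.frame(child = suggestions$child[live],
                            parent = suggestions$parent[live]))
  verts <- unique(c(edges$child, edges$parent))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = verts))
  memb <- igraph::components(g, mode = "strong")$membership
  on_cycle <- memb[suggestions$child[live]] == memb[suggestions$parent[live]]
  suggestions$status[live[on_cycle]] <- "removed_cycle"
  suggestions
}

#' Remove redundant suggestions
#'
#' A suggestion is redundant when it is derivable by transitive
#' reachability from the existing IS-A edges together with all the other
#' kept suggestions. Suggestions are examined in sorted `(child, parent)`
#' order and the pass repeats to a fixed point, which makes the result
#' deterministic even when suggestions mutually imply each other.
#' Cycle-causing suggestions must have been removed first: edges on a
#' cycle would make one another trivially derivable.
#'
#' @inheritParams remove_cycle_causing
#' @return The data.frame with `status` updated.
#' @export
remove_redundant <- function(ontology, suggestions) {
  ord <- order(suggestions$child, suggestions$parent)
  repeat {
    live <- intersect(ord, which(suggestions$status == "kept"))
    changed <- FALSE
    for (i in live) {
      others <- setdiff(which(suggestions$status == "kept"), i)
      edges <- rbind(ontology$isa[, c("child", "parent")],
                     data.frame(child = suggestions$child[others],
                                parent = suggestions$parent[others]))
      if (.reaches(edges, suggestions$child[i], suggestions$parent[i])) {
        suggestions$status[i] <- "removed_redundant"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  suggestions
}

# is `to` reachable from `from` following child->parent edges?
.reaches <- function(edges, from, to) {
  frontier <- from
  seen <- character(0)
  adj <- split(edges$parent, edges$child)
  while (length(frontier)) {
    if (to %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
  }
  FALSE
}

#' Detect potentially missing IS-A relations
#'
#' Runs the full pipeline over an ontology: extract non-lattice subgraphs,
#' generate hierarchically-unrelated candidate pairs inside them, screen
#' each orientation by logical-definition and lexical subsumption, then
#' discard cycle-causing and redundant suggestions.
#'
#' @inheritParams ancestors
#' @param config a [pipeline_config()].
#' @return Object of class `isa_report`: list with `suggestions` (the full
#'   suggestion data.frame, statuses included), `kept` (the surviving
#'   rows), `counts` (per-stage counts) and `config`.
#' @export
find_missing_isa <- function(ontology, config = pipeline_config()) {
  subgraphs <- nonlattice_subgraphs(ontology)
  cands <- candidate_pairs(ontology, subgraphs)
  # cheap vectorized version of the supertype filters, to skip candidates
  # where neither orientation can pass them
  ids <- ontology$concepts$id
  viable <- rep(TRUE, length(ids))
  if (config$require_primitive_supertype)
    viable <- viable & ontology$concepts$definition_status == "primitive"
  if (config$require_attribute_relation)
    viable <- viable & ids %in% ontology$attributes$source
  viable <- setNames(viable, ids)
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    x <- cands$x[i]; y <- cands$y[i]
    if (!viable[x] && !viable[y]) next
    rows[[length(rows) + 1]] <-
      evaluate_pair(ontology, x, y, config, cands$source_subgraphs[[i]])
  }
  sug <- do.call(rbind, c(list(.empty_suggestions()), rows))
  sug <- sug[order(sug$child, sug$parent), , drop = FALSE]
  rownames(sug) <- NULL
  n_raw <- nrow(sug)
  sug <- remove_cycle_causing(ontology, sug)
  sug <- remove_redundant(ontology, sug)
  counts <- c(subgraphs = length(subgraphs),
              candidates = nrow(cands),
              raw_suggestions = n_raw,
              removed_cycle = sum(sug$status == "removed_cycle"),
              removed_redundant = sum(sug$status == "removed_redundant"),
              kept = sum(sug$status == "kept"))
  structure(list(suggestions = sug,
                 kept = sug[sug$status == "kept", , drop = FALSE],
                 counts = counts, config = config),
            class = "isa_report")
}

#' @export
print.isa_report <- function(x, ...) {
  cat("<isa_report>\n")
  cat(sprintf("  non-lattice subgraphs : %d\n", x$counts[["subgraphs"]]))
  cat(sprintf("  candidate pairs       : %d\n", x$counts[["candidates"]]))
  cat(sprintf("  raw suggestions       : %d\n", x$counts[["raw_suggestions"]]))
  cat(sprintf("  removed (cycle)       : %d\n", x$counts[["removed_cycle"]]))
  cat(sprintf("  removed (redundant)   : %d\n", x$counts[["removed_redundant"]]))
  cat(sprintf("  kept                  : %d\n", x$counts[["kept"]]))
  invisible(x)
}

#' @export
summary.isa_report <- function(object, ...) {
  print(object)
  k <- object$kept
  for (i in seq_len(nrow(k))) {
    cat(sprintf("  %s IS-A %s  [%s, lexical margin %d]\n",
                k$child_name[i], k$parent_name[i],
                k$rule_summary[i], k$lexical_margin[i]))
  }
  invisible(object)
}

#' Write suggestions as a TSV
#'
#' One row per suggestion (kept and removed), sorted by child then parent
#' id, with the logical evidence serialized as JSON. Output is
#' byte-identical across reruns on identical inputs.
#'
#' @param report an `isa_report` from [find_missing_isa()], or a
#'   suggestion data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_suggestions <- function(report, path) {
  sug <- if (inherits(report, "isa_report")) report$suggestions else report
  sug <- sug[order(sug$child, sug$parent), , drop = FALSE]
  out <- data.frame(
    child_id = sug$child, child_name = sug$child_name,
    parent_id = sug$parent, parent_name = sug$parent_name,
    status = sug$status, rule_summary = sug$rule_summary,
    lexical_margin = sug$lexical_margin,
    source_subgraphs = vapply(sug$source_subgraphs, paste, "", collapse = ","),
    logical_evidence = vapply(sug$logical, function(e)
      as.character(.evidence_json(e)), ""),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
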
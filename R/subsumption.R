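# Relation-group-level logical subsumption.
#
# A concept X is more specific than Y in logical definitions when every
# relation group of Y has a corresponding group of X that is more specific;
# a group is more specific when every relation of the supertype group has a
# corresponding more-specific relation in the subtype group. Two rules
# decide relation-level specificity: the inclusion rule (attribute and
# value each the same or a descendant) and the property-chain rule (the
# subtype value reaches the supertype value through an intermediate
# attribute licensed by a chain axiom, e.g. Causative agent o
# Is modification of -> Causative agent).

#' Compare two defining relations
#'
#' Decides whether relation `rx` is more specific than relation `ry`.
#' The inclusion rule is tried first; on failure the property-chain rule is
#' tried. IS-A relations only ever compare against IS-A relations (the
#' hierarchy is structural, not part of the attribute model).
#'
#' @inheritParams ancestors
#' @param rx,ry [defining_relation()]s (attribute/value id pairs).
#' @param chain_value_subtype_allowed if `TRUE`, the chain rule accepts an
#'   intermediate relation whose value is a descendant of `ry`'s value; by
#'   default the value must match exactly.
#' @return `"inclusion"` or `"chain"` naming the first rule that succeeds,
#'   or `NULL` if neither holds.
#' @export
relation_more_specific <- function(ontology, rx, ry,
                                   chain_value_subtype_allowed = FALSE) {
  .check_id(ontology, c(rx$attribute, rx$value, ry$attribute, ry$value))
  isa_id <- ontology$isa_attribute_id
  x_isa <- rx$attribute == isa_id
  y_isa <- ry$attribute == isa_id
  if (x_isa || y_isa) {
    # IS-A matches IS-A and nothing else
    if (x_isa && y_isa && is_subsumed_by(ontology, rx$value, ry$value))
      return("inclusion")
    return(NULL)
  }
  if (is_subsumed_by(ontology, rx$attribute, ry$attribute) &&
      is_subsumed_by(ontology, rx$value, ry$value))
    return("inclusion")

  ch <- ontology$chains
  if (nrow(ch)) {
    for (i in seq_len(nrow(ch))) {
      # chain applicable when its super-attribute is ry's attribute or a
      # descendant of it, and rx's attribute falls under the leading one
      if (!is_subsumed_by(ontology, ch$super[i], ry$attribute)) next
      if (!is_subsumed_by(ontology, rx$attribute, ch$leading[i])) next
      at <- ontology$attributes
      linked <- at[at$source == rx$value & at$attribute == ch$intermediate[i], ,
                   drop = FALSE]
      if (!nrow(linked)) next
      ok <- if (chain_value_subtype_allowed) {
        any(vapply(linked$value, function(v)
          is_subsumed_by(ontology, v, ry$value), TRUE))
      } else {
        ry$value %in% linked$value
      }
      if (ok) return("chain")
    }
  }
  NULL
}

#' Compare two relation groups
#'
#' Group `gx` is more specific than group `gy` when every relation of `gy`
#' has at least one more-specific relation in `gx` (existential,
#' non-injective matching). Returns the per-relation match records, or
#' `NULL` on failure.
#'
#' @inheritParams relation_more_specific
#' @param gx,gy relation groups as produced by [inferred_definition()]
#'   (lists with a `relations` element), or bare lists of
#'   [defining_relation()]s.
#' @return `NULL`, or a list of records `list(supertype_relation,
#'   subtype_relation, rule)`.
#' @export
group_more_specific <- function(ontology, gx, gy,
                                chain_value_subtype_allowed = FALSE) {
  rx_list <- if (!is.null(gx$relations)) gx$relations else gx
  ry_list <- if (!is.null(gy$relations)) gy$relations else gy
  matches <- vector("list", length(ry_list))
  for (j in seq_along(ry_list)) {
    found <- NULL
    for (rx in rx_list) {
      rule <- relation_more_specific(ontology, rx, ry_list[[j]],
                                     chain_value_subtype_allowed)
      if (!is.null(rule)) {
        found <- list(supertype_relation = ry_list[[j]],
                      subtype_relation = rx, rule = rule)
        break
      }
    }
    if (is.null(found)) return(NULL)
    matches[[j]] <- found
  }
  matches
}

#' Compare two inferred definitions
#'
#' Definition `Ix` is more specific than `Iy` when every relation group of
#' `Iy` is matched by some group of `Ix` that is more specific than it.
#' By default the matching is existential and non-injective: one subtype
#' group may witness several supertype groups. With
#' `injective_group_matching = TRUE`, distinct supertype groups must be
#' matched by distinct subtype groups (decided by exhaustive search; group
#' counts are small in practice).
#'
#' @inheritParams relation_more_specific
#' @param Ix,Iy [inferred_definition()]s over the same ontology (`Ix` the
#'   would-be subtype).
#' @param injective_group_matching require a one-to-one group matching.
#' @return Object of class `logical_evidence`: list with `holds` (logical),
#'   `group_matching` (supertype group index -> subtype group index) and
#'   `relation_matches` (per supertype group, the relation match records).
#' @export
definition_more_specific <- function(ontology, Ix, Iy,
                                     chain_value_subtype_allowed = FALSE,
                                     injective_group_matching = FALSE) {
  ny <- length(Iy$groups)
  nx <- length(Ix$groups)
  # cands[[m]]: subtype group indices able to serve supertype group m
  cands <- vector("list", ny)
  rel_matches <- vector("list", ny)
  for (m in seq_len(ny)) {
    for (n in seq_len(nx)) {
      res <- group_more_specific(ontology, Ix$groups[[n]], Iy$groups[[m]],
                                 chain_value_subtype_allowed)
      if (!is.null(res)) {
        cands[[m]] <- c(cands[[m]], n)
        if (is.null(rel_matches[[m]])) rel_matches[[m]] <- list()
        rel_matches[[m]][[as.character(n)]] <- res
      }
    }
  }
  failed <- structure(list(holds = FALSE, group_matching = integer(0),
                           relation_matches = list()),
                      class = "logical_evidence")
  if (any(vapply(cands, is.null, TRUE)) && ny > 0) return(failed)

  if (!injective_group_matching || ny == 0) {
    matching <- vapply(cands, function(v) if (length(v)) v[1] else NA_integer_, 0L)
  } else {
    matching <- .injective_assignment(cands)
    if (is.null(matching)) return(failed)
  }
  names(matching) <- as.character(seq_len(ny))
  structure(list(
    holds = TRUE,
    group_matching = matching,
    relation_matches = lapply(seq_len(ny), function(m)
      rel_matches[[m]][[as.character(matching[m])]])),
    class = "logical_evidence")
}

# backtracking search for a system of distinct representatives
.injective_assignment <- function(cands, used = integer(0)) {
  if (!length(cands)) return(integer(0))
  for (n in cands[[1]]) {
    if (n %in% used) next
    rest <- .injective_assignment(cands[-1], c(used, n))
    if (!is.null(rest)) return(c(n, rest))
  }
  NULL
}

#' @export
print.logical_evidence <- function(x, ...) {
  if (!x$holds) {
    cat("<logical_evidence> does not hold\n")
    return(invisible(x))
  }
  cat("<logical_evidence> holds; group matching (supertype -> subtype):",
      paste(sprintf("%s->%d", names(x$group_matching), x$group_matching),
            collapse = ", "), "\n")
  invisible(x)
}

# compact serialization for the suggestions TSV
.evidence_json <- function(ev) {
  rules <- lapply(ev$relation_matches, function(grp)
    lapply(grp, function(r) list(
      supertype = c(r$supertype_relation$attribute, r$supertype_relation$value),
      subtype = c(r$subtype_relation$attribute, r$subtype_relation$value),
      rule = r$rule)))
  jsonlite::toJSON(list(holds = ev$holds,
                        group_matching = as.list(ev$group_matching),
                        relation_matches = rules),
                   auto_unbox = TRUE)
}

.rule_summary <- function(ev) {
  rules <- unlist(lapply(ev$relation_matches, function(grp)
    vapply(grp, `[[`, "", "rule")))
  if (!length(rules)) return("none")
  paste(sort(unique(rules)), collapse = "+")
}
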
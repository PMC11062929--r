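#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# SNOMED CT RF2 metadata identifiers used by the snapshot reader.
.rf2 <- list(
  isa_type          = "116680003",
  fsn_type          = "900000000000003001",
  inferred          = "900000000000011006",
  fully_defined     = "900000000000073002",
  primitive         = "900000000000074008"
)

#' Construct a terminology ontology
#'
#' An `ontology` is the universe every other operation in the package
#' queries: a set of concepts, a directed acyclic IS-A hierarchy
#' (child -> parent edges), grouped attribute relations, and property-chain
#' axioms. Hierarchical relations are represented uniformly with a reserved
#' IS-A attribute identifier (SNOMED CT's `116680003` by default); they live
#' in the `isa` table, never in the `attributes` table.
#'
#' @param concepts data.frame with columns `id`, `name`, and optionally
#'   `definition_status` (`"primitive"` or `"fully_defined"`, default
#'   primitive) and `active` (logical, default `TRUE`). Inactive concepts
#'   are dropped together with any relations that mention them.
#' @param isa data.frame with columns `child`, `parent`, or `NULL` for an
#'   edgeless hierarchy.
#' @param attributes data.frame with columns `source`, `group_index`,
#'   `attribute`, `value` holding grouped non-IS-A defining relations, or
#'   `NULL`. A missing/NA `group_index` column assigns every relation its
#'   own singleton group (the convention used for terminologies that do not
#'   group relations, such as the NCI thesaurus).
#' @param chains data.frame with columns `leading`, `intermediate`, `super`:
#'   property-chain axioms "leading o intermediate is a sub-property of
#'   super", or `NULL`. Transitive attributes are expressed as
#'   `k o k -> k` rows.
#' @param isa_attribute_id reserved concept id that stands for the IS-A
#'   attribute.
#' @return An object of class `ontology`.
#' @examples
#' ont <- ontology(
#'   concepts = data.frame(id = c("a", "b", "116680003"),
#'                         name = c("Alpha (finding)", "Beta (finding)",
#'                                  "Is a (attribute)")),
#'   isa = data.frame(child = "a", parent = "b")
#' )
#' ancestors(ont, "a")
#' @export
ontology <- function(concepts, isa = NULL, attributes = NULL, chains = NULL,
                     isa_attribute_id = "116680003") {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(concepts)))
    stop("`concepts` needs columns `id` and `name`")
  concepts$id <- as.character(concepts$id)
  concepts$name <- as.character(concepts$name)
  if (is.null(concepts$definition_status)) concepts$definition_status <- "primitive"
  concepts$definition_status <- as.character(concepts$definition_status)
  if (is.null(concepts$active)) concepts$active <- TRUE
  if (is.character(concepts$active))
    concepts$active <- concepts$active %in% c("1", "true", "TRUE")
  inactive <- concepts$id[!concepts$active]
  concepts <- concepts[concepts$active, c("id", "name", "definition_status", "active")]

  if (any(!nzchar(concepts$id))) stop("validation error: empty concept id")
  dup <- concepts$id[duplicated(concepts$id)]
  if (length(dup))
    stop("validation error: duplicate concept id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(concepts$name)))
    stop("validation error: empty name for concept(s): ",
         paste(concepts$id[!nzchar(concepts$name)], collapse = ", "))
  bad <- setdiff(concepts$definition_status, c("primitive", "fully_defined"))
  if (length(bad))
    stop("validation error: unknown definition_status: ", paste(bad, collapse = ", "))

  isa <- .as_edge_table(isa, c("child", "parent"))
  attributes <- .as_attr_table(attributes)
  chains <- .as_edge_table(chains, c("leading", "intermediate", "super"))
  if (length(inactive)) {
    # relations touching an inactivated concept go with it
    isa <- isa[!(isa$child %in% inactive | isa$parent %in% inactive), , drop = FALSE]
    attributes <- attributes[!(attributes$source %in% inactive |
                               attributes$attribute %in% inactive |
                               attributes$value %in% inactive), , drop = FALSE]
    chains <- chains[!(chains$leading %in% inactive |
                       chains$intermediate %in% inactive |
                       chains$super %in% inactive), , drop = FALSE]
  }

  ids <- concepts$id
  .check_refs <- function(x, what) {
    missing <- setdiff(unique(x), ids)
    if (length(missing))
      stop("validation error: unknown id referenced by ", what, ": ",
           paste(missing, collapse = ", "))
  }
  .check_refs(c(isa$child, isa$parent), "isa edges")
  .check_refs(c(attributes$source, attributes$attribute, attributes$value),
              "attribute relations")
  .check_refs(unlist(chains[, c("leading", "intermediate", "super")]), "property chains")
  if ((nrow(isa) || nrow(attributes) || nrow(chains)) &&
      !(isa_attribute_id %in% ids))
    stop("validation error: isa_attribute_id `", isa_attribute_id,
         "` is not a concept in the ontology")
  if (any(attributes$attribute == isa_attribute_id))
    stop("validation error: IS-A relations must use the isa table, ",
         "not the attributes table")
  isa <- unique(isa)
  if (any(isa$child == isa$parent))
    stop("validation error: cycle in IS-A edges: ",
         isa$child[isa$child == isa$parent][1], " -> itself")

  g <- igraph::graph_from_data_frame(
    isa, directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    stop("validation error: cycle in IS-A edges involving: ",
         paste(cyc, collapse = " -> "))
  }

  structure(
    list(concepts = concepts, isa = isa, attributes = attributes,
         chains = chains, isa_attribute_id = isa_attribute_id,
         graph = g, cache = new.env(parent = emptyenv())),
    class = "ontology")
}

.as_edge_table <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    x <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(cols %in% names(x)))
    stop("table needs columns: ", paste(cols, collapse = ", "))
  x <- x[, cols, drop = FALSE]
  x[] <- lapply(x, as.character)
  rownames(x) <- NULL
  x
}

.as_attr_table <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(data.frame(source = character(), group_index = integer(),
                      attribute = character(), value = character()))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("source", "attribute", "value") %in% names(x)))
    stop("attributes table needs columns source, attribute, value")
  x$source <- as.character(x$source)
  x$attribute <- as.character(x$attribute)
  x$value <- as.character(x$value)
  if (is.null(x$group_index) || all(is.na(x$group_index))) {
    # ungrouped input: every relation its own singleton group, per source
    x$group_index <- stats::ave(seq_len(nrow(x)), x$source, FUN = seq_along)
  }
  x$group_index <- as.integer(x$group_index)
  if (any(is.na(x$group_index) | x$group_index < 0))
    stop("validation error: group_index must be a non-negative integer")
  x <- unique(x[, c("source", "group_index", "attribute", "value")])
  rownames(x) <- NULL
  x
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d concepts, %d IS-A edges, %d attribute relations (%d groups), %d property chains\n",
    nrow(x$concepts), nrow(x$isa), nrow(x$attributes),
    nrow(unique(x$attributes[, c("source", "group_index")])), nrow(x$chains)))
  invisible(x)
}

.check_id <- function(ontology, id) {
  missing <- setdiff(id, ontology$concepts$id)
  if (length(missing))
    stop("unknown concept id(s): ", paste(missing, collapse = ", "))
  invisible(id)
}

# Lazily cached n x n logical matrix: M[i, j] is TRUE iff j is an
# ancestor-or-self of i. Rows/cols named by concept id.
.anc_matrix <- function(ontology) {
  if (!is.null(ontology$cache$anc)) return(ontology$cache$anc)
  ids <- ontology$concepts$id
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(m) <- TRUE
  if (nrow(ontology$isa)) {
    # child -> parent edges; process parents before children
    ord <- rev(names(igraph::topo_sort(ontology$graph, mode = "out")))
    parents <- split(ontology$isa$parent, ontology$isa$child)
    for (v in ord) {
      for (p in parents[[v]]) m[v, ] <- m[v, ] | m[p, ]
    }
  }
  ontology$cache$anc <- m
  m
}

#' Ancestors and descendants of a concept
#'
#' Transitive closure over the IS-A hierarchy, excluding the concept itself.
#'
#' @param ontology an [ontology()].
#' @param concept_id a concept id.
#' @return Character vector of concept ids (possibly empty), sorted.
#' @export
ancestors <- function(ontology, concept_id) {
  .check_id(ontology, concept_id)
  m <- .anc_matrix(ontology)
  sort(setdiff(colnames(m)[m[concept_id, ]], concept_id))
}

#' @rdname ancestors
#' @export
descendants <- function(ontology, concept_id) {
  .check_id(ontology, concept_id)
  m <- .anc_matrix(ontology)
  sort(setdiff(rownames(m)[m[, concept_id]], concept_id))
}

#' Hierarchical subsumption test
#'
#' `TRUE` iff concept `a` is the same as, or a descendant of, concept `b` —
#' the "same as or a subtype" test used throughout the logical subsumption
#' rules.
#'
#' @inheritParams ancestors
#' @param a,b concept ids.
#' @export
is_subsumed_by <- function(ontology, a, b) {
  .check_id(ontology, c(a, b))
  if (a == b) return(TRUE)
  unname(.anc_matrix(ontology)[a, b])
}

#' A single defining relation (attribute-value pair)
#'
#' @param attribute attribute concept id (the reserved IS-A id for
#'   hierarchical relations).
#' @param value value concept id.
#' @export
defining_relation <- function(attribute, value) {
  structure(list(attribute = as.character(attribute),
                 value = as.character(value)),
            class = "defining_relation")
}

#' @export
format.defining_relation <- function(x, ...) {
  sprintf("(%s : %s)", x$attribute, x$value)
}

#' Inferred logical definition of a concept
#'
#' A concept's inferred definition is its set of relation groups: every
#' direct IS-A parent contributes one singleton group (hierarchical
#' relations are never grouped with attributes), and each attribute
#' relation group from the ontology contributes one group. Groups are
#' re-indexed deterministically: IS-A singletons first (sorted by parent
#' id), then attribute groups in their stored group order.
#'
#' @inheritParams ancestors
#' @return Object of class `inferred_definition`: a list with `concept` and
#'   `groups`; each group has `group_index`, `kind` (`"isa"` or
#'   `"attribute"`) and a list of `relations` ([defining_relation()]s).
#' @export
inferred_definition <- function(ontology, concept_id) {
  .check_id(ontology, concept_id)
  isa_id <- ontology$isa_attribute_id
  parents <- sort(ontology$isa$parent[ontology$isa$child == concept_id])
  groups <- lapply(parents, function(p)
    list(kind = "isa", relations = list(defining_relation(isa_id, p))))

  at <- ontology$attributes[ontology$attributes$source == concept_id, , drop = FALSE]
  if (nrow(at)) {
    for (gi in sort(unique(at$group_index))) {
      rows <- at[at$group_index == gi, , drop = FALSE]
      rows <- rows[order(rows$attribute, rows$value), , drop = FALSE]
      rels <- Map(defining_relation, rows$attribute, rows$value)
      names(rels) <- NULL
      groups <- c(groups, list(list(kind = "attribute", relations = rels)))
    }
  }
  for (i in seq_along(groups)) groups[[i]]$group_index <- i
  structure(list(concept = concept_id, groups = groups),
            class = "inferred_definition")
}

#' @export
print.inferred_definition <- function(x, ...) {
  cat(sprintf("<inferred_definition> %s: %d relation group(s)\n",
              x$concept, length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  [%d] {%s}\n", g$group_index,
                paste(vapply(g$relations, format, ""), collapse = ", ")))
  }
  invisible(x)
}

#' Does a definition carry at least one attribute relation?
#'
#' Definitions consisting only of hierarchical (IS-A) groups say too little
#' about a concept to anchor a subsumption comparison; the suggestion
#' pipeline requires candidate supertypes to pass this test by default.
#'
#' @param definition an [inferred_definition()].
#' @export
has_attribute_relation <- function(definition) {
  any(vapply(definition$groups, function(g) g$kind == "attribute", TRUE))
}

# ---- native table format ----------------------------------------------------

#' Read an ontology from native tables
#'
#' The native format is a directory of UTF-8 tab-separated tables with
#' header rows: `concepts.tsv` (id, name, definition_status, active),
#' `isa.tsv` (child_id, parent_id), and optionally `attributes.tsv`
#' (source_id, group_index, attribute_id, value_id) and `chains.tsv`
#' (leading_id, intermediate_id, super_id). A single JSON document with the
#' same field names is accepted as well (a file path ending in `.json`).
#'
#' @param path directory containing the tables, or a `.json` file.
#' @param isa_attribute_id reserved IS-A attribute concept id.
#' @return An [ontology()].
#' @export
load_native_tables <- function(path, isa_attribute_id = "116680003") {
  if (file.exists(path) && !dir.exists(path) && grepl("\\.json$", path)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(ontology(doc$concepts, .rename_native(doc$isa, "isa"),
                    .rename_native(doc$attributes, "attributes"),
                    .rename_native(doc$chains, "chains"),
                    isa_attribute_id = isa_attribute_id))
  }
  if (!dir.exists(path)) stop("load error: no such directory or file: ", path)
  rd <- function(file, required = TRUE) {
    f <- file.path(path, file)
    if (!file.exists(f)) {
      if (required) stop("load error: missing file: ", f)
      return(NULL)
    }
    read.delim(f, sep = "\t", quote = "", colClasses = "character",
               fileEncoding = "UTF-8", check.names = FALSE)
  }
  ontology(rd("concepts.tsv"),
           .rename_native(rd("isa.tsv"), "isa"),
           .rename_native(rd("attributes.tsv", required = FALSE), "attributes"),
           .rename_native(rd("chains.tsv", required = FALSE), "chains"),
           isa_attribute_id = isa_attribute_id)
}

.rename_native <- function(x, what) {
  if (is.null(x)) return(NULL)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  map <- switch(what,
    isa = c(child_id = "child", parent_id = "parent"),
    attributes = c(source_id = "source", attribute_id = "attribute",
                   value_id = "value"),
    chains = c(leading_id = "leading", intermediate_id = "intermediate",
               super_id = "super"))
  hit <- names(map) %in% names(x)
  names(x)[match(names(map)[hit], names(x))] <- map[hit]
  x
}

#' Write an ontology as native tables
#'
#' Inverse of [load_native_tables()]: writes `concepts.tsv`, `isa.tsv`,
#' `attributes.tsv` and `chains.tsv` into `dir`.
#'
#' @param ontology an [ontology()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_native_tables <- function(ontology, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, file) {
    write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(ontology$concepts, "concepts.tsv")
  isa <- ontology$isa; names(isa) <- c("child_id", "parent_id")
  wr(isa, "isa.tsv")
  at <- ontology$attributes
  names(at) <- c("source_id", "group_index", "attribute_id", "value_id")
  wr(at, "attributes.tsv")
  ch <- ontology$chains
  names(ch) <- c("leading_id", "intermediate_id", "super_id")
  wr(ch, "chains.tsv")
  invisible(dir)
}

# ---- SNOMED CT RF2 snapshot -------------------------------------------------

#' Read a SNOMED CT RF2 snapshot release
#'
#' Loads the concept, description (fully specified names) and inferred
#' relationship files of an RF2 *Snapshot* release directory. Only rows
#' with `active = 1` are kept; only relationships with the inferred
#' characteristic type (`900000000000011006`) are kept. Relationship rows
#' with the IS-A type id (`116680003`) become hierarchy edges; all other
#' rows become attribute relations grouped by `(sourceId,
#' relationshipGroup)`, except that `relationshipGroup = 0` rows (SNOMED's
#' ungrouped relations) each form their own singleton group.
#'
#' @param path directory containing `sct2_Concept*`, `sct2_Description*`
#'   and `sct2_Relationship*` tab-separated files (searched recursively).
#' @return An [ontology()].
#' @export
load_rf2_snapshot <- function(path) {
  if (!dir.exists(path)) stop("load error: no such directory: ", path)
  find1 <- function(pattern, label) {
    f <- list.files(path, pattern = pattern, recursive = TRUE, full.names = TRUE)
    if (!length(f)) stop("load error: missing RF2 ", label,
                         " file (pattern ", pattern, ") under ", path)
    f[1]
  }
  rd <- function(f) read.delim(f, sep = "\t", quote = "",
                               colClasses = "character",
                               fileEncoding = "UTF-8")
  con <- rd(find1("^sct2_Concept", "concept"))
  des <- rd(find1("^sct2_Description", "description"))
  rel <- rd(find1("^sct2_Relationship", "relationship"))

  con <- con[con$active == "1", , drop = FALSE]
  status <- ifelse(con$definitionStatusId == .rf2$fully_defined,
                   "fully_defined", "primitive")
  unknown <- setdiff(unique(con$definitionStatusId),
                     c(.rf2$fully_defined, .rf2$primitive))
  if (length(unknown))
    stop("validation error: unknown definitionStatusId: ",
         paste(unknown, collapse = ", "))

  des <- des[des$active == "1" & des$typeId == .rf2$fsn_type &
               des$conceptId %in% con$id, , drop = FALSE]
  name <- setNames(des$term, des$conceptId)
  if (any(!(con$id %in% names(name))))
    stop("validation error: concept(s) without an active FSN: ",
         paste(setdiff(con$id, names(name)), collapse = ", "))

  rel <- rel[rel$active == "1" &
               rel$characteristicTypeId == .rf2$inferred, , drop = FALSE]
  isa <- rel[rel$typeId == .rf2$isa_type, c("sourceId", "destinationId")]
  names(isa) <- c("child", "parent")
  at <- rel[rel$typeId != .rf2$isa_type, , drop = FALSE]
  attributes <- NULL
  if (nrow(at)) {
    gi <- as.integer(at$relationshipGroup)
    # each relationshipGroup=0 row is its own singleton group
    for (s in unique(at$sourceId[gi == 0])) {
      sel <- which(at$sourceId == s & gi == 0)
      gi[sel] <- max(gi[at$sourceId == s], 0L) + seq_along(sel)
    }
    attributes <- data.frame(source = at$sourceId, group_index = gi,
                             attribute = at$typeId, value = at$destinationId)
  }
  ontology(
    data.frame(id = con$id, name = unname(name[con$id]),
               definition_status = status, active = TRUE),
    isa = isa, attributes = attributes,
    isa_attribute_id = .rf2$isa_type)
}
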
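# Lexical feature sets of concept names.
#
# Three feature classes are aggregated from a concept's (tag-stripped,
# lowercased) name: dependency pairs for "pobj"/"dobj" dependencies
# ("head word + object word", e.g. "of nerve"), multi-word base noun
# phrases, and the residual single words not consumed by any dependency
# pair. Enrichment unions in the features of every ancestor; the
# subsumption check is a plain (non-strict) superset test.

.prepositions <- c("of", "in", "on", "at", "by", "for", "with", "to",
                   "from", "without")

#' Strip the trailing SNOMED semantic tag from a concept name
#'
#' Removes one trailing parenthesized tag such as `"(disorder)"` together
#' with the whitespace before it; names without a trailing tag pass
#' through unchanged. Only the final tag is removed, so an embedded
#' parenthetical earlier in the name survives.
#'
#' @param name non-empty concept name.
#' @export
strip_semantic_tag <- function(name) {
  sub("\\s+\\([^()]*\\)$", "", name)
}

#' Syntactic analysis providers
#'
#' The package's feature extraction is parameterized over a provider that
#' turns a (tag-stripped) concept name into a token analysis: tokens with
#' dependency labels and head indices, plus base noun-phrase spans. The
#' bundled `"rulebased"` provider is deterministic and handles the
#' `<modifier>* <noun> (<preposition> <modifier>* <noun>)*` shapes that
#' dominate terminology labels: each maximal run of non-preposition tokens
#' is a noun-phrase span, and the head noun (last token) of every
#' post-preposition run is labelled `pobj` with the preposition as its
#' head. Statistical parsers can be plugged in by constructing a provider
#' with a custom `analyze` function, at the cost of bit-stable output.
#'
#' @param name provider identifier; `"rulebased"` is bundled.
#' @param analyze for custom providers, a `function(text)` returning a
#'   token analysis (list with `tokens` data.frame — columns `surface`,
#'   `lower`, `dep`, `head_index` — and `np_spans`, a list of
#'   `c(start, end)` half-open index pairs).
#' @param deterministic does the provider always return the same analysis
#'   for the same input?
#' @return Object of class `lexical_provider`.
#' @export
lexical_provider <- function(name = "rulebased", analyze = NULL,
                             deterministic = TRUE) {
  if (is.null(analyze)) {
    if (!identical(name, "rulebased"))
      stop("no bundled analyzer for provider `", name,
           "`; supply an `analyze` function")
    analyze <- .rulebased_analyze
  }
  structure(list(name = name, analyze = analyze,
                 deterministic = deterministic),
            class = "lexical_provider")
}

.rulebased_analyze <- function(text) {
  surface <- strsplit(trimws(text), "\\s+")[[1]]
  surface <- surface[nzchar(surface)]
  n <- length(surface)
  lower <- tolower(surface)
  dep <- rep("", n)
  head_index <- rep(NA_integer_, n)
  is_prep <- lower %in% .prepositions
  dep[is_prep] <- "prep"

  # maximal runs of non-preposition tokens
  np_spans <- list()
  i <- 1
  while (i <= n) {
    if (is_prep[i]) { i <- i + 1; next }
    j <- i
    while (j < n && !is_prep[j + 1]) j <- j + 1
    np_spans[[length(np_spans) + 1]] <- c(i, j + 1)  # half-open
    # head noun of a post-preposition run gets pobj with the preposition
    if (i > 1 && is_prep[i - 1]) {
      dep[j] <- "pobj"
      head_index[j] <- i - 1L
    }
    i <- j + 1
  }
  list(tokens = data.frame(surface = surface, lower = lower, dep = dep,
                           head_index = head_index,
                           stringsAsFactors = FALSE),
       np_spans = np_spans)
}

#' Dependency-pair features of a token analysis
#'
#' For every token with a `pobj` or `dobj` dependency, emits the lowercase
#' feature `"<head word> <object word>"`. The token indices consumed by
#' these pairs (head and dependent) are attached as the `"consumed"`
#' attribute, for the residual-word rule.
#'
#' @param analysis a token analysis (see [lexical_provider()]).
#' @return Character vector of features with attribute `consumed`.
#' @export
extract_dependency_pairs <- function(analysis) {
  tok <- analysis$tokens
  sel <- which(tok$dep %in% c("pobj", "dobj") & !is.na(tok$head_index))
  feats <- vapply(sel, function(i)
    paste(tok$lower[tok$head_index[i]], tok$lower[i]), "")
  structure(sort(unique(feats)),
            consumed = sort(unique(c(sel, tok$head_index[sel]))))
}

#' Multi-word noun-phrase features of a token analysis
#'
#' Lowercase text of every noun-phrase span containing two or more tokens.
#' Single-token phrases are not emitted here; they fall through to the
#' residual-word rule of [initial_feature_set()].
#'
#' @inheritParams extract_dependency_pairs
#' @export
extract_noun_phrase_features <- function(analysis) {
  tok <- analysis$tokens
  spans <- Filter(function(s) s[2] - s[1] >= 2, analysis$np_spans)
  sort(unique(vapply(spans, function(s)
    paste(tok$lower[seq(s[1], s[2] - 1)], collapse = " "), "")))
}

#' Initial lexical feature set of a concept name
#'
#' Strips the semantic tag, runs the provider, and unions three feature
#' classes: dependency pairs, multi-word noun phrases, and the lowercase
#' single words whose token was not consumed by any dependency pair.
#'
#' @param name concept name (fully specified name, tag allowed).
#' @param provider a [lexical_provider()].
#' @return Sorted character vector of lowercase features.
#' @export
initial_feature_set <- function(name, provider = lexical_provider()) {
  stopifnot(nzchar(name))
  analysis <- tryCatch(provider$analyze(strip_semantic_tag(name)),
                       error = function(e)
                         stop("lexical provider `", provider$name,
                              "` failed on \"", name, "\": ",
                              conditionMessage(e)))
  pairs <- extract_dependency_pairs(analysis)
  nps <- extract_noun_phrase_features(analysis)
  residual_idx <- setdiff(seq_len(nrow(analysis$tokens)),
                          attr(pairs, "consumed"))
  residual <- analysis$tokens$lower[residual_idx]
  sort(unique(c(as.character(pairs), nps, residual)))
}

#' Ancestor-enriched lexical feature set
#'
#' The concept's own initial feature set unioned with the initial feature
#' sets of all its proper ancestors, giving a broader view of the
#' concept's semantics. Per-concept initial sets are memoized in the
#' ontology's cache (or a caller-supplied environment).
#'
#' @inheritParams ancestors
#' @param provider a [lexical_provider()].
#' @param cache environment memoizing initial sets by concept id; defaults
#'   to a provider-keyed slot of the ontology's own cache.
#' @return Sorted character vector of lowercase features.
#' @export
enriched_feature_set <- function(ontology, concept_id,
                                 provider = lexical_provider(),
                                 cache = NULL) {
  .check_id(ontology, concept_id)
  if (is.null(cache)) {
    key <- paste0("lexical_", provider$name)
    if (is.null(ontology$cache[[key]]))
      ontology$cache[[key]] <- new.env(parent = emptyenv())
    cache <- ontology$cache[[key]]
  }
  name_of <- setNames(ontology$concepts$name, ontology$concepts$id)
  get1 <- function(id) {
    if (is.null(cache[[id]]))
      cache[[id]] <- initial_feature_set(name_of[[id]], provider)
    cache[[id]]
  }
  ids <- c(concept_id, ancestors(ontology, concept_id))
  sort(unique(unlist(lapply(ids, get1))))
}

#' Lexical subsumption check
#'
#' `TRUE` iff the would-be parent's feature set is a (non-strict) subset of
#' the would-be child's — i.e. the child is lexically at least as specific.
#'
#' @param child_set,parent_set feature sets (character vectors).
#' @export
lexical_subsumes <- function(child_set, parent_set) {
  all(parent_set %in% child_set)
}
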
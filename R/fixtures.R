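# Worked-example fixtures and synthetic ontology generators.
#
# The two bundled fixtures are hand-transcribed reconstructions of the
# neoplasm-of-peripheral-nerve non-lattice fragment and the edetate
# property-chain comparison from the SNOMED CT US Edition (March 2020 /
# September 2021); they are modeled reconstructions for testing, not
# release content. The generators build random hierarchies and planted
# missing-IS-A instances so every pipeline stage is testable without any
# licensed terminology download.

.run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Worked-example neoplasm fixture
#'
#' A 14-concept ontology reconstructing the non-lattice subgraph around
#' the pair ("Neoplasm of peripheral nerves of trunk (disorder)",
#' "Neoplasm of abdomen (disorder)") with its three maximal common
#' descendants, the relation groups of the primitive supertype "Neoplasm
#' of peripheral nerves of abdomen (disorder)" (two IS-A singletons plus a
#' two-relation attribute group), and the morphology / body-structure
#' support concepts the comparisons need.
#'
#' @return An [ontology()].
#' @export
paper_fixture_snomed <- function() {
  load_native_tables(system.file("extdata", "snomed_neoplasm",
                                 package = "isagap", mustWork = TRUE))
}

#' Worked-example property-chain fixture
#'
#' The edetate adverse-reaction comparison: "Sodium calcium edetate
#' (substance)" is not a hierarchical subtype of "Edetate (substance)",
#' but carries an "Is modification of" relation to it, and the chain
#' Causative agent o Is modification of -> Causative agent licenses the
#' specificity of its causative-agent relation.
#'
#' @return An [ontology()].
#' @export
paper_fixture_chain <- function() {
  load_native_tables(system.file("extdata", "edetate",
                                 package = "isagap", mustWork = TRUE))
}

.name_vocab <- list(
  modifiers = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                "eta", "theta"),
  nouns = c("lesion", "mass", "nodule", "growth", "swelling", "defect"),
  sites = c("arm", "leg", "torso", "head", "gland", "duct", "vessel",
            "membrane"))

.synthetic_name <- function(k) {
  v <- .name_vocab
  paste0(v$modifiers[sample.int(length(v$modifiers), 1)], " ",
         v$nouns[sample.int(length(v$nouns), 1)], " of ",
         v$sites[sample.int(length(v$sites), 1)], " (finding)")
}

#' Random acyclic ontology
#'
#' Concepts `c1..cn` with independent child-to-parent edges drawn only
#' from higher to lower index (acyclic by construction) and synthetic
#' multi-word names so lexical operations are exercisable. Identical
#' `(n, edge_prob, seed)` give identical ontologies.
#'
#' @param n number of concepts (>= 1).
#' @param edge_prob probability of each higher-to-lower-index edge.
#' @param seed RNG seed.
#' @return An [ontology()].
#' @export
random_dag <- function(n, edge_prob, seed) {
  if (n < 1) stop("n must be >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  .run_seeded(seed, {
    ids <- paste0("c", seq_len(n))
    names <- vapply(seq_len(n), .synthetic_name, "")
    edges <- NULL
    if (n >= 2 && edge_prob > 0) {
      child <- character(0); parent <- character(0)
      for (j in 2:n) {
        sel <- which(stats::runif(j - 1) < edge_prob)
        if (length(sel)) {
          child <- c(child, rep(ids[j], length(sel)))
          parent <- c(parent, ids[sel])
        }
      }
      edges <- data.frame(child = child, parent = parent)
    }
    concepts <- data.frame(id = c(ids, "116680003"),
                           name = c(names, "Is a (attribute)"))
    ontology(concepts, isa = edges)
  })
}

#' Synthetic ontology with planted missing IS-A relations
#'
#' Generates `n_planted` disjoint five-concept motifs, each engineered so
#' the pipeline's every condition holds for exactly one missing relation:
#' a primitive parent with one attribute group; a fully defined child
#' whose groups are pointwise same-or-more-specific (odd-numbered motifs
#' via the inclusion rule, even-numbered via a property chain through an
#' "is modification of"-style intermediate); child and parent placed
#' under two shared roots next to a decoy concept so the roots form a
#' non-lattice pair with three maximal common descendants; and a child
#' name that prefixes the parent's with a modifier token so the lexical
#' superset holds after enrichment. A background random DAG (see
#' [random_dag()]) of `n_background` attribute-free concepts surrounds the
#' motifs; attribute-free supertypes cannot pass the pipeline's filters,
#' so certified instances have no valid pair beyond the planted ones.
#'
#' @param n_background background concepts (default 200).
#' @param n_planted planted relations (>= 1, default 5).
#' @param seed RNG seed.
#' @param background_edge_prob edge probability of the background DAG;
#'   the default `4 / n_background` gives about two parents per concept.
#' @return Object of class `planted_instance`: list with `ontology`,
#'   `planted` (data.frame `child`, `parent`, `rule`), and `certificate`
#'   (per-planted logical: the post-construction self-check ran the full
#'   pipeline and recovered exactly the planted set).
#' @export
plant_missing_isas <- function(n_background = 200, n_planted = 5, seed = 1,
                               background_edge_prob = 4 / n_background) {
  if (n_planted < 1) stop("n_planted must be >= 1")
  bg <- random_dag(n_background, background_edge_prob, seed)
  concepts <- bg$concepts
  isa <- bg$isa
  attributes <- NULL
  chains <- NULL
  planted <- NULL

  add_concept <- function(id, name, status = "primitive") {
    concepts <<- rbind(concepts,
                       data.frame(id = id, name = name,
                                  definition_status = status, active = TRUE))
  }
  add_edge <- function(child, parent) {
    isa <<- rbind(isa, data.frame(child = child, parent = parent))
  }
  add_attr <- function(source, group, attribute, value) {
    attributes <<- rbind(attributes,
                         data.frame(source = source, group_index = group,
                                    attribute = attribute, value = value))
  }

  for (i in seq_len(n_planted)) {
    p <- function(x) paste0("k", i, "-", x)
    site <- paste0("sector", i)
    noun <- paste0("plasmoid", i)
    use_chain <- i %% 2 == 0

    add_concept(p("root1"), paste0(site, " structure (body structure)"))
    add_concept(p("root2"), paste0("disease of ", site, " (disorder)"))
    add_concept(p("parent"), paste0(noun, " of ", site, " (disorder)"),
                "primitive")
    add_concept(p("child"), paste0("variant ", noun, " of ", site,
                                   " (disorder)"), "fully_defined")
    add_concept(p("decoy"), paste0("nodulus", i, " of ", site, " (disorder)"),
                "fully_defined")
    for (x in c("parent", "child", "decoy")) {
      add_edge(p(x), p("root1"))
      add_edge(p(x), p("root2"))
    }

    if (!use_chain) {
      add_concept(p("attr"), "associated morphology (attribute)")
      add_concept(p("val"), "neoplasm (morphologic abnormality)")
      add_concept(p("valsub"), "malignant neoplasm (morphologic abnormality)")
      add_edge(p("valsub"), p("val"))
      add_attr(p("parent"), 1L, p("attr"), p("val"))
      add_attr(p("child"), 1L, p("attr"), p("valsub"))
    } else {
      add_concept(p("attr"), "causative agent (attribute)")
      add_concept(p("mod"), "is modification of (attribute)")
      add_concept(p("val"), "edetate (substance)")
      add_concept(p("valmod"), "sodium edetate (substance)")
      add_attr(p("valmod"), 1L, p("mod"), p("val"))
      add_attr(p("parent"), 1L, p("attr"), p("val"))
      add_attr(p("child"), 1L, p("attr"), p("valmod"))
      chains <- rbind(chains,
                      data.frame(leading = p("attr"), intermediate = p("mod"),
                                 super = p("attr")))
    }
    planted <- rbind(planted,
                     data.frame(child = p("child"), parent = p("parent"),
                                rule = if (use_chain) "chain" else "inclusion"))
  }

  ont <- ontology(concepts, isa, attributes, chains)
  planted <- planted[order(planted$child, planted$parent), , drop = FALSE]
  rownames(planted) <- NULL

  # self-check: the full pipeline must recover exactly the planted set
  report <- find_missing_isa(ont)
  kept <- report$kept[, c("child", "parent")]
  kept_keys <- paste(kept$child, kept$parent)
  planted_keys <- paste(planted$child, planted$parent)
  certificate <- planted_keys %in% kept_keys &
    length(setdiff(kept_keys, planted_keys)) == 0

  structure(list(ontology = ont, planted = planted,
                 certificate = certificate, seed = seed),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("<planted_instance> seed %s: %d concepts, %d planted relation(s), %s\n",
              format(x$seed), nrow(x$ontology$concepts), nrow(x$planted),
              if (all(x$certificate)) "certified" else "NOT certified"))
  invisible(x)
}
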
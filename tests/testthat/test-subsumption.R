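# build an inferred_definition-shaped object from bare relation groups
make_def <- function(concept, groups) {
  structure(list(
    concept = concept,
    groups = lapply(seq_along(groups), function(i)
      list(kind = "attribute", relations = groups[[i]], group_index = i))),
    class = "inferred_definition")
}

test_that("inclusion rule: same-or-subtype on both attribute and value", {
  ont <- paper_fixture_snomed()
  expect_true(is_subsumed_by(ont, wx$morph_malignant, wx$morph_neoplasm))
  expect_equal(relation_more_specific(
    ont,
    defining_relation(wx$assoc_morph, wx$morph_malignant),
    defining_relation(wx$assoc_morph, wx$morph_neoplasm)), "inclusion")
  # any relation vs itself
  expect_equal(relation_more_specific(
    ont,
    defining_relation(wx$finding_site, wx$site),
    defining_relation(wx$finding_site, wx$site)), "inclusion")
  # reversed direction fails
  expect_null(relation_more_specific(
    ont,
    defining_relation(wx$assoc_morph, wx$morph_neoplasm),
    defining_relation(wx$assoc_morph, wx$morph_malignant)))
  # IS-A only compares against IS-A
  expect_null(relation_more_specific(
    ont,
    defining_relation("116680003", wx$morph_malignant),
    defining_relation(wx$assoc_morph, wx$morph_neoplasm)))
  expect_error(relation_more_specific(
    ont, defining_relation("nope", wx$site),
    defining_relation(wx$finding_site, wx$site)), "unknown concept")
})

test_that("property-chain rule licenses the edetate comparison", {
  ont <- paper_fixture_chain()
  rx <- defining_relation("causative-agent", "subst-sce")
  ry <- defining_relation("causative-agent", "subst-edetate")
  # not a hierarchical subtype, so inclusion cannot apply ...
  expect_false(is_subsumed_by(ont, "subst-sce", "subst-edetate"))
  # ... but the chain through "Is modification of" does
  expect_equal(relation_more_specific(ont, rx, ry), "chain")

  # with the chain table emptied the comparison fails
  bare <- ontology(ont$concepts, ont$isa, ont$attributes, chains = NULL)
  expect_null(relation_more_specific(bare, rx, ry))
})

test_that("group comparison quantifies universally over the supertype group", {
  ont <- paper_fixture_snomed()
  gx <- list(defining_relation(wx$assoc_morph, wx$morph_malignant),
             defining_relation(wx$finding_site, wx$site))
  gy <- list(defining_relation(wx$assoc_morph, wx$morph_neoplasm),
             defining_relation(wx$finding_site, wx$site))
  res <- group_more_specific(ont, gx, gy)
  expect_length(res, 2)
  expect_setequal(vapply(res, `[[`, "", "rule"), "inclusion")

  # identical groups always succeed
  expect_length(group_more_specific(ont, gy, gy), 2)

  # an unmatched supertype relation fails the whole group
  gy2 <- c(gy, list(defining_relation(wx$finding_site, "npn-trunk")))
  expect_null(group_more_specific(ont, gx, gy2))
})

test_that("definition comparison matches every supertype group", {
  ont <- paper_fixture_snomed()
  Ix <- inferred_definition(ont, wx$malignant)
  Iy <- inferred_definition(ont, wx$supertype)
  ev <- definition_more_specific(ont, Ix, Iy)
  expect_true(ev$holds)
  expect_length(ev$group_matching, 3)
  expect_false(definition_more_specific(ont, Iy, Ix)$holds)

  # reflexivity over every fixture concept
  for (id in ont$concepts$id) {
    I <- inferred_definition(ont, id)
    expect_true(definition_more_specific(ont, I, I)$holds)
  }

  # an empty supertype definition holds vacuously
  empty <- make_def("none", list())
  expect_true(definition_more_specific(ont, Ix, empty)$holds)
})

test_that("group matching monotonicity: widening Ix preserves, widening Iy can only shrink", {
  for (seed in 1:6) {
    ont <- random_dag(25, 0.12, seed)
    ids <- ont$concepts$id
    set.seed(seed + 50)
    specialize <- function(v) {
      d <- descendants(ont, v)
      if (length(d)) sample(c(v, d), 1) else v
    }
    rand_group <- function() {
      n <- sample(1:2, 1)
      lapply(seq_len(n), function(i)
        defining_relation(sample(ids, 1), sample(ids, 1)))
    }
    Iy <- make_def("y", lapply(seq_len(sample(1:3, 1)), function(i) rand_group()))
    # Ix built by pointwise specializing Iy's relations
    Ix <- make_def("x", lapply(Iy$groups, function(g)
      lapply(g$relations, function(r)
        defining_relation(specialize(r$attribute), specialize(r$value)))))
    expect_true(definition_more_specific(ont, Ix, Iy)$holds)

    # adding any group to Ix preserves the result
    Ix_plus <- make_def("x", c(lapply(Ix$groups, `[[`, "relations"),
                               list(rand_group())))
    expect_true(definition_more_specific(ont, Ix_plus, Iy)$holds)

    # adding a group to Iy can only remove it: extended holds => original holds
    Iy_plus <- make_def("y", c(lapply(Iy$groups, `[[`, "relations"),
                               list(rand_group())))
    if (definition_more_specific(ont, Ix, Iy_plus)$holds)
      expect_true(definition_more_specific(ont, Ix, Iy)$holds)
  }
})

test_that("inclusion-only specificity is transitive", {
  for (seed in 1:6) {
    ont <- random_dag(25, 0.12, seed + 10)
    ids <- ont$concepts$id
    set.seed(seed + 500)
    specialize <- function(v) {
      d <- descendants(ont, v)
      if (length(d)) sample(c(v, d), 1) else v
    }
    spec_def <- function(I, name) make_def(name, lapply(I$groups, function(g)
      lapply(g$relations, function(r)
        defining_relation(specialize(r$attribute), specialize(r$value)))))
    Iz <- make_def("z", lapply(seq_len(sample(1:3, 1)), function(i)
      lapply(seq_len(sample(1:2, 1)), function(j)
        defining_relation(sample(ids, 1), sample(ids, 1)))))
    Iy <- spec_def(Iz, "y")
    Ix <- spec_def(Iy, "x")
    expect_true(definition_more_specific(ont, Iy, Iz)$holds)
    expect_true(definition_more_specific(ont, Ix, Iy)$holds)
    expect_true(definition_more_specific(ont, Ix, Iz)$holds)
  }
})

test_that("injective group matching refuses a single witness serving twice", {
  ont <- paper_fixture_snomed()
  g <- list(defining_relation(wx$assoc_morph, wx$morph_malignant))
  Ix <- make_def("x", list(g))
  Iy <- make_def("y", list(
    list(defining_relation(wx$assoc_morph, wx$morph_neoplasm)),
    list(defining_relation(wx$assoc_morph, wx$morph_malignant))))
  expect_true(definition_more_specific(ont, Ix, Iy)$holds)
  expect_false(definition_more_specific(ont, Ix, Iy,
                                        injective_group_matching = TRUE)$holds)
  # with two witnesses the injective matching succeeds again
  Ix2 <- make_def("x", list(g, g))
  expect_true(definition_more_specific(ont, Ix2, Iy,
                                       injective_group_matching = TRUE)$holds)
})

test_that("attribute-relation presence check", {
  ont <- paper_fixture_snomed()
  expect_true(has_attribute_relation(inferred_definition(ont, wx$supertype)))
  # IS-A-only definition
  expect_false(has_attribute_relation(inferred_definition(ont, wx$morph_malignant)))
  expect_false(has_attribute_relation(make_def("e", list())))
})

test_that("fully defined concepts' definitions refine their parents' in the fixture", {
  ont <- paper_fixture_snomed()
  fd <- ont$concepts$id[ont$concepts$definition_status == "fully_defined"]
  for (child in fd) {
    for (parent in ont$isa$parent[ont$isa$child == child]) {
      expect_true(definition_more_specific(
        ont,
        inferred_definition(ont, child),
        inferred_definition(ont, parent))$holds)
    }
  }
})
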
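test_that("native tables load, validate, and round-trip", {
  ont <- paper_fixture_snomed()
  expect_s3_class(ont, "ontology")
  expect_equal(nrow(ont$concepts), 14)

  # empty isa table -> no concept has parents
  d <- withr::local_tempdir()
  write.table(data.frame(id = c("a", "b"), name = c("A one", "B one"),
                         definition_status = "primitive", active = TRUE),
              file.path(d, "concepts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(child_id = character(), parent_id = character()),
              file.path(d, "isa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  flat <- load_native_tables(d)
  expect_equal(nrow(flat$isa), 0)
  expect_equal(ancestors(flat, "a"), character(0))

  # write -> load round-trips the worked-example fixture
  out <- withr::local_tempdir()
  write_native_tables(ont, out)
  ont2 <- load_native_tables(out)
  expect_equal(ont2$concepts, ont$concepts)
  expect_equal(ont2$isa, ont$isa)
  expect_equal(ont2$attributes, ont$attributes)
  expect_equal(ont2$chains, ont$chains)
})

test_that("construction rejects duplicates, dangling references, and cycles", {
  cs <- data.frame(id = c("a", "b", "116680003"),
                   name = c("A one", "B one", "Is a (attribute)"))
  expect_error(ontology(rbind(cs, cs[1, ])), "duplicate")
  expect_error(ontology(cs, isa = data.frame(child = "a", parent = "zzz")),
               "unknown id")
  expect_error(ontology(cs, isa = data.frame(child = c("a", "b"),
                                             parent = c("b", "a"))),
               "cycle")
  expect_error(ontology(cs, isa = data.frame(child = "a", parent = "a")),
               "cycle")
  # IS-A relations may not masquerade as attribute relations
  expect_error(ontology(cs, attributes = data.frame(
    source = "a", group_index = 1, attribute = "116680003", value = "b")),
    "isa table")
})

test_that("RF2 snapshot loading honours activity, characteristic type, and grouping", {
  d <- write_rf2_fixture(
    withr::local_tempdir(),
    concepts = rbind(rf2_concept_row("116680003"), rf2_concept_row("100"),
                     rf2_concept_row("200", status = "900000000000073002"),
                     rf2_concept_row("300"), rf2_concept_row("400"),
                     rf2_concept_row("999", active = "0")),
    descriptions = rbind(
      rf2_description_row("116680003", "Is a (attribute)"),
      rf2_description_row("100", "Parent thing (finding)"),
      rf2_description_row("200", "Child thing (finding)"),
      rf2_description_row("200", "Child synonym", typeId = "syn"),
      rf2_description_row("300", "Some attribute (attribute)"),
      rf2_description_row("400", "Some value (substance)"),
      rf2_description_row("999", "Gone (finding)")),
    relationships = rbind(
      rf2_relationship_row("200", "100", "116680003"),
      # two rows sharing relationshipGroup=1 -> one group with 2 relations
      rf2_relationship_row("200", "400", "300", relationshipGroup = "1"),
      rf2_relationship_row("200", "100", "300", relationshipGroup = "1"),
      # inactive and stated rows must be dropped
      rf2_relationship_row("100", "400", "300", active = "0"),
      rf2_relationship_row("100", "400", "300",
                           characteristicTypeId = "stated")))
  ont <- load_rf2_snapshot(d)
  expect_setequal(ont$concepts$id, c("116680003", "100", "200", "300", "400"))
  expect_equal(ont$concepts$definition_status[ont$concepts$id == "200"],
               "fully_defined")
  expect_equal(nrow(ont$isa), 1)
  expect_equal(ont$isa$child, "200")
  def <- inferred_definition(ont, "200")
  attr_groups <- Filter(function(g) g$kind == "attribute", def$groups)
  expect_length(attr_groups, 1)
  expect_length(attr_groups[[1]]$relations, 2)
  # none of 100's relations survived the active/characteristic filters
  expect_false("100" %in% ont$attributes$source)

  expect_error(load_rf2_snapshot(withr::local_tempdir()), "missing RF2")
})

test_that("RF2 relationshipGroup=0 rows become singleton groups", {
  d <- write_rf2_fixture(
    withr::local_tempdir(),
    concepts = rbind(rf2_concept_row("116680003"), rf2_concept_row("1"),
                     rf2_concept_row("2"), rf2_concept_row("3")),
    descriptions = rbind(rf2_description_row("116680003", "Is a (attribute)"),
                         rf2_description_row("1", "One (finding)"),
                         rf2_description_row("2", "Two (attribute)"),
                         rf2_description_row("3", "Three (substance)")),
    relationships = rbind(
      rf2_relationship_row("1", "3", "2", relationshipGroup = "0"),
      rf2_relationship_row("1", "2", "2", relationshipGroup = "0")))
  ont <- load_rf2_snapshot(d)
  def <- inferred_definition(ont, "1")
  expect_length(def$groups, 2)
  expect_true(all(vapply(def$groups, function(g) length(g$relations), 0L) == 1))
})

test_that("RF2 -> native -> native round-trip preserves the ontology", {
  d <- write_rf2_fixture(
    withr::local_tempdir(),
    concepts = rbind(rf2_concept_row("116680003"), rf2_concept_row("10"),
                     rf2_concept_row("20"), rf2_concept_row("30"),
                     rf2_concept_row("40", status = "900000000000073002")),
    descriptions = rbind(rf2_description_row("116680003", "Is a (attribute)"),
                         rf2_description_row("10", "Ten (finding)"),
                         rf2_description_row("20", "Twenty (finding)"),
                         rf2_description_row("30", "Thirty (attribute)"),
                         rf2_description_row("40", "Forty (finding)")),
    relationships = rbind(
      rf2_relationship_row("40", "10", "116680003"),
      rf2_relationship_row("40", "20", "116680003"),
      rf2_relationship_row("40", "20", "30", relationshipGroup = "1")))
  ont <- load_rf2_snapshot(d)
  out <- withr::local_tempdir()
  write_native_tables(ont, out)
  ont2 <- load_native_tables(out)
  expect_equal(ont2$concepts[order(ont2$concepts$id), ],
               ont$concepts[order(ont$concepts$id), ], ignore_attr = TRUE)
  expect_equal(ont2$isa[order(ont2$isa$child, ont2$isa$parent), ],
               ont$isa[order(ont$isa$child, ont$isa$parent), ],
               ignore_attr = TRUE)
  expect_equal(ont2$attributes, ont$attributes)
})

test_that("ancestors/descendants agree with the fixed-point oracle and each other", {
  for (seed in 1:6) {
    ont <- random_dag(40, 0.08, seed)
    ids <- ont$concepts$id
    for (id in sample(ids, 10)) {
      expect_equal(ancestors(ont, id), oracle_ancestors(ont, id))
    }
    # b in ancestors(a) <=> a in descendants(b)
    a <- sample(ids, 1)
    for (b in ancestors(ont, a)) expect_true(a %in% descendants(ont, b))
    for (b in setdiff(ids, c(a, ancestors(ont, a))))
      expect_false(a %in% descendants(ont, b))
  }
  expect_error(ancestors(paper_fixture_snomed(), "nope"), "unknown concept")
})

test_that("is_subsumed_by is a preorder (reflexive and transitive)", {
  ont <- random_dag(30, 0.1, 99)
  ids <- ont$concepts$id
  for (id in ids) expect_true(is_subsumed_by(ont, id, id))
  anc_map <- oracle_anc_map(ont)
  for (a in sample(ids, 8)) {
    for (b in anc_map[[a]]) {
      for (c in anc_map[[b]]) {
        expect_true(is_subsumed_by(ont, a, c))
      }
    }
  }
  # siblings under a common parent are unrelated both ways
  sib <- ontology(
    data.frame(id = c("p", "x", "y", "116680003"),
               name = c("P one", "X one", "Y one", "Is a (attribute)")),
    isa = data.frame(child = c("x", "y"), parent = "p"))
  expect_false(is_subsumed_by(sib, "x", "y"))
  expect_false(is_subsumed_by(sib, "y", "x"))
})

test_that("inferred definitions expose parents as singleton IS-A groups", {
  ont <- paper_fixture_snomed()
  def <- inferred_definition(ont, wx$supertype)
  expect_length(def$groups, 3)
  kinds <- vapply(def$groups, `[[`, "", "kind")
  expect_equal(sum(kinds == "isa"), 2)
  sizes <- vapply(def$groups, function(g) length(g$relations), 0L)
  expect_equal(sort(sizes), c(1L, 1L, 2L))
  expect_equal(unique(vapply(def$groups, `[[`, 0L, "group_index")), 1:3)

  # isolated concept -> empty definition; adding a parent adds one group
  iso <- ontology(data.frame(id = c("a", "b", "116680003"),
                             name = c("A one", "B one", "Is a (attribute)")))
  expect_length(inferred_definition(iso, "a")$groups, 0)
  iso2 <- ontology(iso$concepts, isa = data.frame(child = "a", parent = "b"))
  expect_length(inferred_definition(iso2, "a")$groups, 1)
  expect_false(has_attribute_relation(inferred_definition(iso2, "a")))
})
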
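# Brute-force oracles, deliberately independent of the package internals:
# plain fixed-point expansion over the isa edge table only.

oracle_ancestors <- function(ont, id) {
  parents <- split(ont$isa$parent, ont$isa$child)
  acc <- character(0)
  frontier <- id
  repeat {
    nxt <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                   c(acc, id))
    if (!length(nxt)) break
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

# ancestor-or-self sets for every concept, as a named list
oracle_anc_map <- function(ont) {
  ids <- ont$concepts$id
  setNames(lapply(ids, function(i) c(i, oracle_ancestors(ont, i))), ids)
}

oracle_mcd <- function(ont, a, b, anc_map = oracle_anc_map(ont)) {
  ids <- ont$concepts$id
  common <- ids[vapply(anc_map, function(s) a %in% s && b %in% s, TRUE)]
  keep <- vapply(common, function(c) {
    !any(vapply(setdiff(common, c), function(d) d %in% anc_map[[c]] && d != c,
                TRUE))
  }, TRUE)
  sort(common[keep])
}

oracle_mca <- function(ont, set, anc_map = oracle_anc_map(ont)) {
  common <- Reduce(intersect, anc_map[set])
  keep <- vapply(common, function(c) {
    !any(vapply(setdiff(common, c), function(d) c %in% anc_map[[d]], TRUE))
  }, TRUE)
  sort(common[keep])
}

oracle_nonlattice_pairs <- function(ont) {
  ids <- sort(ont$concepts$id)
  anc_map <- oracle_anc_map(ont)
  out <- NULL
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (length(oracle_mcd(ont, ids[i], ids[j], anc_map)) >= 2)
        out <- rbind(out, data.frame(a = ids[i], b = ids[j]))
    }
  }
  if (is.null(out)) data.frame(a = character(), b = character()) else out
}

# reachability by fixed point over an explicit edge table
oracle_reaches <- function(edges, from, to) {
  parents <- split(edges$parent, edges$child)
  seen <- character(0)
  frontier <- from
  while (length(frontier)) {
    if (to %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

# random hierarchically-unrelated pairs of an ontology, as a suggestion frame
random_unrelated_suggestions <- function(ont, n, seed) {
  set.seed(seed)
  ids <- ont$concepts$id
  anc_map <- oracle_anc_map(ont)
  out <- NULL
  for (k in seq_len(n * 20)) {
    p <- sample(ids, 2)
    if (p[2] %in% anc_map[[p[1]]] || p[1] %in% anc_map[[p[2]]]) next
    out <- rbind(out, data.frame(child = p[1], parent = p[2]))
    if (nrow(out) >= n) break
  }
  if (is.null(out)) return(NULL)
  out <- unique(out)
  out$status <- "kept"
  out
}

# minimal tab-separated RF2 snapshot fixture written into `dir`
write_rf2_fixture <- function(dir,
                              concepts = NULL, descriptions = NULL,
                              relationships = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, file) write.table(x, file.path(dir, file), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  wr(concepts, "sct2_Concept_Snapshot.txt")
  wr(descriptions, "sct2_Description_Snapshot.txt")
  wr(relationships, "sct2_Relationship_Snapshot.txt")
  dir
}

rf2_concept_row <- function(id, status = "900000000000074008", active = "1") {
  data.frame(id = id, effectiveTime = "20210901", active = active,
             moduleId = "m", definitionStatusId = status)
}

rf2_description_row <- function(conceptId, term, active = "1",
                                typeId = "900000000000003001") {
  data.frame(id = paste0("d", conceptId), effectiveTime = "20210901",
             active = active, moduleId = "m", conceptId = conceptId,
             languageCode = "en", typeId = typeId, term = term,
             caseSignificanceId = "cs")
}

rf2_relationship_row <- function(sourceId, destinationId, typeId,
                                 relationshipGroup = "0", active = "1",
                                 characteristicTypeId = "900000000000011006") {
  data.frame(id = paste0("r", sourceId, destinationId, typeId,
                         relationshipGroup),
             effectiveTime = "20210901", active = active, moduleId = "m",
             sourceId = sourceId, destinationId = destinationId,
             relationshipGroup = relationshipGroup, typeId = typeId,
             characteristicTypeId = characteristicTypeId, modifierId = "mo")
}

# ids of the worked-example fixture, named for readability in tests
wx <- list(
  pair_a = "npn-trunk",                      # Neoplasm of peripheral nerves of trunk
  pair_b = "n-abdomen",                      # Neoplasm of abdomen
  supertype = "126992002",                   # Neoplasm of peripheral nerves of abdomen
  malignant = "188326001",                   # Malignant neoplasm of peripheral nerve of abdomen
  benign = "benign-ganglioneuroma-abdomen",  # Benign ganglioneuroma of abdomen
  morph_neoplasm = "morph-neoplasm",
  morph_malignant = "morph-malignant",
  site = "site-pn-abdomen",
  assoc_morph = "assoc-morph",
  finding_site = "finding-site")
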
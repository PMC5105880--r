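test_that("identifier normalization strips prefixes, annotations and case", {
  expect_equal(normalizeId("uniprotkb:p04637"), "P04637")
  expect_equal(normalizeId("STAT1"), "STAT1")
  expect_equal(normalizeId(" ensembl:ENSG00000115415 "), "ENSG00000115415")
  expect_equal(normalizeId("taxid:9606(human)"), "9606")
  expect_error(normalizeId("db:(only annotation)"), "unusable identifier")
})

test_that("MITAB parsing keeps well-formed lines and counts malformed ones", {
  lines <- c(mitabLine("P1", "P2"), mitabLine("P2", "P3"),
             mitabLine("P1", "P3"))
  rec <- parseMitab(lines)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$id_a, paste0("uniprotkb:", c("P1", "P2", "P1")))
  expect_equal(attr(rec, "nMalformed"), 0L)
  expect_equal(rec$taxid_a, rep("9606", 3))  # prefix and parens stripped

  short <- paste(rep("-", 14), collapse = "\t")  # 14 columns
  rec2 <- parseMitab(c(mitabLine("P1", "P2"), short))
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "nMalformed"), 1L)

  expect_error(parseMitab(character(0)), "empty database")
  expect_error(parseMitab(short), "empty database")
})

test_that("toy database deduplicates pairs and drops self-interactions", {
  db <- toyDb()
  expect_equal(nEdges(db), 7L)
  expect_equal(backgroundSize(db), 6L)
  expect_setequal(dbNodes(db), c("A", "B", "C", "D", "E", "F"))
  expect_equal(unname(dbDegree(db, c("A", "C", "E", "B", "D", "F"))),
               c(3L, 3L, 3L, 2L, 2L, 1L))
  expect_equal(interactorsOf(db, "A"), c("B", "C", "D"))
})

test_that("single-record database is symmetric with N = 2", {
  db <- buildInteractionDb(parseEdgeList("A\tB"))
  expect_equal(backgroundSize(db), 2L)
  expect_equal(nEdges(db), 1L)
  expect_equal(interactorsOf(db, "A"), "B")
  expect_equal(interactorsOf(db, "B"), "A")
})

test_that("species filter requires both interactors to match", {
  lines <- c(mitabLine("P1", "P2"),
             mitabLine("P2", "P3", taxb = "taxid:10090(mouse)"),
             mitabLine("P3", "P4", taxa = "-"))
  rec <- parseMitab(lines)
  db <- buildInteractionDb(rec, filterCriteria(species = "9606"))
  expect_equal(nEdges(db), 1L)
  expect_setequal(dbNodes(db), c("P1", "P2"))
  expect_error(
    buildInteractionDb(rec, filterCriteria(species = "7227")),
    "empty database after filtering")
})

test_that("interaction-type filter matches MI ids exactly, labels by substring", {
  lines <- c(
    mitabLine("P1", "P2", type = "psi-mi:\"MI:0915\"(physical association)"),
    mitabLine("P2", "P3", type = "psi-mi:\"MI:0407\"(direct interaction)"))
  rec <- parseMitab(lines)
  db1 <- buildInteractionDb(rec, filterCriteria(interactionTypes = "MI:0915"))
  expect_setequal(dbNodes(db1), c("P1", "P2"))
  db2 <- buildInteractionDb(
    rec, filterCriteria(interactionTypes = "Direct Interaction"))
  expect_setequal(dbNodes(db2), c("P2", "P3"))
})

test_that("id-namespace filter drops records from other namespaces", {
  lines <- c(mitabLine("P1", "P2"),
             paste("ensembl:ENSG1", "uniprotkb:P2",
                   "-", "-", "-", "-", "-", "-", "-",
                   "taxid:9606", "taxid:9606", "-", "-", "-", "-",
                   sep = "\t"))
  rec <- parseMitab(lines)
  expect_message(
    db <- buildInteractionDb(rec, filterCriteria(idNamespace = "uniprotkb")),
    "namespace")
  expect_setequal(dbNodes(db), c("P1", "P2"))
})

test_that("database-size check warns strictly below the threshold", {
  db <- toyDb()
  expect_true(checkMinSize(db, 10000L))
  expect_false(checkMinSize(db, 0L))
  expect_false(checkMinSize(db, 7L))   # boundary: exactly 7 edges, no warn
  expect_true(checkMinSize(db, 8L))
})

test_that("adjacency is symmetric and degrees match an edge-count oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    pairs <- t(utils::combn(LETTERS[1:n], 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) keep[1] <- TRUE
    db <- buildInteractionDb(parseEdgeList(
      paste(pairs[keep, 1], pairs[keep, 2], sep = "\t")))
    for (v in dbNodes(db)) {
      for (w in interactorsOf(db, v)) {
        expect_true(v %in% interactorsOf(db, w))
        expect_false(v %in% interactorsOf(db, v))
      }
    }
    # dedup conservation: n_edges equals distinct unordered pair count
    expect_equal(nEdges(db), sum(keep))
  }
})

test_that("rebuilding a database from its own edge list is idempotent", {
  db <- toyDb()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(db, path)
  db2 <- readInteractionDb(path, "edgelist")
  expect_identical(dbEdges(db2), dbEdges(db))
  expect_identical(db2@adjacency, db@adjacency)
})

test_that("adding filter criteria never grows the database", {
  lines <- c(mitabLine("P1", "P2"),
             mitabLine("P2", "P3", taxb = "taxid:10090(mouse)"),
             mitabLine("P3", "P4",
                       type = "psi-mi:\"MI:0407\"(direct interaction)"),
             mitabLine("P4", "P5"))
  rec <- parseMitab(lines)
  unfiltered <- buildInteractionDb(rec)
  bySpecies <- buildInteractionDb(rec, filterCriteria(species = "9606"))
  byBoth <- buildInteractionDb(
    rec, filterCriteria(species = "9606", interactionTypes = "MI:0915"))
  expect_lte(nEdges(bySpecies), nEdges(unfiltered))
  expect_lte(backgroundSize(bySpecies), backgroundSize(unfiltered))
  expect_lte(nEdges(byBoth), nEdges(bySpecies))
  expect_lte(backgroundSize(byBoth), backgroundSize(bySpecies))
})

test_that("edge list written for provenance is in lexicographic pair order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(toyDb(), path)
  lines <- readLines(path)
  expect_equal(lines, sort(lines, method = "radix"))
  parts <- do.call(rbind, strsplit(lines, "\t"))
  expect_true(all(parts[, 1] < parts[, 2]))
})
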
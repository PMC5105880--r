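#' Run the full contextual-hub pipeline
#'
#' Single-command orchestration: parse and filter the interaction database,
#' parse the contextual gene table and evaluate the predicate, build the seed
#' + first-neighbor network, score every network node with the hypergeometric
#' test, BH-correct, rank under both criteria and compare the top lists. All
#' result tables are written to `outDir`:
#'
#' * `scores.tsv` — one row per network node: `node`, `role`, `contextual`,
#'   `n`, `k`, `db_degree`, `p_raw`, `p_adj` (full precision),
#'   `rank_contextual`, `rank_degree`;
#' * `network.sif` — display edges;
#' * `network.graphml` — full network with `displayed` edge attribute;
#' * `comparison.tsv` — side-by-side top contextual vs top degree hubs;
#' * `run.json` — metadata: N, K, network size, BH family size m, warnings,
#'   resolved configuration and package version.
#'
#' Identical inputs and configuration produce byte-identical `scores.tsv`.
#' On any component error the partial outputs are removed and the error is
#' re-thrown.
#'
#' @param dbPath path to the interaction database file.
#' @param contextPath path to the contextual gene table (CSV or TSV).
#' @param outDir output directory (created if absent).
#' @param dbFormat `"edgelist"` or `"mitab"`.
#' @param idColumn identifier column of the context table.
#' @param predicate a [contextPredicate()] or `"all"`.
#' @param species,interactionTypes,idNamespace filter criteria, see
#'   [filterCriteria()].
#' @param top hub-list size (default 20).
#' @param minDbEdges database-size warning threshold (default 10,000).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `db`, `context`, `contextSet`, `network`,
#'   `scores`, `rankings` (contextual and degree), `comparison`, `metadata`
#'   and the written `paths`.
#' @export
runPipeline <- function(dbPath, contextPath, outDir,
                        dbFormat = c("edgelist", "mitab"),
                        idColumn = "gene", predicate = "all",
                        species = NULL, interactionTypes = NULL,
                        idNamespace = NULL,
                        top = 20L, minDbEdges = 10000L, quiet = FALSE) {
  dbFormat <- match.arg(dbFormat)
  if (!file.exists(dbPath))
    stop("file not found: database path '", dbPath, "' does not exist")
  if (!file.exists(contextPath))
    stop("file not found: context path '", contextPath, "' does not exist")
  if (top < 1L)
    stop("top must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scores = file.path(outDir, "scores.tsv"),
             sif = file.path(outDir, "network.sif"),
             graphml = file.path(outDir, "network.graphml"),
             comparison = file.path(outDir, "comparison.tsv"),
             metadata = file.path(outDir, "run.json"))
  say <- function(...) if (!quiet) message(...)
  result <- tryCatch({
    criteria <- filterCriteria(species, interactionTypes, idNamespace)
    db <- readInteractionDb(dbPath, dbFormat, criteria)
    warnings <- character(0)
    if (checkMinSize(db, minDbEdges)) {
      warnings <- c(warnings, sprintf(
        "database has %d interactions, fewer than the recommended %d",
        nEdges(db), as.integer(minDbEdges)))
      say("warning: ", warnings[1L])
    }
    say("database: N = ", backgroundSize(db), ", ", nEdges(db), " edges")
    context <- parseContextTable(contextPath, idColumn, predicate)
    cset <- resolveContext(context, db)
    say("contextual set: K = ", contextK(cset), " (",
        length(missingNodes(cset)), " not in database)")
    net <- buildNetwork(db, context)
    say("network: ", length(seedNodes(net)), " seeds + ",
        length(neighborNodes(net)), " neighbors")
    scores <- scoreNetwork(db, net, cset)
    rkC <- rankHubs(scores, "contextual", top)
    rkD <- rankHubs(scores, "degree", top)
    scores$rank_contextual <-
      match(scores$node, rankingTable(rkC)$node)
    scores$rank_degree <- match(scores$node, rankingTable(rkD)$node)
    comparison <- reportComparison(rkC, rkD)

    .writeScoresTsv(scores, paths[["scores"]])
    exportSif(net, paths[["sif"]])
    exportGraphml(net, cset, paths[["graphml"]])
    utils::write.table(comparison$table, paths[["comparison"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metadata <- list(
      tool = "contexthubs",
      version = as.character(utils::packageVersion("contexthubs")),
      N = backgroundSize(db),
      K = contextK(cset),
      networkSize = length(networkNodes(net)),
      m = nrow(scores),
      nSeeds = length(seedNodes(net)),
      nNeighbors = length(neighborNodes(net)),
      nEdgesDb = nEdges(db),
      nDisplayEdges = nrow(displayEdges(net)),
      nHiddenEdges = nrow(hiddenEdges(net)),
      missingContextual = as.list(missingNodes(cset)),
      sharedTopNodes = comparison$nShared,
      topJaccard = comparison$jaccard,
      warnings = as.list(warnings),
      config = list(dbPath = dbPath, dbFormat = dbFormat,
                    contextPath = contextPath, idColumn = idColumn,
                    predicate = if (identical(predicate, "all"))
                      "all" else predicate,
                    species = species, interactionTypes = interactionTypes,
                    idNamespace = idNamespace,
                    top = as.integer(top),
                    minDbEdges = as.integer(minDbEdges))
    )
    jsonlite::write_json(metadata, paths[["metadata"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    say(paste(comparison$lines, collapse = "; "))
    list(db = db, context = context, contextSet = cset, network = net,
         scores = scores,
         rankings = list(contextual = rkC, degree = rkD),
         comparison = comparison, metadata = metadata, paths = paths)
  }, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop(conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

# full-precision, locale-independent scores table; byte-stable across runs
.writeScoresTsv <- function(scores, path) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    node = scores$node,
    role = scores$role,
    contextual = ifelse(scores$contextual, "true", "false"),
    n = scores$n, k = scores$k, db_degree = scores$db_degree,
    p_raw = fmt(scores$p_raw), p_adj = fmt(scores$p_adj),
    rank_contextual = scores$rank_contextual,
    rank_degree = scores$rank_degree,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(colnames(out), collapse = "\t"),
               do.call(paste, c(unname(out), sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}
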
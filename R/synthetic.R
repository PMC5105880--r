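#' Construct a synthetic-data specification
#'
#' @param nNodes number of nodes in the background graph.
#' @param edgeProb background edge probability of the uniform (Erdos-Renyi)
#'   model; mutually exclusive with `degreeExponent`.
#' @param degreeExponent power-law exponent (> 2) of the heavy-tailed
#'   background model; the target edge count is `round(2.5 * nNodes)` (mean
#'   degree 5, typical of curated interactome subsets).
#' @param K number of contextual labels.
#' @param nPlantedContextual,plantedDegree,contextualWiringRate planted
#'   contextual hubs: each is wired to `plantedDegree` distinct partners of
#'   which a fraction `contextualWiringRate` (stochastic rounding) are drawn
#'   from the contextual set.
#' @param nPlantedPromiscuous,promiscuousDegree planted promiscuous hubs:
#'   each is wired to `promiscuousDegree` partners drawn uniformly, so their
#'   expected contextual fraction is the background rate K/N.
#' @param seed integer random seed; every output is a pure function of the
#'   spec including the seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nNodes, edgeProb = NULL, degreeExponent = NULL,
                          K, nPlantedContextual = 0L, plantedDegree = 0L,
                          contextualWiringRate = 0,
                          nPlantedPromiscuous = 0L, promiscuousDegree = 0L,
                          seed = 1L) {
  if (!is.null(edgeProb) && !is.null(degreeExponent))
    stop("set either edgeProb or degreeExponent, not both")
  new("SyntheticSpec",
      nNodes = as.integer(nNodes),
      edgeProb = as.numeric(edgeProb %||% NA_real_),
      degreeExponent = as.numeric(degreeExponent %||% NA_real_),
      K = as.integer(K),
      nPlantedContextual = as.integer(nPlantedContextual),
      plantedDegree = as.integer(plantedDegree),
      contextualWiringRate = as.numeric(contextualWiringRate),
      nPlantedPromiscuous = as.integer(nPlantedPromiscuous),
      promiscuousDegree = as.integer(promiscuousDegree),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SyntheticSpec", function(object) {
  model <- if (!is.na(object@edgeProb))
    sprintf("G(n, p = %g)", object@edgeProb)
  else sprintf("power law (gamma = %g)", object@degreeExponent)
  cat("SyntheticSpec:", object@nNodes, "nodes,", model,
      ", K =", object@K, ", seed =", object@seed, "\n")
  if (object@nPlantedContextual > 0L)
    cat("  planted contextual hubs:", object@nPlantedContextual,
        "at degree", object@plantedDegree,
        sprintf("(wiring rate %.2f)\n", object@contextualWiringRate))
  if (object@nPlantedPromiscuous > 0L)
    cat("  planted promiscuous hubs:", object@nPlantedPromiscuous,
        "at degree", object@promiscuousDegree, "\n")
})

.syntheticNodeNames <- function(n) {
  sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
}

# background edge matrix under the spec's graph model; caller owns set.seed
.backgroundEdges <- function(spec) {
  n <- spec@nNodes
  g <- if (!is.na(spec@edgeProb)) {
    igraph::sample_gnp(n, spec@edgeProb)
  } else {
    igraph::sample_fitness_pl(n, round(2.5 * n), spec@degreeExponent)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- .syntheticNodeNames(n)
  if (nrow(el) == 0L)
    return(matrix(character(0), ncol = 2L))
  cbind(nm[el[, 1L]], nm[el[, 2L]])
}

#' Generate a null synthetic dataset
#'
#' A background random graph with contextual labels assigned to a uniformly
#' random K-subset of the nodes that have at least one edge. There is no
#' planted signal: every node's contextual-interactor count follows the
#' hypergeometric null, which makes these datasets the calibration standard
#' for the test's type-I behavior.
#'
#' @param spec a [SyntheticSpec-class] (planted counts ignored).
#' @return list with `db` ([InteractionDb-class]), `context`
#'   ([ContextInput-class], predicate `"all"`), and `truth` (list with empty
#'   planted-hub sets and the drawn `contextualNodes`).
#' @export
generateNull <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  edges <- .backgroundEdges(spec)
  if (nrow(edges) == 0L)
    stop("degenerate spec: the background graph has no edges")
  db <- .newInteractionDb(edges)
  connected <- dbNodes(db)
  if (length(connected) < spec@K)
    stop("degenerate spec: fewer connected nodes than K")
  contextual <- sample(connected, spec@K)
  context <- .contextFromGenes(contextual)
  list(db = db, context = context,
       truth = list(plantedContextualHubs = character(0),
                    plantedPromiscuousHubs = character(0),
                    contextualNodes = sort(contextual, method = "radix")))
}

.contextFromGenes <- function(genes) {
  new("ContextInput",
      table = data.frame(gene = genes, weight = 1,
                         stringsAsFactors = FALSE),
      idColumn = "gene",
      eligible = genes,
      predicate = list(all = TRUE))
}

# stochastic rounding: floor(x) + 1 with probability frac(x)
.stochasticRound <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(1) < (x - f)))
}

#' Generate a planted-hub synthetic dataset
#'
#' Starts from the background graph of [generateNull()], then wires planted
#' hubs with known ground truth. Each planted contextual hub receives
#' `plantedDegree` distinct partners of which a `contextualWiringRate`
#' fraction (stochastic rounding) are contextual — these nodes are genuinely
#' enriched for contextual interactors. Each planted promiscuous hub receives
#' `promiscuousDegree` partners drawn uniformly, making it a high-degree node
#' whose contextual fraction matches the background rate. Contextual hubs are
#' wired at lower total degree than promiscuous hubs, so degree ranking and
#' contextual ranking dissociate by construction.
#'
#' @param spec a [SyntheticSpec-class] with planted counts set.
#' @return list with `db`, `context`, and `truth` (planted contextual hubs,
#'   planted promiscuous hubs, contextual nodes).
#' @export
generatePlanted <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (spec@nPlantedContextual > 0L &&
      spec@plantedDegree > spec@nNodes - 1L)
    stop("infeasible spec: plantedDegree exceeds available partners")
  if (spec@nPlantedPromiscuous > 0L &&
      spec@promiscuousDegree > spec@nNodes - 1L)
    stop("infeasible spec: promiscuousDegree exceeds available partners")
  set.seed(spec@seed)
  nodes <- .syntheticNodeNames(spec@nNodes)
  edges <- .backgroundEdges(spec)
  contextual <- sample(nodes, spec@K)
  pool <- setdiff(nodes, contextual)
  if (length(pool) < spec@nPlantedContextual + spec@nPlantedPromiscuous)
    stop("infeasible spec: not enough non-contextual nodes for planted hubs")
  ctxHubs <- if (spec@nPlantedContextual > 0L)
    sample(pool, spec@nPlantedContextual) else character(0)
  promHubs <- if (spec@nPlantedPromiscuous > 0L)
    sample(setdiff(pool, ctxHubs), spec@nPlantedPromiscuous) else character(0)
  planted <- list()
  for (h in ctxHubs) {
    nCtx <- min(.stochasticRound(spec@contextualWiringRate *
                                   spec@plantedDegree),
                spec@plantedDegree, length(contextual))
    nBg <- spec@plantedDegree - nCtx
    bgPool <- setdiff(nodes, c(h, contextual))
    if (nBg > length(bgPool))
      stop("infeasible spec: planted wiring exceeds available partners")
    partners <- c(sample(contextual, nCtx),
                  if (nBg > 0L) sample(bgPool, nBg) else character(0))
    planted[[h]] <- cbind(rep(h, length(partners)), partners)
  }
  for (h in promHubs) {
    partners <- sample(setdiff(nodes, h), spec@promiscuousDegree)
    planted[[h]] <- cbind(rep(h, length(partners)), partners)
  }
  allEdges <- rbind(edges, do.call(rbind, unname(planted)))
  if (is.null(allEdges) || nrow(allEdges) == 0L)
    stop("degenerate spec: the generated graph has no edges")
  db <- .newInteractionDb(allEdges)
  contextualInDb <- contextual[contextual %in% dbNodes(db)]
  if (length(contextualInDb) == 0L)
    stop("degenerate spec: no contextual node has an edge")
  context <- .contextFromGenes(contextualInDb)
  list(db = db, context = context,
       truth = list(
         plantedContextualHubs = sort(ctxHubs, method = "radix"),
         plantedPromiscuousHubs = sort(promHubs, method = "radix"),
         contextualNodes = sort(contextual, method = "radix")))
}

#' Write a synthetic dataset to disk
#'
#' Emits `edges.tsv` (edge list), `edges.mitab` (a minimal valid 15-column
#' PSI-MITAB 2.5 rendering of the same edges, with placeholder taxon
#' `taxid:9606` and type `psi-mi:"MI:0915"(physical association)` so that
#' species/type filters exercise cleanly), `context.tsv`, `truth.tsv`, and —
#' when the spec is supplied — `params.json` recording all generator
#' parameters including the seed. Re-reading `edges.mitab` through
#' [parseMitab()] + [buildInteractionDb()] reproduces the database exactly.
#'
#' @param db an [InteractionDb-class].
#' @param context a [ContextInput-class].
#' @param truth ground-truth list from the generators.
#' @param dir output directory (created if absent).
#' @param spec optional [SyntheticSpec-class] recorded as `params.json`.
#' @return named character vector of the written file paths, invisibly.
#' @export
writeFixture <- function(db, context, truth, dir, spec = NULL) {
  stopifnot(is(db, "InteractionDb"), is(context, "ContextInput"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             mitab = file.path(dir, "edges.mitab"),
             context = file.path(dir, "context.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeEdgeList(db, paths[["edges"]])
  e <- dbEdges(db)
  writeLines(sprintf(paste0(
    "uniprotkb:%s\tuniprotkb:%s\t-\t-\t-\t-\t-\t-\t-\t",
    "taxid:9606(human)\ttaxid:9606(human)\t",
    "psi-mi:\"MI:0915\"(physical association)\t-\t-\t-"),
    e[, 1L], e[, 2L]), paths[["mitab"]])
  utils::write.table(context@table, paths[["context"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthTab <- data.frame(
    node = c(truth$plantedContextualHubs, truth$plantedPromiscuousHubs,
             truth$contextualNodes),
    role = c(rep("contextual_hub", length(truth$plantedContextualHubs)),
             rep("promiscuous_hub", length(truth$plantedPromiscuousHubs)),
             rep("contextual", length(truth$contextualNodes))),
    stringsAsFactors = FALSE)
  utils::write.table(truthTab, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    paths <- c(paths, params = file.path(dir, "params.json"))
    slots <- slotNames(spec)
    vals <- lapply(stats::setNames(slots, slots), function(s) slot(spec, s))
    jsonlite::write_json(vals, paths[["params"]], auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(paths)
}
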
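#' @import methods
NULL

#' Filter criteria for building an interaction database
#'
#' Describes which interaction records qualify for the statistical background:
#' an optional NCBI taxon filter (both interactors must match), an optional set
#' of interaction-type terms (PSI-MI identifiers such as `"MI:0915"` are
#' matched exactly; anything else is matched as a case-insensitive substring of
#' the type label), and an optional identifier namespace (the `db:` prefix a
#' record's identifiers must carry, e.g. `"uniprotkb"`).
#'
#' @slot species character vector of length 0 or 1; NCBI taxon id as a string.
#' @slot interactionTypes character vector (possibly empty) of type terms.
#' @slot idNamespace character vector of length 0 or 1; identifier prefix.
#'
#' @seealso [filterCriteria()], [buildInteractionDb()]
#' @exportClass FilterCriteria
setClass("FilterCriteria",
  representation(
    species = "character",
    interactionTypes = "character",
    idNamespace = "character"
  ),
  prototype(
    species = character(0),
    interactionTypes = character(0),
    idNamespace = character(0)
  )
)

setValidity("FilterCriteria", function(object) {
  msgs <- character(0)
  if (length(object@species) > 1L)
    msgs <- c(msgs, "species must have length 0 or 1")
  if (length(object@species) == 1L && !nzchar(object@species))
    msgs <- c(msgs, "species, when set, must be a non-empty string")
  if (length(object@interactionTypes) > 0L &&
      any(!nzchar(object@interactionTypes)))
    msgs <- c(msgs, "interactionTypes must not contain empty strings")
  if (length(object@idNamespace) > 1L)
    msgs <- c(msgs, "idNamespace must have length 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Deduplicated undirected interaction database
#'
#' The statistical universe for contextual-hub analysis: a simple undirected
#' graph over normalized gene identifiers. Self-interactions are disregarded
#' and multiple evidence lines for the same pair collapse to one edge. The
#' number of nodes (each has at least one edge by construction) is the
#' background population size N of the hypergeometric test.
#'
#' @slot edges two-column character matrix of unordered pairs, stored with the
#'   lexicographically smaller identifier first and rows in lexicographic
#'   order; one row per distinct non-self pair.
#' @slot adjacency named list mapping each node to the sorted character vector
#'   of its interaction partners; symmetric by construction.
#'
#' @seealso [buildInteractionDb()], [backgroundSize()], [dbDegree()]
#' @exportClass InteractionDb
setClass("InteractionDb",
  representation(
    edges = "matrix",
    adjacency = "list"
  )
)

setValidity("InteractionDb", function(object) {
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (nrow(e) == 0L)
    return("database must contain at least one edge")
  if (any(e[, 1L] == e[, 2L]))
    return("self-interactions are not allowed")
  if (any(e[, 1L] > e[, 2L]))
    return("edge pairs must be stored smaller identifier first")
  if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\t")))
    return("duplicate edges are not allowed")
  adj <- object@adjacency
  if (is.null(names(adj)) || anyDuplicated(names(adj)))
    return("adjacency must be uniquely named")
  # symmetry: b in adj[[a]] <=> a in adj[[b]]
  for (a in names(adj)) {
    for (b in adj[[a]]) {
      if (is.null(adj[[b]]) || !(a %in% adj[[b]]))
        return(sprintf("adjacency is not symmetric at %s-%s", a, b))
    }
  }
  if (any(lengths(adj) == 0L))
    return("every stored node must have at least one neighbor")
  TRUE
})

#' User-supplied contextual gene table
#'
#' The parsed gene list with its attribute columns, plus the subset of genes
#' designated contextually relevant by the user predicate (e.g. fold-change
#' above a threshold). All listed genes seed the network; the predicate
#' controls only contextual status.
#'
#' @slot table data.frame with one row per distinct gene; first column holds
#'   the normalized gene identifier.
#' @slot idColumn name of the identifier column in `table`.
#' @slot eligible character vector of normalized gene identifiers satisfying
#'   the contextual predicate.
#' @slot predicate list describing the predicate (or the string `"all"`),
#'   retained for run metadata.
#'
#' @seealso [parseContextTable()], [resolveContext()]
#' @exportClass ContextInput
setClass("ContextInput",
  representation(
    table = "data.frame",
    idColumn = "character",
    eligible = "character",
    predicate = "list"
  )
)

setValidity("ContextInput", function(object) {
  msgs <- character(0)
  if (nrow(object@table) == 0L)
    msgs <- c(msgs, "context table must have at least one row")
  if (!(object@idColumn %in% colnames(object@table)))
    msgs <- c(msgs, "idColumn must name a column of the table")
  else if (anyDuplicated(object@table[[object@idColumn]]))
    msgs <- c(msgs, "gene identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Contextual gene set resolved against a database
#'
#' The contextually relevant genes partitioned into those present in the
#' interaction database (these define K, the success count of the
#' hypergeometric background) and those absent from it.
#'
#' @slot contextual sorted character vector of contextual genes with at least
#'   one database interaction.
#' @slot missing character vector of contextual genes absent from the
#'   database, in input order.
#'
#' @seealso [resolveContext()], [contextK()]
#' @exportClass ContextSet
setClass("ContextSet",
  representation(
    contextual = "character",
    missing = "character"
  )
)

setValidity("ContextSet", function(object) {
  msgs <- character(0)
  if (length(object@contextual) == 0L)
    msgs <- c(msgs, "contextual set must be non-empty")
  if (length(intersect(object@contextual, object@missing)) > 0L)
    msgs <- c(msgs, "contextual and missing sets must be disjoint")
  if (anyDuplicated(object@contextual))
    msgs <- c(msgs, "contextual genes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Seed plus first-neighbor network
#'
#' The analysis network: all uploaded genes found in the database (seeds)
#' together with their first-neighbor interactors. Edges touching at least one
#' seed are display edges; edges between first neighbors are part of the
#' analysis but hidden from visualization.
#'
#' @slot seeds sorted character vector of seed nodes.
#' @slot neighborNodes sorted character vector of first neighbors (disjoint
#'   from seeds).
#' @slot displayEdges two-column character matrix: database edges with at
#'   least one seed endpoint.
#' @slot hiddenEdges two-column character matrix: database edges with both
#'   endpoints among the first neighbors.
#'
#' @seealso [buildNetwork()], [exportSif()], [exportGraphml()]
#' @exportClass ContextNetwork
setClass("ContextNetwork",
  representation(
    seeds = "character",
    neighborNodes = "character",
    displayEdges = "matrix",
    hiddenEdges = "matrix"
  )
)

setValidity("ContextNetwork", function(object) {
  msgs <- character(0)
  if (length(object@seeds) == 0L)
    msgs <- c(msgs, "network must have at least one seed")
  if (length(intersect(object@seeds, object@neighborNodes)) > 0L)
    msgs <- c(msgs, "seeds and neighbors must be disjoint")
  nodes <- c(object@seeds, object@neighborNodes)
  de <- object@displayEdges
  he <- object@hiddenEdges
  if (nrow(de) > 0L &&
      !all(de[, 1L] %in% object@seeds | de[, 2L] %in% object@seeds))
    msgs <- c(msgs, "every display edge must touch a seed")
  if (nrow(he) > 0L &&
      !all(he[, 1L] %in% object@neighborNodes &
           he[, 2L] %in% object@neighborNodes))
    msgs <- c(msgs, "hidden edges must join two neighbors")
  keyd <- if (nrow(de)) paste(de[, 1L], de[, 2L]) else character(0)
  keyh <- if (nrow(he)) paste(he[, 1L], he[, 2L]) else character(0)
  if (length(intersect(keyd, keyh)) > 0L)
    msgs <- c(msgs, "an edge cannot be both displayed and hidden")
  if (length(msgs)) msgs else TRUE
})

#' Ranked hub table
#'
#' A deterministic ordering of node scores under one of two criteria:
#' `"contextual"` (ascending adjusted p-value of the contextual-interactor
#' enrichment test) or `"degree"` (descending database degree). The full
#' ordering is retained; `top` records how many leading entries form the hub
#' list used in comparisons.
#'
#' @slot table data.frame of scores in ranked order with a leading `rank`
#'   column.
#' @slot criterion `"contextual"` or `"degree"`.
#' @slot top number of leading entries in the hub list.
#'
#' @seealso [rankHubs()], [topNodes()], [compareRankings()]
#' @exportClass HubRanking
setClass("HubRanking",
  representation(
    table = "data.frame",
    criterion = "character",
    top = "integer"
  )
)

setValidity("HubRanking", function(object) {
  msgs <- character(0)
  if (!(object@criterion %in% c("contextual", "degree")))
    msgs <- c(msgs, "criterion must be 'contextual' or 'degree'")
  if (object@top < 1L)
    msgs <- c(msgs, "top must be >= 1")
  if (nrow(object@table) == 0L)
    msgs <- c(msgs, "ranking must contain at least one score")
  if (length(msgs)) msgs else TRUE
})

#' Specification for synthetic benchmark data
#'
#' Parameters of the synthetic interaction-database generator: a background
#' random graph (uniform Erdos-Renyi density `edgeProb`, or a heavy-tailed
#' degree distribution with exponent `degreeExponent`), K contextual labels,
#' and optional planted hubs. Planted contextual hubs are wired to
#' `plantedDegree` partners of which a fraction `contextualWiringRate` are
#' contextual; planted promiscuous hubs are wired to `promiscuousDegree`
#' partners drawn uniformly.
#'
#' @slot nNodes number of nodes.
#' @slot edgeProb background edge probability (NA when using the heavy-tailed
#'   model).
#' @slot degreeExponent power-law exponent of the heavy-tailed background (NA
#'   when using the uniform model).
#' @slot K number of contextual labels.
#' @slot nPlantedContextual number of planted contextual hubs.
#' @slot plantedDegree wiring degree of each planted contextual hub.
#' @slot contextualWiringRate fraction of a planted contextual hub's partners
#'   drawn from the contextual set.
#' @slot nPlantedPromiscuous number of planted promiscuous hubs.
#' @slot promiscuousDegree wiring degree of each planted promiscuous hub.
#' @slot seed integer random seed; all outputs are pure functions of the spec.
#'
#' @seealso [syntheticSpec()], [generateNull()], [generatePlanted()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nNodes = "integer",
    edgeProb = "numeric",
    degreeExponent = "numeric",
    K = "integer",
    nPlantedContextual = "integer",
    plantedDegree = "integer",
    contextualWiringRate = "numeric",
    nPlantedPromiscuous = "integer",
    promiscuousDegree = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (object@nNodes < 2L)
    msgs <- c(msgs, "nNodes must be >= 2")
  if (is.na(object@edgeProb) && is.na(object@degreeExponent))
    msgs <- c(msgs, "one of edgeProb or degreeExponent must be set")
  if (!is.na(object@edgeProb) &&
      (object@edgeProb < 0 || object@edgeProb > 1))
    msgs <- c(msgs, "edgeProb must be in [0, 1]")
  if (!is.na(object@degreeExponent) && object@degreeExponent <= 0)
    msgs <- c(msgs, "degreeExponent must be positive")
  if (object@K < 1L || object@K > object@nNodes)
    msgs <- c(msgs, "K must be in [1, nNodes]")
  if (object@nPlantedContextual < 0L ||
      object@nPlantedContextual > object@nNodes)
    msgs <- c(msgs, "nPlantedContextual must be in [0, nNodes]")
  if (object@nPlantedPromiscuous < 0L ||
      object@nPlantedPromiscuous > object@nNodes)
    msgs <- c(msgs, "nPlantedPromiscuous must be in [0, nNodes]")
  if (object@nPlantedContextual > 0L && object@plantedDegree < 1L)
    msgs <- c(msgs, "plantedDegree must be >= 1")
  if (object@contextualWiringRate < 0 || object@contextualWiringRate > 1)
    msgs <- c(msgs, "contextualWiringRate must be in [0, 1]")
  if (object@nPlantedPromiscuous > 0L && object@promiscuousDegree < 1L)
    msgs <- c(msgs, "promiscuousDegree must be >= 1")
  if (is.na(object@seed))
    msgs <- c(msgs, "seed must be set")
  if (length(msgs)) msgs else TRUE
})
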
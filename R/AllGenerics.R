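#' Number of genes in the statistical background
#'
#' Returns N, the number of genes with at least one interaction in the
#' database: the population size of the hypergeometric test. Every node stored
#' in an [InteractionDb-class] has at least one edge, so this equals the node
#' count.
#'
#' @param db an [InteractionDb-class].
#' @return integer scalar N.
#' @examples
#' db <- buildInteractionDb(data.frame(
#'   id_a = c("A", "A"), id_b = c("B", "C"),
#'   taxid_a = "", taxid_b = "", interaction_type = "",
#'   source_line = 1:2))
#' backgroundSize(db)
#' @export
setGeneric("backgroundSize", function(db) standardGeneric("backgroundSize"))

#' Database accessors
#'
#' `dbNodes` returns the sorted node identifiers, `dbEdges` the deduplicated
#' edge matrix, `nEdges` the number of distinct unordered non-self pairs,
#' `dbDegree` the number of distinct interaction partners of each query node
#' (self excluded), and `interactorsOf` the sorted partners of one node.
#'
#' @param db an [InteractionDb-class].
#' @param nodes character vector of node identifiers.
#' @param node a single node identifier.
#' @return `dbNodes`/`interactorsOf`: character vector; `dbEdges`: two-column
#'   character matrix; `nEdges`: integer; `dbDegree`: named integer vector.
#' @name db-accessors
#' @export
setGeneric("dbNodes", function(db) standardGeneric("dbNodes"))

#' @rdname db-accessors
#' @export
setGeneric("dbEdges", function(db) standardGeneric("dbEdges"))

#' @rdname db-accessors
#' @export
setGeneric("nEdges", function(db) standardGeneric("nEdges"))

#' @rdname db-accessors
#' @export
setGeneric("dbDegree", function(db, nodes) standardGeneric("dbDegree"))

#' @rdname db-accessors
#' @export
setGeneric("interactorsOf", function(db, node) standardGeneric("interactorsOf"))

#' Contextual-set accessors
#'
#' `contextK` returns K, the number of contextual genes with at least one
#' database interaction (the success count of the hypergeometric background);
#' `contextualNodes` the sorted contextual genes present in the database;
#' `missingNodes` the contextual genes absent from it, in input order.
#'
#' @param x a [ContextSet-class].
#' @return `contextK`: integer; the others: character vectors.
#' @name context-accessors
#' @export
setGeneric("contextK", function(x) standardGeneric("contextK"))

#' @rdname context-accessors
#' @export
setGeneric("contextualNodes", function(x) standardGeneric("contextualNodes"))

#' @rdname context-accessors
#' @export
setGeneric("missingNodes", function(x) standardGeneric("missingNodes"))

#' Network accessors
#'
#' `seedNodes` returns the seed genes (uploaded genes found in the database),
#' `neighborNodes` their first-neighbor interactors, `networkNodes` the union
#' of the two, `displayEdges` the edges shown in a visualization (at least one
#' seed endpoint) and `hiddenEdges` the neighbor-neighbor edges that are part
#' of the analysis but hidden from display.
#'
#' @param x a [ContextNetwork-class].
#' @return character vectors, or two-column character matrices for the edge
#'   accessors.
#' @name network-accessors
#' @export
setGeneric("seedNodes", function(x) standardGeneric("seedNodes"))

#' @rdname network-accessors
#' @export
setGeneric("neighborNodes", function(x) standardGeneric("neighborNodes"))

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname network-accessors
#' @export
setGeneric("displayEdges", function(x) standardGeneric("displayEdges"))

#' @rdname network-accessors
#' @export
setGeneric("hiddenEdges", function(x) standardGeneric("hiddenEdges"))

#' Ranking accessors
#'
#' `topNodes` returns the identifiers of the leading `top` entries of a hub
#' ranking; `rankingTable` the full ordered score table with rank column.
#'
#' @param x a [HubRanking-class].
#' @return `topNodes`: character vector; `rankingTable`: data.frame.
#' @name ranking-accessors
#' @export
setGeneric("topNodes", function(x) standardGeneric("topNodes"))

#' @rdname ranking-accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
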
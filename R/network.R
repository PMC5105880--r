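#' Build the seed + first-neighbor network
#'
#' Every uploaded gene found in the database seeds the network, regardless of
#' its contextual status. All first-neighbor interactors of the seeds are
#' added. Database edges restricted to the network are partitioned into
#' display edges (at least one seed endpoint, i.e. seed-seed and
#' seed-neighbor) and hidden edges (neighbor-neighbor); both partitions enter
#' the statistical analysis, but visualizations conventionally omit the
#' neighbor-neighbor edges for clarity.
#'
#' @param db an [InteractionDb-class].
#' @param input a [ContextInput-class].
#' @return a [ContextNetwork-class].
#' @examples
#' tab <- c("gene\tlogFC", "B\t2.5", "E\t3.0")
#' # with a database over nodes A..F, seeds {B, E} pull in their neighbors
#' @export
buildNetwork <- function(db, input) {
  stopifnot(is(db, "InteractionDb"), is(input, "ContextInput"))
  ids <- inputNodes(input)
  seeds <- sort(unique(ids[ids %in% dbNodes(db)]), method = "radix")
  if (length(seeds) == 0L)
    stop("no seed genes found: none of the uploaded genes is in the database")
  nb <- sort(setdiff(unique(unlist(db@adjacency[seeds], use.names = FALSE)),
                     seeds), method = "radix")
  e <- dbEdges(db)
  touches_seed <- e[, 1L] %in% seeds | e[, 2L] %in% seeds
  both_nb <- e[, 1L] %in% nb & e[, 2L] %in% nb
  new("ContextNetwork",
      seeds = seeds,
      neighborNodes = nb,
      displayEdges = e[touches_seed, , drop = FALSE],
      hiddenEdges = e[both_nb, , drop = FALSE])
}

#' @rdname network-accessors
setMethod("seedNodes", "ContextNetwork", function(x) x@seeds)

#' @rdname network-accessors
setMethod("neighborNodes", "ContextNetwork", function(x) x@neighborNodes)

#' @rdname network-accessors
setMethod("networkNodes", "ContextNetwork", function(x) {
  sort(c(x@seeds, x@neighborNodes), method = "radix")
})

#' @rdname network-accessors
setMethod("displayEdges", "ContextNetwork", function(x) x@displayEdges)

#' @rdname network-accessors
setMethod("hiddenEdges", "ContextNetwork", function(x) x@hiddenEdges)

#' @export
setMethod("show", "ContextNetwork", function(object) {
  cat("ContextNetwork:", length(object@seeds), "seed(s),",
      length(object@neighborNodes), "first neighbor(s);",
      nrow(object@displayEdges), "display +",
      nrow(object@hiddenEdges), "hidden edge(s)\n")
})

#' Export display edges as SIF
#'
#' Simple interaction format: three tab-separated columns
#' (`id`, `pp`, `id`), one line per display edge, lexicographic order.
#'
#' @param net a [ContextNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportSif <- function(net, path) {
  stopifnot(is(net, "ContextNetwork"))
  e <- displayEdges(net)
  writeLines(paste(e[, 1L], "pp", e[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export the full network as GraphML
#'
#' Writes display and hidden edges together, with a boolean edge attribute
#' `displayed`, and node attributes `role` (`seed`/`neighbor`) and
#' `contextual` (`true`/`false`).
#'
#' @param net a [ContextNetwork-class].
#' @param context a [ContextSet-class] supplying contextual flags.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportGraphml <- function(net, context, path) {
  stopifnot(is(net, "ContextNetwork"), is(context, "ContextSet"))
  de <- displayEdges(net)
  he <- hiddenEdges(net)
  edges <- data.frame(
    from = c(de[, 1L], he[, 1L]),
    to = c(de[, 2L], he[, 2L]),
    displayed = c(rep(TRUE, nrow(de)), rep(FALSE, nrow(he))),
    stringsAsFactors = FALSE
  )
  nodes <- networkNodes(net)
  vertices <- data.frame(
    name = nodes,
    role = ifelse(nodes %in% seedNodes(net), "seed", "neighbor"),
    contextual = ifelse(nodes %in% contextualNodes(context),
                        "true", "false"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
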
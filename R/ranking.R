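#' Rank hubs by contextual enrichment or by degree
#'
#' `"contextual"` ranks by ascending adjusted p-value, breaking ties by
#' ascending raw p-value, then descending k, then descending database degree,
#' then lexicographic node identifier. `"degree"` ranks by descending
#' database degree, breaking ties by ascending adjusted p-value, then
#' lexicographic identifier. Tie-breaking is fully deterministic (radix
#' ordering, locale-independent), so identical inputs give byte-identical
#' rankings on any platform.
#'
#' @param scores data.frame from [scoreNetwork()].
#' @param criterion `"contextual"` or `"degree"`.
#' @param top size of the leading hub list (default 20, the conventional
#'   display size); when larger than the score family the full list is used.
#' @return a [HubRanking-class].
#' @export
rankHubs <- function(scores, criterion = c("contextual", "degree"),
                     top = 20L) {
  if (length(criterion) != 1L || !(criterion %in% c("contextual", "degree")))
    stop("invalid criterion: must be 'contextual' or 'degree'")
  stopifnot(is.data.frame(scores), nrow(scores) > 0L, top >= 1L)
  ord <- if (criterion == "contextual") {
    order(scores$p_adj, scores$p_raw, -scores$k, -scores$db_degree,
          scores$node, method = "radix")
  } else {
    order(-scores$db_degree, scores$p_adj, scores$node, method = "radix")
  }
  tab <- scores[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  new("HubRanking", table = tab, criterion = criterion,
      top = as.integer(min(top, nrow(tab))))
}

#' @rdname ranking-accessors
setMethod("topNodes", "HubRanking", function(x) {
  x@table$node[seq_len(x@top)]
})

#' @rdname ranking-accessors
setMethod("rankingTable", "HubRanking", function(x) x@table)

#' @export
setMethod("show", "HubRanking", function(object) {
  cat("HubRanking (", object@criterion, "), top ", object@top, " of ",
      nrow(object@table), " node(s)\n", sep = "")
  cols <- c("rank", "node", "n", "k", "p_raw", "p_adj")
  cols <- intersect(cols, colnames(object@table))
  print(utils::head(object@table[, cols], object@top), row.names = FALSE)
})

#' Compare two hub rankings
#'
#' Measures the overlap of the two top lists: the shared node set and the
#' Jaccard index of the two lists. Disjoint top lists (Jaccard 0) indicate
#' that contextual hubs and conventional degree hubs capture different nodes.
#'
#' @param a,b [HubRanking-class] objects over the same score family.
#' @return list with `shared` (sorted character vector), `nShared`, and
#'   `jaccard`.
#' @export
compareRankings <- function(a, b) {
  stopifnot(is(a, "HubRanking"), is(b, "HubRanking"))
  ta <- topNodes(a)
  tb <- topNodes(b)
  shared <- sort(intersect(ta, tb), method = "radix")
  list(shared = shared,
       nShared = length(shared),
       jaccard = length(shared) / length(union(ta, tb)))
}

#' Node analyzer report
#'
#' Details the connectivity pattern of a single scored node: all of its
#' database interactors, each flagged for contextual status and for
#' membership in the constructed network, ordered contextual-first then
#' lexicographically.
#'
#' @param db an [InteractionDb-class].
#' @param scores data.frame from [scoreNetwork()].
#' @param net a [ContextNetwork-class].
#' @param context a [ContextSet-class].
#' @param node identifier of a scored node.
#' @return list with `node`, `p_adj`, and `interactors` (data.frame with
#'   columns `interactor`, `contextual`, `in_network`).
#' @export
nodeReport <- function(db, scores, net, context, node) {
  stopifnot(is(db, "InteractionDb"), is(net, "ContextNetwork"),
            is(context, "ContextSet"))
  row <- match(node, scores$node)
  if (is.na(row))
    stop("node not in network: '", node, "' was not scored")
  nb <- interactorsOf(db, node)
  ctx <- nb %in% contextualNodes(context)
  innet <- nb %in% networkNodes(net)
  ord <- order(!ctx, nb, method = "radix")
  list(node = node,
       p_adj = scores$p_adj[row],
       interactors = data.frame(interactor = nb[ord],
                                contextual = ctx[ord],
                                in_network = innet[ord],
                                stringsAsFactors = FALSE))
}

#' Side-by-side ranking comparison report
#'
#' Builds the comparison table shown to the user: for each rank position, the
#' contextual hub with its adjusted p-value next to the degree hub with its
#' database degree, followed by overlap statistics.
#'
#' @param contextual a [HubRanking-class] with criterion `"contextual"`.
#' @param degree a [HubRanking-class] with criterion `"degree"`.
#' @return list with `table` (data.frame: `rank`, `contextual_node`, `p_adj`,
#'   `degree_node`, `db_degree`), `nShared`, `jaccard`, and `lines`
#'   (human-readable summary).
#' @export
reportComparison <- function(contextual, degree) {
  stopifnot(is(contextual, "HubRanking"), is(degree, "HubRanking"))
  if (contextual@criterion != "contextual" || degree@criterion != "degree")
    stop("invalid criterion: expected one contextual and one degree ranking")
  ov <- compareRankings(contextual, degree)
  nr <- min(contextual@top, degree@top)
  ct <- rankingTable(contextual)
  dt <- rankingTable(degree)
  tab <- data.frame(
    rank = seq_len(nr),
    contextual_node = ct$node[seq_len(nr)],
    p_adj = ct$p_adj[seq_len(nr)],
    degree_node = dt$node[seq_len(nr)],
    db_degree = dt$db_degree[seq_len(nr)],
    stringsAsFactors = FALSE
  )
  lines <- c(
    sprintf("top %d contextual vs top %d degree hubs",
            contextual@top, degree@top),
    sprintf("shared: %d", ov$nShared),
    sprintf("jaccard: %.4f", ov$jaccard)
  )
  list(table = tab, nShared = ov$nShared, jaccard = ov$jaccard,
       lines = lines)
}
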
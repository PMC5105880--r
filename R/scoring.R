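#' Score one node for contextual-interactor enrichment
#'
#' Computes the node's interactor count n (distinct database partners, self
#' excluded), the number k of those partners that are contextual, and the raw
#' upper-tail hypergeometric p-value against the database-wide background
#' (N, K). A node's own contextual status never enters its score: a node is
#' not its own interactor.
#'
#' @param db an [InteractionDb-class].
#' @param context a [ContextSet-class].
#' @param node a single node identifier present in the database.
#' @return one-row data.frame with columns `node`, `n`, `k`, `db_degree`
#'   (alias of `n`, the degree used for conventional hub ranking), `p_raw`.
#' @export
scoreNode <- function(db, context, node) {
  stopifnot(is(db, "InteractionDb"), is(context, "ContextSet"))
  nb <- interactorsOf(db, node)
  n <- length(nb)
  k <- sum(nb %in% contextualNodes(context))
  p <- hypergeomUpperTail(backgroundSize(db), contextK(context), n, k)
  data.frame(node = node, n = n, k = k, db_degree = n, p_raw = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction: the i-th smallest
#' p-value is adjusted to `min over j >= i of p_(j) * m / j`, capped at 1,
#' and results are returned in the input order. Delegates to
#' [stats::p.adjust()] after validating that every input lies in (0, 1].
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.005, 0.01, 0.03, 0.8))  # 0.02 0.02 0.04 0.8
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L)
    stop("invalid p-value: empty vector")
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("invalid p-value: all values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score every node of the network
#'
#' Runs the hypergeometric test on each node of the seed + first-neighbor
#' network. n and k are computed from the FULL filtered database adjacency
#' (not restricted to display edges), for consistency with the database-wide
#' background (N, K) and with the degree used for conventional hub ranking.
#' The BH family is exactly the set of network nodes (m = network size).
#'
#' @param db an [InteractionDb-class].
#' @param net a [ContextNetwork-class].
#' @param context a [ContextSet-class].
#' @return data.frame with one row per network node (lexicographic order):
#'   `node`, `role` (`seed`/`neighbor`), `contextual` (logical), `n`, `k`,
#'   `db_degree`, `p_raw`, `p_adj`.
#' @export
scoreNetwork <- function(db, net, context) {
  stopifnot(is(db, "InteractionDb"), is(net, "ContextNetwork"),
            is(context, "ContextSet"))
  nodes <- networkNodes(net)
  ctx <- contextualNodes(context)
  N <- backgroundSize(db)
  K <- contextK(context)
  n <- unname(dbDegree(db, nodes))
  k <- vapply(nodes, function(v) sum(db@adjacency[[v]] %in% ctx),
              integer(1), USE.NAMES = FALSE)
  p_raw <- hypergeomUpperTail(rep(N, length(nodes)), K, n, k)
  data.frame(
    node = nodes,
    role = ifelse(nodes %in% seedNodes(net), "seed", "neighbor"),
    contextual = nodes %in% ctx,
    n = n, k = k, db_degree = n,
    p_raw = p_raw,
    p_adj = bhAdjust(p_raw),
    stringsAsFactors = FALSE
  )
}
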
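# Shared fixtures and independent oracles, built in code.

# toy 7-edge database: adjacency A:{B,C,D} B:{A,C} C:{A,B,E} D:{A,E}
# E:{C,D,F} F:{E}; raw input contains a duplicate (B-A) and a self-loop (F-F)
toyEdgeLines <- function() {
  c("A\tB", "B\tA", "A\tC", "A\tD", "B\tC", "C\tE", "D\tE", "E\tF", "F\tF")
}

toyDb <- function() {
  buildInteractionDb(parseEdgeList(toyEdgeLines()))
}

toyContext <- function(genes = c("B", "C", "E")) {
  parseContextTable(c("gene", genes), "gene", "all")
}

# one valid 15-column MITAB line
mitabLine <- function(a, b, taxa = "taxid:9606(human)", taxb = taxa,
                      type = "psi-mi:\"MI:0915\"(physical association)") {
  paste(paste0("uniprotkb:", a), paste0("uniprotkb:", b),
        "-", "-", "-", "-", "-", "-", "-", taxa, taxb, type, "-", "-", "-",
        sep = "\t")
}

# independent hypergeometric oracle: enumerate every n-subset of a population
# in which elements 1..K are the successes, and count subsets with >= k
# successes. Exact (integer counts, small N), shares no code with the
# log-space implementation.
enumUpperTail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)   # elements 1..K are the successes
  sum(hits >= k) / ncol(subsets)
}

# independent BH step-up oracle: direct min over the tail, O(m^2)
stepUpOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# brute-force first-neighbor oracle: scan every edge touching a seed
bruteForceNetworkNodes <- function(db, seeds) {
  e <- dbEdges(db)
  nodes <- seeds
  for (i in seq_len(nrow(e))) {
    if (e[i, 1] %in% seeds || e[i, 2] %in% seeds)
      nodes <- union(nodes, e[i, ])
  }
  sort(nodes, method = "radix")
}
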
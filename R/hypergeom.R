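#' Upper-tail hypergeometric probability
#'
#' The probability that a node with n interactors has k or more contextual
#' interactors by chance, when K of the N background genes are contextual:
#'
#' \deqn{P(X \ge k) = \sum_{x=k}^{\min(n,K)}
#'   \binom{K}{x}\binom{N-K}{n-x} \big/ \binom{N}{n}}
#'
#' Terms are evaluated in log-space via `lchoose` and summed from the largest
#' term downward, so the tail is stable for database-scale parameters
#' (N in the tens of thousands). The result is capped at 1 to absorb
#' floating-point rounding; `P(X >= 0)` is exactly 1.
#'
#' @param N background population size: genes with at least one qualifying
#'   interaction in the database.
#' @param K number of contextual genes among the N.
#' @param n number of distinct interactors of the node under test.
#' @param k observed number of contextual interactors.
#' @return probability in (0, 1]. Vectorized over `k` (and over `N`, `K`,
#'   `n` when given equal lengths).
#' @examples
#' hypergeomUpperTail(6, 3, 3, 2)   # 0.5
#' hypergeomUpperTail(10, 4, 3, 2)  # 1/3
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(as.numeric(N), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); k <- rep_len(as.numeric(k), len)
  if (anyNA(c(N, K, n, k)))
    stop("invalid hypergeometric parameters: NA not allowed")
  if (any(K < 0 | K > N))
    stop("invalid hypergeometric parameters: need 0 <= K <= N")
  if (any(n < 0 | n > N))
    stop("invalid hypergeometric parameters: need 0 <= n <= N")
  if (any(k < 0 | k > pmin(n, K)))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K)")
  vapply(seq_len(len), function(i) {
    if (k[i] == 0) return(1)
    x <- seq.int(k[i], min(n[i], K[i]))
    lt <- lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) -
      lchoose(N[i], n[i])
    m <- max(lt)
    min(1, exp(m) * sum(exp(lt - m)))
  }, numeric(1))
}
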
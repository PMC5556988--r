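#' Karlin-Altschul statistics for an ungapped match/mismatch scheme
#'
#' Solves the scale parameter lambda numerically from
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` and computes the lattice-case K
#' via truncated convolution of the score distribution. With identity
#' scoring the score distribution reduces to two atoms: `match` with the
#' probability that two background letters agree, `mismatch` otherwise.
#' For the classic nucleotide scheme +1/-2 on uniform composition this
#' yields lambda = 1.33, K = 0.621, matching published values.
#'
#' Gapped alignments reuse the ungapped lambda and K as a documented
#' approximation, as is common for seeded nucleotide searches.
#'
#' @param match,mismatch Match reward (> 0) and mismatch penalty (< 0).
#' @param base_freq Background base frequencies over A, C, G, T (recycled to
#'   sum to one). Defaults to uniform.
#' @return A list with elements `lambda`, `K`, `H` (relative entropy, nats)
#'   and `p_match`.
#' @export
#' @examples
#' karlin_altschul_params(1, -2)
karlin_altschul_params <- function(match = 2, mismatch = -3,
                                   base_freq = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, length(base_freq) == 4, all(base_freq >= 0))
  f <- base_freq / sum(base_freq)
  p_match <- sum(f^2)
  ev <- p_match * match + (1 - p_match) * mismatch
  if (ev >= 0) {
    abort("expected score must be negative for Karlin-Altschul statistics")
  }
  lam <- uniroot(
    function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1,
    c(1e-9, 50), tol = 1e-12
  )$root

  # lattice K: scores are integers (scaled to their gcd)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  stopifnot(match == round(match), mismatch == round(mismatch))
  delta <- gcd2(abs(match), abs(mismatch))
  lo <- min(match, mismatch)
  span <- max(match, mismatch) - lo
  pmf <- numeric(span + 1)
  pmf[match - lo + 1] <- p_match
  pmf[mismatch - lo + 1] <- pmf[mismatch - lo + 1] + 1 - p_match
  sigma <- 0
  cur <- 1
  cur_lo <- 0
  for (k in 1:80) {
    newv <- numeric(length(cur) + span)
    for (i in seq_along(pmf)) {
      if (pmf[i] > 0) {
        idx <- seq_along(cur) + (i - 1)
        newv[idx] <- newv[idx] + cur * pmf[i]
      }
    }
    cur <- newv
    cur_lo <- cur_lo + lo
    vals <- cur_lo + seq_along(cur) - 1
    neg <- vals < 0
    sigma <- sigma + (sum(cur[neg] * exp(lam * vals[neg])) + sum(cur[!neg])) / k
  }
  vals <- lo + seq_along(pmf) - 1
  H <- lam * sum(vals * pmf * exp(lam * vals))
  K <- delta * lam * exp(-2 * sigma) / (H * (1 - exp(-lam * delta)))
  list(lambda = lam, K = K, H = H, p_match = p_match)
}

#' E-value of an alignment score
#'
#' Karlin-Altschul expectation `E = K m n exp(-lambda S)` for a raw score
#' `S` in a search space of query length `m` against subject length `n`.
#' Computed in log space so that very strong hits report `evalue = 0`
#' while `log10_evalue` stays informative.
#'
#' @param score Raw alignment score(s).
#' @param m,n Query and subject (total) lengths in bp.
#' @param ka List from [karlin_altschul_params()].
#' @return Tibble with columns `score`, `evalue`, `log10_evalue`, `bit_score`.
#' @export
alignment_evalue <- function(score, m, n, ka = karlin_altschul_params()) {
  stopifnot(m > 0, n > 0)
  log_e <- log(ka$K) + log(m) + log(n) - ka$lambda * score
  tibble(
    score = score,
    evalue = exp(log_e),
    log10_evalue = log_e / log(10),
    bit_score = (ka$lambda * score - log(ka$K)) / log(2)
  )
}
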
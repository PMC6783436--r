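# MCMC convergence diagnostics: split rank-normalized R-hat and effective
# sample size (Geyer initial-monotone autocorrelation estimator).

split_chains <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2L
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1L):n, , drop = FALSE])
}

rank_normalize <- function(draws) {
  r <- rank(as.vector(draws), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}

rhat_basic <- function(draws) {
  m <- ncol(draws); n <- nrow(draws)
  mu <- colMeans(draws)
  s2 <- apply(draws, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split rank-normalized R-hat
#'
#' Chains are split in half, draws are replaced by their normal scores
#' (computed from pooled ranks), and the classic potential scale reduction
#' factor is computed on the result. Values near 1 indicate mixing; a
#' constant (zero-variance) input has no defined R-hat and returns `NA`.
#'
#' @param draws Matrix of posterior draws, iterations x chains (>= 2 chains
#'   with >= 4 draws each).
#' @return Scalar R-hat (>= 1 up to floating error), or `NA` for
#'   degenerate draws.
#' @export
compute_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) {
    stop("R-hat needs at least 2 chains", call. = FALSE)
  }
  if (nrow(draws) < 4L) stop("R-hat needs at least 4 draws per chain",
                             call. = FALSE)
  if (!all(is.finite(draws))) return(NA_real_)
  if (max(draws) - min(draws) < .Machine$double.eps^0.5) return(NA_real_)
  sp <- split_chains(draws)
  max(rhat_basic(rank_normalize(sp)),
      rhat_basic(rank_normalize(abs(sweep(sp, 2, apply(sp, 2, stats::median))))),
      na.rm = TRUE)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain ESS from the combined autocorrelation function (per-chain
#' autocovariances pooled against the between/within variance estimate),
#' with Geyer's initial positive-sequence and monotone truncation. For
#' independent draws the estimate is close to the total number of draws;
#' a constant chain returns 0.
#'
#' @param draws Matrix of posterior draws, iterations x chains (a vector is
#'   treated as one chain).
#' @return Scalar effective sample size.
#' @export
compute_ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4L) stop("ESS needs at least 4 draws", call. = FALSE)
  if (!all(is.finite(draws))) return(NA_real_)
  if (max(draws) - min(draws) < .Machine$double.eps^0.5) return(0)
  s2 <- apply(draws, 2, var)
  W <- mean(s2)
  var_plus <- W * (n - 1) / n + if (m > 1) var(colMeans(draws)) else 0
  # per-chain autocovariances (biased, as in standard practice)
  max_lag <- n - 2L
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = max_lag, plot = FALSE,
             type = "covariance", demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- matrix(acov, ncol = m)
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer: accumulate adjacent-lag pair sums while they stay positive,
  # enforcing monotone decrease; tau = -1 + 2 * sum of pairs
  tau <- -1
  t <- 1L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(tau, 1 / log10(m * n + 10))
  ess <- m * n / tau
  min(ess, m * n * log10(m * n))  # cap antithetic estimates
}
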
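# Group-level random-effects Bayesian model selection on per-subject
# log-evidence (summed PSIS-LOO scores): variational Dirichlet update over
# model frequencies, exceedance probabilities by Monte Carlo, and the
# Bayesian omnibus risk from a free-energy comparison against the
# equal-frequency null.

#' Random-effects Bayesian model selection
#'
#' Treats the model identity of each subject as a draw from unknown
#' population frequencies with a flat Dirichlet prior, updated by a
#' variational scheme. Reports expected model frequencies, exceedance
#' probabilities (probability a model is the most frequent), the Bayesian
#' omnibus risk `BOR` (posterior probability that all frequencies are
#' equal), and protected exceedance probabilities
#' `pxp = (1 - BOR) * xp + BOR / K`.
#'
#' @param evidence Subjects x models matrix of log model evidence
#'   (e.g. from [evidence_matrix()]).
#' @param n_draws Monte-Carlo draws from the Dirichlet posterior for the
#'   exceedance probabilities.
#' @param seed Seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence control for the variational iteration.
#' @return A `loop_bms`: `expected_frequencies`, `exceedance_prob`, `pxp`
#'   (each a simplex over models), `bor`, `alpha` (Dirichlet posterior
#'   counts), `assignment` (subject x model responsibilities), and the
#'   free energies `F1`, `F0`.
#' @export
bms <- function(evidence, n_draws = 1e5, seed = 1L, tol = 1e-8,
                max_iter = 1000L) {
  ev <- as.matrix(evidence)
  if (!all(is.finite(ev))) stop("non-finite evidence values", call. = FALSE)
  n <- nrow(ev); K <- ncol(ev)
  if (K < 2L) stop("model selection needs at least 2 models", call. = FALSE)
  models <- colnames(ev)
  if (is.null(models)) models <- paste0("M", seq_len(K))

  alpha0 <- rep(1, K)
  alpha <- alpha0
  z <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    w <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    z_new <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(z_new)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new; z <- z_new
      break
    }
    alpha <- alpha_new; z <- z_new
  }
  ef <- alpha / sum(alpha)

  # exceedance probabilities by Monte Carlo over the Dirichlet posterior
  xp <- withr::with_seed(seed, {
    g <- matrix(rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                n_draws, K)
    win <- max.col(g, ties.method = "random")
    tabulate(win, K) / n_draws
  })

  # free energy of the random-effects model vs the equal-frequency null
  dg <- digamma(alpha) - digamma(sum(alpha))
  z_safe <- pmax(z, 1e-300)
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * dg)
  F1 <- sum(z * ev) + sum(z * rep(dg, each = n)) -
    sum(z * log(z_safe)) - kl_dir
  F0 <- sum(apply(ev, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / K

  structure(list(expected_frequencies = setNames(ef, models),
                 exceedance_prob = setNames(xp, models),
                 pxp = setNames(pxp, models),
                 bor = bor, alpha = setNames(alpha, models),
                 assignment = z, F1 = F1, F0 = F0,
                 n_subjects = n),
            class = "loop_bms")
}

#' @export
print.loop_bms <- function(x, ...) {
  cat("<loop_bms> ", x$n_subjects, " subjects, ",
      length(x$pxp), " models\n", sep = "")
  tab <- rbind(`E[freq]` = x$expected_frequencies,
               xp = x$exceedance_prob, pxp = x$pxp)
  print(round(tab, 4))
  cat("BOR:", signif(x$bor, 3), "\n")
  invisible(x)
}

#' Write a BMS result to JSON
#' @param x A `loop_bms`.
#' @param path Output file.
#' @export
write_bms <- function(x, path) {
  jsonlite::write_json(
    list(expected_frequencies = as.list(x$expected_frequencies),
         exceedance_prob = as.list(x$exceedance_prob),
         pxp = as.list(x$pxp), bor = x$bor),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
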
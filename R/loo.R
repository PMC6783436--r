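# Approximate leave-one-out cross-validation from posterior draws via
# Pareto-smoothed importance sampling (PSIS).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit (shape k, scale sigma) to tail exceedances by the
# Zhang & Stephens (2009) profile posterior-mean method, with the usual
# weak-prior shrinkage of k toward 0.5.
gpd_fit <- function(x, prior_shift = TRUE) {
  x <- sort.int(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  # shape k in the heavy-tail-positive convention; grid over theta = -k/sigma
  k_of <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_theta <- n * (log(-theta / k_of) - k_of - 1)  # profile log-lik
  l_theta[!is.finite(l_theta)] <- -Inf
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (prior_shift) k <- (k * n + 5) / (n + 10)
  c(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * (((1 - p)^(-k)) - 1) / k
}

# Pareto-smooth one vector of log importance ratios. Returns normalized
# log-weights and the Pareto shape diagnostic k-hat.
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  tail_ids <- order(lw, decreasing = TRUE)[seq_len(m)]
  cutoff <- max(lw[-tail_ids])
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(lw) - min(lw) < .Machine$double.eps^0.25 ||
      max(exceed) <= .Machine$double.eps^0.5) {
    # (near-)uniform ratios: nothing to smooth, tail shape effectively -Inf
    khat <- -Inf
  } else {
    fit <- gpd_fit(exceed[exceed > 0])
    khat <- unname(fit["k"])
    if (is.finite(khat)) {
      ord <- order(exp(lw[tail_ids]))
      qq <- qgpd((seq_len(m) - 0.5) / m, fit["k"], fit["sigma"]) + exp(cutoff)
      lw[tail_ids[ord]] <- pmin(log(qq), 0)  # cap at the pre-smoothing max
    }
  }
  lw <- lw - logsumexp(lw)
  list(log_weights = lw, khat = khat)
}

#' PSIS-LOO from a pointwise log-likelihood matrix
#'
#' For each trial, importance ratios proportional to the inverse pointwise
#' likelihood are stabilized by replacing the largest
#' `M = min(0.2 S, 3 sqrt(S))` weights with quantiles of a generalized
#' Pareto distribution fitted to them; the fitted shape k-hat diagnoses
#' reliability (trials with k-hat > `khat_threshold` are flagged). The
#' expected log predictive density per trial is the weighted average of the
#' likelihood over draws; the total is their sum with the usual
#' `sqrt(n * var)` standard error.
#'
#' @param pointwise_loglik Draws x trials matrix of log-likelihoods, or a
#'   [fit_subject()] result.
#' @param khat_threshold Flagging threshold for the Pareto shape
#'   (default 0.7).
#' @return A `loop_loo`: `elpd_loo`, `loo_se`, `pointwise` (per-trial
#'   elpd), `khat`, `flagged_trials`, `n_trials`, and `subject_id`/`model`
#'   when computed from a fit.
#' @export
psis_loo <- function(pointwise_loglik, khat_threshold = 0.7) {
  subject_id <- NA_character_; model_name <- NA_character_
  if (inherits(pointwise_loglik, "loop_fit")) {
    subject_id <- pointwise_loglik$subject_id
    model_name <- pointwise_loglik$model$name
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  }
  ll <- as.matrix(pointwise_loglik)
  s <- nrow(ll); n <- ncol(ll)
  if (s < 100L) stop("PSIS-LOO needs at least 100 posterior draws",
                     call. = FALSE)
  if (!all(is.finite(ll))) {
    bad <- which(!apply(is.finite(ll), 2, all))
    stop("non-finite log-likelihoods for trial(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  pointwise <- numeric(n); khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    khat[i] <- sm$khat
    pointwise[i] <- logsumexp(sm$log_weights + ll[, i])
  }
  flagged <- which(khat > khat_threshold)
  structure(list(subject_id = subject_id, model = model_name,
                 elpd_loo = sum(pointwise),
                 loo_se = sqrt(n * var(pointwise)),
                 pointwise = pointwise, khat = khat,
                 flagged_trials = flagged,
                 khat_threshold = khat_threshold, n_trials = n),
            class = "loop_loo")
}

#' @export
print.loop_loo <- function(x, ...) {
  cat("<loop_loo> elpd_loo ", round(x$elpd_loo, 1), " (SE ",
      round(x$loo_se, 1), "), ", length(x$flagged_trials), "/", x$n_trials,
      " trials with k-hat > ", x$khat_threshold, "\n", sep = "")
  invisible(x)
}

#' PSIS-LOO for every fit in a fitset
#' @param fitset A [fit_cohort()] result.
#' @param ... Passed to [psis_loo()].
#' @return Nested list `loos[[model]][[subject]]` of `loop_loo` objects.
#' @export
loo_set <- function(fitset, ...) {
  lapply(fitset, function(fits) lapply(fits, psis_loo, ...))
}

#' Subject x model evidence matrix of summed PSIS-LOO scores
#' @param loos A [loo_set()] result.
#' @return Numeric matrix (subjects x models) of `elpd_loo` values.
#' @export
evidence_matrix <- function(loos) {
  models <- names(loos)
  subjects <- names(loos[[1]])
  out <- vapply(models, function(m)
    vapply(subjects, function(s) loos[[m]][[s]]$elpd_loo, numeric(1)),
    numeric(length(subjects)))
  matrix(out, nrow = length(subjects), ncol = length(models),
         dimnames = list(subjects, models))
}

#' Re-score after dropping unreliable trials
#'
#' Removes the pointwise contributions of every trial flagged
#' (k-hat above threshold) in *any* model for a given subject, so that all
#' models remain scored on the same trials, and returns the corrected
#' evidence matrix for re-running model selection.
#'
#' @param loos A [loo_set()] result.
#' @return List with `evidence` (corrected subject x model matrix),
#'   `dropped` (named list of dropped trial indices per subject) and
#'   `n_dropped`.
#' @export
loo_sensitivity <- function(loos) {
  models <- names(loos)
  subjects <- names(loos[[1]])
  dropped <- setNames(lapply(subjects, function(s) {
    sort(unique(unlist(lapply(models, function(m)
      loos[[m]][[s]]$flagged_trials))))
  }), subjects)
  evidence <- vapply(models, function(m) vapply(subjects, function(s) {
    l <- loos[[m]][[s]]
    d <- dropped[[s]]
    if (length(d)) sum(l$pointwise[-d]) else l$elpd_loo
  }, numeric(1)), numeric(length(subjects)))
  evidence <- matrix(evidence, nrow = length(subjects),
                     dimnames = list(subjects, models))
  list(evidence = evidence, dropped = dropped,
       n_dropped = sum(lengths(dropped)))
}

#' Paired difference in expected predictive accuracy between two models
#'
#' The difference is the sum of the per-trial elpd differences; its
#' standard error comes from the variance of those paired pointwise
#' differences (`sqrt(n * var)`), the convention used when reporting a
#' model's deficit relative to the comparison winner.
#'
#' @param loo_a,loo_b `loop_loo` objects, or lists of them covering the
#'   same subjects and trials under two models.
#' @return List with `diff` (elpd_a - elpd_b) and `se`.
#' @export
loo_diff <- function(loo_a, loo_b) {
  pw <- function(x) {
    if (inherits(x, "loop_loo")) return(x$pointwise)
    unlist(lapply(x, `[[`, "pointwise"))
  }
  a <- pw(loo_a); b <- pw(loo_b)
  if (length(a) != length(b)) {
    stop("models were scored on different trial sets", call. = FALSE)
  }
  d <- a - b
  list(diff = sum(d), se = sqrt(length(d) * var(d)))
}
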
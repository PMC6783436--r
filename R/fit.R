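# Per-subject Bayesian fitting by adaptive Metropolis-within-Gibbs MCMC.

#' Sampler configuration
#'
#' Defaults follow the paradigm's fitting protocol: 3 chains, 1000 warmup
#' iterations per chain, 2400 retained draws in total after thinning by 3
#' (800 per chain, i.e. 3400 iterations per chain overall). Priors are
#' weakly informative and scale-appropriate: learning rates uniform on
#' \[0, 1\], initial beliefs (and condition means) normal(50, 20) truncated
#' to the rating scale, observation noise half-normal(20).
#'
#' @param n_chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param n_warmup Warmup iterations per chain (proposal scales adapt only
#'   here).
#' @param n_retained Total retained draws across chains (after thinning).
#' @param thin Thinning factor.
#' @param seed Integer seed making the fit deterministic.
#' @param priors List with `init_mean`, `init_sd`, `noise_scale`.
#' @return An object of class `loop_sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, n_warmup = 1000L,
                           n_retained = 2400L, thin = 3L, seed = 1L,
                           priors = list(init_mean = 50, init_sd = 20,
                                         noise_scale = 20)) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_retained >= n_chains, thin >= 1)
  if (n_retained %% n_chains != 0) {
    stop("n_retained must be divisible by n_chains", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_retained = as.integer(n_retained),
                 thin = as.integer(thin), seed = as.integer(seed),
                 priors = priors),
            class = "loop_sampler_config")
}

# Map init slots to per-condition indices for the C++ core.
init_slot_map <- function(model) {
  switch(model$init_scheme,
    fitted_per_condition = seq_along(model$conditions),
    fitted_combined = {
      agent_of_cond <- sub("_(high|low)$", "", model$conditions)
      match(paste0("init_", agent_of_cond), model$init_slots)
    },
    fixed_first_rating = integer(0))
}

#' Fit one subject's data with one learning model
#'
#' Posterior sampling by component-wise reflecting random-walk Metropolis
#' with per-parameter proposal scales adapted during warmup. Pointwise
#' log-likelihoods are evaluated at every retained draw, and split rank
#' normalized R-hat and effective sample sizes are computed per parameter.
#'
#' @param model A [model_spec()].
#' @param data A behavioral dataset (`loop_data` or data frame with columns
#'   `trial`, `agent`, `ability`, `feedback`, `exp_rating`).
#' @param cfg A [sampler_config()].
#' @param state Likelihood state formulation, see [predict_trajectory()].
#' @return An object of class `loop_fit`: `draws` (array draw x chain x
#'   parameter), `pointwise_loglik` (total draws x trials),
#'   `posterior_mean`, `posterior_median`, `rhat`, `ess`, `accept_rate`,
#'   `subject_id`, `model`, `cfg`.
#' @export
fit_subject <- function(model, data, cfg = sampler_config(),
                        state = c("latent", "observed")) {
  state <- match.arg(state)
  stopifnot(inherits(model, "loop_model"),
            inherits(cfg, "loop_sampler_config"))
  data <- as.data.frame(data)
  if (!nrow(data)) stop("data must be nonempty", call. = FALSE)
  enc <- encode_design(model, data)
  rating <- as.numeric(data$exp_rating)
  if (anyNA(rating)) stop("exp_rating contains missing values", call. = FALSE)

  n_cond <- length(model$conditions)
  imap <- init_slot_map(model)
  mean_model <- model$rule == "mean"
  if (mean_model) imap <- seq_len(n_cond)
  n_theta2 <- if (mean_model) n_cond else length(model$init_slots)
  fixed_inits <- if (!mean_model && model$init_scheme == "fixed_first_rating") {
    vapply(seq_len(n_cond), function(c) {
      i <- which(enc$cond_idx == c)[1]
      if (is.na(i)) 50 else rating[i]
    }, numeric(1))
  } else numeric(n_cond)

  P <- model$n_alpha_slots + n_theta2 + 1L
  par_names <- c(model$alpha_slots,
                 if (mean_model) model$mean_slots else model$init_slots,
                 "noise_sd")

  # start values: alphas mid-prior, second block at each condition's first
  # rating (or 50), noise at the rating-residual scale
  start2 <- vapply(seq_len(n_theta2), function(j) {
    i <- which(imap == j & !duplicated(imap))[1]
    i <- which(enc$cond_idx %in% which(imap == j))[1]
    if (is.na(i)) 50 else rating[i]
  }, numeric(1))
  start <- c(rep(0.3, model$n_alpha_slots), start2, 10)
  scales0 <- c(rep(0.1, model$n_alpha_slots), rep(5, n_theta2), 2)
  per_chain <- cfg$n_retained %/% cfg$n_chains
  n_post <- per_chain * cfg$thin
  prior <- c(cfg$priors$init_mean, cfg$priors$init_sd,
             cfg$priors$noise_scale)

  draws <- array(NA_real_, dim = c(per_chain, cfg$n_chains, P),
                 dimnames = list(NULL, NULL, par_names))
  acc <- matrix(NA_real_, cfg$n_chains, P)
  withr::with_seed(cfg$seed, {
    for (ch in seq_len(cfg$n_chains)) {
      # overdisperse chain starts deterministically within the seeded block
      st <- start
      if (model$n_alpha_slots > 0) {
        st[seq_len(model$n_alpha_slots)] <- runif(model$n_alpha_slots, 0.05, 0.6)
      }
      st[P] <- runif(1, 5, 20)
      res <- cpp_mwg_sample(enc$feedback, enc$cond_idx, enc$slot_pos,
                            enc$slot_neg, rating, as.integer(imap),
                            fixed_inits, mean_model, state == "observed",
                            model$n_alpha_slots, n_theta2, n_cond,
                            cfg$n_warmup, n_post, cfg$thin,
                            st, prior, scales0)
      draws[, ch, ] <- res$draws
      acc[ch, ] <- res$accept_rate
    }
  })

  flat <- matrix(draws, nrow = per_chain * cfg$n_chains, ncol = P,
                 dimnames = list(NULL, par_names))
  pw <- cpp_pointwise_loglik(flat, enc$feedback, enc$cond_idx, enc$slot_pos,
                             enc$slot_neg, rating, as.integer(imap),
                             fixed_inits, mean_model, state == "observed",
                             model$n_alpha_slots, n_theta2, n_cond)
  rhat <- vapply(seq_len(P), function(j) compute_rhat(draws[, , j, drop = TRUE]),
                 numeric(1))
  ess <- vapply(seq_len(P), function(j) compute_ess(draws[, , j, drop = TRUE]),
                numeric(1))
  structure(list(subject_id = if (!is.null(data$subject_id))
                   as.character(data$subject_id[1]) else NA_character_,
                 model = model,
                 draws = draws,
                 pointwise_loglik = pw,
                 posterior_mean = setNames(colMeans(flat), par_names),
                 posterior_median = setNames(apply(flat, 2, stats::median),
                                             par_names),
                 rhat = setNames(rhat, par_names),
                 ess = setNames(ess, par_names),
                 accept_rate = colMeans(acc),
                 cfg = cfg, state = state),
            class = "loop_fit")
}

#' @export
print.loop_fit <- function(x, ...) {
  cat("<loop_fit> subject ", x$subject_id, ", model ", x$model$name, "\n",
      sep = "")
  print(round(rbind(mean = x$posterior_mean, rhat = x$rhat, ess = x$ess), 3))
  invisible(x)
}

#' Fit a set of models to every subject of a cohort
#'
#' @param data A `loop_cohort`, or a long data frame with a `subject_id`
#'   column.
#' @param models A list of [model_spec()]s (default: the full
#'   [model_space()] of the cohort's experiment).
#' @param cfg A [sampler_config()]; each subject x model fit gets a distinct
#'   seed derived from `cfg$seed`.
#' @param progress Print one line per subject.
#' @return A `loop_fitset`: nested list `fits[[model]][[subject]]`.
#' @export
fit_cohort <- function(data, models = NULL, cfg = sampler_config(),
                       progress = FALSE) {
  if (inherits(data, "loop_cohort")) {
    experiment <- data$experiment
    df <- data$data
  } else {
    df <- as.data.frame(data)
    experiment <- attr(data, "experiment")
  }
  if (is.null(models)) {
    if (is.null(experiment)) stop("supply models or a loop_cohort",
                                  call. = FALSE)
    models <- model_space(experiment)
  }
  if (inherits(models, "loop_model")) models <- list(models)
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, "", "name")
  }
  subjects <- unique(df$subject_id)
  fits <- lapply(seq_along(models), function(m) {
    ml <- models[[m]]
    out <- lapply(seq_along(subjects), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- (cfg$seed + 7919L * m + 104729L * i) %% 2147483647L
      fit_subject(ml, df[df$subject_id == subjects[i], , drop = FALSE], cfg_i)
    })
    if (progress) message("fitted model ", ml$name)
    setNames(out, subjects)
  })
  structure(setNames(fits, names(models)), class = "loop_fitset")
}

#' Posterior-mean parameter table for one model across subjects
#'
#' @param fitset A [fit_cohort()] result.
#' @param model Model name (default: first model in the set).
#' @param central `"mean"` (default) or `"median"` posterior summary.
#' @return Data frame, one row per subject, one column per parameter.
#' @export
posterior_parameters <- function(fitset, model = names(fitset)[1],
                                 central = c("mean", "median")) {
  central <- match.arg(central)
  fits <- fitset[[model]]
  est <- t(vapply(fits, function(f)
    if (central == "mean") f$posterior_mean else f$posterior_median,
    fits[[1]]$posterior_mean))
  out <- data.frame(subject_id = names(fits), est, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the convergence-based exclusion rule
#'
#' A subject is excluded when any parameter of any of their fitted models
#' has R-hat above the threshold (or an undefined R-hat from degenerate
#' chains). As a soft plausibility screen, subjects whose mean learning
#' rate lies more than 10 SDs from the cohort mean are flagged (never
#' auto-excluded).
#'
#' @param fits A `loop_fitset`, or flat list of `loop_fit`s.
#' @param threshold R-hat exclusion threshold (default 1.1).
#' @return List with `retained` (subject ids), `excluded` (data frame:
#'   subject, model, parameter, rhat, reason) and `flagged` (plausibility
#'   flags).
#' @export
apply_exclusions <- function(fits, threshold = 1.1) {
  flat <- if (inherits(fits, "loop_fitset")) unlist(fits, recursive = FALSE)
          else fits
  rows <- list()
  for (f in flat) {
    bad <- which(is.na(f$rhat) | f$rhat > threshold)
    for (j in bad) {
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = f$subject_id, model = f$model$name,
                   parameter = names(f$rhat)[j], rhat = f$rhat[[j]],
                   reason = if (is.na(f$rhat[[j]]))
                     "undefined R-hat (degenerate chains)"
                   else sprintf("R-hat %.3f > %.2f", f$rhat[[j]], threshold),
                   stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), model = character(0),
               parameter = character(0), rhat = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  subjects <- unique(vapply(flat, `[[`, "", "subject_id"))

  # plausibility flag: mean alpha far from the cohort mean
  amean <- vapply(flat, function(f) {
    a <- f$posterior_mean[f$model$alpha_slots]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1))
  flagged <- character(0)
  ok <- is.finite(amean)
  if (sum(ok) >= 3 && sd(amean[ok]) > 0) {
    z <- abs(amean - mean(amean[ok])) / sd(amean[ok])
    flagged <- unique(vapply(flat[which(ok & z > 10)], `[[`, "",
                             "subject_id"))
  }
  list(retained = setdiff(subjects, unique(excluded$subject_id)),
       excluded = excluded, flagged = flagged)
}

#' Serialize fit summaries and diagnostics to a directory of JSON files
#'
#' @param fitset A `loop_fitset`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_fit_summaries <- function(fitset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in names(fitset)) {
    for (s in names(fitset[[m]])) {
      f <- fitset[[m]][[s]]
      out <- list(subject_id = f$subject_id, model = f$model$name,
                  posterior_mean = as.list(f$posterior_mean),
                  posterior_median = as.list(f$posterior_median),
                  rhat = as.list(f$rhat), ess = as.list(f$ess))
      p <- file.path(dir, paste0(m, "_", s, ".json"))
      jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
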
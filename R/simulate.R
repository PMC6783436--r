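# Generative counterpart of the fitted models: synthetic subjects and cohorts.

#' Simulate one subject's expectation ratings on a design
#'
#' Latent expectations evolve by the model's delta rule against the design's
#' feedback; observed ratings are the latent expectations plus Gaussian
#' observation noise of scale `params$noise_sd`, clipped to the 0-100
#' rating scale. With `noise_sd = 0` the ratings reproduce
#' [predict_trajectory()] exactly.
#'
#' @param design A [build_design()] result.
#' @param model A [model_spec()].
#' @param params A [parameter_set()] for the model.
#' @param seed Integer seed for the observation noise.
#' @param subject_id Identifier stored with the data.
#' @param group Optional group label (e.g. `"private"`/`"public"`).
#' @return A data frame of class `loop_data` with columns `subject_id`,
#'   `group`, `trial`, `agent`, `ability`, `condition`, `feedback`,
#'   `exp_rating`; the generating parameters are kept in
#'   `attr(x, "true_params")`.
#' @export
simulate_subject <- function(design, model, params, seed, subject_id = "s01",
                             group = NA_character_) {
  stopifnot(inherits(model, "loop_model"), inherits(params, "loop_params"))
  if (model$init_scheme == "fixed_first_rating") {
    stop("simulation requires fitted initial values, not 'fixed_first_rating'",
         call. = FALSE)
  }
  traj <- predict_trajectory(model, params, design, state = "latent")
  n <- nrow(traj)
  ratings <- withr::with_seed(seed, {
    if (params$noise_sd == 0) traj$latent_exp
    else pmin(100, pmax(0, traj$latent_exp + rnorm(n, 0, params$noise_sd)))
  })
  out <- data.frame(subject_id = subject_id, group = group,
                    trial = traj$trial, agent = traj$agent,
                    ability = traj$ability, condition = traj$condition,
                    feedback = traj$feedback, exp_rating = ratings,
                    stringsAsFactors = FALSE)
  attr(out, "true_params") <- params
  attr(out, "model") <- model$name
  attr(out, "experiment") <- attr(design, "experiment")
  class(out) <- c("loop_data", "data.frame")
  out
}

#' Population distributions for cohort simulation
#'
#' Defaults place Beta distributions over the valence-model learning rates
#' with means/SDs at the values typically recovered for this paradigm
#' (self: alpha_neg 0.14 +- 0.09, alpha_pos 0.12 +- 0.06; other: alpha_neg
#' 0.10 +- 0.07, alpha_pos 0.11 +- 0.08; audience task uses the
#' private-group self values 0.10 +- 0.08 / 0.07 +- 0.06), initial beliefs
#' near the 50th percentile (truncated normal 50 +- 10) and a common
#' observation noise of 10 rating points.
#'
#' @param experiment Experiment label.
#' @return A list with `alphas` (per-slot `list(mean, sd)`), `init`
#'   (`list(mean, sd)`), `noise_sd`.
#' @export
default_population <- function(experiment) {
  cls <- experiment_class(experiment)
  alphas <- if (cls == "agent") {
    list(alpha_pos_self  = list(mean = 0.12, sd = 0.06),
         alpha_neg_self  = list(mean = 0.14, sd = 0.09),
         alpha_pos_other = list(mean = 0.11, sd = 0.08),
         alpha_neg_other = list(mean = 0.10, sd = 0.07))
  } else {
    list(alpha_pos = list(mean = 0.07, sd = 0.06),
         alpha_neg = list(mean = 0.10, sd = 0.08))
  }
  list(alphas = alphas, init = list(mean = 50, sd = 10), noise_sd = 10)
}

# Beta shapes by method of moments; mean in (0,1), sd^2 < mean(1-mean).
beta_shapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible Beta moments: sd too large for mean ", mean,
         call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a cohort with trait scores coupled to the learning asymmetry
#'
#' Per-subject true learning rates are drawn from the population Beta
#' distributions, each subject gets a fresh trial design, and trait scores
#' (self-esteem on an SDQ-III-like scale, social anxiety on a SIAS-like
#' scale) are generated through a Gaussian copula with the requested
#' correlation to each subject's *true* self-referent valence bias score
#' `(alpha_pos - alpha_neg) / (alpha_pos + alpha_neg)`. True parameters are
#' returned for recovery testing.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param experiment Experiment label (see [build_design()]).
#' @param param_population Population spec as from [default_population()].
#' @param trait_coupling Named numeric vector of correlations in \[-1, 1\]
#'   between each trait and the true self valence bias; defaults to
#'   `c(self_esteem = 0.44, social_anxiety = -0.39)`.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param model Generating model; defaults to the valence model (with
#'   self/other split for agent experiments).
#' @return An object of class `loop_cohort`: list with `data` (long data
#'   frame over subjects), `datasets` (list of per-subject `loop_data`),
#'   `traits` (data frame `subject_id`, `self_esteem`, `social_anxiety`),
#'   `true_params` (data frame of generating parameters incl. the true
#'   bias score), `experiment`, `model`.
#' @export
simulate_cohort <- function(n_subjects, experiment,
                            param_population = default_population(experiment),
                            trait_coupling = c(self_esteem = 0.44,
                                               social_anxiety = -0.39),
                            seed = 1L,
                            model = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (length(trait_coupling)) {
    if (is.null(names(trait_coupling)) || any(names(trait_coupling) == "")) {
      stop("trait_coupling must be a named vector of correlations",
           call. = FALSE)
    }
    if (any(!is.finite(trait_coupling)) || any(abs(trait_coupling) > 1)) {
      stop("trait correlations must lie in [-1, 1]", call. = FALSE)
    }
  }
  cls <- experiment_class(experiment)
  if (is.null(model)) {
    model <- model_spec(if (cls == "agent") "M6_valence_SO" else "M3_valence",
                        experiment)
  }
  pop <- param_population
  missing_slots <- setdiff(model$alpha_slots, names(pop$alphas))
  if (length(missing_slots)) {
    stop("param_population lacks alpha distributions for: ",
         paste(missing_slots, collapse = ", "), call. = FALSE)
  }

  withr::with_seed(seed, {
    true <- data.frame(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                       stringsAsFactors = FALSE)
    for (slot in model$alpha_slots) {
      sh <- beta_shapes(pop$alphas[[slot]]$mean, pop$alphas[[slot]]$sd)
      true[[slot]] <- rbeta(n_subjects, sh["shape1"], sh["shape2"])
    }
    for (slot in model$init_slots) {
      true[[slot]] <- rtruncnorm1(n_subjects, pop$init$mean, pop$init$sd,
                                  0, 100)
    }
    true$noise_sd <- rep(pop$noise_sd, n_subjects)

    pos_slot <- if (model$agent_split) "alpha_pos_self" else "alpha_pos"
    neg_slot <- if (model$agent_split) "alpha_neg_self" else "alpha_neg"
    has_bias <- all(c(pos_slot, neg_slot) %in% names(true))
    true$valence_bias <- if (has_bias) {
      valence_bias_score(true[[pos_slot]], true[[neg_slot]])
    } else NA_real_
    if (length(trait_coupling) && !has_bias) {
      stop("trait coupling requires a valence model (no valence bias is ",
           "defined for ", model$name, ")", call. = FALSE)
    }

    # Gaussian copula: normal scores of the true bias, then correlated
    # latent trait variables mapped to questionnaire-like scales.
    zb <- if (has_bias) {
      qnorm(rank(true$valence_bias, ties.method = "average") /
              (n_subjects + 1))
    } else numeric(n_subjects)
    traits <- data.frame(subject_id = true$subject_id,
                         stringsAsFactors = FALSE)
    scales <- list(self_esteem = c(mean = 100, sd = 15, lo = 30, hi = 170),
                   social_anxiety = c(mean = 25, sd = 13, lo = 0, hi = 80))
    for (tr in names(trait_coupling)) {
      r <- trait_coupling[[tr]]
      zt <- r * zb + sqrt(1 - r^2) * rnorm(n_subjects)
      sc <- if (tr %in% names(scales)) scales[[tr]]
            else c(mean = 0, sd = 1, lo = -Inf, hi = Inf)
      traits[[tr]] <- pmin(sc[["hi"]], pmax(sc[["lo"]],
                                            sc[["mean"]] + sc[["sd"]] * zt))
    }

    group <- if (grepl("public", experiment)) "public" else "private"
    datasets <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      design <- build_design(experiment, seed = sample.int(2^30, 1L))
      pars <- parameter_set(
        model,
        alphas = setNames(as.numeric(true[i, model$alpha_slots]),
                          model$alpha_slots),
        init_values = setNames(as.numeric(true[i, model$init_slots]),
                               model$init_slots),
        noise_sd = true$noise_sd[i])
      datasets[[i]] <- simulate_subject(design, model, pars,
                                        seed = sample.int(2^30, 1L),
                                        subject_id = true$subject_id[i],
                                        group = group)
    }
    data <- do.call(rbind, lapply(datasets, as.data.frame))
    rownames(data) <- NULL
    structure(list(data = data, datasets = datasets, traits = traits,
                   true_params = true, experiment = experiment,
                   model = model),
              class = "loop_cohort")
  })
}

#' @export
print.loop_cohort <- function(x, ...) {
  cat("<loop_cohort> ", length(x$datasets), " subjects, ", x$experiment,
      ", generated by ", x$model$name, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to delimited files
#'
#' Writes `cohort.csv` (subject_id, group, trial, agent, ability, feedback,
#' exp_rating), `traits.csv`, and `true_params.json` into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "loop_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "traits.csv", "true_params.json"))
  cols <- c("subject_id", "group", "trial", "agent", "ability", "feedback",
            "exp_rating")
  utils::write.csv(cohort$data[, cols], paths[1], row.names = FALSE)
  utils::write.csv(cohort$traits, paths[2], row.names = FALSE)
  jsonlite::write_json(cohort$true_params, paths[3], digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `cohort.csv` (and optionally
#'   `traits.csv`).
#' @return A list with `data` and, if present, `traits`.
#' @export
read_cohort <- function(dir) {
  data <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  data$condition <- condition_label(data$agent, data$ability)
  out <- list(data = data)
  tp <- file.path(dir, "traits.csv")
  if (file.exists(tp)) out$traits <- utils::read.csv(tp,
                                                     stringsAsFactors = FALSE)
  out
}
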
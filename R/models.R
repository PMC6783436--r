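#' @useDynLib loopbelief, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm dnorm pnorm qnorm runif rgamma rbeta var sd cor
#'   aov lm pt complete.cases setNames optim quantile acf
NULL

# Experiment labels and their condition structure ------------------------------

.AGENT_EXPERIMENTS <- c("agent_private", "agent_public")
.AUDIENCE_EXPERIMENTS <- c("audience_private", "audience_public")
.EXPERIMENTS <- c(.AGENT_EXPERIMENTS, .AUDIENCE_EXPERIMENTS)

.TRIALS_PER_CONDITION <- c(agent = 25L, audience = 30L)

experiment_class <- function(experiment) {
  if (!is.character(experiment) || length(experiment) != 1L ||
      !experiment %in% .EXPERIMENTS) {
    stop("unknown experiment label: ", paste(experiment, collapse = ", "),
         " (expected one of ", paste(.EXPERIMENTS, collapse = ", "), ")",
         call. = FALSE)
  }
  if (experiment %in% .AGENT_EXPERIMENTS) "agent" else "audience"
}

experiment_conditions <- function(experiment) {
  if (experiment_class(experiment) == "agent") {
    expand.grid(agent = c("self", "other"), ability = c("high", "low"),
                stringsAsFactors = FALSE)[, c("agent", "ability")]
  } else {
    data.frame(agent = "self", ability = c("high", "low"),
               stringsAsFactors = FALSE)
  }
}

condition_label <- function(agent, ability) paste(agent, ability, sep = "_")

# Model space ------------------------------------------------------------------

.AGENT_MODELS <- c("M1_unity", "M2_ability", "M3_valence",
                   "M4_unity_SO", "M5_ability_SO", "M6_valence_SO", "M_mean")
.AUDIENCE_MODELS <- c("M1_unity", "M2_ability", "M3_valence", "M_mean")

#' Define one member of the learning-model space
#'
#' A model spec fixes the update rule family (single learning rate; one rate
#' per ability condition; one rate per prediction-error valence; each
#' optionally split by agent, i.e. learning about oneself vs another person)
#' and the initial-belief parameterization. The mean model has no learning
#' rates and predicts a fitted constant per condition.
#'
#' @param name One of `"M1_unity"`, `"M2_ability"`, `"M3_valence"`,
#'   `"M4_unity_SO"`, `"M5_ability_SO"`, `"M6_valence_SO"`, `"M_mean"`.
#'   The `_SO` variants carry separate parameters for self and other and are
#'   only meaningful for the agent experiments.
#' @param experiment Experiment label (`"agent_private"`, `"agent_public"`,
#'   `"audience_private"`, `"audience_public"`).
#' @param init_scheme How initial beliefs enter: `"fitted_per_condition"`
#'   (default; one fitted initial value per condition),
#'   `"fitted_combined"` (one per agent, shared across ability conditions),
#'   or `"fixed_first_rating"` (fixed at each condition's first observed
#'   rating).
#' @return An object of class `loop_model`.
#' @export
model_spec <- function(name, experiment = "agent_private",
                       init_scheme = c("fitted_per_condition",
                                       "fitted_combined",
                                       "fixed_first_rating")) {
  cls <- experiment_class(experiment)
  init_scheme <- match.arg(init_scheme)
  valid <- if (cls == "agent") .AGENT_MODELS else .AUDIENCE_MODELS
  if (!name %in% valid) {
    stop("unknown model '", name, "' for ", cls, " experiments", call. = FALSE)
  }
  conds <- experiment_conditions(experiment)
  cond_labels <- condition_label(conds$agent, conds$ability)

  rule <- switch(name,
    M1_unity = "unity", M4_unity_SO = "unity",
    M2_ability = "ability", M5_ability_SO = "ability",
    M3_valence = "valence", M6_valence_SO = "valence",
    M_mean = "mean")
  agent_split <- name %in% c("M4_unity_SO", "M5_ability_SO", "M6_valence_SO")

  alpha_slots <- if (rule == "mean") {
    character(0)
  } else {
    base <- switch(rule,
      unity = "alpha_uni",
      ability = c("alpha_HA", "alpha_LA"),
      valence = c("alpha_pos", "alpha_neg"))
    if (agent_split) {
      as.vector(vapply(c("self", "other"),
                       function(a) paste(base, a, sep = "_"),
                       character(length(base))))
    } else base
  }

  init_slots <- if (rule == "mean") character(0) else switch(init_scheme,
    fitted_per_condition = paste0("init_", cond_labels),
    fitted_combined = paste0("init_", unique(conds$agent)),
    fixed_first_rating = character(0))
  mean_slots <- if (rule == "mean") paste0("mean_", cond_labels) else character(0)

  structure(
    list(name = name, experiment = experiment, experiment_class = cls,
         rule = rule, agent_split = agent_split,
         init_scheme = init_scheme,
         alpha_slots = alpha_slots, n_alpha_slots = length(alpha_slots),
         init_slots = init_slots, mean_slots = mean_slots,
         conditions = cond_labels),
    class = "loop_model")
}

#' The full model space for an experiment
#'
#' Agent experiments compare 7 models (unity/ability/valence, each with and
#' without separate self/other parameters, plus a no-learning mean model with
#' four condition means); audience experiments compare 4 (unity, ability,
#' valence, mean with two condition means).
#'
#' @inheritParams model_spec
#' @return A named list of [model_spec()] objects.
#' @export
model_space <- function(experiment, init_scheme = "fitted_per_condition") {
  names_ <- if (experiment_class(experiment) == "agent") .AGENT_MODELS
            else .AUDIENCE_MODELS
  setNames(lapply(names_, model_spec, experiment = experiment,
                  init_scheme = init_scheme), names_)
}

#' @export
print.loop_model <- function(x, ...) {
  cat("<loop_model> ", x$name, " (", x$experiment, ")\n", sep = "")
  cat("  rule: ", x$rule,
      if (x$agent_split) ", self/other split" else "", "\n", sep = "")
  cat("  alpha slots:", if (x$n_alpha_slots)
    paste(x$alpha_slots, collapse = ", ") else "none", "\n")
  cat("  init scheme:", x$init_scheme, "\n")
  invisible(x)
}

# Parameter sets ---------------------------------------------------------------

#' Bundle parameter values for a learning model
#'
#' @param model A [model_spec()].
#' @param alphas Named numeric vector of learning rates in \[0, 1\], one per
#'   alpha slot of the model (empty for the mean model).
#' @param init_values Named numeric vector of initial beliefs on the 0-100
#'   rating scale, one per init slot (ignored under `fixed_first_rating`).
#' @param condition_means Named numeric vector of per-condition means
#'   (mean model only).
#' @param noise_sd Observation noise standard deviation on the rating scale;
#'   must be > 0 for likelihood evaluation, may be 0 for noise-free
#'   simulation.
#' @return An object of class `loop_params` (a named list).
#' @export
parameter_set <- function(model, alphas = numeric(0), init_values = numeric(0),
                          condition_means = numeric(0), noise_sd = 10) {
  stopifnot(inherits(model, "loop_model"))
  alphas <- unlist(alphas); init_values <- unlist(init_values)
  condition_means <- unlist(condition_means)
  if (length(alphas) != model$n_alpha_slots ||
      (model$n_alpha_slots > 0 && !setequal(names(alphas), model$alpha_slots))) {
    stop("model '", model$name, "' needs alphas for slots: ",
         paste(model$alpha_slots, collapse = ", "), call. = FALSE)
  }
  if (any(alphas < 0 | alphas > 1)) {
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(model$init_slots)) {
    if (!setequal(names(init_values), model$init_slots)) {
      stop("init_values must be named for slots: ",
           paste(model$init_slots, collapse = ", "), call. = FALSE)
    }
    if (any(init_values < 0 | init_values > 100)) {
      stop("initial beliefs must lie on the [0, 100] rating scale",
           call. = FALSE)
    }
  }
  if (model$rule == "mean" && !setequal(names(condition_means), model$mean_slots)) {
    stop("mean model needs condition_means for: ",
         paste(model$mean_slots, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  structure(list(alphas = alphas[if (model$n_alpha_slots) model$alpha_slots else integer(0)],
                 init_values = if (length(model$init_slots))
                   init_values[model$init_slots] else numeric(0),
                 condition_means = if (model$rule == "mean")
                   condition_means[model$mean_slots] else numeric(0),
                 noise_sd = noise_sd, model_name = model$name),
            class = "loop_params")
}

# Core delta rule --------------------------------------------------------------

#' One Rescorla-Wagner delta-rule update
#'
#' `exp + alpha * (fb - exp)`: the new expectation moves a fraction `alpha`
#' of the prediction error toward the feedback, so it always lies between
#' the old expectation and the feedback.
#'
#' @param exp Current expectation (rating scale).
#' @param fb Received feedback (rating scale).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expectation; vectorized over all arguments.
#' @export
rw_update <- function(exp, fb, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("learning rate alpha must lie in [0, 1]", call. = FALSE)
  }
  exp + alpha * (fb - exp)
}

#' Map a trial context to the learning rate a model uses
#'
#' Unity models use their single rate per agent; ability models key on the
#' high/low ability condition; valence models key on the sign of the
#' prediction error. A prediction error of exactly zero is routed to the
#' positive-valence slot (an arbitrary but fixed convention; zero errors are
#' vanishingly rare under the continuous noise model).
#'
#' @param model A [model_spec()] (not the mean model).
#' @param agent `"self"` or `"other"` (ignored by models without a
#'   self/other split).
#' @param ability `"high"` or `"low"`.
#' @param pe Prediction error (its sign selects the slot for valence models).
#' @param params Optional [parameter_set()]; if supplied the rate value is
#'   returned, otherwise the slot name.
#' @return Slot name (character) or, with `params`, the learning rate.
#' @export
resolve_alpha <- function(model, agent, ability, pe, params = NULL) {
  stopifnot(inherits(model, "loop_model"))
  if (model$rule == "mean") {
    stop("the mean model has no learning-rate slots", call. = FALSE)
  }
  if (!ability %in% c("high", "low")) stop("unknown ability: ", ability,
                                           call. = FALSE)
  if (!agent %in% c("self", "other")) stop("unknown agent: ", agent,
                                           call. = FALSE)
  slot <- switch(model$rule,
    unity = "alpha_uni",
    ability = if (ability == "high") "alpha_HA" else "alpha_LA",
    valence = if (pe >= 0) "alpha_pos" else "alpha_neg")
  if (model$agent_split) slot <- paste(slot, agent, sep = "_")
  if (is.null(params)) slot else unname(params$alphas[[slot]])
}

# Trajectory prediction and likelihood -----------------------------------------

# Integer encodings shared with the C++ core: for each trial, the condition
# index (latent-state slot) and the alpha slot used for positive / negative
# prediction errors (0 = mean model).
encode_design <- function(model, design) {
  stopifnot(inherits(model, "loop_model"))
  df <- as.data.frame(design)
  need <- c("trial", "agent", "ability", "feedback")
  if (!all(need %in% names(df))) {
    stop("design must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cond <- condition_label(df$agent, df$ability)
  bad <- !cond %in% model$conditions
  if (any(bad)) {
    stop("design references condition(s) with no model state: ",
         paste(unique(cond[bad]), collapse = ", "), call. = FALSE)
  }
  cond_idx <- match(cond, model$conditions)
  if (model$rule == "mean") {
    slot_pos <- slot_neg <- rep(0L, nrow(df))
  } else {
    slot_pos <- vapply(seq_len(nrow(df)), function(i)
      match(resolve_alpha(model, df$agent[i], df$ability[i], pe = 1),
            model$alpha_slots), integer(1))
    slot_neg <- vapply(seq_len(nrow(df)), function(i)
      match(resolve_alpha(model, df$agent[i], df$ability[i], pe = -1),
            model$alpha_slots), integer(1))
  }
  list(feedback = as.numeric(df$feedback), cond_idx = cond_idx,
       slot_pos = slot_pos, slot_neg = slot_neg, cond = cond, df = df)
}

# Expand init slots to one value per condition.
init_per_condition <- function(model, params, enc, observations = NULL) {
  switch(model$init_scheme,
    fitted_per_condition = unname(params$init_values[paste0("init_", model$conditions)]),
    fitted_combined = {
      agent_of_cond <- sub("_(high|low)$", "", model$conditions)
      unname(params$init_values[paste0("init_", agent_of_cond)])
    },
    fixed_first_rating = {
      if (is.null(observations)) {
        stop("init_scheme 'fixed_first_rating' needs observed ratings",
             call. = FALSE)
      }
      vapply(seq_along(model$conditions), function(c) {
        i <- which(enc$cond_idx == c)[1]
        if (is.na(i)) 50 else observations[i]
      }, numeric(1))
    })
}

#' Predict the latent expectation trajectory of a model
#'
#' Each (agent x ability) condition carries its own latent expectation,
#' initialized per the model's init scheme and updated only on that
#' condition's trials. By default prediction errors are computed against the
#' model's own latent expectation (`state = "latent"`); with
#' `state = "observed"` the update instead starts from the observed rating
#' of the trial (requires `observations`). The mean model predicts its
#' fitted condition mean on every trial.
#'
#' @param model A [model_spec()].
#' @param params A [parameter_set()] for the model.
#' @param design A trial design (see [build_design()]) or any data frame
#'   with columns `trial`, `agent`, `ability`, `feedback`.
#' @param observations Optional observed ratings (needed for
#'   `state = "observed"` or `init_scheme = "fixed_first_rating"`).
#' @param state `"latent"` (default) or `"observed"`.
#' @return A data frame of class `loop_trajectory` with columns `trial`,
#'   `agent`, `ability`, `condition`, `feedback`, `latent_exp` (the model's
#'   pre-feedback expectation), `pe` (feedback minus expectation).
#' @export
predict_trajectory <- function(model, params, design, observations = NULL,
                               state = c("latent", "observed")) {
  state <- match.arg(state)
  stopifnot(inherits(params, "loop_params"))
  enc <- encode_design(model, design)
  n <- length(enc$feedback)
  if (state == "observed" && is.null(observations)) {
    stop("state = 'observed' requires the observed ratings", call. = FALSE)
  }
  inits <- init_per_condition(model, params, enc, observations)
  out <- cpp_trajectory(enc$feedback, enc$cond_idx, enc$slot_pos, enc$slot_neg,
                        as.numeric(params$alphas), inits,
                        as.numeric(params$condition_means),
                        model$rule == "mean",
                        state == "observed",
                        if (is.null(observations)) numeric(0)
                        else as.numeric(observations))
  res <- data.frame(trial = enc$df$trial, agent = enc$df$agent,
                    ability = enc$df$ability, condition = enc$cond,
                    feedback = enc$feedback,
                    latent_exp = out$latent, pe = out$pe)
  class(res) <- c("loop_trajectory", "data.frame")
  res
}

#' Per-trial Gaussian log-likelihood of observed ratings under a model
#'
#' Trial `t` contributes the normal log-density of the observed rating given
#' the model's latent expectation for that trial and the observation noise
#' `noise_sd`; the joint log-likelihood is the sum over trials.
#'
#' @inheritParams predict_trajectory
#' @param data A behavioral dataset: data frame with columns `trial`,
#'   `agent`, `ability`, `feedback`, `exp_rating`.
#' @return Numeric vector of per-trial log-densities (length = trials).
#' @export
log_likelihood_pointwise <- function(model, params, data,
                                     state = c("latent", "observed")) {
  state <- match.arg(state)
  if (params$noise_sd <= 0) {
    stop("noise_sd must be > 0 for likelihood evaluation", call. = FALSE)
  }
  if (!"exp_rating" %in% names(data)) {
    stop("data must contain an exp_rating column", call. = FALSE)
  }
  traj <- predict_trajectory(model, params, data,
                             observations = data$exp_rating, state = state)
  dnorm(data$exp_rating, mean = traj$latent_exp, sd = params$noise_sd,
        log = TRUE)
}

# JSON serialization (model registry) ------------------------------------------

#' Serialize model specs and parameter sets to JSON
#'
#' Round-trippable JSON so that fits are reproducible from configuration
#' alone.
#' @param x A `loop_model` or `loop_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
loop_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "loop_model") || inherits(x, "loop_params"))
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Rebuild a model spec from its JSON registry entry
#' @param json JSON string or path to a JSON file.
#' @return A `loop_model`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  model_spec(x$name, x$experiment, x$init_scheme)
}
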
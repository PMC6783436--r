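# Feedback schedules and trial designs for the performance-feedback task.
#
# Low-ability feedback is delivered as percentiles in [1, 60] with mean 35
# and SD 16; high-ability feedback in [40, 99] with mean 65 and SD 16.
# Draws come from a parent normal distribution rejection-truncated into the
# condition's range; the parent (mu, sigma) is solved numerically so that
# the *truncated* distribution realizes the stated mean and SD (a plain
# N(35, 16) truncated to [1, 60] would deliver mean 33.7 and SD 13.4).

.FEEDBACK_SPEC <- list(
  low  = list(range = c(1, 60), mean = 35, sd = 16),
  high = list(range = c(40, 99), mean = 65, sd = 16)
)

.calib_cache <- new.env(parent = emptyenv())

truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                    ((dnorm(al) - dnorm(be)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) whose truncation to `range` has the target moments.
feedback_calibration <- function(ability) {
  key <- as.character(ability)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  spec <- .FEEDBACK_SPEC[[key]]
  a <- spec$range[1]; b <- spec$range[2]
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), a, b)
    sum((m - c(spec$mean, spec$sd))^2)
  }
  fit <- optim(c(spec$mean, log(spec$sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  if (fit$value > 1e-6) {
    stop("feedback calibration failed for ability '", key, "'", call. = FALSE)
  }
  .calib_cache[[key]] <- out
  out
}

#' Generate a feedback percentile schedule for one ability condition
#'
#' Percentile feedback (integers) for the low condition lies in \[1, 60\]
#' with mean 35 and SD 16; for the high condition in \[40, 99\] with mean 65
#' and SD 16. Values are drawn from a calibrated normal distribution,
#' rejection-sampled into the range (preserving a smooth within-range
#' shape rather than piling mass at the bounds) and rounded to whole
#' percentiles as displayed to participants.
#'
#' @param ability `"high"` or `"low"`.
#' @param n_trials Number of feedback values (>= 1).
#' @param seed Integer seed; the schedule is a pure function of
#'   `(ability, n_trials, seed)`.
#' @return An object of class `loop_schedule`: list with `ability`,
#'   `feedback` (integer vector), `n_trials`.
#' @export
generate_feedback_schedule <- function(ability, n_trials, seed) {
  if (!is.character(ability) || length(ability) != 1L ||
      !ability %in% names(.FEEDBACK_SPEC)) {
    stop("unknown ability label: ", paste(ability, collapse = ", "),
         " (expected 'high' or 'low')", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  spec <- .FEEDBACK_SPEC[[ability]]
  cal <- feedback_calibration(ability)
  fb <- withr::with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_trials) {
      x <- rnorm(2L * (n_trials - length(out)) + 20L, cal["mu"], cal["sigma"])
      out <- c(out, x[x >= spec$range[1] & x <= spec$range[2]])
    }
    out[seq_len(n_trials)]
  })
  structure(list(ability = ability,
                 feedback = as.integer(round(fb)),
                 n_trials = n_trials),
            class = "loop_schedule")
}

#' @export
print.loop_schedule <- function(x, ...) {
  cat("<loop_schedule> ", x$ability, " ability, ", x$n_trials, " trials; ",
      "mean ", round(mean(x$feedback), 1), ", sd ",
      round(sd(x$feedback), 1), "\n", sep = "")
  invisible(x)
}

# Condition sequence with per-condition counts and no run longer than
# max_run. Sequential sampling among eligible conditions with restart on
# dead ends; feasibility requires max(count) <= max_run * (sum(others) + 1).
sample_condition_sequence <- function(counts, max_run = 2L, max_restarts = 1000L) {
  k <- length(counts)
  labels <- names(counts)
  if (max(counts) > max_run * (sum(counts) - max(counts) + 1L)) {
    stop("no condition order with runs <= ", max_run,
         " exists for the requested counts", call. = FALSE)
  }
  total <- sum(counts)
  for (r in seq_len(max_restarts)) {
    left <- counts
    seqc <- character(total)
    run_label <- ""; run_len <- 0L
    ok <- TRUE
    for (t in seq_len(total)) {
      elig <- which(left > 0L & !(labels == run_label & run_len >= max_run))
      if (!length(elig)) { ok <- FALSE; break }
      # prefer conditions whose remaining count is critical to avoid dead ends
      pick <- elig[sample.int(length(elig), 1L,
                              prob = left[elig] / sum(left[elig]))]
      lab <- labels[pick]
      seqc[t] <- lab
      left[pick] <- left[pick] - 1L
      if (lab == run_label) run_len <- run_len + 1L
      else { run_label <- lab; run_len <- 1L }
    }
    if (ok) return(seqc)
  }
  stop("failed to build a condition order within ", max_restarts,
       " restarts", call. = FALSE)
}

#' Build a complete trial design for one experiment
#'
#' Agent experiments cross Agent (self/other) with Ability (high/low),
#' 25 trials per cell (100 trials); audience experiments have the two
#' self-related ability conditions with 30 trials each (60 trials).
#' Conditions are interleaved with at most two consecutive trials of the
#' same condition, and each condition's feedback comes from
#' [generate_feedback_schedule()].
#'
#' @param experiment One of `"agent_private"`, `"agent_public"`,
#'   `"audience_private"`, `"audience_public"`.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A data frame of class `loop_design` with columns `trial`,
#'   `agent`, `ability`, `condition`, `feedback`, and attributes
#'   `experiment` and `n_trials`.
#' @export
build_design <- function(experiment, seed) {
  cls <- experiment_class(experiment)
  conds <- experiment_conditions(experiment)
  labels <- condition_label(conds$agent, conds$ability)
  n_per <- .TRIALS_PER_CONDITION[[cls]]
  counts <- setNames(rep(n_per, nrow(conds)), labels)

  design <- withr::with_seed(seed, {
    seqc <- sample_condition_sequence(counts, max_run = 2L)
    fb <- numeric(length(seqc))
    for (i in seq_along(labels)) {
      sched <- generate_feedback_schedule(conds$ability[i], n_per,
                                          seed = sample.int(2^30, 1L))
      fb[seqc == labels[i]] <- sched$feedback
    }
    idx <- match(seqc, labels)
    data.frame(trial = seq_along(seqc),
               agent = conds$agent[idx],
               ability = conds$ability[idx],
               condition = seqc,
               feedback = as.integer(fb),
               stringsAsFactors = FALSE)
  })
  attr(design, "experiment") <- experiment
  attr(design, "n_trials") <- nrow(design)
  class(design) <- c("loop_design", "data.frame")
  design
}

#' Longest same-condition run in a design
#' @param design A `loop_design` (or any data frame with a `condition`
#'   column).
#' @return Integer maximum run length.
#' @export
max_condition_run <- function(design) {
  max(rle(as.character(design$condition))$lengths)
}
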
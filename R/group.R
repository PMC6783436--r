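# Group-level statistics on fitted learning parameters.

#' Valence bias score
#'
#' `(alpha_pos - alpha_neg) / (alpha_pos + alpha_neg)`: a normalized
#' asymmetry in \[-1, 1\], positive for a positivity bias (stronger
#' updating from better-than-expected feedback), negative for a negativity
#' bias. Scale-invariant: multiplying both rates by a positive constant
#' leaves it unchanged. Undefined (returned as `NA` with a warning) when
#' both rates are 0.
#'
#' @param alpha_pos,alpha_neg Learning rates (>= 0); vectorized.
#' @return Numeric vector of bias scores.
#' @export
valence_bias_score <- function(alpha_pos, alpha_neg) {
  if (any(alpha_pos < 0 | alpha_neg < 0, na.rm = TRUE)) {
    stop("learning rates must be non-negative", call. = FALSE)
  }
  both_zero <- alpha_pos == 0 & alpha_neg == 0
  if (any(both_zero, na.rm = TRUE)) {
    warning(sum(both_zero, na.rm = TRUE),
            " bias score(s) undefined (both learning rates 0); returning NA")
  }
  out <- (alpha_pos - alpha_neg) / (alpha_pos + alpha_neg)
  out[both_zero] <- NA_real_
  out
}

#' Repeated-measures ANOVA on a long table
#'
#' Split-plot decomposition via `stats::aov` with an `Error(subject/...)`
#' stratum per within-subject effect; an optional between-subjects factor
#' enters all strata. Designs produced by this package are balanced, where
#' the sums-of-squares decomposition is unambiguous (type I = type III).
#'
#' @param data Long data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional between-subjects factor column.
#' @param subject Subject identifier column.
#' @return A data frame of class `loop_anova` with columns `effect`, `df1`,
#'   `df2`, `F`, `p` (effects with zero effect and error variance are
#'   reported as F = 0, p = 1 and flagged in a `note` column).
#' @export
rm_anova <- function(data, dv, within, between = NULL,
                     subject = "subject_id") {
  df <- as.data.frame(data)
  need <- c(dv, within, between, subject)
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)),
                                      collapse = ", "), call. = FALSE)
  }
  for (v in c(within, between, subject)) df[[v]] <- factor(df[[v]])
  # every subject must fill every within-cell
  cell <- interaction(df[within], drop = FALSE)
  tab <- table(df[[subject]], cell)
  if (any(tab == 0)) stop("missing within-subject cells", call. = FALSE)
  if (length(unique(as.vector(tab))) > 1L) {
    stop("unbalanced within-subject cells", call. = FALSE)
  }
  if (!is.null(between)) {
    bt <- table(df[[subject]], df[[between]]) > 0
    if (any(rowSums(bt) != 1L)) {
      stop("each subject must belong to exactly one between-group level",
           call. = FALSE)
    }
    if (any(colSums(bt) < 2L)) {
      stop("need >= 2 subjects per between-group level", call. = FALSE)
    }
  }
  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "),
                "))")
  form <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- aov(form, data = df)
  res <- list()
  for (stratum in summary(fit)) {
    tabs <- stratum[[1]]
    rn <- trimws(rownames(tabs))
    resid_row <- which(rn == "Residuals")
    df2 <- if (length(resid_row)) tabs[resid_row, "Df"] else NA_real_
    ms_err <- if (length(resid_row)) tabs[resid_row, "Mean Sq"] else NA_real_
    for (i in setdiff(seq_along(rn), resid_row)) {
      Fv <- tabs[i, "F value"]; pv <- tabs[i, "Pr(>F)"]
      note <- ""
      if (isTRUE(tabs[i, "Mean Sq"] < 1e-10)) {
        Fv <- 0; pv <- 1; note <- "zero-variance cell means"
      } else if (!is.finite(Fv) || (is.finite(ms_err) && ms_err < 1e-10)) {
        note <- "undefined F (zero error variance)"
      }
      res[[length(res) + 1L]] <- data.frame(
        effect = gsub(":", " x ", rn[i]), df1 = tabs[i, "Df"], df2 = df2,
        F = Fv, p = pv, note = note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("loop_anova", "data.frame")
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear removal
#' of the control variables; with no controls this is the plain Pearson
#' correlation. The p value uses the t distribution with
#' `n - 2 - n_controls` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional numeric vector, matrix or data frame of control
#'   variables.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_corr <- function(x, y, controls = NULL) {
  if (is.null(controls)) {
    ctrl <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    ctrl <- as.matrix(as.data.frame(controls))
  }
  keep <- complete.cases(x, y, ctrl)
  x <- x[keep]; y <- y[keep]
  ctrl <- ctrl[keep, , drop = FALSE]
  n <- length(x); g <- ncol(ctrl)
  if (n <= g + 2L) stop("need n > number of controls + 2", call. = FALSE)
  if (g > 0) {
    X <- cbind(1, ctrl)
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient control variables", call. = FALSE)
    }
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    warning("degenerate partial correlation: a variable is fully ",
            "explained by the controls; returning r = 0")
    return(list(r = 0, p = 1, df = n - 2L - g, n = n, degenerate = TRUE))
  }
  r <- cor(x, y)
  df <- n - 2L - g
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df, n = n,
       degenerate = FALSE)
}

#' Compare two independent correlations (Fisher z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p value from the standard normal.
#'
#' @param r1,r2 Correlations with |r| < 1.
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must satisfy |r| < 1", call. = FALSE)
  }
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Rebuild a parameter set from a named vector (e.g. posterior means).
params_from_vector <- function(model, v) {
  parameter_set(model,
                alphas = v[model$alpha_slots],
                init_values = if (length(model$init_slots))
                  v[model$init_slots] else numeric(0),
                condition_means = if (model$rule == "mean")
                  v[model$mean_slots] else numeric(0),
                noise_sd = unname(v[["noise_sd"]]))
}

# Per-condition trial position (1..n within each condition), the "Trial"
# factor of the model-free analysis.
condition_position <- function(data) {
  stats::ave(seq_len(nrow(data)),
             interaction(data$subject_id, data$condition),
             FUN = seq_along)
}

#' Model-free repeated-measures analysis of expectation ratings
#'
#' The Trial x Ability (x Agent) ANOVA on per-trial ratings, with Trial
#' being the within-condition position (1..25 or 1..30).
#'
#' @param data Long behavioral data (one row per subject x trial).
#' @param dv Rating column (default `exp_rating`).
#' @param between Optional between-subjects factor column.
#' @return A [rm_anova()] table.
#' @export
model_free_anova <- function(data, dv = "exp_rating", between = NULL) {
  df <- as.data.frame(data)
  df$trial_pos <- condition_position(df)
  within <- c("trial_pos", "ability",
              if (length(unique(df$agent)) > 1L) "agent")
  rm_anova(df, dv, within = within, between = between)
}

#' Posterior predictive check: variance captured by a fitted model
#'
#' For each subject the fitted model's predicted trajectory (at the
#' posterior central tendency of the parameters) is regressed against the
#' observed ratings, giving an R-squared per condition and overall; the
#' model-free Trial x condition analysis is additionally repeated on the
#' predicted data to check that the model reproduces the design's core
#' effects. Constant predictions (e.g. a grand mean) give R-squared 0 and
#' are flagged.
#'
#' @param fits List of `loop_fit`s for one model across subjects (or a
#'   `loop_fitset` plus `model`).
#' @param data Long behavioral data covering the same subjects.
#' @param model Model name when `fits` is a fitset.
#' @param central Posterior central tendency, `"mean"` or `"median"`.
#' @return A `loop_ppc`: `r2` (subject x condition table, including
#'   `overall`), `mean_r2`, `sd_r2` (overall, across subjects), `anova`
#'   (model-free ANOVA on predictions), `predicted` (long data frame).
#' @export
ppc <- function(fits, data, model = NULL, central = c("mean", "median")) {
  central <- match.arg(central)
  if (inherits(fits, "loop_fitset")) {
    fits <- fits[[if (is.null(model)) 1L else model]]
  }
  df <- as.data.frame(data)
  rows <- list(); pred_all <- list()
  for (f in fits) {
    sub <- df[df$subject_id == f$subject_id, , drop = FALSE]
    if (!nrow(sub)) stop("no data for subject ", f$subject_id, call. = FALSE)
    v <- if (central == "mean") f$posterior_mean else f$posterior_median
    pars <- params_from_vector(f$model, v)
    traj <- predict_trajectory(f$model, pars, sub,
                               observations = sub$exp_rating,
                               state = f$state)
    sub$predicted <- traj$latent_exp
    pred_all[[length(pred_all) + 1L]] <- sub
    r2_of <- function(obs, pred) {
      if (sd(pred) < 1e-12) return(c(r2 = 0, flag = 1))
      c(r2 = summary(lm(obs ~ pred))$r.squared, flag = 0)
    }
    for (cond in unique(sub$condition)) {
      i <- sub$condition == cond
      v2 <- r2_of(sub$exp_rating[i], sub$predicted[i])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = f$subject_id, condition = cond, r2 = v2[["r2"]],
        constant_prediction = v2[["flag"]] == 1, stringsAsFactors = FALSE)
    }
    v2 <- r2_of(sub$exp_rating, sub$predicted)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = f$subject_id, condition = "overall", r2 = v2[["r2"]],
      constant_prediction = v2[["flag"]] == 1, stringsAsFactors = FALSE)
  }
  r2 <- do.call(rbind, rows)
  predicted <- do.call(rbind, pred_all)
  overall <- r2[r2$condition == "overall", ]
  # the group-level re-analysis of predictions needs >= 2 subjects
  anova_pred <- if (length(unique(predicted$subject_id)) >= 2L) {
    model_free_anova(predicted, dv = "predicted")
  } else NULL
  structure(list(r2 = r2, mean_r2 = mean(overall$r2),
                 sd_r2 = sd(overall$r2), anova = anova_pred,
                 predicted = predicted),
            class = "loop_ppc")
}

#' @export
print.loop_ppc <- function(x, ...) {
  cat("<loop_ppc> overall R2 = ", round(x$mean_r2, 2), " +- ",
      round(x$sd_r2, 2), " (M +- SD over ",
      sum(x$r2$condition == "overall"), " subjects)\n", sep = "")
  invisible(x)
}

#' Per-subject valence bias scores from a fitted valence model
#'
#' @param fitset A [fit_cohort()] result containing a valence model.
#' @param model Valence model name (default `"M6_valence_SO"` when present,
#'   else `"M3_valence"`).
#' @param referent `"self"` or `"other"` (only for self/other models).
#' @param central Posterior central tendency.
#' @return Data frame `subject_id`, `valence_bias`.
#' @export
bias_scores <- function(fitset, model = NULL,
                        referent = c("self", "other"),
                        central = "mean") {
  referent <- match.arg(referent)
  if (is.null(model)) {
    model <- if ("M6_valence_SO" %in% names(fitset)) "M6_valence_SO"
             else "M3_valence"
  }
  est <- posterior_parameters(fitset, model, central)
  spec <- fitset[[model]][[1]]$model
  suff <- if (spec$agent_split) paste0("_", referent) else ""
  data.frame(subject_id = est$subject_id,
             valence_bias = valence_bias_score(
               est[[paste0("alpha_pos", suff)]],
               est[[paste0("alpha_neg", suff)]]),
             stringsAsFactors = FALSE)
}
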
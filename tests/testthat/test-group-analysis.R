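test_that("valence bias scores normalize the learning asymmetry", {
  expect_equal(valence_bias_score(0.1, 0.1), 0)
  expect_equal(valence_bias_score(0.2, 0), 1)
  expect_equal(valence_bias_score(0.09, 0.15), -0.25)
  # scale invariance and oddness under swapping
  for (i in 1:10) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1); c <- runif(1, 0.1, 10)
    expect_equal(valence_bias_score(c * a, c * b),
                 valence_bias_score(a, b), tolerance = 1e-12)
    expect_equal(valence_bias_score(a, b), -valence_bias_score(b, a))
    expect_gte(abs(valence_bias_score(a, b)), 0)
    expect_lte(abs(valence_bias_score(a, b)), 1)
  }
  expect_warning(out <- valence_bias_score(c(0, 0.1), c(0, 0.2)),
                 "undefined")
  expect_true(is.na(out[1])); expect_equal(out[2], -1 / 3)
  expect_error(valence_bias_score(-0.1, 0.2), "non-negative")
})

test_that("the repeated-measures ANOVA matches a manual sums-of-squares oracle", {
  # 4 subjects x Agent(2) x Valence(2), hand-decomposed
  y <- c(5, 7, 6, 9,   4, 6, 5, 8,   6, 9, 8, 12,  5, 7, 7, 9)
  d <- data.frame(subject_id = rep(paste0("s", 1:4), times = 4),
                  agent = rep(c("self", "other"), each = 8),
                  valence = rep(rep(c("pos", "neg"), each = 4), times = 2),
                  y = y)
  tab <- rm_anova(d, "y", within = c("agent", "valence"))

  # independent oracle: classical within-subject decomposition
  m <- tapply(d$y, list(d$subject_id, d$agent, d$valence), mean)
  grand <- mean(y)
  ms <- apply(m, 1, mean); ma <- apply(m, 2, mean); mv <- apply(m, 3, mean)
  msa <- apply(m, c(1, 2), mean); msv <- apply(m, c(1, 3), mean)
  mav <- apply(m, c(2, 3), mean)
  ss_a <- 4 * 2 * sum((ma - grand)^2)
  ss_ea <- 2 * sum((msa - outer(ms, ma, `+`) + grand)^2)
  ss_v <- 4 * 2 * sum((mv - grand)^2)
  ss_ev <- 2 * sum((msv - outer(ms, mv, `+`) + grand)^2)
  ss_av <- 4 * sum((mav - outer(ma, mv, `+`) + grand)^2)
  resid <- m
  for (s in 1:4) for (a in 1:2) for (v in 1:2) {
    resid[s, a, v] <- m[s, a, v] - msa[s, a] - msv[s, v] - mav[a, v] +
      ms[s] + ma[a] + mv[v] - grand
  }
  ss_eav <- sum(resid^2)
  f_oracle <- c(agent = (ss_a / 1) / (ss_ea / 3),
                valence = (ss_v / 1) / (ss_ev / 3),
                inter = (ss_av / 1) / (ss_eav / 3))
  expect_equal(tab$F[tab$effect == "agent"], f_oracle[["agent"]],
               tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "valence"], f_oracle[["valence"]],
               tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "agent x valence"], f_oracle[["inter"]],
               tolerance = 1e-10)
  expect_true(all(tab$df1 == 1) && all(tab$df2 == 3))

  # location invariance of the interaction
  d2 <- d; d2$y <- d2$y + 100
  tab2 <- rm_anova(d2, "y", within = c("agent", "valence"))
  expect_equal(tab2$F[tab2$effect == "agent x valence"],
               tab$F[tab$effect == "agent x valence"], tolerance = 1e-8)

  # degenerate inputs
  d3 <- d; d3$y <- 7
  tab3 <- rm_anova(d3, "y", within = c("agent", "valence"))
  expect_true(all(tab3$F == 0) && all(tab3$p == 1))
  expect_true(all(tab3$note == "zero-variance cell means"))
  expect_error(rm_anova(d[-1, ], "y", within = c("agent", "valence")),
               "cells")
})

test_that("partial correlations equal the residual-regression oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 6.1)
  y <- c(0.8, 2.9, 2.5, 4.9, 5.2, 5.8)
  z <- c(1.0, 2.0, 1.5, 3.5, 3.0, 4.0)

  plain <- partial_corr(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(plain$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(plain$p, ct$p.value, tolerance = 1e-10)

  pc <- partial_corr(x, y, z)
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, 3)

  expect_warning(deg <- partial_corr(x, z, z), "degenerate")
  expect_equal(deg$r, 0)
  expect_error(partial_corr(x, y, cbind(z, 2 * z)), "rank-deficient")
  expect_error(partial_corr(x[1:3], y[1:3], z[1:3]), "controls")
})

test_that("Fisher z compares independent correlations", {
  eq <- fisher_z_compare(0.4, 30, 0.4, 50)
  expect_equal(eq$z, 0); expect_equal(eq$p, 1)

  a <- fisher_z_compare(0.5, 40, 0.2, 40)
  b <- fisher_z_compare(0.2, 40, 0.5, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  # correlations and group sizes on the scale of a private/public contrast
  res <- fisher_z_compare(0.06, 52, -0.39, 60)
  expect_gt(abs(res$z), 2.2); expect_lt(abs(res$z), 2.6)
  expect_lt(res$p, 0.05)

  expect_error(fisher_z_compare(1, 30, 0.2, 30), "\\|r\\| < 1")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 30), "n >= 4")
})

test_that("posterior predictive checks capture near-noise-free data", {
  m <- model_spec("M3_valence", "audience_private")
  d <- build_design("audience_private", seed = 17)
  p <- parameter_set(m, alphas = c(alpha_pos = 0.15, alpha_neg = 0.25),
                     init_values = c(init_self_high = 50,
                                     init_self_low = 50),
                     noise_sd = 1)
  dat <- simulate_subject(d, m, p, seed = 3, subject_id = "s1")
  dat2 <- simulate_subject(d, m, p, seed = 4, subject_id = "s2")
  f <- fit_subject(m, dat, quick_cfg(11))
  f2 <- fit_subject(m, dat2, quick_cfg(13))
  rep1 <- ppc(list(f, f2), rbind(dat, dat2))
  expect_gt(rep1$mean_r2, 0.9)
  expect_true(all(rep1$r2$r2 <= 1))
  expect_s3_class(rep1$anova, "loop_anova")
  expect_true("trial_pos x ability" %in% rep1$anova$effect)

  # a pure mean model predicts constants within condition: flagged R2 = 0
  mm <- model_spec("M_mean", "audience_private")
  fm <- fit_subject(mm, dat, quick_cfg(12))
  repm <- ppc(list(fm), dat)
  percond <- repm$r2[repm$r2$condition != "overall", ]
  expect_true(all(percond$r2 == 0))
  expect_true(all(percond$constant_prediction))
})

test_that("trait associations built into a cohort are recovered from fits", {
  m <- model_spec("M3_valence", "audience_private")
  rs <- vapply(1:3, function(s) {
    co <- simulate_cohort(60, "audience_private",
                          trait_coupling = c(social_anxiety = -0.4),
                          seed = s)
    fs <- fit_cohort(co, models = list(M3_valence = m),
                     cfg = quick_cfg(s + 30))
    vb <- bias_scores(fs, "M3_valence")
    # the fitted bias must track the true generative asymmetry closely
    expect_gt(cor(vb$valence_bias, co$true_params$valence_bias), 0.8)
    cor(vb$valence_bias, co$traits$social_anxiety)
  }, numeric(1))
  r <- mean(rs)
  expect_gt(r, -0.6); expect_lt(r, -0.2)
})
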
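test_that("the delta rule moves expectations a fraction alpha toward feedback", {
  expect_equal(rw_update(50, 50, 0.3), 50)
  expect_equal(rw_update(50, 96, 1.0), 96)
  expect_equal(rw_update(40, 60, 0.14), 42.8)
  # stays between expectation and feedback
  for (i in 1:20) {
    e <- runif(1, 0, 100); f <- runif(1, 0, 100); a <- runif(1)
    u <- rw_update(e, f, a)
    expect_gte(u, min(e, f)); expect_lte(u, max(e, f))
  }
  expect_error(rw_update(50, 60, 1.4), "\\[0, 1\\]")
})

test_that("trial context maps to the correct learning-rate slot", {
  m6 <- model_spec("M6_valence_SO", "agent_private")
  expect_equal(resolve_alpha(m6, "self", "low", pe = -4), "alpha_neg_self")
  expect_equal(resolve_alpha(m6, "other", "high", pe = 2), "alpha_pos_other")
  expect_equal(resolve_alpha(m6, "self", "high", pe = 0), "alpha_pos_self")

  m2 <- model_spec("M2_ability", "agent_private")
  expect_equal(resolve_alpha(m2, "self", "high", pe = -1), "alpha_HA")
  expect_equal(resolve_alpha(m2, "other", "low", pe = 3), "alpha_LA")

  m1 <- model_spec("M1_unity", "agent_private")
  for (ag in c("self", "other")) for (ab in c("high", "low")) {
    expect_equal(resolve_alpha(m1, ag, ab, pe = rnorm(1)), "alpha_uni")
  }
  mm <- model_spec("M_mean", "agent_private")
  expect_error(resolve_alpha(mm, "self", "high", 1), "mean model")
})

test_that("the model space has the right size and slot counts", {
  ag <- model_space("agent_private")
  au <- model_space("audience_private")
  expect_length(ag, 7)
  expect_length(au, 4)
  expect_equal(vapply(ag, `[[`, 0L, "n_alpha_slots"),
               c(M1_unity = 1L, M2_ability = 2L, M3_valence = 2L,
                 M4_unity_SO = 2L, M5_ability_SO = 4L, M6_valence_SO = 4L,
                 M_mean = 0L))
  expect_length(ag$M_mean$mean_slots, 4)
  expect_length(au$M_mean$mean_slots, 2)
  for (m in c(ag, au)) {
    expect_equal(length(unique(m$alpha_slots)), m$n_alpha_slots)
  }
  expect_error(model_spec("M6_valence_SO", "audience_private"), "unknown model")
})

test_that("trajectories follow the geometric closed form under constant feedback", {
  m <- model_spec("M1_unity", "audience_private")
  e0 <- 20; f <- 70; a <- 0.35
  d <- data.frame(trial = 1:16,
                  agent = "self",
                  ability = rep(c("high", "low"), each = 8),
                  feedback = f)
  p <- parameter_set(m, alphas = c(alpha_uni = a),
                     init_values = c(init_self_high = e0, init_self_low = e0),
                     noise_sd = 5)
  traj <- predict_trajectory(m, p, d)
  # expectation before the t-th feedback of a condition: f + (1-a)^(t-1) (e0-f)
  for (cond in c("high", "low")) {
    lat <- traj$latent_exp[traj$ability == cond]
    expect_equal(lat, f + (1 - a)^(0:7) * (e0 - f), tolerance = 1e-12)
  }
  # alpha = 0: constant at inits
  p0 <- parameter_set(m, alphas = c(alpha_uni = 0),
                      init_values = c(init_self_high = 33, init_self_low = 66),
                      noise_sd = 5)
  t0 <- predict_trajectory(m, p0, d)
  expect_true(all(t0$latent_exp[t0$ability == "high"] == 33))
  expect_true(all(t0$latent_exp[t0$ability == "low"] == 66))
})

test_that("richer models with tied parameters reproduce their parents exactly", {
  d <- build_design("agent_private", seed = 8)
  dat <- simulate_subject(d, model_spec("M6_valence_SO", "agent_private"),
                          m6_params(model_spec("M6_valence_SO", "agent_private")),
                          seed = 4)
  inits4 <- c(init_self_high = 48, init_self_low = 52,
              init_other_high = 55, init_other_low = 45)
  m1 <- model_spec("M1_unity", "agent_private")
  m4 <- model_spec("M4_unity_SO", "agent_private")
  m6 <- model_spec("M6_valence_SO", "agent_private")
  m3 <- model_spec("M3_valence", "agent_private")
  m5 <- model_spec("M5_ability_SO", "agent_private")

  a <- 0.27; s <- 9
  p1 <- parameter_set(m1, alphas = c(alpha_uni = a), init_values = inits4,
                      noise_sd = s)
  p4 <- parameter_set(m4, alphas = c(alpha_uni_self = a, alpha_uni_other = a),
                      init_values = inits4, noise_sd = s)
  p6 <- parameter_set(m6, alphas = c(alpha_pos_self = a, alpha_neg_self = a,
                                     alpha_pos_other = a, alpha_neg_other = a),
                      init_values = inits4, noise_sd = s)
  p3 <- parameter_set(m3, alphas = c(alpha_pos = a, alpha_neg = a),
                      init_values = inits4, noise_sd = s)
  p5 <- parameter_set(m5, alphas = c(alpha_HA_self = a, alpha_LA_self = a,
                                     alpha_HA_other = a, alpha_LA_other = a),
                      init_values = inits4, noise_sd = s)
  ll <- function(m, p) log_likelihood_pointwise(m, p, dat)
  base <- ll(m1, p1)
  expect_identical(ll(m4, p4), base)
  expect_identical(ll(m6, p6), base)
  expect_identical(ll(m3, p3), base)
  expect_identical(ll(m5, p5), base)

  # self/other split with distinct self vs other rates: M6 tied within
  # valence equals M4
  p4b <- parameter_set(m4, alphas = c(alpha_uni_self = 0.1,
                                      alpha_uni_other = 0.4),
                       init_values = inits4, noise_sd = s)
  p6b <- parameter_set(m6, alphas = c(alpha_pos_self = 0.1,
                                      alpha_neg_self = 0.1,
                                      alpha_pos_other = 0.4,
                                      alpha_neg_other = 0.4),
                       init_values = inits4, noise_sd = s)
  expect_identical(ll(m6, p6b), ll(m4, p4b))
})

test_that("latent expectations stay inside the rating scale", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      m <- model_spec(sample(c("M1_unity", "M3_valence"), 1),
                      "audience_private")
      d <- build_design("audience_private", seed = sample.int(1e6, 1))
      al <- runif(m$n_alpha_slots)
      p <- parameter_set(m, alphas = setNames(al, m$alpha_slots),
                         init_values = setNames(runif(2, 0, 100),
                                                m$init_slots),
                         noise_sd = 5)
      traj <- predict_trajectory(m, p, d)
      expect_true(all(traj$latent_exp >= 0 & traj$latent_exp <= 100))
      # update direction follows the prediction-error sign
      for (cond in unique(traj$condition)) {
        sub <- traj[traj$condition == cond, ]
        dlt <- diff(sub$latent_exp)
        pe <- sub$pe[-nrow(sub)]
        if (all(al > 0)) expect_true(all(sign(dlt) == sign(pe) | pe == 0))
      }
    }
  })
})

test_that("pointwise log-likelihood matches independent arithmetic to 1e-10", {
  m <- model_spec("M6_valence_SO", "agent_private")
  d5 <- data.frame(trial = 1:5,
                   agent = c("self", "self", "other", "self", "other"),
                   ability = c("low", "low", "high", "low", "high"),
                   feedback = c(22, 41, 88, 30, 55),
                   exp_rating = c(48.2, 44.9, 51.3, 40.0, 62.7))
  p <- parameter_set(m,
    alphas = c(alpha_pos_self = 0.12, alpha_neg_self = 0.31,
               alpha_pos_other = 0.05, alpha_neg_other = 0.22),
    init_values = c(init_self_high = 47, init_self_low = 52,
                    init_other_high = 58, init_other_low = 44),
    noise_sd = 7.5)
  got <- log_likelihood_pointwise(m, p, d5)
  want <- ref_loglik_valence_so(
    d5,
    alphas = list(pos_self = 0.12, neg_self = 0.31, pos_other = 0.05,
                  neg_other = 0.22),
    inits = c(self_high = 47, self_low = 52, other_high = 58,
              other_low = 44),
    noise_sd = 7.5)
  expect_equal(got, want, tolerance = 1e-10)
  expect_length(got, 5)

  # zero residuals: every entry is -log(s * sqrt(2*pi))
  d0 <- d5
  traj <- predict_trajectory(m, p, d0)
  d0$exp_rating <- traj$latent_exp
  expect_equal(log_likelihood_pointwise(m, p, d0),
               rep(-log(7.5 * sqrt(2 * pi)), 5), tolerance = 1e-12)

  p0 <- parameter_set(m, alphas = p$alphas,
                      init_values = p$init_values, noise_sd = 0)
  expect_error(log_likelihood_pointwise(m, p0, d5), "noise_sd")
})

test_that("parameter sets validate slots and ranges", {
  m <- model_spec("M3_valence", "audience_private")
  expect_error(parameter_set(m, alphas = c(alpha_pos = 0.2),
                             init_values = c(init_self_high = 50,
                                             init_self_low = 50)),
               "slots")
  expect_error(parameter_set(m, alphas = c(alpha_pos = 1.2, alpha_neg = 0.1),
                             init_values = c(init_self_high = 50,
                                             init_self_low = 50)),
               "\\[0, 1\\]")
  mm <- model_spec("M_mean", "audience_private")
  pm <- parameter_set(mm, condition_means = c(mean_self_high = 60,
                                              mean_self_low = 40),
                      noise_sd = 8)
  d <- build_design("audience_private", 3)
  traj <- predict_trajectory(mm, pm, d)
  expect_true(all(traj$latent_exp[traj$ability == "high"] == 60))
  expect_true(all(traj$latent_exp[traj$ability == "low"] == 40))
})

test_that("model specs round-trip through JSON", {
  m <- model_spec("M5_ability_SO", "agent_public", "fitted_combined")
  json <- loop_to_json(m)
  m2 <- model_from_json(json)
  expect_equal(m2$name, m$name)
  expect_equal(m2$alpha_slots, m$alpha_slots)
  expect_equal(m2$init_scheme, m$init_scheme)
})
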
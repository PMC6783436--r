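# Shared helpers: reduced sampler settings for simulation studies, and an
# independent hand-rolled likelihood path used as an oracle.

quick_cfg <- function(seed, n_warmup = 300L, n_retained = 600L) {
  sampler_config(n_chains = 2L, n_warmup = n_warmup,
                 n_retained = n_retained, thin = 1L, seed = seed)
}

# Independent arithmetic path for the delta-rule likelihood: explicit R
# loop, explicit Gaussian log-density formula, its own slot resolution.
ref_loglik_valence_so <- function(data, alphas, inits, noise_sd) {
  # alphas: list with pos_self, neg_self, pos_other, neg_other
  # inits: named by condition label (e.g. self_high)
  state <- inits
  out <- numeric(nrow(data))
  for (t in seq_len(nrow(data))) {
    cond <- paste(data$agent[t], data$ability[t], sep = "_")
    mu <- state[[cond]]
    out[t] <- -0.5 * log(2 * pi * noise_sd^2) -
      (data$exp_rating[t] - mu)^2 / (2 * noise_sd^2)
    pe <- data$feedback[t] - mu
    a <- if (pe >= 0) {
      if (data$agent[t] == "self") alphas$pos_self else alphas$pos_other
    } else {
      if (data$agent[t] == "self") alphas$neg_self else alphas$neg_other
    }
    state[[cond]] <- mu + a * pe
  }
  out
}

# Analytic leave-one-out for the conjugate normal-mean model: y_i ~ N(theta,
# sigma), theta ~ N(mu0, tau0); returns draws, pointwise log-lik and the
# exact LOO elpd.
conjugate_loo_case <- function(n, sigma = 2, tau0 = 5, mu0 = 0,
                               n_draws = 2000, seed = 1) {
  withr::with_seed(seed, {
    y <- rnorm(n, 1.5, sigma)
    tau_n <- 1 / sqrt(n / sigma^2 + 1 / tau0^2)
    mu_n <- tau_n^2 * (sum(y) / sigma^2 + mu0 / tau0^2)
    th <- rnorm(n_draws, mu_n, tau_n)
    ll <- vapply(y, function(yi) dnorm(yi, th, sigma, log = TRUE),
                 numeric(n_draws))
    exact <- vapply(seq_len(n), function(i) {
      tn <- 1 / sqrt((n - 1) / sigma^2 + 1 / tau0^2)
      mn <- tn^2 * (sum(y[-i]) / sigma^2 + mu0 / tau0^2)
      dnorm(y[i], mn, sqrt(sigma^2 + tn^2), log = TRUE)
    }, numeric(1))
    list(y = y, loglik = ll, exact_elpd = sum(exact),
         exact_pointwise = exact)
  })
}

# Default M6 parameter set on round numbers, for trajectory tests.
m6_params <- function(model, pos_self = 0.12, neg_self = 0.18,
                      pos_other = 0.11, neg_other = 0.10, noise_sd = 10,
                      init = 50) {
  parameter_set(model,
    alphas = c(alpha_pos_self = pos_self, alpha_neg_self = neg_self,
               alpha_pos_other = pos_other, alpha_neg_other = neg_other),
    init_values = setNames(rep(init, 4), model$init_slots),
    noise_sd = noise_sd)
}
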
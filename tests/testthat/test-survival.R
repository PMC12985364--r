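test_that("time discretization uses type-7 quartiles of uncensored subjects", {
  d <- discretize_times(c(1:100, 200, 300), c(rep(0, 100), 1, 1))
  expect_equal(d$cuts, c(25.75, 50.5, 75.25))
  labs <- d$labels[1:100]
  expect_equal(unname(table(labs)), c(25, 25, 25, 25), ignore_attr = TRUE)
  # censored times beyond the last cut take the last interval
  expect_equal(d$labels[101:102], c(3L, 3L))
  # a censored time below the first cut takes label 0
  d2 <- discretize_times(c(1:20, 2.5), c(rep(0, 20), 1))
  expect_equal(d2$labels[21], 0L)
  expect_error(discretize_times(rep(5, 10), rep(0, 10)), "degenerate")
  expect_error(discretize_times(c(1, 2), c(0, 0), n_intervals = 4), "uncensored")
})

test_that("survival curves from hazards: closed forms and monotonicity", {
  expect_equal(unname(survival_from_hazard(rep(0, 4))), rep(1, 5))
  expect_equal(unname(survival_from_hazard(rep(0.5, 4))),
               c(1, 0.5, 0.25, 0.125, 0.0625))
  set.seed(71)
  for (rep in 1:10) {
    h <- runif(6)
    s <- survival_from_hazard(h)
    expect_equal(unname(s[1]), 1)
    # cumulative-product loop oracle
    acc <- 1
    for (u in seq_along(h)) {
      acc <- acc * (1 - h[u])
      expect_equal(unname(s[u + 1]), acc, tolerance = 1e-15)
    }
    expect_true(all(diff(s) <= 0))
  }
  expect_error(survival_from_hazard(c(0.5, 1.2)), "hazards")
})

test_that("survival loss reproduces the hand-computed cases exactly", {
  # censored subject with zero hazards: -log S = 0
  expect_equal(survival_loss(rep(0, 4), label = 2, censor = 1, beta = 0.5), 0)
  # uncensored in the first interval with h_1 = 1: -log S(0) - log h_1 = 0
  expect_equal(survival_loss(c(1, 0.3, 0.3, 0.3), label = 0, censor = 0,
                             beta = 0.5), 0)
  # uncensored in the first interval, h = 0.5, beta = 0: L = ln 2
  expect_equal(survival_loss(rep(0.5, 4), label = 0, censor = 0, beta = 0),
               log(2))
  expect_error(survival_loss(rep(0.5, 4), label = 7, censor = 0), "range")
})

test_that("beta mixes the censored and uncensored loss parts as specified", {
  h <- c(0.2, 0.4, 0.3, 0.1)
  # uncensored: L == L_uncensored, so the mix is beta-independent
  for (b in c(0, 0.3, 1)) {
    expect_equal(survival_loss(h, 2, 0, b),
                 -log(prod(1 - h[1:2])) - log(h[3]), tolerance = 1e-12)
  }
  # censored: L_unc = 0, so L_surv = (1 - beta) * L
  L <- -log(prod(1 - h[1:3]))
  expect_equal(survival_loss(h, 2, 1, 0), L, tolerance = 1e-12)
  expect_equal(survival_loss(h, 2, 1, 0.5), 0.5 * L, tolerance = 1e-12)
  expect_equal(survival_loss(h, 2, 1, 1), 0, tolerance = 1e-12)
})

test_that("concordance index: closed cases and O(n^2) oracle with censoring", {
  t0 <- c(3, 1, 4, 2, 5)
  expect_equal(concordance_index(t0, t0), 1)
  expect_equal(concordance_index(-t0, t0), 0)
  set.seed(72)
  for (rep in 1:10) {
    n <- 20
    times <- rexp(n)
    censor <- rbinom(n, 1, 0.3)
    scores <- rnorm(n)
    expect_equal(concordance_index(scores, times, censor),
                 oracle_cindex(scores, times, censor), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms of the scores
  s <- rnorm(20); tm <- rexp(20); cs <- rbinom(20, 1, 0.2)
  expect_equal(concordance_index(s, tm, cs),
               concordance_index(exp(s), tm, cs))
  # score ties count one half
  expect_equal(concordance_index(c(1, 1), c(1, 2), c(0, 0)), 0.5)
  expect_error(concordance_index(1:3, c(2, 2, 2), rep(0, 3)), "admissible")
})

test_that("concordance agrees with the survival package on risk scores", {
  set.seed(73)
  n <- 150
  risk <- rnorm(n)
  times <- rexp(n, exp(risk))
  censor <- rbinom(n, 1, 0.25)
  got <- concordance_index(-risk, times, censor)
  cf <- survival::concordance(survival::Surv(times, 1 - censor) ~ risk,
                              reverse = TRUE)
  expect_equal(got, unname(cf$concordance), tolerance = 1e-10)
})

test_that("hazard model fitting: lr = 0 freezes parameters; fitting recovers risk ranking", {
  co <- generate_survival_cohort(300, 4, c(1, -1, 0.5, 0), 0.2, seed = 5)
  f0 <- fit_hazard_model(co, epochs = 5, learning_rate = 0, seed = 9)
  fresh <- fit_hazard_model(co, epochs = 1, learning_rate = 0, seed = 9)
  expect_equal(f0$weights, fresh$weights, tolerance = 1e-12)
  fit <- fit_hazard_model(co, epochs = 300, learning_rate = 0.1, seed = 9)
  expect_lt(tail(fit$trace, 1), fit$trace[1])
  # weights recover the generating direction
  expect_gt(cor(fit$weights, co$true_weights), 0.8)
  ci <- concordance_index(-predict(fit, co$features), co$time, co$censor)
  expect_gt(ci, 0.65)
  # hazard/survival predictions are coherent
  h <- predict(fit, co$features[1:3, ], type = "hazard")
  s <- predict(fit, co$features[1:3, ], type = "survival")
  expect_equal(s[, 3], (1 - h[, 1]) * (1 - h[, 2]), tolerance = 1e-12)
})

test_that("slide pooling: average, single spot, and zero-gate attention", {
  m <- matrix(c(1, 3, 2, 6), 2, 2)
  expect_equal(pool_slide(m, "average"), c(2, 4))
  expect_equal(pool_slide(m[1, , drop = FALSE], "average"), c(1, 2))
  expect_equal(pool_slide(m[1, , drop = FALSE], "attention", gate = c(1, -1)),
               c(1, 2))
  # zero gating scores = uniform weights = the average
  expect_equal(pool_slide(m, "attention"), pool_slide(m, "average"),
               tolerance = 1e-12)
  const <- matrix(5, 4, 3)
  expect_equal(pool_slide(const, "average"), rep(5, 3))
  expect_error(pool_slide(m[0, , drop = FALSE], "average"), "empty")
})

test_that("Kaplan-Meier stratification: textbook curves and risk separation", {
  # distinct event times, no censoring: steps of 1/n
  times <- c(1, 2, 3, 4)
  km <- km_stratify(c(10, 9, 1, 2), times, rep(0, 4))
  low <- km$curves[km$curves$group == "low", ]
  expect_equal(low$survival, c(0.5, 0), tolerance = 1e-12)
  # all censored: flat curve at 1
  km2 <- km_stratify(c(3, 1, 4, 2), times, rep(1, 4))
  expect_true(all(km2$curves$survival == 1))
  expect_error(km_stratify(rep(1, 4), times, rep(0, 4)), "constant")
  # product-limit estimator matches the loop oracle within one group
  set.seed(74)
  tt <- sort(rexp(30)); ev <- rep(1, 30)
  km3 <- km_stratify(c(rnorm(29), 100), tt, 1 - ev)
  grp_low <- which(km3$group == "low")
  oracle <- oracle_km(tt[grp_low], ev[grp_low])
  got <- km3$curves[km3$curves$group == "low", ]
  expect_equal(got$survival[match(oracle$time, got$time)], oracle$surv,
               tolerance = 1e-12)
  # informative cohort: the high-risk curve sits below the low-risk curve
  co <- generate_survival_cohort(400, 3, c(1.5, -1, 0.5), 0.2, seed = 6)
  fitc <- fit_hazard_model(co, seed = 2)
  km4 <- km_stratify(predict(fitc, co$features), co$time, co$censor)
  tgrid <- seq(0.05, 2, by = 0.05)
  step_at <- function(curve, t) {
    ix <- which(curve$time <= t)
    if (length(ix) == 0) 1 else curve$survival[max(ix)]
  }
  hi <- km4$curves[km4$curves$group == "high", ]
  lo <- km4$curves[km4$curves$group == "low", ]
  expect_true(all(vapply(tgrid, function(t) {
    step_at(hi, t) <= step_at(lo, t) + 1e-12
  }, logical(1))))
  expect_lt(km4$p_value, 0.01)
})

test_that("integrated gradients: zero at baseline, exact for linear models, complete", {
  w <- c(0.5, -1, 2)
  f_lin <- function(z) sum(w * z)
  g_lin <- function(z) w
  x <- c(1, 2, 3)
  expect_equal(integrated_gradients(f_lin, x, x, steps = 8, grad_fn = g_lin),
               rep(0, 3))
  x0 <- c(0, 1, -1)
  expect_equal(integrated_gradients(f_lin, x, x0, steps = 4, grad_fn = g_lin),
               w * (x - x0), tolerance = 1e-12)
  # nonlinear completeness at 512 steps (smooth moderate-curvature target)
  f_nl <- function(z) tanh(sum(z) / 4) + 0.05 * sum(z^2)
  ig <- integrated_gradients(f_nl, x, x0, steps = 512)
  expect_lt(abs(sum(ig) - (f_nl(x) - f_nl(x0))), 1e-3)
  expect_error(integrated_gradients(f_lin, x, c(0, 0), steps = 8), "length")
  expect_error(integrated_gradients(f_lin, x, x0, steps = 1), "steps")
})

test_that("hazard attribution heatmap has one row per interval and obeys completeness", {
  co <- generate_survival_cohort(120, 4, c(1, -0.5, 0.8, 0), 0.2, seed = 8)
  fit <- fit_hazard_model(co, seed = 3)
  att <- hazard_attribution(fit, co$features, steps = 256)
  expect_equal(dim(att), c(4, 4))
  # completeness averaged over slides, interval 1
  h1 <- function(z) plogis(fit$intercepts[1] + sum(z * fit$weights))
  deltas <- vapply(seq_len(nrow(co$features)), function(i) {
    h1(co$features[i, ]) - h1(numeric(4))
  }, numeric(1))
  ig_sum <- sum(hazard_attribution(fit, co$features, steps = 512)[1, ])
  expect_lt(abs(ig_sum - mean(deltas)), 1e-3)
})
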
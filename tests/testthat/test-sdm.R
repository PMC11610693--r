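test_that("presence fit is deterministic and shrinks toward flat under null truth", {
  cov <- make_cov_table(2000, seed = 31)
  obs <- simulate_observations(cov, null_truth(beta0 = 0.3), seed = 32)
  m1 <- fit_presence(cov, obs$presence)
  m2 <- fit_presence(cov, obs$presence)
  expect_equal(stats::coef(m1$fit), stats::coef(m2$fit), tolerance = 1e-8)

  # null recovery is a distributional property: over replicated null draws,
  # fitted smooths are overwhelmingly flat, though single terms can pick up
  # spurious wiggle in any one draw
  edfs <- c()
  models <- list()
  for (r in 1:5) {
    covr <- make_cov_table(2000, seed = 310 + r)
    obsr <- simulate_observations(covr, null_truth(beta0 = 0.3), seed = 320 + r)
    models[[r]] <- fit_presence(covr, obsr$presence)
    edfs <- c(edfs, model_diagnostics(models[[r]])$terms$edf)
  }
  expect_gte(mean(edfs <= 1.5), 0.8)
  expect_lte(stats::median(edfs), 0.5)

  # in the flattest replicate, the model reduces to its intercept:
  # probability at all-zero covariates is logistic(intercept) and the
  # partial-effect curves are near zero everywhere
  flat <- models[[which.min(vapply(models, function(m)
    max(model_diagnostics(m)$terms$edf), numeric(1)))]]
  nd <- make_cov_table(1, seed = 1)
  nd[, 3:6] <- 0
  pr <- predict(flat, nd)
  expect_equal(pr$probability,
               stats::plogis(unname(stats::coef(flat$fit)[1])), tolerance = 0.02)
  pe <- partial_effects(flat)
  expect_lt(max(abs(pe$effect)), 0.2)
})

test_that("presence fit rejects degenerate label sets", {
  cov <- make_cov_table(100, seed = 33)
  expect_error(fit_presence(cov, rep(TRUE, 100)), "single class")
  expect_error(fit_presence(cov, c(rep(TRUE, 95), rep(FALSE, 5))), ">= 20")
  cov$fall_spatial[1] <- NA
  expect_error(fit_presence(cov, rep(c(TRUE, FALSE), 50)), "non-finite")
})

test_that("binomial predictions are probabilities with strict-threshold labels and extrapolation flags", {
  cov <- make_cov_table(600, seed = 34)
  obs <- simulate_observations(cov, synth_truth(), seed = 35)
  m <- fit_presence(cov, obs$presence)
  pr <- predict(m, cov)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  # training rows are inside training ranges, hence never flagged
  expect_true(!any(pr$extrapolation))
  # a probability exactly at the threshold is labeled absent (strict >)
  pr2 <- predict(m, cov[1, ], threshold = pr$probability[1])
  expect_false(pr2$label)
  # rows beyond the training range are flagged
  out <- cov[1, ]; out$fall_spatial <- max(cov$fall_spatial) + 1
  expect_true(predict(m, out)$extrapolation)
  # self-consistency with the stored fitted values
  expect_equal(pr$probability[1:50], unname(stats::fitted(m$fit)[1:50]),
               tolerance = 1e-8)
})

test_that("cover fit recovers a known concave dependence and stays flat under pure noise", {
  cov <- make_cov_table(1500, seed = 36)
  # pure noise around a constant
  set.seed(37)
  y0 <- stats::rnorm(1500, 11, 3)
  m0 <- fit_abundance(cov, y0)
  dg0 <- model_diagnostics(m0)
  expect_true(all(dg0$terms$edf <= 1.5))
  expect_equal(unname(stats::coef(m0$fit)[1]), mean(y0), tolerance = 0.01)
  # Pearson dispersion agrees with the residual variance for a well-specified fit
  expect_true(dg0$dispersion / stats::var(stats::residuals(m0$fit)) > 0.8 &&
              dg0$dispersion / stats::var(stats::residuals(m0$fit)) < 1.2)
  # concave-down dependence on fall_spatial peaking at 0.5
  y1 <- 15 - 4 * (cov$fall_spatial - 0.5)^2 + stats::rnorm(1500, 0, 2)
  m1 <- fit_abundance(cov, y1)
  pe <- partial_effects(m1, n_grid = 201)
  fs <- pe[pe$term == "fall_spatial", ]
  expect_lt(abs(fs$x[which.max(fs$effect)] - 0.5), 0.5)
  # the fitted curve tracks the generative one on the response scale
  # over the central 90% of the training covariate distribution
  qs <- stats::quantile(cov$fall_spatial, c(0.05, 0.95))
  band <- fs[fs$x >= qs[1] & fs$x <= qs[2], ]
  f_true <- -4 * (band$x - 0.5)^2
  rmse <- sqrt(mean((band$effect - mean(band$effect) -
                       (f_true - mean(f_true)))^2))
  expect_lt(rmse, 0.5)
  # clamped predictions stay in [0, 100]
  pr <- predict(m1, cov)
  expect_true(all(pr$cover_pred_clamped >= 0 & pr$cover_pred_clamped <= 100))
  expect_error(fit_abundance(cov[1:30, ], y0[1:30]), ">= 50")
})

test_that("partial-effect grids span the training range of each covariate", {
  cov <- make_cov_table(500, seed = 38)
  obs <- simulate_observations(cov, synth_truth(), seed = 39)
  m <- fit_presence(cov, obs$presence)
  pe <- partial_effects(m, n_grid = 50)
  for (tm in m$terms) {
    s <- pe[pe$term == tm, ]
    expect_equal(range(s$x), range(cov[[tm]]))
    expect_equal(nrow(s), 50L)
    expect_true(all(s$se > 0))
  }
})

test_that("an under-dimensioned basis fitted to a wiggly signal raises the basis flag", {
  cov <- make_cov_table(1500, seed = 40)
  y <- 4 * sin(2.5 * cov$fall_spatial) + stats::rnorm(1500, 0, 0.5)
  m <- fit_abundance(cov, y, gam_config(k = 4))
  dg <- model_diagnostics(m)
  expect_true(dg$terms$flag_basis[dg$terms$term == "fall_spatial"])
  expect_named(dg[c("family", "terms", "dispersion", "residual_summary", "n")])
})

test_that("increasing the smoothing penalty never increases the training log-likelihood", {
  cov <- make_cov_table(800, seed = 41)
  obs <- simulate_observations(cov, synth_truth(), seed = 42)
  d <- cov[, c("fall_spatial", "spring_spatial", "fall_temporal", "spring_temporal")]
  d$presence <- as.integer(obs$presence)
  f <- presence ~ s(fall_spatial, bs = "cr", k = 10) + s(spring_spatial, bs = "cr", k = 10) +
    s(fall_temporal, bs = "cr", k = 10) + s(spring_temporal, bs = "cr", k = 10)
  ll <- sapply(c(1e-3, 1, 1e3), function(sp)
    as.numeric(stats::logLik(mgcv::gam(f, family = stats::binomial(), data = d,
                                       sp = rep(sp, 4)))))
  expect_true(all(diff(ll) <= 1e-6))
})

test_that("the model JSON record carries the fit's defining quantities", {
  cov <- make_cov_table(300, seed = 43)
  obs <- simulate_observations(cov, synth_truth(), seed = 44)
  m <- fit_presence(cov, obs$presence)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  model_to_json(m, path, constants = list(spatial = list(fall = list(mean = 1, sd = 2))))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$family, "binomial")
  expect_equal(rec$k, 10)
  expect_equal(length(rec$coefficients), length(stats::coef(m$fit)))
  expect_equal(sort(names(rec$knots)), sort(m$terms))
  expect_equal(rec$n_train, 300)
  expect_true(nzchar(rec$scaling_constants_hash))
})
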
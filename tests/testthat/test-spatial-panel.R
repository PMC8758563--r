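test_that("HT unit-root test: bias-corrected plim on random walks,
           rejection on noise, short-panel guard", {
  set.seed(21)
  Y <- t(apply(matrix(rnorm(200 * 12), 200, 12), 1, cumsum))
  r <- ht_unit_root(Y, demean = TRUE)
  expect_equal(r$T, 11L)
  expect_lt(abs(r$statistic - 0.75), 0.02)   # 1 - 3/(T+1) at T = 11
  expect_gt(r$p, 0.01)                       # unit root not rejected
  rn <- ht_unit_root(matrix(rnorm(100 * 11), 100, 11))
  expect_lt(rn$p, 0.01)                      # stationary noise rejects
  expect_error(ht_unit_root(matrix(rnorm(10 * 2), 10, 2)), "3 time")
  expect_error(ht_unit_root(matrix(c(NA, rnorm(29)), 10, 3)),
               "unbalanced")
})

test_that("LM statistics are nonnegative, chi-square sized under the null
           and exactly zero for lag-orthogonal residuals", {
  W <- china_adjacency()
  set.seed(22)
  d <- iid_panel(W)
  lt <- lm_diagnostics(fml6, d, W)
  expect_true(all(lt$statistic >= 0))
  expect_true(all(lt$p >= 0 & lt$p <= 1))
  # constructed case: residuals e with e' W e = 0 exactly
  labs <- letters[1:4]
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w[1, 3] <- w[3, 1] <- 1; w[2, 4] <- w[4, 2] <- 1; w[3, 4] <- w[4, 3] <- 1
  e <- c(1, -1, 0, 0)
  x1 <- c(1, 1, 2, 2)                     # e is orthogonal to [1, x1]
  d0 <- data.frame(unit = rep(labs, 2), year = rep(1:2, each = 4),
                   x1 = rep(x1, 2), y = rep(x1 + e, 2))
  lt0 <- lm_diagnostics(y ~ x1, d0, spatial_weights(w))
  expect_equal(lt0$statistic[lt0$test == "LM-error"], 0,
               tolerance = 1e-20)
})

test_that("ML spatial fits: zero weights collapse to OLS, likelihood at
           rho = 0 equals the OLS likelihood, SDM recovers its DGP", {
  W <- china_adjacency()
  g <- generate_sdm_panel(sdm_spec(W, rho = 0.4, effects = "time",
                                   seed = 2))
  W0 <- spatial_weights(matrix(0, 31, 31), W$labels)
  f0 <- fit_spatial_panel(fml6, g$data, W0, model = "slm",
                          effects = "time")
  fo <- fit_spatial_panel(fml6, g$data, W0, model = "ols",
                          effects = "time")
  expect_equal(f0$rho, 0)
  expect_equal(f0$beta, fo$beta, tolerance = 1e-10)
  # pooled (no effects): the lag likelihood at rho = 0 is the OLS one
  set.seed(23)
  dp <- iid_panel(W, Tn = 4)
  fslm <- fit_spatial_panel(fml6, dp, W0, model = "slm",
                            effects = "none")
  fols <- fit_spatial_panel(fml6, dp, W0, model = "ols",
                            effects = "none")
  expect_equal(fslm$loglik, fols$loglik, tolerance = 1e-8)
  # single-panel SDM point estimates land near the truth
  f <- fit_spatial_panel(fml6, g$data, W, model = "sdm",
                         effects = "time")
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$rho - 0.4), 4 * se["rho"])
  expect_true(all(abs(f$beta[f$xnames] -
                        c(.5, -.3, .2, .8, -.5, .1)) <
                    4 * se[f$xnames] + 1e-8))
  expect_gt(f$sigma2, 0)
  expect_true(is.finite(f$loglik))
  expect_true(f$r2 >= 0 && f$r2 <= 1)
  # accessor methods
  expect_equal(unname(coef(f)["rho"]), f$rho)
  expect_equal(length(residuals(f)), 341L)
  expect_equal(length(predict(f)), 341L)
  expect_s3_class(summary(f), "summary.spfit")
})

test_that("Hausman: zero for identical fits, invariant to covariate order,
           conservative under an RE-consistent process", {
  W <- china_adjacency()
  set.seed(24)
  d <- iid_panel(W)
  ai <- rnorm(31)[match(d$unit, W$labels)]
  d$y <- d$y + ai
  fe <- fit_spatial_panel(fml6, d, W, model = "ols",
                          effects = "individual")
  re <- fit_spatial_panel(fml6, d, W, model = "ols", effects = "random")
  h <- hausman_test(fe, re)
  expect_gte(h$statistic, 0)
  expect_true(h$p >= 0 && h$p <= 1)
  expect_equal(hausman_test(fe, fe)$statistic, 0, tolerance = 1e-10)
  h2 <- hausman_test(fe, re)                # covariate order: reuse fits
  fml_r <- y ~ x6 + x5 + x4 + x3 + x2 + x1
  fe2 <- fit_spatial_panel(fml_r, d, W, model = "ols",
                           effects = "individual")
  re2 <- fit_spatial_panel(fml_r, d, W, model = "ols",
                           effects = "random")
  expect_equal(hausman_test(fe2, re2)$statistic, h2$statistic,
               tolerance = 1e-6)
  # size under RE truth (modest replicate count; the acceptance suite
  # runs the full design)
  rej <- 0
  for (r in 1:40) {
    set.seed(8000 + r)
    d <- iid_panel(W)
    d$y <- d$y + rnorm(31)[match(d$unit, W$labels)]
    feh <- fit_spatial_panel(fml6, d, W, model = "ols",
                             effects = "individual")
    reh <- fit_spatial_panel(fml6, d, W, model = "ols",
                             effects = "random")
    rej <- rej + (suppressMessages(hausman_test(feh, reh))$p < 0.05)
  }
  expect_lte(rej / 40, 0.10)
})

test_that("LR and Wald degeneracy tests: zero under the restriction,
           nonnegative by nesting, correct df", {
  W <- china_adjacency()
  g <- generate_sdm_panel(sdm_spec(W, rho = 0.4, effects = "time",
                                   seed = 2))
  fsd <- fit_spatial_panel(fml6, g$data, W, model = "sdm", effects = "time")
  fse <- fit_spatial_panel(fml6, g$data, W, model = "sem", effects = "time")
  fsl <- fit_spatial_panel(fml6, g$data, W, model = "slm", effects = "time")
  lw <- lr_wald_degeneracy(fsd, fse, fsl)
  expect_true(all(lw$statistic >= 0))
  expect_true(all(lw$df == 6))
  expect_true(all(lw$p >= 0 & lw$p <= 1))
  # under a Durbin-free process the LR against the lag model is small
  g0 <- generate_sdm_panel(sdm_spec(W, rho = 0.4,
                                    theta_durbin = rep(0, 6),
                                    effects = "time", seed = 3))
  fsd0 <- fit_spatial_panel(fml6, g0$data, W, model = "sdm", effects = "time")
  fsl0 <- fit_spatial_panel(fml6, g0$data, W, model = "slm", effects = "time")
  lr0 <- 2 * (fsd0$loglik - fsl0$loglik)
  expect_gte(lr0, -1e-8)
  expect_lt(lr0, qchisq(0.99, 6))
})

test_that("effect decomposition: exact additivity, the rho = 0 identity,
           and the 3-unit closed form", {
  W <- china_adjacency()
  g <- generate_sdm_panel(sdm_spec(W, rho = 0.4, effects = "time",
                                   seed = 2))
  f <- fit_spatial_panel(fml6, g$data, W, model = "sdm", effects = "time")
  e <- decompose_effects(f, n_draws = 200, seed = 7)
  expect_equal(e$estimates[, "total"],
               e$estimates[, "direct"] + e$estimates[, "indirect"],
               tolerance = 1e-10)
  e2 <- decompose_effects(f, n_draws = 200, seed = 7)
  expect_identical(e$table$sd, e2$table$sd)   # seeded draws
  # rho = 0: direct = beta, indirect = theta exactly
  f0 <- f; f0$rho <- 0
  e0 <- decompose_effects(f0, n_draws = 0)
  expect_equal(unname(e0$estimates[, "direct"]),
               unname(f0$beta[f0$xnames]), tolerance = 1e-12)
  expect_equal(unname(e0$estimates[, "indirect"]),
               unname(f0$theta_durbin), tolerance = 1e-12)
  # 3-unit uniform W, rho = .5, beta = 1, theta = 0:
  # (I - .5 W)^{-1} = 0.8 I + 0.4 J gives direct 1.2, total 2, indirect .8
  w3 <- (matrix(1, 3, 3) - diag(3)) / 2
  fake <- f
  fake$W <- w3; fake$rho <- 0.5
  fake$xnames <- "x1"
  fake$model <- "sdm"
  fake$beta <- c(x1 = 1, W.x1 = 0)
  e3 <- decompose_effects(fake, n_draws = 0)
  expect_equal(unname(e3$estimates["x1", ]),
               c(1.2, 0.8, 2.0), tolerance = 1e-12)
})

test_that("the selection tree returns SDM with time effects on its own
           process and plain OLS without spatial structure", {
  W <- china_adjacency()
  g <- generate_sdm_panel(sdm_spec(W, rho = 0.4, effects = "time",
                                   seed = 1))
  sel <- suppressMessages(select_model(fml6, g$data, W))
  expect_equal(sel$model, "sdm")
  expect_equal(sel$effects, "time")
  expect_true(sel$diagnostics$stationary)
  # covariate scaling leaves every decision unchanged
  g2 <- g$data
  g2$x1 <- g2$x1 * 100; g2$x4 <- g2$x4 / 50
  sel2 <- suppressMessages(select_model(fml6, g2, W))
  expect_equal(sel2$model, sel$model)
  expect_equal(sel2$effects, sel$effects)
  expect_equal(sel2$fit$rho, sel$fit$rho, tolerance = 1e-6)
  # iid process: LM insignificant, OLS retained
  set.seed(25)
  d <- iid_panel(W)
  sel0 <- suppressMessages(select_model(fml6, d, W))
  expect_equal(sel0$model, "ols")
})
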
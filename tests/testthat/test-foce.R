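test_that("with omega2 = 0 the OFV is the exact pooled Gaussian -2LL", {
  set.seed(21)
  times <- list(c(24, 96, 168, 172), c(12, 60, 150))
  rate <- 0.4
  cl <- 38
  v <- 280
  conc <- purrr::map(times, function(tt)
    conc_at(tt, rate, cl, v) * (1 + rnorm(length(tt), 0, 0.2)))
  ds <- toy_dataset(conc, times, rate = rate)
  model <- pk_model(cl = cl, v = v, omega2 = 0, sigma2_normal = 0.05,
                    sigma2_outlier = 0.05)
  ofv <- as.numeric(foce_ofv(ds, model))
  # independent closed-form evaluation per observation
  expected <- 0
  for (i in 1:2) {
    f <- conc_at(times[[i]], rate, cl, v)
    vj <- 0.05 * f^2
    expected <- expected +
      sum(log(2 * pi * vj) + (conc[[i]] - f)^2 / vj)
  }
  expect_equal(ofv, expected, tolerance = 1e-10)
})

test_that("Laplace OFV matches adaptive Gauss-Hermite quadrature on toys", {
  gaps <- purrr::map_dbl(1:8, function(s) {
    inst <- random_toy_instance(s)
    abs(as.numeric(foce_ofv(inst$dataset, inst$model)) -
          marginal_ofv_gh(inst$dataset, inst$model))
  })
  expect_true(all(gaps <= 0.5))
  # the approximation tightens as omega2 shrinks
  inst <- random_toy_instance(3)
  inst$model$omega2 <- 1e-4
  gap_small <- abs(as.numeric(foce_ofv(inst$dataset, inst$model)) -
                     marginal_ofv_gh(inst$dataset, inst$model))
  expect_lt(gap_small, 0.01)
})

test_that("a covariate term fixed at its null value leaves the OFV unchanged", {
  vs <- simulate_study(small_config(outlier_frac = 0), seed = 5)
  ds <- flag_outliers(vs$dataset)
  base <- pk_model(cl = 42, v = 320, omega2 = 0.04, sigma2_normal = 0.09)
  with_null_power <- base
  with_null_power$covariates <- list(cov_term("clcr", "power",
                                              reference = 79.22, value = 0))
  with_null_ratio <- base
  with_null_ratio$covariates <- list(cov_term("study", "ratio", level = "MM",
                                              value = 1))
  o0 <- as.numeric(foce_ofv(ds, base))
  expect_equal(as.numeric(foce_ofv(ds, with_null_power)), o0)
  expect_equal(as.numeric(foce_ofv(ds, with_null_ratio)), o0)
})

test_that("post-hoc eta is zero when data equal the population prediction", {
  # with interaction the conditional mode carries an O(sigma2) offset even
  # for perfect data, so the check is made in the small-noise regime
  times <- list(c(24, 96, 168))
  model <- pk_model(cl = 42.1, v = 319, omega2 = 0.1, sigma2_normal = 1e-8)
  conc <- list(conc_at(times[[1]], 0.4, 42.1, 319))
  ds <- toy_dataset(conc, times)
  et <- posthoc_etas(ds, model)
  expect_lt(abs(et$eta_cl), 1e-6)
  expect_equal(et$individual_cl, 42.1, tolerance = 1e-5)
})

test_that("doubled plateau concentrations give eta near -log(2)", {
  times <- list(c(120, 144, 168))
  plateau <- 0.4 / 42.1 * 1000
  ds <- toy_dataset(list(rep(2 * plateau, 3)), times)
  model <- pk_model(cl = 42.1, v = 319, omega2 = 50, sigma2_normal = 1e-6)
  et <- posthoc_etas(ds, model)
  expect_equal(et$eta_cl, -log(2), tolerance = 1e-3)
})

test_that("patients without usable observations get eta 0 and a flag", {
  times <- list(c(24, 96, 168), c(24, 96))
  conc <- list(conc_at(times[[1]], 0.4, 40, 300), c(0.01, 0.02)) # all BLQ
  ds <- toy_dataset(conc, times)
  et <- posthoc_etas(ds, pk_model(cl = 40, v = 300))
  expect_equal(et$eta_cl[et$patient_id == "t02"], 0)
  expect_true(et$no_data[et$patient_id == "t02"])
})

test_that("etas from a full synthetic study are centred at zero", {
  vs <- simulate_study(sim_config(outlier_frac = 0), seed = 13)
  ds <- flag_outliers(vs$dataset)
  fit <- fit_pk_model(ds, sepantronium_final_model(), compute_se = FALSE)
  e <- fit$etas$eta_cl
  expect_lt(abs(mean(e)), 3 * sd(e) / sqrt(length(e)))
})

test_that("noise-free data with no IIV are recovered within 2%", {
  truth <- sepantronium_final_model()
  truth$omega2 <- 0
  truth$sigma2_normal <- 1e-4   # CV 1%
  vs <- simulate_study(small_config(n = c(NSCLC = 10, HRPC = 10, MM = 10),
                                    model = truth, outlier_frac = 0),
                       seed = 3)
  ds <- flag_outliers(vs$dataset)
  start <- pk_model(cl = 30, v = 200, omega2 = 0.05, sigma2_normal = 0.05,
                    covariates = truth$covariates)
  fit <- fit_pk_model(ds, start, compute_se = FALSE)
  expect_equal(fit$model$cl, 42.1, tolerance = 0.02)
  expect_equal(fit$model$v, 319, tolerance = 0.02)
})

test_that("perturbed starting values reach the same optimum", {
  vs <- simulate_study(small_config(n = c(NSCLC = 6, HRPC = 6, MM = 6),
                                    outlier_frac = 0), seed = 17)
  ds <- flag_outliers(vs$dataset)
  base <- pk_model(cl = 42, v = 320, omega2 = 0.04, sigma2_normal = 0.09)
  f1 <- fit_pk_model(ds, base, compute_se = FALSE)
  up <- pk_model(cl = 84, v = 640, omega2 = 0.08, sigma2_normal = 0.18)
  dn <- pk_model(cl = 21, v = 160, omega2 = 0.02, sigma2_normal = 0.045)
  f2 <- fit_pk_model(ds, up, compute_se = FALSE)
  f3 <- fit_pk_model(ds, dn, compute_se = FALSE)
  expect_equal(f2$ofv, f1$ofv, tolerance = 1e-5)
  expect_equal(f3$ofv, f1$ofv, tolerance = 1e-5)
  expect_equal(f2$model$cl, f1$model$cl, tolerance = 1e-3)
})

test_that("OFV is invariant to patient order and to the time unit", {
  vs <- simulate_study(small_config(), seed = 23)
  ds <- flag_outliers(vs$dataset)
  model <- sepantronium_final_model()
  o1 <- as.numeric(foce_ofv(ds, model))

  perm <- ds
  set.seed(1)
  perm$patients <- perm$patients[sample(nrow(perm$patients)), ]
  expect_equal(as.numeric(foce_ofv(perm, model)), o1, tolerance = 1e-8)

  # express time in days with rates in mg/day: CL and V rescale consistently
  days <- ds
  days$observations$time <- days$observations$time / 24
  days$doses <- dplyr::mutate(days$doses, start = start / 24,
                              duration = duration / 24, rate = rate * 24)
  model_days <- model
  model_days$cl <- model$cl * 24
  o2 <- as.numeric(foce_ofv(days, model_days))
  expect_equal(o2, o1, tolerance = 1e-6)
})

test_that("a nested model never fits better than the model containing it", {
  vs <- simulate_study(small_config(n = c(NSCLC = 10, HRPC = 10, MM = 10),
                                    outlier_frac = 0), seed = 29)
  ds <- flag_outliers(vs$dataset)
  base <- fit_pk_model(ds, pk_model(), compute_se = FALSE)
  bigger <- base$model
  bigger$covariates <- list(cov_term("clcr", "power", reference = 79.22))
  full <- fit_pk_model(ds, bigger, compute_se = FALSE)
  expect_lte(full$ofv, base$ofv + 1e-3)
})

test_that("clearance and omega2 are consistently estimated across replicates", {
  ests <- purrr::map(1:10, function(s) {
    vs <- simulate_study(sim_config(outlier_frac = 0), seed = 100 + s)
    ds <- flag_outliers(vs$dataset)
    f <- fit_pk_model(ds, sepantronium_final_model(), compute_se = FALSE)
    c(cl = f$model$cl, omega2 = f$model$omega2)
  })
  m <- colMeans(do.call(rbind, ests))
  expect_equal(unname(m["cl"]), 42.1, tolerance = 0.05)
  expect_equal(unname(m["omega2"]), 0.0385, tolerance = 0.20)
})

test_that("weighted residuals are calibrated under the true model", {
  vs <- simulate_study(sim_config(outlier_frac = 0), seed = 41)
  ds <- flag_outliers(vs$dataset)
  fit <- fit_pk_model(ds, sepantronium_final_model(), compute_se = FALSE)
  w <- fit$gof$wres
  expect_lt(abs(mean(w)), 0.1)
  expect_gt(mean(w > -2 & w < 2), 0.88)
  expect_equal(nrow(fit$gof), fit$n_obs)
  expect_true(all(fit$gof$pred >= 0 & fit$gof$ipred >= 0))
})

test_that("a grossly wrong volume leaves a systematic WRES-time trend", {
  vs <- simulate_study(sim_config(outlier_frac = 0), seed = 43)
  ds <- flag_outliers(vs$dataset)
  good <- fit_pk_model(ds, sepantronium_final_model(), compute_se = FALSE)
  bad_model <- good$model
  bad_model$v <- good$model$v * 10
  bad <- good
  bad$model <- bad_model
  bad$etas <- posthoc_etas(ds, bad_model)
  g <- gof_table(bad, ds)
  post <- g[g$time > 168, ]   # single-cycle design: post-infusion samples
  # post-infusion residuals under a 10x volume are systematically signed
  expect_gt(abs(mean(sign(post$wres))), 0.5)
})

test_that("noise-free observations at eta = 0 give vanishing residuals", {
  times <- list(c(24, 96, 168, 170))
  conc <- list(conc_at(times[[1]], 0.4, 42.1, 319))
  ds <- toy_dataset(conc, times)
  model <- pk_model(cl = 42.1, v = 319, omega2 = 0.04,
                    sigma2_normal = 0.01)
  fake_fit <- structure(list(model = model, etas = posthoc_etas(ds, model)),
                        class = "pk_fit")
  g <- gof_table(fake_fit, ds)
  expect_true(all(abs(g$wres) < 1e-6))
  expect_equal(g$pred, conc[[1]], tolerance = 1e-9)
})
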
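# Dose-response and inhibition-kinetics fitting.

dr_concs <- 10^seq(log10(0.01), log10(500), length.out = 8)
uncomp_design <- expand.grid(substrate_uM = c(10, 25, 50, 100, 200),
                             inhibitor_uM = c(0, 0.5, 1, 2))

test_that("noiseless dose-response data recover the generating parameters", {
  d <- simulate_dose_response(dr_concs, top = 100, bottom = 0, ic50 = 1.1)
  fit <- fit_dose_response(d)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["ic50"]], 1.1, tolerance = 1e-6)
  expect_equal(fit$estimates[["top"]], 100, tolerance = 1e-6)
  expect_equal(fit$estimates[["bottom"]], 0, tolerance = 1e-4)
  expect_equal(fit$estimates[["hill"]], 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # the response at conc = IC50 is exactly halfway between the plateaus
  expect_equal(predict(fit, data.frame(conc_uM = fit$estimates[["ic50"]])),
               (fit$estimates[["top"]] + fit$estimates[["bottom"]]) / 2)

  # hill fixed at 1 gives the same fit here since the truth has hill 1
  fit1 <- fit_dose_response(d, hill_mode = "fixed_1")
  expect_equal(fit1$estimates[["ic50"]], 1.1, tolerance = 1e-6)
})

test_that("dose-response fit is equivariant under concentration rescaling", {
  d <- simulate_dose_response(dr_concs, top = 90, bottom = 5, ic50 = 2.4,
                              hill = 1.3)
  f1 <- fit_dose_response(d)
  d10 <- transform(d, conc_uM = conc_uM * 10)
  f10 <- fit_dose_response(d10)
  expect_equal(f10$estimates[["log10_ic50"]], f1$estimates[["log10_ic50"]] + 1,
               tolerance = 1e-6)
  # fitted curve is monotone between the plateaus
  grid <- data.frame(conc_uM = 10^seq(-3, 3, length.out = 200))
  expect_false(is.unsorted(predict(f1, grid)))
})

test_that("degenerate dose-response inputs are rejected", {
  expect_error(fit_dose_response(data.frame(conc_uM = c(1, 2, 5), response = 1:3)),
               "5 distinct")
  expect_error(fit_dose_response(data.frame(conc_uM = c(1, 2, 3, 4, 5),
                                            response = 1:5)), "2 log units")
  expect_error(fit_dose_response(data.frame(conc_uM = dr_concs,
                                            response = 7)), "equal")
})

test_that("noiseless uncompetitive data recover the generating parameters", {
  d <- simulate_kinetics(vmax = 100, km = 50, alpha_ki = 0.69,
                         design = uncomp_design)
  fit <- fit_uncompetitive(d)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["vmax"]], 100, tolerance = 1e-6)
  expect_equal(fit$estimates[["km"]], 50, tolerance = 1e-6)
  expect_equal(fit$estimates[["alpha_ki"]], 0.69, tolerance = 1e-6)

  # closed form: I = 0, S = Km -> v = Vmax / 2
  expect_equal(predict(fit, data.frame(substrate_uM = fit$estimates[["km"]],
                                       inhibitor_uM = 0)),
               fit$estimates[["vmax"]] / 2, tolerance = 1e-6)

  # fitted curves for increasing inhibitor are pointwise non-increasing
  for (S in c(5, 50, 500)) {
    v <- predict(fit, data.frame(substrate_uM = S, inhibitor_uM = c(0, 0.5, 1, 2, 4)))
    expect_false(is.unsorted(rev(v)))
  }
})

test_that("mixed-model fit recovers its own truth and nests the uncompetitive fit", {
  d <- simulate_kinetics(vmax = 80, km = 40, alpha_ki = 1.2, ki = 3,
                         design = uncomp_design)
  fit <- fit_mixed_inhibition(d)
  expect_equal(fit$estimates[["vmax"]], 80, tolerance = 1e-4)
  expect_equal(fit$estimates[["km"]], 40, tolerance = 1e-4)
  expect_equal(fit$estimates[["ki"]], 3, tolerance = 1e-3)
  expect_equal(fit$estimates[["alpha_ki"]], 1.2, tolerance = 1e-3)

  # on uncompetitive truth the mixed fit cannot beat uncompetitive by much
  du <- simulate_kinetics(vmax = 100, km = 50, alpha_ki = 0.69,
                          design = uncomp_design, noise_sd = 2, seed = 77)
  expect_lte(fit_mixed_inhibition(du)$rss, fit_uncompetitive(du)$rss + 1e-6)
})

test_that("kinetics data-contract violations are flagged", {
  d <- simulate_kinetics(100, 50, 0.69, uncomp_design)
  expect_error(fit_uncompetitive(d[d$substrate_uM == 10, ]), "4 distinct")
  expect_error(fit_uncompetitive(d[d$inhibitor_uM == 0, ]), "2 inhibitor")
  expect_warning(fit_uncompetitive(d[d$inhibitor_uM > 0, ]), "weakly identified")
  expect_error(simulate_kinetics(100, 50, 0.69, uncomp_design, noise_sd = -1),
               "noise_sd")
})

test_that("simulators are deterministic per seed and calibrated in noise", {
  a <- simulate_kinetics(100, 50, 0.69, uncomp_design, noise_sd = 3, seed = 5)
  b <- simulate_kinetics(100, 50, 0.69, uncomp_design, noise_sd = 3, seed = 5)
  expect_identical(a, b)
  c0 <- simulate_kinetics(100, 50, 0.69, uncomp_design, noise_sd = 0)
  expect_equal(c0$rate_rfu_min,
               100 * c0$substrate_uM /
                 (50 + c0$substrate_uM * (1 + c0$inhibitor_uM / 0.69)))

  des <- data.frame(substrate_uM = rep(100, 1000), inhibitor_uM = 0)
  noisy <- simulate_kinetics(100, 50, 0.69, des, noise_sd = 3, seed = 6)
  expect_equal(sd(noisy$rate_rfu_min), 3, tolerance = 0.15)
})

test_that("parameter recovery bias vanishes on a noise ladder", {
  err_at <- function(noise_sd, n_rep = 30) {
    errs <- vapply(seq_len(n_rep), function(r) {
      d <- simulate_dose_response(dr_concs, 100, 0, 1.1, 1,
                                  noise_sd = noise_sd, seed = 1000 + r)
      abs(fit_dose_response(d)$estimates[["ic50"]] - 1.1) / 1.1
    }, numeric(1))
    median(errs)
  }
  ladder <- vapply(c(5, 1, 0.1), err_at, numeric(1))
  expect_false(is.unsorted(rev(ladder)))
  expect_lt(ladder[3], 0.01)
})
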
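hill_curve <- function(conc, ec50, h, lo = 0, hi = 1)
  lo + (hi - lo) / (1 + 10^((log10(ec50) - log10(conc)) * h))

test_that("Hill fit recovers noiseless parameters and the midpoint identity", {
  conc <- c(0, 10, 30, 100, 300, 1000, 10000)
  y <- hill_curve(conc, 100, 2, 0.1, 1)
  f <- fit_hill(conc, y)
  expect_equal(f$ec50, 100, tolerance = 1e-5)
  expect_equal(f$h, 2, tolerance = 1e-5)
  expect_equal(f$floor, 0.1, tolerance = 1e-5)
  expect_equal(f$ceiling, 1, tolerance = 1e-5)
  # response at conc = EC50 is the midpoint
  expect_equal(hill_curve(f$ec50, f$ec50, f$h, f$floor, f$ceiling),
               (f$floor + f$ceiling) / 2)
  # one-site truth fitted with free h returns h ~ 1
  y1 <- hill_curve(conc, 150, 1, 0.2, 0.8)
  expect_equal(fit_hill(conc, y1)$h, 1, tolerance = 1e-4)
})

test_that("Hill fit is scale invariant with free bounds and matches the
           rectangular hyperbola when h is fixed at 1", {
  conc <- c(3, 10, 30, 100, 300, 1000)
  y <- hill_curve(conc, 50, 1.5, 0, 1)
  f1 <- fit_hill(conc, y)
  f9 <- fit_hill(conc, 9 * y)
  expect_equal(f9$ec50, f1$ec50, tolerance = 1e-5)
  expect_equal(f9$h, f1$h, tolerance = 1e-5)
  # h = 1 Hill curve in log space equals conc/(conc + ec50)
  yh <- hill_curve(conc, 80, 1)
  expect_equal(yh, conc / (conc + 80))
  fh <- fit_hill(conc, yh, fix_h_to_one = TRUE)
  expect_equal(fh$ec50, 80, tolerance = 1e-6)
  # constant series: unidentifiable flag, no crash
  fc <- fit_hill(conc, rep(0.7, 6))
  expect_true(fc$unidentifiable)
})

test_that("low-affinity exclusion masks only decayed post-maximum points", {
  conc <- c(1, 3, 10, 30, 100, 300, 1000)
  mono <- sigma_series(conc, hill_curve(conc, 20, 1.5, 0.05, 1))
  expect_true(all(exclude_low_affinity_phase(mono)$included))
  # rise then 30% decay: post-max decayed points masked, maximum kept
  s <- c(0.1, 0.4, 0.8, 1.0, 0.9, 0.8, 0.7)
  ser <- sigma_series(conc, s)
  ex <- exclude_low_affinity_phase(ser)
  expect_identical(ex$included, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                  FALSE))
  # idempotent
  expect_identical(exclude_low_affinity_phase(ex)$included, ex$included)
  # points within tolerance of the maximum survive
  s2 <- c(0.1, 0.4, 0.8, 1.0, 0.97, 0.7, 0.6)
  ex2 <- exclude_low_affinity_phase(sigma_series(conc, s2))
  expect_identical(ex2$included[5], TRUE)
  expect_identical(ex2$included[6], FALSE)
})

test_that("biphasic series is fit on its high-affinity phase", {
  cfg <- generator_config("PQ", conc_nM = 10^seq(0.5, 6.5, 0.25),
                          noise = list(current_sd = 0), seed = 3)
  dr <- generate_dose_response_family(cfg)
  tr <- attr(dr, "truth")
  expect_true(tr$biphasic)
  # interior maximum present
  expect_lt(which.max(dr$sigma_beta), nrow(dr))
  ser <- sigma_series(dr$conc_nM, dr$sigma_beta, ligand = "Ca")
  f <- fit_sigma_series(ser, fix_h_to_one = TRUE)
  expect_equal(f$ec50, tr$ec50_beta, tolerance = 0.1)
  # unmasked fit is worse
  f_raw <- fit_sigma_series(ser, fix_h_to_one = TRUE, exclude = FALSE)
  expect_gt(abs(f_raw$ec50 / tr$ec50_beta - 1),
            abs(f$ec50 / tr$ec50_beta - 1))
})

test_that("EC50 voltage fit recovers the electrical-distance product", {
  V <- c(-40, 0, 40, 80)
  RTln10 <- .o_R * .o_T * log(10)
  ec <- 300 * 10^(-(0.5) * (V / 1000) * .o_F / RTln10)
  f <- fit_ec50_voltage(V, ec, z_ca = 2)
  expect_equal(f$zf_product, 0.5, tolerance = 1e-10)
  expect_equal(f$f_v, 0.25, tolerance = 1e-10)
  expect_equal(f$ec50_0, 300, tolerance = 1e-8)
  # residuals are exactly zero on noiseless data (pure linear algebra)
  expect_lt(max(abs(residuals(f$fit))), 1e-12)
  # EC50 falls ~4.87-fold between 0 and +80 mV for zf = 0.5
  expect_equal(ec[V == 0] / ec[V == 80], 10^0.688, tolerance = 1e-3)
  # flat EC50: fV ~ 0
  expect_equal(fit_ec50_voltage(V, rep(200, 4))$f_v, 0, tolerance = 1e-12)
  expect_error(fit_ec50_voltage(c(0, 80), c(100, 50)), ">= 3")
})

test_that("rundown correction restores the true dose-response", {
  # geometric reference decay 100 -> 90 -> 81; test truly at 50% of local max
  tab <- data.frame(
    epoch = c(0, 1, 2, 3, 4),
    conc_nM = c(1e4, 50, 1e4, 50, 1e4),
    response = c(100, 0.5 * sqrt(100 * 90), 90, 0.5 * sqrt(90 * 81), 81),
    is_reference = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  out <- rundown_correct(tab)
  # linear interpolation of brackets approximates the geometric mean closely
  expect_equal(out$response / max(out$response), c(1, 1),
               tolerance = 1e-3)
  expect_equal(max(out$response), 1)
  # constant references: identity up to normalization
  tab2 <- data.frame(epoch = 0:4, conc_nM = c(1e4, 10, 1e4, 100, 1e4),
                     response = c(80, 20, 80, 60, 80),
                     is_reference = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  out2 <- rundown_correct(tab2)
  expect_equal(out2$response, c(20, 60) / 60)
  # unbracketed test point dropped with a warning
  tab3 <- rbind(tab2, data.frame(epoch = 5, conc_nM = 300, response = 70,
                                 is_reference = FALSE))
  expect_warning(out3 <- rundown_correct(tab3), "unbracketed")
  expect_identical(nrow(out3), 2L)
})

test_that("rundown-corrected EC50 is unbiased where the raw fit is biased", {
  # steady-state responses under cumulative rundown, saturating references
  # interleaved; epoch-ordered low -> high concentration
  set.seed(17)
  conc <- c(3, 10, 30, 100, 300, 1000)
  truth_ec50 <- 60; truth_h <- 2.1
  decay_per_train <- 0.12
  epoch <- 0; rows <- list(); rd <- 1
  for (i in seq_along(conc)) {
    rows[[length(rows) + 1]] <- data.frame(
      epoch = epoch, conc_nM = 1e5, response = rd, is_reference = TRUE)
    rd <- rd * (1 - decay_per_train); epoch <- epoch + 1
    y <- hill_curve(conc[i], truth_ec50, truth_h)
    rows[[length(rows) + 1]] <- data.frame(
      epoch = epoch, conc_nM = conc[i], response = y * rd,
      is_reference = FALSE)
    rd <- rd * (1 - decay_per_train); epoch <- epoch + 1
  }
  rows[[length(rows) + 1]] <- data.frame(epoch = epoch, conc_nM = 1e5,
                                         response = rd, is_reference = TRUE)
  tab <- do.call(rbind, rows)
  corr <- rundown_correct(tab)
  f_corr <- fit_hill(corr$conc_nM, corr$response, fix_bounds = TRUE)
  expect_equal(f_corr$ec50, truth_ec50, tolerance = 0.05)
  raw <- tab[!tab$is_reference, ]
  f_raw <- fit_hill(raw$conc_nM, raw$response / max(raw$response),
                    fix_bounds = TRUE)
  expect_gt(abs(f_raw$ec50 / truth_ec50 - 1), 0.10)
})
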
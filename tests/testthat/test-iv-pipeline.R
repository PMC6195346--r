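make_sweeps <- function(prepulse, V = seq(-100, 120, 20), I = NULL,
                        patch = "p1", epoch = 0L, conc = 100) {
  if (is.null(I)) I <- seq_along(V)
  data.frame(patch_id = patch, epoch = epoch, ligand = "Ca", conc_nM = conc,
             prepulse_mV = 80, prepulse_pA = prepulse, V_mV = V, I_pA = I)
}

test_that("pre-pulse normalization corrects multiplicative drift", {
  # equal pre-pulses: identity
  s <- make_sweeps(prepulse = rep(100, 12))
  expect_equal(normalize_prepulse(s)$I_pA, s$I_pA)
  # 10% rundown on the second half: scaled back by median/90
  s2 <- make_sweeps(prepulse = c(rep(100, 6), rep(90, 6)))
  out <- normalize_prepulse(s2)
  med <- median(s2$prepulse_pA)
  expect_equal(out$I_pA[7:12], s2$I_pA[7:12] * med / 90)
  expect_equal(out$I_pA[1:6], s2$I_pA[1:6] * med / 100)
  # zero pre-pulse flagged and excluded
  s3 <- make_sweeps(prepulse = c(0, rep(100, 11)))
  expect_warning(out3 <- normalize_prepulse(s3), "zero pre-pulse")
  expect_identical(nrow(out3), 11L)
})

test_that("rundown-distorted trains are exactly restored by pre-pulse correction", {
  # noiseless 12% per-train rundown: after correction the fitted sigma equal
  # the generator truth and A tracks each recording's median pre-pulse level
  cfg <- generator_config(conc_nM = c(30, 100, 300),
                          noise = list(current_sd = 0, leak_nS = 0),
                          seed = 7)
  g <- generate_patch(cfg, 1)
  sw <- normalize_prepulse(g$sweeps)
  recs <- sweeps_to_recordings(sw)
  test_recs <- Filter(function(r) r$conc > 0, recs)
  truth_by_epoch <- setNames(g$truth$conditions,
                             sapply(g$truth$conditions, `[[`, "epoch"))
  ratios <- sapply(test_recs, function(r) {
    f <- fit_iv(r)
    tr <- truth_by_epoch[[as.character(r$epoch)]]
    expect_equal(f$sigma_beta, tr$sigma_beta, tolerance = 1e-5)
    expect_equal(f$sigma_h, tr$sigma_h, tolerance = 1e-5)
    # amplitude scale implied by the recording's own pre-pulse level
    p_tr <- permeation_params(A = tr$A, sigma_h = tr$sigma_h,
                              sigma_beta = tr$sigma_beta)
    f$A / (r$prepulse_med / barrier_current(p_tr, r$prepulse_mV) * tr$A)
  })
  expect_lt(max(abs(ratios - 1)), 0.01)
})

test_that("reference normalization is idempotent and scale invariant", {
  p <- permeation_params(sigma_h = 0.4, sigma_beta = 0.1)
  cv <- iv_curve(p, seq(-100, 120, 20))
  rec <- iv_recording("p1", "Ca", 100, cv$V, cv$I)
  n1 <- normalize_reference(rec)
  expect_equal(n1$I[which(n1$V == 120)], 1)
  n2 <- normalize_reference(n1)
  expect_equal(n2$I, n1$I)
  rec_k <- iv_recording("p1", "Ca", 100, cv$V, 37 * cv$I)
  expect_equal(normalize_reference(rec_k)$I, n1$I)
  # symmetric-barrier curve: normalized I(-100) is the sinh RI oracle
  sym <- iv_recording("p1", "Ca", 100, cv$V,
                      barrier_current(permeation_params(), cv$V))
  nsym <- normalize_reference(sym)
  expect_equal(nsym$I[which(nsym$V == -100)],
               sinh_current(1, 150, -100) / sinh_current(1, 150, 120),
               tolerance = 1e-10)
  expect_error(normalize_reference(rec, ref_V = 110), "110")
})

test_that("background subtraction removes shared leak and enforces the grid", {
  V <- seq(-100, 120, 20)
  p <- permeation_params(A = 2, sigma_h = 0.4, sigma_beta = 0.1)
  leak <- 0.5 * V
  rec <- iv_recording("p1", "Ca", 100, V, barrier_current(p, V) + leak)
  bg <- iv_recording("p1", "none", 0, V, leak)
  out <- background_subtract(rec, bg)
  expect_equal(out$I, barrier_current(p, V))
  expect_identical(out$norm_state, "background-subtracted")
  self <- background_subtract(rec, rec)
  expect_true(all(self$I == 0))
  zero_bg <- iv_recording("p1", "none", 0, V, rep(0, length(V)))
  expect_equal(background_subtract(rec, zero_bg)$I, rec$I)
  bad <- iv_recording("p1", "none", 0, V + 10, leak)
  expect_error(background_subtract(rec, bad), "grid")
  # normalization state can only advance
  expect_error(normalize_reference(out), "cannot go back")
})

test_that("QC keeps stable patches and rejects drifting or unbracketed ones", {
  V <- seq(-100, 120, 20)
  I0 <- barrier_current(permeation_params(A = 4e-5, sigma_h = 0.2,
                                          sigma_beta = 0.05), V)
  zrec <- function(epoch, scale = 1)
    iv_recording("p1", "none", 0, V, scale * I0, epoch = epoch)
  trec <- function(epoch)
    iv_recording("p1", "Ca", 100, V, 2 * I0, epoch = epoch)
  ok <- qc_filter(list(zrec(0), trec(1), zrec(2)))
  expect_length(ok$kept, 1)
  expect_identical(ok$reasons, character(0))
  # brackets differing two-fold: deteriorated
  bad <- qc_filter(list(zrec(0), trec(1), zrec(2, scale = 2)))
  expect_length(bad$kept, 0)
  expect_true("deteriorated" %in% bad$reasons)
  # no trailing zero bracket
  unb <- qc_filter(list(zrec(0), trec(1)))
  expect_identical(unb$reasons, "unbracketed")
  # zero-ligand current at -100 beyond the leak bound
  leaky <- qc_filter(list(zrec(0, scale = 10), trec(1), zrec(2, scale = 10)))
  expect_true("leaky" %in% leaky$reasons)
})

test_that("QC separates injected leaky patches from healthy ones at defaults", {
  cfg <- generator_config(n_patches = 10, conc_nM = c(10, 100, 1000),
                          noise = list(leaky_rate = 0.3), seed = 11)
  g <- generate_cohort(cfg)
  truth_leaky <- sapply(g$truths, `[[`, "is_leaky")
  expect_true(any(truth_leaky) && !all(truth_leaky))
  sw <- normalize_prepulse(g$sweeps)
  recs <- sweeps_to_recordings(sw)
  patches <- split(recs, sapply(recs, `[[`, "patch_id"))
  rejected <- sapply(names(patches), function(pid)
    length(qc_filter(patches[[pid]])$kept) == 0)
  expect_identical(unname(rejected), unname(truth_leaky))
})

test_that("model fit recovers parameters across the sigma grid", {
  V <- seq(-100, 120, 20)
  for (sh in c(0.05, 0.2, 1, 3)) for (sb in c(0.05, 0.2, 1, 3)) {
    p <- permeation_params(A = 1, sigma_h = sh, sigma_beta = sb)
    f <- fit_iv(iv_curve(p, V))
    expect_true(f$converged)
    expect_equal(f$A, 1, tolerance = 1e-6)
    expect_equal(f$sigma_h, sh, tolerance = 1e-6)
    expect_equal(f$sigma_beta, sb, tolerance = 1e-6)
  }
})

test_that("fit amplitude is equivariant and sigma invariant under scaling", {
  V <- seq(-100, 120, 20)
  p <- permeation_params(A = 1, sigma_h = 0.5, sigma_beta = 0.1)
  cv <- iv_curve(p, V)
  f1 <- fit_iv(cv)
  cv37 <- data.frame(V = cv$V, I = 37 * cv$I)
  f37 <- fit_iv(cv37)
  expect_equal(f37$A, 37 * f1$A, tolerance = 1e-6)
  expect_equal(f37$sigma_beta, f1$sigma_beta, tolerance = 1e-6)
  expect_equal(f37$sigma_h, f1$sigma_h, tolerance = 1e-6)
  # reference-normalized curve: same sigma, A = 1/|I_model(+120)|
  rec <- normalize_reference(iv_recording("p", "Ca", 1, cv$V, cv$I))
  fn <- fit_iv(data.frame(V = rec$V, I = rec$I))
  expect_equal(fn$sigma_beta, f1$sigma_beta, tolerance = 1e-6)
  expect_equal(fn$A, 1 / abs(barrier_current(p, 120)), tolerance = 1e-6)
  expect_error(fit_iv(cv[cv$V > 0, ]), "both signs")
})

test_that("noisy fits are unbiased and their CIs bracket the truth", {
  set.seed(301)
  V <- seq(-100, 120, 20)
  p <- permeation_params(A = 4e-5, sigma_h = 0.45, sigma_beta = 0.3)
  I0 <- barrier_current(p, V)
  iscale <- abs(barrier_current(permeation_params(A = 4e-5), 120))
  est <- replicate(60, {
    f <- fit_iv(data.frame(V = V, I = I0 + rnorm(length(V), 0, 0.02 * iscale)))
    c(f$sigma_beta, f$conf.int["sigma_beta", ])
  })
  expect_lt(abs(median(est[1, ]) / 0.3 - 1), 0.05)
  covered <- mean(est[2, ] <= 0.3 & 0.3 <= est[3, ])
  expect_gt(covered, 0.85)
})

test_that("patch aggregation returns closed-form means and s.e.m.", {
  V <- c(-100, 0, 120)
  r1 <- iv_recording("a", "Ca", 1, V, c(1, 1, 1))
  r3 <- iv_recording("b", "Ca", 1, V, c(3, 3, 3))
  agg <- aggregate_patches(list(r1, r3))
  expect_equal(agg$mean, c(2, 2, 2))
  expect_equal(agg$sem, c(1, 1, 1))
  same <- aggregate_patches(list(r1, r1, r1))
  expect_equal(same$sem, c(0, 0, 0))
  expect_warning(single <- aggregate_patches(list(r1)), "single patch")
  expect_true(all(is.na(single$sem)))
  # s.e.m. shrinks as 1/sqrt(N)
  set.seed(5)
  mk <- function(n) lapply(seq_len(n), function(i)
    iv_recording(paste0("p", i), "Ca", 1, V, rnorm(3)))
  s4 <- mean(aggregate_patches(mk(40))$sem)
  s16 <- mean(aggregate_patches(mk(160))$sem)
  expect_equal(s16 / s4, 0.5, tolerance = 0.35)
})
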
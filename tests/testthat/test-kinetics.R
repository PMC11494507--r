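test_that("single-exponential fit recovers noise-free curves exactly", {
  tc <- gen_time_course(seq(1, 400, length.out = 12), 0.01, 0.01, 1,
                        plateau = 0.9)
  f <- fit_single_exponential(tc)
  expect_true(f$converged)
  expect_equal(f$k_fast, 0.01, tolerance = 1e-6)
  expect_equal(f$plateau, 0.9, tolerance = 1e-6)
  # the slow C10(n1c)-like regime: 6 days of time points at 4e-5 /min
  tc2 <- gen_time_course(seq(0, 8640, length.out = 15)[-1], 4e-5, 4e-5, 1,
                         plateau = 0.9)
  f2 <- fit_single_exponential(tc2)
  expect_equal(f2$k_fast, 4e-5, tolerance = 1e-6)
  # fixing the plateau gives the same answer on clean data
  f3 <- fit_single_exponential(tc2, plateau_fixed = 0.9)
  expect_equal(f3$k_fast, 4e-5, tolerance = 1e-8)
})

test_that("degenerate constant-zero data never crash the fitter", {
  tc <- tibble::tibble(time_min = 1:10, fraction = rep(0, 10))
  f <- fit_single_exponential(tc)
  expect_s3_class(f, "kinetic_fit")
  # flagged non-convergence, or an estimate whose s.e. spans zero
  if (f$converged) expect_true(!is.finite(f$se_k_fast) ||
                                 f$se_k_fast >= f$k_fast ||
                                 f$k_fast < 1e-6 || f$plateau < 1e-6)
})

test_that("double-exponential fit recovers the biphasic truth exactly", {
  tc <- gen_time_course(biphasic_schedule()[-1], 0.60, 0.01, 0.8)
  f <- suppressWarnings(fit_double_exponential(tc))
  expect_true(f$converged)
  expect_equal(f$k_fast, 0.60, tolerance = 1e-4)
  expect_equal(f$k_slow, 0.01, tolerance = 1e-4)
  expect_equal(f$frac_fast, 0.8, tolerance = 1e-4)
  expect_true(f$k_fast >= f$k_slow)
  expect_error(fit_double_exponential(tc[1:4, ]), "at least 5")
})

test_that("double-exponential nests the single when the slow amplitude is zero", {
  tc <- gen_time_course(seq(0.5, 20, length.out = 15), 0.45, 0.002, 1)
  fs <- fit_single_exponential(tc)
  fd <- suppressWarnings(fit_double_exponential(tc))
  expect_equal(fd$k_fast, fs$k_fast, tolerance = 1e-6)
  # nesting: the double fit never has a larger residual RMS
  set.seed(5)
  for (i in 1:3) {
    tcn <- gen_time_course(biphasic_schedule(), 0.3, 0.01, 0.7,
                           noise_sd = 0.02, seed = 100 + i)
    rs <- fit_single_exponential(tcn)$residual_rms
    rd <- suppressWarnings(fit_double_exponential(tcn))$residual_rms
    expect_lte(rd, rs + 1e-8)
  }
})

test_that("Monte-Carlo recovery of the fast phase is unbiased at gel noise", {
  ks <- vapply(1:30, function(sd) {
    tc <- gen_time_course(biphasic_schedule(), 0.60, 0.01, 0.8,
                          noise_sd = 0.02, seed = sd)
    suppressWarnings(fit_double_exponential(tc))$k_fast
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.60) / 0.60, 0.02)
  expect_lt(sd(ks), 0.06)
})

test_that("model selection applies the slow-reaction heuristic", {
  # fast biphasic curve: double selected
  tc_fast <- gen_time_course(biphasic_schedule(), 0.60, 0.01, 0.8,
                             noise_sd = 0.01, seed = 1)
  sel_fast <- select_kinetic_model(tc_fast)
  expect_identical(sel_fast$model, "double")
  # slow monophasic curve: single selected
  tc_slow <- gen_time_course(seq(0, 8640, length.out = 15)[-1], 5e-5, 5e-5,
                             1, plateau = 0.9, noise_sd = 0.01, seed = 2)
  sel_slow <- select_kinetic_model(tc_slow)
  expect_identical(sel_slow$model, "single")
  # borderline: a rate exactly at the threshold goes to single
  tc_border <- gen_time_course(seq(1, 600, length.out = 20), 0.01, 0.01, 1)
  sel_border <- select_kinetic_model(tc_border)
  expect_identical(sel_border$model, "single")
  expect_match(attr(sel_border, "rule"), "chose single")
})

test_that("replicate summaries follow the three-experiment reporting rule", {
  expect_equal(summarize_replicates(c(0.59, 0.60, 0.61)),
               tibble::tibble(mean_k = 0.60, sd_k = 0.01, n = 3L))
  s2 <- summarize_replicates(c(5.1, 4.7, 5.5))
  expect_equal(s2$mean_k, 5.1, tolerance = 1e-12)
  expect_equal(s2$sd_k, 0.4, tolerance = 1e-12)
  expect_identical(summarize_replicates(c(2, 2, 2))$sd_k, 0)
  expect_error(summarize_replicates(c(1, 2)), "three independent")
})

test_that("tidiers expose fit parameters broom-style", {
  tc <- gen_time_course(biphasic_schedule()[-1], 0.60, 0.01, 0.8)
  f <- suppressWarnings(fit_double_exponential(tc))
  td <- tidy(f)
  expect_identical(td$term, c("k_fast", "k_slow", "frac_fast", "plateau"))
  expect_equal(td$estimate[1], 0.60, tolerance = 1e-4)
  g <- glance(f)
  expect_identical(g$model, "double")
  expect_true(g$converged)
})
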
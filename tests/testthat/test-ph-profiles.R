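test_that("single-pKa model follows Henderson-Hasselbalch limits", {
  expect_equal(model_single_pka(6.4, 1, 6.4), 0.5)
  expect_equal(model_single_pka(3.4, 1, 6.4), 1, tolerance = 1e-3)
  # curve passing through the measured unmodified rate at pH 6.0:
  # k_int back-solved from 0.60 /min and pKa 6.4
  k_int <- 0.6 * (1 + 10^(6.0 - 6.4))
  expect_equal(model_single_pka(6.0, k_int, 6.4), 0.60, tolerance = 1e-12)
  # monotone non-increasing in pH
  ph <- seq(3, 11, by = 0.1)
  expect_true(all(diff(model_single_pka(ph, 1, 6.4)) <= 0))
})

test_that("double-pKa model nests the single model and is unimodal", {
  ph <- seq(2, 12, by = 0.01)
  expect_equal(model_double_pka(ph, 1, 6.4, -20),
               model_single_pka(ph, 1, 6.4), tolerance = 1e-8)
  # at pH = pka_nuc the rate is half the single-pKa value
  expect_equal(model_double_pka(3.5, 1, 6.4, 3.5),
               model_single_pka(3.5, 1, 6.4) / 2, tolerance = 1e-12)
  # symmetric factors peak midway between the two pKas (dense-grid oracle)
  k <- model_double_pka(ph, 1, 7.5, 4.5)
  expect_equal(ph[which.max(k)], (7.5 + 4.5) / 2, tolerance = 0.02)
  # unimodal: one sign change of the derivative
  expect_equal(sum(diff(sign(diff(k))) != 0), 1)
  expect_warning(model_double_pka(6, 1, 4, 6), "pka_nuc")
})

test_that("pH-profile fitting recovers apparent pKa from clean data", {
  grid <- seq(5.5, 8.5, by = 0.5)
  for (pka in c(6.4, 6.5)) {
    ds <- gen_ph_rate_data(0.84, pka, ph_grid = grid, cv = 0, n_reps = 1)
    fit <- fit_ph_profile(ds, "single_pka")
    expect_true(fit$identifiable)
    expect_equal(fit$pka_acid, pka, tolerance = 1e-4)
    expect_equal(fit$k_int, 0.84, tolerance = 1e-4)
  }
  # double-pKa fit on bell-shaped data
  ds2 <- gen_ph_rate_data(1.2, 7.2, pka_nuc = 4.8,
                          ph_grid = seq(3, 10, by = 0.5), cv = 0, n_reps = 1)
  fit2 <- fit_ph_profile(ds2, "double_pka")
  expect_equal(fit2$pka_acid, 7.2, tolerance = 1e-3)
  expect_equal(fit2$pka_nuc, 4.8, tolerance = 1e-3)
  expect_error(fit_ph_profile(ds[ds$pH < 7, ], "single_pka"), "distinct pH")
})

test_that("flat pH-independent data are flagged unidentifiable", {
  grid <- seq(5.5, 8.5, by = 0.5)
  flat <- gen_ph_rate_data(4.4e-5, 20, ph_grid = grid, cv = 0.1,
                           n_reps = 3, seed = 3)
  fit <- fit_ph_profile(flat, "single_pka")
  expect_false(fit$identifiable)
  expect_true(!is.finite(fit$se_pka_acid) || fit$se_pka_acid > 2)
  expect_identical(fit$note, "no pH dependence")
  # exactly constant rates: degenerate fit, not an error
  const <- tibble::tibble(pH = grid, k_obs = rep(0.5, length(grid)))
  fitc <- fit_ph_profile(const, "single_pka")
  expect_false(fitc$identifiable)
})

test_that("fitting its own generated data recovers parameters within 3 s.e.", {
  grid <- seq(5.5, 8.5, by = 0.5)
  k_int <- 0.6 * (1 + 10^(6.0 - 6.4))
  hits <- vapply(1:30, function(sd) {
    ds <- gen_ph_rate_data(k_int, 6.4, ph_grid = grid, cv = 0.1,
                           n_reps = 3, seed = sd)
    fit <- fit_ph_profile(ds, "single_pka")
    abs(fit$pka_acid - 6.4) <= 3 * fit$se_pka_acid
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("relative-rate table reproduces the printed measured-rate ratios", {
  refs <- mtr1_reference_values()$rates
  tab <- relative_rate_table(dplyr::rename(refs, k = "k_mean"))
  expect_equal(tab$rel_rate_display, refs$rel_rate_printed)
  # reference over itself is one
  expect_identical(
    tab$rel_rate[tab$variant == "unmodified" & tab$pH == 6.0], 1)
  # invariance to rate units
  tab2 <- relative_rate_table(
    dplyr::mutate(dplyr::rename(refs, k = "k_mean"), k = k * 60))
  expect_equal(tab2$rel_rate, tab$rel_rate, tolerance = 1e-12)
  expect_error(
    relative_rate_table(data.frame(variant = "x", pH = 7, k = 1)),
    "missing")
})

test_that("mechanism model enforces the pKa sum and feeds computed profiles", {
  th <- mtr1_reference_values()$thermo
  for (i in seq_len(nrow(th))) {
    mm <- mechanism_model(th$variant[i], th$dG_barrier[i], th$pka_soln[i],
                          th$dpka_shift[i])
    expect_equal(mm$pka_ribozyme, th$pka_ribozyme[i])
  }
  mm <- mechanism_model("unmodified", 16.3, 4.2, 2.1)
  curve <- build_computed_profile(mm, ph_grid = seq(4, 9, by = 0.001))
  # half-maximal pH equals the ribozyme pKa exactly under the model
  half <- max(curve$k_model) / 2
  expect_equal(curve$pH[which.min(abs(curve$k_model - half))], 6.3,
               tolerance = 1e-3)
  # equal ribozyme pKa and equal barriers give identical curves
  mm2 <- mechanism_model("copy", 16.3, 3.2, 3.1)
  expect_equal(build_computed_profile(mm2)$k_model,
               build_computed_profile(mm)$k_model, tolerance = 1e-12)
})

test_that("computed profiles are internally consistent with TST ratios", {
  ctx <- thermo_ctx()
  mm_a <- mechanism_model("unmodified", 16.3, 4.2, 2.1)
  mm_b <- mechanism_model("C10_n1c_c5n", 15.7, 3.7, 2.9)
  low_ph <- tibble::tibble(pH = 3)
  ka <- build_computed_profile(mm_a, ctx, ph_grid = 3)$k_model
  kb <- build_computed_profile(mm_b, ctx, ph_grid = 3)$k_model
  # at low pH both acids are fully protonated: the curve ratio is the TST
  # relative intrinsic rate
  expect_equal(kb / ka, relative_rate_from_barriers(16.3, 15.7, ctx),
               tolerance = 1e-3)
})

test_that("profile normalization aligns maxima and reuses the reference scalar", {
  mm <- mechanism_model("unmodified", 16.3, 4.2, 2.1)
  comp <- build_computed_profile(mm)
  same <- normalize_profiles(comp, comp)
  expect_equal(attr(same, "scalar"), 1)
  double <- dplyr::mutate(comp, k_model = 2 * k_model)
  halved <- normalize_profiles(double, comp)
  expect_equal(attr(halved, "scalar"), 0.5)
  expect_equal(halved$k_model, comp$k_model, tolerance = 1e-12)
  # a second variant's curve is scaled by the reference-derived scalar,
  # not its own
  mm2 <- mechanism_model("C10_n1c_c5n", 15.7, 3.7, 2.9)
  comp2 <- build_computed_profile(mm2)
  scaled2 <- normalize_profiles(comp2, scalar = attr(halved, "scalar"))
  expect_equal(scaled2$k_model, comp2$k_model * 0.5, tolerance = 1e-12)
  expect_error(normalize_profiles(dplyr::mutate(comp, k_model = 0), comp),
               "zero")
})
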
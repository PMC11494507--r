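# End-to-end orchestration: synthesize -> sample -> estimate -> fit ->
# report, with deterministic per-stage seeds derived from one global seed.

#' Published measured and calculated reference values
#'
#' Loads the bundled tables of measured rate constants per (variant, pH)
#' and of calculated barriers, relative intrinsic rates and pKa quantities
#' for the unmodified ribozyme and its three atomic variants. These printed
#' values are inputs to [reproduce_published_tables()] and to the pipeline's
#' default generating parameters.
#'
#' @return List of two tibbles: `rates` (variant, pH, k_mean, k_sd,
#'   rel_rate_printed) and `thermo` (variant, dG_barrier, k_int_rel_calc,
#'   k_int_rel_expt, pka_soln, dpka_shift, pka_ribozyme, pka_apparent).
#' @export
mtr1_reference_values <- function() {
  dir <- system.file("extdata", "published_values", package = "mtrkit",
                     mustWork = TRUE)
  list(
    rates = readr::read_csv(file.path(dir, "rates.csv"),
                            show_col_types = FALSE),
    thermo = readr::read_csv(file.path(dir, "thermo.csv"),
                             show_col_types = FALSE)
  )
}

#' Recompute the derived cells of the summary tables
#'
#' Re-derives every derivable cell of the measured-rate and thermodynamic
#' summary tables from their primitive inputs and diffs against the printed
#' values: relative rates from the printed rate constants (compared exactly
#' at the printed two-significant-figure precision), ribozyme pKas as
#' solution pKa plus shift (exact), and calculated relative intrinsic rates
#' from the printed barriers via transition-state theory at 298.15 K
#' (compared within `tst_tol`, default 15%, reflecting the 0.1 kcal/mol
#' rounding of the printed barriers; the ~1e-11 entry is checked as order of
#' magnitude only since it derives from an unavailable exact rate
#' expression).
#'
#' @param values Reference values as returned by [mtr1_reference_values()].
#' @param ctx [thermo_ctx()] for the TST conversions (default 298.15 K).
#' @param tst_tol Relative tolerance for TST rate ratios (default 0.15).
#' @return Tibble with one row per checkable cell: `table`, `variant`,
#'   `quantity`, `printed`, `recomputed`, `pass`.
#' @export
reproduce_published_tables <- function(values = mtr1_reference_values(),
                                   ctx = thermo_ctx(), tst_tol = 0.15) {
  rates <- values$rates
  thermo <- values$thermo
  rel <- relative_rate_table(
    dplyr::rename(rates, k = "k_mean"), ref_variant = "unmodified",
    ref_pH = 6.0)
  t1 <- tibble::tibble(
    table = "rates", variant = rel$variant,
    quantity = paste0("rel_rate_pH", rel$pH),
    printed = rates$rel_rate_printed,
    recomputed = rel$rel_rate,
    pass = signif(rel$rel_rate, 2) == rates$rel_rate_printed
  )
  t2_pka <- tibble::tibble(
    table = "thermo", variant = thermo$variant, quantity = "pka_ribozyme",
    printed = thermo$pka_ribozyme,
    recomputed = ribozyme_pka(thermo$pka_soln, thermo$dpka_shift),
    pass = abs(printed - recomputed) < 1e-9
  )
  dg_ref <- thermo$dG_barrier[thermo$variant == "unmodified"]
  tst <- relative_rate_from_barriers(dg_ref, thermo$dG_barrier, ctx)
  t2_tst <- tibble::tibble(
    table = "thermo", variant = thermo$variant, quantity = "k_int_rel_calc",
    printed = thermo$k_int_rel_calc,
    recomputed = tst,
    pass = ifelse(printed < 1e-6,
                  abs(log10(recomputed / printed)) < 1,   # order of magnitude
                  abs(recomputed - printed) / printed <= tst_tol)
  )
  out <- dplyr::bind_rows(t1, t2_pka, t2_tst)
  out$pass[is.na(out$printed)] <- NA
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the study defaults:
#' generating parameters for each variant taken from the published tables,
#' gel-scale kinetic noise (additive s.d. 0.02 on fractions), 10% log-normal
#' rate noise across pH 5.5-8.5, 3 replicates, and the simulation (298.15 K)
#' and kinetics (310.15 K) temperature contexts. Stage seeds are derived
#' deterministically from the global seed.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory (created if needed); NULL to skip writing.
#' @param stages Character vector of stages to run, any of "kinetics",
#'   "ph", "landscape", "alchemical".
#' @param n_reps Kinetic replicates per variant (>= 3).
#' @param kinetic_noise_sd Additive s.d. on progress-curve fractions.
#' @param ph_cv Coefficient of variation of the log-normal rate noise.
#' @param n_alchemical_windows Lambda windows for the pKa-shift stage.
#' @param n_per_window Samples per lambda window.
#' @param spacing Surface grid spacing, Angstrom.
#' @return A `run_config` list.
#' @export
mtr_config <- function(seed = 1L, outdir = NULL,
                       stages = c("kinetics", "ph", "landscape", "alchemical"),
                       n_reps = 3L, kinetic_noise_sd = 0.02, ph_cv = 0.1,
                       n_alchemical_windows = 25L, n_per_window = 150L,
                       spacing = 0.05) {
  stopifnot(n_reps >= 3L)
  structure(
    list(seed = as.integer(seed), outdir = outdir, stages = stages,
         n_reps = n_reps, kinetic_noise_sd = kinetic_noise_sd,
         ph_cv = ph_cv, n_alchemical_windows = n_alchemical_windows,
         n_per_window = n_per_window, spacing = spacing,
         ctx_sim = thermo_ctx(298.15), ctx_kin = thermo_ctx(310.15)),
    class = "run_config"
  )
}

# deterministic stage seed: global seed plus a fixed offset per stage/unit
.stage_seed <- function(config, stage_offset, unit = 0L) {
  (config$seed * 1000L + stage_offset * 100L + unit) %% .Machine$integer.max
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order with ground truth taken
#' from the published tables: simulates and refits replicate progress
#' curves per variant, simulates and refits pH-rate profiles, builds the
#' variant free-energy surfaces and extracts string-method barriers, and
#' estimates alchemical pKa shifts by MBAR; then assembles measured-rate
#' and thermodynamic summary tables. With a fixed config and seed the
#' result is fully deterministic; artifacts (CSV/JSON plus an md5 checksum
#' manifest) are written when `config$outdir` is set.
#'
#' @param config A [mtr_config()].
#' @return List of class `pipeline_result` with `table1_like`,
#'   `table2_like`, `details` (per-stage intermediate tibbles) and `config`.
#' @export
run_pipeline <- function(config = mtr_config()) {
  stopifnot(inherits(config, "run_config"))
  refs <- mtr1_reference_values()
  details <- list()

  kin_tbl <- NULL
  if ("kinetics" %in% config$stages) {
    sim <- refs$rates
    fits <- vector("list", nrow(sim))
    for (i in seq_len(nrow(sim))) {
      k_true <- sim$k_mean[i]
      reps <- lapply(seq_len(config$n_reps), function(r) {
        biphasic <- k_true >= 0.01
        t_max <- min(max(5 * log(2) / k_true, 10), 10000)
        times <- seq(0, t_max, length.out = 20)[-1]
        tc <- gen_time_course(
          times, k_fast = k_true,
          k_slow = if (biphasic) k_true / 60 else k_true,
          frac_fast = if (biphasic) 0.8 else 1,
          plateau = if (biphasic) 1 else 0.9,
          noise_sd = config$kinetic_noise_sd,
          seed = .stage_seed(config, 1L, i * 10L + r),
          variant_id = sim$variant[i], pH = sim$pH[i])
        suppressWarnings(select_kinetic_model(tc))
      })
      s <- summarize_replicates(reps)
      fits[[i]] <- dplyr::bind_cols(
        tibble::tibble(variant = sim$variant[i], pH = sim$pH[i],
                       k_true = k_true), s)
    }
    kin_tbl <- dplyr::bind_rows(fits)
    details$kinetics <- kin_tbl
  }

  ph_tbl <- NULL
  if ("ph" %in% config$stages) {
    ph_truth <- tibble::tibble(
      variant = c("unmodified", "C10_n1c_c5n"),
      pka = c(6.4, 6.5),
      k60 = c(0.6, 0.67))
    ph_fits <- lapply(seq_len(nrow(ph_truth)), function(i) {
      k_int <- ph_truth$k60[i] * (1 + 10^(6.0 - ph_truth$pka[i]))
      ds <- gen_ph_rate_data(k_int, ph_truth$pka[i], cv = config$ph_cv,
                             n_reps = config$n_reps,
                             seed = .stage_seed(config, 2L, i),
                             variant_id = ph_truth$variant[i])
      fit <- fit_ph_profile(ds, "single_pka")
      tibble::tibble(variant = ph_truth$variant[i],
                     pka_true = ph_truth$pka[i],
                     pka_fit = fit$pka_acid, se = fit$se_pka_acid,
                     k_int_true = k_int, k_int_fit = fit$k_int,
                     identifiable = fit$identifiable)
    })
    ph_tbl <- dplyr::bind_rows(ph_fits)
    details$ph <- ph_tbl
  }

  land_tbl <- NULL
  if ("landscape" %in% config$stages) {
    land <- lapply(seq_len(nrow(refs$thermo)), function(i) {
      b <- refs$thermo$dG_barrier[i]
      s <- mtr1_surface(barrier = b, spacing = config$spacing)
      basins <- attr(s, "basins")
      path <- string_mfep(s, basins$R, basins$P, until_converged = TRUE,
                          waypoints = rbind(basins$I))
      prof <- profile_along_path(s, path)
      ts <- ts_coordinates(prof)
      rc <- ts[which.max(ts$G), ]
      tibble::tibble(variant = refs$thermo$variant[i], barrier_true = b,
                     barrier_string = prof$rate_controlling_barrier,
                     ts2_xi_at = if (nrow(rc)) rc$xi_at else NA_real_,
                     converged = path$converged)
    })
    land_tbl <- dplyr::bind_rows(land)
    details$landscape <- land_tbl
  }

  alch_tbl <- NULL
  if ("alchemical" %in% config$stages) {
    alch <- lapply(seq_len(nrow(refs$thermo)), function(i) {
      shift_true <- refs$thermo$dpka_shift[i]
      ddg_true <- ddg_from_delta_pka(shift_true, config$ctx_sim)
      ds <- gen_alchemical_samples(ddg_true,
                                   n_windows = config$n_alchemical_windows,
                                   n_per_window = config$n_per_window,
                                   seed = .stage_seed(config, 3L, i))
      est <- alchemical_ddg(ds)
      tibble::tibble(
        variant = refs$thermo$variant[i],
        ddg_true = ddg_true, ddg_est = est$ddg, ddg_se = est$se,
        dpka_true = shift_true,
        dpka_est = delta_pka_from_ddg(est$ddg, config$ctx_sim),
        pka_ribozyme_est = ribozyme_pka(refs$thermo$pka_soln[i],
                                        delta_pka_from_ddg(est$ddg,
                                                           config$ctx_sim)))
    })
    alch_tbl <- dplyr::bind_rows(alch)
    details$alchemical <- alch_tbl
  }

  # table 1-like: simulated measured rates and relative rates
  table1 <- NULL
  if (!is.null(kin_tbl)) {
    table1 <- relative_rate_table(dplyr::rename(kin_tbl, k = "mean_k"))
    k_ref_true <- refs$rates$k_mean[refs$rates$variant == "unmodified" &
                                      refs$rates$pH == 6.0]
    truth <- tibble::tibble(variant = refs$rates$variant,
                            pH = refs$rates$pH,
                            rel_rate_true = refs$rates$k_mean / k_ref_true)
    table1 <- dplyr::left_join(table1, truth, by = c("variant", "pH"))
  }

  # table 2-like: barriers, TST relative intrinsic rates, pKa chain
  dg_ref <- refs$thermo$dG_barrier[refs$thermo$variant == "unmodified"]
  table2 <- tibble::tibble(
    variant = refs$thermo$variant,
    dG_barrier = if (!is.null(land_tbl)) land_tbl$barrier_string
    else refs$thermo$dG_barrier,
    k_int_rel_calc = relative_rate_from_barriers(
      dg_ref, refs$thermo$dG_barrier, config$ctx_sim),
    k_int_rel_expt = refs$thermo$k_int_rel_expt,
    pka_soln = refs$thermo$pka_soln,
    dpka_shift = if (!is.null(alch_tbl)) alch_tbl$dpka_est
    else refs$thermo$dpka_shift,
    pka_apparent_expt = refs$thermo$pka_apparent
  )
  table2$pka_ribozyme <- ribozyme_pka(table2$pka_soln, table2$dpka_shift)

  result <- structure(
    list(table1_like = table1, table2_like = table2, details = details,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$outdir)) .write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(x$config$stages, collapse = ", "),
      "\n")
  if (!is.null(x$table1_like)) {
    cat("table1_like:\n"); print(x$table1_like)
  }
  cat("table2_like:\n"); print(x$table2_like)
  invisible(x)
}

.write_pipeline_artifacts <- function(result) {
  outdir <- result$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    df_out <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.numeric), ~ signif(.x, 12)))
    readr::write_csv(df_out, p)
    files <<- c(files, p)
  }
  if (!is.null(result$table1_like)) wr(result$table1_like, "table1_like.csv")
  wr(result$table2_like, "table2_like.csv")
  for (nm in names(result$details))
    wr(result$details[[nm]], paste0("stage_", nm, ".csv"))
  cfg <- result$config
  cfg$ctx_sim <- unclass(cfg$ctx_sim)
  cfg$ctx_kin <- unclass(cfg$ctx_kin)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, file.path(outdir, "config.json"))
  checks <- tools::md5sum(files)
  jsonlite::write_json(as.list(checks), file.path(outdir, "checksums.json"),
                       auto_unbox = TRUE)
  invisible(files)
}
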
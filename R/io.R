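## File interchange and pipeline runners. Everything is plain CSV with
## explicit headers (UTF-8, "." decimal separator): transients as
## `time_s,intensity`, spectra as `wavelength_nm,intensity`, melts as
## `temperature_C,ellipticity`, activity traces as `time_s,A340`, plus a
## manifest tying transient files to sample metadata. Configuration is
## YAML or JSON. Every applied correction (reference scale, normalization
## divisor) is logged so the preprocessing is auditable.

#' Read an analysis configuration file
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Binding parameters from a configuration list
#'
#' Expects keys `kd_uM`, `delta_H_kcal_mol` and `T_ref_C` (optionally
#' `delta_Cp_kcal_mol_K`).
#'
#' @param cfg Named list, e.g. one entry of a config file's `binding`
#'   block.
#' @return A [binding_parameters()] object.
#' @export
binding_from_config <- function(cfg) {
  need <- c("kd_uM", "delta_H_kcal_mol", "T_ref_C")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config binding block is missing key(s): ", paste(miss, collapse = ", "))
  binding_parameters(kd_ref = cfg$kd_uM, delta_H = cfg$delta_H_kcal_mol,
                     T_ref = cfg$T_ref_C + 273.15,
                     delta_Cp = cfg$delta_Cp_kcal_mol_K %||% 0)
}

#' Kinetic scenario from a configuration list
#'
#' Keys mirror the arguments of [kinetic_scenario()]; a nested `binding`
#' block is converted with [binding_from_config()].
#'
#' @param cfg Named list (e.g. the `scenario` block of a config file).
#' @return A [kinetic_scenario()].
#' @export
scenario_from_config <- function(cfg) {
  if (!is.null(cfg$binding)) cfg$binding <- binding_from_config(cfg$binding)
  known <- names(formals(kinetic_scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  do.call(kinetic_scenario, cfg)
}

#' Write / read one transient CSV
#'
#' @param x A [transient_record()].
#' @param file Path of the `time_s,intensity` CSV.
#' @return `write_transient()` returns `file` invisibly; `read_transient()`
#'   a [transient_record()] populated from the manifest fields given.
#' @export
write_transient <- function(x, file) {
  stopifnot(inherits(x, "transient_record"))
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_transient
#' @param enzyme_total,ligand_total,T_initial,T_final,replicate,label
#'   Metadata for the record (usually from the manifest).
#' @export
read_transient <- function(file, enzyme_total = NA_real_,
                           ligand_total = NA_real_, T_initial = NA_real_,
                           T_final = NA_real_, replicate = 1L, label = "") {
  d <- utils::read.csv(file)
  transient_record(d$time_s, d$intensity, enzyme_total = enzyme_total,
                   ligand_total = ligand_total, T_initial = T_initial,
                   T_final = T_final, replicate = replicate, label = label)
}

#' Simulate a T-jump experiment to disk
#'
#' Generates the full experiment of a scenario and writes one CSV per
#' transient, the free-Trp reference, a manifest
#' (`sample_id,enzyme_uM,ligand_uM,replicate,file`), a ground-truth JSON
#' sidecar and the scenario configuration itself.
#'
#' @param scenario A [kinetic_scenario()], or a config list / config file
#'   path understood by [scenario_from_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(scenario, outdir, seed = NULL) {
  if (is.character(scenario)) scenario <- read_config(scenario)$scenario
  if (!inherits(scenario, "kinetic_scenario"))
    scenario <- scenario_from_config(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create '%s'", outdir))
  exp <- simulate(scenario, seed = seed)
  rows <- lapply(exp$transients, function(tr) {
    f <- paste0(tr$label, ".csv")
    write_transient(tr, file.path(outdir, f))
    data.frame(sample_id = tr$label, enzyme_uM = tr$enzyme_total,
               ligand_uM = tr$ligand_total, replicate = tr$replicate,
               file = f)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  write_transient(exp$reference, file.path(outdir, "reference.csv"))
  truth <- list(per_sample = exp$truth,
                k_on = scenario$k_on, k_off = scenario$k_off,
                k_slow = scenario$k_slow)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- list(scenario = c(
    scenario[setdiff(names(unclass(scenario)), "binding")],
    list(binding = list(kd_uM = scenario$binding$kd_ref,
                        delta_H_kcal_mol = scenario$binding$delta_H,
                        T_ref_C = scenario$binding$T_ref - 273.15))))
  jsonlite::write_json(cfg, file.path(outdir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## Load manifest + transients + reference back from a simulated (or
## hand-assembled) directory.
.load_experiment <- function(dir, T_initial = NA_real_, T_final = 36) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop(sprintf("no manifest.csv in '%s'", dir))
  manifest <- utils::read.csv(mf)
  if (nrow(manifest) == 0L) stop("manifest is empty")
  sc <- NULL
  scf <- file.path(dir, "scenario.json")
  if (file.exists(scf)) {
    cfg <- read_config(scf)$scenario
    T_initial <- cfg$T_initial %||% T_initial
    T_final <- cfg$T_final %||% T_final
    sc <- cfg
  }
  transients <- lapply(seq_len(nrow(manifest)), function(i)
    read_transient(file.path(dir, manifest$file[i]),
                   enzyme_total = manifest$enzyme_uM[i],
                   ligand_total = manifest$ligand_uM[i],
                   T_initial = T_initial, T_final = T_final,
                   replicate = manifest$replicate[i],
                   label = manifest$sample_id[i]))
  reference <- NULL
  rf <- file.path(dir, "reference.csv")
  if (file.exists(rf))
    reference <- read_transient(rf, T_initial = T_initial, T_final = T_final,
                                label = "trp_reference")
  list(manifest = manifest, transients = transients, reference = reference,
       scenario_cfg = sc)
}

#' Fit every transient of a simulated/measured experiment directory
#'
#' Reads the manifest and transient CSVs, applies reference subtraction
#' and normalization, fits each transient to a double exponential and
#' writes `fits.csv`
#' (`sample_id,k_fast,k_fast_se,k_slow,k_slow_se,amp_fast,amp_slow,baseline,rms,converged`).
#' Non-convergent samples are reported by message.
#'
#' @param dir Directory holding `manifest.csv`, the transient CSVs and
#'   optionally `reference.csv`.
#' @param guesses Optional starting rates for the fits.
#' @return The fit-results data frame, invisibly.
#' @export
run_fit_transients <- function(dir, guesses = NULL) {
  ex <- .load_experiment(dir)
  rows <- lapply(ex$transients, function(tr) {
    if (!is.null(ex$reference)) tr <- subtract_reference(tr, ex$reference)
    tr <- normalize_transient(tr)
    ft <- fit_double_exponential(tr, guesses = guesses)
    cf <- ft$coefficients
    data.frame(sample_id = tr$label,
               k_fast = cf[["k_fast"]], k_fast_se = ft$se[["k_fast"]],
               k_slow = cf[["k_slow"]], k_slow_se = ft$se[["k_slow"]],
               amp_fast = cf[["amp_fast"]], amp_slow = cf[["amp_slow"]],
               baseline = cf[["baseline"]], rms = ft$rms,
               converged = ft$converged)
  })
  fits <- do.call(rbind, rows)
  bad <- fits$sample_id[!fits$converged]
  if (length(bad))
    message("non-convergent fits: ", paste(bad, collapse = ", "))
  utils::write.csv(fits, file.path(dir, "fits.csv"), row.names = FALSE)
  invisible(fits)
}

#' Run the full kinetics analysis on an experiment directory
#'
#' Loads the transients, runs [tjump_kinetics()] end-to-end, and writes a
#' per-enzyme summary CSV
#' (`enzyme,k_on,k_on_se,k_off,k_off_se,kd_tjump,kd_itc,r_fast,r_slow,verdict_fast,verdict_slow,slow_mean,slow_sd,n`)
#' plus a human-readable `report.txt` that states both verdicts and the
#' critical correlation values used.
#'
#' @param dir Experiment directory (see [run_simulate()]).
#' @param binding [binding_parameters()]; defaults to the directory's
#'   `scenario.json` binding block when present.
#' @param kd_itc Optional ITC Kd (uM); defaults to `binding$kd_ref`.
#' @param enzyme Enzyme label for the report.
#' @param levels Confidence levels for the classification.
#' @return The [tjump_kinetics()] object, invisibly.
#' @export
run_analyze <- function(dir, binding = NULL, kd_itc = NULL,
                        enzyme = "enzyme", levels = c(0.99, 0.90, 0.80)) {
  ex <- .load_experiment(dir)
  if (is.null(binding)) {
    if (is.null(ex$scenario_cfg$binding))
      stop("no binding parameters: supply 'binding' or a scenario.json")
    binding <- binding_from_config(ex$scenario_cfg$binding)
  }
  res <- tjump_kinetics(ex$transients, binding = binding,
                        reference = ex$reference, kd_itc = kd_itc,
                        levels = levels, enzyme = enzyme)
  out <- data.frame(enzyme = enzyme,
                    k_on = res$k_on, k_on_se = res$k_on_se,
                    k_off = res$k_off, k_off_se = res$k_off_se,
                    kd_tjump = res$kd_tjump, kd_itc = res$kd_itc,
                    r_fast = res$fast_test$r, r_slow = res$slow_test$r,
                    verdict_fast = res$fast_test$verdict,
                    verdict_slow = res$slow_test$verdict,
                    slow_mean = res$slow_mean, slow_sd = res$slow_sd,
                    n = res$slow_n)
  utils::write.csv(out, file.path(dir, "summary.csv"), row.names = FALSE)
  rep <- c(
    sprintf("T-jump relaxation kinetics summary: %s", enzyme),
    sprintf("transients analysed: %d (DF = %d)", res$slow_n, res$slow_n - 2L),
    sprintf("fast phase: r = %.3f -> %s", res$fast_test$r,
            res$fast_test$verdict),
    sprintf("slow phase: r = %.3f -> %s", res$slow_test$r,
            res$slow_test$verdict),
    sprintf("critical r: %s",
            paste(sprintf("%.3f @ %.0f%%", res$fast_test$critical_values,
                          100 * res$fast_test$confidence_levels),
                  collapse = ", ")),
    if (res$fast_withheld)
      "k_on/k_off withheld: fast phase not significantly concentration dependent"
    else c(sprintf("k_on  = %.4g +/- %.3g uM-1 s-1", res$k_on, res$k_on_se),
           sprintf("k_off = %.5g +/- %.4g s-1", res$k_off, res$k_off_se),
           sprintf("Kd (kinetic) = %.4g uM; Kd (ITC) = %.4g uM; ratio %.3g",
                   res$kd_tjump, res$kd_itc, res$kd_ratio)),
    sprintf("slow rate: %.4g +/- %.3g s-1 (n = %d)",
            res$slow_mean, res$slow_sd, res$slow_n))
  writeLines(rep, file.path(dir, "report.txt"))
  invisible(res)
}

#' Write equilibrium fixture data (spectra, melts, activity traces)
#'
#' Generates CSV fixtures for the equilibrium workflow: per-mutant
#' emission spectra for each complex (from [midw_spectral_scenario()]
#' presets), melt curves with the configured melting temperatures, and
#' activity traces relative to wild type.
#'
#' @param outdir Output directory.
#' @param mutants Mutants to include.
#' @param Tm Named melting temperatures (C) including `"WT"`.
#' @param activity Named relative activities (fraction of WT).
#' @param noise_sd Spectral noise (fraction of apo peak).
#' @param melt_noise_sd Melt noise (mdeg).
#' @param seed Base seed.
#' @return Invisibly, the list of written files.
#' @export
write_equilibrium_fixtures <- function(outdir,
                                       mutants = c("midW22", "midW30", "midW47",
                                                   "midW74", "midW133"),
                                       Tm = c(midW22 = 46, midW30 = 42,
                                              midW47 = 49, midW74 = 45,
                                              midW133 = 45, WT = 48),
                                       activity = c(midW22 = 0.90,
                                                    midW30 = 0.25,
                                                    midW47 = 0.20,
                                                    midW74 = 0.33,
                                                    midW133 = 0.28, WT = 1),
                                       noise_sd = 0.005,
                                       melt_noise_sd = 0.1, seed = 1L) {
  dir.create(file.path(outdir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "melts"), showWarnings = FALSE)
  dir.create(file.path(outdir, "activity"), showWarnings = FALSE)
  files <- character(0)
  for (m in mutants) {
    sc <- midw_spectral_scenario(m, noise_sd = noise_sd,
                                 seed = seed + match(m, mutants) * 101L)
    for (lab in names(sc$quench)) {
      s <- generate_spectrum(sc, lab)
      f <- file.path(outdir, "spectra", sprintf("%s_%s.csv", m, lab))
      utils::write.csv(as.data.frame(s), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  for (e in names(Tm)) {
    f <- file.path(outdir, "melts", paste0(e, ".csv"))
    utils::write.csv(
      generate_melt_curve(Tm = Tm[[e]], noise_sd = melt_noise_sd,
                          seed = seed + 7L * match(e, names(Tm))),
      f, row.names = FALSE)
    files <- c(files, f)
  }
  base_rate <- 0.01
  for (e in names(activity)) {
    f <- file.path(outdir, "activity", paste0(e, ".csv"))
    utils::write.csv(
      generate_activity_trace(initial_rate = base_rate * activity[[e]],
                              seed = seed + 13L * match(e, names(activity))),
      f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Run the equilibrium characterization on fixture directories
#'
#' Computes (a) the percent-of-apoenzyme quench table from full-peak
#' integrals of each complex spectrum, (b) melting temperatures from the
#' melt curves, and (c) relative activities versus the `WT` trace, and
#' writes `quench_table.csv`, `melting_temperatures.csv` and
#' `relative_activity.csv` into `outdir`.
#'
#' @param dir Directory produced by [write_equilibrium_fixtures()] (or
#'   laid out the same way: `spectra/<enzyme>_<complex>.csv`,
#'   `melts/<enzyme>.csv`, `activity/<enzyme>.csv`).
#' @param outdir Where to write the result tables (default `dir`).
#' @return A list with the three data frames, invisibly.
#' @export
run_equilibrium <- function(dir, outdir = dir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  spdir <- file.path(dir, "spectra")
  if (dir.exists(spdir)) {
    files <- list.files(spdir, pattern = "\\.csv$")
    info <- do.call(rbind, lapply(files, function(f) {
      parts <- strsplit(sub("\\.csv$", "", f), "_")[[1]]
      data.frame(enzyme = parts[1],
                 complex = paste(parts[-1], collapse = "_"), file = f)
    }))
    rows <- list()
    for (e in unique(info$enzyme)) {
      sub <- info[info$enzyme == e, ]
      ints <- vapply(seq_len(nrow(sub)), function(i) {
        d <- utils::read.csv(file.path(spdir, sub$file[i]))
        integrate_full_peak(spectrum_record(d$wavelength_nm, d$intensity,
                                            complex_label = sub$complex[i],
                                            enzyme = e))
      }, numeric(1))
      names(ints) <- sub$complex
      if (!"apo" %in% names(ints))
        stop(sprintf("no apo spectrum for enzyme '%s'", e))
      rows[[e]] <- data.frame(
        enzyme = e, complex = names(ints),
        percent_of_apo = percent_of_apo(ints, ints[["apo"]]))
    }
    out$quench <- do.call(rbind, rows)
    rownames(out$quench) <- NULL
    utils::write.csv(out$quench, file.path(outdir, "quench_table.csv"),
                     row.names = FALSE)
  }

  mdir <- file.path(dir, "melts")
  if (dir.exists(mdir)) {
    files <- list.files(mdir, pattern = "\\.csv$")
    out$melts <- do.call(rbind, lapply(files, function(f) {
      fit <- fit_melt(utils::read.csv(file.path(mdir, f)))
      data.frame(enzyme = sub("\\.csv$", "", f),
                 Tm = fit$coefficients[["Tm"]], Tm_se = fit$se[["Tm"]],
                 width = fit$coefficients[["width"]],
                 converged = fit$converged)
    }))
    utils::write.csv(out$melts, file.path(outdir, "melting_temperatures.csv"),
                     row.names = FALSE)
  }

  adir <- file.path(dir, "activity")
  if (dir.exists(adir)) {
    wtf <- file.path(adir, "WT.csv")
    if (!file.exists(wtf)) stop("activity directory has no WT.csv trace")
    wt <- utils::read.csv(wtf)
    files <- list.files(adir, pattern = "\\.csv$")
    out$activity <- do.call(rbind, lapply(files, function(f) {
      d <- utils::read.csv(file.path(adir, f))
      data.frame(enzyme = sub("\\.csv$", "", f),
                 relative_activity_pct = relative_activity(d, wt))
    }))
    utils::write.csv(out$activity, file.path(outdir, "relative_activity.csv"),
                     row.names = FALSE)
  }

  invisible(out)
}
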
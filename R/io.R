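# File formats and the pipeline orchestrator.  Decay histograms use a
# plain-text TSV dialect: "#" header lines carrying key=value metadata
# (dt_ns, t_start_ns, plus acquisition keys), then two tab-separated
# columns time_ns and counts.  Titration tables and TRES series are CSV.

decay_header_map <- c(wavelength_nm = "wavelength_nm",
                      polarizer_deg = "polarizer_deg",
                      quencher_M = "quencher_M",
                      lipid_uM = "lipid_uM",
                      solvent = "solvent",
                      background = "background",
                      G = "G",
                      peptide_id = "peptide_id",
                      environment = "environment")

#' Write a decay histogram to the TSV dialect
#'
#' @param decay a [decay_histogram()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "decay_histogram"))
  hdr <- c(sprintf("# dt_ns=%.12g", decay$grid$dt),
           sprintf("# t_start_ns=%.12g", decay$grid$t_start))
  for (k in names(decay$meta)) {
    v <- decay$meta[[k]]
    hdr <- c(hdr, sprintf("# %s=%s", k,
                          if (is.numeric(v)) sprintf("%.12g", v) else v))
  }
  t <- grid_times(decay$grid)
  body <- sprintf("%.12g\t%d", t, decay$counts)
  writeLines(c(hdr, "time_ns\tcounts", body), path)
  invisible(path)
}

#' Read a decay histogram from the TSV dialect
#'
#' Malformed lines are reported with their line numbers; missing `dt_ns`
#' metadata is inferred from the (required-uniform) time column with a
#' warning.
#'
#' @param path input file path
#' @return a [decay_histogram()]
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  meta_raw <- list()
  for (ln in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1) stop("malformed header line: ", ln)
    meta_raw[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!is_hdr]
  body <- body[!grepl("^time_ns", body) & nzchar(body)]
  offset <- which(!is_hdr & !grepl("^time_ns", lines) & nzchar(lines))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed data line(s) at file line(s): ",
         paste(offset[bad], collapse = ", "))
  tv <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  cv <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(tv) | is.na(cv))
  if (length(bad))
    stop("non-numeric value(s) at file line(s): ",
         paste(offset[bad], collapse = ", "))
  bad <- which(cv < 0 | abs(cv - round(cv)) > 1e-9)
  if (length(bad))
    stop("counts must be non-negative integers; offending line(s): ",
         paste(offset[bad], collapse = ", "))
  if (!is.null(meta_raw$dt_ns)) {
    dt <- as.numeric(meta_raw$dt_ns)
  } else {
    dts <- diff(tv)
    dt <- stats::median(dts)
    warning("dt_ns metadata missing; inferred dt = ", signif(dt, 6),
            " ns from the time column")
  }
  if (length(tv) > 1L && any(abs(diff(tv) - dt) > 1e-6 * dt))
    stop("time column is not uniform within tolerance 1e-6 * dt")
  t_start <- if (!is.null(meta_raw$t_start_ns))
    as.numeric(meta_raw$t_start_ns) else tv[1]
  grid <- time_grid(t_start, dt, length(tv))
  meta <- list()
  for (k in intersect(names(meta_raw), names(decay_header_map))) {
    v <- meta_raw[[k]]
    meta[[k]] <- if (k %in% c("solvent", "peptide_id", "environment")) v
                 else as.numeric(v)
  }
  decay_histogram(grid, cv, meta)
}

#' Write / read a titration table (CSV)
#'
#' Long-format table with columns `wavelength_nm`, `lipid_uM`,
#' `intensity`.
#' @param table data.frame
#' @param path file path
#' @return `path` invisibly (write); data.frame (read)
#' @export
write_titration_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "lipid_uM", "intensity")
  if (!all(need %in% names(tab)))
    stop("titration CSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Write a TRES decay set to a long-format CSV
#'
#' Columns `wavelength_nm`, `time_ns`, `counts`.
#' @param decays list of [decay_histogram()] with `wavelength_nm` metadata
#' @param path file path
#' @return `path`, invisibly
#' @export
write_tres_csv <- function(decays, path) {
  rows <- lapply(decays, function(d)
    data.frame(wavelength_nm = d$meta$wavelength_nm,
               time_ns = grid_times(d$grid), counts = d$counts))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format TRES CSV back into decay histograms
#'
#' @param path file path
#' @return list of [decay_histogram()]
#' @export
read_tres_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "time_ns", "counts")
  if (!all(need %in% names(tab)))
    stop("TRES CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$wavelength_nm), function(d) {
    d <- d[order(d$time_ns), ]
    dt <- stats::median(diff(d$time_ns))
    decay_histogram(time_grid(d$time_ns[1], dt, nrow(d)), d$counts,
                    list(wavelength_nm = d$wavelength_nm[1]))
  })
}

PIPELINE_STAGES <- c("decay", "tres", "anisotropy", "quenching",
                     "leakage", "partition", "decompose")

CONFIG_KEYS <- c("peptide_id", "seed", "stages", "out_dir", "peak_counts",
                 "n_bins", "t_max_ns", "irf_fwhm_ns", "irf_center_ns",
                 "G", "thetas_deg", "wavelengths_nm", "times_ns",
                 "Q_list_M", "cL_list_uM", "noise_cv", "nssr_cutoff",
                 "q_stat", "leak_fraction", "n_components")

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; a seed is mandatory (every stochastic stage
#' derives its sub-seed from it).
#'
#' @param config named list, or path to a YAML file
#' @return the validated config list with defaults filled in
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  bad <- setdiff(names(config), CONFIG_KEYS)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$seed))
    stop("config must provide an explicit `seed`")
  defaults <- list(
    peptide_id = "V4W", stages = PIPELINE_STAGES, peak_counts = 2e4,
    n_bins = 1024L, t_max_ns = 50, irf_fwhm_ns = 0.25, irf_center_ns = 2,
    G = 1.1, thetas_deg = c(0, 90), wavelengths_nm = seq(310, 370, 4),
    times_ns = seq(0.2, 25, length.out = 30),
    Q_list_M = c(0, 0.1, 0.2, 0.3, 0.4),
    cL_list_uM = c(0, 15, 30, 60, 90), noise_cv = 0.02,
    nssr_cutoff = 1.5, q_stat = 1.2, leak_fraction = 0.5,
    n_components = 3L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  bad_stage <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad_stage))
    stop("unknown stages: ", paste(bad_stage, collapse = ", "))
  config
}

#' Run the simulate-and-analyze pipeline
#'
#' Simulates the configured synthetic experiments for one peptide
#' scenario and runs the toggled analysis stages: magic-angle decay fit,
#' TRES + relaxation fit, global anisotropy, global quenching, calcein
#' leakage, partition titration (with NSSR interval), and the
#' partition-weighted decomposition of the limiting anisotropy.  Stage
#' failures are recorded in the report and dependent stages are skipped,
#' not crashed.  Two runs with the same config produce identical reports.
#'
#' @param config named list or YAML path; see [validate_config()]
#' @return a list report with one entry per stage plus a `summary`
#'   data.frame mirroring the endpoint-table layout (Kd, r_inf and nu_inf
#'   endpoints); written as JSON to `out_dir` when set
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  sc <- scenario_from_table(cfg$peptide_id, seed = cfg$seed)
  grid <- time_grid(0, cfg$t_max_ns / cfg$n_bins, cfg$n_bins)
  irf <- make_gaussian_irf(cfg$irf_fwhm_ns, cfg$irf_center_ns, grid)
  report <- list(config = cfg[order(names(cfg))])
  run_stage <- function(name, expr) {
    if (!name %in% cfg$stages)
      return(list(status = "skipped"))
    tryCatch(c(list(status = "ok"), expr()),
             error = function(e) list(status = "error",
                                      message = conditionMessage(e)))
  }

  report$decay <- run_stage("decay", function() {
    d <- simulate_polarized_set(sc, magic_angle(), G = cfg$G,
                                peak_counts = cfg$peak_counts,
                                seed = cfg$seed + 11L, grid = grid,
                                irf = irf)[[1]]
    fit <- fit_multiexp_reconvolution(d, irf,
                                      n_components = cfg$n_components)
    list(lifetimes = fit$model$lifetimes,
         amplitudes = fit$model$amplitudes,
         tau_av = amplitude_avg_lifetime(fit$model),
         reduced_chi2 = fit$reduced_chi2)
  })

  report$tres <- run_stage("tres", function() {
    decays <- simulate_tres_dataset(sc, cfg$wavelengths_nm,
                                    peak_counts = cfg$peak_counts,
                                    seed = cfg$seed + 23L, grid = grid,
                                    irf = irf)
    tr <- tres_pipeline(decays, irf, cfg$times_ns,
                        n_components = cfg$n_components)
    list(t_relax = tr$relax_fit$t_relax, C = tr$relax_fit$C,
         nu_inf = tr$relax_fit$nu_inf,
         nu_t = tr$nu_t, fwhm_t = tr$fwhm_t, times = tr$times)
  })

  report$anisotropy <- run_stage("anisotropy", function() {
    decays <- simulate_polarized_set(sc, cfg$thetas_deg, G = cfg$G,
                                     peak_counts = cfg$peak_counts,
                                     seed = cfg$seed + 37L, grid = grid,
                                     irf = irf)
    fit <- fit_anisotropy_global(decays, irf, sc$lifetimes, G = cfg$G)
    list(B = fit$aniso$B, phi = fit$aniso$phi, r_inf = fit$aniso$r_inf,
         r0 = fit$aniso$B + fit$aniso$r_inf,
         reduced_chi2 = fit$reduced_chi2)
  })

  report$quenching <- run_stage("quenching", function() {
    decays <- simulate_quench_series(sc, cfg$Q_list_M,
                                     peak_counts = cfg$peak_counts,
                                     seed = cfg$seed + 41L, grid = grid,
                                     irf = irf)
    fit <- fit_quench_series(decays, irf,
                             n_components = cfg$n_components)
    list(kq = fit$kq, Q_list = fit$Q_list)
  })

  report$leakage <- run_stage("leakage", function() {
    d <- simulate_calcein_sample(cfg$leak_fraction, Q_stat = cfg$q_stat,
                                 peak_counts = cfg$peak_counts,
                                 seed = cfg$seed + 53L, grid = grid,
                                 irf = irf)
    cf <- fit_calcein_decay(d, irf)
    L <- leakage(cf$B_F, 0, cf$B_E, Q_stat = cfg$q_stat)
    list(L = as.numeric(L), B_F = cf$B_F, B_E = cf$B_E,
         clamped = attr(L, "clamped"))
  })

  report$partition <- run_stage("partition", function() {
    tab <- simulate_partition_titration(
      sc$Kd, cfg$cL_list_uM, default_partition_endpoints(sc),
      noise_cv = cfg$noise_cv, seed = cfg$seed + 67L)
    fit <- fit_partition_titration(tab, cutoff = cfg$nssr_cutoff)
    list(Kd = fit$Kd, K = fit$K, nssr_interval = fit$nssr$interval,
         nssr_open = as.logical(fit$nssr$open))
  })

  report$decompose <- run_stage("decompose", function() {
    Kd <- if (identical(report$partition$status, "ok"))
      report$partition$Kd else sc$Kd
    cl <- cfg$cL_list_uM
    X <- bound_fraction(cl, sc$Kd)
    set.seed(cfg$seed + 71L)
    r_obs <- X * sc$aniso_m$r_inf + (1 - X) * sc$aniso_aq$r_inf +
      stats::rnorm(length(cl), 0, 0.002)
    fit <- fit_partition_weighted(r_obs, cl, Kd_fixed = Kd,
                                  observable = "r_inf")
    list(observable = "r_inf", p_aq = fit$p_aq, p_m = fit$p_m,
         Kd_fixed = fit$Kd_fixed)
  })

  ok <- function(st) identical(st$status, "ok")
  report$summary <- data.frame(
    peptide = cfg$peptide_id,
    Kd_uM = if (ok(report$partition)) report$partition$Kd else NA_real_,
    r_inf_aq = sc$aniso_aq$r_inf,
    r_inf_m = if (ok(report$anisotropy)) report$anisotropy$r_inf
              else NA_real_,
    nu_inf_aq_1e3cm = sc$relax_aq$nu_inf / 1e3,
    nu_inf_m_1e3cm = if (ok(report$tres)) report$tres$nu_inf / 1e3
                     else NA_real_)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(cfg$out_dir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}
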
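# End-to-end orchestration: replicate induction times -> per-condition
# nucleation rates -> per-solvent CNT fits and derived cluster
# thermodynamics -> solvent-property correlations -> optional conformer
# populations; emitted as a report bundle and (optionally) CSV/JSON files.

#' Configuration for a full pipeline run
#'
#' Every field has a default; the object round-trips losslessly through
#' JSON. A single seed governs all stochastic stages (bootstrap CIs);
#' per-stage sub-seeds are derived from it deterministically.
#'
#' @param induction_csv Path to an induction-time CSV (see
#'   [read_induction_csv()]), or `NULL` when `replicates` are passed to
#'   [run_pipeline()] directly.
#' @param trajectory_file,selections_file Optional trajectory (PDB/XYZ)
#'   and selection-config paths for the conformer stage.
#' @param solute A [solute_spec()].
#' @param method Rate estimator, `"probability_fit"` or `"mean_inverse"`.
#' @param t_growth_s Fixed detection lag, seconds.
#' @param n_boot Bootstrap resamples for rate CIs.
#' @param imhb_d_max_A,imhb_angle_min_deg Hydrogen-bond criterion.
#' @param seed Master seed.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(induction_csv = NULL, trajectory_file = NULL,
                       selections_file = NULL, solute = solute_spec(),
                       method = "probability_fit", t_growth_s = 0,
                       n_boot = 1000, imhb_d_max_A = 2.5,
                       imhb_angle_min_deg = 120, seed = 1L,
                       out_dir = NULL) {
  structure(list(induction_csv = induction_csv,
                 trajectory_file = trajectory_file,
                 selections_file = selections_file, solute = solute,
                 method = method, t_growth_s = t_growth_s, n_boot = n_boot,
                 imhb_d_max_A = imhb_d_max_A,
                 imhb_angle_min_deg = imhb_angle_min_deg,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the nucleation-kinetics and conformer pipeline
#'
#' Estimates a nucleation rate (with bootstrap CI) for every replicate
#' group, fits the CNT rate law per solvent, derives interfacial energy
#' and per-supersaturation critical-cluster properties, computes
#' solvent-property correlations when a property table is supplied, and
#' summarizes conformer populations when a trajectory is supplied. The
#' run is deterministic given the config and seed; on failure nothing is
#' written.
#'
#' @param config A [run_config()].
#' @param replicates Optional named list of [induction_replicates()]
#'   (bypasses `config$induction_csv`); each condition must carry
#'   `solvent`, `S` and `T_K` unless generated synthetically.
#' @param solvent_properties Optional solvent-property table (defaults to
#'   the built-in published one when correlations are requested).
#' @return A list of class `"report_bundle"` with elements `rates`
#'   (per-condition table), `fits` (per-solvent `"cnt_fit"`), `cnt_table`
#'   (per-condition derived quantities in the published layout),
#'   `correlations`, `conformers` (population table or `NULL`), and
#'   `manifest` (inputs, seed, decisions in force).
#' @export
run_pipeline <- function(config, replicates = NULL,
                         solvent_properties = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(replicates)) {
    if (is.null(config$induction_csv))
      stop_domain("no induction data: set induction_csv or pass replicates")
    replicates <- read_induction_csv(config$induction_csv)
  }
  v <- config$solute$molecular_volume_A3
  # stage 1: per-condition nucleation rates (sub-seeded bootstrap)
  rates <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    est <- estimate_rate(r, method = config$method,
                         t_growth_s = config$t_growth_s,
                         n_boot = config$n_boot,
                         seed = config$seed + i)
    data.frame(solvent = r$condition$solvent %||% "unknown",
               S = r$condition$S, T_K = r$condition$T_K,
               J = est$J, ci_low = est$ci_low, ci_high = est$ci_high,
               n_used = est$n_used, n_censored = est$n_censored)
  }))
  # stage 2: per-solvent CNT fits and derived cluster properties
  fits <- lapply(split(rates, rates$solvent), function(g) {
    if (length(unique(g$S)) < 2) return(NULL)
    fit_cnt(g$S, g$J, T_K = g$T_K[1], v_A3 = v)
  })
  fits <- Filter(Negate(is.null), fits)
  cnt_table <- do.call(rbind, lapply(names(fits), function(sv) {
    f <- fits[[sv]]
    d <- f$derived
    if (is.null(d))
      d <- data.frame(S = f$points$S, r_c_A = NA, n_star = NA,
                      zeldovich = NA, attachment_rate = NA)
    data.frame(solvent = sv, S = d$S, J = f$points$J,
               ln_A0 = f$ln_A0, B = f$B, gamma_mJ_m2 = f$gamma_mJ_m2,
               r_squared = f$r_squared, non_physical = f$non_physical,
               r_c_A = d$r_c_A, n_star = d$n_star,
               zeldovich = d$zeldovich,
               attachment_rate = d$attachment_rate)
  }))
  # stage 3: solvent-property correlations (needs >= 2 solvents with data)
  correlations <- NULL
  if (!is.null(solvent_properties)) {
    dm <- solvent_properties$equal_time_driving_force_J_mol
    keep <- !is.na(dm)
    correlations <- list(
      driving_force_vs_boiling_point =
        correlate(solvent_properties$boiling_point_C[keep], dm[keep]),
      driving_force_vs_dielectric =
        correlate(solvent_properties$dielectric_constant[keep], dm[keep]))
  }
  # stage 4: conformer descriptors
  conformers <- NULL
  if (!is.null(config$trajectory_file)) {
    traj <- read_trajectory(config$trajectory_file,
                            selections = config$selections_file %||% list())
    series <- conformer_state_series(traj,
                                     d_max_A = config$imhb_d_max_A,
                                     angle_min_deg = config$imhb_angle_min_deg)
    conformers <- list(series = series, populations = population_table(series))
  }
  manifest <- list(
    seed = config$seed, method = config$method,
    t_growth_s = config$t_growth_s, n_boot = config$n_boot,
    solute = unclass(config$solute),
    constants = nk_constants,
    imhb_criterion = list(d_max_A = config$imhb_d_max_A,
                          angle_min_deg = config$imhb_angle_min_deg),
    inputs = list(induction_csv = config$induction_csv,
                  trajectory_file = config$trajectory_file))
  bundle <- structure(list(rates = rates, fits = fits,
                           cnt_table = cnt_table,
                           correlations = correlations,
                           conformers = conformers, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Emits `cnt_table.csv`, `rates.csv`, `report.json` (fits, correlations,
#' populations and the manifest) and, when conformer results are present,
#' `conformers.csv` and `populations.csv`.
#'
#' @param bundle A `"report_bundle"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$cnt_table, file.path(dir, "cnt_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$rates, file.path(dir, "rates.csv"),
                   row.names = FALSE)
  json <- list(
    fits = lapply(bundle$fits, function(f)
      f[c("ln_A0", "B", "gamma_mJ_m2", "r_squared", "non_physical")]),
    correlations = bundle$correlations,
    populations = if (!is.null(bundle$conformers))
      list(fractions = bundle$conformers$populations$fractions,
           class_marginal = bundle$conformers$populations$class_marginal,
           imhb_marginal = bundle$conformers$populations$imhb_marginal),
    manifest = bundle$manifest)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(bundle$conformers)) {
    write_conformer_csv(bundle$conformers$series,
                        file.path(dir, "conformers.csv"))
    utils::write.csv(as.data.frame(bundle$conformers$populations$fractions),
                     file.path(dir, "populations.csv"))
  }
  invisible(dir)
}
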
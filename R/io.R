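# CSV readers/writers with strict schema validation. Column names carry
# their units as suffixes (_K, _s, _m3, _A, _deg, _g_per_g); files with
# unexpected or missing columns are rejected with an itemized message.

validate_columns <- function(df, required, optional = character(0),
                             file = "<data>") {
  missing <- setdiff(required, names(df))
  unknown <- setdiff(names(df), c(required, optional))
  msgs <- character(0)
  if (length(missing))
    msgs <- c(msgs, sprintf("missing mandatory column(s): %s",
                            paste(missing, collapse = ", ")))
  if (length(unknown))
    msgs <- c(msgs, sprintf(paste0("unknown column(s): %s (units are ",
                                   "declared by suffix, e.g. temperature_K ",
                                   "in kelvin, t_seconds, vial_volume_m3)"),
                            paste(unknown, collapse = ", ")))
  if (length(msgs))
    stop_domain("schema violation in %s: %s", file,
                paste(msgs, collapse = "; "))
  invisible(df)
}

#' Read a solubility table
#'
#' Schema `solvent, temperature_K, x_star, c_star_g_per_g`; either
#' concentration column may be blank and is derived from the other using
#' the solute and solvent molar masses.
#'
#' @param path CSV path.
#' @param solute A [solute_spec()] used for unit conversion.
#' @param solvents Solvent table with `solvent` and `molar_mass_g_mol`.
#' @return A validated data.frame with both concentration columns filled.
#' @export
read_solubility_csv <- function(path, solute = solute_spec(),
                                solvents = ritonavir_solvent_properties()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_columns(df, c("solvent", "temperature_K"),
                   c("x_star", "c_star_g_per_g"), file = path)
  if (is.null(df$x_star)) df$x_star <- NA_real_
  if (is.null(df$c_star_g_per_g)) df$c_star_g_per_g <- NA_real_
  if (any(is.na(df$x_star) & is.na(df$c_star_g_per_g)))
    stop_domain("schema violation in %s: each row needs x_star or c_star_g_per_g",
                path)
  mm <- solvents$molar_mass_g_mol[match(df$solvent, solvents$solvent)]
  if (any(is.na(mm)))
    stop_domain("unknown solvent(s) in %s: %s", path,
                paste(unique(df$solvent[is.na(mm)]), collapse = ", "))
  fill_c <- is.na(df$c_star_g_per_g)
  df$c_star_g_per_g[fill_c] <- mole_fraction_to_mass_ratio(
    df$x_star[fill_c], solute$molar_mass_g_mol, mm[fill_c])
  fill_x <- is.na(df$x_star)
  df$x_star[fill_x] <- mass_ratio_to_mole_fraction(
    df$c_star_g_per_g[fill_x], solute$molar_mass_g_mol, mm[fill_x])
  if (any(df$temperature_K <= 0 | df$temperature_K > 1000))
    stop_domain("%s: temperature_K out of range; supply kelvin, not celsius",
                path)
  df
}

#' Read a supersaturated-conditions table
#'
#' Schema `solvent, temperature_K, c_g_per_g, S`; `S` may be blank and is
#' then derived from the concentration and a solubility table.
#'
#' @param path CSV path.
#' @param solubility Optional data.frame from [read_solubility_csv()],
#'   required when any `S` is blank.
#' @return A validated data.frame with `S` and `driving_force_J_mol`.
#' @export
read_conditions_csv <- function(path, solubility = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_columns(df, c("solvent", "temperature_K", "c_g_per_g"), "S",
                   file = path)
  if (is.null(df$S)) df$S <- NA_real_
  need <- is.na(df$S)
  if (any(need)) {
    if (is.null(solubility))
      stop_domain("%s: blank S requires a solubility table", path)
    c_star <- solubility$c_star_g_per_g[match(df$solvent[need],
                                              solubility$solvent)]
    df$S[need] <- supersaturation(df$c_g_per_g[need], c_star)
  }
  df$driving_force_J_mol <- driving_force(df$S, df$temperature_K)
  df
}

#' Read a replicate induction-time table
#'
#' Schema `solvent, S, T_K, replicate_id, t_seconds, censored,
#' vial_volume_m3`; rows are grouped by condition into
#' [induction_replicates()] objects.
#'
#' @param path CSV path.
#' @param hold_time_s Hold time used for the censoring bound, seconds.
#' @return A named list of `"induction_replicates"`, one per
#'   (solvent, S) condition, with names `solvent@S`.
#' @export
read_induction_csv <- function(path, hold_time_s = 72000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_columns(df, c("solvent", "S", "T_K", "replicate_id",
                         "t_seconds", "censored", "vial_volume_m3"),
                   file = path)
  if (any(df$censored %in% c(0, 1) == FALSE))
    stop_domain("%s: censored must be 0 or 1", path)
  key <- paste0(df$solvent, "@", format(df$S))
  out <- lapply(split(df, key), function(g) {
    hold <- if (any(g$censored == 1)) max(g$t_seconds[g$censored == 1])
            else hold_time_s
    induction_replicates(
      g$t_seconds, g$censored == 1,
      vial_volume_m3 = g$vial_volume_m3[1], hold_time_s = hold,
      condition = list(solvent = g$solvent[1], S = g$S[1], T_K = g$T_K[1]))
  })
  out
}

#' Write replicate induction times in the standard schema
#'
#' @param replicates A named list of [induction_replicates()] (as from
#'   [gen_induction_times()] or [read_induction_csv()]); conditions must
#'   carry `S` and `T_K`.
#' @param path Output CSV path.
#' @param solvent Solvent name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_induction_csv <- function(replicates, path, solvent = "synthetic") {
  rows <- do.call(rbind, lapply(replicates, function(r) {
    data.frame(solvent = r$condition$solvent %||% solvent,
               S = r$condition$S, T_K = r$condition$T_K,
               replicate_id = seq_along(r$times_s),
               t_seconds = r$times_s,
               censored = as.integer(r$censored),
               vial_volume_m3 = r$vial_volume_m3)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-frame conformer descriptor table
#'
#' Schema `frame, angle_deg, class, imhb, r_gyr_A` (the radius column is
#' omitted when the series carries none).
#'
#' @param series A `"conformer_series"` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conformer_csv <- function(series, path) {
  keep <- intersect(c("frame", "angle_deg", "class", "imhb", "r_gyr_A"),
                    names(series))
  utils::write.csv(series[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
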
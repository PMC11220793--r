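# From replicate induction times to nucleation rates and CNT fits.
#
# Under a constant nucleation rate J in a vial of volume V, the waiting time
# to the first nucleus is exponential with rate J*V; a detection/growth lag
# t_g shifts the observed times, and vials that never nucleate within the
# hold time are right-censored there. The exponential MLE with right
# censoring is closed-form: J = n_events / (V * sum_i (t_i - t_g)).

#' Bundle replicate induction times for one condition
#'
#' @param times_s Observed induction times, seconds; censored entries carry
#'   the hold time.
#' @param censored Logical (or 0/1) vector aligned with `times_s`; `TRUE`
#'   marks vials that had not nucleated when the hold ended.
#' @param vial_volume_m3 Vial solution volume in m^3 (default 1 mL).
#' @param hold_time_s Isothermal hold duration, seconds (default 20 h).
#' @param condition Optional condition record (see
#'   [supersaturated_condition()]).
#' @return A list of class `"induction_replicates"`.
#' @export
induction_replicates <- function(times_s, censored = NULL,
                                 vial_volume_m3 = 1e-6,
                                 hold_time_s = 72000,
                                 condition = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(times_s))
  censored <- as.logical(censored)
  if (length(times_s) != length(censored))
    stop_domain("times and censor flags must have equal length")
  if (any(!is.finite(times_s)) || any(times_s <= 0))
    stop_domain("induction times must be positive")
  if (vial_volume_m3 <= 0) stop_domain("vial volume must be > 0")
  if (any(censored & abs(times_s - hold_time_s) > 1e-6 * hold_time_s))
    stop_domain("censored replicates must carry the hold time")
  structure(list(times_s = as.numeric(times_s), censored = censored,
                 vial_volume_m3 = vial_volume_m3, hold_time_s = hold_time_s,
                 condition = condition),
            class = "induction_replicates")
}

# Coefficient of determination computed directly from residuals, so
# noiseless inputs give exactly 1 without summary.lm's perfect-fit warning.
r_squared_of <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
}

# Closed-form censored-exponential MLE for the nucleation rate.
# With d uncensored observations and total (lag-adjusted) time at risk
# T_tot, the MLE of the exponential rate J*V is d / T_tot.
censored_exp_rate_mle <- function(times_s, censored, t_growth_s) {
  adj <- pmax(times_s - t_growth_s, 0)
  d <- sum(!censored)
  if (d == 0) return(NA_real_)
  d / sum(adj)
}

#' Estimate the nucleation rate from replicate induction times
#'
#' Two estimators are provided. `"probability_fit"` (default) is the
#' maximum-likelihood rate for the induction-probability model
#' `P(t) = 1 - exp(-J V (t - t_g))` with right-censoring at the hold time;
#' for this model the MLE is closed-form, `J = d / (V * sum(t_i - t_g))`
#' with `d` the number of nucleated vials and the sum over all vials.
#' `"mean_inverse"` is the simpler `J = 1 / (mean(t) * V)` over uncensored
#' times only; the two coincide when nothing is censored and `t_g = 0`.
#' Confidence intervals come from a seeded nonparametric bootstrap over
#' replicates (percentile method).
#'
#' @param replicates An [induction_replicates()] object.
#' @param method `"probability_fit"` or `"mean_inverse"`.
#' @param t_growth_s Fixed detection/growth lag subtracted from every
#'   observed time (seconds, default 0).
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 disables).
#' @param conf_level Bootstrap CI coverage (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `"nucleation_rate_estimate"` with elements `J`
#'   (m^-3 s^-1), `ci_low`, `ci_high`, `method`, `n_used`, `n_censored`.
#'   When every replicate is censored, estimation fails with an error
#'   carrying the censoring bound `J < 1 / (V * hold)`.
#' @export
estimate_rate <- function(replicates,
                          method = c("probability_fit", "mean_inverse"),
                          t_growth_s = 0, n_boot = 1000, conf_level = 0.95,
                          seed = 1L) {
  stopifnot(inherits(replicates, "induction_replicates"))
  method <- match.arg(method)
  times <- replicates$times_s
  cens <- replicates$censored
  V <- replicates$vial_volume_m3
  if (all(cens)) {
    bound <- 1 / (V * (replicates$hold_time_s - t_growth_s))
    stop_domain(paste0("all replicates censored: the data only bound the ",
                       "rate, J < %.4g m^-3 s^-1"), bound)
  }
  if (method == "mean_inverse") {
    point <- function(t, cn) {
      u <- pmax(t[!cn] - t_growth_s, .Machine$double.eps)
      1 / (mean(u) * V)
    }
  } else {
    if (sum(!cens) < 1) stop_domain("need at least one uncensored replicate")
    point <- function(t, cn) {
      rate <- censored_exp_rate_mle(t, cn, t_growth_s)
      rate / V
    }
  }
  J <- point(times, cens)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    n <- length(times)
    draws <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(cens[idx])) return(NA_real_)
      point(times[idx], cens[idx])
    }, numeric(1))
    draws <- draws[is.finite(draws)]
    if (length(draws) > 10) {
      a <- (1 - conf_level) / 2
      ci <- unname(stats::quantile(draws, c(a, 1 - a)))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(J = J, ci_low = min(ci[1], J, na.rm = TRUE),
                 ci_high = max(ci[2], J, na.rm = TRUE), method = method,
                 n_used = sum(!cens), n_censored = sum(cens)),
            class = "nucleation_rate_estimate")
}

#' Log-likelihood of a censored-exponential induction model
#'
#' Density terms for nucleated vials and survival terms for censored ones,
#' under `P(t) = 1 - exp(-J V (t - t_g))`. Exposed mainly so the likelihood
#' surface can be inspected or profiled over `t_g`.
#'
#' @inheritParams estimate_rate
#' @param J Candidate nucleation rate, m^-3 s^-1.
#' @return Log-likelihood value.
#' @export
induction_loglik <- function(replicates, J, t_growth_s = 0) {
  stopifnot(inherits(replicates, "induction_replicates"))
  rate <- J * replicates$vial_volume_m3
  adj <- pmax(replicates$times_s - t_growth_s, 0)
  cens <- replicates$censored
  # density terms for nucleated vials, survival terms for censored ones
  sum(log(rate) - rate * adj[!cens]) - rate * sum(adj[cens])
}

#' Fit the CNT rate law to supersaturation-rate pairs
#'
#' Ordinary least squares of `ln(J / S)` on `1 / ln^2 S`: the intercept is
#' `ln A0` and the negative slope is the thermodynamic parameter B. The
#' interfacial energy is then recovered from B and per-point critical
#' cluster properties derived.
#'
#' @param S Supersaturations (> 1), length >= 2 with distinct values.
#' @param J Nucleation rates, m^-3 s^-1, aligned with `S`.
#' @param T_K Temperature, kelvin.
#' @param v_A3 Molecular volume, cubic angstrom.
#' @return A list of class `"cnt_fit"` with `ln_A0`, `B`, `gamma_mJ_m2`,
#'   `r_squared`, `non_physical` (`TRUE` when the fitted slope is positive,
#'   i.e. B < 0), `points` (the input pairs), and `derived` (per-point
#'   critical-cluster table, `NULL` for non-physical fits).
#' @examples
#' S <- c(3, 4, 5, 6)
#' fit_cnt(S, nucleation_rate(5, S, 10), T_K = 283.15, v_A3 = 903)
#' @export
fit_cnt <- function(S, J, T_K, v_A3) {
  if (length(S) != length(J)) stop_domain("S and J must be aligned")
  if (length(unique(S)) < 2)
    stop_domain("need at least 2 distinct supersaturations")
  if (any(S <= 1)) stop_domain("all S must exceed 1")
  if (any(J <= 0)) stop_domain("all rates must be positive")
  x <- 1 / log(S)^2
  y <- log(J / S)
  fit <- stats::lm(y ~ x)
  ln_A0 <- unname(stats::coef(fit)[1])
  B <- -unname(stats::coef(fit)[2])
  r2 <- r_squared_of(fit, y)
  non_physical <- B < 0
  derived <- NULL
  if (!non_physical) {
    params <- cnt_parameters(ln_A0 = ln_A0, B = B, v_A3 = v_A3, T_K = T_K)
    derived <- if (B > 0) critical_cluster(params, S) else NULL
    gamma <- params$gamma_mJ_m2
  } else {
    gamma <- NA_real_
  }
  structure(list(ln_A0 = ln_A0, B = B, gamma_mJ_m2 = gamma,
                 r_squared = r2, non_physical = non_physical,
                 points = data.frame(S = S, J = J),
                 T_K = T_K, v_A3 = v_A3, derived = derived),
            class = "cnt_fit")
}

#' @export
print.cnt_fit <- function(x, ...) {
  cat("CNT rate-law fit: ln A0 =", format(x$ln_A0, digits = 4),
      " B =", format(x$B, digits = 4),
      " gamma =", format(x$gamma_mJ_m2, digits = 4), "mJ m^-2",
      " R^2 =", format(x$r_squared, digits = 4), "\n")
  if (x$non_physical) cat("  [non-physical: fitted B < 0]\n")
  invisible(x)
}

#' Exponential fit of induction time against driving force
#'
#' Least squares of `ln t` on the driving force: `ln t = a + b * dmu`. The
#' slope is expected negative (a higher driving force shortens the
#' induction time), giving the exponential curves used to compare solvents
#' at a common induction time.
#'
#' @param times_s Induction times, seconds; must be positive.
#' @param driving_forces_J_mol Driving forces `RT ln S`, J mol^-1, aligned.
#' @return A list of class `"exp_time_fit"` with `a` (ln seconds), `b`
#'   ((J mol^-1)^-1) and `r_squared`.
#' @export
fit_exponential_time <- function(times_s, driving_forces_J_mol) {
  if (length(times_s) != length(driving_forces_J_mol))
    stop_domain("inputs must be aligned")
  if (length(times_s) < 2 || length(unique(driving_forces_J_mol)) < 2)
    stop_domain("need >= 2 points with distinct driving forces")
  if (any(times_s <= 0)) stop_domain("times must be positive")
  y <- log(times_s)
  fit <- stats::lm(y ~ driving_forces_J_mol)
  r2 <- r_squared_of(fit, y)
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]), r_squared = r2),
            class = "exp_time_fit")
}

#' Driving force at a common induction time
#'
#' Inverts an [fit_exponential_time()] fit at a target induction time:
#' `dmu* = (ln t* - a) / b`. Used to rank solvents by the driving force
#' they need to nucleate within the same time.
#'
#' @param fit An `"exp_time_fit"` object.
#' @param t_star_s Target induction time, seconds.
#' @return Driving force in J mol^-1.
#' @export
equal_time_driving_force <- function(fit, t_star_s) {
  stopifnot(inherits(fit, "exp_time_fit"))
  if (fit$b == 0) stop_domain("flat fit: no driving force solves ln t* = a")
  if (t_star_s <= 0) stop_domain("target time must be positive")
  (log(t_star_s) - fit$a) / fit$b
}

#' Interpolate the nucleation rate at a target supersaturation
#'
#' Fits `ln J` linearly in S (an exponential rate-supersaturation curve)
#' and evaluates it at `S_star`; flags extrapolation outside the data
#' range.
#'
#' @param S,J Observed supersaturation-rate pairs (J in m^-3 s^-1).
#' @param S_star Supersaturation at which to evaluate.
#' @return A list with `J` (m^-3 s^-1), `extrapolated` (logical), and the
#'   fit coefficients `intercept`, `slope` on the ln J scale.
#' @export
interpolate_rate_at_S <- function(S, J, S_star) {
  if (length(S) < 2 || length(unique(S)) < 2)
    stop_domain("need >= 2 distinct supersaturations")
  if (any(J <= 0)) stop_domain("rates must be positive")
  fit <- stats::lm(log(J) ~ S)
  co <- unname(stats::coef(fit))
  list(J = exp(co[1] + co[2] * S_star),
       extrapolated = S_star < min(S) | S_star > max(S),
       intercept = co[1], slope = co[2])
}

#' Simple linear correlation between two solvent-level quantities
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination, for property-vs-property comparisons (driving force
#' against boiling point or dielectric constant, solvation free energy
#' against log solubility, and the like).
#'
#' @param x,y Equal-length numeric vectors, `x` not constant.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_domain("need two aligned vectors of length >= 2")
  if (stats::var(x) == 0) stop_domain("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else r_squared_of(fit, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
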
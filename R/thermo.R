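# Gas constant in kJ mol^-1 K^-1; energies are handled in kJ/mol throughout.
GAS_CONSTANT_KJ <- 8.3145e-3
# Reference temperature (K) for lattice-energy <-> sublimation conversions
# performed at constant temperature.
REFERENCE_T_K <- 298

#' Convert kcal/mol to kJ/mol
#'
#' @param x Energy in kcal/mol.
#' @return Energy in kJ/mol (1 kcal = 4.184 kJ).
#' @export
kcal_to_kj <- function(x) x * 4.184

#' Fit the van't Hoff line to temperature-dependent solubility data
#'
#' Ordinary least squares of log10 solubility on reciprocal absolute
#' temperature. Under the assumption that the standard enthalpy of solution
#' is constant over the temperature range,
#' `log10 S = -dH_sol / (ln(10) R T) + constant`, so the standard enthalpy
#' of solution is recovered from the slope as `dH_sol = -slope * ln(10) * R`
#' with R the molar gas constant (kJ/(mol K)).
#'
#' @param temperature Temperatures in Kelvin (>= 2 distinct values, all > 0).
#' @param log10_solubility log10 solubility (molar) at each temperature.
#' @return An object of class `vant_hoff_fit`: `slope`, `intercept`,
#'   `dH_sol` (kJ/mol), `r_squared_of_line`, `n_points`.
#' @examples
#' tt <- c(283.15, 298.15, 313.15)
#' fit <- fit_vant_hoff(tt, -25 / (log(10) * 8.3145e-3 * tt) - 3)
#' fit$dH_sol # 25 kJ/mol
#' @export
fit_vant_hoff <- function(temperature, log10_solubility) {
  stopifnot(length(temperature) == length(log10_solubility))
  if (length(temperature) < 2L) stop("need at least 2 points for a van't Hoff fit")
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperatures must be positive Kelvin")
  }
  if (length(unique(temperature)) < 2L) {
    stop("need at least 2 distinct temperatures")
  }
  x <- 1 / temperature
  fit <- stats::lm.fit(cbind(1, x), log10_solubility)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log10_solubility - mean(log10_solubility))^2)
  structure(
    list(slope = slope,
         intercept = intercept,
         dH_sol = -slope * log(10) * GAS_CONSTANT_KJ,
         r_squared_of_line = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_points = length(temperature)),
    class = "vant_hoff_fit")
}

#' Predict log10 solubility at a temperature from a van't Hoff fit
#'
#' Interpolates or extrapolates solubility along the fitted line:
#' `-dH_sol / (ln(10) R T) + intercept`.
#'
#' @param fit A `vant_hoff_fit`.
#' @param temperature Temperature(s) in Kelvin, > 0.
#' @return Predicted log10 solubility.
#' @export
predict_log_solubility <- function(fit, temperature) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperatures must be positive Kelvin")
  }
  -fit$dH_sol / (log(10) * GAS_CONSTANT_KJ * temperature) + fit$intercept
}

#' Sublimation enthalpy from lattice energy (and back)
#'
#' Under the standard approximation `dH_sub = -E_latt - 2 R T`, with
#' energies in kJ/mol and T in Kelvin.
#'
#' @param e_latt Lattice energy in kJ/mol.
#' @param temperature Temperature in Kelvin (default 298 K).
#' @return Sublimation enthalpy in kJ/mol.
#' @export
sublimation_from_lattice <- function(e_latt, temperature = REFERENCE_T_K) {
  stopifnot(all(temperature > 0))
  -e_latt - 2 * GAS_CONSTANT_KJ * temperature
}

#' @rdname sublimation_from_lattice
#' @param dH_sub Sublimation enthalpy in kJ/mol.
#' @export
lattice_from_sublimation <- function(dH_sub, temperature = REFERENCE_T_K) {
  stopifnot(all(temperature > 0))
  -dH_sub - 2 * GAS_CONSTANT_KJ * temperature
}

#' Complete or check a set of fusion-related thermodynamic terms
#'
#' Uses the fusion relation `Tm = dH_fus / dS_fus`, the decomposition
#' `dH_fus = dH_sub + dH_cond`, and `dH_sub = -E_latt - 2 R T` (at
#' `temperature`) to fill in derivable fields from a partial set, iterating
#' until no more can be derived. Over-determined inputs are checked for
#' consistency to `tol` kJ/mol (K for Tm).
#'
#' @param terms Named list with any of `Tm`, `dH_fus`, `dS_fus`, `dH_sub`,
#'   `dH_cond`, `E_latt` (kJ/mol, K, kJ/(mol K)).
#' @param temperature Temperature (K) at which the lattice relation holds.
#' @param tol Consistency tolerance.
#' @return List with `terms` (completed), `complete` (logical: all six
#'   fields known), and `violations` (character vector, empty if consistent).
#' @export
fusion_consistency <- function(terms, temperature = REFERENCE_T_K,
                               tol = 1e-6) {
  fields <- c("Tm", "dH_fus", "dS_fus", "dH_sub", "dH_cond", "E_latt")
  t <- stats::setNames(as.list(rep(NA_real_, length(fields))), fields)
  t[names(terms)] <- terms
  known <- function(f) !is.na(t[[f]])
  violations <- character(0)
  # each rule: (target, needed fields, compute); applied to fixed point
  rules <- list(
    list("Tm", c("dH_fus", "dS_fus"), function() t$dH_fus / t$dS_fus),
    list("dH_fus", c("Tm", "dS_fus"), function() t$Tm * t$dS_fus),
    list("dS_fus", c("Tm", "dH_fus"), function() t$dH_fus / t$Tm),
    list("dH_fus", c("dH_sub", "dH_cond"), function() t$dH_sub + t$dH_cond),
    list("dH_sub", c("dH_fus", "dH_cond"), function() t$dH_fus - t$dH_cond),
    list("dH_cond", c("dH_fus", "dH_sub"), function() t$dH_fus - t$dH_sub),
    list("dH_sub", "E_latt",
         function() sublimation_from_lattice(t$E_latt, temperature)),
    list("E_latt", "dH_sub",
         function() lattice_from_sublimation(t$dH_sub, temperature)))
  repeat {
    changed <- FALSE
    for (r in rules) {
      if (all(vapply(r[[2]], known, logical(1)))) {
        v <- r[[3]]()
        if (!known(r[[1]])) {
          t[[r[[1]]]] <- v
          changed <- TRUE
        } else if (abs(t[[r[[1]]]] - v) > tol) {
          violations <- c(violations, sprintf(
            "%s inconsistent: stated %.6g vs derived %.6g",
            r[[1]], t[[r[[1]]]], v))
        }
      }
    }
    if (!changed) break
  }
  list(terms = t,
       complete = all(vapply(fields, known, logical(1))),
       violations = unique(violations))
}

#' Pearson correlation of lattice energy against melting point
#'
#' Computes the Pearson correlation coefficient from the textbook covariance
#' formula and a one-tail p value: the probability, under the
#' zero-correlation null, of a correlation as negative as that observed
#' (lower tail of the t distribution with n - 2 degrees of freedom).
#'
#' @param e_latt Lattice energies (kJ/mol).
#' @param melting_point Melting points (K), same length.
#' @return List with `r`, `one_tail_p` and `n`.
#' @export
correlate_lattice_melting <- function(e_latt, melting_point) {
  stopifnot(length(e_latt) == length(melting_point),
            all(is.finite(e_latt)), all(is.finite(melting_point)))
  n <- length(e_latt)
  if (n < 3L) stop("need at least 3 pairs")
  sx <- stats::sd(e_latt)
  sy <- stats::sd(melting_point)
  if (sx == 0 || sy == 0) stop("zero variance in one of the variables")
  r <- stats::cov(e_latt, melting_point) / (sx * sy)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, one_tail_p = stats::pt(tstat, df = n - 2), n = n)
}

#' Van't Hoff fits for every material in a solubility dataset
#'
#' Fits the van't Hoff line separately to each material with at least
#' `min_points` distinct temperatures, exposing the distribution of fitted
#' standard enthalpies of solution and per-material line r-squared values.
#'
#' @param dataset A `qspr_dataset` with endpoint kind `"solubility"`.
#' @param min_points Minimum temperature count per material (default 2).
#' @return data.frame: `material_key`, `n_points`, `dH_sol`, `intercept`,
#'   `r_squared_of_line`.
#' @export
vant_hoff_by_material <- function(dataset, min_points = 2L) {
  stopifnot(inherits(dataset, "qspr_dataset"),
            dataset$endpoint_kind == "solubility")
  inst <- dataset$instances
  keys <- unique(inst$material_key)
  rows <- lapply(keys, function(k) {
    sub <- inst[inst$material_key == k, ]
    if (length(unique(sub$temperature)) < min_points) return(NULL)
    fit <- fit_vant_hoff(sub$temperature, sub$endpoint)
    data.frame(material_key = k, n_points = fit$n_points,
               dH_sol = fit$dH_sol, intercept = fit$intercept,
               r_squared_of_line = fit$r_squared_of_line,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
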
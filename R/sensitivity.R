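#' Sensitivity of mutual information to execution-variable perturbations
#'
#' Quantifies how fragile a strategy's predictability is: each of frequency,
#' amplitude and initial ball angle is perturbed by plus and minus 10% of
#' its standard map-domain range (0.04 Hz, 3.6 cm, pi/10 rad; the initial
#' angular velocity is left unperturbed since its influence on the measures
#' is minor), the mutual information is recomputed for each perturbed
#' strategy, and the sensitivity is the largest absolute MI deviation
#' expressed in units of 10% of the map's MI range:
#' `S = max |MI_pert - MI| / (0.1 mi_range)`.
#' Values above 1 simply mean the MI deviation exceeds 10% of the map range.
#'
#' @param s A [strategy()], normally inside [map_domain()].
#' @param params [model_params()].
#' @param mi_range Span of MI over the evaluated result-space map (nat); use
#'   the range of the map's `mi` surface.
#' @param duration,rate,force_model Simulation settings, as in
#'   [strategy_measures()].
#' @param domain Execution-variable ranges, see [map_domain()].
#' @return Dimensionless sensitivity (>= 0), with attribute `"deviations"`
#'   naming the absolute MI change per perturbation. Perturbations that
#'   leave the simulable domain (non-positive amplitude or frequency) are
#'   skipped with a warning.
#' @export
mi_sensitivity <- function(s, params = model_params(), mi_range,
                           duration = 45, rate = 120,
                           force_model = "rendered", domain = map_domain()) {
  if (!is.finite(mi_range) || mi_range <= 0) stop("mi_range must be > 0")
  base_tr <- simulate_strategy(s, params, duration, rate, force_model)
  mi0 <- mutual_information(base_tr$force, base_tr$phase)
  steps <- list(
    frequency = 0.1 * diff(domain$frequency),
    amplitude_pp = 0.1 * diff(domain$amplitude_pp),
    theta0 = 0.1 * diff(domain$theta0))
  dev <- c()
  for (field in names(steps)) {
    for (sgn in c(-1, 1)) {
      cand <- unclass(s)
      cand[[field]] <- cand[[field]] + sgn * steps[[field]]
      nm <- sprintf("%s%+d", field, sgn)
      if (cand$amplitude_pp < 0 || cand$frequency <= 0) {
        warning(sprintf("perturbation %s leaves the simulable domain; skipped", nm))
        next
      }
      sp <- strategy(cand$amplitude_pp, cand$frequency, cand$theta0, cand$omega0)
      tr <- tryCatch(simulate_strategy(sp, params, duration, rate, force_model),
                     error = function(e) {
                       warning(sprintf("perturbation %s failed: %s", nm,
                                       conditionMessage(e)))
                       NULL
                     })
      if (is.null(tr)) next
      dev[nm] <- abs(mutual_information(tr$force, tr$phase) - mi0)
    }
  }
  if (!length(dev)) stop("no perturbation could be evaluated")
  structure(max(dev) / (0.1 * mi_range), deviations = dev, mi = mi0)
}
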
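#' Shipped reference scenarios
#'
#' Named synthetic scenarios whose planted effect sizes match the published
#' functional observations the package's estimators are designed to recover:
#'
#' \describe{
#'   \item{`vecad_turnover_frap`}{VE-cadherin FRAP turnover at adherens
#'     junctions under receptor knockdown: a pair of [frap_scenario()]s
#'     (control mobile fraction 0.8; knockdown 0.504, a 37% reduction),
#'     24 cells per condition, 2 pre-bleach and 50 post-bleach frames at
#'     1.4 s.}
#'   \item{`vecad_internalization`}{surface-biotinylation capture-ELISA of
#'     VE-cadherin endocytosis under receptor knockdown: an
#'     [assay_scenario()] with control internalized fraction 0.30 and
#'     knockdown 0.222 (a 26% reduction).}
#'   \item{`miniwars_nrp1_uptake`}{NRP1 endocytosis under mini-WARS
#'     overexpression: control fraction 0.40, treated 0.324 (19% reduction).}
#'   \item{`miniwars_vecad_uptake`}{VE-cadherin endocytosis under mini-WARS
#'     overexpression: control fraction 0.30, treated 0.246 (18% reduction).}
#' }
#'
#' Absolute levels the source experiments did not print (control mobile
#' fraction, bleach depth, time constant, OD scales, noise) are fixed,
#' field-plausible defaults; only the planted percent reductions are the
#' published effects.
#'
#' @param name scenario name (see above).
#' @param seed integer seed; condition-level substreams are derived from it.
#' @return for `vecad_turnover_frap`, a list with `ctrl` and `treat`
#'   [frap_scenario()]s; otherwise a single [assay_scenario()].
#' @export
reference_scenario <- function(name = c("vecad_turnover_frap",
                                        "vecad_internalization",
                                        "miniwars_nrp1_uptake",
                                        "miniwars_vecad_uptake"),
                               seed = 1L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  switch(name,
    vecad_turnover_frap = list(
      ctrl = frap_scenario(mobile_fraction = 0.8, tau_s = 12,
                           bleach_floor = 0.2, noise_sd = 0.05,
                           n_cells = 24L, seed = mix_seed(seed, 1)),
      treat = frap_scenario(mobile_fraction = 0.8 * (1 - 0.37), tau_s = 12,
                            bleach_floor = 0.2, noise_sd = 0.05,
                            n_cells = 24L, seed = mix_seed(seed, 2))),
    vecad_internalization = assay_scenario(
      internalized_fraction_ctrl = 0.30,
      internalized_fraction_treat = 0.30 * (1 - 0.26),
      surface_signal = 1.0, background_od = 0.05, noise_cv = 0.05,
      n_replicates = 3L, seed = seed),
    miniwars_nrp1_uptake = assay_scenario(
      internalized_fraction_ctrl = 0.40,
      internalized_fraction_treat = 0.40 * (1 - 0.19),
      surface_signal = 1.0, background_od = 0.05, noise_cv = 0.05,
      n_replicates = 3L, seed = seed),
    miniwars_vecad_uptake = assay_scenario(
      internalized_fraction_ctrl = 0.30,
      internalized_fraction_treat = 0.30 * (1 - 0.18),
      surface_signal = 1.0, background_od = 0.05, noise_cv = 0.05,
      n_replicates = 3L, seed = seed))
}

#' Estimate the FRAP mobile-fraction reduction of a scenario pair
#'
#' Simulates both conditions, estimates per-cell mobile fractions
#' ([normalize_frap()] anchoring + [mobile_fraction()]), averages per
#' condition and returns the percent reduction with its delta-method SE.
#'
#' @param scenarios list with `ctrl` and `treat` [frap_scenario()]s, e.g.
#'   `reference_scenario("vecad_turnover_frap")`.
#' @param ... passed to [mobile_fraction()] via [fit_frap()].
#' @return list with `percent_change`, `se`, and the two `frap_fit`s.
#' @export
estimate_frap_reduction <- function(scenarios, ...) {
  fit_c <- fit_frap(simulate_frap(scenarios$ctrl), ...)
  fit_t <- fit_frap(simulate_frap(scenarios$treat), ...)
  pc <- percent_change(fit_c$mean, fit_t$mean, fit_c$sem, fit_t$sem)
  c(pc, list(ctrl = fit_c, treat = fit_t))
}

#' Estimate the internalization reduction of an assay scenario
#'
#' Simulates the paired capture-ELISA plates, quantifies
#' [internalization_percent()] per condition and returns the percent
#' reduction with its delta-method SE.
#'
#' @param scenario an [assay_scenario()].
#' @return list with `percent_change`, `se`, and the per-condition
#'   internalization estimates.
#' @export
estimate_internalization_reduction <- function(scenario) {
  plate <- simulate_assays(scenario)$elisa
  est_c <- internalization_percent(plate, "ctrl")
  est_t <- internalization_percent(plate, "treat")
  pc <- percent_change(est_c$percent, est_t$percent, est_c$se, est_t$se)
  c(pc, list(ctrl = est_c, treat = est_t))
}
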
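#' Scenario for a synthetic AP-MS pull-down experiment
#'
#' Describes the generative model of [simulate_apms()]: log-normal background
#' intensities (normal on the log2 scale), planted interactors enriched over
#' the unlabeled control by a fixed log2 fold change in their compartment(s),
#' replicate-level noise, and intensity-dependent (missing-not-at-random)
#' dropout following a logistic detection curve.
#'
#' The default design mirrors a three-group pull-down: a surface-labeled group
#' (internalization blocked at 4 degrees C), an endosome-containing group
#' (brief 37 degrees C chase), and an unlabeled control, each with four
#' biological replicates. Background binders appear at full intensity in every
#' group, including the control (non-specific bead binding); planted
#' interactors sit `planted_log2fc` log2 units above their own control level
#' in their compartment(s).
#'
#' Dropout: a cell with true log2 intensity `x` is observed with probability
#' `plogis(dropout_slope * (x - dropout_midpoint))`. The defaults are
#' calibrated so roughly 15% of control-channel cells are missing under the
#' default background distribution, making left-censored imputation the
#' approximately correct downstream model.
#'
#' @param n_background number of background (non-interactor) proteins.
#' @param n_planted_surface,n_planted_endosomal,n_planted_shared numbers of
#'   planted true interactors enriched in the surface group only, the
#'   endosomal group only, or both.
#' @param planted_log2fc log2 enrichment of planted proteins over control.
#' @param base_log2_mean,base_log2_sd mean and SD of protein-level baseline
#'   abundance on the log2 scale.
#' @param noise_sd replicate-level log2 noise SD (> 0).
#' @param dropout_midpoint,dropout_slope logistic detection-probability
#'   parameters versus log2 intensity; `dropout_slope = Inf` disables dropout
#'   above the midpoint. Set `dropout_slope = 0` for no dropout at all
#'   (detection probability 1 is obtained with `dropout_midpoint = -Inf`).
#' @param n_replicates biological replicates per group (>= 2).
#' @param seed RNG seed.
#'
#' @return an object of class `apms_scenario`.
#' @export
apms_scenario <- function(n_background = 2000,
                          n_planted_surface = 10,
                          n_planted_endosomal = 10,
                          n_planted_shared = 10,
                          planted_log2fc = 2,
                          base_log2_mean = 25,
                          base_log2_sd = 2,
                          noise_sd = 0.3,
                          dropout_midpoint = 22.35,
                          dropout_slope = 1.1,
                          n_replicates = 4,
                          seed = 1L) {
  s <- list(n_background = n_background,
            n_planted_surface = n_planted_surface,
            n_planted_endosomal = n_planted_endosomal,
            n_planted_shared = n_planted_shared,
            planted_log2fc = planted_log2fc,
            base_log2_mean = base_log2_mean,
            base_log2_sd = base_log2_sd,
            noise_sd = noise_sd,
            dropout_midpoint = dropout_midpoint,
            dropout_slope = dropout_slope,
            n_replicates = as.integer(n_replicates),
            seed = as.integer(seed))
  counts <- c(s$n_background, s$n_planted_surface, s$n_planted_endosomal,
              s$n_planted_shared)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("protein counts must be non-negative integers")
  num <- c(s$planted_log2fc, s$base_log2_mean, s$base_log2_sd, s$noise_sd,
           s$dropout_slope)
  if (any(!is.finite(num)))
    stop("scenario parameters must be finite")
  if (!is.finite(s$dropout_midpoint) && s$dropout_midpoint != -Inf)
    stop("dropout_midpoint must be finite or -Inf")
  if (s$noise_sd <= 0) stop("noise_sd must be > 0")
  if (s$base_log2_sd < 0) stop("base_log2_sd must be >= 0")
  if (s$n_replicates < 2) stop("n_replicates must be >= 2")
  structure(s, class = "apms_scenario")
}

#' Scenario for synthetic FRAP recovery traces
#'
#' Describes the generative model of [simulate_frap()]: pre-bleach frames at
#' 1, bleach frames and the immediate post-bleach floor at `bleach_floor`,
#' then single-exponential recovery
#' `F(t) = b + Mf * (1 - b) * (1 - exp(-t / tau))` with additive Gaussian
#' noise, where `b` is the bleach floor and `Mf` the mobile fraction. The
#' default frame design is 2 pre-bleach, 2 bleach and 50 post-bleach frames
#' acquired every 1.4 s.
#'
#' @param mobile_fraction true plateau fraction in `[0, 1]`.
#' @param tau_s recovery time constant in seconds (> 0).
#' @param bleach_floor post-bleach fluorescence as a fraction of pre-bleach,
#'   in `[0, 1)`.
#' @param n_pre,n_bleach,n_post frame counts (defaults 2, 2, 50).
#' @param frame_interval_s seconds between frames (default 1.4).
#' @param noise_sd additive Gaussian noise SD on the normalized intensity.
#' @param n_cells number of traces (cells).
#' @param seed RNG seed.
#' @return an object of class `frap_scenario`.
#' @export
frap_scenario <- function(mobile_fraction = 0.8,
                          tau_s = 12,
                          bleach_floor = 0.2,
                          n_pre = 2L, n_bleach = 2L, n_post = 50L,
                          frame_interval_s = 1.4,
                          noise_sd = 0.05,
                          n_cells = 24L,
                          seed = 1L) {
  s <- list(mobile_fraction = mobile_fraction, tau_s = tau_s,
            bleach_floor = bleach_floor,
            n_pre = as.integer(n_pre), n_bleach = as.integer(n_bleach),
            n_post = as.integer(n_post),
            frame_interval_s = frame_interval_s,
            noise_sd = noise_sd, n_cells = as.integer(n_cells),
            seed = as.integer(seed))
  if (any(!is.finite(unlist(s[c("mobile_fraction", "tau_s", "bleach_floor",
                                "frame_interval_s", "noise_sd")]))))
    stop("scenario parameters must be finite")
  if (s$mobile_fraction < 0 || s$mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (s$tau_s <= 0) stop("tau_s must be > 0")
  if (s$bleach_floor < 0 || s$bleach_floor >= 1)
    stop("bleach_floor must lie in [0, 1)")
  if (s$n_post < 2) stop("n_post must be >= 2 (mobile fraction undefined)")
  if (s$n_pre < 1) stop("n_pre must be >= 1")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (s$n_cells < 1) stop("n_cells must be >= 1")
  structure(s, class = "frap_scenario")
}

#' Scenario for paired internalization-ELISA and permeability readouts
#'
#' Describes the generative model of [simulate_assays()]. The capture-ELISA
#' side mimics a surface-biotinylation internalization assay: total-label
#' wells read `surface_signal + background_od`, internalized wells read
#' `surface_signal * internalized_fraction + background_od` (surface biotin
#' stripped before lysis), and stripped-control wells read `background_od`;
#' all optical densities carry multiplicative log-normal noise of coefficient
#' of variation `noise_cv`. The permeability side mimics a transwell tracer
#' assay: the basal-compartment signal at time `t` is
#' `apical_input * flux_rate * t`, noised, sampled at `sample_times_h`.
#'
#' @param internalized_fraction_ctrl,internalized_fraction_treat true
#'   internalized fractions of the surface pool per condition, in `[0, 1]`.
#' @param surface_signal total labeled OD (arbitrary units).
#' @param background_od strip-control OD.
#' @param flux_rate_ctrl,flux_rate_treat fraction of apical tracer transferred
#'   per hour, per condition.
#' @param sample_times_h strictly increasing measurement times in hours.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param n_replicates replicate wells / inserts per condition (default 3).
#' @param seed RNG seed.
#' @return an object of class `assay_scenario`.
#' @export
assay_scenario <- function(internalized_fraction_ctrl = 0.3,
                           internalized_fraction_treat = 0.3,
                           surface_signal = 1.0,
                           background_od = 0.05,
                           flux_rate_ctrl = 0.05,
                           flux_rate_treat = 0.05,
                           sample_times_h = c(2, 4, 6),
                           noise_cv = 0.05,
                           n_replicates = 3L,
                           seed = 1L) {
  s <- list(internalized_fraction_ctrl = internalized_fraction_ctrl,
            internalized_fraction_treat = internalized_fraction_treat,
            surface_signal = surface_signal,
            background_od = background_od,
            flux_rate_ctrl = flux_rate_ctrl,
            flux_rate_treat = flux_rate_treat,
            sample_times_h = as.numeric(sample_times_h),
            noise_cv = noise_cv,
            n_replicates = as.integer(n_replicates),
            seed = as.integer(seed))
  fr <- c(s$internalized_fraction_ctrl, s$internalized_fraction_treat)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("internalized fractions must lie in [0, 1]")
  if (!all(is.finite(s$sample_times_h)) ||
      any(diff(s$sample_times_h) <= 0))
    stop("sample_times_h must be strictly increasing")
  if (!is.finite(s$noise_cv) || s$noise_cv < 0)
    stop("noise_cv must be >= 0")
  if (s$surface_signal <= 0) stop("surface_signal must be > 0")
  if (s$background_od < 0) stop("background_od must be >= 0")
  if (s$n_replicates < 1) stop("n_replicates must be >= 1")
  structure(s, class = "assay_scenario")
}

#' Read a scenario from a YAML file
#'
#' @param path YAML file with a top-level `type` field
#'   (`apms`, `frap` or `assay`) and scenario parameters.
#' @return a scenario object of the corresponding class.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  type <- y$type
  if (is.null(type)) stop("scenario YAML must carry a 'type' field")
  y$type <- NULL
  ctor <- switch(type,
                 apms = apms_scenario,
                 frap = frap_scenario,
                 assay = assay_scenario,
                 stop("unknown scenario type '", type, "'"))
  do.call(ctor, y)
}

#' Write a scenario to a YAML file
#'
#' @param scenario a scenario object.
#' @param path output path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  type <- sub("_scenario$", "", class(scenario)[1])
  yaml::write_yaml(c(list(type = type), unclass(scenario)), path)
  invisible(path)
}

# deterministic per-unit substream seed: mixing keeps streams stable when
# more units are added, and the result stays below 2^31 - 1
mix_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807 + 12345) %%
               2147483647)
}
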
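#' Percent of the surface pool internalized, from a capture-ELISA plate
#'
#' Background-corrected ratio of internalized to total surface label:
#' `% = (mean internalized OD - mean background OD) /
#' (mean total OD - mean background OD) * 100`. The estimate is invariant to
#' the OD unit. The standard error is propagated from the per-well-type
#' replicate SEMs by the delta method.
#'
#' @param plate data frame with columns `condition`, `well_type`
#'   (`internalized`, `total`, `background`), `od` (and optionally
#'   `replicate`), as produced by [simulate_assays()].
#' @param condition which condition to quantify.
#' @return list with `percent`, `se`, and the mean ODs used.
#' @export
internalization_percent <- function(plate, condition) {
  d <- plate[plate$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("condition '", condition, "' absent from plate")
  stat <- function(type) {
    od <- d$od[d$well_type == type]
    if (length(od) == 0) stop("no '", type, "' wells for condition '",
                              condition, "'")
    c(mean = mean(od),
      sem = if (length(od) > 1) stats::sd(od) / sqrt(length(od)) else 0)
  }
  mi <- stat("internalized"); mt <- stat("total"); mb <- stat("background")
  denom <- mt["mean"] - mb["mean"]
  if (denom <= 0) stop("total OD must exceed background OD")
  num <- mi["mean"] - mb["mean"]
  pct <- 100 * num / denom
  # delta method on f(mi, mt, mb) = (mi - mb) / (mt - mb)
  d_mi <- 1 / denom
  d_mt <- -num / denom^2
  d_mb <- (num - denom) / denom^2
  se <- 100 * sqrt(d_mi^2 * mi["sem"]^2 + d_mt^2 * mt["sem"]^2 +
                     d_mb^2 * mb["sem"]^2)
  list(percent = unname(pct), se = unname(se),
       mean_od = c(internalized = unname(mi["mean"]),
                   total = unname(mt["mean"]),
                   background = unname(mb["mean"])))
}

#' Transported fraction and flux slope from a permeability time course
#'
#' Per timepoint, the transported fraction is the basal-compartment signal
#' divided by the apical input; the summary slope (fraction per hour) is a
#' least-squares fit through the origin over all timepoints and replicates.
#' When the sequential sampling removed a known aliquot from a known basal
#' volume at each earlier timepoint, the depleted tracer is added back
#' before computing fractions.
#'
#' @param tc data frame with columns `time_h`, `basal_signal`,
#'   `apical_input` (and optionally `replicate`), one condition.
#' @param aliquot_volume_ul,basal_volume_ul optional sampling metadata; when
#'   both are given, signal at time k is corrected by
#'   `+ (aliquot / basal volume) * sum of earlier signals` within each
#'   replicate.
#' @return list with `fractions` (data frame `time_h`, `fraction`, averaged
#'   over replicates), `slope_per_h`, `slope_se`.
#' @export
permeability_flux <- function(tc, aliquot_volume_ul = NULL,
                              basal_volume_ul = NULL) {
  need <- c("time_h", "basal_signal", "apical_input")
  if (!all(need %in% names(tc)))
    stop("time course needs columns: ", paste(need, collapse = ", "))
  if (length(unique(tc$time_h)) < 2) stop("need >= 2 timepoints")
  if (any(tc$apical_input <= 0)) stop("apical input must be > 0")
  if (is.null(tc$replicate)) tc$replicate <- 1L
  correct <- !is.null(aliquot_volume_ul) && !is.null(basal_volume_ul)
  per_rep <- lapply(split(tc, tc$replicate), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (any(diff(d$time_h) <= 0))
      stop("times must be strictly increasing within a replicate")
    sig <- d$basal_signal
    if (correct) {
      v <- aliquot_volume_ul / basal_volume_ul
      sig <- sig + v * c(0, cumsum(sig))[seq_along(sig)]
    }
    data.frame(time_h = d$time_h, fraction = sig / d$apical_input)
  })
  all_pts <- do.call(rbind, per_rep)
  # least squares through the origin: slope = sum(t*f) / sum(t^2)
  slope <- sum(all_pts$time_h * all_pts$fraction) / sum(all_pts$time_h^2)
  resid <- all_pts$fraction - slope * all_pts$time_h
  slope_se <- if (nrow(all_pts) > 1)
    sqrt(sum(resid^2) / (nrow(all_pts) - 1) / sum(all_pts$time_h^2))
  else 0
  fractions <- stats::aggregate(fraction ~ time_h, all_pts, mean)
  list(fractions = fractions, slope_per_h = slope, slope_se = slope_se)
}

#' Signed percent change between control and treated estimates
#'
#' Reported as a reduction: `100 * (ctrl - treat) / ctrl`, so a positive
#' value means the treated condition is lower than control and a negative
#' value means an increase. The standard error is propagated from the two
#' estimates' SEs by the delta method.
#'
#' @param ctrl,treat scalar estimates (control must be non-zero).
#' @param se_ctrl,se_treat their standard errors (default 0).
#' @return list with `percent_change` and `se`.
#' @export
percent_change <- function(ctrl, treat, se_ctrl = 0, se_treat = 0) {
  if (!is.finite(ctrl) || ctrl == 0) stop("control estimate must be non-zero")
  pc <- 100 * (ctrl - treat) / ctrl
  # delta method on g(c, t) = 100 (1 - t/c)
  se <- 100 * sqrt(se_treat^2 / ctrl^2 + treat^2 * se_ctrl^2 / ctrl^4)
  list(percent_change = pc, se = se)
}
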
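#' Split a multi-cell FRAP table into per-cell traces
#'
#' @param traces a `frap_traces` data frame (columns `cell_id`, `frame`,
#'   `time_s`, `intensity`, `phase`).
#' @return named list of single-cell data frames, frames ordered by time.
#' @export
split_frap_traces <- function(traces) {
  lapply(split(as.data.frame(traces), traces$cell_id),
         function(d) d[order(d$time_s), , drop = FALSE])
}

validate_frap_trace <- function(trace) {
  need <- c("time_s", "intensity", "phase")
  if (!all(need %in% names(trace)))
    stop("FRAP trace needs columns: ", paste(need, collapse = ", "))
  if (sum(trace$phase == "pre") < 1) stop("trace needs >= 1 pre-bleach frame")
  if (sum(trace$phase == "post") < 2)
    stop("trace needs >= 2 post-bleach frames")
  if (any(diff(trace$time_s) <= 0))
    stop("frame times must be strictly increasing")
  trace
}

# pre-bleach mean and post-bleach floor of one trace; f0_frames > 1 averages
# the first post-bleach frames for robustness to noise
frap_anchors <- function(trace, f0_frames = 1L) {
  f_pre <- mean(trace$intensity[trace$phase == "pre"])
  post <- trace$intensity[trace$phase == "post"]
  f0 <- mean(post[seq_len(min(f0_frames, length(post)))])
  if (f_pre == f0)
    stop("pre-bleach mean equals the post-bleach floor; no bleach depth")
  list(f_pre = f_pre, f0 = f0)
}

#' Normalize a FRAP trace to percent recovery
#'
#' Maps the pre-bleach mean to 100% and the first post-bleach frame to 0%:
#' `R(t) = (F(t) - F0) / (F_pre - F0) * 100` for every post-bleach frame.
#' The normalization is affine, hence invariant to rescaling the raw trace.
#'
#' @param trace single-cell data frame with columns `time_s`, `intensity`,
#'   `phase`.
#' @param f0_frames number of leading post-bleach frames averaged into the
#'   floor `F0` (default 1).
#' @return data frame `time_s` (measured from the first post-bleach frame)
#'   and `recovery_percent`, one row per post-bleach frame.
#' @export
normalize_frap <- function(trace, f0_frames = 1L) {
  trace <- validate_frap_trace(trace)
  a <- frap_anchors(trace, f0_frames)
  post <- trace[trace$phase == "post", , drop = FALSE]
  data.frame(time_s = post$time_s - post$time_s[1],
             recovery_percent = (post$intensity - a$f0) /
               (a$f_pre - a$f0) * 100)
}

#' Mobile fraction of a FRAP trace
#'
#' `Mf = (F_recovered - F0) / (F_pre - F0)` with `F_pre` the pre-bleach mean,
#' `F0` the first post-bleach frame and `F_recovered` the recovery plateau.
#' The default plateau estimator is the mean of the last `k` post-bleach
#' frames; `method = "expfit"` instead fits a single-exponential recovery
#' `F(t) = F0 + A * (1 - exp(-t / tau))` to the post-bleach frames and uses
#' its asymptote `F0 + A`.
#'
#' @param trace single-cell FRAP data frame.
#' @param k number of trailing post-bleach frames in the plateau mean
#'   (default 5).
#' @param method `"plateau"` (default) or `"expfit"`.
#' @param f0_frames see [normalize_frap()].
#' @return list with `mobile_fraction` (clipped to `[0, 1]`), `raw` (the
#'   unclipped estimate), `f_pre`, `f0`, `plateau`, and for `"expfit"` the
#'   fitted `tau_s`.
#' @export
mobile_fraction <- function(trace, k = 5L, method = c("plateau", "expfit"),
                            f0_frames = 1L) {
  method <- match.arg(method)
  trace <- validate_frap_trace(trace)
  a <- frap_anchors(trace, f0_frames)
  post <- trace[trace$phase == "post", , drop = FALSE]
  tau_s <- NA_real_
  if (method == "plateau") {
    kk <- min(k, nrow(post))
    plateau <- mean(utils::tail(post$intensity, kk))
  } else {
    t_rel <- post$time_s - post$time_s[1]
    y <- post$intensity
    start <- list(A = max(mean(utils::tail(y, 5)) - a$f0, 1e-3),
                  tau = max(diff(range(t_rel)) / 5, 1e-3))
    fit <- stats::nls(y ~ f0c + A * (1 - exp(-t_rel / tau)),
                      data = list(y = y, t_rel = t_rel, f0c = a$f0),
                      start = start,
                      control = stats::nls.control(warnOnly = TRUE))
    cf <- stats::coef(fit)
    plateau <- a$f0 + cf[["A"]]
    tau_s <- cf[["tau"]]
  }
  raw <- (plateau - a$f0) / (a$f_pre - a$f0)
  list(mobile_fraction = min(max(raw, 0), 1), raw = raw,
       f_pre = a$f_pre, f0 = a$f0, plateau = plateau, tau_s = tau_s)
}

#' Fit mobile fractions across a set of FRAP traces
#'
#' Applies [mobile_fraction()] per cell and summarizes the condition: mean
#' mobile fraction, SD and SEM across cells.
#'
#' @param traces a `frap_traces` data frame (multiple cells).
#' @param ... passed to [mobile_fraction()].
#' @return object of class `frap_fit`: list with `cells` (per-cell data
#'   frame), `mean`, `sd`, `sem`, `n`.
#' @export
fit_frap <- function(traces, ...) {
  per_cell <- split_frap_traces(traces)
  est <- lapply(per_cell, mobile_fraction, ...)
  cells <- data.frame(cell_id = names(per_cell),
                      mobile_fraction = vapply(est, `[[`, numeric(1),
                                               "mobile_fraction"),
                      raw = vapply(est, `[[`, numeric(1), "raw"),
                      stringsAsFactors = FALSE, row.names = NULL)
  mf <- cells$mobile_fraction
  structure(list(cells = cells, mean = mean(mf), sd = stats::sd(mf),
                 sem = stats::sd(mf) / sqrt(length(mf)), n = length(mf)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("frap_fit: %d cells, mobile fraction %.3f +/- %.3f (SEM)\n",
              x$n, x$mean, x$sem))
  invisible(x)
}

#' Mean recovery curve across cells of a FRAP fit input
#'
#' @param traces a `frap_traces` data frame.
#' @param f0_frames see [normalize_frap()].
#' @return data frame `time_s`, `mean_recovery_percent`, `sem`.
#' @export
mean_recovery_curve <- function(traces, f0_frames = 1L) {
  curves <- lapply(split_frap_traces(traces), normalize_frap,
                   f0_frames = f0_frames)
  rec <- do.call(cbind, lapply(curves, `[[`, "recovery_percent"))
  data.frame(time_s = curves[[1]]$time_s,
             mean_recovery_percent = rowMeans(rec),
             sem = apply(rec, 1, stats::sd) / sqrt(ncol(rec)))
}
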
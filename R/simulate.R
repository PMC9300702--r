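#' Simulate an AP-MS pull-down intensity matrix
#'
#' Draws a protein-by-sample matrix of linear-scale LFQ-like intensities under
#' the generative model of [apms_scenario()], together with the truth table of
#' planted interactors. Each protein uses its own RNG substream derived from
#' the scenario seed, so enlarging the scenario never reshuffles the draws of
#' existing proteins.
#'
#' @param scenario an [apms_scenario()].
#' @return a list with elements
#'   \describe{
#'     \item{matrix}{an [intensity_matrix()] on the linear scale with groups
#'       `surface`, `endosomal`, `control`, each with
#'       `scenario$n_replicates` columns; undetected cells are `NA`.}
#'     \item{truth}{data frame of planted proteins with logical columns
#'       `surface` and `endosomal` giving the compartment(s) each was planted
#'       in.}
#'   }
#' @export
simulate_apms <- function(scenario) {
  stopifnot(inherits(scenario, "apms_scenario"))
  s <- scenario
  n_total <- s$n_background + s$n_planted_surface + s$n_planted_endosomal +
    s$n_planted_shared
  if (n_total == 0L) stop("scenario contains no proteins")
  ids <- sprintf("P%05d", seq_len(n_total))
  # planted proteins occupy the leading rows, in surface / endosomal / shared
  # blocks; background fills the rest
  planted_surface <- seq_len(s$n_planted_surface)
  planted_endo <- s$n_planted_surface + seq_len(s$n_planted_endosomal)
  planted_shared <- s$n_planted_surface + s$n_planted_endosomal +
    seq_len(s$n_planted_shared)
  in_surface <- seq_len(n_total) %in% c(planted_surface, planted_shared)
  in_endo <- seq_len(n_total) %in% c(planted_endo, planted_shared)

  nr <- s$n_replicates
  groups <- rep(c("surface", "endosomal", "control"), each = nr)
  reps <- rep(seq_len(nr), times = 3)
  n_col <- 3L * nr

  vals <- matrix(NA_real_, n_total, n_col,
                 dimnames = list(ids, paste(groups, reps, sep = "_")))
  fc <- rep(0, n_col)
  for (i in seq_len(n_total)) {
    set.seed(mix_seed(s$seed, i))
    base <- stats::rnorm(1, s$base_log2_mean, s$base_log2_sd)
    shift <- (groups == "surface") * in_surface[i] * s$planted_log2fc +
      (groups == "endosomal") * in_endo[i] * s$planted_log2fc
    x <- base + shift + stats::rnorm(n_col, 0, s$noise_sd)
    if (is.infinite(s$dropout_midpoint)) {
      detected <- rep(TRUE, n_col)
    } else {
      p_det <- stats::plogis(s$dropout_slope * (x - s$dropout_midpoint))
      detected <- stats::runif(n_col) < p_det
    }
    vals[i, detected] <- 2^x[detected]
  }

  planted <- which(in_surface | in_endo)
  truth <- data.frame(protein = ids[planted],
                      surface = in_surface[planted],
                      endosomal = in_endo[planted],
                      stringsAsFactors = FALSE)
  list(matrix = intensity_matrix(vals, groups, reps, scale = "linear"),
       truth = truth)
}

#' Simulate FRAP recovery traces
#'
#' Generates `n_cells` fluorescence traces under the single-exponential
#' recovery law of [frap_scenario()]: pre-bleach frames at 1, bleach frames at
#' the bleach floor, and post-bleach frames following
#' `F(t) = b + Mf * (1 - b) * (1 - exp(-t / tau))` with `t` measured from the
#' first post-bleach frame, plus additive Gaussian noise.
#'
#' @param scenario a [frap_scenario()].
#' @return a long-format data frame with columns `cell_id`, `frame`, `time_s`,
#'   `intensity` and `phase` (`pre`, `bleach` or `post`), class `frap_traces`.
#' @export
simulate_frap <- function(scenario) {
  stopifnot(inherits(scenario, "frap_scenario"))
  s <- scenario
  n_frames <- s$n_pre + s$n_bleach + s$n_post
  frame <- seq_len(n_frames)
  time_s <- (frame - 1) * s$frame_interval_s
  phase <- rep(c("pre", "bleach", "post"), c(s$n_pre, s$n_bleach, s$n_post))
  t_post0 <- time_s[match("post", phase)]
  b <- s$bleach_floor
  mf <- s$mobile_fraction
  clean <- ifelse(phase == "pre", 1,
                  ifelse(phase == "bleach", b,
                         b + mf * (1 - b) *
                           (1 - exp(-(time_s - t_post0) / s$tau_s))))
  out <- vector("list", s$n_cells)
  for (cell in seq_len(s$n_cells)) {
    set.seed(mix_seed(s$seed, cell))
    noise <- if (s$noise_sd > 0) stats::rnorm(n_frames, 0, s$noise_sd) else 0
    out[[cell]] <- data.frame(cell_id = sprintf("cell_%02d", cell),
                              frame = frame, time_s = time_s,
                              intensity = clean + noise, phase = phase,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("frap_traces", "data.frame")
  res
}

# log-normal multiplicative noise factors with unit mean and CV = cv
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate paired internalization-ELISA plates and permeability time courses
#'
#' For each condition (`ctrl`, `treat`) generates a capture-ELISA plate with
#' `internalized`, `total` and `background` wells, and a transwell
#' permeability time course, under the model of [assay_scenario()].
#'
#' @param scenario an [assay_scenario()].
#' @return a list with elements
#'   \describe{
#'     \item{elisa}{data frame `condition`, `well_type`
#'       (`internalized` / `total` / `background`), `replicate`, `od`.}
#'     \item{permeability}{data frame `condition`, `replicate`, `time_h`,
#'       `basal_signal`, `apical_input`.}
#'   }
#' @export
simulate_assays <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  s <- scenario
  conditions <- c(ctrl = s$internalized_fraction_ctrl,
                  treat = s$internalized_fraction_treat)
  flux <- c(ctrl = s$flux_rate_ctrl, treat = s$flux_rate_treat)
  apical_input <- 100
  nr <- s$n_replicates
  nt <- length(s$sample_times_h)

  elisa <- vector("list", 2L)
  perm <- vector("list", 2L)
  for (k in seq_along(conditions)) {
    cond <- names(conditions)[k]
    set.seed(mix_seed(s$seed, k))
    frac <- conditions[[k]]
    clean <- c(internalized = s$surface_signal * frac + s$background_od,
               total = s$surface_signal + s$background_od,
               background = s$background_od)
    od <- rep(clean, each = nr) * ln_noise(3L * nr, s$noise_cv)
    elisa[[k]] <- data.frame(condition = cond,
                             well_type = rep(names(clean), each = nr),
                             replicate = rep(seq_len(nr), times = 3L),
                             od = unname(od), stringsAsFactors = FALSE)
    basal <- apical_input * flux[[k]] *
      rep(s$sample_times_h, times = nr) * ln_noise(nt * nr, s$noise_cv)
    perm[[k]] <- data.frame(condition = cond,
                            replicate = rep(seq_len(nr), each = nt),
                            time_h = rep(s$sample_times_h, times = nr),
                            basal_signal = unname(basal),
                            apical_input = apical_input,
                            stringsAsFactors = FALSE)
  }
  list(elisa = do.call(rbind, elisa),
       permeability = do.call(rbind, perm))
}

#' Write FRAP traces to CSV
#'
#' Long format: `cell_id`, `frame`, `time_s`, `intensity`, `phase`.
#'
#' @param traces a `frap_traces` data frame from [simulate_frap()].
#' @param path output file.
#' @export
write_frap_csv <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read FRAP traces from CSV
#'
#' @param path CSV file as written by [write_frap_csv()].
#' @return a `frap_traces` data frame.
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "time_s", "intensity", "phase")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("FRAP CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  class(df) <- c("frap_traces", "data.frame")
  df
}
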
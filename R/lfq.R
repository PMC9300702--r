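#' Parameters for downshifted-normal imputation
#'
#' Missing (left-censored) intensities are replaced with draws from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)`, where `mu_s` and
#' `sigma_s` are the mean and SD of the observed values of the cell's sample
#' column. The defaults (width 0.3, downshift 1.8) are the conventional
#' Perseus-style settings for label-free proteomics.
#'
#' @param width fraction of the per-sample SD used as imputation SD (> 0).
#' @param downshift number of per-sample SDs subtracted from the per-sample
#'   mean (>= 0).
#' @param seed RNG seed governing the imputation draws.
#' @return an object of class `imputation_params`.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (!is.finite(downshift) || downshift < 0) stop("downshift must be >= 0")
  structure(list(width = width, downshift = downshift,
                 seed = as.integer(seed)),
            class = "imputation_params")
}

#' Parameters for interactor calling
#'
#' A protein is called an interactor in a compartment when its mean fold
#' change over the control is at least `fc_threshold` (inclusive) and its raw
#' one-sample t-test p value is below `p_threshold` (strict).
#'
#' @param fc_threshold minimum linear fold change (> 1; default 1.5).
#' @param p_threshold maximum raw p value (default 0.05, exclusive).
#' @param min_valid minimum non-missing values per group for the validity
#'   filter (default 3).
#' @param n_replicates replicates per group (default 4).
#' @param use_q if `TRUE`, call on the BH q value instead of the raw p value.
#' @return an object of class `calling_params`.
#' @export
calling_params <- function(fc_threshold = 1.5, p_threshold = 0.05,
                           min_valid = 3L, n_replicates = 4L,
                           use_q = FALSE) {
  if (!is.finite(fc_threshold) || fc_threshold <= 1)
    stop("fc_threshold must be > 1")
  if (!is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  min_valid <- as.integer(min_valid)
  n_replicates <- as.integer(n_replicates)
  if (min_valid > n_replicates)
    stop("min_valid must not exceed n_replicates")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 min_valid = min_valid, n_replicates = n_replicates,
                 use_q = isTRUE(use_q)),
            class = "calling_params")
}

#' Filter proteins by replicate validity
#'
#' Keeps exactly the proteins quantified (non-missing) in at least
#' `params$min_valid` replicates of at least one experimental group. Column
#' set and row order are unchanged; an empty result is legal.
#'
#' @param m an [intensity_matrix()].
#' @param params a [calling_params()]; only `min_valid` is used.
#' @return the filtered `intensity_matrix`.
#' @export
filter_by_valid_values <- function(m, params = calling_params()) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(params, "calling_params"))
  if (nrow(m$values) < 1) stop("matrix has no proteins")
  keep <- rep(FALSE, nrow(m$values))
  for (g in unique(m$group)) {
    n_valid <- rowSums(!is.na(m$values[, m$group == g, drop = FALSE]))
    keep <- keep | (n_valid >= params$min_valid)
  }
  subset_proteins(m, keep)
}

#' Log2-transform an intensity matrix
#'
#' @param m an [intensity_matrix()] on the linear scale; all present values
#'   must be positive. The missingness pattern is unchanged.
#' @return the matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive intensity for protein '",
         rownames(m$values)[bad[1, 1]], "', sample '",
         colnames(m$values)[bad[1, 2]], "'")
  intensity_matrix(log2(m$values), m$group, m$replicate, scale = "log2")
}

#' Invert the log2 transform
#'
#' @param m an `intensity_matrix` on the log2 scale.
#' @return the matrix on the linear scale.
#' @export
unlog2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale != "log2") stop("matrix is not on the log2 scale")
  intensity_matrix(2^m$values, m$group, m$replicate, scale = "linear")
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample column: missing cells are replaced by draws from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)` with `mu_s`,
#' `sigma_s` the observed mean and SD of that column. Observed cells are
#' untouched. Columns whose observed SD is zero are imputed at the constant
#' `mu_s` with a warning; columns with fewer than two observed values are
#' rejected.
#'
#' @param m an [intensity_matrix()] on the log2 scale.
#' @param p an [imputation_params()].
#' @return the imputed matrix (no missing values).
#' @export
impute_downshifted_normal <- function(m, p = imputation_params()) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(p, "imputation_params"))
  if (m$scale != "log2") stop("imputation requires a log2-scale matrix")
  vals <- m$values
  if (!anyNA(vals)) return(m)
  set.seed(p$seed)
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (!any(miss)) next
    obs <- vals[!miss, j]
    if (length(obs) < 2)
      stop("column '", colnames(vals)[j],
           "' has fewer than 2 observed values; SD undefined")
    mu <- mean(obs)
    sigma <- stats::sd(obs)
    if (sigma == 0) {
      warning("column '", colnames(vals)[j],
              "' has zero observed SD; imputing the constant mean")
      vals[miss, j] <- mu
    } else {
      vals[miss, j] <- stats::rnorm(sum(miss),
                                    mean = mu - p$downshift * sigma,
                                    sd = p$width * sigma)
    }
  }
  intensity_matrix(vals, m$group, m$replicate, scale = "log2")
}

#' Replicate-paired log2 ratios versus the control group
#'
#' For each protein, ratio_i = value(compartment, replicate i) -
#' value(control, replicate i) on the log2 scale (the log2 of the linear
#' quotient). With `paired = FALSE`, every compartment replicate is compared
#' with the control mean instead.
#'
#' @param m an [intensity_matrix()] on the log2 scale with no missing values.
#' @param compartment group label to compare against `control`.
#' @param paired pair replicate i with control replicate i (default) or with
#'   the control mean.
#' @return numeric matrix, proteins x replicates, of log2 ratios.
#' @export
compute_ratios <- function(m, compartment, paired = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale != "log2") stop("ratios require a log2-scale matrix")
  if (anyNA(m$values))
    stop("matrix contains missing values; impute before computing ratios")
  comp_cols <- group_columns(m, compartment)
  ctrl_cols <- group_columns(m, "control")
  if (length(comp_cols) != length(ctrl_cols))
    stop("unequal replicate counts between '", compartment,
         "' and 'control'")
  comp <- m$values[, comp_cols, drop = FALSE]
  if (paired) {
    ratios <- comp - m$values[, ctrl_cols, drop = FALSE]
  } else {
    ratios <- comp - rowMeans(m$values[, ctrl_cols, drop = FALSE])
  }
  colnames(ratios) <- paste0("ratio_", seq_len(ncol(ratios)))
  ratios
}

#' One-sample t test against zero, row-wise
#'
#' For each row of `ratios`, computes `t = mean / (sd / sqrt(n))` and the
#' two-sided p value from the Student t distribution with `n - 1` degrees of
#' freedom. Degenerate rows (sd = 0) are flagged: p = 0 when the mean is
#' non-zero, p = 1 when it is zero.
#'
#' @param ratios numeric matrix (proteins x replicates) with at least two
#'   columns, or a numeric vector of length >= 2 for a single protein.
#' @return data frame with columns `mean`, `t`, `p`, `df`, `degenerate`.
#' @export
one_sample_ttest <- function(ratios) {
  if (is.vector(ratios)) ratios <- matrix(ratios, nrow = 1)
  n <- ncol(ratios)
  if (n < 2) stop("at least 2 ratios per protein are required")
  mn <- rowMeans(ratios)
  sdv <- apply(ratios, 1, stats::sd)
  degenerate <- sdv == 0
  tval <- mn / (sdv / sqrt(n))
  pval <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  tval[degenerate & mn != 0] <- Inf * sign(mn[degenerate & mn != 0])
  pval[degenerate & mn != 0] <- 0
  tval[degenerate & mn == 0] <- 0
  pval[degenerate & mn == 0] <- 1
  data.frame(mean = mn, t = tval, p = pval, df = n - 1,
             degenerate = degenerate,
             row.names = rownames(ratios))
}

#' Benjamini-Hochberg q values
#'
#' Step-up adjusted p values: `q_i = min over j with rank >= rank(i) of
#' p_j * n / rank_j`, capped at 1; input order preserved.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return numeric vector of q values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Build the per-compartment enrichment table
#'
#' Runs [compute_ratios()], [one_sample_ttest()] and [bh_fdr()] for each
#' compartment and assembles the long-format enrichment table. BH adjustment
#' is applied within each compartment.
#'
#' @param m an imputed log2-scale [intensity_matrix()].
#' @param compartments group labels to test against control.
#' @param paired see [compute_ratios()].
#' @return data frame with columns `protein`, `compartment`,
#'   `mean_log2_ratio`, `t`, `p`, `q`, `degenerate`, plus one `ratio_<i>`
#'   column per replicate.
#' @export
enrichment_table <- function(m, compartments = c("surface", "endosomal"),
                             paired = TRUE) {
  out <- lapply(compartments, function(comp) {
    ratios <- compute_ratios(m, comp, paired = paired)
    tt <- one_sample_ttest(ratios)
    data.frame(protein = rownames(m$values), compartment = comp,
               mean_log2_ratio = tt$mean, t = tt$t, p = tt$p,
               q = bh_fdr(tt$p), degenerate = tt$degenerate,
               ratios, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Call interactors by fold change and p value
#'
#' Adds the logical `interactor` column: mean linear fold change at least
#' `fc_threshold` (i.e. mean log2 ratio >= log2(fc_threshold), inclusive) and
#' raw p value strictly below `p_threshold`. With `params$use_q` the q value
#' is used in place of the raw p. Flags are annotations; no rows are removed.
#'
#' @param table an enrichment table from [enrichment_table()].
#' @param params a [calling_params()].
#' @return the table with an `interactor` column.
#' @export
call_interactors <- function(table, params = calling_params()) {
  stopifnot(inherits(params, "calling_params"))
  pcol <- if (params$use_q) table$q else table$p
  table$interactor <- table$mean_log2_ratio >= log2(params$fc_threshold) &
    pcol < params$p_threshold
  table
}

#' Flag probable background binders
#'
#' Annotates proteins that appear in a contaminant-repository background
#' frequency table (CRAPome-style: fraction of negative-control pull-down
#' runs in which the protein was detected) at or above `flag_threshold`.
#' The flag never changes the `interactor` call - background proteins are
#' highlighted, not excluded.
#'
#' @param table an enrichment table.
#' @param bg data frame with columns `protein` and `frequency` in `[0, 1]`,
#'   or `NULL` for no flagging.
#' @param flag_threshold minimum repository frequency to flag (default 0.5).
#' @return the table with a logical `background_flag` column.
#' @export
flag_background <- function(table, bg = NULL, flag_threshold = 0.5) {
  if (is.null(bg)) {
    table$background_flag <- FALSE
    return(table)
  }
  stopifnot(all(c("protein", "frequency") %in% names(bg)))
  if (any(bg$frequency < 0 | bg$frequency > 1))
    stop("background frequencies must lie in [0, 1]")
  freq <- bg$frequency[match(table$protein, bg$protein)]
  table$background_flag <- !is.na(freq) & freq >= flag_threshold
  table
}

#' Export volcano-plot data
#'
#' One row per protein per compartment: `x` = mean log2 ratio, `y` =
#' -log10(p), with the interactor and background flags carried over
#' losslessly.
#'
#' @param table a called enrichment table.
#' @return data frame `protein`, `compartment`, `x`, `y`, `interactor`,
#'   `background_flag`.
#' @export
export_volcano <- function(table) {
  data.frame(protein = table$protein, compartment = table$compartment,
             x = table$mean_log2_ratio, y = -log10(table$p),
             interactor = if (is.null(table$interactor)) NA else
               table$interactor,
             background_flag = if (is.null(table$background_flag)) NA else
               table$background_flag,
             stringsAsFactors = FALSE)
}
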
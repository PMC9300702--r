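#' Fit the AP-MS interactome model
#'
#' The end-to-end statistical analysis of a pull-down intensity matrix
#' against its unlabeled control: replicate-validity filtering, log2
#' scaling, downshifted-normal imputation, paired control ratios, one-sample
#' t tests per compartment, Benjamini-Hochberg q values, fold-change /
#' p-value interactor calling and optional background flagging.
#'
#' @param x an [intensity_matrix()] on the linear scale (e.g. from
#'   [simulate_apms()] or [load_intensity_table()]).
#' @param calling a [calling_params()].
#' @param imputation an [imputation_params()].
#' @param background optional background-frequency data frame for
#'   [flag_background()].
#' @param compartments compartment group labels tested against `control`.
#' @param paired pair replicate i with control replicate i (default) or
#'   compare with the control mean.
#' @param flag_threshold background-frequency flag threshold.
#' @return an object of class `interactome_fit`: a list with the called
#'   `enrichment` table, the filtered+imputed matrix (`matrix`), the input
#'   parameters, the seed, and per-compartment interactor counts. Use
#'   [interactor_sets()] to extract the called ID lists and
#'   [export_volcano()] on `$enrichment` for plotting data.
#' @seealso [summary.interactome_fit()], [plot.interactome_fit()]
#' @export
fit_interactome <- function(x,
                            calling = calling_params(),
                            imputation = imputation_params(),
                            background = NULL,
                            compartments = c("surface", "endosomal"),
                            paired = TRUE,
                            flag_threshold = 0.5) {
  stopifnot(inherits(x, "intensity_matrix"))
  n_input <- nrow(x$values)
  m <- filter_by_valid_values(x, calling)
  n_filtered <- nrow(m$values)
  if (m$scale == "linear") m <- log2_transform(m)
  warnings_log <- character()
  m <- withCallingHandlers(
    impute_downshifted_normal(m, imputation),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  tab <- enrichment_table(m, compartments = compartments, paired = paired)
  tab <- call_interactors(tab, calling)
  tab <- flag_background(tab, background, flag_threshold)
  counts <- vapply(compartments, function(comp)
    sum(tab$interactor[tab$compartment == comp]), integer(1))
  structure(list(enrichment = tab, matrix = m,
                 calling = calling, imputation = imputation,
                 compartments = compartments, paired = paired,
                 seed = imputation$seed,
                 n_input = n_input, n_filtered = n_filtered,
                 n_interactors = counts, warnings = warnings_log),
            class = "interactome_fit")
}

#' Extract called interactor ID sets from a fit
#'
#' @param fit an `interactome_fit`.
#' @return named list of character vectors, one per compartment, of the
#'   protein IDs called as interactors.
#' @export
interactor_sets <- function(fit) {
  stopifnot(inherits(fit, "interactome_fit"))
  tab <- fit$enrichment
  sets <- lapply(fit$compartments, function(comp)
    sort(tab$protein[tab$compartment == comp & tab$interactor]))
  names(sets) <- fit$compartments
  sets
}

#' @export
print.interactome_fit <- function(x, ...) {
  cat("interactome_fit\n")
  cat(sprintf("  proteins: %d quantified, %d after validity filter\n",
              x$n_input, x$n_filtered))
  for (comp in x$compartments)
    cat(sprintf("  %s interactors: %d\n", comp, x$n_interactors[[comp]]))
  cat(sprintf("  calling: FC >= %.2f, %s < %.3g; imputation width %.2f, downshift %.2f (seed %d)\n",
              x$calling$fc_threshold, if (x$calling$use_q) "q" else "p",
              x$calling$p_threshold, x$imputation$width,
              x$imputation$downshift, x$seed))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Summarize an interactome fit
#'
#' @param object an `interactome_fit`.
#' @param ... unused.
#' @return a list with counts (quantified, filtered, interactors per
#'   compartment, shared, union, background-flagged) and the parameter echo,
#'   class `summary.interactome_fit`.
#' @export
summary.interactome_fit <- function(object, ...) {
  sets <- interactor_sets(object)
  shared <- if (length(sets) >= 2) Reduce(intersect, sets) else character()
  un <- Reduce(union, sets)
  bg <- unique(object$enrichment$protein[
    object$enrichment$background_flag & object$enrichment$interactor])
  out <- list(n_input = object$n_input, n_filtered = object$n_filtered,
              n_interactors = object$n_interactors,
              n_shared = length(shared), n_union = length(un),
              n_background_flagged = length(bg),
              calling = object$calling, imputation = object$imputation,
              seed = object$seed)
  class(out) <- "summary.interactome_fit"
  out
}

#' @export
print.summary.interactome_fit <- function(x, ...) {
  cat("Interactome analysis summary\n")
  cat(sprintf("  quantified proteins:     %d\n", x$n_input))
  cat(sprintf("  after validity filter:   %d\n", x$n_filtered))
  for (comp in names(x$n_interactors))
    cat(sprintf("  %-23s %d\n", paste0(comp, " interactors:"),
                x$n_interactors[[comp]]))
  cat(sprintf("  shared interactors:      %d\n", x$n_shared))
  cat(sprintf("  union (distinct):        %d\n", x$n_union))
  cat(sprintf("  background-flagged:      %d\n", x$n_background_flagged))
  invisible(x)
}

#' Volcano plot of an interactome fit
#'
#' Mean log2 ratio against -log10(p) per compartment, interactors filled,
#' background-flagged interactors marked.
#'
#' @param x an `interactome_fit`.
#' @param compartment which compartment to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.interactome_fit <- function(x, compartment = x$compartments[1], ...) {
  v <- export_volcano(x$enrichment)
  v <- v[v$compartment == compartment, ]
  col <- ifelse(v$interactor, "firebrick", "grey60")
  pch <- ifelse(!is.na(v$background_flag) & v$background_flag, 17, 16)
  graphics::plot(v$x, v$y, col = col, pch = pch,
                 xlab = "mean log2(compartment / control)",
                 ylab = "-log10 p", main = paste("volcano:", compartment),
                 ...)
  graphics::abline(v = log2(x$calling$fc_threshold), lty = 2)
  graphics::abline(h = -log10(x$calling$p_threshold), lty = 2)
  invisible(v)
}
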
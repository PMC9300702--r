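#' Load a protein-by-sample intensity table
#'
#' Reads a TSV with protein IDs in the first column and one intensity column
#' per sample. Sample columns are either named `<group>_<replicate>`
#' directly, or mapped through `sample_map`. Dialects: `"na"` (default)
#' treats `NA`/empty cells as missing; `"maxquant"` additionally maps 0 to
#' missing, the encoding MaxQuant uses for undetected LFQ intensities.
#'
#' @param path TSV file.
#' @param sample_map optional data frame with columns `column`, `group`,
#'   `replicate` assigning every intensity column; unmapped intensity
#'   columns are an error.
#' @param dialect `"na"` or `"maxquant"`.
#' @return an [intensity_matrix()] on the linear scale.
#' @export
load_intensity_table <- function(path, sample_map = NULL,
                                 dialect = c("na", "maxquant")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("intensity table needs an ID column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_cols <- names(df)[-1]
  if (is.null(sample_map)) {
    ok <- grepl("^.+_[0-9]+$", sample_cols)
    if (any(!ok))
      stop("column(s) not of the form <group>_<replicate> and no sample_map ",
           "given: ", paste(sample_cols[!ok], collapse = ", "))
    group <- sub("_[0-9]+$", "", sample_cols)
    replicate <- as.integer(sub("^.*_", "", sample_cols))
  } else {
    stopifnot(all(c("column", "group", "replicate") %in% names(sample_map)))
    idx <- match(sample_cols, sample_map$column)
    if (anyNA(idx))
      stop("unmapped intensity column(s): ",
           paste(sample_cols[is.na(idx)], collapse = ", "))
    group <- as.character(sample_map$group[idx])
    replicate <- as.integer(sample_map$replicate[idx])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (dialect == "maxquant") vals[vals == 0] <- NA_real_
  rownames(vals) <- ids
  intensity_matrix(vals, group, replicate, scale = "linear")
}

#' Read a background-frequency table
#'
#' TSV with columns `protein` and `frequency` (fraction of repository
#' negative-control runs detecting the protein, in `[0, 1]`).
#'
#' @param path TSV file.
#' @return data frame `protein`, `frequency`.
#' @export
read_background_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "frequency") %in% names(df)))
    stop("background table needs columns 'protein' and 'frequency'")
  if (any(df$frequency < 0 | df$frequency > 1))
    stop("background frequencies must lie in [0, 1]")
  df
}

#' Assemble a pipeline run configuration
#'
#' @param matrix path to the intensity TSV (or an [intensity_matrix()]).
#' @param annotations optional path to the annotation TSV (or data frame).
#' @param background optional path to the background-frequency TSV (or data
#'   frame).
#' @param categories optional path to a GMT file (or named list).
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param calling a [calling_params()].
#' @param imputation an [imputation_params()]; its seed is overridden by
#'   `seed`.
#' @param enrichment_fdr FDR threshold for category enrichment.
#' @param bg_flag_threshold background-frequency flag threshold.
#' @param dialect intensity-table dialect, see [load_intensity_table()].
#' @param sample_map see [load_intensity_table()].
#' @param paired replicate pairing for control ratios.
#' @param seed global seed; all randomness in the run flows from it.
#' @return a `run_config` list.
#' @export
run_config <- function(matrix, annotations = NULL, background = NULL,
                       categories = NULL, out_dir = NULL,
                       calling = calling_params(),
                       imputation = imputation_params(),
                       enrichment_fdr = 0.05, bg_flag_threshold = 0.5,
                       dialect = "na", sample_map = NULL, paired = TRUE,
                       seed = 1L) {
  imputation$seed <- as.integer(seed)
  structure(list(matrix = matrix, annotations = annotations,
                 background = background, categories = categories,
                 out_dir = out_dir, calling = calling,
                 imputation = imputation, enrichment_fdr = enrichment_fdr,
                 bg_flag_threshold = bg_flag_threshold, dialect = dialect,
                 sample_map = sample_map, paired = paired,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `calling` and
#' `imputation` are nested maps of their parameter constructors. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  run_config(
    matrix = resolve(y$matrix),
    annotations = resolve(y$annotations),
    background = resolve(y$background),
    categories = resolve(y$categories),
    out_dir = y$out_dir,
    calling = do.call(calling_params, if (is.null(y$calling)) list()
                      else y$calling),
    imputation = do.call(imputation_params,
                         if (is.null(y$imputation)) list() else y$imputation),
    enrichment_fdr = if (is.null(y$enrichment_fdr)) 0.05 else y$enrichment_fdr,
    bg_flag_threshold = if (is.null(y$bg_flag_threshold)) 0.5
                        else y$bg_flag_threshold,
    dialect = if (is.null(y$dialect)) "na" else y$dialect,
    paired = if (is.null(y$paired)) TRUE else y$paired,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Run the full interactome analysis
#'
#' Executes filter, log2, imputation, control ratios, t tests, BH, interactor
#' calling and background flagging ([fit_interactome()]); then, when
#' annotations are supplied, topology/location classification, surface/
#' endosomal set partition, membrane-location grouping and, when categories
#' are supplied, hypergeometric enrichment over the remaining (neither
#' transmembrane nor endosome-located) interactors against the filtered
#' universe. All tables are written to `config$out_dir` (if set) with rows
#' sorted by protein ID, so equal seeds give byte-identical files.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: counts, parameter echo, seed, warnings, and
#'   the fit, sets and tables.
#' @export
run_interactome <- function(config) {
  stopifnot(inherits(config, "run_config"))
  m <- if (inherits(config$matrix, "intensity_matrix")) config$matrix
       else load_intensity_table(config$matrix, config$sample_map,
                                 config$dialect)
  bg <- if (is.null(config$background)) NULL
        else if (is.data.frame(config$background)) config$background
        else read_background_tsv(config$background)
  fit <- fit_interactome(m, calling = config$calling,
                         imputation = config$imputation,
                         background = bg, paired = config$paired,
                         flag_threshold = config$bg_flag_threshold)
  sets_called <- interactor_sets(fit)
  sets <- partition_sets(sets_called$surface, sets_called$endosomal)

  ann <- NULL; chord <- NULL; enrich <- NULL
  tm <- character(); endo_located <- character()
  warnings_log <- fit$warnings
  if (!is.null(config$annotations)) {
    ann <- if (is.data.frame(config$annotations)) config$annotations
           else read_annotations(config$annotations)
    ann_union <- ann[ann$protein %in% sets$union, , drop = FALSE]
    withCallingHandlers({
      tm <- classify_transmembrane(ann_union)
      endo_located <- classify_endosomal(ann_union)
      chord <- group_membrane_locations(
        ann_union[ann_union$protein %in% tm, , drop = FALSE])
    }, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    if (!is.null(config$categories)) {
      cats <- if (is.list(config$categories)) config$categories
              else read_gmt(config$categories)
      # the remaining-interactor analysis excludes the transmembrane and
      # endosome-located branches; universe = proteins passing the filter
      remaining <- setdiff(sets$union, union(tm, endo_located))
      universe <- rownames(fit$matrix$values)
      if (length(remaining) > 0)
        enrich <- hypergeometric_enrichment(
          intersect(remaining, universe), cats, universe,
          fdr = config$enrichment_fdr)
    }
  }

  report <- structure(list(
    n_quantified = fit$n_input,
    n_filtered = fit$n_filtered,
    n_interactors = as.list(fit$n_interactors),
    n_shared = unname(sets$counts["shared"]),
    n_union = unname(sets$counts["union"]),
    n_transmembrane = length(tm),
    n_endosome_located = length(endo_located),
    seed = config$seed,
    params = list(calling = unclass(config$calling),
                  imputation = unclass(config$imputation),
                  enrichment_fdr = config$enrichment_fdr,
                  bg_flag_threshold = config$bg_flag_threshold,
                  paired = config$paired),
    warnings = warnings_log,
    fit = fit, sets = sets, transmembrane = sort(tm),
    endosome_located = sort(endo_located), chord = chord,
    category_enrichment = enrich),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    enr <- fit$enrichment
    enr <- enr[order(enr$compartment, enr$protein), , drop = FALSE]
    write_tsv(enr, file.path(od, "enrichment.tsv"))
    volc <- export_volcano(fit$enrichment)
    volc <- volc[order(volc$compartment, volc$protein), , drop = FALSE]
    write_tsv(volc, file.path(od, "volcano.tsv"))
    writeLines(sets$surface, file.path(od, "surface_interactors.txt"))
    writeLines(sets$endosomal, file.path(od, "endosomal_interactors.txt"))
    writeLines(sets$shared, file.path(od, "shared_interactors.txt"))
    if (!is.null(chord)) {
      chord_out <- chord[order(chord$protein, chord$group), , drop = FALSE]
      write_tsv(chord_out, file.path(od, "membrane_groups.tsv"))
    }
    if (!is.null(enrich))
      write_tsv(enrich, file.path(od, "category_enrichment.tsv"))
    meta <- report[c("n_quantified", "n_filtered", "n_interactors",
                     "n_shared", "n_union", "n_transmembrane",
                     "n_endosome_located", "seed", "params", "warnings")]
    jsonlite::write_json(meta, file.path(od, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Interactome run report\n")
  cat(sprintf("  quantified: %d; after filter: %d\n",
              x$n_quantified, x$n_filtered))
  cat(sprintf("  interactors: %s; shared %d; distinct %d\n",
              paste(sprintf("%s %d", names(x$n_interactors),
                            unlist(x$n_interactors)), collapse = ", "),
              x$n_shared, x$n_union))
  if (x$n_transmembrane + x$n_endosome_located > 0)
    cat(sprintf("  transmembrane: %d; endosome-located: %d\n",
                x$n_transmembrane, x$n_endosome_located))
  cat(sprintf("  seed: %d; warnings: %d\n", x$seed, length(x$warnings)))
  invisible(x)
}

#' Run the functional-assay quantifications
#'
#' Dispatches to the FRAP, capture-ELISA and permeability estimators for
#' whichever inputs are supplied, and computes the control-versus-treated
#' percent changes. Summaries are written as TSV when `out_dir` is set.
#'
#' @param frap optional list with `ctrl` and `treat` `frap_traces` data
#'   frames (or CSV paths).
#' @param elisa optional ELISA plate data frame (or CSV path with columns
#'   `condition`, `well_type`, `od`).
#' @param permeability optional permeability data frame (or CSV path with
#'   columns `condition`, `time_h`, `basal_signal`, `apical_input`).
#' @param out_dir optional output directory.
#' @return list with per-assay condition summaries and comparisons.
#' @export
run_assays <- function(frap = NULL, elisa = NULL, permeability = NULL,
                       out_dir = NULL) {
  out <- list()
  if (!is.null(frap)) {
    tr <- lapply(frap, function(x)
      if (is.character(x)) read_frap_csv(x) else x)
    fits <- lapply(tr, fit_frap)
    pc <- percent_change(fits$ctrl$mean, fits$treat$mean,
                         fits$ctrl$sem, fits$treat$sem)
    out$frap <- list(
      summary = data.frame(condition = names(fits),
                           mobile_fraction = vapply(fits, `[[`, numeric(1),
                                                    "mean"),
                           sem = vapply(fits, `[[`, numeric(1), "sem"),
                           n_cells = vapply(fits, `[[`, numeric(1), "n"),
                           row.names = NULL),
      comparison = data.frame(statistic = "mobile_fraction_reduction",
                              percent_change = pc$percent_change,
                              se = pc$se))
  }
  if (!is.null(elisa)) {
    plate <- if (is.character(elisa))
      utils::read.csv(elisa, stringsAsFactors = FALSE) else elisa
    conds <- unique(plate$condition)
    ests <- lapply(conds, internalization_percent, plate = plate)
    names(ests) <- conds
    summ <- data.frame(condition = conds,
                       internalized_percent = vapply(ests, `[[`, numeric(1),
                                                     "percent"),
                       se = vapply(ests, `[[`, numeric(1), "se"),
                       row.names = NULL)
    out$elisa <- list(summary = summ)
    if (all(c("ctrl", "treat") %in% conds)) {
      pc <- percent_change(ests$ctrl$percent, ests$treat$percent,
                           ests$ctrl$se, ests$treat$se)
      out$elisa$comparison <- data.frame(
        statistic = "internalization_reduction",
        percent_change = pc$percent_change, se = pc$se)
    }
  }
  if (!is.null(permeability)) {
    tc <- if (is.character(permeability))
      utils::read.csv(permeability, stringsAsFactors = FALSE)
    else permeability
    conds <- unique(tc$condition)
    fl <- lapply(conds, function(cd)
      permeability_flux(tc[tc$condition == cd, , drop = FALSE]))
    names(fl) <- conds
    summ <- data.frame(condition = conds,
                       slope_per_h = vapply(fl, `[[`, numeric(1),
                                            "slope_per_h"),
                       se = vapply(fl, `[[`, numeric(1), "slope_se"),
                       row.names = NULL)
    out$permeability <- list(summary = summ)
    if (all(c("ctrl", "treat") %in% conds)) {
      pc <- percent_change(fl$ctrl$slope_per_h, fl$treat$slope_per_h,
                           fl$ctrl$slope_se, fl$treat$slope_se)
      out$permeability$comparison <- data.frame(
        statistic = "flux_reduction",
        percent_change = pc$percent_change, se = pc$se)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (assay in names(out)) {
      write_tsv(out[[assay]]$summary,
                file.path(out_dir, paste0(assay, "_summary.tsv")))
      if (!is.null(out[[assay]]$comparison))
        write_tsv(out[[assay]]$comparison,
                  file.path(out_dir, paste0(assay, "_comparison.tsv")))
    }
  }
  out
}
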
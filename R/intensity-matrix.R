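#' Protein-by-sample intensity matrix
#'
#' The central container of the pipeline: a numeric matrix of label-free
#' quantification (LFQ-style) intensities, proteins in rows, samples in
#' columns, with per-column group/replicate metadata and a scale flag.
#' Missing values are `NA`.
#'
#' @param values numeric matrix, rownames = unique protein IDs, one column per
#'   sample. `NA` encodes a missing (not detected) intensity.
#' @param group character vector, one entry per column; the experimental group
#'   of each sample (e.g. `"surface"`, `"endosomal"`, `"control"`).
#' @param replicate integer vector, one entry per column; replicate index,
#'   unique within each group.
#' @param scale `"linear"` or `"log2"`.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `group`, `replicate`, `scale`.
#' @export
intensity_matrix <- function(values, group, replicate,
                             scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("'values' must have protein IDs as rownames")
    rownames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (length(group) != ncol(values) || length(replicate) != ncol(values))
    stop("'group' and 'replicate' must have one entry per column")
  group <- as.character(group)
  replicate <- as.integer(replicate)
  for (g in unique(group)) {
    if (anyDuplicated(replicate[group == g]))
      stop("replicate indices must be unique within group '", g, "'")
  }
  present <- values[!is.na(values)]
  if (scale == "log2" && any(!is.finite(present)))
    stop("log2-scale matrix contains non-finite present values")
  colnames(values) <- paste(group, replicate, sep = "_")
  structure(list(values = values, group = group, replicate = replicate,
                 scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%% of cells\n",
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by protein
#'
#' @param x an `intensity_matrix`.
#' @param proteins character vector of protein IDs or logical/integer row index.
#' @return an `intensity_matrix` with the selected rows, column set unchanged.
#' @export
subset_proteins <- function(x, proteins) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values[proteins, , drop = FALSE]
  intensity_matrix(v, x$group, x$replicate, x$scale)
}

# columns belonging to one group, ordered by replicate index
group_columns <- function(x, group) {
  idx <- which(x$group == group)
  if (length(idx) == 0L)
    stop("group '", group, "' absent from sample metadata")
  idx[order(x$replicate[idx])]
}

#' Write an intensity matrix to TSV
#'
#' First column `protein`, then one column per sample named
#' `<group>_<replicate>`; missing cells are written as `NA`. Rows are written
#' in the matrix's row order.
#'
#' @param x an `intensity_matrix`.
#' @param path output file path.
#' @export
write_intensity_tsv <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(protein = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
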
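#' Read a protein annotation table
#'
#' TSV with columns `protein`, `topology` (UniProt "Topology"-style free
#' text) and `locations` (UniProt "Subcellular location" terms, pipe
#' separated). Comparisons downstream are case-insensitive after trimming.
#'
#' @param path TSV file.
#' @return data frame `protein`, `topology`, `locations` (each a single
#'   pipe-separated string; may be empty).
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("protein", "topology", "locations")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$protein))
    stop("duplicate protein IDs in annotation table")
  df$topology[is.na(df$topology)] <- ""
  df$locations[is.na(df$locations)] <- ""
  df[need]
}

trim_lower <- function(x) tolower(trimws(x))

split_locations <- function(locations) {
  lapply(strsplit(locations, "|", fixed = TRUE),
         function(v) trim_lower(v[nzchar(trimws(v))]))
}

# topology terms defining an integral membrane protein
TRANSMEMBRANE_TERMS <- c("single-pass type i membrane protein",
                         "single-pass type ii membrane protein",
                         "multi-pass membrane protein")

# subcellular-location categories defining the endosomal/vesicular system;
# "cytoplasmic vesicle" matches singular and plural
ENDOSOMAL_CATEGORIES <- c("early endosome", "late endosome", "lysosome",
                          "cytoplasmic vesicle")

# membrane location groups used for the chord-style membership export
MEMBRANE_GROUPS <- c(Membrane = "membrane",
                     `Focal adhesion` = "focal adhesion",
                     `Cell membrane` = "cell membrane",
                     `Cell Junction` = "cell junction")

#' Select transmembrane proteins by topology annotation
#'
#' A protein is transmembrane when its topology string contains (case-
#' insensitive substring) any of "Single-pass type I membrane protein",
#' "Single-pass type II membrane protein" or "Multi-pass membrane protein".
#' Proteins with an empty topology string are treated as non-transmembrane
#' with a warning.
#'
#' @param records annotation data frame as from [read_annotations()].
#' @return character vector of transmembrane protein IDs.
#' @export
classify_transmembrane <- function(records) {
  topo <- trim_lower(records$topology)
  empty <- !nzchar(topo)
  if (any(empty))
    warning(sum(empty), " protein(s) lack topology annotation; ",
            "treated as non-transmembrane")
  hit <- rep(FALSE, nrow(records))
  for (term in TRANSMEMBRANE_TERMS)
    hit <- hit | grepl(term, topo, fixed = TRUE)
  records$protein[hit]
}

#' Select endosome-located proteins by subcellular location
#'
#' A protein is endosome-located when any of its subcellular-location strings
#' matches (case-insensitive substring) one of "Early endosome",
#' "Late endosome", "Lysosome" or "Cytoplasmic vesicle(s)" (singular and
#' plural both accepted).
#'
#' @param records annotation data frame.
#' @return character vector of endosome-located protein IDs.
#' @export
classify_endosomal <- function(records) {
  locs <- split_locations(records$locations)
  empty <- lengths(locs) == 0
  if (any(empty))
    warning(sum(empty), " protein(s) lack subcellular-location annotation")
  hit <- vapply(locs, function(v) {
    any(vapply(ENDOSOMAL_CATEGORIES, function(cat)
      any(grepl(cat, v, fixed = TRUE)), logical(1)))
  }, logical(1))
  records$protein[hit]
}

#' Group transmembrane proteins by membrane location
#'
#' Assigns each transmembrane protein to one or more of the groups
#' "Membrane", "Focal adhesion", "Cell membrane" and "Cell Junction" by
#' case-insensitive substring match on its subcellular locations; a protein
#' with k matching groups yields k rows. Proteins matching no group are
#' emitted under "Other" with a warning. The long-format table is the export
#' used for chord-style membership diagrams.
#'
#' @param records annotation data frame restricted to the transmembrane
#'   subset.
#' @return data frame `protein`, `group`, one row per membership.
#' @export
group_membrane_locations <- function(records) {
  locs <- split_locations(records$locations)
  out <- vector("list", nrow(records))
  n_other <- 0L
  for (i in seq_len(nrow(records))) {
    joined <- paste(locs[[i]], collapse = " | ")
    grp <- names(MEMBRANE_GROUPS)[vapply(MEMBRANE_GROUPS, function(pat)
      grepl(pat, joined, fixed = TRUE), logical(1))]
    # "cell membrane" contains "membrane": restrict the bare "Membrane"
    # group to locations that are exactly "membrane"
    if ("Membrane" %in% grp && !any(locs[[i]] == "membrane"))
      grp <- setdiff(grp, "Membrane")
    if (length(grp) == 0) {
      grp <- "Other"
      n_other <- n_other + 1L
    }
    out[[i]] <- data.frame(protein = records$protein[i], group = grp,
                           stringsAsFactors = FALSE)
  }
  if (n_other > 0)
    warning(n_other, " transmembrane protein(s) matched no membrane group; ",
            "emitted under 'Other'")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein = character(), group = character())
  rownames(res) <- NULL
  res
}

#' Partition surface and endosomal interactor sets
#'
#' Exact set algebra over two ID lists: shared = intersection, union, and
#' the counts reported alongside.
#'
#' @param surface,endosomal character vectors of unique protein IDs.
#' @return an object of class `interactome_sets`: list with `surface`,
#'   `endosomal`, `shared`, `union` and a `counts` vector.
#' @export
partition_sets <- function(surface, endosomal) {
  if (anyDuplicated(surface)) stop("duplicate IDs in the surface list")
  if (anyDuplicated(endosomal)) stop("duplicate IDs in the endosomal list")
  shared <- sort(intersect(surface, endosomal))
  un <- sort(union(surface, endosomal))
  structure(list(surface = sort(surface), endosomal = sort(endosomal),
                 shared = shared, union = un,
                 counts = c(surface = length(surface),
                            endosomal = length(endosomal),
                            shared = length(shared),
                            union = length(un))),
            class = "interactome_sets")
}

#' @export
print.interactome_sets <- function(x, ...) {
  cat("interactome_sets:",
      sprintf("%d surface / %d endosomal / %d shared / %d distinct\n",
              x$counts["surface"], x$counts["endosomal"],
              x$counts["shared"], x$counts["union"]))
  invisible(x)
}

#' Read a GMT category file
#'
#' Standard gene-set format: one tab-separated line per category with the
#' category name, a description, then member IDs.
#'
#' @param path GMT file.
#' @return named list of character member vectors; descriptions in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write categories to a GMT file
#'
#' @param categories named list of character member vectors.
#' @param path output path.
#' @param description optional description per category (recycled).
#' @export
write_gmt <- function(categories, path, description = "") {
  description <- rep_len(description, length(categories))
  lines <- vapply(seq_along(categories), function(i)
    paste(c(names(categories)[i], description[i], categories[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric category over-representation test
#'
#' For each category, tests whether the query set overlaps it more than
#' expected by chance within the universe: one-sided
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = |universe|,
#' K = |category ∩ universe|, n = |query|)`. BH adjustment is applied across
#' the tested categories; categories with fewer than `min_category_size`
#' members in the universe are skipped as degenerate.
#'
#' @param query character vector of IDs; must be a subset of `universe`.
#' @param categories named list of member ID vectors (GMT-like).
#' @param universe character vector of background IDs.
#' @param fdr significance threshold on the BH q value (default 0.05).
#' @param min_category_size smallest in-universe category tested (default 2).
#' @return data frame `category`, `size` (in universe), `overlap`, `expected`,
#'   `p`, `q`, `significant`, ordered by p.
#' @export
hypergeometric_enrichment <- function(query, categories, universe,
                                      fdr = 0.05, min_category_size = 2L) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query set")
  if (!all(query %in% universe))
    stop("query contains IDs absent from the universe")
  sizes <- vapply(categories, function(memb)
    length(intersect(memb, universe)), integer(1))
  keep <- sizes >= min_category_size
  categories <- categories[keep]
  sizes <- sizes[keep]
  if (length(categories) == 0)
    return(data.frame(category = character(), size = integer(),
                      overlap = integer(), expected = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  N <- length(universe)
  n <- length(query)
  overlap <- vapply(categories, function(memb)
    length(intersect(intersect(memb, universe), query)), integer(1))
  # P(X >= k) = upper tail of the hypergeometric at k - 1
  p <- stats::phyper(overlap - 1, sizes, N - sizes, n, lower.tail = FALSE)
  q <- bh_fdr(p)
  res <- data.frame(category = names(categories), size = sizes,
                    overlap = overlap, expected = n * sizes / N,
                    p = p, q = q, significant = q < fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p, res$category), , drop = FALSE]
}
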
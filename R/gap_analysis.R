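#' Intra-specific and intra-generic divergence summary
#'
#' Summarises pairwise p-distances per species (all conspecific pairs) and
#' per genus (all heterospecific pairs within the genus, i.e. inter-specific
#' comparisons between all individuals), reporting minimum, mean and maximum
#' of the defined distances, plus pooled totals. Species with a single
#' sequence and genera with a single species yield `NA` rows.
#'
#' @param m A `pdist` object from [distance_matrix()].
#' @param records Matching record `data.frame`.
#' @return A list of class `divergence_summary` with data frames
#'   `per_species` (`species`, `n`, `min`, `mean`, `max`), `per_genus`
#'   (`genus`, `n_species`, `min`, `mean`, `max`) and `total` (rows
#'   `intraspecific`, `intrageneric`).
#' @export
divergence_summary <- function(m, records) {
  pt <- pair_table(m, records)
  summ <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) c(min = NA_real_, mean = NA_real_, max = NA_real_)
    else c(min = min(x), mean = mean(x), max = max(x))
  }
  sp_levels <- unique(records$species)
  per_species <- do.call(rbind, lapply(sp_levels, function(sp) {
    dd <- pt$d[pt$same_species & pt$species1 == sp]
    data.frame(species = sp, n = sum(records$species == sp), t(summ(dd)),
               stringsAsFactors = FALSE)
  }))
  gn_levels <- unique(records$genus)
  per_genus <- do.call(rbind, lapply(gn_levels, function(g) {
    dd <- pt$d[pt$same_genus & !pt$same_species & pt$genus1 == g]
    data.frame(genus = g,
               n_species = length(unique(records$species[records$genus == g])),
               t(summ(dd)), stringsAsFactors = FALSE)
  }))
  total <- rbind(
    data.frame(class = "intraspecific", t(summ(pt$d[pt$same_species]))),
    data.frame(class = "intrageneric",
               t(summ(pt$d[pt$same_genus & !pt$same_species]))))
  structure(list(per_species = per_species, per_genus = per_genus,
                 total = total),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Divergence summary (p-distance, %):\n")
  tt <- x$total
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-14s min %.2f  mean %.2f  max %.2f\n", tt$class[i],
                100 * tt$min[i], 100 * tt$mean[i], 100 * tt$max[i]))
  invisible(x)
}

#' Percentile threshold of intra-specific distances
#'
#' The q-th percentile of all pooled intra-specific pairwise distances,
#' the conventional data-driven identification threshold (the classic
#' choice is q = 95). Linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param m A `pdist` object.
#' @param records Matching record `data.frame`.
#' @param q Percentile in `[0, 100]`; default 95.
#' @return A single distance in `[0, 1]`.
#' @export
percentile_threshold <- function(m, records, q = 95) {
  pt <- pair_table(m, records)
  intra <- pt$d[pt$same_species & !is.na(pt$d)]
  if (length(intra) == 0L)
    stop("empty-set error: no defined intra-specific pairs")
  unname(stats::quantile(intra, q / 100, type = 7))
}

#' Global barcoding-gap report
#'
#' Builds frequency histograms of conspecific (intra-specific) versus
#' heterospecific (inter-specific) pairwise distances on shared bins and
#' quantifies their overlap: the overlap interval is
#' `[min inter-specific, max intra-specific]`; a global barcoding gap is
#' present when the interval is empty (max intra < min inter). The
#' `overlap_fraction` is the fraction of all defined pairwise distances
#' falling inside the interval. A trimmed variant of the interval, computed
#' after discarding the extreme 5% of each class, is also reported
#' (`overlap_interval_trimmed`); this is one reading of the "90% overlap"
#' statistic of classic barcode-clustering software and is labelled as an
#' interpretation.
#'
#' At `grouping = "species"` all pairs in the dataset are used (one global
#' report). At `"genus"` or `"higher_taxon"` comparisons are restricted to
#' pairs within each group and one report per group is returned.
#'
#' @param m A `pdist` object.
#' @param records Matching record `data.frame`.
#' @param grouping `"species"`, `"genus"` or `"higher_taxon"`.
#' @param bin_width Histogram bin width on the distance scale (default 0.01,
#'   i.e. one percentage point).
#' @return A `gap_report` (or, for group-restricted runs, a named list of
#'   `gap_report`s): histograms, `overlap_interval`, `overlap_width`,
#'   `overlap_fraction`, `global_gap_present`, plus the trimmed interval.
#' @export
global_gap_report <- function(m, records,
                              grouping = c("species", "genus", "higher_taxon"),
                              bin_width = 0.01) {
  grouping <- match.arg(grouping)
  pt <- pair_table(m, records)
  if (grouping == "species") return(gap_report_from_pairs(pt, bin_width))
  key <- if (grouping == "genus") records$genus else records$higher_taxon
  within <- if (grouping == "genus") pt$same_genus else pt$same_higher
  groups <- unique(key)
  out <- lapply(groups, function(g) {
    sub <- pt[within &
                (if (grouping == "genus") pt$genus1 else pt$higher1) == g,
              , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    gap_report_from_pairs(sub, bin_width)
  })
  names(out) <- groups
  out[!vapply(out, is.null, logical(1))]
}

# internal: gap report from a pair table subset
gap_report_from_pairs <- function(pt, bin_width) {
  intra <- pt$d[pt$same_species & !is.na(pt$d)]
  inter <- pt$d[!pt$same_species & !is.na(pt$d)]
  if (length(intra) == 0L || length(inter) == 0L) {
    return(structure(list(
      n_intra = length(intra), n_inter = length(inter),
      histogram = NULL, overlap_interval = c(NA_real_, NA_real_),
      overlap_width = NA_real_, overlap_fraction = NA_real_,
      global_gap_present = NA,
      overlap_interval_trimmed = c(NA_real_, NA_real_)),
      class = "gap_report"))
  }
  breaks <- seq(0, ceiling(max(intra, inter) / bin_width) * bin_width +
                  bin_width, by = bin_width)
  h_intra <- graphics::hist(intra, breaks = breaks, plot = FALSE)
  h_inter <- graphics::hist(inter, breaks = breaks, plot = FALSE)
  lower <- min(inter)
  upper <- max(intra)
  width <- max(0, upper - lower)
  all_d <- c(intra, inter)
  frac <- if (width > 0) mean(all_d >= lower & all_d <= upper) else 0
  trim <- function(x) stats::quantile(x, c(0.05, 0.95), type = 7)
  ti <- trim(intra); te <- trim(inter)
  structure(list(
    n_intra = length(intra), n_inter = length(inter),
    histogram = data.frame(bin_lower = breaks[-length(breaks)],
                           bin_upper = breaks[-1],
                           intra = h_intra$counts, inter = h_inter$counts),
    overlap_interval = c(lower = lower, upper = upper),
    overlap_width = width,
    overlap_fraction = frac,
    global_gap_present = upper < lower,
    overlap_interval_trimmed = c(lower = unname(te[1]), upper = unname(ti[2]))),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Barcoding-gap report:", x$n_intra, "intra /", x$n_inter, "inter pairs\n")
  if (!is.na(x$overlap_width)) {
    cat(sprintf("  overlap interval [%.2f%%, %.2f%%], width %.2f%%, %.2f%% of pairs inside\n",
                100 * x$overlap_interval[1], 100 * x$overlap_interval[2],
                100 * x$overlap_width, 100 * x$overlap_fraction))
    cat("  global barcoding gap:", if (isTRUE(x$global_gap_present)) "present" else "absent", "\n")
  }
  invisible(x)
}

#' Local barcoding-gap table
#'
#' For every species with at least two sequences: the maximum intra-specific
#' distance (distance to the furthest conspecific) versus the
#' nearest-neighbour distance (minimum distance from any member to any
#' heterospecific sequence). A local gap is present when max intra < NN.
#' Species with a single sequence are omitted, since their maximum
#' intra-specific distance is undefined.
#'
#' @param m A `pdist` object.
#' @param records Matching record `data.frame`.
#' @return A `data.frame` with columns `species`, `n`, `max_intra`,
#'   `nn_dist`, `nearest_neighbour` (species name) and `local_gap_present`.
#' @export
local_gap_table <- function(m, records) {
  pt <- pair_table(m, records)
  sp_counts <- table(records$species)
  multi <- names(sp_counts)[sp_counts >= 2L]
  out <- lapply(multi, function(sp) {
    intra <- pt$d[pt$same_species & pt$species1 == sp]
    inter_rows <- !pt$same_species & (pt$species1 == sp | pt$species2 == sp)
    inter <- pt$d[inter_rows]
    if (all(is.na(intra)) || all(is.na(inter))) return(NULL)
    nn_idx <- which.min(pt$d[inter_rows])
    nn_row <- pt[inter_rows, ][nn_idx, ]
    nn_sp <- if (nn_row$species1 == sp) nn_row$species2 else nn_row$species1
    data.frame(species = sp, n = as.integer(sp_counts[sp]),
               max_intra = max(intra, na.rm = TRUE),
               nn_dist = min(inter, na.rm = TRUE),
               nearest_neighbour = nn_sp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(data.frame(species = character(), n = integer(),
                                      max_intra = numeric(), nn_dist = numeric(),
                                      nearest_neighbour = character(),
                                      local_gap_present = logical()))
  res$local_gap_present <- res$max_intra < res$nn_dist
  rownames(res) <- NULL
  res
}
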
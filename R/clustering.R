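#' Single-linkage threshold clustering of a barcode library
#'
#' Clusters sequences by the transitive closure of pairwise distances:
#' two sequences share a cluster iff they are connected by a chain of pairs
#' each at distance `<= threshold` (inclusive). This chaining rule is the
#' one under which a cluster's largest internal distance can *exceed* the
#' threshold — the classic "threshold violation". Implemented as
#' single-linkage agglomeration cut at the threshold height; undefined
#' pairwise distances are treated as non-edges (with a warning).
#'
#' @param m A `pdist` object.
#' @param threshold Distance threshold (p-distance scale).
#' @return An object of class `cluster_partition`: `threshold`,
#'   `membership` (named integer vector, id -> cluster index),
#'   `n_clusters`, `cluster_max_dist` (max internal distance per cluster;
#'   `NA` for singletons), `violation` (per-cluster flag:
#'   max internal distance > threshold). Taxonomy-dependent fields are
#'   filled in by [accuracy_and_violations()].
#' @export
cluster_at_threshold <- function(m, threshold) {
  stopifnot(inherits(m, "pdist"))
  d <- m$d
  if (anyNA(d[upper.tri(d)])) {
    warning("undefined pairwise distances treated as non-edges")
    d[is.na(d)] <- Inf
  }
  # inclusive threshold (<=) with a relative guard against representation
  # noise in distances computed as 1 - matches/overlap
  eps <- threshold * 1e-9 + 1e-12
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  membership <- stats::cutree(hc, h = threshold + eps)
  names(membership) <- m$ids
  k <- max(membership)
  cmax <- vapply(seq_len(k), function(cl) {
    ids <- which(membership == cl)
    if (length(ids) < 2L) return(NA_real_)
    sub <- m$d[ids, ids]
    max(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  structure(list(threshold = threshold, membership = membership,
                 n_clusters = k, cluster_max_dist = cmax,
                 violation = !is.na(cmax) & cmax > threshold + eps,
                 perfect = NULL, taxonomic_accuracy = NA_real_,
                 violation_percent = NA_real_,
                 max_species_per_cluster = NA_integer_),
            class = "cluster_partition")
}

#' Taxonomic accuracy as a percentage
#'
#' `100 * n_perfect / n_species`: the share of recognized species that are
#' represented by a *perfect* cluster (one containing all sequences of
#' exactly one species and only those).
#'
#' @param n_perfect Number of perfect clusters.
#' @param n_species Number of currently recognized species.
#' @return A percentage.
#' @export
taxonomic_accuracy <- function(n_perfect, n_species) {
  if (n_species <= 0) stop("argument error: n_species must be positive")
  100 * n_perfect / n_species
}

#' Score a cluster partition against the taxonomy
#'
#' Fills in the taxonomy-dependent fields of a [cluster_at_threshold()]
#' partition: per-cluster *perfect* flags (cluster = all sequences of
#' exactly one species and only those), taxonomic accuracy relative to the
#' number of recognized species, the percentage of clusters with threshold
#' violations, and the maximum number of species found in any one cluster.
#'
#' @param partition A `cluster_partition`.
#' @param records Matching record `data.frame`.
#' @param n_recognized_species Denominator of the taxonomic accuracy;
#'   defaults to the number of distinct species labels in `records`.
#' @return The updated `cluster_partition`.
#' @export
accuracy_and_violations <- function(partition, records,
                                    n_recognized_species = NULL) {
  stopifnot(inherits(partition, "cluster_partition"))
  check_records(records)
  if (is.null(n_recognized_species))
    n_recognized_species <- length(unique(records$species))
  if (n_recognized_species <= 0)
    stop("argument error: n_recognized_species must be positive")
  sp <- records$species[match(names(partition$membership), records$id)]
  sp_sizes <- table(sp)
  k <- partition$n_clusters
  perfect <- logical(k)
  n_species_in <- integer(k)
  for (cl in seq_len(k)) {
    in_cl <- sp[partition$membership == cl]
    u <- unique(in_cl)
    n_species_in[cl] <- length(u)
    perfect[cl] <- length(u) == 1L && length(in_cl) == sp_sizes[[u]]
  }
  partition$perfect <- perfect
  partition$taxonomic_accuracy <- taxonomic_accuracy(sum(perfect),
                                                     n_recognized_species)
  partition$violation_percent <- 100 * sum(partition$violation) / k
  partition$max_species_per_cluster <- max(n_species_in)
  partition
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Threshold clustering at %.4g: %d clusters", x$threshold,
              x$n_clusters))
  if (!is.null(x$perfect))
    cat(sprintf(", %d perfect (accuracy %.2f%%), %d violating (%.2f%%)",
                sum(x$perfect), x$taxonomic_accuracy, sum(x$violation),
                x$violation_percent))
  cat("\n")
  invisible(x)
}

#' Threshold sweep
#'
#' Clusters the library at each threshold and scores each partition; the
#' cluster count is non-increasing as the threshold grows.
#'
#' @param m A `pdist` object.
#' @param records Matching record `data.frame`.
#' @param thresholds Numeric vector of thresholds.
#' @param n_recognized_species See [accuracy_and_violations()].
#' @return A list of class `threshold_sweep`: `partitions` (one
#'   `cluster_partition` per threshold) and `summary` (`data.frame` with
#'   `threshold`, `n_clusters`, `n_perfect`, `taxonomic_accuracy`,
#'   `n_violations`, `violation_percent`, `max_species_per_cluster`).
#' @export
threshold_sweep <- function(m, records, thresholds,
                            n_recognized_species = NULL) {
  parts <- lapply(thresholds, function(th)
    accuracy_and_violations(cluster_at_threshold(m, th), records,
                            n_recognized_species))
  summary <- do.call(rbind, lapply(parts, function(p)
    data.frame(threshold = p$threshold, n_clusters = p$n_clusters,
               n_perfect = sum(p$perfect),
               taxonomic_accuracy = p$taxonomic_accuracy,
               n_violations = sum(p$violation),
               violation_percent = p$violation_percent,
               max_species_per_cluster = p$max_species_per_cluster)))
  structure(list(partitions = parts, summary = summary),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Threshold sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
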
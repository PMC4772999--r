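#' Pairwise p-distance between two aligned sequences
#'
#' The p-distance is the proportion of differing sites among the sites where
#' both sequences carry an unambiguous base (`A`, `C`, `G`, `T`); gaps and
#' ambiguity codes are dropped for that pair only (pairwise deletion). When
#' fewer than `min_overlap` sites are shared the distance is undefined and
#' `NA` is returned.
#'
#' @param seq_a,seq_b Aligned DNA strings of equal length.
#' @param min_overlap Minimum number of shared unambiguous sites for the
#'   distance to be defined.
#' @return A single numeric in `[0, 1]`, or `NA` if the overlap is too short.
#' @export
p_distance <- function(seq_a, seq_b, min_overlap = 300) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("argument error: sequences have unequal lengths")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  shared <- a %in% bases & b %in% bases
  n_shared <- sum(shared)
  if (n_shared < min_overlap) return(NA_real_)
  sum(a[shared] != b[shared]) / n_shared
}

#' Pairwise p-distance matrix for a barcode library
#'
#' Computes all pairwise p-distances under pairwise deletion (see
#' [p_distance()]) using indicator-matrix cross-products, so the full
#' matrix for hundreds of sequences takes well under a second. Pairs whose
#' shared unambiguous overlap falls below `min_overlap` are flagged
#' undefined (`NA`) and excluded from downstream summaries.
#'
#' @param records Record `data.frame` (see [read_alignment()]).
#' @param min_overlap Minimum shared unambiguous sites per pair; the
#'   conventional sweep values are 300, 400, 500, 600.
#' @return An object of class `pdist` — a list with `ids`, `d` (symmetric
#'   p-distance matrix, `NA` where undefined), `overlap` (symmetric matrix
#'   of shared-site counts) and `min_overlap`.
#' @export
distance_matrix <- function(records, min_overlap = 300) {
  check_records(records)
  if (nrow(records) < 2L) stop("argument error: need at least 2 records")
  M <- seq_matrix(records)
  bases <- c("A", "C", "G", "T")
  ind <- lapply(bases, function(b) (M == b) * 1)
  valid <- Reduce(`+`, ind)
  overlap <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  d <- 1 - matches / overlap
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- dimnames(overlap) <- list(records$id, records$id)
  structure(list(ids = records$id, d = d, overlap = overlap,
                 min_overlap = min_overlap),
            class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  n <- length(x$ids)
  nd <- sum(is.na(x$d[upper.tri(x$d)]))
  cat("p-distance matrix:", n, "sequences,", choose(n, 2), "pairs (",
      nd, "undefined at min overlap", x$min_overlap, ")\n")
  invisible(x)
}

# internal: logical masks over pairs (upper triangle, as index matrix)
# returns data.frame of pair indices i<j with distance and labels
pair_table <- function(m, records) {
  stopifnot(inherits(m, "pdist"))
  if (!identical(m$ids, records$id))
    records <- records[match(m$ids, records$id), ]
  idx <- which(upper.tri(m$d), arr.ind = TRUE)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    id1 = m$ids[idx[, 1]], id2 = m$ids[idx[, 2]],
    d = m$d[idx],
    same_species = records$species[idx[, 1]] == records$species[idx[, 2]],
    same_genus = records$genus[idx[, 1]] == records$genus[idx[, 2]],
    same_higher = records$higher_taxon[idx[, 1]] == records$higher_taxon[idx[, 2]],
    species1 = records$species[idx[, 1]], species2 = records$species[idx[, 2]],
    genus1 = records$genus[idx[, 1]], genus2 = records$genus[idx[, 2]],
    higher1 = records$higher_taxon[idx[, 1]],
    stringsAsFactors = FALSE)
}

#' Write / read a distance matrix as TSV
#'
#' Square format: ids in the first row and column. Long format: columns
#' `id1`, `id2`, `distance`, `overlap` (one row per unordered pair).
#'
#' @param m A `pdist` object.
#' @param path Output file.
#' @param format `"square"` or `"long"`.
#' @return Invisibly, `m`.
#' @export
write_distance_matrix <- function(m, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.table(m$d, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    idx <- which(upper.tri(m$d), arr.ind = TRUE)
    utils::write.table(
      data.frame(id1 = m$ids[idx[, 1]], id2 = m$ids[idx[, 2]],
                 distance = m$d[idx], overlap = m$overlap[idx]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(m)
}
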
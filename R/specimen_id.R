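#' Distance-based specimen identification criteria
#'
#' Leave-one-out query identification against a barcode reference library,
#' following the classic best match / best close match / all species
#' barcodes criteria. The query's own sequence is always excluded from its
#' candidate matches; distance ties keep the full tied set, which is what
#' creates the "ambiguous" verdict.
#'
#' * `best_match()`: find the minimum distance to any other sequence;
#'   *success* if every equally-best match is conspecific, *misidentified*
#'   if all are allospecific, *ambiguous* if the best set mixes species.
#' * `best_close_match()`: as `best_match()` but only matches at distance
#'   `<= threshold` are eligible; *no_match* when none qualifies.
#' * `all_species_barcodes()`: consider every sequence within the threshold:
#'   *success* iff the set is non-empty, all conspecific and contains all
#'   conspecifics of the query; *misidentified* if all allospecific;
#'   *no_match* if empty; *ambiguous* otherwise (mixed, or some conspecific
#'   missing from the set).
#'
#' @param query_id Id of the query record (must be present in the library).
#' @param m A `pdist` object over the full library (query included).
#' @param records Matching record `data.frame`.
#' @param threshold Distance threshold on the p-distance scale (e.g. 0.01).
#' @return A one-row `data.frame`: `query_id`, `criterion`, `threshold`,
#'   `verdict` (`success` / `ambiguous` / `misidentified` / `no_match`),
#'   `evidence` (comma-separated matched species).
#' @name distance_identification
NULL

# internal: distances from one query to all others, with labels
query_candidates <- function(query_id, m, records) {
  if (length(m$ids) < 2L) stop("argument error: library of size 1")
  qi <- match(query_id, m$ids)
  if (is.na(qi)) stop("argument error: query not in library: ", query_id)
  rec <- records[match(m$ids, records$id), ]
  d <- m$d[qi, -qi]
  data.frame(id = m$ids[-qi], species = rec$species[-qi], d = d,
             stringsAsFactors = FALSE)
}

verdict_from_species <- function(matched_species, query_species) {
  same <- matched_species == query_species
  if (all(same)) "success" else if (!any(same)) "misidentified" else "ambiguous"
}

id_outcome <- function(query_id, criterion, threshold, verdict, evidence) {
  data.frame(query_id = query_id, criterion = criterion,
             threshold = if (is.null(threshold)) NA_real_ else threshold,
             verdict = verdict,
             evidence = paste(unique(evidence), collapse = ","),
             stringsAsFactors = FALSE)
}

#' @rdname distance_identification
#' @export
best_match <- function(query_id, m, records) {
  cand <- query_candidates(query_id, m, records)
  qsp <- records$species[match(query_id, records$id)]
  cand <- cand[!is.na(cand$d), , drop = FALSE]
  if (nrow(cand) == 0L)
    return(id_outcome(query_id, "best_match", NULL, "ambiguous", character()))
  best <- cand[cand$d == min(cand$d), , drop = FALSE]
  id_outcome(query_id, "best_match", NULL,
             verdict_from_species(best$species, qsp), best$species)
}

#' @rdname distance_identification
#' @export
best_close_match <- function(query_id, m, records, threshold) {
  cand <- query_candidates(query_id, m, records)
  qsp <- records$species[match(query_id, records$id)]
  eps <- threshold * 1e-9 + 1e-12   # inclusive cut-off, float-noise guard
  cand <- cand[!is.na(cand$d) & cand$d <= threshold + eps, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(id_outcome(query_id, "best_close_match", threshold, "no_match",
                      character()))
  best <- cand[cand$d == min(cand$d), , drop = FALSE]
  id_outcome(query_id, "best_close_match", threshold,
             verdict_from_species(best$species, qsp), best$species)
}

#' @rdname distance_identification
#' @export
all_species_barcodes <- function(query_id, m, records, threshold) {
  cand <- query_candidates(query_id, m, records)
  qsp <- records$species[match(query_id, records$id)]
  eps <- threshold * 1e-9 + 1e-12   # inclusive cut-off, float-noise guard
  inset <- cand[!is.na(cand$d) & cand$d <= threshold + eps, , drop = FALSE]
  if (nrow(inset) == 0L)
    return(id_outcome(query_id, "all_species_barcodes", threshold, "no_match",
                      character()))
  n_consp_total <- sum(cand$species == qsp)
  n_consp_in <- sum(inset$species == qsp)
  all_consp <- all(inset$species == qsp)
  verdict <- if (all_consp && n_consp_in == n_consp_total) "success"
  else if (n_consp_in == 0L) "misidentified"
  else "ambiguous"
  id_outcome(query_id, "all_species_barcodes", threshold, verdict,
             inset$species)
}

#' Leave-one-out identification report
#'
#' Runs every record once as a query under best match (threshold-free),
#' best close match and all species barcodes (at every supplied threshold),
#' and optionally the two tree-based criteria when a tree is given.
#' Aggregates verdict counts and percentages per criterion/threshold.
#'
#' @param records Record `data.frame`.
#' @param m A `pdist` object over the same records.
#' @param thresholds Numeric vector of distance thresholds (p-distance
#'   scale); the conventional set is `c(0.01, 0.03, 0.06, 0.09)` plus the
#'   95th-percentile threshold of the library.
#' @param tree Optional rooted tree (`phylo`, tips = record ids) on which
#'   the tree-based criteria are also evaluated.
#' @return A list of class `id_report`: `outcomes` (long `data.frame`) and
#'   `summary` (counts and percentages per criterion/threshold/verdict;
#'   percentages per criterion-threshold cell sum to 100).
#' @export
identification_report <- function(records, m, thresholds, tree = NULL) {
  check_records(records)
  out <- list()
  for (id in records$id) out[[length(out) + 1L]] <- best_match(id, m, records)
  for (th in thresholds) {
    for (id in records$id) {
      out[[length(out) + 1L]] <- best_close_match(id, m, records, th)
      out[[length(out) + 1L]] <- all_species_barcodes(id, m, records, th)
    }
  }
  outcomes <- do.call(rbind, out)
  if (!is.null(tree)) {
    outcomes <- rbind(outcomes,
                      tree_id_hebert(tree, records),
                      tree_id_meier(tree, records))
  }
  key <- paste(outcomes$criterion,
               ifelse(is.na(outcomes$threshold), "-", outcomes$threshold))
  tab <- table(key, factor(outcomes$verdict,
                           levels = c("success", "ambiguous",
                                      "misidentified", "no_match")))
  summary <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(summary) <- c("criterion_threshold", "verdict", "n")
  totals <- stats::ave(summary$n, summary$criterion_threshold, FUN = sum)
  summary$percent <- 100 * summary$n / totals
  structure(list(outcomes = outcomes, summary = summary), class = "id_report")
}

#' @export
print.id_report <- function(x, ...) {
  s <- x$summary[x$summary$verdict == "success", ]
  cat("Identification report (", length(unique(x$outcomes$query_id)),
      " queries):\n", sep = "")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-28s success %.1f%%\n", s$criterion_threshold[i],
                s$percent[i]))
  invisible(x)
}

#' Consensus barcode of one species
#'
#' Per-site strict-majority consensus: the most frequent base wins; ties
#' among bases are encoded as the IUPAC ambiguity code of the tied set, and
#' sites where gaps are at least as frequent as any base become gaps.
#'
#' @param sequences Character vector of aligned sequences of one species.
#' @return A single consensus string.
#' @export
consensus_barcode <- function(sequences) {
  if (length(sequences) == 0L) stop("argument error: no sequences")
  if (length(unique(nchar(sequences))) > 1L)
    stop("alignment error: unequal lengths")
  M <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
              nrow = length(sequences), byrow = TRUE)
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  apply(M, 2, function(col) {
    bases <- c("A", "C", "G", "T")
    cnt <- vapply(bases, function(b) sum(col == b), numeric(1))
    n_gap <- sum(col == "-")
    if (max(cnt) == 0 || n_gap >= max(cnt)) return("-")
    winners <- bases[cnt == max(cnt)]
    iupac[[paste(winners, collapse = "")]]
  }) |> paste(collapse = "")
}

#' Consensus-barcode uniqueness across species
#'
#' Builds one consensus barcode per species and reports whether any two
#' species share an identical consensus (i.e. fail to retain a unique
#' barcode at the consensus level).
#'
#' @param records Record `data.frame`.
#' @return A list: `consensus` (`data.frame` with `species`, `consensus`),
#'   `all_unique` (logical), `duplicates` (character vector of species in
#'   shared-consensus groups, empty when all unique).
#' @export
consensus_unique <- function(records) {
  check_records(records)
  sp <- unique(records$species)
  cons <- vapply(sp, function(s)
    consensus_barcode(records$sequence[records$species == s]), character(1))
  dup_seq <- unique(cons[duplicated(cons)])
  list(consensus = data.frame(species = sp, consensus = unname(cons),
                              stringsAsFactors = FALSE),
       all_unique = length(dup_seq) == 0L,
       duplicates = sp[cons %in% dup_seq])
}
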
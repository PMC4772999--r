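#' Read a species-labelled barcode alignment
#'
#' Reads an aligned FASTA file plus a 5-column tab-separated metadata table
#' (`id`, `species`, `genus`, `family`, `higher_taxon`, with header) and
#' returns one record per sequence, in FASTA file order. Sequences are
#' uppercased and `U` is mapped to `T`.
#'
#' All sequences must have identical (aligned) length, every FASTA id must
#' appear in the metadata, and ids must be unique. Records with an ungapped
#' length below `min_ungapped` (default 500, the usual barcode-standard
#' minimum) trigger a warning but are kept, since short-but-informative
#' barcodes are routinely retained in reference libraries.
#'
#' @param fasta_path Path to an aligned FASTA file (gap character `-`).
#' @param metadata_path Path to the metadata TSV.
#' @param min_ungapped Minimum ungapped length below which a warning is
#'   issued (not an error).
#' @return A `data.frame` with columns `id`, `species`, `genus`, `family`,
#'   `higher_taxon`, `sequence`.
#' @export
read_alignment <- function(fasta_path, metadata_path, min_ungapped = 500) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  dna <- seqinr::read.fasta(fasta_path, as.string = TRUE,
                            forceDNAtolower = FALSE)
  ids <- names(dna)
  seqs <- toupper(vapply(dna, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  needed <- c("id", "species", "genus", "family", "higher_taxon")
  if (!all(needed %in% names(meta)))
    stop("metadata error: missing column(s): ",
         paste(setdiff(needed, names(meta)), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate error: duplicated FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(meta$id))
    stop("duplicate error: duplicated metadata id(s)")
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(nchar(seqs))), collapse = ", "), ")")
  missing <- setdiff(ids, meta$id)
  if (length(missing) > 0L)
    stop("metadata error: FASTA id(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  m <- meta[match(ids, meta$id), needed]
  if (any(!nzchar(as.matrix(m))))
    stop("metadata error: empty taxonomic label(s)")
  rec <- data.frame(m, sequence = unname(seqs), stringsAsFactors = FALSE,
                    row.names = NULL)
  if (any(!grepl("[ACGT]", rec$sequence)))
    stop("alignment error: sequence(s) with no unambiguous base")
  short <- nchar(gsub("-", "", rec$sequence)) < min_ungapped
  if (any(short))
    warning(sum(short), " sequence(s) shorter than ", min_ungapped,
            " ungapped bases: ", paste(rec$id[short], collapse = ", "))
  rec
}

#' Write a barcode alignment and its metadata
#'
#' Inverse of [read_alignment()]: writes the aligned FASTA and the 5-column
#' metadata TSV so that reading them back reproduces the records.
#'
#' @param records Record `data.frame` as returned by [read_alignment()].
#' @param fasta_path,metadata_path Output file paths.
#' @return Invisibly, the record data frame.
#' @export
write_alignment <- function(records, fasta_path, metadata_path) {
  check_records(records)
  lines <- as.vector(rbind(paste0(">", records$id), records$sequence))
  writeLines(lines, fasta_path)
  utils::write.table(records[, c("id", "species", "genus", "family",
                                 "higher_taxon")],
                     metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}

# internal: validate a record data frame
check_records <- function(records) {
  needed <- c("id", "species", "genus", "family", "higher_taxon", "sequence")
  if (!is.data.frame(records) || !all(needed %in% names(records)))
    stop("records must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  if (nrow(records) < 1L) stop("argument error: empty record set")
  if (anyDuplicated(records$id)) stop("duplicate error: duplicated ids")
  if (length(unique(nchar(records$sequence))) > 1L)
    stop("alignment error: unequal sequence lengths")
  invisible(records)
}

# internal: alignment as a character matrix (rows = sequences)
seq_matrix <- function(records) {
  L <- nchar(records$sequence[1])
  matrix(unlist(strsplit(records$sequence, "", fixed = TRUE), use.names = FALSE),
         nrow = nrow(records), ncol = L, byrow = TRUE,
         dimnames = list(records$id, NULL))
}

#' Library-level composition and site statistics
#'
#' Pools base frequencies over all unambiguous bases (`A`, `C`, `G`, `T`)
#' of all sequences, and classifies alignment sites. A site is *conserved*
#' when all non-gap, non-ambiguous states agree (ambiguity codes are treated
#' as non-contradicting), *variable* otherwise, and a *singleton* when
#' exactly one sequence differs from the shared state of all the others.
#'
#' @param records Record `data.frame` (see [read_alignment()]).
#' @return A list of class `alignment_stats`: `n_sequences`,
#'   `alignment_length`, `base_frequencies` (named, sums to 1),
#'   `gc_content`, `n_conserved`, `n_variable`, `n_singleton`,
#'   `min_length_ungapped`.
#' @export
composition_stats <- function(records) {
  check_records(records)
  M <- seq_matrix(records)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) sum(M == b), numeric(1))
  if (sum(counts) == 0) stop("argument error: no unambiguous bases")
  freqs <- counts / sum(counts)
  per_site <- apply(M, 2, function(col) {
    obs <- col[col %in% bases]
    if (length(obs) == 0L) return(c(conserved = 1, variable = 0, singleton = 0))
    tab <- table(obs)
    if (length(tab) == 1L) return(c(conserved = 1, variable = 0, singleton = 0))
    single <- as.integer(length(tab) == 2L && min(tab) == 1L)
    c(conserved = 0, variable = 1, singleton = single)
  })
  structure(list(
    n_sequences = nrow(records),
    alignment_length = ncol(M),
    base_frequencies = freqs,
    gc_content = unname(freqs["G"] + freqs["C"]),
    n_conserved = sum(per_site["conserved", ]),
    n_variable = sum(per_site["variable", ]),
    n_singleton = sum(per_site["singleton", ]),
    min_length_ungapped = min(nchar(gsub("-", "", records$sequence)))
  ), class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat("Alignment of", x$n_sequences, "sequences,", x$alignment_length, "sites\n")
  cat(sprintf("  base frequencies: A=%.1f%% C=%.1f%% G=%.1f%% T=%.1f%% (GC=%.1f%%)\n",
              100 * x$base_frequencies["A"], 100 * x$base_frequencies["C"],
              100 * x$base_frequencies["G"], 100 * x$base_frequencies["T"],
              100 * x$gc_content))
  cat(sprintf("  sites: %d conserved, %d variable, %d singleton\n",
              x$n_conserved, x$n_variable, x$n_singleton))
  invisible(x)
}

#' Stop-codon screen under the vertebrate mitochondrial code
#'
#' Translates every record in the given reading frame under the vertebrate
#' mitochondrial genetic code (where `AGA`/`AGG` are stops in addition to
#' `TAA`/`TAG`) and reports the number of stop codons per record, a standard
#' pseudogene screen for protein-coding barcodes. Codons containing gaps or
#' ambiguity codes are not translated and are flagged instead.
#'
#' @param records Record `data.frame`.
#' @param frame Reading frame offset: 0, 1 or 2.
#' @return A `data.frame` with columns `id`, `n_stops`,
#'   `n_gap_codons` (codons containing a gap) and `clean`
#'   (`TRUE` when no stops and no gap codons).
#' @export
translation_check <- function(records, frame = 0) {
  check_records(records)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- strsplit(records$sequence[i], "", fixed = TRUE)[[1]]
    s <- s[(frame + 1):length(s)]
    n_codon <- length(s) %/% 3L
    s <- s[seq_len(n_codon * 3L)]
    has_gap <- colSums(matrix(s == "-", nrow = 3L)) > 0
    s_clean <- ifelse(s %in% c("A", "C", "G", "T"), s, "N")
    aa <- seqinr::translate(s_clean, numcode = 2)
    data.frame(id = records$id[i],
               n_stops = sum(aa == "*" & !has_gap),
               n_gap_codons = sum(has_gap),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$clean <- res$n_stops == 0L & res$n_gap_codons == 0L
  res
}
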
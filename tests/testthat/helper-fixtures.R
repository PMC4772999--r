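# Fixture builders: all synthetic, generated in code.

# records data.frame from parallel vectors, with default taxonomy
fix_records <- function(ids, species, seqs, genus = NULL, family = "f1",
                        higher = "h1") {
  if (is.null(genus)) genus <- rep("g1", length(ids))
  data.frame(id = ids, species = species, genus = genus, family = family,
             higher_taxon = higher, sequence = seqs,
             stringsAsFactors = FALSE)
}

# a sequence of length L equal to the reference except at `diff_at` positions
mutate_seq <- function(ref, diff_at) {
  s <- strsplit(ref, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  s[diff_at] <- swap[s[diff_at]]
  paste(s, collapse = "")
}

base_seq <- function(L, seed = 7) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# two-species fixture with an exact distance structure:
# species A: a1 vs a2 differ at n_intra sites; species B: b1 = a1 mutated at
# n_inter sites disjoint from the intra set, b2 = b1.
gap_fixture <- function(L, n_intra, n_inter) {
  ref <- base_seq(L)
  a1 <- ref
  a2 <- mutate_seq(ref, seq_len(n_intra))
  b1 <- mutate_seq(ref, L - seq_len(n_inter) + 1L)
  fix_records(c("a1", "a2", "b1", "b2"),
              c("A", "A", "B", "B"),
              c(a1, a2, b1, b1),
              genus = c("g1", "g1", "g1", "g1"))
}

# K well-separated species blocks; 5 of them carry an internal chain
# a-b 0.02 / b-c 0.02 / a-c 0.04 (L = 100) so they violate a 3% threshold.
violation_fixture <- function(n_clusters = 24, n_violating = 5, L = 100) {
  ref <- base_seq(L)
  recs <- list()
  for (k in seq_len(n_clusters)) {
    # separate blocks by ~20% so clusters never chain together
    block_ref <- mutate_seq(ref, ((k - 1) * 3) %% (L - 30) + seq_len(20))
    sp <- sprintf("v%02d", k)
    if (k <= n_violating) {
      a <- block_ref
      b <- mutate_seq(block_ref, 21:22)
      c_ <- mutate_seq(block_ref, 23:24)
      recs[[k]] <- fix_records(paste0(sp, "_", 1:3), rep(sp, 3),
                               c(a, b, c_))
    } else {
      recs[[k]] <- fix_records(paste0(sp, "_", 1:2), rep(sp, 2),
                               c(block_ref, mutate_seq(block_ref, 21L)))
    }
  }
  do.call(rbind, recs)
}

# wrap a plain distance matrix in the pdist container (for tree tests)
as_pdist <- function(d, ids = rownames(d)) {
  structure(list(ids = ids, d = d,
                 overlap = matrix(1e6, nrow(d), ncol(d)),
                 min_overlap = 1),
            class = "pdist")
}

# random labelled alignment with optional gaps/ambiguities
random_records <- function(n_seq, L, n_species, seed, gap_frac = 0,
                           amb_frac = 0) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  seqs <- replicate(n_seq, {
    s <- sample(alphabet, L, replace = TRUE)
    if (gap_frac > 0) s[sample(L, round(gap_frac * L))] <- "-"
    if (amb_frac > 0) s[sample(L, round(amb_frac * L))] <- "N"
    paste(s, collapse = "")
  })
  sp <- sprintf("sp%d", rep_len(seq_len(n_species), n_seq))
  fix_records(sprintf("q%02d", seq_len(n_seq)), sp, seqs,
              genus = sprintf("g%d", rep_len(seq_len(max(1, n_species %/% 2)),
                                             n_seq)))
}
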
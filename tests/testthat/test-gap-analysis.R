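test_that("divergence summary matches a brute-force group-wise oracle", {
  rec <- random_records(8, 60, 3, 21)
  m <- distance_matrix(rec, min_overlap = 1)
  ds <- divergence_summary(m, rec)
  # brute force over explicit index pairs
  for (sp in unique(rec$species)) {
    idx <- which(rec$species == sp)
    vals <- c()
    if (length(idx) >= 2)
      for (i in idx) for (j in idx) if (i < j) vals <- c(vals, m$d[i, j])
    row <- ds$per_species[ds$per_species$species == sp, ]
    if (length(vals)) {
      expect_equal(row$min, min(vals)); expect_equal(row$max, max(vals))
      expect_equal(row$mean, mean(vals))
    } else expect_true(is.na(row$min))
  }
  tot <- ds$total
  expect_true(all(tot$min <= tot$mean & tot$mean <= tot$max, na.rm = TRUE))
})

test_that("degenerate groups give collapsed min/mean/max", {
  rec <- fix_records(c("a1", "a2", "b1"), c("A", "A", "B"),
                     c("AAAAAAAAAA", "AAAAAAAAAA", "TTTTAAAAAA"),
                     genus = rep("g1", 3))
  m <- distance_matrix(rec, min_overlap = 1)
  ds <- divergence_summary(m, rec)
  a <- ds$per_species[ds$per_species$species == "A", ]
  expect_equal(c(a$min, a$mean, a$max), c(0, 0, 0))
  g <- ds$per_genus[ds$per_genus$genus == "g1", ]
  expect_equal(c(g$min, g$mean, g$max), rep(0.4, 3))
})

test_that("percentile threshold follows the sort-and-interpolate oracle", {
  rec <- fix_records(c("a1", "a2"), c("A", "A"),
                     c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAT"))
  m <- distance_matrix(rec, min_overlap = 1)
  # constant sample: every percentile equals it
  for (q in c(0, 50, 95, 100))
    expect_equal(percentile_threshold(m, rec, q), 0.05)

  # ten known intra distances 0.01..0.10 via ten pairs in ten species
  L <- 100
  ref <- base_seq(L)
  recs <- do.call(rbind, lapply(1:10, function(k)
    fix_records(sprintf("s%d_%d", k, 1:2), rep(sprintf("sp%d", k), 2),
                c(ref, mutate_seq(ref, seq_len(k))))))
  m10 <- distance_matrix(recs, min_overlap = 1)
  xs <- (1:10) / 100
  # type-7 oracle computed from first principles
  oracle_q <- function(p) {
    h <- (10 - 1) * p + 1
    lo <- floor(h)
    sort(xs)[lo] + (h - lo) * (sort(xs)[min(lo + 1, 10)] - sort(xs)[lo])
  }
  expect_equal(percentile_threshold(m10, recs, 95), oracle_q(0.95))
  expect_equal(percentile_threshold(m10, recs, 100), max(xs))
  # monotone in q
  qs <- sapply(seq(0, 100, by = 5), function(q)
    percentile_threshold(m10, recs, q))
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("overlap interval and width reproduce printed-bound arithmetic", {
  rec <- gap_fixture(L = 10000, n_intra = 1710, n_inter = 313)
  m <- distance_matrix(rec, min_overlap = 1)
  gr <- global_gap_report(m, rec)
  expect_equal(unname(gr$overlap_interval), c(0.0313, 0.1710))
  expect_equal(gr$overlap_width, 0.1397)
  expect_false(gr$global_gap_present)
  # brute-force overlap fraction: pairs inside [min inter, max intra]
  all_d <- m$d[upper.tri(m$d)]
  expect_equal(gr$overlap_fraction,
               mean(all_d >= gr$overlap_interval["lower"] &
                      all_d <= gr$overlap_interval["upper"]))
})

test_that("disjoint intra/inter ranges flag a global gap of width zero", {
  rec <- gap_fixture(L = 1000, n_intra = 50, n_inter = 90)
  m <- distance_matrix(rec, min_overlap = 1)
  gr <- global_gap_report(m, rec)
  expect_true(gr$global_gap_present)
  expect_equal(gr$overlap_width, 0)
  expect_equal(gr$overlap_fraction, 0)
})

test_that("pooled max intra equals the upper end of the overlap interval", {
  for (seed in 1:3) {
    rec <- random_records(8, 80, 3, seed)
    m <- distance_matrix(rec, min_overlap = 1)
    ds <- divergence_summary(m, rec)
    gr <- global_gap_report(m, rec)
    expect_equal(unname(gr$overlap_interval["upper"]),
                 ds$total$max[ds$total$class == "intraspecific"])
  }
})

test_that("grouped gap reports restrict comparisons within each group", {
  rec <- rbind(gap_fixture(1000, 20, 100),
               within(gap_fixture(1000, 10, 200), {
                 id <- paste0(id, "x"); species <- paste0(species, "x")
                 genus <- "g2"
               }))
  m <- distance_matrix(rec, min_overlap = 1)
  byg <- global_gap_report(m, rec, grouping = "genus")
  expect_named(byg, c("g1", "g2"))
  expect_equal(unname(byg$g1$overlap_interval), c(0.100, 0.020))
  expect_true(byg$g1$global_gap_present)
})

test_that("local gap table matches a brute-force per-species scan", {
  rec <- random_records(10, 80, 4, 5)
  m <- distance_matrix(rec, min_overlap = 1)
  lg <- local_gap_table(m, rec)
  for (sp in lg$species) {
    idx <- which(rec$species == sp)
    intra <- c(); inter <- c()
    for (i in seq_len(9)) for (j in (i + 1):10) {
      if (rec$species[i] == sp && rec$species[j] == sp)
        intra <- c(intra, m$d[i, j])
      else if (xor(rec$species[i] == sp, rec$species[j] == sp))
        inter <- c(inter, m$d[i, j])
    }
    row <- lg[lg$species == sp, ]
    expect_equal(row$max_intra, max(intra))
    expect_equal(row$nn_dist, min(inter))
    expect_equal(row$local_gap_present, max(intra) < min(inter))
  }
  # singleton species are omitted
  rec2 <- rbind(rec[1, ], rec[3:10, ])
  rec2$species[1] <- "lonely"
  lg2 <- local_gap_table(distance_matrix(rec2, min_overlap = 1), rec2)
  expect_false("lonely" %in% lg2$species)
})
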
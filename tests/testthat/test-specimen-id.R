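# fixture with controlled distances (L = 100):
# species A: a1,a2,a3 mutually within 1-2%; species B: b1,b2 within 1%;
# species C: singleton c1; A-B about 10%, C about 20% from everything.
id_fixture <- function() {
  ref <- base_seq(100, seed = 3)
  a1 <- ref
  a2 <- mutate_seq(ref, 1)
  a3 <- mutate_seq(ref, 2:3)
  b1 <- mutate_seq(ref, 11:20)
  b2 <- mutate_seq(b1, 1)
  c1 <- mutate_seq(ref, 31:50)
  fix_records(c("a1", "a2", "a3", "b1", "b2", "c1"),
              c("A", "A", "A", "B", "B", "C"),
              c(a1, a2, a3, b1, b2, c1))
}

test_that("best match follows the tie-aware nearest-neighbour rule", {
  rec <- id_fixture()
  m <- distance_matrix(rec, min_overlap = 1)
  expect_equal(best_match("a1", m, rec)$verdict, "success")
  # singleton species: nearest is always allospecific
  expect_equal(best_match("c1", m, rec)$verdict, "misidentified")
  # exact tie between a conspecific and an allospecific -> ambiguous
  ref <- base_seq(60, seed = 9)
  tie <- fix_records(c("q", "con", "allo"), c("A", "A", "B"),
                     c(ref, mutate_seq(ref, 1:3), mutate_seq(ref, 11:13)))
  mt <- distance_matrix(tie, min_overlap = 1)
  expect_equal(best_match("q", mt, tie)$verdict, "ambiguous")
})

test_that("best close match adds the no-match verdict at the threshold", {
  rec <- id_fixture()
  m <- distance_matrix(rec, min_overlap = 1)
  expect_equal(best_close_match("a1", m, rec, 0.01)$verdict, "success")
  # nearest neighbour of c1 is ~18% away: no match at small thresholds
  expect_equal(best_close_match("c1", m, rec, 0.01)$verdict, "no_match")
  expect_equal(best_close_match("c1", m, rec, 0.06)$verdict, "no_match")
  # inclusive threshold: distance exactly at the cut-off still matches
  expect_equal(best_close_match("a2", m, rec, 0.01)$verdict, "success")
})

test_that("all species barcodes demands the complete conspecific set", {
  rec <- id_fixture()
  m <- distance_matrix(rec, min_overlap = 1)
  # all of a1's conspecifics within 2%, nothing else
  expect_equal(all_species_barcodes("a1", m, rec, 0.02)$verdict, "success")
  # at 1% a1 sees a2 (1%) but not a3 (2%): incomplete -> ambiguous
  expect_equal(all_species_barcodes("a1", m, rec, 0.01)$verdict, "ambiguous")
  expect_equal(all_species_barcodes("c1", m, rec, 0.01)$verdict, "no_match")
  # only an allospecific within threshold -> misidentified
  expect_equal(all_species_barcodes("c1", m, rec, 0.25)$verdict,
               "misidentified")
})

test_that("success nests across the three criteria at a fixed threshold", {
  for (seed in 1:3) {
    sc <- make_scenario(scenario_config("overlapping", K = 4, n_i = 3,
                                        L = 300, seed = seed))
    rec <- sc$records
    m <- distance_matrix(rec, min_overlap = 100)
    for (th in c(0.01, 0.05)) {
      for (id in rec$id) {
        asb <- all_species_barcodes(id, m, rec, th)$verdict
        bcm <- best_close_match(id, m, rec, th)$verdict
        bm <- best_match(id, m, rec)$verdict
        if (asb == "success") expect_equal(bcm, "success")
        if (bcm == "success") expect_equal(bm, "success")
      }
    }
  }
})

test_that("identification report partitions queries and finds clean gaps", {
  rec <- id_fixture()
  m <- distance_matrix(rec, min_overlap = 1)
  rep <- identification_report(rec, m, thresholds = c(0.01, 0.05))
  # percentages sum to 100 within each criterion/threshold cell
  agg <- tapply(rep$summary$percent, rep$summary$criterion_threshold, sum)
  expect_true(all(abs(agg - 100) < 1e-9))
  # verdicts partition the query set
  agg_n <- tapply(rep$summary$n, rep$summary$criterion_threshold, sum)
  expect_true(all(agg_n == nrow(rec)))
  # the singleton is no_match under BCM but misidentified under BM
  oc <- rep$outcomes
  expect_equal(oc$verdict[oc$query_id == "c1" &
                            oc$criterion == "best_close_match" &
                            oc$threshold == 0.01], "no_match")
  expect_equal(oc$verdict[oc$query_id == "c1" &
                            oc$criterion == "best_match"], "misidentified")

  # two deeply separated species with a mid-gap threshold: 100% success
  clean <- gap_fixture(500, 5, 100)    # intra 1%, inter >= 20%
  mc <- distance_matrix(clean, min_overlap = 1)
  repc <- identification_report(clean, mc, thresholds = 0.05)
  expect_true(all(repc$summary$percent[repc$summary$verdict == "success"]
                  == 100))
})

test_that("consensus barcodes follow per-site majority with IUPAC ties", {
  expect_equal(consensus_barcode("ACGT"), "ACGT")
  expect_equal(consensus_barcode(c("AAAT", "AAAC", "AAAT")), "AAAT")
  # 1:1 tie at the last site -> IUPAC code for C/T
  expect_equal(consensus_barcode(c("AAAT", "AAAC")), "AAAY")
  # gap majority wins
  expect_equal(consensus_barcode(c("A-GT", "A-GT", "AAGT")), "A-GT")
  rec <- fix_records(c("x1", "x2", "y1", "y2"), c("X", "X", "Y", "Y"),
                     rep("ACGTACGT", 4))
  cu <- consensus_unique(rec)
  expect_false(cu$all_unique)
  expect_setequal(cu$duplicates, c("X", "Y"))
})

test_that("tree criteria handle monophyly, paraphyly and singletons", {
  rec <- fix_records(c("a1", "a2", "a3", "b1", "b2", "c1"),
                     c("A", "A", "A", "B", "B", "C"),
                     rep("ACGT", 6))
  tree <- ape::read.tree(
    text = "(((a1:1,a2:1):1,a3:2):2,((b1:1,b2:1):2,c1:3):1);")
  h <- tree_id_hebert(tree, rec)
  expect_true(all(h$verdict[h$query_id %in% c("a1", "a2", "a3")] == "success"))
  expect_true(all(h$verdict[h$query_id %in% c("b1", "b2")] == "success"))
  expect_equal(h$verdict[h$query_id == "c1"], "ambiguous")

  # split species A across two clades: hebert fails, meier still succeeds
  para <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,((a3:1,a4:1):1,c1:2):1);")
  prec <- fix_records(c("a1", "a2", "a3", "a4", "b1", "b2", "c1"),
                      c("A", "A", "A", "A", "B", "B", "C"),
                      rep("ACGT", 7))
  hp <- tree_id_hebert(para, prec)
  mp <- tree_id_meier(para, prec)
  a_ids <- c("a1", "a2", "a3", "a4")
  expect_true(all(hp$verdict[hp$query_id %in% a_ids] == "misidentified"))
  expect_true(all(mp$verdict[mp$query_id %in% a_ids] == "success"))
  # species with exactly two sequences is ambiguous under the relaxed rule
  expect_true(all(mp$verdict[mp$query_id %in% c("b1", "b2")] == "ambiguous"))
  # query nested inside an allospecific cluster is misidentified
  nest <- ape::read.tree(
    text = "(((b1:1,a1:1):1,b2:2):1,((a2:1,a3:1):1,a4:2):1);")
  nrec <- fix_records(c("a1", "a2", "a3", "a4", "b1", "b2"),
                      c("A", "A", "A", "A", "B", "B"),
                      rep("ACGT", 6))
  mn <- tree_id_meier(nest, nrec)
  expect_equal(mn$verdict[mn$query_id == "a1"], "misidentified")
})
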
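test_that("branching times are the sorted internal-node ages", {
  tr2 <- ape::read.tree(text = "(a:0.4,b:0.4);")
  expect_equal(branching_times(tr2), 0.4)
  tr4 <- ape::read.tree(text = "((a:0.1,b:0.1):0.4,(c:0.1,d:0.1):0.4);")
  expect_equal(branching_times(tr4), c(0.1, 0.1, 0.5))
  trn <- simulate_species_tree(12, 2, seed = 5)
  expect_length(branching_times(trn), 11)
  bad <- ape::read.tree(text = "(a:0.2,b:0.5);")
  expect_error(branching_times(bad), "ultrametric")
})

test_that("the interval likelihood matches brute-force enumeration", {
  for (seed in 1:5) {
    sc <- make_scenario(scenario_config("clean_gap", K = 3, n_i = 3,
                                        seed = seed))
    tr <- upgma_tree(distance_matrix(collapse_identical(sc$records)$records,
                                     min_overlap = 1))
    bt <- branching_times(tr)
    m <- length(unique(round(bt / max(bt), 6)))   # distinct ages
    for (j in c(0, 1, 2, m)) {
      for (rates in list(c(5, 100), c(0.5, 20), c(50, 1000))) {
        expect_equal(gmyc_loglik(tr, j, rates[1], rates[2]),
                     oracle_gmyc_loglik(tr, j, rates[1], rates[2]),
                     tolerance = 1e-8,
                     info = sprintf("seed %d j %d", seed, j))
      }
    }
  }
})

test_that("fit boundaries give one entity and n entities", {
  tr <- simulate_species_tree(8, 2, seed = 3)
  fit <- gmyc_fit(tr)
  cand <- fit$candidates
  expect_equal(cand$n_entities[cand$n_speciation_ages == 0], 1)
  expect_equal(max(cand$n_entities), length(tr$tip.label))
  # the retained threshold maximises the candidate profile
  expect_equal(fit$logL_alt, max(cand$logL))
  expect_gte(fit$lr_stat, -1e-8)
})

test_that("likelihood-ratio statistic is non-negative across random trees", {
  for (seed in 1:8) {
    tr <- simulate_species_tree(10 + seed, 1.5, seed = seed)
    fit <- gmyc_fit(tr)
    expect_gte(fit$lr_stat, -1e-8)
    expect_true(fit$n_entities >= 1 &&
                  fit$n_entities <= length(tr$tip.label))
  }
})

test_that("clean-gap trees yield the true number of entities", {
  sc <- make_scenario(scenario_config("clean_gap", K = 5, n_i = 4, seed = 11))
  col <- collapse_identical(sc$records)
  tr <- upgma_tree(distance_matrix(col$records, min_overlap = 1))
  fit <- gmyc_fit(tr)
  expect_equal(fit$n_entities, 5)
  sp <- sub("_.*", "", names(fit$entities))
  expect_true(all(tapply(fit$entities, sp, function(x)
    length(unique(x))) == 1))
  expect_lt(fit$p_value, 0.05)
})

test_that("entity partition is invariant to tip-order permutation", {
  sc <- make_scenario(scenario_config("clean_gap", K = 4, n_i = 3, seed = 2))
  col <- collapse_identical(sc$records)
  tr <- upgma_tree(distance_matrix(col$records, min_overlap = 1))
  fit1 <- gmyc_fit(tr)
  tr2 <- ape::rotate(tr, length(tr$tip.label) + 1)
  tr2 <- ape::read.tree(text = ape::write.tree(tr2))
  fit2 <- gmyc_fit(tr2)
  expect_equal(fit2$n_entities, fit1$n_entities)
  g1 <- unname(split(names(fit1$entities), fit1$entities))
  g2 <- unname(split(names(fit2$entities), fit2$entities))
  expect_setequal(lapply(g1, sort), lapply(g2, sort))
})

test_that("partitioned GMYC aggregates groups and scores accuracy", {
  sc <- make_scenario(scenario_config("clean_gap", K = 8, n_i = 4, seed = 4))
  repA <- gmyc_partitioned(sc$records, level = "A", min_overlap = 1)
  expect_equal(repA$n_entities_total, 8)
  expect_equal(repA$taxonomic_accuracy, 100)
  # level C: families of 4 species each, fitted independently
  repC <- gmyc_partitioned(sc$records, level = "C", min_overlap = 1)
  expect_equal(sum(vapply(repC$fits, function(f) f$n_entities, numeric(1))),
               repC$n_entities_total)
  expect_true(all(repC$per_species$n_entities >= 1))
  # degenerate group: fewer than 3 haplotypes is carried as one entity
  tiny <- sc$records[sc$records$species %in% c("sp1", "sp2"), ]
  tiny2 <- rbind(sc$records[sc$records$species == "sp3", ][1:2, ], tiny)
  tiny2$higher_taxon <- c("hX", "hX", rep("hY", nrow(tiny)))
  expect_warning(repB <- gmyc_partitioned(tiny2, level = "B",
                                          min_overlap = 1),
                 "single entity")
  expect_equal(length(unique(repB$entities[1:2])), 1)
})
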
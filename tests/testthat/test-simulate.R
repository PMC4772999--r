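test_that("generators are deterministic under a fixed seed", {
  t1 <- simulate_species_tree(6, 3, seed = 99)
  t2 <- simulate_species_tree(6, 3, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s1 <- make_scenario(scenario_config("clean_gap", K = 3, n_i = 3, L = 200,
                                      seed = 7))
  s2 <- make_scenario(scenario_config("clean_gap", K = 3, n_i = 3, L = 200,
                                      seed = 7))
  expect_identical(s1$records, s2$records)
  expect_identical(ape::write.tree(s1$trees$full),
                   ape::write.tree(s2$trees$full))
})

test_that("species-tree split ages follow the stated waiting-time law", {
  expect_equal(length(simulate_species_tree(1, 1)$tip.label), 1)
  # K = 2: split age ~ Exp(birth_rate); check the mean over many draws
  br <- 4
  ages <- vapply(1:1000, function(s)
    max(ape::node.depth.edgelength(simulate_species_tree(2, br, seed = s))),
    numeric(1))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 1 / br), 3 * se)
  expect_error(simulate_species_tree(0, 1), "K must be")
})

test_that("gene trees stay ultrametric and match the coalescent mean", {
  sp <- simulate_species_tree(4, 2, seed = 1)
  gg <- simulate_gene_trees(sp, n_i = 3, coal_scale = 0.01, seed = 2)
  expect_true(is_ultrametric_tree(gg$tree))
  expect_equal(length(gg$tree$tip.label), 12)
  expect_setequal(unique(unname(gg$tip_species)), sp$tip.label)
  # n_i = 1 everywhere reduces to the species tree
  gg1 <- simulate_gene_trees(sp, n_i = 1, coal_scale = 0.01, seed = 3)
  expect_equal(sort(ape::branching.times(gg1$tree)),
               sort(ape::branching.times(sp)), tolerance = 1e-9)
  # pair coalescence age has mean coal_scale (deep species tree so the
  # within-branch constraint is effectively never binding)
  cs <- 0.01
  deep <- simulate_species_tree(2, 0.05, seed = 42)
  ages <- vapply(1:1000, function(s) {
    g <- simulate_gene_trees(deep, n_i = c(2, 1), coal_scale = cs, seed = s)
    h <- ape::node.depth.edgelength(g$tree)
    sub <- ape::cophenetic.phylo(g$tree)[c("sp1_01", "sp1_02"),
                                         c("sp1_01", "sp1_02")]
    sub[1, 2] / 2
  }, numeric(1))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - cs), 3 * se)
})

test_that("JC69 simulation matches the closed-form expected p-distance", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")   # path length 0.1
  expected <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  ps <- vapply(1:100, function(s) {
    seqs <- evolve_sequences(tr, L = 10000, seed = s)
    p_distance(seqs["a"], seqs["b"], min_overlap = 1)
  }, numeric(1))
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
  # zero rate: sequences identical
  s0 <- evolve_sequences(tr, L = 200, rate = 0, seed = 1)
  expect_equal(s0[["a"]], s0[["b"]])
})

test_that("K2P and HKY simulators hit their equilibrium and distances", {
  tr <- ape::read.tree(text = "(a:0.4,b:0.4);")
  sk <- evolve_sequences(tr, L = 20000, model = "K2P", kappa = 6, seed = 5)
  freq <- table(strsplit(sk[["a"]], "")[[1]]) / 20000
  expect_true(all(abs(freq - 0.25) < 0.02))
  fr <- c(0.35, 0.15, 0.2, 0.3)
  sh <- evolve_sequences(tr, L = 20000, model = "HKY", kappa = 4,
                         base_freqs = fr, seed = 6)
  freq <- table(factor(strsplit(sh[["a"]], "")[[1]],
                       c("A", "C", "G", "T"))) / 20000
  expect_true(all(abs(freq - fr) < 0.02))
})

test_that("presets realize their declared properties", {
  sc <- make_scenario(scenario_config("clean_gap", K = 4, n_i = 3, seed = 5))
  dg <- sc$truth$diagnostics
  expect_true(dg$max_intra < dg$min_inter)
  expect_true(all(dg$per_species_max_intra < dg$min_inter))

  so <- make_scenario(scenario_config("overlapping", K = 4, n_i = 4,
                                      seed = 5))
  do_ <- so$truth$diagnostics
  expect_true(do_$max_intra > do_$min_inter)

  sp <- make_scenario(scenario_config("paraphyly", K = 4, n_i = 3, seed = 5))
  split_tips <- sp$records$id[sp$records$species == "sp1"]
  expect_false(ape::is.monophyletic(sp$trees$full, split_tips))

  ss <- make_scenario(scenario_config("singletons", K = 5, n_i = 3,
                                      seed = 5))
  expect_true(any(table(ss$records$species) == 1))
})

test_that("realized divergences rise with the coalescent scale", {
  mean_intra <- vapply(c(0.001, 0.004, 0.016, 0.064), function(cs) {
    set.seed(1)
    sp <- simulate_species_tree(3, 0.5)
    gg <- simulate_gene_trees(sp, n_i = 4, coal_scale = cs)
    seqs <- evolve_sequences(gg$tree, L = 663)
    rec <- fix_records(names(seqs), unname(gg$tip_species), unname(seqs))
    m <- distance_matrix(rec, min_overlap = 1)
    ds <- divergence_summary(m, rec)
    ds$total$mean[ds$total$class == "intraspecific"]
  }, numeric(1))
  expect_true(all(diff(mean_intra) > 0))
})
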
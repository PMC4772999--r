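#' Scenario configuration for the synthetic barcode generator
#'
#' Bundles the parameters of the generator. Defaults emulate the divergence
#' structure of a typical mitochondrial barcode reference library: deep
#' between-species splits (intra-generic p-distances of roughly 3-24%) and
#' shallow within-species coalescent variation, with marker length 663 bp.
#'
#' @param preset One of `"clean_gap"` (every species' maximum intra-specific
#'   distance below the global minimum inter-specific distance),
#'   `"overlapping"` (at least one species' intra-specific variation
#'   exceeds the minimum inter-specific distance, i.e. no global gap),
#'   `"paraphyly"` (one species' label spans two non-sister clades) or
#'   `"singletons"` (at least one species with a single sequence).
#' @param K Number of species.
#' @param n_i Individuals per species (constant or length-`K` vector).
#' @param L Sequence length (sites).
#' @param birth_rate Species-tree branching rate: going back from the
#'   present with `j` lineages, the waiting time to the next (older) split
#'   is exponential with rate `(j - 1) * birth_rate`, so a two-species tree
#'   has split age `~ Exp(birth_rate)` (tree-depth units are expected
#'   substitutions per site).
#' @param coal_scale Within-species coalescent scale: with `j` lineages the
#'   waiting time to the next coalescence is exponential with rate
#'   `choose(j, 2) / coal_scale`, so a two-sequence species has expected
#'   node age `coal_scale`.
#' @param model Substitution model: `"JC69"`, `"K2P"` or `"HKY"`.
#' @param rate Rate multiplier applied to all branch lengths.
#' @param kappa Transition/transversion rate ratio (K2P, HKY).
#' @param base_freqs Equilibrium base frequencies (HKY), order A,C,G,T.
#' @param gap_factor Margin defining a *clean* gap: the preset requires the
#'   minimum inter-specific distance to exceed `gap_factor` times the
#'   maximum intra-specific distance, so entity crown ages are much
#'   shallower than between-entity splits.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param max_retries Bounded number of sub-seeded retries used by
#'   [make_scenario()] to achieve the preset's declared property.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(preset = c("clean_gap", "overlapping",
                                       "paraphyly", "singletons"),
                            K = 5, n_i = 4, L = 663,
                            birth_rate = 5,
                            coal_scale = switch(match.arg(preset),
                                                overlapping = 0.08, 0.002),
                            model = "JC69", rate = 1, kappa = 4,
                            base_freqs = c(0.25, 0.25, 0.25, 0.25),
                            gap_factor = 5, seed = 1, max_retries = 20) {
  preset <- match.arg(preset)
  if (K < 1) stop("argument error: K must be >= 1")
  if (L < 1) stop("argument error: L must be >= 1")
  if (birth_rate <= 0 || coal_scale <= 0 || rate < 0)
    stop("argument error: rates must be positive")
  if (length(n_i) == 1L) n_i <- rep(n_i, K)
  if (length(n_i) != K) stop("argument error: n_i must have length K")
  if (preset == "singletons" && !any(n_i == 1L))
    n_i[seq_len(max(1L, K %/% 3L))] <- 1L
  if (preset == "overlapping") birth_rate <- max(birth_rate, 20)
  structure(list(preset = preset, K = K, n_i = n_i, L = L,
                 birth_rate = birth_rate, coal_scale = coal_scale,
                 model = model, rate = rate, kappa = kappa,
                 base_freqs = base_freqs / sum(base_freqs),
                 gap_factor = gap_factor, seed = seed,
                 max_retries = max_retries),
            class = "scenario_config")
}

# internal: backward-merge ultrametric tree builder. `rate_fun(j)` gives the
# exponential rate of the waiting time while j lineages remain. Returns a
# rooted ultrametric phylo with the given tip labels (n >= 2).
backward_merge_tree <- function(tip_labels, rate_fun) {
  n <- length(tip_labels)
  stopifnot(n >= 2L)
  age <- c(rep(0, n), rep(NA_real_, n - 1L))
  lineages <- seq_len(n)
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  t <- 0
  ne <- 0L
  for (j in n:2) {
    t <- t + stats::rexp(1L, rate_fun(j))
    pick <- sample(length(lineages), 2L)
    anc <- n + (n - (n - j + 1L))          # creation order k = n-j+1 -> id
    age[anc] <- t
    for (ch in lineages[pick]) {
      ne <- ne + 1L
      edges[ne, ] <- c(anc, ch)
      elen[ne] <- t - age[ch]
    }
    lineages <- c(lineages[-pick], anc)
  }
  structure(list(edge = edges, edge.length = elen, Nnode = n - 1L,
                 tip.label = tip_labels),
            class = "phylo") |> reorder_phylo_safe()
}

# internal: make internal node numbering conform to ape (root = n+1)
reorder_phylo_safe <- function(tree) {
  # renumber internal nodes so the root gets n+1 in preorder
  n <- length(tree$tip.label)
  root_old <- setdiff(tree$edge[, 1], tree$edge[, 2])
  # breadth-first renumber from the root
  map <- integer(max(tree$edge))
  map[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  todo <- root_old
  while (length(todo) > 0L) {
    cur <- todo[1L]; todo <- todo[-1L]
    map[cur] <- nxt; nxt <- nxt + 1L
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    todo <- c(todo, kids[kids > n])
  }
  tree$edge <- matrix(map[tree$edge], ncol = 2L)
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a Yule-style species tree
#'
#' Ultrametric pure-birth species tree with `K` tips built by backward
#' merging: with `j` lineages the waiting time to the next older split is
#' `Exp((j - 1) * birth_rate)`, so for `K = 2` the split age is
#' `Exp(birth_rate)`. A fixed seed is reproducible.
#'
#' @param K Number of species (tips); `K = 1` returns a degenerate
#'   single-tip tree.
#' @param birth_rate Branching rate (> 0).
#' @param seed Optional integer seed.
#' @return A `phylo` tree with tips `sp1 ... spK`.
#' @export
simulate_species_tree <- function(K, birth_rate, seed = NULL) {
  if (K < 1) stop("argument error: K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("sp%d", seq_len(K))
  if (K == 1L)
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          edge.length = 0, Nnode = 1L, tip.label = labels),
                     class = "phylo"))
  backward_merge_tree(labels, function(j) (j - 1) * birth_rate)
}

# internal: newick string of a tree where each tip may be replaced by a
# subtree string with its depth subtracted from the stem
compose_newick <- function(tree, tip_sub) {
  n <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, stem_len) {
    if (node <= n) {
      lab <- tree$tip.label[node]
      sub <- tip_sub[[lab]]
      if (is.null(sub)) return(sprintf("%s:%.12g", lab, stem_len))
      if (sub$depth > stem_len + 1e-12)
        stop("graft error: gene tree deeper than the terminal branch")
      return(sprintf("%s:%.12g", sub$newick, stem_len - sub$depth))
    }
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e)
      rec(tree$edge[e, 2], tree$edge.length[e]), character(1))
    sprintf("(%s):%.12g", paste(parts, collapse = ","), stem_len)
  }
  root <- n + 1L
  kids <- children[[as.character(root)]]
  parts <- vapply(kids, function(e)
    rec(tree$edge[e, 2], tree$edge.length[e]), character(1))
  sprintf("(%s);", paste(parts, collapse = ","))
}

#' Graft within-species coalescent genealogies onto a species tree
#'
#' Simulates a Kingman-coalescent genealogy for each species (waiting time
#' with `j` lineages `~ Exp(choose(j, 2) / coal_scale)`) and grafts it onto
#' the corresponding species-tree tip, so the full tree stays ultrametric.
#' A genealogy deeper than its terminal species branch is redrawn (bounded
#' retries); this enforces coalescence within the species branch, i.e. no
#' deep coalescence across species boundaries.
#'
#' @param species_tree Ultrametric `phylo` from [simulate_species_tree()].
#' @param n_i Individuals per species (constant or per-tip vector, in
#'   species-tree tip-label order `sp1 ... spK`).
#' @param coal_scale Coalescent scale (> 0).
#' @param seed Optional integer seed.
#' @return A list: `tree` (full ultrametric `phylo`, tips named
#'   `<species>_<index>`), `tip_species` (named character vector).
#' @export
simulate_gene_trees <- function(species_tree, n_i, coal_scale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(species_tree$tip.label)
  if (length(n_i) == 1L) n_i <- rep(n_i, K)
  stopifnot(length(n_i) == K, all(n_i >= 1L))
  sp <- species_tree$tip.label
  if (K == 1L) {
    ids <- sprintf("%s_%02d", sp[1], seq_len(n_i[1]))
    tip_species <- stats::setNames(rep(sp[1], n_i[1]), ids)
    full <- if (n_i[1] == 1L) {
      tr <- simulate_species_tree(1L); tr$tip.label <- ids; tr
    } else backward_merge_tree(ids, function(j) choose(j, 2) / coal_scale)
    return(list(tree = full, tip_species = tip_species))
  }
  # terminal branch length per species tip
  term_len <- vapply(seq_len(K), function(i) {
    species_tree$edge.length[species_tree$edge[, 2] == i]
  }, numeric(1))
  tip_sub <- list()
  tip_species <- character(0)
  for (i in seq_len(K)) {
    ids <- sprintf("%s_%02d", sp[i], seq_len(n_i[i]))
    tip_species[ids] <- sp[i]
    if (n_i[i] == 1L) {
      tip_sub[[sp[i]]] <- list(newick = ids, depth = 0)
      next
    }
    for (try in seq_len(1000L)) {
      g <- backward_merge_tree(ids, function(j) choose(j, 2) / coal_scale)
      depth <- max(ape::node.depth.edgelength(g))
      if (depth < term_len[i]) break
      g <- NULL
    }
    if (is.null(g))
      stop("scenario error: coalescent genealogy never fit inside the ",
           "terminal branch of ", sp[i],
           " (coal_scale too large for the species-tree depth)")
    nwk <- ape::write.tree(g)
    tip_sub[[sp[i]]] <- list(newick = sub(";$", "", nwk), depth = depth)
  }
  full <- ape::read.tree(text = compose_newick(species_tree, tip_sub))
  list(tree = full, tip_species = tip_species)
}

# internal: transition probability matrices
pmat_jc69 <- function(t) {
  e <- exp(-4 * t / 3)
  P <- matrix((1 - e) / 4, 4, 4)
  diag(P) <- (1 + 3 * e) / 4
  P
}

pmat_general <- function(t, Q) {
  eig <- eigen(Q)
  V <- eig$vectors
  Re(V %*% diag(exp(eig$values * t)) %*% solve(V))
}

# internal: normalised rate matrix for K2P / HKY (rows/cols in A,C,G,T order)
rate_matrix <- function(model, kappa, base_freqs) {
  pur <- c(1, 3); pyr <- c(2, 4)          # A,G and C,T
  Q <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    transition <- (a %in% pur && b %in% pur) || (a %in% pyr && b %in% pyr)
    Q[a, b] <- (if (transition) kappa else 1) * base_freqs[b]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))        # expected rate per unit time
  Q / mu
}

#' Evolve sequences along a tree
#'
#' Simulates site-independent sequence evolution from a root sequence drawn
#' at the model's equilibrium frequencies. Branch lengths (times `rate`)
#' are in expected substitutions per site; under JC69 the expected
#' p-distance between two tips at total path length `t` is
#' `(3/4) (1 - exp(-4 t / 3))`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param L Sequence length.
#' @param model `"JC69"`, `"K2P"` or `"HKY"`.
#' @param rate Rate multiplier on branch lengths.
#' @param kappa Transition/transversion ratio (K2P/HKY).
#' @param base_freqs Equilibrium frequencies A,C,G,T (HKY; K2P and JC69 use
#'   uniform frequencies).
#' @param seed Optional integer seed.
#' @return Named character vector of sequences, one per tip.
#' @export
evolve_sequences <- function(tree, L, model = "JC69", rate = 1, kappa = 4,
                             base_freqs = c(0.25, 0.25, 0.25, 0.25),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model, c("JC69", "K2P", "HKY"))
  bases <- c("A", "C", "G", "T")
  freqs <- switch(model, HKY = base_freqs / sum(base_freqs),
                  rep(0.25, 4))
  Q <- if (model != "JC69") rate_matrix(model, kappa, freqs) else NULL
  pmat <- function(t) {
    if (model == "JC69") pmat_jc69(t) else pmat_general(t, Q)
  }
  n <- length(tree$tip.label)
  n_node <- n + tree$Nnode
  seqs <- matrix(NA_integer_, n_node, L)
  root <- n + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = freqs)
  eo <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in eo) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e] * rate
    if (t <= 0) { seqs[ch, ] <- seqs[p, ]; next }
    P <- pmat(t)
    parent <- seqs[p, ]
    child <- integer(L)
    for (s in 1:4) {
      idx <- which(parent == s)
      if (length(idx))
        child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = pmax(P[s, ], 0))
    }
    seqs[ch, ] <- child
  }
  out <- apply(seqs[seq_len(n), , drop = FALSE], 1,
               function(r) paste(bases[r], collapse = ""))
  stats::setNames(out, tree$tip.label)
}

#' Generate a complete synthetic barcode scenario
#'
#' Composes the species-tree, gene-tree and sequence simulators into a
#' labelled dataset with known truth, and verifies that the preset's
#' declared property actually holds in the realized data (re-generating
#' with bounded sub-seeded retries until it does). Genera, families and
#' higher taxa are assigned as nested blocks of species so that
#' group-restricted analyses are exercised.
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `synthetic_scenario`: `records` (the same
#'   `data.frame` dialect [read_alignment()] returns), `truth` (species
#'   label per sequence, species tree, full genealogy, realized divergence
#'   diagnostics), `trees` (species and full tree), `cfg`, and `attempts`.
#' @export
make_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  for (attempt in seq_len(cfg$max_retries)) {
    sub_seed <- (cfg$seed + (attempt - 1L) * 7919L) %% .Machine$integer.max
    out <- try(generate_once(cfg, sub_seed), silent = TRUE)
    if (!inherits(out, "try-error") && isTRUE(out$property_ok)) {
      out$attempts <- attempt
      return(out)
    }
  }
  stop("scenario error: preset property '", cfg$preset,
       "' not achieved within ", cfg$max_retries, " retries; ",
       "last diagnostics: ",
       if (inherits(out, "try-error")) conditionMessage(attr(out, "condition"))
       else paste(utils::capture.output(utils::str(out$truth$diagnostics)),
                  collapse = " "))
}

# internal: one generation pass + property check
generate_once <- function(cfg, seed) {
  set.seed(seed)
  K_sim <- if (cfg$preset == "paraphyly") cfg$K + 1L else cfg$K
  sp_tree <- simulate_species_tree(K_sim, cfg$birth_rate)
  n_i <- cfg$n_i
  relabel <- NULL
  if (cfg$preset == "paraphyly") {
    # pick a donor tip that is NOT sister to sp1 and give it sp1's label,
    # so sp1's sequences span two non-sister clades
    sis <- sister_tips(sp_tree, "sp1")
    candidates <- setdiff(sp_tree$tip.label, c("sp1", sis))
    if (length(candidates) == 0L) stop("no non-sister donor available")
    relabel <- candidates[length(candidates)]
    n_i <- c(n_i, max(2L, n_i[1]))
  }
  gg <- simulate_gene_trees(sp_tree, n_i, cfg$coal_scale)
  seqs <- evolve_sequences(gg$tree, cfg$L, model = cfg$model,
                           rate = cfg$rate, kappa = cfg$kappa,
                           base_freqs = cfg$base_freqs)
  tip_species <- gg$tip_species
  if (!is.null(relabel))
    tip_species[tip_species == relabel] <- "sp1"
  sp_index <- as.integer(sub("sp", "", tip_species))
  sp_index[tip_species == "sp1"] <- 1L
  ids <- names(tip_species)
  records <- data.frame(
    id = ids,
    species = unname(tip_species),
    genus = sprintf("g%d", (pmin(sp_index, cfg$K) - 1L) %/% 2L + 1L),
    family = sprintf("f%d", (pmin(sp_index, cfg$K) - 1L) %/% 4L + 1L),
    higher_taxon = sprintf("h%d", (pmin(sp_index, cfg$K) - 1L) %/% 8L + 1L),
    sequence = unname(seqs[ids]),
    stringsAsFactors = FALSE)
  diag_tab <- scenario_diagnostics(records, cfg)
  ok <- switch(cfg$preset,
    clean_gap = isTRUE(diag_tab$clean_gap),
    overlapping = isTRUE(diag_tab$has_overlap),
    singletons = any(table(records$species) == 1L),
    paraphyly = !ape::is.monophyletic(
      gg$tree, records$id[records$species == "sp1"]))
  structure(list(records = records,
                 truth = list(species = stats::setNames(records$species,
                                                        records$id),
                              species_tree = sp_tree, gene_tree = gg$tree,
                              diagnostics = diag_tab),
                 trees = list(species = sp_tree, full = gg$tree),
                 cfg = cfg, property_ok = ok, seed_used = seed),
            class = "synthetic_scenario")
}

# internal: realized intra/inter divergence diagnostics
scenario_diagnostics <- function(records, cfg) {
  if (nrow(records) < 2L)
    return(list(clean_gap = NA, has_overlap = NA))
  m <- distance_matrix(records, min_overlap = min(300L, cfg$L))
  pt <- pair_table(m, records)
  intra <- pt$d[pt$same_species]
  inter <- pt$d[!pt$same_species]
  max_intra <- if (length(intra)) max(intra, na.rm = TRUE) else NA_real_
  min_inter <- if (length(inter)) min(inter, na.rm = TRUE) else NA_real_
  per_sp_max <- tapply(pt$d[pt$same_species], pt$species1[pt$same_species], max)
  gf <- if (is.null(cfg$gap_factor)) 1 else cfg$gap_factor
  list(max_intra = max_intra, min_inter = min_inter,
       per_species_max_intra = per_sp_max,
       clean_gap = !is.na(min_inter) &&
         (length(intra) == 0L || gf * max_intra < min_inter),
       has_overlap = !is.na(min_inter) && length(intra) > 0L &&
         max_intra > min_inter)
}
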
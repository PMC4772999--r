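#' Branching times of an ultrametric tree
#'
#' Ages of the internal nodes measured from the tips (age 0) upward,
#' sorted ascending.
#'
#' @param tree An ultrametric `phylo` tree with at least 2 tips.
#' @param tol Ultrametricity tolerance passed to [is_ultrametric_tree()].
#' @return Sorted numeric vector of node ages (one per internal node).
#' @export
branching_times <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("argument error: need a 'phylo' tree")
  if (length(tree$tip.label) < 2L) stop("argument error: need >= 2 tips")
  if (!is_ultrametric_tree(tree, tol))
    stop("argument error: tree is not ultrametric")
  sort(node_ages(tree)$internal)
}

# internal: ages of all nodes (tips ~ 0) on an ultrametric tree
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  h <- max(depths[seq_len(n_tip)])
  ages <- h - depths
  list(all = ages, internal = ages[(n_tip + 1):length(ages)], height = h)
}

# internal: interval bookkeeping shared by the GMYC likelihood.
# Intervals are delimited by the DISTINCT internal-node ages (tied ages --
# common on average-linkage trees -- are one multi-event boundary).
# Interval i spans (t_end[i], t_start[i]); mult[i] counts the branching
# events at its lower end (0 for the final interval, which ends at the
# present). Node ages within a rounding tolerance of each other are tied.
gmyc_intervals <- function(tree) {
  na <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  eps <- 1e-9 * max(na$height, 1)
  ages_desc <- sort(na$internal, decreasing = TRUE)
  distinct <- ages_desc[c(TRUE, diff(ages_desc) < -eps)]
  q <- length(distinct)
  t_start <- distinct
  t_end <- c(distinct[-1], 0)
  # events ending interval i: nodes at age t_end[i] (none for the last);
  # extra nodes tied with the root age end a zero-length top interval and
  # are counted on interval 1
  counts <- vapply(distinct, function(a)
    sum(abs(na$internal - a) <= eps), integer(1))
  mult <- c(counts[-1], 0L)
  mult[1] <- mult[1] + (counts[1] - 1L)
  parent_age <- na$all[tree$edge[, 1]]
  child_age <- na$all[tree$edge[, 2]]
  # edge alive in interval i iff it spans it; eps guards border rounding
  alive <- outer(parent_age + eps, t_start, ">=") &
    outer(child_age - eps, t_end, "<=")
  list(m = q, t_start = t_start, t_end = t_end, mult = mult,
       x = t_start - t_end, alive = alive, n_tip = n_tip,
       ages = na$all, age_eps = eps)
}

# internal: classify edges for the candidate whose age threshold sits just
# below the c-th distinct node age (c = 0 puts every node below the
# threshold). Nodes with age >= t_start[c] are speciation (between-entity)
# nodes. An edge is a between-entity (Yule) lineage iff its parent node is
# a speciation node; other edges belong to the entity rooted where their
# lineage last crossed the threshold. Returns yule flag per edge, entity id
# per edge (0 = Yule), entity id per node (0 for speciation nodes).
gmyc_classify <- function(tree, iv, c_idx) {
  n_tip <- iv$n_tip
  n_node <- n_tip + tree$Nnode
  spec <- rep(FALSE, n_node)
  if (c_idx > 0) {
    cutoff <- iv$t_start[c_idx] - iv$age_eps
    spec[(n_tip + 1):n_node] <- iv$ages[(n_tip + 1):n_node] >= cutoff
  }
  root <- n_tip + 1L
  ent_node <- integer(n_node)
  next_ent <- 0L
  if (!spec[root]) { next_ent <- 1L; ent_node[root] <- 1L }
  # preorder over edges (ape trees from our constructors are preorder-safe;
  # reorder defensively)
  eo <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  yule_edge <- logical(nrow(tree$edge))
  ent_edge <- integer(nrow(tree$edge))
  for (e in eo) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    if (spec[p]) {
      yule_edge[e] <- TRUE
      if (c <= n_tip || !spec[c]) {        # stem edge: starts a new entity
        next_ent <- next_ent + 1L
        ent_node[c] <- next_ent
      }
    } else {
      ent_edge[e] <- ent_node[p]
      ent_node[c] <- ent_node[p]
    }
  }
  list(yule_edge = yule_edge, ent_edge = ent_edge, ent_node = ent_node,
       n_entities = next_ent)
}

# internal: per-interval rate components for a candidate classification:
# k = between-entity lineage count, C = sum_j n_j (n_j - 1) over entities.
gmyc_rate_components <- function(iv, cls) {
  m <- iv$m
  k <- colSums(iv$alive & cls$yule_edge)
  C <- numeric(m)
  crown <- cls$ent_edge > 0L
  for (i in seq_len(m)) {
    ids <- cls$ent_edge[crown & iv$alive[, i]]
    if (length(ids)) {
      tab <- tabulate(ids)
      C[i] <- sum(tab * (tab - 1))
    }
  }
  list(k = k, C = C)
}

#' GMYC interval log-likelihood at fixed classification and rates
#'
#' Waiting-time log-likelihood of the mixed Yule/coalescent branching
#' model: within each inter-node interval the total branching rate is
#' `b = lambda_yule * k + lambda_coal * sum_j n_j (n_j - 1)`, where `k`
#' counts between-entity lineages (edges whose parent node is older than
#' the threshold) and `n_j` counts lineages inside entity `j`. Each
#' interval that ends in a branching event contributes
#' `log(b) - b * x`; the final interval (to the present) contributes its
#' survival term `-b * x` only. The root event is conditioned upon.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param n_speciation_ages Number of oldest *distinct* node ages whose
#'   nodes are classified as speciation (between-entity) nodes; 0 puts the
#'   whole tree below the threshold.
#' @param lambda_yule,lambda_coal Non-negative branching rates.
#' @return Log-likelihood (scalar; `-Inf` when an observed event falls in a
#'   zero-rate interval).
#' @export
gmyc_loglik <- function(tree, n_speciation_ages, lambda_yule, lambda_coal) {
  iv <- gmyc_intervals(tree)
  if (n_speciation_ages > iv$m)
    stop("argument error: only ", iv$m, " distinct node ages")
  cls <- gmyc_classify(tree, iv, n_speciation_ages)
  rc <- gmyc_rate_components(iv, cls)
  gmyc_loglik_kC(rc$k, rc$C, iv$x, iv$mult, lambda_yule, lambda_coal)
}

# internal: likelihood from precomputed components
gmyc_loglik_kC <- function(k, C, x, mult, ly, lc) {
  b <- ly * k + lc * C
  if (any(b[mult > 0] <= 0)) return(-Inf)
  sum(mult * log(pmax(b, 1e-300))) - sum(b * x)
}

# internal: maximise over rates for one candidate; returns list(ly, lc, logL)
gmyc_profile_fit <- function(k, C, x, mult) {
  ev <- mult > 0
  n_ev <- sum(mult)
  sk <- sum(k * x); sC <- sum(C * x)
  if (all(C[ev] == 0) && all(k[ev] > 0)) {
    # pure-Yule candidate: coalescent rate unidentified, profile it out at 0
    ly <- n_ev / sk
    return(list(ly = ly, lc = 0,
                logL = gmyc_loglik_kC(k, C, x, mult, ly, 0)))
  }
  if (all(k[ev] == 0) && all(C[ev] > 0)) {
    lc <- n_ev / sC
    return(list(ly = 0, lc = lc, logL = gmyc_loglik_kC(k, C, x, mult, 0, lc)))
  }
  negll <- function(par) {
    v <- -gmyc_loglik_kC(k, C, x, mult, exp(par[1]), exp(par[2]))
    if (!is.finite(v)) 1e10 else v
  }
  init <- log(c(max(n_ev / max(sk, 1e-12), 1e-6),
                max(n_ev / max(sC, 1e-12), 1e-6)))
  opt <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(ly = exp(opt$par[1]), lc = exp(opt$par[2]), logL = -opt$value)
}

#' Single-threshold GMYC species delimitation
#'
#' Fits the single-threshold generalized mixed Yule coalescent model on an
#' ultrametric tree: nodes older than a threshold age are speciation events
#' of a Yule (pure-birth) process between entities; younger nodes are
#' coalescent branching within entities. Candidate thresholds are the
#' internal-node ages (the likelihood only changes when the threshold
#' crosses a node); the two rates are optimised per candidate and the
#' threshold maximising the profile likelihood is retained. The null model
#' is the same waiting-time likelihood with a single rate class over the
#' whole tree (it coincides with the all-speciation candidate, so the LR
#' statistic is non-negative by construction) and is compared by a
#' chi-square test with 2 degrees of freedom.
#'
#' Identical haplotypes should be collapsed beforehand
#' ([collapse_identical()]): zero-length terminal branches produce
#' zero-length intervals that carry no waiting-time information.
#'
#' @param tree Ultrametric `phylo` tree with at least 3 tips.
#' @return An object of class `gmyc_fit`: `threshold_age`, `lambda_yule`,
#'   `lambda_coal`, `logL_alt`, `logL_null`, `lr_stat`, `p_value`,
#'   `entities` (named integer vector: tip -> entity), `n_entities`, and
#'   `candidates` (per-candidate profile table with `n_speciation_ages`,
#'   `threshold_age`, `logL`, `n_entities`).
#' @export
gmyc_fit <- function(tree) {
  if (!inherits(tree, "phylo")) stop("argument error: need a 'phylo' tree")
  if (length(tree$tip.label) < 3L)
    stop("degenerate-fit error: need >= 3 tips")
  if (!is_ultrametric_tree(tree))
    stop("argument error: tree is not ultrametric")
  iv <- gmyc_intervals(tree)
  m <- iv$m                     # number of distinct node ages
  # null: one rate class over all lineages
  k0 <- colSums(iv$alive)
  lam0 <- sum(iv$mult) / sum(k0 * iv$x)
  logL_null <- gmyc_loglik_kC(k0, numeric(m), iv$x, iv$mult, lam0, 0)
  cand <- vector("list", m + 1L)
  for (j in 0:m) {
    cls <- gmyc_classify(tree, iv, j)
    rc <- gmyc_rate_components(iv, cls)
    fit <- gmyc_profile_fit(rc$k, rc$C, iv$x, iv$mult)
    thr <- if (j == 0L) iv$t_start[1] else
      (iv$t_start[j] + (if (j < m) iv$t_start[j + 1] else 0)) / 2
    cand[[j + 1L]] <- list(j = j, thr = thr, fit = fit, cls = cls)
  }
  logLs <- vapply(cand, function(cc) cc$fit$logL, numeric(1))
  best <- cand[[which.max(logLs)]]
  tips <- seq_len(iv$n_tip)
  entities <- best$cls$ent_node[tips]
  # tips that are their own entity already have ids from the stem pass
  entities <- match(entities, unique(entities))
  names(entities) <- tree$tip.label
  lr <- 2 * (best$fit$logL - logL_null)
  structure(list(
    threshold_age = best$thr,
    lambda_yule = best$fit$ly, lambda_coal = best$fit$lc,
    logL_alt = best$fit$logL, logL_null = logL_null,
    lr_stat = lr,
    p_value = stats::pchisq(max(lr, 0), df = 2, lower.tail = FALSE),
    entities = entities,
    n_entities = length(unique(entities)),
    candidates = data.frame(
      n_speciation_ages = vapply(cand, function(cc) cc$j, numeric(1)),
      threshold_age = vapply(cand, function(cc) cc$thr, numeric(1)),
      logL = logLs,
      n_entities = vapply(cand, function(cc) cc$cls$n_entities, numeric(1)))),
    class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf("GMYC single-threshold fit: %d entities, threshold age %.4g\n",
              x$n_entities, x$threshold_age))
  cat(sprintf("  lambda_yule %.4g, lambda_coal %.4g\n", x$lambda_yule,
              x$lambda_coal))
  cat(sprintf("  logL %.3f vs null %.3f; LR = %.3f, p = %.4f\n",
              x$logL_alt, x$logL_null, x$lr_stat, x$p_value))
  invisible(x)
}

#' Partitioned GMYC analysis (whole library / higher taxa / families)
#'
#' Runs independent single-threshold GMYC fits on dataset partitions:
#' level `"A"` analyses all sequences together, `"B"` fits one model per
#' higher taxon, `"C"` one per family. Within each group identical
#' haplotypes are collapsed first; groups with fewer than 3 unique
#' haplotypes cannot be fitted and are carried as a single entity each
#' (with a warning). When no trees are supplied, UPGMA trees built from
#' the group's p-distances are used; externally dated ultrametric trees
#' can be supplied instead via `trees` (a named list, one `phylo` per
#' group, tips = collapsed haplotype ids or any superset).
#'
#' Taxonomic accuracy is scored as in threshold clustering: a species is
#' counted when its sequences map to exactly one entity and that entity
#' contains no other species.
#'
#' @param records Record `data.frame`.
#' @param trees Optional named list of ultrametric trees per group.
#' @param level `"A"`, `"B"` or `"C"`.
#' @param n_recognized Accuracy denominator; defaults to the number of
#'   distinct species labels.
#' @param min_overlap Passed to [distance_matrix()] when trees are built
#'   internally.
#' @return A list of class `gmyc_partition_report`: `level`, `fits`
#'   (per-group `gmyc_fit` or `NULL` for pass-through groups), `entities`
#'   (named vector over all sequence ids), `n_entities_total`,
#'   `taxonomic_accuracy`, `per_species` (`data.frame` with species and
#'   entity counts).
#' @export
gmyc_partitioned <- function(records, trees = NULL, level = c("A", "B", "C"),
                             n_recognized = NULL, min_overlap = 300) {
  level <- match.arg(level)
  check_records(records)
  if (is.null(n_recognized)) n_recognized <- length(unique(records$species))
  key <- switch(level, A = rep("all", nrow(records)),
                B = records$higher_taxon, C = records$family)
  groups <- unique(key)
  fits <- list()
  entities <- integer(0)
  offset <- 0L
  for (g in groups) {
    sub <- records[key == g, , drop = FALSE]
    col <- collapse_identical(sub)
    if (nrow(col$records) < 3L) {
      warning("group '", g, "' has fewer than 3 unique haplotypes; ",
              "carried as a single entity")
      fits[[g]] <- NULL
      ent <- stats::setNames(rep(offset + 1L, nrow(sub)), sub$id)
      offset <- offset + 1L
    } else {
      tr <- if (!is.null(trees) && !is.null(trees[[g]])) {
        tt <- trees[[g]]
        if (!all(col$records$id %in% tt$tip.label))
          stop("configuration error: tree for group '", g,
               "' is missing haplotype tips")
        ape::keep.tip(tt, col$records$id)
      } else {
        upgma_tree(distance_matrix(col$records, min_overlap = min_overlap))
      }
      fit <- gmyc_fit(tr)
      fits[[g]] <- fit
      ent <- integer(0)
      for (rep_id in names(fit$entities)) {
        members <- col$map[[rep_id]]
        ent[members] <- offset + fit$entities[[rep_id]]
      }
      offset <- offset + fit$n_entities
    }
    entities <- c(entities, ent)
  }
  entities <- entities[records$id]
  sp <- records$species
  per_species <- do.call(rbind, lapply(unique(sp), function(s) {
    e <- unique(entities[sp == s])
    data.frame(species = s, n_entities = length(e), stringsAsFactors = FALSE)
  }))
  perfect <- vapply(unique(sp), function(s) {
    e <- unique(entities[sp == s])
    length(e) == 1L && all(sp[entities == e] == s)
  }, logical(1))
  structure(list(level = level, fits = fits, entities = entities,
                 n_entities_total = length(unique(entities)),
                 taxonomic_accuracy = taxonomic_accuracy(sum(perfect),
                                                         n_recognized),
                 per_species = per_species),
            class = "gmyc_partition_report")
}

#' @export
print.gmyc_partition_report <- function(x, ...) {
  cat(sprintf("GMYC partition report (level %s): %d entities, accuracy %.2f%%\n",
              x$level, x$n_entities_total, x$taxonomic_accuracy))
  invisible(x)
}
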
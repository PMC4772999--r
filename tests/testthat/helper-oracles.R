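# union-find oracle for the transitive closure at a threshold
uf_clusters <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(d[i, j]) && d[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}


# Brute-force interval-likelihood oracle: classifies edges and counts
# lineages by direct midpoint enumeration, independently of the package's
# interval bookkeeping.
oracle_gmyc_loglik <- function(tree, c_idx, ly, lc) {
  n <- length(tree$tip.label)
  dep <- ape::node.depth.edgelength(tree)
  age <- max(dep[1:n]) - dep
  tol <- 1e-9 * max(age)
  ages_desc <- sort(age[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
  distinct <- ages_desc[c(TRUE, diff(ages_desc) < -tol)]
  thr <- if (c_idx == 0) Inf else distinct[c_idx] - tol
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  # entity of a tip: walk up while the parent is younger than the threshold
  ent_of_tip <- vapply(1:n, function(tip) {
    cur <- tip
    repeat {
      p <- parent_of(cur)
      if (is.na(p) || age[p] > thr) return(cur)
      cur <- p
    }
  }, integer(1))
  bounds <- c(distinct, 0)
  counts <- vapply(distinct, function(a)
    sum(abs(ages_desc - a) <= tol), integer(1))
  mult <- c(counts[-1], 0L)
  mult[1] <- mult[1] + (counts[1] - 1L)
  ll <- 0
  for (i in seq_along(distinct)) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    alive <- which(age[tree$edge[, 1]] > mid & age[tree$edge[, 2]] < mid)
    yule <- age[tree$edge[alive, 1]] > thr
    k <- sum(yule)
    ents <- vapply(alive[!yule], function(e)
      ent_of_tip[tips_below(tree$edge[e, 2])[1]], integer(1))
    tab <- table(ents)
    C <- sum(tab * (tab - 1))
    b <- ly * k + lc * C
    x <- bounds[i] - bounds[i + 1]
    ll <- ll + mult[i] * log(b) - b * x
  }
  ll
}

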
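# Independent brute-force oracles used to validate the package's
# graph/ROC computations, deliberately implemented without the package's
# own code paths (edge-list enumeration, BFS, O(n^2) pair counting,
# exhaustive scans).

# Degree by counting an explicit edge list.
oracle_degree <- function(adjacency) {
  g <- ncol(adjacency)
  edges <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  deg <- integer(g)
  for (k in seq_len(nrow(edges))) {
    deg[edges[k, 1]] <- deg[edges[k, 1]] + 1L
    deg[edges[k, 2]] <- deg[edges[k, 2]] + 1L
  }
  deg
}

# All-pairs shortest paths by breadth-first search from each node.
oracle_bfs_distances <- function(adjacency) {
  g <- ncol(adjacency)
  d <- matrix(Inf, g, g)
  for (s in seq_len(g)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adjacency[v, ] == 1)
        new <- nb[d[s, nb] == Inf]
        d[s, new] <- depth
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_global_efficiency <- function(adjacency) {
  g <- ncol(adjacency)
  if (g < 2) return(0)
  d <- oracle_bfs_distances(adjacency)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (g * (g - 1))
}

oracle_local_efficiency <- function(adjacency) {
  g <- ncol(adjacency)
  vals <- vapply(seq_len(g), function(i) {
    nb <- which(adjacency[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adjacency[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# AUC by explicit concordant/discordant pair counting (ties = 1/2).
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate cut-off.
oracle_youden <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  cuts <- sort(unique(c(-Inf, values)))
  best <- -Inf
  for (cc in cuts) {
    j <- mean(pos > cc) + mean(neg <= cc) - 1
    if (j > best) best <- j
  }
  best
}

# Erdos-Renyi-style random symmetric 0/1 adjacency.
random_adjacency <- function(g, p = 0.3) {
  a <- matrix(0L, g, g)
  ut <- upper.tri(a)
  a[ut] <- stats::rbinom(sum(ut), 1, p)
  a + t(a)
}

# Small cohort for fast end-to-end tests.
tiny_cohort <- function(seed = 1L, effects = list(), n = 6L, g = 20L,
                        n_volumes = 120L, spike_rate = 0,
                        spike_amplitude = 0) {
  spec <- cohort_spec(n_per_group = c(HC = n, SD = n, MDD = n), g = g,
                      n_volumes = n_volumes, effects = effects,
                      motion_model = list(spike_rate = spike_rate,
                                          spike_amplitude = spike_amplitude,
                                          drift_scale = 0.02),
                      seed = seed)
  generate_cohort(spec)
}

pheno_with_fd <- function(cohort, prep) {
  ph <- cohort_phenotype(cohort)
  ph$mean_fd <- prep$qc$mean_fd[match(ph$subject_id, prep$qc$subject_id)]
  ph[ph$subject_id %in% names(prep$clean), , drop = FALSE]
}
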
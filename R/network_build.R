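#' Pearson functional-connectivity matrix
#'
#' Entry (i, j) is the Pearson correlation of ROI time series i and j;
#' the diagonal is forced to 1. A constant column makes the correlation
#' undefined and raises an error naming the node.
#'
#' @param series T' x g matrix with at least 3 rows.
#' @return g x g symmetric correlation matrix of class `fc_matrix`.
#' @export
compute_fc <- function(series) {
  if (nrow(series) < 3L) stop("need at least 3 time points for correlation")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant time series at node(s): ", paste(bad, collapse = ", "),
         "; correlation undefined")
  }
  r <- stats::cor(series)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  structure(r, class = c("fc_matrix", "matrix"))
}

# Deterministic total order on the upper-triangle edges: decreasing
# correlation, ties broken by ascending (i, j). Nested top-K sets across
# sparsities follow from using one fixed order.
edge_order <- function(fc) {
  g <- ncol(fc)
  ut <- which(upper.tri(fc))
  i <- row(fc)[ut]
  j <- col(fc)[ut]
  ut[order(-fc[ut], i, j)]
}

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Keeps the K = round(S * g(g-1)/2) strongest (most positive)
#' correlations as edges of an undirected, unweighted graph. Boundary
#' ties are broken by ascending (i, j) order so the edge count is exact
#' and deterministic.
#'
#' @param fc g x g correlation matrix.
#' @param sparsity target sparsity S in (0, 1): the fraction of all
#'   possible edges retained.
#' @return an object of class `binary_network`: `adjacency` (g x g 0/1
#'   matrix, zero diagonal), `sparsity`, `edge_count`.
#' @export
threshold_by_sparsity <- function(fc, sparsity) {
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must lie in (0, 1)")
  g <- ncol(fc)
  k <- round(sparsity * g * (g - 1) / 2)
  adjacency <- matrix(0L, g, g)
  if (k > 0) {
    keep <- edge_order(fc)[seq_len(k)]
    adjacency[keep] <- 1L
    adjacency <- adjacency + t(adjacency)
  }
  structure(list(adjacency = adjacency, sparsity = sparsity,
                 edge_count = as.integer(k)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("Binary network: %d nodes, %d edges (sparsity %.2f)\n",
              ncol(x$adjacency), x$edge_count, x$sparsity))
  invisible(x)
}

#' Sparsity sweep
#'
#' Binarizes a connectivity matrix at every sparsity from `s_min` to
#' `s_max` in steps of `step` (inclusive endpoints). The default sweep
#' 0.05-0.40 by 0.01 yields 36 networks; edge sets are nested across
#' increasing sparsity.
#'
#' @param fc g x g correlation matrix.
#' @param s_min,s_max,step sweep limits and increment.
#' @return named list of `binary_network`, one per threshold.
#' @export
sparsity_sweep <- function(fc, s_min = 0.05, s_max = 0.40, step = 0.01) {
  if (s_min > s_max) stop("s_min must not exceed s_max")
  n <- floor((s_max - s_min) / step + 1e-9) + 1
  sparsities <- round(s_min + step * (0:(n - 1)), 10)
  nets <- lapply(sparsities, function(s) threshold_by_sparsity(fc, s))
  names(nets) <- formatC(sparsities, format = "f", digits = 2)
  nets
}

#' Degree centrality
#'
#' The degree centrality of node i in a binary undirected network is the
#' number of edges connecting it to the other g - 1 nodes (self-
#' connections excluded).
#'
#' @param net a `binary_network` or 0/1 adjacency matrix.
#' @return integer vector of per-node degrees.
#' @export
degree_centrality <- function(net) {
  adjacency <- if (inherits(net, "binary_network")) net$adjacency else net
  as.integer(rowSums(adjacency))
}

as_igraph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                      diag = FALSE)
}

efficiency_from_adjacency <- function(adjacency) {
  g <- ncol(adjacency)
  if (g < 2L) return(0)
  d <- igraph::distances(as_igraph(adjacency))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (g * (g - 1))
}

#' Global efficiency
#'
#' Mean over all ordered node pairs of the inverse shortest-path length;
#' disconnected pairs contribute 0.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  adjacency <- if (inherits(net, "binary_network")) net$adjacency else net
  efficiency_from_adjacency(adjacency)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's
#' neighbour-induced subgraph; nodes with fewer than two neighbours
#' contribute 0.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  adjacency <- if (inherits(net, "binary_network")) net$adjacency else net
  g <- ncol(adjacency)
  eff <- vapply(seq_len(g), function(i) {
    nb <- which(adjacency[i, ] > 0)
    if (length(nb) < 2L) return(0)
    efficiency_from_adjacency(adjacency[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

# Average clustering coefficient and characteristic path length on the
# largest connected component.
clustering_and_path <- function(graph) {
  cc <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  comps <- igraph::components(graph)
  main <- igraph::induced_subgraph(
    graph, which(comps$membership == which.max(comps$csize)))
  list(C = mean(cc), L = igraph::mean_distance(main, directed = FALSE),
       n_components = comps$no)
}

#' Threshold-selection diagnostics
#'
#' For each network of a sparsity sweep, reports the connected-component
#' count, global and local efficiency, and the small-world coefficient
#' sigma = (C / C_rand) / (L / L_rand), where C is the average clustering
#' coefficient, L the characteristic path length on the largest
#' component, and the null values come from degree-preserving
#' (Maslov-Sneppen) rewirings. These diagnostics support choosing a
#' reporting threshold that keeps the network intact and small-world.
#'
#' @param fc g x g correlation matrix.
#' @param sweep optional precomputed [sparsity_sweep()] result.
#' @param n_null number of rewired null networks per threshold
#'   (default 20).
#' @param seed RNG seed for the rewiring.
#' @param ... passed to [sparsity_sweep()] when `sweep` is NULL.
#' @return data.frame: sparsity, edge_count, n_components,
#'   global_efficiency, local_efficiency, clustering, path_length, sigma.
#' @export
threshold_diagnostics <- function(fc, sweep = NULL, n_null = 20L,
                                  seed = 1L, ...) {
  if (is.null(sweep)) sweep <- sparsity_sweep(fc, ...)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rows <- lapply(sweep, function(net) {
    graph <- as_igraph(net$adjacency)
    obs <- clustering_and_path(graph)
    sigma <- NA_real_
    if (net$edge_count >= 2) {
      nulls <- vapply(seq_len(n_null), function(k) {
        rew <- igraph::rewire(
          graph, igraph::keeping_degseq(niter = 10 * net$edge_count))
        nv <- clustering_and_path(rew)
        c(nv$C, nv$L)
      }, numeric(2))
      c_rand <- mean(nulls[1, ])
      l_rand <- mean(nulls[2, ])
      if (is.finite(c_rand) && c_rand > 0 && is.finite(l_rand) &&
          l_rand > 0 && is.finite(obs$L))
        sigma <- (obs$C / c_rand) / (obs$L / l_rand)
    }
    data.frame(sparsity = net$sparsity, edge_count = net$edge_count,
               n_components = obs$n_components,
               global_efficiency = global_efficiency(net),
               local_efficiency = local_efficiency(net),
               clustering = obs$C, path_length = obs$L, sigma = sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subjects-by-nodes degree-centrality table
#'
#' For each preprocessed subject: Pearson FC, binarization at the
#' reporting sparsity, nodal degree centrality; results are stacked into
#' a subjects x nodes integer matrix. Every row sums to twice the edge
#' budget 2 * round(S * g(g-1)/2). Subjects whose FC cannot be computed
#' are dropped with a warning.
#'
#' @param clean named list of `clean_series` (from [prep_cohort()]) or of
#'   plain T' x g matrices.
#' @param sparsity reporting sparsity (default 0.30).
#' @param node_labels optional node names; defaults to "BNA-001"...
#' @return integer matrix of class `dc_table` with attributes `sparsity`
#'   and row/column names.
#' @export
build_dc_table <- function(clean, sparsity = 0.30, node_labels = NULL) {
  series_of <- function(x) if (inherits(x, "clean_series")) x$series else x
  ids <- names(clean)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(clean))
  rows <- list()
  for (i in seq_along(clean)) {
    s <- series_of(clean[[i]])
    dc <- tryCatch({
      net <- threshold_by_sparsity(compute_fc(s), sparsity)
      degree_centrality(net)
    }, error = function(e) {
      warning(sprintf("subject %s dropped: %s", ids[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(dc)) rows[[ids[i]]] <- dc
  }
  if (length(rows) == 0L) stop("no subject yielded a valid network")
  values <- do.call(rbind, rows)
  g <- ncol(values)
  if (is.null(node_labels)) node_labels <- sprintf("BNA-%03d", seq_len(g))
  colnames(values) <- node_labels
  structure(values, sparsity = sparsity, class = c("dc_table", "matrix"))
}
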
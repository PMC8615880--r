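#' Proportional thresholding of a weighted connectivity matrix
#'
#' Ranks the off-diagonal upper-triangle weights in descending order and
#' retains exactly the top `ceiling(p * E)` edges (`E = N(N-1)/2`),
#' zeroing the rest and keeping the surviving weights (no
#' binarization). Ties at the cut are broken deterministically by
#' `(i, j)` lexicographic order, so the retained edge set at a lower
#' `p` is always a subset of the set at a higher `p`.
#'
#' @param matrix a [connectivity_matrix()] (or plain symmetric matrix).
#' @param p retained proportion, `0 < p <= 1`.
#' @return object of class `thresholded_graph`: `region_labels`,
#'   `weights` (symmetric, zeros for removed edges), `retention`,
#'   `normalized` flag.
#' @export
proportional_threshold <- function(matrix, p) {
  if (!(is.numeric(p) && length(p) == 1 && p > 0 && p <= 1))
    stop("retention proportion p must lie in (0, 1]")
  if (inherits(matrix, "connectivity_matrix")) {
    labs <- matrix$region_labels; w <- matrix$values
  } else {
    w <- as.matrix(matrix)
    labs <- rownames(w)
    if (is.null(labs)) labs <- sprintf("N%02d", seq_len(nrow(w)))
  }
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  # lexicographic (i, j) among ties: order by weight desc, then i, then j
  ord <- order(-w[upper.tri(w)], idx[, 1], idx[, 2])
  keep_n <- ceiling(p * nrow(idx))
  keep <- idx[ord[seq_len(keep_n)], , drop = FALSE]
  out <- w * 0
  out[keep] <- w[keep]
  out <- out + t(out)
  dimnames(out) <- list(labs, labs)
  structure(list(region_labels = labs, weights = out,
                 retention = p, normalized = FALSE),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges retained (p = %g)%s\n",
              length(x$region_labels), sum(x$weights[upper.tri(x$weights)] > 0),
              x$retention, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize graph weights to (0, 1]
#'
#' Divides every retained weight by the maximum retained weight, so the
#' strongest connection becomes 1. Nodal measures that depend on the
#' mean connection weight are computed on this normalized graph.
#'
#' @param graph a `thresholded_graph`.
#' @return the graph with `normalized = TRUE`.
#' @export
normalize_weights <- function(graph) {
  stopifnot(inherits(graph, "thresholded_graph"))
  mx <- max(graph$weights)
  if (mx <= 0) stop("graph has no retained edges; cannot normalize")
  graph$weights <- graph$weights / mx
  graph$normalized <- TRUE
  graph
}

# weighted clustering coefficient, geometric-mean-of-triangles variant
# (weights assumed scaled to at most 1)
weighted_clustering <- function(w) {
  n <- nrow(w)
  w3 <- w^(1 / 3)
  cyc <- diag(w3 %*% w3 %*% w3)        # 2 * sum of triangle intensities
  k <- rowSums(w > 0)
  cl <- numeric(n)
  ok <- k >= 2
  cl[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  cl
}

# weighted shortest-path length matrix, edge length = 1 / weight
wsp_lengths <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  igraph::distances(g, weights = len)
}

#' Nodal metrics of a thresholded, normalized weighted graph
#'
#' Per node: `degree` (count of incident retained edges), `strength`
#' (sum of incident weights), `clustering` (weighted triangle
#' coefficient, geometric-mean variant) and `local_efficiency` (mean
#' inverse weighted shortest-path length, edge length `1/weight`,
#' between the node's neighbors in the subgraph that excludes the node
#' itself). Isolated or degree-1 nodes get clustering and local
#' efficiency 0 by convention.
#'
#' @param graph a `thresholded_graph`, normally after
#'   [normalize_weights()].
#' @return data frame with columns `node`, `degree`, `strength`,
#'   `clustering`, `local_efficiency`.
#' @export
nodal_metrics <- function(graph) {
  stopifnot(inherits(graph, "thresholded_graph"))
  w <- graph$weights
  n <- nrow(w)
  deg <- rowSums(w > 0)
  stren <- rowSums(w)
  cl <- weighted_clustering(w)
  leff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    d <- wsp_lengths(sub)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    leff[v] <- mean(inv)
  }
  data.frame(node = graph$region_labels, degree = as.integer(deg),
             strength = stren, clustering = cl, local_efficiency = leff,
             row.names = NULL)
}

# one degree-preserving rewiring pass; edge weights travel with the
# rewired edges (Maslov-Sneppen double edge swap)
rewire_preserving_degree <- function(w, n_attempts) {
  el <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ne <- nrow(el)
  if (ne < 2) return(w)
  wt <- w[el]
  for (it in seq_len(n_attempts)) {
    ab <- sample.int(ne, 2)
    a <- el[ab[1], 1]; b <- el[ab[1], 2]
    c <- el[ab[2], 1]; d <- el[ab[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # propose a-d, c-b
    if (length(unique(c(a, b, c, d))) < 4) next
    if (w[a, d] > 0 || w[c, b] > 0) next
    w[a, b] <- 0; w[b, a] <- 0
    w[c, d] <- 0; w[d, c] <- 0
    w[a, d] <- wt[ab[1]]; w[d, a] <- wt[ab[1]]
    w[c, b] <- wt[ab[2]]; w[b, c] <- wt[ab[2]]
    el[ab[1], ] <- c(min(a, d), max(a, d))
    el[ab[2], ] <- c(min(c, b), max(c, b))
    wt[ab[1]] <- w[el[ab[1], 1], el[ab[1], 2]]
    wt[ab[2]] <- w[el[ab[2], 1], el[ab[2], 2]]
  }
  w
}

#' Small-world indices of a weighted graph
#'
#' Compares the graph's mean weighted clustering `C` and characteristic
#' path length `L` (mean weighted shortest-path length over finite
#' pairs, edge length `1/weight`) with the averages over degree-
#' preserving rewired null graphs that carry the edge weights with the
#' rewired edges. Reports `gamma = C/Crandom`, `lambda = L/Lrandom` and
#' the small-world index `sigma = gamma/lambda`; a small-world topology
#' shows `gamma > 1` with `lambda` near 1, hence `sigma > 1`.
#'
#' @param graph a `thresholded_graph` (>= 4 nodes).
#' @param n_nulls number of rewired null graphs (default 20).
#' @param rewires_per_edge swap attempts per edge per null (default 10).
#' @param seed integer seed for the rewiring.
#' @return object of class `small_world_result` with fields `c_real`,
#'   `c_random`, `l_real`, `l_random`, `gamma`, `lambda`, `sigma`,
#'   `n_nulls`.
#' @export
small_world <- function(graph, n_nulls = 20, rewires_per_edge = 10,
                        seed = 1L) {
  stopifnot(inherits(graph, "thresholded_graph"),
            length(graph$region_labels) >= 4, n_nulls >= 1)
  w <- graph$weights
  cw <- function(m) mean(weighted_clustering(m))
  lw <- function(m) {
    d <- wsp_lengths(m)
    vals <- d[upper.tri(d)]
    mean(vals[is.finite(vals)])
  }
  c_real <- cw(w); l_real <- lw(w)
  ne <- sum(w[upper.tri(w)] > 0)
  set.seed(seed)
  cr <- lr <- numeric(n_nulls)
  for (k in seq_len(n_nulls)) {
    wn <- rewire_preserving_degree(w, n_attempts = rewires_per_edge * ne)
    cr[k] <- cw(wn); lr[k] <- lw(wn)
  }
  c_random <- mean(cr); l_random <- mean(lr)
  if (c_random == 0)
    stop("degenerate null model: no triangles in any rewired graph")
  gamma <- c_real / c_random
  lambda <- l_real / l_random
  structure(list(c_real = c_real, c_random = c_random,
                 l_real = l_real, l_random = l_random,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_nulls = as.integer(n_nulls)),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world> gamma = %.3f, lambda = %.3f, sigma = %.3f (%d nulls)\n",
              x$gamma, x$lambda, x$sigma, x$n_nulls))
  invisible(x)
}

#' Small-world-controlled threshold selection for a cohort
#'
#' For each candidate retention proportion `p`, thresholds and
#' normalizes every subject's matrix and computes the small-world index
#' `sigma`; returns the largest `p` whose cohort-mean `sigma` exceeds 1.
#' Reading "larger threshold" as larger retained proportion keeps the
#' densest graphs that still show small-world topology and discards
#' the fragmented graphs arising at low retention.
#'
#' @param matrices list of [connectivity_matrix()] (one per subject).
#' @param p_grid ascending grid of candidate retention proportions.
#' @param n_nulls,rewires_per_edge,seed forwarded to [small_world()].
#' @param sw_fun small-world engine, by default [small_world()]
#'   (injectable for testing the selection rule in isolation).
#' @return list with `p_star` (selected proportion) and `profile`
#'   (data frame `p`, `mean_sigma`). Errors, printing the sigma-vs-p
#'   table, when no `p` qualifies.
#' @export
select_threshold <- function(matrices, p_grid = seq(0.1, 0.9, by = 0.05),
                             n_nulls = 20, rewires_per_edge = 10,
                             seed = 1L, sw_fun = small_world) {
  stopifnot(length(matrices) >= 1, length(p_grid) >= 1,
            !is.unsorted(p_grid))
  mean_sigma <- vapply(p_grid, function(p) {
    sig <- vapply(seq_along(matrices), function(s) {
      g <- normalize_weights(proportional_threshold(matrices[[s]], p))
      # a triangle-free (defragmented) graph has no small-world index;
      # such retention levels are what the rule is meant to discard
      tryCatch(
        sw_fun(g, n_nulls = n_nulls, rewires_per_edge = rewires_per_edge,
               seed = seed + s)$sigma,
        error = function(e) NA_real_)
    }, numeric(1))
    mean(sig)
  }, numeric(1))
  profile <- data.frame(p = p_grid, mean_sigma = mean_sigma)
  ok <- which(mean_sigma > 1)
  if (length(ok) == 0L)
    stop("no retention proportion preserves small-world topology:\n",
         paste(utils::capture.output(print(profile)), collapse = "\n"))
  list(p_star = p_grid[max(ok)], profile = profile)
}
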
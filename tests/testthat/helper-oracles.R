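# Independent brute-force oracles used by several test files.
# These deliberately re-derive quantities by enumeration, without
# touching the implementation paths they check.

# all-pairs weighted shortest paths by Floyd-Warshall, edge length 1/w
oracle_fw <- function(w) {
  n <- nrow(w)
  d <- 1 / w
  d[w == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# nodal metrics by explicit enumeration of neighbor pairs/triangles
oracle_nodal_metrics <- function(w) {
  n <- nrow(w)
  deg <- stren <- cl <- leff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    deg[v] <- length(nb)
    stren[v] <- sum(w[v, nb])
    if (length(nb) >= 2) {
      s <- 0
      for (a in nb) for (b in nb) if (a != b)
        s <- s + (w[v, a] * w[v, b] * w[a, b])^(1 / 3)
      cl[v] <- s / (deg[v] * (deg[v] - 1))
      sub <- w[nb, nb, drop = FALSE]
      d <- oracle_fw(sub)
      acc <- 0; np <- 0
      for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b) {
        acc <- acc + if (is.finite(d[a, b])) 1 / d[a, b] else 0
        np <- np + 1
      }
      leff[v] <- acc / np
    }
  }
  list(degree = deg, strength = stren, clustering = cl,
       local_efficiency = leff)
}

# random symmetric weighted matrix with entries in (0, 1), zero diagonal
random_weighted_matrix <- function(n, seed, density = 0.8) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut), 0.05, 0.95)
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w + t(w)
}

# Bayes factor by brute-force trapezoid quadrature on a fixed fine grid,
# independent of the adaptive-integration path in the package
oracle_bf <- function(r, n, kappa, side = "positive", n_grid = 200001L) {
  sup <- switch(side, two_sided = c(-1, 1), positive = c(0, 1),
                negative = c(-1, 0))
  rho <- seq(sup[1] + 1e-9, sup[2] - 1e-9, length.out = n_grid)
  h2f1 <- function(z) {
    term <- 1; s <- 1
    for (k in 0:5000) {
      term <- term * (0.5 + k)^2 / ((n - 0.5 + k) * (k + 1)) * z
      s <- s + term
      if (abs(term) < 1e-16 * abs(s)) break
    }
    s
  }
  ll <- function(p) (n - 1) / 2 * log1p(-p^2) - (n - 1.5) * log1p(-p * r) +
    log(h2f1((1 + p * r) / 2))
  l0 <- ll(0)
  prior <- 0.5 * stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa)
  mass <- if (side == "two_sided") 1 else 0.5
  f <- vapply(rho, function(p) exp(ll(p) - l0), numeric(1)) * prior / mass
  sum((f[-1] + f[-length(f)]) / 2) * diff(rho[1:2])
}

# two-region pure-tone signals with an exact phase offset (integer cycles)
pure_tone_pair <- function(freq = 10, fs = 100, n_samp = 200, n_epochs = 3,
                           lag = pi / 3) {
  dat <- array(0, c(n_epochs, 2, n_samp))
  tt <- seq(0, by = 1 / fs, length.out = n_samp)
  for (e in seq_len(n_epochs)) {
    ph0 <- 2 * pi * e / 7
    dat[e, 1, ] <- cos(2 * pi * freq * tt + ph0)
    dat[e, 2, ] <- cos(2 * pi * freq * tt + ph0 - lag)
  }
  epoched_parcel_signals(dat, c("A", "B"), fs)
}
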
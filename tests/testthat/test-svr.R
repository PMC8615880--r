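cohort_with_edge <- function(n, labs, noise_sd, seed,
                             edge = c("N01", "N02")) {
  pe <- data.frame(region_a = edge[1], region_b = edge[2],
                   target = "y", beta = 1)
  simulate_cohort_connectivity(
    cohort_spec(n, labs, pe, noise_sd = noise_sd, target_names = "y",
                seed = seed))
}

test_that("edge features are the lower triangle in fixed row-major order", {
  labs <- c("A", "B", "C", "D")
  w <- matrix(0, 4, 4)
  w[lower.tri(w)] <- 1:6 / 10
  w <- w + t(w)
  ft <- extract_edge_features(list(connectivity_matrix(w, labs)))
  expect_equal(ncol(ft$values), 6)            # m(m-1)/2
  expect_equal(ft$edge_labels,
               c("B--A", "C--A", "C--B", "D--A", "D--B", "D--C"))
  # row-major lower-triangle values: (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)
  expect_equal(unname(ft$values[1, ]),
               c(w[2, 1], w[3, 1], w[3, 2], w[4, 1], w[4, 2], w[4, 3]))
  # symmetry: the strictly-upper extraction would be identical
  expect_equal(unname(ft$values[1, ]),
               c(w[1, 2], w[1, 3], w[2, 3], w[1, 4], w[2, 4], w[3, 4]))
  # shape: 10 subjects x 10 nodes
  sim <- cohort_with_edge(10, sprintf("N%02d", 1:10), 1, seed = 44)
  ft10 <- extract_edge_features(sim$matrices)
  expect_equal(dim(ft10$values), c(10, 45))
  # label mismatch across subjects errors
  m1 <- connectivity_matrix(w, labs)
  m2 <- connectivity_matrix(w, c("A", "B", "C", "E"))
  expect_error(extract_edge_features(list(m1, m2)), "share")
})

test_that("LOSO SVR recovers a noiseless planted linear target", {
  sim <- cohort_with_edge(20, sprintf("N%02d", 1:4), noise_sd = 0, seed = 5)
  res <- loso_predict(extract_edge_features(sim$matrices), sim$targets$y)
  expect_gt(res$accuracy$r, 0.95)
  expect_equal(res$accuracy$n, 20L)
  expect_length(res$predicted, 20)
  # zero-variance target is rejected
  expect_error(loso_predict(extract_edge_features(sim$matrices),
                            rep(1, 20)), "zero-variance")
})

test_that("an independent Gaussian target is not predictable", {
  labs <- sprintf("N%02d", 1:4)
  set.seed(31)
  rs <- sapply(1:25, function(k) {
    sim <- simulate_cohort_connectivity(
      cohort_spec(20, labs, NULL, noise_sd = 1, target_names = "y",
                  seed = 600 + k))
    loso_predict(extract_edge_features(sim$matrices),
                 sim$targets$y)$accuracy$r
  })
  expect_lt(mean(abs(rs)), 2 / sqrt(20))
})

test_that("no training-fold statistic leaks from the held-out subject", {
  sim <- cohort_with_edge(12, sprintf("N%02d", 1:5), noise_sd = 0.5, seed = 6)
  ft <- extract_edge_features(sim$matrices)
  y <- sim$targets$y
  base <- loso_predict(ft, y)
  for (h in c(1, 7, 12)) {
    y2 <- y
    y2[h] <- y2[h] + 1000            # corrupt the held-out target
    pert <- loso_predict(ft, y2)
    expect_identical(base$predicted[h], pert$predicted[h])
  }
})

test_that("duplicating a training subject leaves the fit unchanged", {
  # convex problem: an exact duplicate of an existing training point
  # (inside the epsilon tube or sharing its constraints) does not move
  # the linear SVR solution on a tiny 3-subject toy
  X <- matrix(c(0, 1, 2, 0.5, 1.5, 2.5), ncol = 2)
  y <- c(-1, 0, 1)
  f1 <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                   cost = 1, epsilon = 0.1, scale = FALSE)
  f2 <- e1071::svm(rbind(X, X), c(y, y), type = "eps-regression",
                   kernel = "linear", cost = 1, epsilon = 0.1, scale = FALSE)
  w1 <- t(f1$coefs) %*% f1$SV
  w2 <- t(f2$coefs) %*% f2$SV
  pred_grid <- matrix(runif(10), ncol = 2)
  expect_equal(predict(f1, pred_grid), predict(f2, pred_grid),
               tolerance = 1e-4)
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-4)
})

test_that("fold order does not affect the concatenated accuracy", {
  sim <- cohort_with_edge(15, sprintf("N%02d", 1:4), noise_sd = 0.8, seed = 7)
  ft <- extract_edge_features(sim$matrices)
  res <- loso_predict(ft, sim$targets$y)
  perm <- sample(15)
  ft_p <- ft
  ft_p$values <- ft$values[perm, , drop = FALSE]
  ft_p$subject_ids <- ft$subject_ids[perm]
  res_p <- loso_predict(ft_p, sim$targets$y[perm])
  expect_equal(res_p$accuracy$r, res$accuracy$r, tolerance = 1e-9)
})

test_that("prediction grid covers the product and flags gated results", {
  labs <- sprintf("N%02d", 1:4)
  nets <- list(net_a = network_definition("net_a", labs[1:3]),
               net_b = network_definition("net_b", labs))
  sim <- cohort_with_edge(15, labs, noise_sd = 0.2, seed = 8)
  targets <- sim$targets
  targets$z_noise <- rnorm(15)       # second, unpredictable target
  cohorts <- list(
    alpha = lapply(nets, function(nt)
      lapply(sim$matrices, restrict_to_network, net = nt)))
  res <- prediction_grid(cohorts, targets)
  expect_length(res, 1 * 2 * 2)      # bands x networks x targets
  flags <- sapply(res, `[[`, "reported")
  checks <- sapply(res, function(x)
    x$accuracy$bf10 > sqrt(10) && x$accuracy$r > 0)
  expect_equal(unname(flags), unname(checks))
  # the planted target in the full network must be gated in
  expect_true(res[["alpha.net_b.y"]]$reported)
})
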
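test_that("proportional thresholding keeps the exact top fraction", {
  w <- random_weighted_matrix(4, seed = 1, density = 1)
  cm <- connectivity_matrix(w, LETTERS[1:4])
  g1 <- proportional_threshold(cm, 1)
  expect_equal(g1$weights, cm$values)
  g05 <- proportional_threshold(cm, 0.5)
  expect_equal(sum(g05$weights[upper.tri(g05$weights)] > 0), 3)  # ceil(.5*6)
  # retained edges are the strongest ones
  kept <- g05$weights[upper.tri(g05$weights)]
  dropped <- cm$values[upper.tri(cm$values)][kept == 0]
  expect_true(min(kept[kept > 0]) >= max(dropped))
  expect_error(proportional_threshold(cm, 0), "p")
  expect_error(proportional_threshold(cm, 1.2), "p")
})

test_that("tied weights break deterministically and nest monotonically", {
  # 4-node fixture with a 3-way tie at the cut
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.5
  w[2, 3] <- 0.5; w[2, 4] <- 0.2; w[3, 4] <- 0.1
  w <- w + t(w)
  cm <- connectivity_matrix(w, LETTERS[1:4])
  g2 <- proportional_threshold(cm, 2 / 6)   # keep 2: the tie resolves to (1,3)
  expect_equal(which(g2$weights[upper.tri(g2$weights)] > 0) |>
                 length(), 2)
  expect_gt(g2$weights[1, 3], 0)
  expect_equal(g2$weights[2, 3], 0)
  expect_equal(g2$weights[1, 4], 0)
  # nesting over the whole grid
  edges_at <- function(p) which(proportional_threshold(cm, p)$weights > 0)
  grid <- seq(1 / 6, 1, by = 1 / 6)
  for (i in seq_along(grid)[-1])
    expect_true(all(edges_at(grid[i - 1]) %in% edges_at(grid[i])))
})

test_that("weight normalization scales to a unit maximum and is idempotent", {
  w <- matrix(0, 3, 3); w[1, 2] <- 0.2; w[2, 3] <- 0.4
  w <- w + t(w)
  g <- proportional_threshold(connectivity_matrix(w, LETTERS[1:3]), 1)
  gn <- normalize_weights(g)
  expect_equal(gn$weights[2, 3], 1)
  expect_equal(gn$weights[1, 2], 0.5)
  expect_equal(normalize_weights(gn)$weights, gn$weights)
  # uniform weights all become 1
  wu <- matrix(0.3, 4, 4); diag(wu) <- 0
  gu <- normalize_weights(
    proportional_threshold(connectivity_matrix(wu, LETTERS[1:4]), 1))
  expect_true(all(gu$weights[upper.tri(wu)] == 1))
  # degree is normalization-invariant; strength scales by 1/max
  mets_raw <- nodal_metrics(g)
  mets_norm <- nodal_metrics(gn)
  expect_equal(mets_raw$degree, mets_norm$degree)
  expect_equal(mets_norm$strength, mets_raw$strength / 0.4)
})

test_that("nodal metrics match hand-computable graphs", {
  # unit triangle
  w <- matrix(1, 3, 3); diag(w) <- 0
  g <- normalize_weights(
    proportional_threshold(connectivity_matrix(w, LETTERS[1:3]), 1))
  m <- nodal_metrics(g)
  expect_equal(m$degree, rep(2L, 3))
  expect_equal(m$strength, rep(2, 3))
  expect_equal(m$clustering, rep(1, 3))
  expect_equal(m$local_efficiency, rep(1, 3))
  # path A-B-C: middle node closes no triangle
  wp <- matrix(0, 3, 3); wp[1, 2] <- wp[2, 3] <- 1
  wp <- wp + t(wp)
  gp <- normalize_weights(
    proportional_threshold(connectivity_matrix(wp, LETTERS[1:3]), 2 / 3))
  mp <- nodal_metrics(gp)
  expect_equal(mp$clustering[2], 0)
  expect_equal(mp$local_efficiency[2], 0)
})

test_that("nodal metrics equal the brute-force oracle on random graphs", {
  for (seed in 1:30) {
    n <- if (seed %% 2) 5 else 6
    w <- random_weighted_matrix(n, seed = 7000 + seed, density = 0.7)
    if (all(w == 0)) next
    g <- normalize_weights(
      proportional_threshold(connectivity_matrix(w, LETTERS[1:n]), 0.8))
    got <- nodal_metrics(g)
    want <- oracle_nodal_metrics(g$weights)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$strength, want$strength, tolerance = 1e-9)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-9)
    expect_equal(got$local_efficiency, want$local_efficiency,
                 tolerance = 1e-9)
  }
})

test_that("rewiring nulls preserve degrees and the weight multiset", {
  w <- random_weighted_matrix(10, seed = 42, density = 0.5)
  g <- normalize_weights(
    proportional_threshold(connectivity_matrix(w, LETTERS[1:10]), 0.6))
  set.seed(11)
  for (k in 1:5) {
    wn <- plvnet:::rewire_preserving_degree(g$weights, 300)
    expect_equal(rowSums(wn > 0), rowSums(g$weights > 0))
    expect_equal(sort(wn[upper.tri(wn) & wn > 0]),
                 sort(g$weights[upper.tri(g$weights) & g$weights > 0]))
    expect_gt(sum(wn != g$weights), 0)  # something actually moved
  }
})

test_that("small-world indices behave on canonical graphs", {
  # complete graph: rewiring is a no-op, so gamma = lambda = sigma = 1
  wc <- matrix(0.8, 6, 6); diag(wc) <- 0
  gc <- normalize_weights(
    proportional_threshold(connectivity_matrix(wc, LETTERS[1:6]), 1))
  swc <- small_world(gc, n_nulls = 5, seed = 2)
  expect_equal(swc$sigma, 1, tolerance = 0.05)
  expect_equal(swc$sigma, swc$gamma / swc$lambda, tolerance = 1e-9)
  # ring lattice N=20, k=4: clearly small-world
  N <- 20; w <- matrix(0, N, N)
  for (i in 1:N) for (s in 1:2) {
    j <- ((i - 1 + s) %% N) + 1
    w[i, j] <- 1; w[j, i] <- 1
  }
  gl <- normalize_weights(
    proportional_threshold(connectivity_matrix(w, sprintf("n%02d", 1:N)), 1))
  swl <- small_world(gl, n_nulls = 10, seed = 4)
  expect_gt(swl$sigma, 1)
  # seeded determinism
  expect_identical(small_world(gl, n_nulls = 5, seed = 9),
                   small_world(gl, n_nulls = 5, seed = 9))
})

test_that("threshold selection picks the largest small-world proportion", {
  # rule in isolation: inject a sigma engine with a known profile
  fake_sigma <- function(graph, ...) {
    p <- graph$retention
    list(sigma = if (p <= 0.5) 1.4 else 0.8)
  }
  mats <- lapply(1:3, function(i)
    connectivity_matrix(random_weighted_matrix(8, seed = 80 + i,
                                               density = 1),
                        LETTERS[1:8]))
  sel <- select_threshold(mats, p_grid = seq(0.1, 0.9, 0.1),
                          sw_fun = fake_sigma)
  expect_equal(sel$p_star, 0.5)
  expect_equal(nrow(sel$profile), 9)
  # single-subject cohort: the mean reduces to that subject
  sel1 <- select_threshold(mats[1], p_grid = c(0.3, 0.6),
                           sw_fun = fake_sigma)
  expect_equal(sel1$p_star, 0.3)
  # degenerate cohort (complete graphs, sigma exactly 1): error with table
  comp <- lapply(1:2, function(i)
    connectivity_matrix(matrix(0.5, 6, 6) - diag(0.5, 6), LETTERS[1:6]))
  expect_error(select_threshold(comp, p_grid = 1, n_nulls = 3),
               "small-world")
  # real engine on a lattice cohort returns a proportion with sigma > 1
  N <- 12; w <- matrix(0, N, N)
  for (i in 1:N) for (s in 1:2) {
    j <- ((i - 1 + s) %% N) + 1
    w[i, j] <- 0.9; w[j, i] <- 0.9
  }
  w[w == 0] <- 0.05; diag(w) <- 0
  latt <- lapply(1:2, function(i) connectivity_matrix(w, sprintf("n%02d", 1:N)))
  sel_real <- select_threshold(latt, p_grid = c(0.2, 0.4), n_nulls = 5,
                               seed = 3)
  expect_true(sel_real$p_star %in% c(0.2, 0.4))
  expect_gt(max(sel_real$profile$mean_sigma), 1)
})
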
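fs <- 250
tt <- seq(0, by = 1 / fs, length.out = 500)

make_signals <- function(...) {
  chans <- list(...)
  dat <- array(0, c(1, length(chans), length(tt)))
  for (i in seq_along(chans)) dat[1, i, ] <- chans[[i]]
  epoched_parcel_signals(dat, sprintf("C%d", seq_along(chans)), fs)
}

test_that("band-pass keeps the pass band and kills stop band and DC", {
  tone10 <- cos(2 * pi * 10 * tt)
  sig <- make_signals(tone10)
  alpha <- canonical_bands()$alpha
  out <- bandpass_epochs(sig, alpha)
  mid <- 100:400
  expect_equal(sd(out$data[1, 1, mid]) / sd(tone10[mid]), 1, tolerance = 0.05)
  gam <- bandpass_epochs(sig, canonical_bands()$gamma)
  expect_lt(sqrt(mean(gam$data[1, 1, ]^2)) / sqrt(mean(tone10^2)), 0.05)
  dc <- bandpass_epochs(make_signals(rep(1, length(tt))), alpha)
  expect_lt(sqrt(mean(dc$data[1, 1, ]^2)), 1e-3)
  # Nyquist violation names the band and the rate
  lowfs <- epoched_parcel_signals(array(rnorm(200), c(1, 1, 200)), "A", 60)
  expect_error(bandpass_epochs(lowfs, canonical_bands()$gamma), "gamma")
})

test_that("instantaneous phase obeys the analytic identities", {
  f <- 10
  sigc <- make_signals(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
  ph <- instantaneous_phase(sigc)
  mid <- 100:400
  # phase advances at 2*pi*f/fs per sample
  slope <- diff(unwrap_phase <- cumsum(c(ph[1, 1, 1],
    atan2(sin(diff(ph[1, 1, ])), cos(diff(ph[1, 1, ]))))))
  expect_equal(mean(slope[mid]), 2 * pi * f / fs, tolerance = 0.01)
  # sin lags cos by pi/2
  d <- ph[1, 1, mid] - ph[1, 2, mid]
  d <- atan2(sin(d), cos(d))
  expect_equal(mean(d), pi / 2, tolerance = 0.05)
  # phase of -x is phase of x shifted by pi (mod 2pi)
  signeg <- make_signals(cos(2 * pi * f * tt), -cos(2 * pi * f * tt))
  phn <- instantaneous_phase(signeg)
  dd <- phn[1, 2, mid] - phn[1, 1, mid]
  expect_equal(abs(atan2(sin(dd), cos(dd))), rep(pi, length(mid)),
               tolerance = 1e-6)
  # all-zero channel has no phase
  expect_error(instantaneous_phase(make_signals(rep(0, length(tt)))),
               "all-zero")
})

test_that("PLV matches its definition, the Monte-Carlo null and invariances", {
  # identical channels lock perfectly
  x <- cos(2 * pi * 10 * tt) + 0.1 * sin(2 * pi * 11 * tt)
  m <- plv_matrix(make_signals(x, x), band = NULL)
  expect_equal(m$values[1, 2], 1, tolerance = 1e-12)
  # phase differences alternating 0 and pi cancel exactly
  expect_equal(phase_locking_value(rep(c(0, pi), 250)), 0, tolerance = 1e-12)
  # uniform random phases: mean resultant length vs Monte-Carlo oracle
  set.seed(21)
  obs <- mean(replicate(300, phase_locking_value(runif(500, -pi, pi))))
  mc <- replicate(10000, sqrt(sum(cos(u <- runif(500, -pi, pi)))^2 +
                                sum(sin(u))^2) / 500)
  se <- sd(mc) / sqrt(300)         # SE of the observed mean of 300 draws
  expect_lt(abs(obs - mean(mc)), 2 * se + 2 * sd(mc) / sqrt(10000))
  # constant phase offset on one channel leaves PLV unchanged
  a <- cos(2 * pi * 10 * tt)
  b <- cos(2 * pi * 10 * tt - 1.1)
  b_off <- cos(2 * pi * 10 * tt - 1.1 + 0.7)
  p1 <- plv_matrix(make_signals(a, b), band = NULL)$values[1, 2]
  p2 <- plv_matrix(make_signals(a, b_off), band = NULL)$values[1, 2]
  expect_equal(p1, p2, tolerance = 1e-9)
  # a pair's PLV ignores the other channels and their order
  set.seed(5)
  extra1 <- rnorm(length(tt)); extra2 <- rnorm(length(tt))
  m4 <- plv_matrix(make_signals(a, b, extra1, extra2), band = NULL)
  m4p <- plv_matrix(make_signals(extra2, a, extra1, b), band = NULL)
  expect_equal(m4$values[1, 2], m4p$values[2, 4], tolerance = 1e-12)
  # degenerate input
  one_samp <- epoched_parcel_signals(array(1, c(1, 2, 1)), c("A", "B"), fs)
  expect_error(plv_matrix(one_samp, band = NULL), "single-sample")
})

test_that("network restriction and intersection follow set algebra", {
  set.seed(8)
  labs <- sprintf("L%02d", 1:12)
  w <- random_weighted_matrix(12, seed = 8, density = 1)
  w <- (w + 0.01) / 1.1; diag(w) <- 0
  cm <- connectivity_matrix(w, labs)
  net_all <- network_definition("all", labs)
  expect_equal(restrict_to_network(cm, net_all)$values, cm$values)
  net2 <- network_definition("pair", c("L05", "L02"))
  r2 <- restrict_to_network(cm, net2)
  expect_equal(dim(r2$values), c(2, 2))
  expect_equal(r2$values["L05", "L02"], cm$values["L05", "L02"])
  expect_equal(r2$region_labels, c("L05", "L02"))  # member order kept
  expect_error(restrict_to_network(cm, network_definition("bad", "Lxx")),
               "Lxx")

  resp <- network_definition("resp", c("A", "B", "C"))
  ei <- network_definition("ei", c("B", "D"))
  ev <- network_definition("ev", c("C", "E"))
  expect_equal(intersection_network(resp, ei, ev)$members, c("B", "C"))
  expect_warning(
    empty <- intersection_network(resp, network_definition("x", "D"),
                                  network_definition("y", "E")),
    "empty")
  expect_length(empty$members, 0)
  expect_equal(
    intersection_network(resp, network_definition("sup", c("A", "B", "C")),
                         ev)$members,
    resp$members)
})

test_that("a 148-region synthetic run yields a 148 x 148 matrix", {
  spec <- oscillator_spec(148, sampling_rate = 250, epoch_length = 2,
                          n_epochs = 2, seed = 1)
  sig <- simulate_coupled_epochs(spec)
  m <- plv_matrix(sig, canonical_bands()$theta)
  expect_equal(dim(m$values), c(148, 148))
  expect_true(all(m$values >= 0 & m$values <= 1))
})
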
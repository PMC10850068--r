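test_that("leaflet assignment uses the midplane zone with label retention", {
  z <- matrix(c(2, 0.5, -2,     # crosses via the zone
                2, 2, 2), nrow = 2, byrow = TRUE)
  tr <- assignLeaflets(z)
  expect_equal(tr$labels[1, ], c("upper", "upper", "lower"))
  expect_equal(tr$labels[2, ], rep("upper", 3))
  ## inside the zone after being upper: upper retained
  z2 <- matrix(c(2, 0.5, 2), nrow = 1)
  expect_equal(assignLeaflets(z2)$labels[1, ], rep("upper", 3))
  ## mirror swaps all labels
  trm <- assignLeaflets(-z)
  expect_true(all((tr$labels == "upper") == (trm$labels == "lower")))
})

test_that("flip-flop detection enforces the residence cutoff", {
  ## a crossing that stays: exactly one event
  z_stay <- makeLeafletScript(400, data.frame(molecule = 1, start = 30,
                                              dwell = Inf))
  ev <- detectFlipFlops(assignLeaflets(z_stay))
  expect_equal(nrow(ev), 1)
  ## dwell of 150 frames: the crossing and the confirmed return are two
  ## translocations under the residence rule
  z_150 <- makeLeafletScript(400, data.frame(molecule = 1, start = 30,
                                             dwell = 150))
  expect_equal(nrow(detectFlipFlops(assignLeaflets(z_150))), 2)
  ## dwell of 50 frames fails the cutoff entirely
  z_50 <- makeLeafletScript(400, data.frame(molecule = 1, start = 30,
                                            dwell = 50))
  expect_equal(nrow(detectFlipFlops(assignLeaflets(z_50))), 0)
  ## monotone drift within one leaflet: no event
  z_mono <- matrix(seq(1.5, 3, length.out = 300), nrow = 1)
  expect_equal(nrow(detectFlipFlops(assignLeaflets(z_mono))), 0)
  ## three molecules crossing once each: three events
  z3 <- makeLeafletScript(500, data.frame(molecule = 1:3,
                                          start = c(20, 60, 100),
                                          dwell = Inf))
  expect_equal(nrow(detectFlipFlops(assignLeaflets(z3))), 3)
})

test_that("flip-flop counts are invariant under z-mirror and time reversal", {
  ## resting runs at both trajectory ends exceed the residence cutoff, so
  ## the reversed trajectory confirms the same translocations
  z <- makeLeafletScript(700, data.frame(molecule = c(1, 1, 2),
                                         start = c(150, 450, 150),
                                         dwell = c(150, Inf, 40)))
  n0 <- nrow(detectFlipFlops(assignLeaflets(z)))
  n_mirror <- nrow(detectFlipFlops(assignLeaflets(-z)))
  n_rev <- nrow(detectFlipFlops(assignLeaflets(z[, ncol(z):1, drop = FALSE])))
  expect_equal(n_mirror, n0)
  expect_equal(n_rev, n0)
})

test_that("flip-flop rates and zero-event upper limits follow the normalization", {
  r <- flipFlopRate(2, n_molecules = 50, analyzed_time = 1)
  expect_equal(r$rate, 0.04)
  expect_true(is.na(r$upper_limit))
  r0 <- flipFlopRate(0, n_molecules = 100, analyzed_time = 10)
  expect_equal(r0$rate, 0)
  expect_equal(r0$upper_limit, 0.001)
  ## doubling the analysed time halves the rate
  expect_equal(flipFlopRate(2, 50, 2)$rate, 0.02)
})

test_that("permeation counting requires complete traversals", {
  ps <- makePermeationScript(
    600, data.frame(walker = c(1, 1, 2, 2, 3, 3, 4, 5, 5),
                    start = c(10, 200, 30, 250, 50, 300, 80, 40, 400),
                    kind = c("cross", "rebound", "cross", "rebound",
                             "rebound", "cross", "cross", "cross",
                             "rebound")))
  n <- countPermeationEvents(ps$z, ps$lower, ps$upper)
  expect_equal(n, ps$n_cross)
  expect_equal(ps$n_cross, 5)
  ## a rebound alone counts nothing
  pr <- makePermeationScript(200, data.frame(walker = 1, start = 20,
                                             kind = "rebound"))
  expect_equal(countPermeationEvents(pr$z, pr$lower, pr$upper), 0)
  ## time reversal preserves the count
  n_rev <- countPermeationEvents(ps$z[, ncol(ps$z):1, drop = FALSE],
                                 ps$lower, ps$upper)
  expect_equal(n_rev, n)
})

test_that("the permeability unit chain gives micrometres per second", {
  p <- permeability(10, time = 100, area = 25)
  expect_equal(p$r, 0.004)
  expect_equal(p$P, 0.004 / (2 * 33.3679) * 1e6, tolerance = 1e-12)
  expect_equal(p$P, 59.94, tolerance = 1e-4)
  expect_equal(permeability(0, 100, 25)$P, 0)
  ## doubling the area halves P
  expect_equal(permeability(10, 100, 50)$P, p$P / 2)
})

test_that("lateral diffusion recovers a known Brownian coefficient", {
  xy <- makeBrownianWalkers(3e-9, n_steps = 1e4, n_walkers = 200, dt = 0.01,
                            seed = 51)
  ld <- lateralDiffusion(xy, dt = 0.01)
  expect_lt(abs(ld$D - 3e-9) / 3e-9, 0.10)
  expect_false(ld$flagged)
  ## static positions: zero
  still <- array(1, dim = c(500, 3, 2))
  expect_equal(lateralDiffusion(still, 0.01)$D, 0)
  ## ballistic motion is flagged as nonlinear
  t <- seq(0, 10, by = 0.01)
  ball <- array(0, dim = c(length(t), 1, 2)); ball[, 1, 1] <- 2 * t
  expect_true(lateralDiffusion(ball, 0.01)$flagged)
})

test_that("the Tanner equation respects its limiting transport channels", {
  ## permeation much faster than lateral diffusion: D_perp -> D_par
  fast <- perpendicularDiffusion(3e-9, P = 1e9, z_w = 10)
  expect_equal(fast$D_perp, 3e-9, tolerance = 1e-3)
  ## permeation-limited: D_perp -> P z_w
  slow <- perpendicularDiffusion(3e-9, P = 10, z_w = 2)
  expect_equal(slow$D_perp, (10e-6) * (2e-9), tolerance = 1e-3)
  expect_equal(slow$D_perp, 3e-9 * 2e-14 / (3e-9 + 2e-14), tolerance = 1e-12)
  ## never exceeds either channel
  set.seed(52)
  for (i in 1:20) {
    D <- 10^runif(1, -10, -8); P <- 10^runif(1, 0, 3); zw <- runif(1, 0.5, 5)
    r <- perpendicularDiffusion(D, P, zw)
    expect_lte(r$D_perp, D + 1e-18)
    expect_lte(r$D_perp, P * 1e-6 * zw * 1e-9 + 1e-18)
  }
  expect_error(perpendicularDiffusion(3e-9, 10, 0), "geometry")
})

test_that("Arrhenius fits recover the activation energy", {
  Tv <- seq(290, 350, by = 10)
  ## noiseless: exact to 3 significant figures
  Pv <- 2 * exp(-14 * 310 / Tv)
  fit <- arrheniusActivation(Pv, Tv)
  expect_equal(fit$E_a, 14, tolerance = 5e-4)
  ## temperature-independent permeability: zero barrier
  expect_equal(arrheniusActivation(rep(3, 5), seq(290, 330, by = 10))$E_a, 0,
               tolerance = 1e-12)
  ## 5 % multiplicative noise, 100 replicates: mean within one unit
  set.seed(53)
  ests <- replicate(100, {
    Pn <- Pv * exp(rnorm(length(Pv), 0, 0.05))
    arrheniusActivation(Pn, Tv)$E_a
  })
  expect_lt(abs(mean(ests) - 14), 1)
  expect_error(arrheniusActivation(c(1, 2), c(300, 310)), "fit error")
})

test_that("binned summaries weight by simulation length and drop thin bins", {
  ## equal weights reduce to the ordinary mean
  b <- binnedSummary(values = c(1, 3), by = c(0.5, 0.6), breaks = c(0, 1))
  expect_equal(b$mean, 2)
  ## weights 3:1
  b2 <- binnedSummary(values = c(10, 2), weights = c(3, 1), by = c(0.5, 0.6),
                      breaks = c(0, 1))
  expect_equal(b2$mean, (3 * 10 + 1 * 2) / 4)
  ## empty bin is absent
  b3 <- binnedSummary(values = c(1, 3), by = c(0.1, 0.2),
                      breaks = c(0, 0.5, 1))
  expect_equal(nrow(b3), 1)
  ## bins with too little data dropped (permeation rule: > 1 us)
  b4 <- binnedSummary(values = c(1, 3), weights = c(0.4, 5),
                      by = c(0.25, 0.75), breaks = c(0, 0.5, 1),
                      min_weight = 1)
  expect_equal(nrow(b4), 1)
  expect_equal(b4$mean, 3)
})
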
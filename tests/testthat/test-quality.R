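test_that("bond quality equals the closed-form Cauchy mass", {
  ## simulated mean on the experimental value with sem = dS: F(1) - F(-1)
  bq <- bondQuality(S_mean = -0.2, s = 0.02^2 * 50, n = 50, S_exp = -0.2)
  expect_equal(bq$P, 0.5, tolerance = 1e-12)
  expect_false(bq$excluded)

  ## vanishing simulation error concentrates all mass inside the bars
  expect_equal(bondQuality(0.1, 0, 10, 0.1)$P, 1)
  expect_equal(bondQuality(0.1, 0, 10, 0.2)$P, 0)

  ## far-away simulation: heavy Cauchy tail still below 1 %
  sem <- 0.001
  bq_far <- bondQuality(0.1 + 100 * sem, sem^2 * 4, 4, 0.1, dS_exp = sem)
  expect_lt(bq_far$P, 0.01)

  ## too-large simulation error bars are excluded, not scored
  bq_ex <- bondQuality(0.1, 0.05^2 * 4, 4, 0.1)
  expect_true(bq_ex$excluded)
  expect_true(is.na(bq_ex$P))

  expect_error(bondQuality(0.1, 0.001, 1, 0.1), "insufficient-sample")
})

test_that("bond quality agrees with numerical integration of the dof-1 t density", {
  set.seed(41)
  for (i in 1:20) {
    S_mean <- runif(1, -0.3, 0.3)
    S_exp <- runif(1, -0.3, 0.3)
    n <- sample(10:100, 1)
    sem <- runif(1, 0.001, 0.019)
    s <- sem^2 * n
    dS <- 0.02
    P <- bondQuality(S_mean, s, n, S_exp, dS)$P
    oracle <- integrate(function(x) dt(x, df = 1),
                        (S_exp - dS - S_mean) / sem,
                        (S_exp + dS - S_mean) / sem,
                        rel.tol = 1e-10)$value
    expect_equal(P, oracle, tolerance = 1e-6)
  }
})

test_that("bond quality is monotone in the deviation and the experimental error", {
  devs <- seq(0, 0.5, length.out = 100)
  P_dev <- vapply(devs, function(d)
    bondQuality(0.1 + d, 0.01^2 * 25, 25, 0.1)$P, numeric(1))
  expect_true(all(diff(P_dev) <= 1e-12))
  dSs <- seq(0.011, 0.1, length.out = 100)    # above sem, so never excluded
  P_dS <- vapply(dSs, function(dS)
    bondQuality(0.15, 0.01^2 * 25, 25, 0.1, dS_exp = dS)$P, numeric(1))
  expect_true(all(diff(P_dS) >= -1e-12))
})

test_that("fragment quality applies the availability penalty exactly", {
  tb <- data.frame(fragment = c("acyl chain sn-1", "acyl chain sn-1"),
                   P = c(0.8, 0.6))
  expect_equal(fragmentQuality(tb, "sn-1")$P_frag, 0.7)
  ## one of two bonds unavailable: 0.8 * 0.5
  tb2 <- data.frame(fragment = c("acyl chain sn-1", "acyl chain sn-1"),
                    P = c(0.8, NA))
  fq <- fragmentQuality(tb2, "sn-1")
  expect_equal(fq$P_frag, 0.4)
  expect_equal(fq$F_frag, 0.5)
  ## nothing available: quality absent, not zero
  tb3 <- data.frame(fragment = "headgroup", P = NA_real_)
  expect_true(is.na(fragmentQuality(tb3, "headgroup")$P_frag))
  ## total spans all fragments
  tb4 <- data.frame(fragment = c("headgroup", "acyl chain sn-2"),
                    P = c(1, 0.5))
  expect_equal(fragmentQuality(tb4, "total")$P_frag, 0.75)
})

test_that("system quality weights lipids by molar fraction", {
  lq <- data.frame(lipid = c("POPC", "CHOL"),
                   P_sn1 = c(0.8, 0.4), P_sn2 = c(0.8, 0.4),
                   P_hg = c(0.9, NA), P_total = c(0.8, 0.4))
  sq <- systemQuality(lq, c(POPC = 0.75, CHOL = 0.25))
  expect_equal(sq$total, 0.7)
  expect_equal(sq$tails, 0.7)
  expect_equal(sq$headgroup, 0.9)   # renormalized over scored lipids
  ## a single lipid keeps its own qualities
  sq1 <- systemQuality(lq[1, ], c(POPC = 1))
  expect_equal(sq1$total, 0.8)
  ## permutation invariance
  sq_perm <- systemQuality(lq[2:1, ], c(CHOL = 0.25, POPC = 0.75))
  expect_equal(sq_perm, sq)
})

test_that("qualities stay within [0, 1] on random inputs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    bq <- bondQuality(runif(1, -0.5, 1), runif(1, 0, 4e-4) * n, n,
                      runif(1, -0.5, 1))
    if (!bq$excluded) {
      expect_gte(bq$P, 0); expect_lte(bq$P, 1)
    }
  }
  tb <- data.frame(fragment = sample(c("headgroup", "acyl chain sn-1"), 20,
                                     replace = TRUE),
                   P = ifelse(runif(20) < 0.3, NA, runif(20)))
  for (fr in c("headgroup", "sn-1", "total")) {
    fq <- fragmentQuality(tb, fr)
    if (!is.na(fq$P_frag)) {
      expect_gte(fq$P_frag, 0); expect_lte(fq$P_frag, 1)
    }
  }
})

test_that("the experimental scaling coefficient is the weighted LS optimum", {
  ## exact proportionality
  q <- seq(0.05, 0.6, by = 0.005)
  Fe <- abs(sin(10 * q) / q)
  sc <- scaleFormFactor(list(q = q, F = 2 * Fe), q, Fe, rep(0.02, length(q)))
  expect_equal(sc$k_e, 2, tolerance = 1e-12)
  ## worked two-point case
  sc2 <- scaleFormFactor(list(q = c(0.1, 0.2), F = c(3, 3)),
                         c(0.1, 0.2), c(1, 2), c(1, 1))
  expect_equal(sc2$k_e, 1.8)
  ## numeric 1-D minimizer oracle on random curves
  set.seed(43)
  for (i in 1:5) {
    Fs <- Fe * runif(1, 0.5, 3) + rnorm(length(q), 0, 0.05)
    dF <- runif(length(q), 0.01, 0.1)
    k <- scaleFormFactor(list(q = q, F = abs(Fs)), q, Fe, dF)$k_e
    k_opt <- optimize(function(kk) sum((abs(Fs) - kk * Fe)^2 / dF^2),
                      c(0, 10), tol = 1e-12)$minimum
    expect_equal(k, k_opt, tolerance = 1e-8)
  }
  expect_error(scaleFormFactor(list(q = q, F = Fe), q, 0 * Fe,
                               rep(1, length(q))), "degenerate-scaling")
})

test_that("form factor quality measures the distance between first minima", {
  slab40 <- makeSlabProfile(40, 0.1)
  slab38 <- makeSlabProfile(38, 0.1)
  ff40 <- formFactor(slab40$profile)
  q <- seq(0.02, 1, by = 0.002)
  ## identical curves: FF_q = 0
  same <- formFactorQuality(ff40, ffQ(ff40), ffAbs(ff40))
  expect_lt(same$FF_q, 1e-9)
  ## analytic slabs at 40 vs 38 Angstrom: |2pi/40 - 2pi/38| * 100
  res <- formFactorQuality(list(q = q, F = slab40$F_analytic(q)),
                           q, slab38$F_analytic(q), rep(0.02, length(q)))
  expect_equal(res$FF_q, abs(2 * pi / 40 - 2 * pi / 38) * 100,
               tolerance = 0.05 / 0.83)
  ## scale invariance: multiplying either curve by a positive constant
  res_scaled <- formFactorQuality(list(q = q, F = 7 * slab40$F_analytic(q)),
                                  q, 0.3 * slab38$F_analytic(q),
                                  rep(0.02, length(q)))
  expect_equal(res_scaled$FF_q, res$FF_q, tolerance = 1e-9)
  ## small zero-mean noise barely moves the filtered minimum
  set.seed(44)
  noisy <- slab40$F_analytic(q) + rnorm(length(q), 0, 0.002)
  res_noise <- formFactorQuality(list(q = q, F = abs(noisy)),
                                 q, slab38$F_analytic(q),
                                 rep(0.02, length(q)))
  expect_lt(abs(res_noise$FF_q - res$FF_q), 0.05)
  ## no minimum in range: absent with a diagnostic
  flat <- formFactorQuality(list(q = q, F = exp(-q)), q,
                            slab38$F_analytic(q), rep(0.02, length(q)))
  expect_true(is.na(flat$FF_q))
  expect_match(paste(flat$diagnostic, collapse = " "), "no first minimum")
})

test_that("joined order-parameter quality evaluation aggregates fragments", {
  bl <- makeSyntheticBilayer(n_lipids = 8, n_frames = 20, seed = 45)
  bonds <- bondsFromMapping(bl$mapping)
  ops <- orderParameters(bl$traj, bonds, "POPC")
  exp_entry <- make_experiment(
    opData = data.frame(bond = paste(bonds$carbon, bonds$hydrogen),
                        S_exp = ifelse(bonds$fragment %in%
                                         c("headgroup", "glycerol backbone"),
                                       bl$S_head, bl$S_chain),
                        dS_exp = 0.02))
  q <- evaluateOrderParameterQuality(ops, bonds, exp_entry)
  ## simulated values equal the experimental targets: near-perfect quality
  expect_gt(q$P_total, 0.9)
  expect_gt(q$P_sn1, 0.9)
  expect_true(all(q$bonds$P > 0.9, na.rm = TRUE))
})
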
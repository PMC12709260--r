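test_that("form factors recover element electron counts at q = 0", {
  fft <- formFactorTable()
  electrons <- c(H = 1, C = 6, N = 7, O = 8, S = 16)
  for (el in names(electrons)) {
    f0 <- idplens:::.cromer_mann_f(el, 0, fft)
    expect_lt(abs(f0 - electrons[[el]]), 0.1)
  }
})

test_that("Debye profile matches a brute-force double loop", {
  set.seed(19)
  q <- defaultQGrid(40)
  for (n in c(5, 20, 50)) {
    X <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
    feff <- matrix(runif(n * length(q), 0.5, 8), n, length(q))
    got <- debyeProfile(X, q = q, feff = feff)@I
    ref <- numeric(length(q))
    for (k in seq_along(q)) {
      s <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) {
        r <- sqrt(sum((X[i, ] - X[j, ])^2))
        sinc <- if (q[k] * r < 1e-12) 1 else sin(q[k] * r) / (q[k] * r)
        s <- s + feff[i, k] * feff[j, k] * sinc
      }
      ref[k] <- s
    }
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("two-point dumbbell follows its closed form and I(0) its limit", {
  q <- defaultQGrid()
  X <- rbind(c(0, 0, 0), c(10, 0, 0))
  sp <- debyeProfile(X, q = q, feff = matrix(1, 2, length(q)))
  expect_equal(sp@I / 4, (1 + sin(q * 10) / (q * 10)) / 2,
               tolerance = 1e-8)
  # any frame: I(0) = (sum f(0))^2
  fr <- buildChain(loadPeptide("GAMDA"), rep(-75, 5), rep(150, 5))
  f0 <- idplens:::.effective_form_factors(topology(fr), 0, vacuum = TRUE)[, 1]
  sp0 <- debyeProfile(fr, q = c(1e-8, 0.01), vacuum = TRUE)
  expect_equal(sp0@I[1], sum(f0)^2, tolerance = 1e-6 * sum(f0)^2)
  # missing element rejected by atom
  top <- topology(fr)
  top$element[3] <- "Zn"
  expect_error(idplens:::.effective_form_factors(top, q), "Zn")
})

test_that("ensemble averaging is an unweighted mean and permutation-safe", {
  q <- defaultQGrid(30)
  X1 <- rbind(c(0, 0, 0), c(8, 0, 0))
  X2 <- rbind(c(0, 0, 0), c(12, 0, 0))
  f <- matrix(1, 2, length(q))
  p1 <- debyeProfile(X1, q = q, feff = f)
  p2 <- debyeProfile(X2, q = q, feff = f)
  avg <- ensembleAverage(list(p1, p2))
  expect_equal(avg@I, (p1@I + p2@I) / 2)
  expect_equal(ensembleAverage(list(p2, p1, p1, p2))@I, avg@I)
  expect_equal(ensembleAverage(list(p1, p1))@I, p1@I)
  bad <- profile(q * 1.01, p1@I)
  expect_error(ensembleAverage(list(p1, bad)), "grid")
})

test_that("Guinier inversion is exact on Gaussian curves and rejects rubbish", {
  q <- seq(0.005, 0.2, by = 0.002)
  g <- guinierRg(profile(q, 100 * exp(-q^2 * 16^2 / 3)))
  expect_equal(g$rg, 16, tolerance = 16 * 1e-3)
  expect_equal(g$I0, 100, tolerance = 0.1)
  expect_error(guinierRg(profile(q, rep(5, length(q)))), "slope")
  # dumbbell Debye curve vs the point-mass Rg (5 A); the tighter window
  # keeps the Guinier truncation error of this two-point extreme below 3%
  qd <- defaultQGrid(150)
  spd <- debyeProfile(rbind(c(0, 0, 0), c(10, 0, 0)), q = qd,
                      feff = matrix(1, 2, length(qd)))
  gd <- guinierRg(spd, qmax_rg = 1.0)
  expect_lt(abs(gd$rg - 5) / 5, 0.03)
})

test_that("dimensionless Kratky has the Guinier peak at sqrt(3), 3/e", {
  q <- seq(0, 0.4, by = 0.0005)
  sp <- profile(q, 50 * exp(-q^2 * 16^2 / 3))
  kk <- kratky(sp, rg = 16, I0 = 50)
  expect_identical(kk$kratky[1], 0)
  expect_equal(kk$qrg[which.max(kk$kratky)], sqrt(3), tolerance = 0.01)
  expect_equal(max(kk$kratky), 3 / exp(1), tolerance = 1e-4)
  # Debye random-coil model plateaus at 2 instead of decaying
  rg <- 16
  x2 <- (q * rg)^2
  coil <- 2 * (exp(-x2) - 1 + x2) / x2^2
  coil[1] <- 1 # analytic q -> 0 limit of the coil function
  kc <- kratky(profile(q, coil), rg = rg, I0 = 1)
  tail_vals <- kc$kratky[kc$qrg > 4]
  expect_true(all(tail_vals > 1.5 & tail_vals < 2.1))
  expect_error(kratky(sp, rg = 16, I0 = -1), "positive")
})

test_that("indirect P(r) finds the dumbbell distance and obeys its limits", {
  q <- seq(0.01, 0.5, length.out = 120)
  sp <- profile(q, 2 + 2 * sin(q * 10) / (q * 10))
  pr <- prIndirect(sp, Dmax = 12)
  expect_equal(pr@r[which.max(pr@P)], 10, tolerance = 0.5)
  expect_equal(pr@P[1], 0)
  expect_equal(pr@P[length(pr@P)], 0)
  expect_true(all(pr@P >= 0))
  # alpha -> infinity kills the curve
  expect_lt(max(abs(prIndirect(sp, Dmax = 12, alpha = 1e9)@P)), 1e-4)
})

test_that("direct P(r) is a unit-area histogram with the right mode", {
  two <- toy_ensemble(list(rbind(c(0, 0, 0), c(10, 0, 0))))
  pd <- prDirect(two, bin_width = 0.5)
  expect_equal(pd@r[which.max(pd@P)], 10.25, tolerance = 0.5)
  area <- sum(diff(pd@r) * (pd@P[-1] + pd@P[-length(pd@P)]) / 2)
  expect_equal(area, 1, tolerance = 1e-6)
  # dense random cluster: globule-like skew, mode below Dmax / 2
  set.seed(3)
  blob <- toy_ensemble(list(matrix(rnorm(3 * 60, sd = 4), ncol = 3)))
  pb <- prDirect(blob, bin_width = 0.5)
  expect_lt(pb@r[which.max(pb@P)], pb@Dmax / 2)
})

test_that("indirect and direct P(r) agree on a synthetic ensemble", {
  cfg <- generatorConfig(seed = 21, n_replicas = 1,
                         frames_per_replica = 80, burn_in = 300,
                         rg_target = 13, rg_spring = 2)
  ens <- sampleEnsemble(aicdPeptide(), cfg)
  sp <- ensembleAverage(ens)
  # one bin at the transform's real-space resolution, pi / qmax
  bw <- pi / max(sp@q)
  pd <- prDirect(ens, bin_width = bw)
  pri <- prIndirect(sp, Dmax = pd@Dmax)
  expect_lt(abs(pri@r[which.max(pri@P)] - pd@r[which.max(pd@P)]), bw)
  # the full curves agree closely once both are unit-normalized
  Pd <- approx(pd@r, pd@P, xout = pri@r, rule = 2)$y
  Pi <- pri@P / sum(pri@P * mean(diff(pri@r)))
  expect_gt(cor(Pd, Pi), 0.97)
})

test_that("the chi-square statistic is the simulated-weighted literal form", {
  qq <- c(1, 2)
  expect_equal(as.numeric(chiSquare(profile(qq, c(3, 1)),
                                    profile(qq, c(1, 2)))), 4.25)
  expect_equal(as.numeric(chiSquare(profile(1, 2), profile(1, 1))), 1.0)
  same <- profile(qq, c(5, 7))
  expect_equal(as.numeric(chiSquare(same, same)), 0)
  expect_error(chiSquare(profile(qq, c(1, 1)), profile(qq, c(0, 2))),
               "zero")
  # chi2 >= 0, equality only for identical curves
  set.seed(8)
  for (i in 1:5) {
    E <- profile(qq, runif(2, 1, 5))
    S <- profile(qq, runif(2, 1, 5))
    expect_gte(as.numeric(chiSquare(E, S)), 0)
  }
  # fitted scale factor removes a pure amplitude mismatch
  sp <- profile(seq(0.01, 0.3, length.out = 30),
                exp(-seq(0.01, 0.3, length.out = 30)^2 * 50))
  scaled <- profile(sp@q, 3.7 * sp@I)
  x2 <- chiSquare(scaled, sp, scale = "fit")
  expect_lt(as.numeric(x2), 1e-20)
  expect_equal(attr(x2, "scale_factor"), 3.7, tolerance = 1e-10)
  # sigma-weighted conventional statistic is a separate operation
  E <- profile(qq, c(3, 1), sigma = c(1, 0.5))
  expect_equal(chiSquareSigma(E, profile(qq, c(1, 2))),
               mean(c((2 / 1)^2, (1 / 0.5)^2)))
})

test_that("scattering curves round-trip through 3-column ASCII", {
  sp <- profile(seq(0.01, 0.3, length.out = 20), runif(20, 1, 5),
                sigma = runif(20, 0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".dat")
  writeScatteringCurve(sp, path)
  back <- readScatteringCurve(path)
  expect_equal(back@q, sp@q, tolerance = 1e-6)
  expect_equal(back@I, sp@I, tolerance = 1e-6)
  expect_equal(back@sigma, sp@sigma, tolerance = 1e-6)
})

test_that("larger-Rg groups decay faster at low q", {
  p <- aicdPeptide()
  mk <- function(target, seed) {
    cfg <- generatorConfig(seed = seed, n_replicas = 1,
                           frames_per_replica = 40, burn_in = 800,
                           rg_target = target, rg_spring = 2)
    ensembleAverage(sampleEnsemble(p, cfg))
  }
  lo <- mk(11, 33)
  hi <- mk(19, 34)
  expect_gt(guinierRg(hi)$rg, guinierRg(lo)$rg)
  # normalized low-q intensity drops faster for the extended group
  qwin <- lo@q > 0.05 & lo@q < 0.15
  expect_true(all((hi@I / hi@I[1])[qwin] < (lo@I / lo@I[1])[qwin]))
})
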
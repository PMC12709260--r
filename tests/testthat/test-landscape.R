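test_that("featurization has the documented dimensions and determinism", {
  ens <- small_ensemble()
  fs <- featurize(ens)
  # sin/cos of phi(2..L) and psi(1..L-1): 4(L-1) features
  expect_equal(ncol(fs$X), 4 * 34)
  expect_equal(nrow(fs$X), nFrames(ens))
  expect_false(any(is.na(fs$X)))
  expect_identical(fs$X, featurize(ens)$X)
  # identical frames give identical rows
  one <- extractGroup(ens, frameIndex("d", c(3L)))
  dup <- one
  dup@coords <- array(rep(coords(one), 2), dim = c(dim(coords(one))[1], 3, 2))
  dup@frameMeta <- data.frame(replica = 1L, frame = 0:1, time_ps = 0:1)
  fd <- featurize(dup)
  expect_identical(fd$X[1, ], fd$X[2, ])
  # ca-distances on 4 residues: the 3 pairs with |i-j| >= 2
  four <- buildChain(loadPeptide("AAAA"), rep(-70, 4), rep(140, 4))
  expect_equal(ncol(featurize(four, "ca-distances")$X), 3)
})

test_that("tICA separates slow from fast AR(1) features", {
  set.seed(123)
  n <- 50000
  ar1 <- function(n, a) {
    x <- numeric(n)
    for (i in 2:n) x[i] <- a * x[i - 1] + rnorm(1)
    x
  }
  X <- cbind(ar1(n, 0.9), ar1(n, 0.1))
  tm <- fitTica(X, tau = 1)
  expect_equal(tm$eigenvalues[1], 0.9, tolerance = 0.03 / 0.9)
  v <- tm$eigenvectors[, 1]
  expect_gt(abs(v[1]) / sqrt(sum(v^2)), 0.99)
  # eigenvalues sorted, bounded, C0-orthonormal eigenvectors
  expect_true(all(diff(tm$eigenvalues) <= 0))
  expect_true(all(abs(tm$eigenvalues) <= 1.05))
  G <- t(tm$eigenvectors) %*% tm$C0 %*% tm$eigenvectors
  expect_equal(unname(G), diag(2), tolerance = 1e-6)
  # white noise: all eigenvalues near zero
  W <- matrix(rnorm(2 * n), ncol = 2)
  expect_lt(max(abs(fitTica(W, tau = 1)$eigenvalues)), 0.05)
})

test_that("tICA eigenvalues decay as a^tau for AR(1) input", {
  set.seed(7)
  n <- 40000
  a <- 0.9
  x <- numeric(n)
  for (i in 2:n) x[i] <- a * x[i - 1] + rnorm(1)
  X <- cbind(x, rnorm(n))
  for (tau in c(1, 5, 10)) {
    lam <- fitTica(X, tau = tau)$eigenvalues[1]
    expect_equal(lam, a^tau, tolerance = 0.1)
  }
})

test_that("lagged pairs never straddle replicas and tau is validated", {
  ens <- small_ensemble() # 2 x 120 frames
  fs <- featurize(ens)
  expect_error(fitTica(fs, tau = 120), "replica")
  tm <- fitTica(fs, tau = 30)
  expect_equal(ncol(tm$projections), ncol(fs$X))
  # constant feature rejected
  Xc <- cbind(fs$X[, 1:3], 1)
  expect_error(fitTica(Xc, tau = 5), "variance")
})

test_that("free-energy surfaces normalize to zero minima with NA voids", {
  set.seed(15)
  x <- c(rnorm(4000, -2, 0.4), rnorm(4000, 2, 0.4))
  y <- c(rnorm(4000, -1, 0.4), rnorm(4000, 1, 0.4))
  fes <- freeEnergySurface(x, y, bins = 40)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  expect_true(anyNA(fes$F)) # empty corners undefined, not infinite
  expect_false(any(is.infinite(fes$F), na.rm = TRUE))
  # the global minimum sits at one component mean, and the other basin
  # holds a deep local minimum at the second mean
  bw <- diff(fes$x_mid[1:2])
  argmin <- which(fes$F == 0, arr.ind = TRUE)[1, ]
  expect_lt(min(abs(fes$x_mid[argmin[1]] - c(-2, 2))), 2 * bw)
  other <- if (fes$x_mid[argmin[1]] < 0) 2 else -2
  sel_x <- which(abs(fes$x_mid - other) < 3 * bw)
  expect_lt(min(fes$F[sel_x, ], na.rm = TRUE), 0.5)
  # uniform-ish density: flat F
  u <- freeEnergySurface(runif(20000), runif(20000), bins = 5)
  expect_lt(max(u$F), 0.25)
})

test_that("observable landscapes average per bin", {
  x <- rep(c(0.5, 1.5, 2.5), each = 100) + runif(300, -0.3, 0.3)
  y <- runif(300)
  sl <- sasaLandscape(x, y, values = x, bins = 3)
  col_means <- apply(sl$mean, 1, mean, na.rm = TRUE)
  expect_true(all(diff(col_means) > 0)) # increases along x
  const <- sasaLandscape(x, y, values = rep(7, 300), bins = 3)
  expect_true(all(abs(const$mean - 7) < 1e-12, na.rm = TRUE))
  expect_error(sasaLandscape(x, y, values = 1:10), "align")
})

test_that("GROMOS clustering finds constructed cluster structure", {
  ens <- small_ensemble()
  one <- coords(ens)[, , 1]
  # five identical frames: one cluster, population 1
  same <- extractGroup(ens, frameIndex("s", 0L))
  same@coords <- array(rep(one, 5), dim = c(nrow(one), 3, 5))
  same@frameMeta <- data.frame(replica = 1L, frame = 0:4, time_ps = 0:4)
  cl <- gromosCluster(same)
  expect_equal(cl$populations, 1)
  expect_equal(sum(cl$populations), 1)
  # two tight bundles of distinct conformations: internal RMSD below the
  # cutoff, inter-bundle far above -> exactly two clusters, 3/5 and 2/5
  other <- coords(ens)[, , which.max(rmsdSeries(ens))]
  set.seed(6)
  jig <- function(X) X + matrix(rnorm(length(X), sd = 0.05), nrow(X), 3)
  bundles <- array(c(jig(one), jig(one), jig(one),
                     jig(other), jig(other)),
                   dim = c(nrow(one), 3, 5))
  two <- same
  two@coords <- bundles
  cl2 <- gromosCluster(two, cutoff_nm = 0.9)
  expect_equal(length(cl2$populations), 2)
  expect_equal(sort(cl2$populations, decreasing = TRUE), c(0.6, 0.4))
  # cutoff -> 0: every distinct frame its own cluster
  sub <- extractGroup(ens, frameIndex("d", 0:9))
  cl0 <- gromosCluster(sub, cutoff_nm = 1e-9)
  expect_equal(length(cl0$populations), 10)
  # frame-order permutation preserves populations (ties documented)
  perm <- extractGroup(sub, frameIndex("p", c(0L, 3L, 5L, 9L)))
  clp <- gromosCluster(perm, cutoff_nm = 0.5)
  expect_equal(sum(clp$populations), 1)
})
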
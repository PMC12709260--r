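test_that("radius of gyration matches hand geometry", {
  # two unit masses 2 A apart
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                masses = c(1, 1)), 1.0)
  # four unit masses at the corners of a 2 A square
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radiusOfGyration(sq, masses = rep(1, 4)), sqrt(2))
  # homogeneity under uniform scaling
  set.seed(7)
  X <- matrix(rnorm(30), ncol = 3)
  m <- runif(10, 0.5, 2)
  expect_equal(radiusOfGyration(3.7 * X, masses = m),
               3.7 * radiusOfGyration(X, masses = m), tolerance = 1e-12)
  expect_error(radiusOfGyration(sq, masses = rep(0, 4)), "mass")
})

test_that("group assignment uses nearest integer bins with half-up ties", {
  part <- assignGroups(c(10.4, 10.5, 15.2, 19.8, 9.1))
  expect_equal(part@assignment, c(10L, 11L, 15L, 20L, 9L))
  expect_equal(groupLabels(part), c(9L, 10L, 11L, 15L, 20L))
  # every frame in exactly one group; counts sum to total
  counts <- vapply(groupLabels(part),
                   function(l) length(groupIndex(part, l)@frames), 1L)
  expect_equal(sum(counts), 5L)
  # group-mean Rg non-decreasing in label
  ens <- small_ensemble()
  p2 <- assignGroups(radiusOfGyration(ens))
  mns <- vapply(groupLabels(p2), function(l)
    mean(rgValues(p2)[groupIndex(p2, l)@frames + 1L]), 0.0)
  expect_true(all(diff(mns) >= 0))
  # configurable bin width
  p3 <- assignGroups(c(1.2, 2.6), bin_width = 2)
  expect_equal(p3@assignment, c(1L, 1L))
})

test_that("RMSD is zero to itself and to any rigid transform", {
  ens <- small_ensemble()
  expect_equal(rmsdSeries(ens)[1], 0, tolerance = 1e-9)
  # rigid rotation + translation of the reference
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  ref <- coords(ens)[, , 1] %*% t(R) + matrix(c(5, -3, 11),
                                              nrow(topology(ens)), 3,
                                              byrow = TRUE)
  expect_lt(rmsdSeries(ens, reference = ref)[1], 1e-7)
  # global rigid transform of the whole ensemble leaves the series alone
  X <- coords(ens)
  Xr <- X
  for (f in seq_len(dim(X)[3]))
    Xr[, , f] <- X[, , f] %*% t(R) + matrix(c(1, 2, 3), dim(X)[1], 3,
                                            byrow = TRUE)
  ens2 <- ens
  ens2@coords <- Xr
  expect_equal(rmsdSeries(ens2), rmsdSeries(ens), tolerance = 1e-9)
  expect_error(rmsdSeries(ens, selection = "ZZ"), "no atoms")
})

test_that("Kabsch RMSD matches a brute-force rotation search", {
  set.seed(11)
  A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(9), 3, 3)
  ens <- toy_ensemble(list(A, B))
  got <- rmsdSeries(ens, reference = 1L, selection = "all")[2] # nm
  # grid search over Euler angles, coarse-to-fine, independent of Kabsch
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rot <- function(a, b, c) {
    Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c)
    sqrt(mean(rowSums((Ac %*% rot(a, b, c) - Bc)^2)))
  best <- c(0, 0, 0); bestv <- Inf
  for (a in seq(0, 2 * pi, by = 0.2)) for (b in seq(0, pi, by = 0.2))
    for (c in seq(0, 2 * pi, by = 0.2)) {
      v <- eval_rmsd(a, b, c)
      if (v < bestv) { bestv <- v; best <- c(a, b, c) }
    }
  for (rounds in 1:3) {
    step <- 0.2 / 4^rounds
    grid <- expand.grid(a = best[1] + step * (-4:4),
                        b = best[2] + step * (-4:4),
                        c = best[3] + step * (-4:4))
    vals <- mapply(eval_rmsd, grid$a, grid$b, grid$c)
    bestv <- min(vals)
    best <- unlist(grid[which.min(vals), ])
  }
  expect_equal(got, bestv / 10, tolerance = 1e-3) # both in nm
})

test_that("KDE normalizes, inherits symmetry, and finds the mode", {
  set.seed(4)
  x <- c(rnorm(2000, -3), rnorm(2000, 3))
  d <- kdeDensity(x)
  dx <- diff(d$x)
  area <- sum(dx * (d$density[-1] + d$density[-length(d$density)]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  # symmetric bimodal input -> near-symmetric density
  sym <- kdeDensity(c(x, -x))
  expect_equal(sym$density, rev(sym$density), tolerance = 0.02)
  # large-n standard normal: mode near 0 (wide kernel stabilises the
  # flat-top mode estimate)
  z <- rnorm(100000)
  dz <- kdeDensity(z, bandwidth = 0.3, n = 2048L)
  expect_lt(abs(dz$x[which.max(dz$density)]), 0.05)
  expect_error(kdeDensity(rep(1, 5)), "bandwidth")
})
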
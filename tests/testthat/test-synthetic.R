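test_that("buildChain reproduces its input dihedrals and ideal geometry", {
  set.seed(31)
  n <- 10
  phi <- runif(n, -180, 180)
  psi <- runif(n, -180, 180)
  ens <- buildChain(loadPeptide("GAMDAVTPEK"), phi, psi)
  di <- backboneDihedrals(ens)
  expect_equal(di$phi[-1, 1], phi[-1], tolerance = 1e-6)
  expect_equal(di$psi[-n, 1], psi[-n], tolerance = 1e-6)
  # bonded distances at ideal values
  top <- topology(ens)
  X <- coords(ens)[, , 1]
  d <- function(a, i, b, j)
    sqrt(sum((X[which(top$atom == a & top$resid == i), ] -
                X[which(top$atom == b & top$resid == j), ])^2))
  for (i in seq_len(n)) {
    expect_equal(d("N", i, "CA", i), 1.458, tolerance = 1e-6)
    expect_equal(d("CA", i, "C", i), 1.525, tolerance = 1e-6)
    expect_equal(d("C", i, "O", i), 1.231, tolerance = 1e-6)
    if (i < n) expect_equal(d("C", i, "N", i + 1), 1.329, tolerance = 1e-6)
  }
  # Pro carries no amide H, Gly no CB
  expect_false(any(top$atom == "H" & top$resid == 8)) # P at position 8
  expect_false(any(top$atom == "CB" & top$resid == 1)) # G at position 1
})

test_that("ideal helix geometry places i,i+4 O..H pairs at H-bond range", {
  h <- ideal_helix(12)
  top <- topology(h)
  X <- coords(h)[, , 1]
  O <- X[top$atom == "O", ]
  H <- X[top$atom == "H", ]
  d <- vapply(1:8, function(i) sqrt(sum((O[i, ] - H[i + 4, ])^2)), 0.0)
  expect_true(all(d > 1.7 & d < 2.4))
})

test_that("extended chain grows about 3.5 A per residue", {
  ext <- extended_chain(12)
  ca <- coords(ext)[topology(ext)$atom == "CA", , 1]
  per_res <- sqrt(sum((ca[12, ] - ca[1, ])^2)) / 11
  expect_gt(per_res, 3.3)
  expect_lt(per_res, 3.8)
})

test_that("a 2-residue chain builds its minimal atom set", {
  ens <- buildChain(loadPeptide("GA"), c(-60, -60), c(140, 140))
  expect_equal(dim(coords(ens))[1], nrow(topology(ens)))
  expect_equal(nrow(topology(ens)), 4 + 1 + 5 + 1) # G: N H CA C O; A: +CB
})

test_that("generator config validates its invariants", {
  expect_error(generatorConfig(basin_weights = c(0.5, 0.6, 0, 0)), "sum")
  expect_error(generatorConfig(basin_weights = c(-0.1, 1.1, 0, 0)), "sum")
  expect_error(generatorConfig(frames_per_replica = 0), "frames")
  expect_error(generatorConfig(clash_cutoff = 0), "clash_cutoff")
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- generatorConfig(seed = 9, rg_target = 14)
  writeGeneratorConfig(cfg, path)
  cfg2 <- readGeneratorConfig(path)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$rg_target, 14)
  expect_equal(unname(cfg2$basin_centers), unname(cfg$basin_centers))
})

test_that("same seed gives bit-identical ensembles; replicas differ", {
  p <- aicdPeptide()
  cfg <- generatorConfig(seed = 17, n_replicas = 2, frames_per_replica = 20,
                         burn_in = 50)
  e1 <- sampleEnsemble(p, cfg)
  e2 <- sampleEnsemble(p, cfg)
  expect_identical(coords(e1), coords(e2))
  r1 <- coords(e1)[, , frameMeta(e1)$replica == 1]
  r2 <- coords(e1)[, , frameMeta(e1)$replica == 2]
  expect_false(isTRUE(all.equal(r1, r2)))
})

test_that("no surviving frame violates the clash cutoff and geometry holds", {
  ens <- small_ensemble()
  top <- topology(ens)
  heavy <- which(top$element != "H")
  res <- top$resid[heavy]
  X <- coords(ens)
  set.seed(1)
  for (f in sample(nFrames(ens), 12)) {
    D <- as.matrix(dist(X[heavy, , f]))
    sep <- abs(outer(res, res, "-")) >= 2
    expect_gte(min(D[sep]), 2.8)
    # bonded N-CA distances stay ideal in every sampled frame
    nref <- X[which(top$atom == "N"), , f]
    caref <- X[which(top$atom == "CA"), , f]
    expect_equal(sqrt(rowSums((nref - caref)^2)), rep(1.458, 35),
                 tolerance = 1e-4)
  }
})

test_that("frame autocorrelation of Rg is positive at lag 1", {
  ens <- small_ensemble()
  rg <- radiusOfGyration(ens)
  for (r in 1:2) {
    x <- rg[frameMeta(ens)$replica == r]
    expect_gt(cor(x[-1], x[-length(x)]), 0)
  }
})

test_that("the Rg bias recovers its target and leaves unbiased runs alone", {
  p <- aicdPeptide()
  cfg <- generatorConfig(seed = 23, n_replicas = 1,
                         frames_per_replica = 400, burn_in = 1500,
                         rg_target = 15, rg_spring = 2)
  rg <- radiusOfGyration(sampleEnsemble(p, cfg))
  expect_lt(abs(mean(rg) - 15), 1)
  # with zero spring the target is inert: identical RNG stream, same draws
  cfg_a <- generatorConfig(seed = 23, n_replicas = 1,
                           frames_per_replica = 100, burn_in = 100,
                           rg_target = 10, rg_spring = 0)
  cfg_b <- generatorConfig(seed = 23, n_replicas = 1,
                           frames_per_replica = 100, burn_in = 100,
                           rg_target = 20, rg_spring = 0)
  expect_identical(coords(sampleEnsemble(p, cfg_a)),
                   coords(sampleEnsemble(p, cfg_b)))
})

test_that("pure-helix weights raise interior helix content over extended", {
  p <- aicdPeptide()
  base <- generatorConfig(seed = 29, n_replicas = 1,
                          frames_per_replica = 60, burn_in = 1500,
                          basin_sigma = 10)
  cfg_h <- base; cfg_h$basin_weights <- c(1, 0, 0, 0)
  cfg_b <- base; cfg_b$basin_weights <- c(0, 1, 0, 0)
  frac_helix <- function(cfg) {
    ss <- assignSecondaryStructure(sampleEnsemble(p, cfg))
    mean(ss$classes[5:31, ] == "helix")
  }
  expect_gt(frac_helix(cfg_h), frac_helix(cfg_b))
})

test_that("pseudo-time bookkeeping follows index times interval", {
  ens <- small_ensemble()
  meta <- frameMeta(ens)
  expect_equal(meta$time_ps, meta$frame * 100)
  one <- extractGroup(ens, frameIndex("one", 0L))
  expect_equal(frameMeta(one)$time_ps, 0)
  expect_error(emulateProtocol(ens, -5), "positive")
  # 70,000 frames at 10 ps -> last pseudo-time 699.99 ns, by arithmetic
  expect_equal((70000 - 1) * 10 / 1000, 699.99)
})
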
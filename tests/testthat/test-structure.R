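test_that("Shrake-Rupley matches the isolated-sphere area and is additive", {
  one <- toy_ensemble(list(matrix(0, 1, 3)))
  s1 <- sasa(one, radii = c(C = 1.7))
  expect_equal(s1$total, 4 * pi * 3.1^2 / 100, tolerance = 0.005)
  # two far-separated atoms: sum of isolated values
  two <- toy_ensemble(list(rbind(c(0, 0, 0), c(100, 0, 0))))
  s2 <- sasa(two, radii = c(C = 1.7))
  expect_equal(s2$total, 2 * s1$total, tolerance = 1e-9)
  # overlap reduces the total and per-residue values sum to the total
  near <- toy_ensemble(list(rbind(c(0, 0, 0), c(1.0, 0, 0))))
  sn <- sasa(near, radii = c(C = 1.7))
  expect_lt(sn$total, 2 * s1$total)
  expect_equal(sum(sn$per_residue[, 1]), sn$total, tolerance = 1e-9)
  expect_true(all(sn$per_residue >= 0))
  expect_error(sasa(one, radii = c(N = 1.55)), "radius")
})

test_that("SASA is occlusion-monotonic as a neighbour approaches", {
  dists <- c(6, 4, 3, 2.5, 2)
  totals <- vapply(dists, function(d) {
    e <- toy_ensemble(list(rbind(c(0, 0, 0), c(d, 0, 0))))
    sasa(e, radii = c(C = 1.7))$total
  }, 0.0)
  expect_true(all(diff(totals) <= 1e-12))
})

test_that("SASA agrees with an independent implementation on a peptide", {
  # oracle: mdtraj shrake_rupley (probe 0.14 nm, 960 points, its radii
  # table) run on the identical deterministically built frame
  set.seed(99)
  fr <- buildChain(aicdPeptide(), runif(35, -150, -50), runif(35, 100, 160))
  s <- sasa(fr, probe = 1.4, n_points = 960,
            radii = c(C = 1.7, H = 1.2, N = 1.55, O = 1.52),
            include_h = TRUE)
  expect_equal(s$total, 37.091819763, tolerance = 0.02 * 37.09)
})

test_that("per-residue SASA variance is invariant to rigid motion", {
  ens <- small_ensemble()
  sub <- extractGroup(ens, frameIndex("s", 0:14))
  s1 <- sasa(sub)
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  X <- coords(sub)
  for (f in seq_len(dim(X)[3]))
    X[, , f] <- X[, , f] %*% t(R) + 7
  sub2 <- sub
  sub2@coords <- X
  s2 <- sasa(sub2)
  # translation leaves the deterministic sphere grid aligned: exact
  sub3 <- sub
  sub3@coords <- coords(sub) + 13.7
  expect_equal(sasa(sub3)$per_residue, s1$per_residue, tolerance = 1e-10)
  # rotation re-samples the fixed point grid: equal to sampling resolution
  expect_equal(apply(s2$per_residue, 1, var),
               apply(s1$per_residue, 1, var), tolerance = 0.1)
})

test_that("group SASA summary normalizes against the grand mean", {
  ens <- small_ensemble()
  sr <- sasa(ens, frames = seq_len(40))
  part <- assignGroups(radiusOfGyration(ens)[1:40])
  gs <- sasaGroupSummary(sr, part)
  expect_equal(mean(gs$group_totals$mean), gs$grand_mean)
  expect_equal(gs$group_totals$deviation,
               gs$group_totals$mean - gs$grand_mean)
  expect_equal(rowSums(gs$per_residue_norm * NA^0) * 0,
               rep(0, 35)) # finite everywhere
  # two hand groups with totals 40 and 50 -> grand mean 45, deviations -5/+5
  sr2 <- list(total = c(40, 50), per_residue = rbind(c(40, 50)),
              frames = 1:2)
  class(sr2) <- "SasaResult"
  part2 <- assignGroups(c(10.1, 19.9))
  gs2 <- sasaGroupSummary(sr2, part2)
  expect_equal(gs2$grand_mean, 45)
  expect_equal(gs2$group_totals$deviation, c(-5, 5))
  # identical frames: all deviations zero
  sr3 <- list(total = c(44, 44), per_residue = rbind(c(44, 44)),
              frames = 1:2)
  class(sr3) <- "SasaResult"
  gs3 <- sasaGroupSummary(sr3, part2)
  expect_equal(gs3$group_totals$deviation, c(0, 0))
})

test_that("minimal CA distance maps are symmetric minima over frames", {
  ens <- small_ensemble()
  sub <- extractGroup(ens, frameIndex("s", 0:9))
  cm <- minCaDistanceMap(sub)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_equal(diag(cm$matrix), rep(0, 35))
  # single frame: exactly that frame's CA distance matrix
  one <- extractGroup(ens, frameIndex("f", 0L))
  top <- topology(one)
  D <- as.matrix(dist(coords(one)[top$atom == "CA", , 1]))
  expect_equal(minCaDistanceMap(one)$matrix, unname(D), tolerance = 1e-12)
  # adding frames can only lower entries
  expect_true(all(cm$matrix <= minCaDistanceMap(one)$matrix + 1e-12))
  # |i - j| = 1 entries stay near the 3.8 A virtual bond
  seq_d <- cm$matrix[cbind(1:34, 2:35)]
  expect_true(all(abs(seq_d - 3.8) < 0.3))
})

test_that("hydrogen-bond maps apply the distance and angle criterion", {
  helix <- ideal_helix(12)
  hb <- hbondMap(helix)
  expect_true(all(hb$matrix >= 0 & hb$matrix <= 1))
  expect_equal(hb$matrix, t(hb$matrix))
  # ideal helix: full occupancy on the (i, i+4) off-diagonal
  expect_equal(hb$matrix[cbind(1:8, 5:12)], rep(1, 8))
  # extended chain: none
  expect_equal(max(hbondMap(extended_chain(12))$matrix), 0)
  # tighter distance cutoff removes the helix bonds
  expect_equal(max(hbondMap(helix, d_cut = 2.0)$matrix), 0)
})

test_that("secondary structure matches full DSSP on frozen fixtures", {
  # oracle: mdtraj compute_dssp (full classes) on identical coordinates,
  # collapsed to the 5-class scheme. Helix: "-HHHHHHHHHH-";
  # hairpin II': "-EEEEEETTEEEEEE-"; 3:5 bulge turn: "------BTTB------".
  ss_h <- assignSecondaryStructure(ideal_helix(12))$classes[, 1]
  expect_equal(ss_h, c("coil", rep("helix", 10), "coil"))
  ss_p <- assignSecondaryStructure(beta_hairpin())$classes[, 1]
  expect_equal(ss_p, c("coil", rep("strand", 6), "turn", "turn",
                       rep("strand", 6), "coil"))
  loose <- buildChain(ala_peptide(16),
                      c(rep(-139, 7), 60, 90, rep(-139, 7)),
                      c(rep(135, 7), 30, 0, rep(135, 7)))
  ss_l <- assignSecondaryStructure(loose)$classes[, 1]
  expect_equal(ss_l, c(rep("coil", 6), "strand", "turn", "turn", "strand",
                       rep("coil", 6)))
  # extended chain: no helix, no strand
  ss_e <- assignSecondaryStructure(extended_chain(12))$classes[, 1]
  expect_false(any(ss_e %in% c("helix", "strand")))
  # probabilities sum to one per residue; group fractions are convex
  ens <- small_ensemble()
  sub <- extractGroup(ens, frameIndex("s", 0:29))
  part <- assignGroups(radiusOfGyration(sub))
  ssa <- assignSecondaryStructure(sub, part)
  expect_equal(rowSums(ssa$probabilities), rep(1, 35))
  expect_equal(unname(rowSums(ssa$group_fractions)),
               rep(1, nrow(ssa$group_fractions)))
  expect_error(assignSecondaryStructure(toy_ensemble(list(matrix(0, 2, 3)))),
               "backbone")
})

test_that("hbond map and Kabsch-Sander agree on ideal helix i,i+4 bonds", {
  helix <- ideal_helix(12)
  geom <- hbondMap(helix)$matrix[cbind(1:8, 5:12)]
  ss <- assignSecondaryStructure(helix)$classes[, 1]
  expect_true(all(geom == 1))
  expect_true(all(ss[2:11] == "helix"))
})

test_that("Ramachandran histograms integrate region fractions", {
  ens <- small_ensemble()
  sub <- extractGroup(ens, frameIndex("s", 0:39))
  full <- ramachandran(sub, regions = list(all = c(-180, 180, -180, 180)))
  expect_equal(unname(full$fractions["all"]), 1)
  expect_equal(sum(full$histogram), full$n)
  # delta ensemble concentrated at the alphaR center
  d <- buildChain(ala_peptide(8), rep(-63, 8), rep(-43, 8))
  rd <- ramachandran(d)
  expect_equal(unname(rd$fractions["alphaR"]), 1)
  # generator basin weights recovered through the region integrals;
  # midpoint-partition regions own each basin's full mass, and a minimal
  # clash cutoff isolates dihedral sampling from excluded-volume depletion
  cfg <- generatorConfig(seed = 2, n_replicas = 2, frames_per_replica = 400,
                         burn_in = 500, clash_cutoff = 1.0, stride = 15)
  big <- sampleEnsemble(aicdPeptide(), cfg)
  rr <- ramachandran(big, regions = recovery_regions())
  expect_gte(rr$n, 1e4)
  expect_lt(max(abs(rr$fractions - c(0.30, 0.35, 0.25, 0.10))), 0.03)
})

test_that("Karplus couplings evaluate the printed coefficients literally", {
  kp <- karplusParams()
  expect_equal(karplusJ(90, kp, "phi"), 1.9)
  expect_equal(karplusJ(180, kp, "phi"), 9.7)
  expect_equal(karplusJ(90, kp, "psi"), 0.5)
  # bounds of the quadratic over cos in [-1, 1], by brute-force grid
  grid <- karplusJ(seq(-180, 180, by = 0.05), kp, "phi")
  expect_lt(max(grid), 9.7 + 1e-9)
  expect_gte(min(grid), 1.9 - 1.4^2 / (4 * 6.4) - 1e-9)
  # a configurable offset shifts the angle argument
  kp60 <- karplusParams(offset_phi = -60)
  expect_equal(karplusJ(60, kp60, "phi"), karplusJ(0, kp, "phi"))
})

test_that("ensemble J-couplings report per-residue group means and SDs", {
  ens <- small_ensemble()
  sub <- extractGroup(ens, frameIndex("s", 0:29))
  part <- assignGroups(radiusOfGyration(sub), bin_width = 5)
  jc <- jCouplings(sub, part = part)
  # first residue lacks phi, last lacks psi
  j3 <- jc[jc$coupling == "J3_phi" & jc$group == jc$group[1], ]
  expect_false(1 %in% j3$residue)
  j2 <- jc[jc$coupling == "J2_psi" & jc$group == jc$group[1], ]
  expect_false(35 %in% j2$residue)
  expect_true(all(jc$sd >= 0))
  # means agree with a direct recomputation for one residue/group
  di <- backboneDihedrals(sub)
  g1 <- groupIndex(part, groupLabels(part)[1])@frames + 1L
  expect_equal(j3$mean[j3$residue == 10],
               mean(karplusJ(di$phi[10, g1], karplusParams(), "phi")))
})
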
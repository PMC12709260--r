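#' Shrake-Rupley solvent-accessible surface area
#'
#' Golden-spiral point sampling: for each atom, the fraction of `n_points`
#' probe-sphere points not occluded by any neighbour times
#' 4 pi (r + probe)^2. Heavy atoms only by default (hydrogens carry no
#' surface), residue sums and totals in nm^2.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points sphere points per atom.
#' @param radii named per-element van der Waals radii, Angstrom.
#' @param include_h include hydrogens as spheres.
#' @param frames optional 1-based frame subset.
#' @return list of class "SasaResult": `total` (nm^2 per frame),
#'   `per_residue` (residues x frames, nm^2), `frames` (the frames used).
#' @export
sasa <- function(ens, probe = 1.4, n_points = 960L, radii = vdwRadii(),
                 include_h = FALSE, frames = NULL) {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  rows <- if (include_h) seq_len(nrow(top)) else which(top$element != "H")
  missing_r <- setdiff(unique(top$element[rows]), names(radii))
  if (length(missing_r))
    stop("no van der Waals radius for element(s): ",
         paste(missing_r, collapse = ", "))
  rad <- unname(radii[top$element[rows]])
  resid <- top$resid[rows]
  L <- length(unique(top$resid))
  if (is.null(frames)) frames <- seq_len(nFrames(ens))
  X <- coords(ens)
  per_res <- matrix(0, nrow = L, ncol = length(frames))
  for (k in seq_along(frames)) {
    a <- cpp_shrake_rupley_fast(matrix(X[rows, , frames[k]], ncol = 3), rad, probe,
                           as.integer(n_points))
    per_res[, k] <- as.numeric(tapply(a, factor(resid, levels = seq_len(L)),
                                      sum, default = 0)) / 100 # A^2 -> nm^2
  }
  structure(list(total = colSums(per_res), per_residue = per_res,
                 frames = frames, probe = probe, n_points = n_points),
            class = "SasaResult")
}

#' Per-group SASA summaries and normalized deviations
#'
#' Group means of total SASA with SD; a grand mean taken as the unweighted
#' mean over group means (a frame-weighted grand mean is available via
#' `weight = "frames"`); deviations of group totals and per-residue group
#' means from the grand means; per-residue variance across all frames.
#'
#' @param sr a SasaResult covering the partitioned frames.
#' @param part an \linkS4class{RgPartition} over the same frames.
#' @param weight "groups" (unweighted over groups) or "frames".
#' @return list with `group_totals` (group, n, mean, sd, deviation),
#'   `grand_mean`, `per_residue_mean` (residues x groups),
#'   `per_residue_norm` (deviation from each residue's grand mean),
#'   `per_residue_var` (variance across all frames, nm^4).
#' @export
sasaGroupSummary <- function(sr, part, weight = c("groups", "frames")) {
  stopifnot(inherits(sr, "SasaResult"), is(part, "RgPartition"))
  weight <- match.arg(weight)
  if (length(sr$total) != length(rgValues(part)))
    stop("SasaResult and partition cover different frame counts")
  labs <- groupLabels(part)
  sizes <- vapply(labs, function(l) length(groupIndex(part, l)@frames), 1L)
  keep <- sizes > 0L
  if (any(!keep)) warning("excluding empty group(s): ",
                          paste(labs[!keep], collapse = ", "))
  labs <- labs[keep]
  means <- sds <- numeric(length(labs))
  prm <- matrix(0, nrow = nrow(sr$per_residue), ncol = length(labs),
                dimnames = list(NULL, labs))
  for (i in seq_along(labs)) {
    sel <- groupIndex(part, labs[i])@frames + 1L
    means[i] <- mean(sr$total[sel])
    sds[i] <- if (length(sel) > 1) stats::sd(sr$total[sel]) else 0
    prm[, i] <- rowMeans(sr$per_residue[, sel, drop = FALSE])
  }
  grand <- if (weight == "groups") mean(means) else mean(sr$total)
  res_grand <- if (weight == "groups") rowMeans(prm)
               else rowMeans(sr$per_residue)
  list(group_totals = data.frame(group = labs, n = sizes[keep],
                                 mean = means, sd = sds,
                                 deviation = means - grand),
       grand_mean = grand,
       per_residue_mean = prm,
       per_residue_norm = prm - res_grand,
       per_residue_var = apply(sr$per_residue, 1, stats::var))
}

#' Minimal C-alpha distance contact map
#'
#' Per residue pair, the minimum CA-CA distance over all frames of the
#' (group) ensemble, in Angstrom.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @return list of class "ContactMap": `matrix` (residues x residues,
#'   symmetric, zero diagonal) and `statistic = "min_ca_distance_A"`.
#' @export
minCaDistanceMap <- function(ens) {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  ca <- .atom_rows(top, "CA")
  if (length(ca) != length(unique(top$resid)))
    stop("CA atoms missing for some residues")
  M <- cpp_min_dist_map(coords(ens)[ca, , , drop = FALSE])
  structure(list(matrix = M, statistic = "min_ca_distance_A"),
            class = "ContactMap")
}

# per-frame backbone atom coordinate extractor: list of L x 3 matrices
.bb_coords <- function(ens, frame) {
  top <- topology(ens)
  X <- coords(ens)[, , frame, drop = TRUE]
  L <- length(unique(top$resid))
  get <- function(name) {
    M <- matrix(NA_real_, L, 3)
    rows <- which(top$atom == name)
    M[top$resid[rows], ] <- X[rows, , drop = FALSE]
    M
  }
  list(N = get("N"), H = get("H"), CA = get("CA"), C = get("C"),
       O = get("O"))
}

#' Backbone hydrogen-bond occupancy map
#'
#' Geometric criterion: donor N to acceptor O distance <= d_cut and
#' H-N-O angle <= angle_cut (the GROMACS hbond defaults). Per residue
#' pair, the fraction of frames with at least one bond in either
#' direction; pairs closer than 2 residues are excluded.
#'
#' @param ens a \linkS4class{ConformerEnsemble} with amide hydrogens.
#' @param d_cut donor-acceptor cutoff, Angstrom.
#' @param angle_cut H-donor-acceptor cutoff, degrees.
#' @return list of class "ContactMap" with `matrix` of occupancies in
#'   [0, 1] and `statistic = "hbond_occupancy"`.
#' @export
hbondMap <- function(ens, d_cut = 3.5, angle_cut = 30) {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  if (!any(top$atom == "H"))
    stop("topology has no amide hydrogens; regenerate with hydrogens present")
  L <- length(unique(top$resid))
  nf <- nFrames(ens)
  occ <- matrix(0, L, L)
  cosmax <- cos(angle_cut * pi / 180)
  for (f in seq_len(nf)) {
    bb <- .bb_coords(ens, f)
    dNO <- .cross_dist(bb$N, bb$O)
    u <- bb$H - bb$N
    ulen <- sqrt(rowSums(u^2))
    bond <- matrix(FALSE, L, L)
    for (i in seq_len(L)) {
      if (is.na(ulen[i])) next # Pro: no donor
      v <- sweep(bb$O, 2, bb$N[i, ])
      cosang <- (v %*% u[i, ]) / (sqrt(rowSums(v^2)) * ulen[i])
      bond[i, ] <- dNO[i, ] <= d_cut & cosang >= cosmax
    }
    bond[abs(row(bond) - col(bond)) < 2] <- FALSE
    occ <- occ + (bond | t(bond))
  }
  structure(list(matrix = occ / nf, statistic = "hbond_occupancy"),
            class = "ContactMap")
}

.cross_dist <- function(A, B) {
  # rows of A vs rows of B euclidean distances
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# Kabsch-Sander electrostatic H-bond energies, kcal/mol: acceptor CO of
# residue i, donor NH of residue j. E = 27.888 (1/rON + 1/rCH - 1/rOH -
# 1/rCN); bond if E < -0.5. Pairs with |i-j| < 2 excluded; Pro donates
# nothing.
.ks_hbonds <- function(bb, L) {
  E <- matrix(Inf, L, L)
  rON <- .cross_dist(bb$O, bb$N)
  rCN <- .cross_dist(bb$C, bb$N)
  okH <- !is.na(bb$H[, 1])
  rOH <- .cross_dist(bb$O, bb$H[ifelse(okH, seq_len(L), 1), , drop = FALSE])
  rCH <- .cross_dist(bb$C, bb$H[ifelse(okH, seq_len(L), 1), , drop = FALSE])
  Em <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  Em[, !okH] <- Inf
  Em[abs(row(Em) - col(Em)) < 2] <- Inf
  A <- Em < -0.5
  A
}

.ss_classes <- c("helix", "strand", "turn", "bend", "coil")

# one frame of Kabsch-Sander-style assignment, priority
# helix > strand > turn > bend > coil
.assign_ss_frame <- function(bb, L) {
  A <- .ks_hbonds(bb, L) # A[i, j]: CO(i) ... HN(j)
  ss <- rep("coil", L)
  turn4 <- function(i) i + 4 <= L && A[i, i + 4]
  turn3 <- function(i) i + 3 <= L && A[i, i + 3]
  # helix: two consecutive i -> i+4 turns mark residues i+1 .. i+4
  is_helix <- rep(FALSE, L)
  for (i in seq_len(L - 5))
    if (turn4(i) && turn4(i + 1)) is_helix[(i + 1):(i + 4)] <- TRUE
  # bridges (|i - j| >= 3): parallel / antiparallel patterns
  is_strand <- rep(FALSE, L)
  for (i in 2:(L - 1)) for (j in 2:(L - 1)) {
    if (abs(i - j) < 3 || j <= i) next
    par <- (A[i - 1, j] && A[j, i + 1]) || (A[j - 1, i] && A[i, j + 1])
    anti <- (A[i, j] && A[j, i]) ||
      (i - 1 >= 1 && j + 1 <= L && j - 1 >= 1 && i + 1 <= L &&
         A[i - 1, j + 1] && A[j - 1, i + 1])
    if (par || anti) { is_strand[i] <- TRUE; is_strand[j] <- TRUE }
  }
  # turns: isolated 3- or 4-turns cover the bracketed residues
  is_turn <- rep(FALSE, L)
  for (i in seq_len(L)) {
    if (turn3(i)) is_turn[(i + 1):(i + 2)] <- TRUE
    if (turn4(i)) is_turn[(i + 1):(i + 3)] <- TRUE
  }
  # bend: CA direction change over (i-2, i, i+2) above 70 degrees
  is_bend <- rep(FALSE, L)
  for (i in 3:(L - 2)) {
    u <- bb$CA[i, ] - bb$CA[i - 2, ]
    v <- bb$CA[i + 2, ] - bb$CA[i, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi > 70) is_bend[i] <- TRUE
  }
  ss[is_bend] <- "bend"
  ss[is_turn] <- "turn"
  ss[is_strand] <- "strand"
  ss[is_helix] <- "helix"
  ss
}

#' Secondary-structure assignment (Kabsch-Sander criteria, 5 classes)
#'
#' Hydrogen bonds by the Kabsch-Sander electrostatic energy
#' E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol with bond at
#' E < -0.5. Helix from runs of two consecutive i -> i+4 bonds, strand
#' from parallel/antiparallel bridge patterns, turn from isolated
#' i -> i+3 / i -> i+4 bonds, bend from a > 70 degree CA direction change,
#' else coil; priority helix > strand > turn > bend. Richer DSSP classes
#' (3-10/pi helices, isolated bridges) are deliberately collapsed into
#' this 5-class scheme.
#'
#' @param ens a \linkS4class{ConformerEnsemble} with backbone N, H, CA, C,
#'   O atoms.
#' @param part optional \linkS4class{RgPartition} for per-group fractions.
#' @return list of class "SsAssignment": `classes` (residues x frames
#'   character matrix), `probabilities` (residues x 5), and when `part`
#'   is given `group_fractions` (groups x 5).
#' @export
assignSecondaryStructure <- function(ens, part = NULL) {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  L <- length(unique(top$resid))
  need <- c("N", "CA", "C", "O")
  for (nm in need) {
    have <- unique(top$resid[top$atom == nm])
    miss <- setdiff(seq_len(L), have)
    if (length(miss))
      stop("backbone atom ", nm, " missing for residue ", miss[1])
  }
  nf <- nFrames(ens)
  cls <- matrix("coil", L, nf)
  for (f in seq_len(nf))
    cls[, f] <- .assign_ss_frame(.bb_coords(ens, f), L)
  probs <- t(apply(cls, 1, function(x)
    table(factor(x, levels = .ss_classes)) / nf))
  out <- list(classes = cls, probabilities = probs)
  if (!is.null(part)) {
    labs <- groupLabels(part)
    gf <- t(vapply(labs, function(l) {
      sel <- groupIndex(part, l)@frames + 1L
      as.numeric(table(factor(cls[, sel], levels = .ss_classes)) /
                   (L * length(sel)))
    }, numeric(5)))
    dimnames(gf) <- list(labs, .ss_classes)
    out$group_fractions <- gf
  }
  class(out) <- "SsAssignment"
  out
}

#' Ramachandran histogram and region fractions
#'
#' Pools (phi, psi) over all residues with both dihedrals defined into a
#' 5-degree 2D histogram; fractions are counts inside each named rectangle
#' over the total.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param regions named list of c(phi_min, phi_max, psi_min, psi_max)
#'   rectangles in degrees. Defaults cover the alphaR, beta, PPII and
#'   alphaL basins; reported fractions always state their regions.
#' @param bin_deg histogram bin width, degrees.
#' @return list with `histogram` (72 x 72 counts by default), `breaks`,
#'   `fractions` (named, one per region), `n` (dihedral pairs counted).
#' @export
ramachandran <- function(ens, regions = ramachandranRegions(),
                         bin_deg = 5) {
  stopifnot(is(ens, "ConformerEnsemble"))
  di <- backboneDihedrals(ens)
  ok <- !is.na(di$phi) & !is.na(di$psi)
  phi <- di$phi[ok]; psi <- di$psi[ok]
  breaks <- seq(-180, 180, by = bin_deg)
  hx <- cut(phi, breaks, include.lowest = TRUE)
  hy <- cut(psi, breaks, include.lowest = TRUE)
  H <- table(hx, hy)
  n <- length(phi)
  fr <- vapply(regions, function(r)
    sum(phi >= r[1] & phi <= r[2] & psi >= r[3] & psi <= r[4]) / n, 0.0)
  list(histogram = unclass(H), breaks = breaks, fractions = fr, n = n)
}

#' Default Ramachandran basin rectangles
#'
#' alphaR [-100,-30] x [-67,-7], beta [-180,-90] x [90,180],
#' PPII [-90,-20] x [120,180], alphaL [30,100] x [7,67], degrees.
#'
#' @return named list of c(phi_min, phi_max, psi_min, psi_max).
#' @export
ramachandranRegions <- function() {
  list(alphaR = c(-100, -30, -67, -7), beta = c(-180, -90, 90, 180),
       PPII = c(-90, -20, 120, 180), alphaL = c(30, 100, 7, 67))
}

#' Karplus coefficients for backbone scalar couplings
#'
#' 3J(HN-HA) = A cos^2(phi + offset_phi) + B cos(phi + offset_phi) + C and
#' 2J(N-CA) = A' cos^2(psi + offset_psi) + B' cos(psi + offset_psi) + C',
#' evaluated literally on the backbone dihedrals; both offsets default to
#' zero and are configurable (conventional 3J(HN-HA) relations use
#' theta = phi - 60 degrees).
#'
#' @param A,B,C phi-coupling coefficients, Hz.
#' @param Ap,Bp,Cp psi-coupling coefficients, Hz.
#' @param offset_phi,offset_psi angle offsets, degrees.
#' @return list of class "KarplusParams".
#' @export
karplusParams <- function(A = 6.4, B = -1.4, C = 1.9, Ap = 2.0, Bp = -0.5,
                          Cp = 0.5, offset_phi = 0, offset_psi = 0) {
  structure(list(A = A, B = B, C = C, Ap = Ap, Bp = Bp, Cp = Cp,
                 offset_phi = offset_phi, offset_psi = offset_psi),
            class = "KarplusParams")
}

#' Evaluate the Karplus equations at given angles
#' @param angle_deg dihedral angle(s), degrees.
#' @param kp a KarplusParams.
#' @param which "phi" (3J) or "psi" (2J).
#' @return coupling in Hz.
#' @export
karplusJ <- function(angle_deg, kp = karplusParams(),
                     which = c("phi", "psi")) {
  which <- match.arg(which)
  if (which == "phi") {
    cth <- cos((angle_deg + kp$offset_phi) * pi / 180)
    kp$A * cth^2 + kp$B * cth + kp$C
  } else {
    cth <- cos((angle_deg + kp$offset_psi) * pi / 180)
    kp$Ap * cth^2 + kp$Bp * cth + kp$Cp
  }
}

#' Ensemble J-couplings per residue and Rg group
#'
#' Per-frame couplings from the Karplus equations, then mean and SD per
#' residue within each group. Residues lacking the relevant dihedral
#' (first residue for phi, last for psi) are excluded and reported.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param kp a KarplusParams.
#' @param part optional \linkS4class{RgPartition}; absent means one group
#'   "all".
#' @return data.frame with group, residue, coupling ("J3_phi"/"J2_psi"),
#'   mean, sd.
#' @export
jCouplings <- function(ens, kp = karplusParams(), part = NULL) {
  stopifnot(is(ens, "ConformerEnsemble"))
  di <- backboneDihedrals(ens)
  J3 <- karplusJ(di$phi, kp, "phi") # residues x frames, NA row 1
  J2 <- karplusJ(di$psi, kp, "psi")
  groups <- if (is.null(part)) list(all = seq_len(nFrames(ens)))
            else {
              g <- lapply(groupLabels(part), function(l)
                groupIndex(part, l)@frames + 1L)
              names(g) <- groupLabels(part)
              g
            }
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (mat in c("J3_phi", "J2_psi")) {
      M <- if (mat == "J3_phi") J3 else J2
      mu <- rowMeans(M[, sel, drop = FALSE])
      sdv <- apply(M[, sel, drop = FALSE], 1, stats::sd)
      sdv[is.na(sdv) & !is.na(mu)] <- 0 # single-frame groups
      ok <- !is.na(mu)
      rows[[paste(g, mat)]] <- data.frame(
        group = g, residue = which(ok), coupling = mat,
        mean = mu[ok], sd = sdv[ok])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a ContactMap as a dense TSV matrix
#' @param cm a ContactMap.
#' @param path output file.
#' @export
writeContactMap <- function(cm, path) {
  stopifnot(inherits(cm, "ContactMap"))
  utils::write.table(cm$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
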
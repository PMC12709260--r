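#' Feature series for time-structure analysis
#'
#' Deterministic per-frame feature vectors with replica boundaries carried
#' through so lagged pairs never straddle replicas.
#'
#' "dihedral-sincos": sin and cos of every defined backbone dihedral (phi
#' for residues 2..L, psi for 1..L-1), 4(L-1) features. "ca-distances":
#' CA-CA distances of all pairs with |i-j| >= 2.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param scheme "dihedral-sincos" or "ca-distances".
#' @return list of class "FeatureSeries": `X` (frames x features),
#'   `replica`, `scheme`.
#' @export
featurize <- function(ens, scheme = c("dihedral-sincos", "ca-distances")) {
  stopifnot(is(ens, "ConformerEnsemble"))
  scheme <- match.arg(scheme)
  if (scheme == "dihedral-sincos") {
    di <- backboneDihedrals(ens)
    L <- nrow(di$phi)
    ang <- rbind(di$phi[-1, , drop = FALSE], di$psi[-L, , drop = FALSE])
    rad <- ang * pi / 180
    X <- t(rbind(sin(rad), cos(rad))) # frames x 4(L-1)
  } else {
    top <- topology(ens)
    ca <- .atom_rows(top, "CA")
    L <- length(ca)
    pairs <- which(upper.tri(matrix(0, L, L)) &
                     abs(row(matrix(0, L, L)) - col(matrix(0, L, L))) >= 2,
                   arr.ind = TRUE)
    C <- coords(ens)
    X <- t(vapply(seq_len(nFrames(ens)), function(f) {
      P <- C[ca, , f, drop = TRUE]
      sqrt(rowSums((P[pairs[, 1], , drop = FALSE] -
                      P[pairs[, 2], , drop = FALSE])^2))
    }, numeric(nrow(pairs))))
  }
  structure(list(X = X, replica = frameMeta(ens)$replica, scheme = scheme),
            class = "FeatureSeries")
}

#' Time-lagged independent component analysis
#'
#' Mean-free instantaneous covariance C0 and symmetrized lagged covariance
#' C_tau = (C(tau) + C(tau)')/2 over all lagged pairs that stay within one
#' replica, then the generalized eigenproblem C_tau v = lambda (C0 + eps I)
#' v via a Cholesky whitening. The symmetrized estimator keeps eigenvalues
#' real and bounded by 1 up to sampling noise; eigenvectors come back
#' C0-orthonormal and eigenvalues sorted descending.
#'
#' @param fs a FeatureSeries (or plain matrix, treated as one replica).
#' @param tau lag in frames.
#' @param epsilon ridge added to C0.
#' @return list of class "TicaModel": `mean`, `C0`, `Ct`, `eigenvalues`,
#'   `eigenvectors` (columns), `projections` (frames x components),
#'   `tau`.
#' @export
fitTica <- function(fs, tau = 100L, epsilon = 1e-8) {
  if (is.matrix(fs))
    fs <- structure(list(X = fs, replica = rep(1L, nrow(fs)),
                         scheme = "matrix"), class = "FeatureSeries")
  stopifnot(inherits(fs, "FeatureSeries"))
  tau <- as.integer(tau)
  X <- fs$X
  reps <- unique(fs$replica)
  shortest <- min(table(fs$replica))
  if (tau < 0L || tau >= shortest)
    stop("tau (", tau, ") must be shorter than the shortest replica (",
         shortest, " frames)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (any(apply(Xc, 2, stats::var) == 0))
    stop("zero-variance feature; remove constant columns")
  i0 <- it <- integer(0)
  for (r in reps) {
    rows <- which(fs$replica == r)
    n <- length(rows)
    if (n > tau) {
      i0 <- c(i0, rows[seq_len(n - tau)])
      it <- c(it, rows[seq_len(n - tau) + tau])
    }
  }
  npair <- length(i0)
  C0 <- (crossprod(Xc[i0, , drop = FALSE]) +
           crossprod(Xc[it, , drop = FALSE])) / (2 * npair)
  Ct <- crossprod(Xc[i0, , drop = FALSE], Xc[it, , drop = FALSE]) / npair
  Ct <- (Ct + t(Ct)) / 2
  C0r <- C0 + diag(epsilon, ncol(C0))
  R <- chol(C0r) # C0r = R'R
  Ri <- backsolve(R, diag(ncol(C0r)))
  Ms <- t(Ri) %*% Ct %*% Ri # R^-T Ct R^-1
  Ms <- (Ms + t(Ms)) / 2
  e <- eigen(Ms, symmetric = TRUE)
  V <- Ri %*% e$vectors
  structure(list(mean = mu, C0 = C0, Ct = Ct, eigenvalues = e$values,
                 eigenvectors = V, projections = Xc %*% V, tau = tau),
            class = "TicaModel")
}

#' Free-energy surface from two projections
#'
#' 2D histogram density rho; F = -ln(rho / rho_max) in kBT. Empty bins are
#' NA (undefined), never infinite; the minimum over occupied bins is 0 by
#' construction.
#'
#' @param x,y projection coordinates.
#' @param bins bins per axis.
#' @return list with `x_mid`, `y_mid`, `F` (bins x bins, kBT), `counts`.
#' @export
freeEnergySurface <- function(x, y, bins = 60L) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  bx <- seq(min(x), max(x), length.out = bins + 1L)
  by <- seq(min(y), max(y), length.out = bins + 1L)
  ix <- pmin(findInterval(x, bx, all.inside = TRUE), bins)
  iy <- pmin(findInterval(y, by, all.inside = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  Fmat <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  Fmat[occ] <- -log(counts[occ] / max(counts))
  list(x_mid = (bx[-1] + bx[-length(bx)]) / 2,
       y_mid = (by[-1] + by[-length(by)]) / 2, F = Fmat, counts = counts)
}

#' Observable-colored landscape: per-bin mean of a frame property
#'
#' @param x,y projection coordinates.
#' @param values per-frame observable (e.g. total SASA), same length.
#' @param bins bins per axis.
#' @return list with `x_mid`, `y_mid`, `mean` (NA in empty bins).
#' @export
sasaLandscape <- function(x, y, values, bins = 60L) {
  if (length(values) != length(x))
    stop("values must align with the projections (one per frame)")
  fes <- freeEnergySurface(x, y, bins)
  bx <- c(fes$x_mid[1] - diff(fes$x_mid[1:2]) / 2,
          fes$x_mid + diff(fes$x_mid[1:2]) / 2)
  ix <- pmin(findInterval(x, bx, all.inside = TRUE), bins)
  by <- c(fes$y_mid[1] - diff(fes$y_mid[1:2]) / 2,
          fes$y_mid + diff(fes$y_mid[1:2]) / 2)
  iy <- pmin(findInterval(y, by, all.inside = TRUE), bins)
  sums <- matrix(0, bins, bins)
  for (k in seq_along(ix))
    sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + values[k]
  M <- matrix(NA_real_, bins, bins)
  occ <- fes$counts > 0
  M[occ] <- sums[occ] / fes$counts[occ]
  list(x_mid = fes$x_mid, y_mid = fes$y_mid, mean = M)
}

#' GROMOS (Daura) conformational clustering
#'
#' Pairwise RMSD after optimal superposition over the selection; the frame
#' with the most neighbours within the cutoff seeds a cluster, it and its
#' neighbours are removed, and the procedure iterates. Ties go to the
#' lowest frame index. O(n^2) in frames: ensembles larger than
#' `max_frames` are subsampled with a recorded stride.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param cutoff_nm neighbour cutoff in nm (default 0.9).
#' @param selection atom-name filter for the RMSD (default "CA").
#' @param max_frames frame cap before stride subsampling.
#' @return list of class "ClusterResult": `cluster` (id per analysed
#'   frame), `frames` (1-based analysed frame numbers), `centers` (frame
#'   per cluster), `populations` (fractions, sum 1), `stride`.
#' @export
gromosCluster <- function(ens, cutoff_nm = 0.9, selection = "CA",
                          max_frames = 20000L) {
  stopifnot(is(ens, "ConformerEnsemble"))
  nf <- nFrames(ens)
  stride <- max(1L, ceiling(nf / max_frames))
  use <- seq(1L, nf, by = stride)
  top <- topology(ens)
  rows <- if (identical(selection, "all")) seq_len(nrow(top))
          else .atom_rows(top, selection)
  if (!length(rows)) stop("selection '", selection, "' matches no atoms")
  M <- cpp_rmsd_matrix(coords(ens)[, , use, drop = FALSE], rows - 1L) / 10
  n <- length(use)
  alive <- rep(TRUE, n)
  cluster <- integer(n)
  centers <- integer(0)
  adj <- M <= cutoff_nm
  cid <- 0L
  while (any(alive)) {
    cid <- cid + 1L
    counts <- colSums(adj[alive, alive, drop = FALSE])
    cand <- which(alive)[which.max(counts)] # which.max: lowest index wins
    members <- which(alive & adj[cand, ])
    cluster[members] <- cid
    centers <- c(centers, use[cand])
    alive[members] <- FALSE
  }
  pops <- as.numeric(table(factor(cluster, levels = seq_len(cid))) / n)
  structure(list(cluster = cluster, frames = use, centers = centers,
                 populations = pops, stride = stride,
                 cutoff_nm = cutoff_nm), class = "ClusterResult")
}
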
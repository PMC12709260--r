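#' Default momentum-transfer grid
#'
#' 100 log-spaced points over 0.0078-0.495 1/Angstrom, mirroring a typical
#' re-binned solution-scattering measurement range.
#'
#' @param n number of points.
#' @param qmin,qmax grid limits, 1/Angstrom.
#' @return numeric q grid.
#' @export
defaultQGrid <- function(n = 100L, qmin = 0.0078, qmax = 0.495) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# Effective per-atom form factors on a q grid, natoms x nq.
# Reduced topologies (backbone + CB) absorb the missing side-chain electrons
# into CB (into CA for Gly): the carbon form factor and dummy-atom volume are
# scaled so f(0) picks up the residue's missing electron count. Terminal H
# (N-terminus) and OH (C-terminus) are added to the first N and last C.
# f_eff = f(q) - rho_s V exp(-q^2 V^(2/3) / (4 pi)); vacuum drops the
# excluded-solvent term.
.effective_form_factors <- function(top, q, fft = formFactorTable(),
                                    vacuum = FALSE) {
  n <- nrow(top)
  known <- fft$coef$element
  bad <- which(!(top$element %in% known))
  if (length(bad))
    stop("no form-factor entry for atom ", top$atom[bad[1]], " (element '",
         top$element[bad[1]], "', residue ", top$resid[bad[1]], ")")
  fbase <- sapply(known, .cromer_mann_f, q = q, tab = fft)
  if (is.null(dim(fbase))) fbase <- matrix(fbase, nrow = 1)
  colnames(fbase) <- known
  vols <- stats::setNames(fft$coef$volume_A3, known)
  f <- t(fbase[, top$element, drop = FALSE]) # natoms x nq
  V <- unname(vols[top$element])

  reduced <- all(top$atom %in% c("N", "H", "CA", "CB", "C", "O")) &&
    all(top$resname %in% .aa_composition$code)
  if (reduced) {
    for (i in unique(top$resid)) {
      rows <- which(top$resid == i)
      code <- top$resname[rows[1]]
      modeled <- 7 + 6 + 6 + 8 +
        (if (any(top$atom[rows] == "H")) 1 else 0) +
        (if (any(top$atom[rows] == "CB")) 6 else 0)
      missing <- .residue_electrons(code) - modeled
      carrier <- rows[top$atom[rows] == "CB"]
      if (!length(carrier)) carrier <- rows[top$atom[rows] == "CA"]
      scale <- (6 + missing) / 6
      f[carrier, ] <- f[carrier, ] * scale
      V[carrier] <- V[carrier] * scale
    }
    first_n <- which(top$resid == min(top$resid) & top$atom == "N")[1]
    last_c <- rev(which(top$resid == max(top$resid) & top$atom == "C"))[1]
    f[first_n, ] <- f[first_n, ] + fbase[, "H"]
    V[first_n] <- V[first_n] + vols["H"]
    f[last_c, ] <- f[last_c, ] + fbase[, "O"] + fbase[, "H"]
    V[last_c] <- V[last_c] + vols["O"] + vols["H"]
  }
  if (!vacuum) {
    expo <- exp(-outer(V^(2 / 3) / (4 * pi), q^2)) # natoms x nq
    f <- f - fft$solvent_density * V * expo
  }
  f
}

#' Debye forward scattering profile of one frame
#'
#' I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij)/(q r_ij) with effective form
#' factors f_eff = f_CM(q) - rho_s V exp(-q^2 V^(2/3)/(4 pi)) (zero
#' hydration-shell contrast; `vacuum = TRUE` drops the excluded-solvent
#' term). The q -> 0 sinc limit is handled analytically.
#'
#' @param x a \linkS4class{ConformerEnsemble} (its `frame`-th frame is
#'   used) or a natoms x 3 coordinate matrix with `feff` supplied.
#' @param frame frame number when `x` is an ensemble.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param fft form-factor table, see \code{\link{formFactorTable}}.
#' @param vacuum disable the excluded-solvent term.
#' @param feff optional precomputed natoms x nq effective form factors
#'   (overrides `fft`; used for closed-form tests with dummy scatterers).
#' @return a \linkS4class{ScatteringProfile}.
#' @export
debyeProfile <- function(x, frame = 1L, q = defaultQGrid(),
                         fft = formFactorTable(), vacuum = FALSE,
                         feff = NULL) {
  if (is(x, "ConformerEnsemble")) {
    X <- coords(x)[, , frame, drop = TRUE]
    if (is.null(feff))
      feff <- .effective_form_factors(topology(x), q, fft, vacuum)
  } else {
    X <- as.matrix(x)
    if (is.null(feff)) stop("feff required for bare coordinate input")
  }
  I <- as.numeric(cpp_debye(X, feff, q))
  new("ScatteringProfile", q = q, I = I, sigma = NA_real_,
      rgMeta = NA_real_)
}

#' Average scattering over frames or profiles
#'
#' Unweighted mean intensity per q point: over a list of
#' \linkS4class{ScatteringProfile}s sharing one grid, or computed directly
#' from an ensemble's frames.
#'
#' @param x list of profiles, or a \linkS4class{ConformerEnsemble}.
#' @param q,fft,vacuum forward-model settings when `x` is an ensemble.
#' @param method "histogram" accumulates type-pair distance histograms
#'   (bin width `dr`) and transforms once -- orders of magnitude faster on
#'   large ensembles, accurate to about 1e-4 relative; "exact" runs the
#'   full Debye sum per frame.
#' @param dr histogram bin width, Angstrom.
#' @return a \linkS4class{ScatteringProfile}.
#' @export
ensembleAverage <- function(x, q = defaultQGrid(), fft = formFactorTable(),
                            vacuum = FALSE, method = c("histogram", "exact"),
                            dr = 0.1) {
  method <- match.arg(method)
  if (is(x, "ConformerEnsemble")) {
    feff <- .effective_form_factors(topology(x), q, fft, vacuum)
    if (method == "histogram") {
      I <- .debye_groups(coords(x), feff, q,
                         list(seq_len(nFrames(x))), dr)[, 1]
    } else {
      I <- rowMeans(cpp_debye_ensemble(coords(x), feff, q))
    }
    return(new("ScatteringProfile", q = q, I = I,
               sigma = NA_real_, rgMeta = NA_real_))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  q0 <- x[[1]]@q
  for (i in seq_along(x))
    if (!isTRUE(all.equal(x[[i]]@q, q0)))
      stop("profile ", i, " is on a different q grid")
  I <- rowMeans(vapply(x, function(sp) sp@I, numeric(length(q0))))
  new("ScatteringProfile", q = q0, I = I, sigma = NA_real_,
      rgMeta = NA_real_)
}

#' Per-group average scattering profiles
#'
#' @param ens the concatenated \linkS4class{ConformerEnsemble}.
#' @param part an \linkS4class{RgPartition} over the same frames.
#' @param q,fft,vacuum forward-model settings.
#' @param dr distance-histogram bin width (see
#'   \code{\link{ensembleAverage}}), Angstrom.
#' @return named list of \linkS4class{ScatteringProfile}s, one per Rg
#'   group, plus "all" for the full ensemble.
#' @export
groupProfiles <- function(ens, part, q = defaultQGrid(),
                          fft = formFactorTable(), vacuum = FALSE,
                          dr = 0.1) {
  stopifnot(is(ens, "ConformerEnsemble"), is(part, "RgPartition"))
  feff <- .effective_form_factors(topology(ens), q, fft, vacuum)
  labs <- groupLabels(part)
  sels <- lapply(labs, function(l) groupIndex(part, l)@frames + 1L)
  M <- .debye_groups(coords(ens), feff, q, sels, dr)
  out <- lapply(seq_along(labs), function(i)
    new("ScatteringProfile", q = q, I = M[, i], sigma = NA_real_,
        rgMeta = mean(rgValues(part)[sels[[i]]])))
  names(out) <- as.character(labs)
  wts <- lengths(sels) / sum(lengths(sels))
  out$all <- new("ScatteringProfile", q = q,
                 I = as.numeric(M %*% wts), sigma = NA_real_,
                 rgMeta = mean(rgValues(part)))
  out
}

# Ensemble/group Debye averages through per-type-pair distance histograms
# (bin width dr, Angstrom); atoms sharing one effective form-factor row
# form a type. Binning error is O((q dr)^2 / 24), about 1e-4 relative at
# the default grid.
.debye_groups <- function(coords, feff, q, frame_sets, dr = 0.1) {
  key <- apply(round(feff, 10), 1, paste, collapse = ",")
  type_id <- as.integer(factor(key, levels = unique(key))) - 1L
  f_types <- feff[!duplicated(key), , drop = FALSE]
  if (is.null(dim(f_types))) f_types <- matrix(f_types, nrow = 1)
  cpp_debye_hist_groups(coords, type_id, nrow(f_types), f_types, q,
                        frame_sets, dr)
}

#' Guinier radius of gyration
#'
#' Iterative linear fit of ln I against q^2 restricted to q Rg < qmax_rg:
#' fit, re-restrict with the fitted Rg, refit until the range is stable.
#' Rg = sqrt(-3 slope).
#'
#' @param sp a \linkS4class{ScatteringProfile}.
#' @param qmax_rg upper limit of q Rg for the fit window (default 1.3).
#' @param min_points minimum points in the window.
#' @return list with rg (Angstrom), I0, q_range, n_points, r_squared.
#' @export
guinierRg <- function(sp, qmax_rg = 1.3, min_points = 5L) {
  stopifnot(is(sp, "ScatteringProfile"))
  ok <- sp@q > 0 & sp@I > 0
  q <- sp@q[ok]; I <- sp@I[ok]
  if (length(q) < min_points) stop("too few usable points for a Guinier fit")
  sel <- seq_len(max(min_points, min(10L, length(q))))
  rg <- NA_real_
  for (iter in 1:25) {
    fit <- stats::lm(log(I[sel]) ~ I(q[sel]^2))
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0)
      stop("non-negative Guinier slope; data are not Guinier-like")
    rg_new <- sqrt(-3 * slope)
    new_sel <- which(q * rg_new < qmax_rg)
    if (length(new_sel) < min_points)
      new_sel <- seq_len(min_points)
    if (!is.na(rg) && identical(new_sel, sel) ||
        (!is.na(rg) && abs(rg_new - rg) < 1e-10)) {
      sel <- new_sel; rg <- rg_new; break
    }
    sel <- new_sel; rg <- rg_new
  }
  fit <- stats::lm(log(I[sel]) ~ I(q[sel]^2))
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) stop("non-negative Guinier slope; data are not Guinier-like")
  list(rg = sqrt(-3 * slope), I0 = exp(stats::coef(fit)[[1]]),
       q_range = range(q[sel]), n_points = length(sel),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Dimensionless Kratky transform
#'
#' x = q Rg, y = (q Rg)^2 I(q)/I(0). I(0) defaults to the Guinier
#' extrapolation, falling back to the lowest-q intensity.
#'
#' @param sp a \linkS4class{ScatteringProfile}.
#' @param rg Rg in Angstrom (default: Guinier estimate).
#' @param I0 forward intensity (default: Guinier extrapolation).
#' @return data.frame with qrg and kratky columns.
#' @export
kratky <- function(sp, rg = NULL, I0 = NULL) {
  stopifnot(is(sp, "ScatteringProfile"))
  if (is.null(rg) || is.null(I0)) {
    g <- tryCatch(guinierRg(sp), error = function(e) NULL)
    if (is.null(rg)) rg <- if (!is.null(g)) g$rg else
      stop("rg not supplied and Guinier fit failed")
    if (is.null(I0)) I0 <- if (!is.null(g)) g$I0 else sp@I[1]
  }
  if (I0 <= 0) stop("I(0) must be positive")
  x <- sp@q * rg
  data.frame(qrg = x, kratky = x^2 * sp@I / I0)
}

#' Indirect-transform pair-distance distribution
#'
#' Expands P(r) in a sine basis vanishing at 0 and Dmax,
#' P(r) = sum_k a_k sin(k pi r / Dmax), and fits the coefficients to I(q)
#' by Tikhonov-regularized least squares (penalty alpha ||k^2 a||^2, so the
#' smoothest curve consistent with the data wins and alpha -> Inf drives
#' P -> 0). The design matrix is the numerically integrated Debye kernel
#' sin(qr)/(qr).
#'
#' @param sp a \linkS4class{ScatteringProfile}.
#' @param Dmax maximum intramolecular distance, Angstrom.
#' @param n_basis number of sine terms.
#' @param alpha regularization strength.
#' @param nonneg clip negative P(r) to zero after the transform.
#' @param n_r output grid size.
#' @param fit_constant also fit a flat intensity offset absorbing the
#'   point-atom self-scattering term (a delta at r = 0 that the sine basis
#'   cannot represent).
#' @return a \linkS4class{PrCurve}; the fit chi^2 (mean squared relative
#'   residual) is stored in the chi2 slot.
#' @export
prIndirect <- function(sp, Dmax, n_basis = 20L, alpha = 1e-6,
                       nonneg = TRUE, n_r = 201L, fit_constant = TRUE) {
  stopifnot(is(sp, "ScatteringProfile"), Dmax > 0)
  q <- sp@q; I <- sp@I
  r <- seq(0, Dmax, length.out = n_r)
  dr <- r[2] - r[1]
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  # A[i, k] = int_0^Dmax sin(k pi r/Dmax) sinc(q_i r) dr (trapezoid)
  wts <- rep(dr, n_r); wts[c(1, n_r)] <- dr / 2
  K <- outer(q, r, function(qq, rr) sinc(qq * rr)) # nq x nr
  B <- sapply(seq_len(n_basis), function(k) sin(k * pi * r / Dmax)) # nr x nb
  A <- K %*% (B * wts)
  if (fit_constant) A <- cbind(A, 1)
  scale <- max(abs(I))
  y <- I / scale
  pen <- (seq_len(n_basis))^2
  if (fit_constant) pen <- c(pen, 0) # the offset is not smoothed away
  D <- diag(pen, nrow = length(pen))
  M <- crossprod(A) + alpha * crossprod(D)
  a <- tryCatch(solve(M, crossprod(A, y)),
                error = function(e)
                  stop("singular normal equations; increase alpha"))
  P <- as.numeric(B %*% a[seq_len(n_basis)])
  if (nonneg) P <- pmax(P, 0)
  P[c(1, n_r)] <- 0
  Ihat <- as.numeric(A %*% a) * scale
  chi2 <- mean(((I - Ihat) / pmax(abs(Ihat), 1e-12 * scale))^2)
  new("PrCurve", r = r, P = P, Dmax = Dmax, chi2 = chi2)
}

#' Direct pair-distance distribution from coordinates
#'
#' Histogram of all interatomic distances weighted by f_i(0) f_j(0),
#' normalized to unit (trapezoid) area; the ensemble version averages
#' per-frame histograms. Serves as the model-free cross-check for
#' \code{\link{prIndirect}}.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param bin_width histogram bin width, Angstrom.
#' @param fft form-factor table for the f(0) weights.
#' @param frames optional frame subset (1-based).
#' @return a \linkS4class{PrCurve} with chi2 = NA.
#' @export
prDirect <- function(ens, bin_width = 0.5, fft = formFactorTable(),
                     frames = NULL) {
  stopifnot(is(ens, "ConformerEnsemble"))
  f0 <- .effective_form_factors(topology(ens), 0, fft, vacuum = TRUE)[, 1]
  X <- coords(ens)
  if (is.null(frames)) frames <- seq_len(nFrames(ens))
  dmax <- 0
  for (f in frames)
    dmax <- max(dmax, max(stats::dist(X[, , f, drop = TRUE])))
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  h <- numeric(length(breaks) - 1L)
  for (f in frames)
    h <- h + as.numeric(cpp_pair_hist(X[, , f, drop = TRUE], f0, breaks))
  h <- h / length(frames)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  r <- c(0, centers, breaks[length(breaks)])
  P <- c(0, h, 0)
  area <- sum(diff(r) * (P[-1] + P[-length(P)]) / 2)
  P <- P / area
  new("PrCurve", r = r, P = P, Dmax = breaks[length(breaks)],
      chi2 = NA_real_)
}

#' Chi-square agreement between experimental and simulated curves
#'
#' chi^2 = sum_i (E_i - S_i)^2 / S_i^2, the simulated-intensity-weighted
#' form (the denominator is the simulated point squared, not an
#' experimental sigma). With `scale = "fit"` a least-squares scale factor
#' on S minimizing this statistic is applied first and reported. For the
#' conventional uncertainty-weighted statistic see
#' \code{\link{chiSquareSigma}}.
#'
#' @param expt,sim \linkS4class{ScatteringProfile}s; `sim` is linearly
#'   interpolated onto the experimental grid when the grids differ (the
#'   result carries attribute `interpolated = TRUE`).
#' @param scale "fixed" (no scaling) or "fit".
#' @return numeric chi^2 with attributes `scale_factor` and `n`.
#' @export
chiSquare <- function(expt, sim, scale = c("fixed", "fit")) {
  scale <- match.arg(scale)
  stopifnot(is(expt, "ScatteringProfile"), is(sim, "ScatteringProfile"))
  interp <- !isTRUE(all.equal(expt@q, sim@q))
  S <- if (interp) stats::approx(sim@q, sim@I, xout = expt@q, rule = 2)$y
       else sim@I
  E <- expt@I
  c0 <- 1
  if (scale == "fit") {
    x <- E / S
    c0 <- sum(x^2) / sum(x) # argmin_c sum (E/(cS) - 1)^2
    S <- c0 * S
  }
  if (any(S == 0)) stop("simulated intensity is zero at some points")
  out <- sum((E - S)^2 / S^2)
  attr(out, "scale_factor") <- c0
  attr(out, "n") <- length(E)
  attr(out, "interpolated") <- interp
  out
}

#' Conventional uncertainty-weighted reduced chi-square
#'
#' chi^2_red = (1/N) sum_i ((E_i - S_i)/sigma_i)^2; requires experimental
#' uncertainties. Provided alongside \code{\link{chiSquare}} for
#' comparison with the literature convention.
#'
#' @param expt,sim \linkS4class{ScatteringProfile}s on one grid.
#' @return numeric reduced chi-square.
#' @export
chiSquareSigma <- function(expt, sim) {
  stopifnot(is(expt, "ScatteringProfile"), is(sim, "ScatteringProfile"))
  if (all(is.na(expt@sigma))) stop("experimental sigma required")
  S <- if (!isTRUE(all.equal(expt@q, sim@q)))
    stats::approx(sim@q, sim@I, xout = expt@q, rule = 2)$y else sim@I
  mean(((expt@I - S) / expt@sigma)^2)
}

#' Read / write 3-column ASCII scattering curves
#'
#' q (1/Angstrom), I, and optional sigma, whitespace-separated, '#'
#' comments — the common .dat layout.
#'
#' @param path file path.
#' @param sp a \linkS4class{ScatteringProfile} (writer).
#' @return reader: a \linkS4class{ScatteringProfile}.
#' @export
readScatteringCurve <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  sigma <- if (ncol(tab) >= 3) tab[[3]] else NA_real_
  new("ScatteringProfile", q = tab[[1]], I = tab[[2]], sigma = sigma,
      rgMeta = NA_real_)
}

#' @rdname readScatteringCurve
#' @export
writeScatteringCurve <- function(sp, path) {
  stopifnot(is(sp, "ScatteringProfile"))
  tab <- data.frame(q = sp@q, I = sp@I)
  if (!all(is.na(sp@sigma))) tab$sigma <- sp@sigma
  utils::write.table(format(tab, digits = 8, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
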
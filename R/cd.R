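#' Construct a CD spectrum object
#'
#' @param wavelength nm grid, strictly increasing.
#' @param signal values in `unit`.
#' @param unit "mdeg" or "delta_epsilon".
#' @param pathlength_cm,conc_g_per_L,mrw_da metadata needed for unit
#'   conversion (NA until known).
#' @return a \linkS4class{CdSpectrum}.
#' @export
cdSpectrum <- function(wavelength, signal, unit = "mdeg",
                       pathlength_cm = NA_real_, conc_g_per_L = NA_real_,
                       mrw_da = NA_real_) {
  new("CdSpectrum", wavelength = as.numeric(wavelength),
      signal = as.numeric(signal), unit = unit,
      meta = list(pathlength_cm = pathlength_cm,
                  conc_g_per_L = conc_g_per_L, mrw_da = mrw_da))
}

#' Convert measured millidegrees to molar circular dichroism
#'
#' Delta-epsilon (M^-1 cm^-1) = CD(mdeg) x MRW(Da) / (32980 x l(cm) x
#' c(g/L)), with the constant 32980 used exactly. The inverse,
#' \code{deltaEpsilonToMdeg}, makes the round trip an identity.
#'
#' @param s a \linkS4class{CdSpectrum} in mdeg with complete metadata
#'   (pathlength, concentration, MRW).
#' @return a \linkS4class{CdSpectrum} in delta_epsilon.
#' @export
mdegToDeltaEpsilon <- function(s) {
  stopifnot(is(s, "CdSpectrum"))
  if (s@unit != "mdeg") stop("input spectrum is not in mdeg")
  m <- s@meta
  missing <- names(m)[vapply(m, function(x) is.na(x) || x <= 0, TRUE)]
  if (length(missing))
    stop("conversion metadata missing or non-positive: ",
         paste(missing, collapse = ", "))
  de <- s@signal * m$mrw_da / (32980 * m$pathlength_cm * m$conc_g_per_L)
  new("CdSpectrum", wavelength = s@wavelength, signal = de,
      unit = "delta_epsilon", meta = m)
}

#' @rdname mdegToDeltaEpsilon
#' @export
deltaEpsilonToMdeg <- function(s) {
  stopifnot(is(s, "CdSpectrum"))
  if (s@unit != "delta_epsilon") stop("input spectrum is not in delta_epsilon")
  m <- s@meta
  mdeg <- s@signal * (32980 * m$pathlength_cm * m$conc_g_per_L) / m$mrw_da
  new("CdSpectrum", wavelength = s@wavelength, signal = mdeg,
      unit = "mdeg", meta = m)
}

#' Packaged reference basis spectra for CD prediction
#'
#' Per-residue delta-epsilon basis curves for helix, strand, turn and coil
#' on 180-260 nm. These are synthetic parametric curves (sums of Gaussian
#' bands at the canonical band positions); see the header of
#' `inst/extdata/cd_basis_synthetic.tsv` for the band table.
#'
#' @return data.frame with wavelength, helix, strand, turn, coil.
#' @export
cdBasisSpectra <- function() .read_extdata("cd_basis_synthetic.tsv")

# map the 5 secondary-structure classes onto the 4 basis classes
.ss_to_basis <- c(helix = "helix", strand = "strand", turn = "turn",
                  bend = "turn", coil = "coil")

#' Ensemble CD spectrum from secondary-structure fractions
#'
#' Per frame, spectrum = sum over classes of fraction x basis curve;
#' averaged over frames. By linearity this equals the ensemble-mean
#' fractions applied to the basis once, which is how it is computed.
#' Bend is pooled with turn for the 4-class basis.
#'
#' @param ss an "SsAssignment" from
#'   \code{\link{assignSecondaryStructure}}, or a named numeric vector of
#'   class fractions over (helix, strand, turn, coil) summing to 1.
#' @param basis basis table from \code{\link{cdBasisSpectra}}.
#' @return a \linkS4class{CdSpectrum} in delta_epsilon.
#' @export
ensembleCd <- function(ss, basis = cdBasisSpectra()) {
  classes <- c("helix", "strand", "turn", "coil")
  if (!all(classes %in% names(basis)))
    stop("basis must provide columns ", paste(classes, collapse = ", "))
  if (inherits(ss, "SsAssignment")) {
    cls <- .ss_to_basis[as.vector(ss$classes)]
    frac <- as.numeric(table(factor(cls, levels = classes)) / length(cls))
    names(frac) <- classes
  } else {
    frac <- ss[classes]
    if (abs(sum(frac) - 1) > 1e-6) stop("fractions must sum to 1")
  }
  sig <- as.matrix(basis[, classes]) %*% frac
  cdSpectrum(basis$wavelength, as.numeric(sig), unit = "delta_epsilon")
}

#' Decompose a CD spectrum onto the basis set
#'
#' Non-negative least squares of the delta-epsilon spectrum onto the basis
#' curves with the fractions constrained to sum to at most 1 (a slack
#' component absorbs the remainder). A simple basis-set decomposition — a
#' summary of secondary-structure content, not a substitute for dedicated
#' deconvolution services.
#'
#' @param s a \linkS4class{CdSpectrum} in delta_epsilon.
#' @param basis basis table from \code{\link{cdBasisSpectra}}.
#' @return list with `fractions` (helix, strand, turn, coil) and
#'   `residual` (root-mean-square misfit).
#' @export
decomposeCd <- function(s, basis = cdBasisSpectra()) {
  stopifnot(is(s, "CdSpectrum"))
  if (s@unit != "delta_epsilon")
    stop("decomposition requires delta_epsilon units; convert first")
  classes <- c("helix", "strand", "turn", "coil")
  B <- as.matrix(basis[, classes])
  y <- if (isTRUE(all.equal(s@wavelength, basis$wavelength))) s@signal
       else stats::approx(s@wavelength, s@signal,
                          xout = basis$wavelength, rule = 2)$y
  if (qr(B)$rank < ncol(B)) stop("degenerate basis")
  frac <- stats::setNames(.nnls_simplex(B, y), classes)
  resid <- sqrt(mean((as.numeric(B %*% frac) - y)^2))
  list(fractions = frac, residual = resid)
}

# Exact solver for min ||Bf - y||^2 with f >= 0 and sum(f) <= 1.
# With <= 4 components, enumerate every active set (which f are zero,
# whether the sum constraint binds), solve the KKT system for each, keep
# the best feasible candidate. Exact and immune to iteration limits.
.nnls_simplex <- function(B, y) {
  p <- ncol(B)
  best <- rep(0, p)
  best_rss <- sum(y^2) # all-zero candidate
  for (mask in seq_len(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    Bf <- B[, free, drop = FALSE]
    G <- crossprod(Bf)
    rhs <- crossprod(Bf, y)
    for (bind_sum in c(FALSE, TRUE)) {
      f_free <- if (!bind_sum) {
        tryCatch(solve(G, rhs), error = function(e) NULL)
      } else {
        one <- rep(1, length(free))
        K <- rbind(cbind(G, one), c(one, 0))
        sol <- tryCatch(solve(K, c(rhs, 1)), error = function(e) NULL)
        if (is.null(sol)) NULL else sol[seq_along(free)]
      }
      if (is.null(f_free) || any(f_free < -1e-12)) next
      if (!bind_sum && sum(f_free) > 1 + 1e-12) next
      f <- rep(0, p)
      f[free] <- pmax(f_free, 0)
      rss <- sum((as.numeric(B %*% f) - y)^2)
      if (rss < best_rss - 1e-15) { best_rss <- rss; best <- f }
    }
  }
  best
}

#' Read / write 2-column ASCII CD spectra
#'
#' Wavelength (nm) and signal; a `# unit:` header line records the unit.
#'
#' @param path file path.
#' @param s a \linkS4class{CdSpectrum} (writer).
#' @return reader: a \linkS4class{CdSpectrum}.
#' @export
readCdSpectrum <- function(path) {
  lines <- readLines(path)
  unit <- "mdeg"
  uh <- grep("^# unit:", lines, value = TRUE)
  if (length(uh)) unit <- trimws(sub("^# unit:", "", uh[1]))
  tab <- utils::read.table(text = lines, comment.char = "#")
  cdSpectrum(tab[[1]], tab[[2]], unit = unit)
}

#' @rdname readCdSpectrum
#' @export
writeCdSpectrum <- function(s, path) {
  stopifnot(is(s, "CdSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", s@unit), con)
  utils::write.table(data.frame(s@wavelength, s@signal), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
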
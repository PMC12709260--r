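#' @import methods
NULL

#' Peptide: a sequence with ionization flags and residue masses
#'
#' Holds a peptide sequence (one-letter codes), the ionization conventions
#' used throughout the package (charged termini, neutral histidine), average
#' residue masses in Da and the resulting molecular weight.
#'
#' @slot residues character vector of one-letter residue codes.
#' @slot terminiCharged logical; N-terminus +1e and C-terminus -1e when TRUE.
#' @slot hisNeutral logical; histidine carries 0e when TRUE, +1e otherwise.
#' @slot residueMasses numeric; per-residue free amino-acid masses (Da).
#' @slot molecularWeight numeric; peptide MW in Da (residue masses minus
#'   one water per peptide bond).
#' @exportClass Peptide
setClass("Peptide", representation(
  residues = "character",
  terminiCharged = "logical",
  hisNeutral = "logical",
  residueMasses = "numeric",
  molecularWeight = "numeric"
))

setValidity("Peptide", function(object) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (length(object@residues) < 2L)
    return("peptide must have at least 2 residues")
  bad <- which(!(object@residues %in% aa))
  if (length(bad))
    return(sprintf("unknown residue code '%s' at position %d",
                   object@residues[bad[1]], bad[1]))
  if (length(object@residueMasses) != length(object@residues))
    return("residueMasses must have one entry per residue")
  L <- length(object@residues)
  mw <- sum(object@residueMasses) - (L - 1) * 18.01528
  if (abs(mw - object@molecularWeight) > 1e-6)
    return("molecularWeight inconsistent with residue masses")
  TRUE
})

#' ConformerEnsemble: ordered coordinate frames over a shared topology
#'
#' @slot topology data.frame with columns atom, resid, resname, element,
#'   mass (Da); one row per atom, fixed across frames.
#' @slot coords numeric array natoms x 3 x nframes, Angstrom.
#' @slot frameMeta data.frame with columns replica, frame (index within
#'   replica, 0-based), time_ps (pseudo-time); one row per frame.
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble", representation(
  topology = "data.frame",
  coords = "array",
  frameMeta = "data.frame"
))

setValidity("ConformerEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be a natoms x 3 x nframes array")
  if (d[1] != nrow(object@topology))
    return("coords atom dimension does not match topology")
  if (d[3] != nrow(object@frameMeta))
    return("frameMeta must have one row per frame")
  need <- c("atom", "resid", "resname", "element", "mass")
  if (!all(need %in% names(object@topology)))
    return(paste("topology must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' FrameIndex: an ordered group of global frame numbers
#'
#' Frame numbers are 0-based in memory; index files on disk are written
#' 1-based (GROMACS convention).
#'
#' @slot name group label.
#' @slot frames strictly increasing 0-based frame numbers.
#' @exportClass FrameIndex
setClass("FrameIndex", representation(name = "character", frames = "integer"))

setValidity("FrameIndex", function(object) {
  f <- object@frames
  if (length(f) && (any(f < 0L) || is.unsorted(f, strictly = TRUE)))
    return("frames must be strictly increasing and non-negative")
  TRUE
})

#' RgPartition: per-frame Rg values and group assignment
#'
#' @slot rg numeric per-frame radius of gyration, Angstrom.
#' @slot binWidth numeric bin width, Angstrom.
#' @slot assignment integer bin-center label per frame.
#' @slot indices named list of \linkS4class{FrameIndex}, one per group.
#' @exportClass RgPartition
setClass("RgPartition", representation(
  rg = "numeric", binWidth = "numeric",
  assignment = "integer", indices = "list"
))

setValidity("RgPartition", function(object) {
  if (length(object@rg) != length(object@assignment))
    return("assignment must have one label per frame")
  n <- sum(vapply(object@indices, function(fi) length(fi@frames), 1L))
  if (n != length(object@rg))
    return("group indices must cover every frame exactly once")
  TRUE
})

#' ScatteringProfile: I(q) on a strictly increasing q grid
#'
#' @slot q momentum transfer, 1/Angstrom, strictly increasing, >= 0.
#' @slot I intensity, arbitrary units.
#' @slot sigma per-point uncertainty (NA when absent).
#' @slot rgMeta optional Rg annotation in Angstrom (NA when absent).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile", representation(
  q = "numeric", I = "numeric", sigma = "numeric", rgMeta = "numeric"
))

setValidity("ScatteringProfile", function(object) {
  if (any(object@q < 0) || is.unsorted(object@q, strictly = TRUE))
    return("q must be non-negative and strictly increasing")
  if (length(object@I) != length(object@q))
    return("I must match q in length")
  if (!all(is.finite(object@I)))
    return("intensities must be finite")
  s <- object@sigma
  if (length(s) && !all(is.na(s)) &&
      (length(s) != length(object@q) || any(s[!is.na(s)] <= 0)))
    return("sigma must be positive where present and match q in length")
  TRUE
})

#' PrCurve: pair-distance distribution on [0, Dmax]
#'
#' @slot r distance grid, Angstrom, from 0 to Dmax.
#' @slot P pair-distance density; vanishes at both endpoints.
#' @slot Dmax maximum intramolecular distance, Angstrom.
#' @slot chi2 fit quality of the indirect transform (NA for direct curves).
#' @exportClass PrCurve
setClass("PrCurve", representation(
  r = "numeric", P = "numeric", Dmax = "numeric", chi2 = "numeric"
))

setValidity("PrCurve", function(object) {
  if (length(object@r) != length(object@P))
    return("r and P must have equal length")
  if (abs(object@P[1]) > 1e-8 || abs(object@P[length(object@P)]) > 1e-8)
    return("P must vanish at r = 0 and r = Dmax")
  TRUE
})

#' CdSpectrum: a circular-dichroism spectrum with unit bookkeeping
#'
#' @slot wavelength nm grid, strictly increasing.
#' @slot signal values in the declared unit.
#' @slot unit "mdeg" or "delta_epsilon" (M^-1 cm^-1).
#' @slot meta list with pathlength_cm, conc_g_per_L, mrw_da (NA permitted
#'   until conversion is requested).
#' @exportClass CdSpectrum
setClass("CdSpectrum", representation(
  wavelength = "numeric", signal = "numeric", unit = "character",
  meta = "list"
))

setValidity("CdSpectrum", function(object) {
  if (is.unsorted(object@wavelength, strictly = TRUE))
    return("wavelength grid must be strictly increasing")
  if (length(object@signal) != length(object@wavelength))
    return("signal must match wavelength in length")
  if (!object@unit %in% c("mdeg", "delta_epsilon"))
    return("unit must be 'mdeg' or 'delta_epsilon'")
  TRUE
})
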
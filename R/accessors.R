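#' @describeIn nFrames frames in a ConformerEnsemble
#' @export
setMethod("nFrames", "ConformerEnsemble", function(x) dim(x@coords)[3])

#' @describeIn nResidues residues of a Peptide
#' @export
setMethod("nResidues", "Peptide", function(x) length(x@residues))

#' @describeIn nResidues residues of a ConformerEnsemble topology
#' @export
setMethod("nResidues", "ConformerEnsemble",
          function(x) length(unique(x@topology$resid)))

#' @describeIn peptideSequence sequence of a Peptide
#' @export
setMethod("peptideSequence", "Peptide",
          function(x) paste(x@residues, collapse = ""))

#' @describeIn molecularWeight MW of a Peptide
#' @export
setMethod("molecularWeight", "Peptide", function(x) x@molecularWeight)

#' @describeIn coords coordinates of a ConformerEnsemble
#' @export
setMethod("coords", "ConformerEnsemble", function(x) x@coords)

#' @describeIn topology topology of a ConformerEnsemble
#' @export
setMethod("topology", "ConformerEnsemble", function(x) x@topology)

#' @describeIn frameMeta frame metadata of a ConformerEnsemble
#' @export
setMethod("frameMeta", "ConformerEnsemble", function(x) x@frameMeta)

#' @describeIn rgValues Rg values of an RgPartition
#' @export
setMethod("rgValues", "RgPartition", function(x) x@rg)

#' @describeIn groupLabels labels of an RgPartition
#' @export
setMethod("groupLabels", "RgPartition",
          function(x) sort(as.integer(names(x@indices))))

#' @describeIn groupIndex group FrameIndex of an RgPartition
#' @export
setMethod("groupIndex", "RgPartition", function(x, label) {
  key <- as.character(as.integer(label))
  if (is.null(x@indices[[key]]))
    stop("no Rg group labelled ", label, " A in this partition")
  x@indices[[key]]
})

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide: %d residues, MW %.2f Da\n", length(object@residues),
              object@molecularWeight))
  cat(" ", peptideSequence(object), "\n")
  cat(sprintf("  termini %s, His %s\n",
              if (object@terminiCharged) "charged" else "neutral",
              if (object@hisNeutral) "neutral" else "protonated"))
})

setMethod("show", "ConformerEnsemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("ConformerEnsemble: %d atoms, %d residues, %d frames, %d replica(s)\n",
              d[1], nResidues(object), d[3],
              length(unique(object@frameMeta$replica))))
})

setMethod("show", "RgPartition", function(object) {
  labs <- groupLabels(object)
  cat(sprintf("RgPartition: %d frames in %d groups (bin width %.2f A)\n",
              length(object@rg), length(labs), object@binWidth))
  counts <- vapply(labs, function(l) length(groupIndex(object, l)@frames), 1L)
  cat("  groups:", paste(sprintf("%d A (%d)", labs, counts), collapse = ", "),
      "\n")
})

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d points, q in [%.4g, %.4g] 1/A%s\n",
              length(object@q), min(object@q), max(object@q),
              if (all(is.na(object@sigma))) "" else ", with uncertainties"))
})

setMethod("show", "PrCurve", function(object) {
  cat(sprintf("PrCurve: Dmax %.1f A, %d grid points, mode at %.1f A\n",
              object@Dmax, length(object@r), object@r[which.max(object@P)]))
})

setMethod("show", "CdSpectrum", function(object) {
  cat(sprintf("CdSpectrum [%s]: %d points, %g-%g nm\n", object@unit,
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength)))
})

setMethod("show", "FrameIndex", function(object) {
  cat(sprintf("FrameIndex '%s': %d frames\n", object@name,
              length(object@frames)))
})
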
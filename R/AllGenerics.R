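#' Number of frames in an ensemble-like object
#' @param x object with frames.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues
#' @param x a Peptide or ConformerEnsemble.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Peptide sequence as a single string
#' @param x a Peptide or ConformerEnsemble.
#' @return character scalar of one-letter codes.
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' Molecular weight in Da
#' @param x a Peptide.
#' @return numeric, Da.
#' @export
setGeneric("molecularWeight", function(x) standardGeneric("molecularWeight"))

#' Coordinates accessor
#' @param x a ConformerEnsemble.
#' @return natoms x 3 x nframes array, Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Topology accessor
#' @param x a ConformerEnsemble.
#' @return data.frame with atom, resid, resname, element, mass.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Frame metadata accessor
#' @param x a ConformerEnsemble.
#' @return data.frame with replica, frame, time_ps.
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' Per-frame radius of gyration values of a partition
#' @param x an RgPartition.
#' @return numeric vector, Angstrom.
#' @export
setGeneric("rgValues", function(x) standardGeneric("rgValues"))

#' Group labels of a partition
#' @param x an RgPartition.
#' @return sorted integer bin-center labels.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Frame index for one group of a partition
#' @param x an RgPartition.
#' @param label integer bin-center label.
#' @return a FrameIndex.
#' @export
setGeneric("groupIndex", function(x, label) standardGeneric("groupIndex"))
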
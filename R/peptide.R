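#' Load a peptide from a sequence string or FASTA file
#'
#' Builds a \linkS4class{Peptide} with average residue masses and the
#' ionization conventions used throughout: charged termini and neutral
#' histidine by default, matching a disordered peptide modelled at neutral
#' pH.
#'
#' @param x one-letter sequence string, or path to a single-record FASTA
#'   file.
#' @param termini_charged logical; N-terminus +1e, C-terminus -1e.
#' @param his_neutral logical; His contributes 0e when TRUE, +1e otherwise.
#' @return a \linkS4class{Peptide}.
#' @examples
#' p <- loadPeptide("GAMDAAVTPEERHLSKMQQNGYENPTYKFFEQMQN")
#' nResidues(p)
#' @export
loadPeptide <- function(x, termini_charged = TRUE, his_neutral = TRUE) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  if (file.exists(x) && grepl("\\.(fa|fasta|faa)$", x, ignore.case = TRUE)) {
    set <- Biostrings::readAAStringSet(x)
    if (length(set) != 1L)
      stop("expected a single-record FASTA, found ", length(set), " records")
    x <- as.character(set[[1L]])
  }
  res <- strsplit(toupper(x), "")[[1]]
  if (length(res) < 2L)
    stop("peptide must have at least 2 residues, got ", length(res))
  bad <- which(!(res %in% names(.aa_mass_free)))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d", res[bad[1]],
                 bad[1]))
  masses <- unname(.aa_mass_free[res])
  mw <- sum(masses) - (length(res) - 1) * .water_mass
  new("Peptide", residues = res, terminiCharged = termini_charged,
      hisNeutral = his_neutral, residueMasses = masses,
      molecularWeight = mw)
}

#' The packaged 35-residue AICD fixture peptide
#'
#' Loads the default fixture: a 35-residue APP intracellular domain fragment
#' containing the YENPTY motif at residues 22-27, with charged termini and
#' neutral histidine (net charge -2e). See the FASTA header in
#' `inst/extdata/aicd35.fasta` for provenance.
#'
#' @return a \linkS4class{Peptide} of length 35.
#' @export
aicdPeptide <- function() {
  loadPeptide(system.file("extdata", "aicd35.fasta", package = "idplens"))
}

#' Kyte-Doolittle hydropathy profile
#'
#' Per-residue hydropathy, optionally smoothed with a centered sliding-window
#' mean (window 1 = raw values; even windows are centered on the right).
#'
#' @param p a \linkS4class{Peptide}.
#' @param window odd-preferred window length, default 1.
#' @return data.frame with position, residue, hydropathy.
#' @export
hydropathyProfile <- function(p, window = 1L) {
  stopifnot(is(p, "Peptide"))
  L <- nResidues(p)
  window <- as.integer(window)
  if (window < 1L || window > L)
    stop("window must be between 1 and the sequence length (", L, ")")
  h <- unname(kyteDoolittle[p@residues])
  if (window > 1L)
    h <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  data.frame(position = seq_len(L), residue = p@residues, hydropathy = h)
}

#' Integer charge profile at physiological pH
#'
#' Asp/Glu -1e, Lys/Arg +1e, His 0e when neutral (else +1e); when the
#' termini are charged the +1e/-1e terminal charges are booked on the first
#' and last residues. Integer assignment only — no fractional titration.
#'
#' @param p a \linkS4class{Peptide}.
#' @return list with `profile` (data.frame position, residue, charge) and
#'   `net_charge` in elementary charge units.
#' @examples
#' chargeProfile(aicdPeptide())$net_charge  # -2
#' @export
chargeProfile <- function(p) {
  stopifnot(is(p, "Peptide"))
  L <- nResidues(p)
  ch <- rep(0, L)
  side <- .aa_charge[p@residues]
  ch[!is.na(side)] <- side[!is.na(side)]
  ch[p@residues == "H"] <- if (p@hisNeutral) 0 else 1
  if (p@terminiCharged) {
    ch[1L] <- ch[1L] + 1
    ch[L] <- ch[L] - 1
  }
  list(profile = data.frame(position = seq_len(L), residue = p@residues,
                            charge = ch),
       net_charge = sum(ch))
}

#' Locate the first exact occurrence of a motif
#'
#' @param p a \linkS4class{Peptide}.
#' @param motif non-empty one-letter residue string.
#' @return named integer c(start, end), 1-based, or NULL when absent.
#' @examples
#' findMotif(aicdPeptide(), "YENPTY")  # c(start = 22, end = 27)
#' @export
findMotif <- function(p, motif) {
  stopifnot(is(p, "Peptide"), is.character(motif), nzchar(motif))
  hit <- regexpr(motif, peptideSequence(p), fixed = TRUE)
  if (hit[1] == -1L) return(NULL)
  c(start = as.integer(hit[1]),
    end = as.integer(hit[1]) + nchar(motif) - 1L)
}

#' Mean residue weight
#'
#' MRW = MW / (length - 1), the per-peptide-bond weight used to convert CD
#' millidegrees to molar circular dichroism.
#'
#' @param p a \linkS4class{Peptide}.
#' @return numeric, Da.
#' @export
meanResidueWeight <- function(p) {
  stopifnot(is(p, "Peptide"))
  L <- nResidues(p)
  if (L < 2L) stop("MRW undefined for sequences shorter than 2 residues")
  p@molecularWeight / (L - 1)
}

#' Write a residue profile table to TSV
#'
#' Combines hydropathy and charge into the standard per-residue table with
#' columns position, residue, hydropathy, charge.
#'
#' @param p a \linkS4class{Peptide}.
#' @param path output file.
#' @param window hydropathy sliding-window length.
#' @return the table, invisibly.
#' @export
writeResidueProfile <- function(p, path, window = 1L) {
  hp <- hydropathyProfile(p, window)
  cp <- chargeProfile(p)$profile
  tab <- data.frame(position = hp$position, residue = hp$residue,
                    hydropathy = hp$hydropathy, charge = cp$charge)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
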
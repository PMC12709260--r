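# Reduced peptide topology: per residue N, [H], CA, [CB], C, O in that
# order. Pro has no amide H; Gly has no CB. Side-chain mass beyond CA is
# lumped onto CB (onto CA for Gly) so chain mass and Rg track the full
# residue.

.bb_atom_masses <- c(N = 14.007, H = 1.008, CA = 13.019, C = 12.011,
                     O = 15.999)

.build_topology <- function(p) {
  res <- p@residues
  L <- length(res)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    code <- res[i]
    has_h <- code != "P"
    has_cb <- code != "G"
    chain_mass <- .aa_mass_free[[code]] - .water_mass
    atoms <- c("N", if (has_h) "H", "CA", if (has_cb) "CB", "C", "O")
    mass <- .bb_atom_masses[c("N", if (has_h) "H", "CA", "C", "O")]
    lump <- chain_mass - sum(mass)
    m <- numeric(length(atoms))
    names(m) <- atoms
    m[c("N", "CA", "C", "O")] <- .bb_atom_masses[c("N", "CA", "C", "O")]
    if (has_h) m["H"] <- .bb_atom_masses["H"]
    if (has_cb) m["CB"] <- lump else m["CA"] <- m["CA"] + lump
    rows[[i]] <- data.frame(
      atom = atoms, resid = i, resname = code,
      element = c(N = "N", H = "H", CA = "C", CB = "C", C = "C",
                  O = "O")[atoms],
      mass = unname(m), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

.atom_rows <- function(top, name) which(top$atom == name)

.has_h <- function(p) p@residues != "P"
.has_cb <- function(p) p@residues != "G"

#' Build a single conformer from backbone dihedrals
#'
#' Constructs backbone coordinates with ideal geometry (N-CA 1.458 A,
#' CA-C 1.525 A, C-N 1.329 A, omega fixed at 180 degrees), places the amide
#' H and carbonyl O in the peptide plane and CB at the tetrahedral
#' L-position (absent for Gly, no amide H for Pro).
#'
#' @param p a \linkS4class{Peptide}.
#' @param phi,psi per-residue dihedrals in degrees (length = residues;
#'   phi[1] and psi[L] only orient the terminal H and O).
#' @return a one-frame \linkS4class{ConformerEnsemble}.
#' @examples
#' p <- loadPeptide("AAAAAAAAAAAA")
#' helix <- buildChain(p, rep(-63, 12), rep(-43, 12))
#' @export
buildChain <- function(p, phi, psi) {
  stopifnot(is(p, "Peptide"))
  L <- nResidues(p)
  if (length(phi) != L || length(psi) != L)
    stop("phi and psi must each have one value per residue (", L, ")")
  X <- cpp_build_chain(as.numeric(phi), as.numeric(psi), .has_h(p),
                       .has_cb(p))
  top <- .build_topology(p)
  new("ConformerEnsemble", topology = top,
      coords = array(X, dim = c(nrow(top), 3L, 1L)),
      frameMeta = data.frame(replica = 1L, frame = 0L, time_ps = 0))
}

#' Backbone dihedral angles for every frame
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i) is undefined for the first residue and
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1) for the last; those entries are NA.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @return list of matrices `phi` and `psi`, residues x frames, degrees.
#' @export
backboneDihedrals <- function(ens) {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  cpp_dihedrals(coords(ens), .atom_rows(top, "N") - 1L,
                .atom_rows(top, "CA") - 1L, .atom_rows(top, "C") - 1L)
}

# single-frame coordinate matrix
.frame <- function(ens, i = 1L) coords(ens)[, , i, drop = TRUE]
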
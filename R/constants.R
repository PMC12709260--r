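# Residue-level physicochemical tables. Sources: Kyte & Doolittle (1982)
# hydropathy scale; average amino-acid masses from standard compilations;
# in-chain elemental compositions of the 20 proteinogenic residues.

#' Kyte-Doolittle hydropathy scale
#' @format named numeric, one value per one-letter residue code.
#' @export
kyteDoolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# average free amino-acid masses, Da (in-chain mass + one water)
.aa_mass_free <- c(
  A = 89.0932, R = 174.2017, N = 132.1179, D = 133.1027, C = 121.1582,
  E = 147.1293, Q = 146.1445, G = 75.0666, H = 155.1546, I = 131.1729,
  L = 131.1729, K = 146.1882, M = 149.2124, F = 165.1891, P = 115.1305,
  S = 105.0926, T = 119.1197, W = 204.2252, Y = 181.1885, V = 117.1463
)

.water_mass <- 18.01528

# integer side-chain charge at physiological pH (neutral His handled by flag)
.aa_charge <- c(D = -1, E = -1, K = 1, R = 1)

# in-chain elemental composition (residue = amino acid - water)
.aa_composition <- data.frame(
  code = c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V"),
  C = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
  H = c(5, 12, 6, 5, 5, 7, 8, 3, 7, 11, 11, 12, 9, 9, 7, 5, 7, 10, 9, 9),
  N = c(1, 4, 2, 1, 1, 1, 2, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
  O = c(1, 1, 2, 3, 1, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 1, 2, 1),
  S = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

.element_electrons <- c(H = 1, C = 6, N = 7, O = 8, S = 16)

# electrons in a whole in-chain residue
.residue_electrons <- function(code) {
  row <- .aa_composition[.aa_composition$code == code, ]
  sum(unlist(row[c("C", "H", "N", "O", "S")]) *
        .element_electrons[c("C", "H", "N", "O", "S")])
}

# package-local cache for tables read from extdata
.idplens_cache <- new.env(parent = emptyenv())

.read_extdata <- function(file) {
  if (!is.null(.idplens_cache[[file]])) return(.idplens_cache[[file]])
  path <- system.file("extdata", file, package = "idplens")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  .idplens_cache[[file]] <- tab
  tab
}

#' Cromer-Mann form-factor table with excluded-solvent volumes
#'
#' Four-Gaussian-plus-constant X-ray atomic form factors for H, C, N, O, S
#' and per-atom excluded solvent volumes (Fraser-type dummy atoms), as used
#' by the Debye forward model with zero hydration-shell contrast.
#'
#' @param solvent_density electron density of the solvent, e/A^3.
#' @return list with data.frame `coef` and numeric `solvent_density`.
#' @export
formFactorTable <- function(solvent_density = 0.334) {
  list(coef = .read_extdata("cromer_mann.tsv"),
       solvent_density = solvent_density)
}

#' van der Waals radii (Bondi set)
#' @return named numeric, Angstrom per element.
#' @export
vdwRadii <- function() {
  tab <- .read_extdata("vdw_radii.tsv")
  stats::setNames(tab$radius_A, tab$element)
}

# evaluate f(q) for one element over a q grid
.cromer_mann_f <- function(element, q, tab) {
  row <- tab$coef[tab$coef$element == element, ]
  if (nrow(row) != 1L) stop("no form-factor entry for element ", element)
  s2 <- (q / (4 * pi))^2
  row$a1 * exp(-row$b1 * s2) + row$a2 * exp(-row$b2 * s2) +
    row$a3 * exp(-row$b3 * s2) + row$a4 * exp(-row$b4 * s2) + row$c
}
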
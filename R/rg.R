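#' Mass-weighted radius of gyration
#'
#' Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i ), over all atoms with
#' masses by default (the gmx gyrate convention) or over C-alpha atoms only.
#'
#' @param x a \linkS4class{ConformerEnsemble}, or a single natoms x 3
#'   coordinate matrix (then `masses` is required).
#' @param masses per-atom masses in Da; taken from the topology for
#'   ensembles.
#' @param selection "all" or "calpha".
#' @return numeric Rg per frame, Angstrom.
#' @export
radiusOfGyration <- function(x, masses = NULL, selection = c("all", "calpha")) {
  selection <- match.arg(selection)
  if (is(x, "ConformerEnsemble")) {
    top <- topology(x)
    rows <- if (selection == "calpha") .atom_rows(top, "CA")
            else seq_len(nrow(top))
    m <- top$mass[rows]
    if (any(m <= 0) || sum(m) <= 0) stop("total mass must be positive")
    X <- coords(x)
    vapply(seq_len(nFrames(x)),
           function(f) cpp_rg(matrix(X[rows, , f], ncol = 3), m), 0.0)
  } else {
    X <- as.matrix(x)
    if (nrow(X) < 2L) stop("need at least 2 atoms")
    if (is.null(masses)) stop("masses required for bare coordinate input")
    if (sum(masses) <= 0) stop("total mass must be positive")
    cpp_rg(X, masses)
  }
}

#' Bin frames into integer-Angstrom Rg groups
#'
#' Each frame joins the nearest bin center (centers at multiples of
#' `bin_width`, integer Angstrom by default); ties at .5 round up (half-up
#' rule). Per-group frame index lists are emitted as
#' \linkS4class{FrameIndex} objects, ready to write as NDX-style files.
#'
#' @param rg per-frame Rg values, Angstrom.
#' @param bin_width bin width, Angstrom (default 1).
#' @return an \linkS4class{RgPartition}.
#' @examples
#' assignGroups(c(10.4, 10.5, 15.2))  # groups 10, 11, 15
#' @export
assignGroups <- function(rg, bin_width = 1.0) {
  stopifnot(length(rg) >= 1L, all(is.finite(rg)), bin_width > 0)
  label <- as.integer(floor(rg / bin_width + 0.5)) # half-up
  centers <- sort(unique(label))
  idx <- lapply(centers, function(ctr)
    frameIndex(sprintf("Rg_%g", ctr * bin_width),
               which(label == ctr) - 1L))
  names(idx) <- as.character(centers)
  new("RgPartition", rg = as.numeric(rg), binWidth = bin_width,
      assignment = label, indices = idx)
}

#' RMSD of every frame to a reference after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch) over the selected atoms,
#' then root-mean-square deviation, reported in nm (the trajectory-analysis
#' convention; coordinates are Angstrom internally).
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param reference reference frame number (1-based, default 1) or a
#'   natoms x 3 matrix sharing the ensemble topology.
#' @param selection atom-name filter, e.g. "CA" (default) or "all".
#' @return numeric RMSD per frame, nm.
#' @export
rmsdSeries <- function(ens, reference = 1L, selection = "CA") {
  stopifnot(is(ens, "ConformerEnsemble"))
  top <- topology(ens)
  rows <- if (identical(selection, "all")) seq_len(nrow(top))
          else .atom_rows(top, selection)
  if (!length(rows)) stop("selection '", selection, "' matches no atoms")
  ref <- if (is.matrix(reference)) reference
         else coords(ens)[, , reference, drop = TRUE]
  if (nrow(ref) != nrow(top))
    stop("reference does not share the ensemble topology")
  cpp_rmsd_to_ref(coords(ens), ref, rows - 1L) / 10
}

#' Gaussian kernel density estimate on an even grid
#'
#' Auto bandwidth is Scott's rule, n^(-1/5) times the sample SD. Thin
#' wrapper over \code{stats::density} so the bandwidth convention is
#' explicit and degenerate input fails loudly.
#'
#' @param values numeric sample, length >= 2.
#' @param bandwidth "auto" or a positive number.
#' @param n grid size.
#' @return data.frame with x and density.
#' @export
kdeDensity <- function(values, bandwidth = "auto", n = 512L) {
  stopifnot(length(values) >= 2L)
  if (identical(bandwidth, "auto")) {
    s <- stats::sd(values)
    if (s == 0)
      stop("zero-variance sample; supply an explicit bandwidth")
    bandwidth <- s * length(values)^(-1 / 5)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian", n = n)
  data.frame(x = d$x, density = d$y)
}

#' Write the frame, Rg, group table of a partition to TSV
#' @param part an \linkS4class{RgPartition}.
#' @param path output file.
#' @return the table, invisibly.
#' @export
writeRgTable <- function(part, path) {
  tab <- data.frame(frame = seq_along(part@rg) - 1L, rg = part@rg,
                    group = part@assignment)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
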
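#' Construct a FrameIndex
#' @param name group label.
#' @param frames 0-based global frame numbers, strictly increasing.
#' @return a \linkS4class{FrameIndex}.
#' @export
frameIndex <- function(name, frames) {
  new("FrameIndex", name = as.character(name),
      frames = as.integer(sort(unique(frames))))
}

#' Write an ensemble to multi-model PDB or concatenated XYZ
#'
#' PDB models carry MODEL/ENDMDL records, occupancy 1.00 and filled element
#' columns; replica and pseudo-time metadata are stored as REMARK 299 lines
#' so a round trip preserves them. XYZ stores the element symbol and the
#' same metadata on the comment line.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param path output file.
#' @param format "pdb" or "xyz" (default from file extension).
#' @return the path, invisibly.
#' @export
writeEnsemble <- function(ens, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(is(ens, "ConformerEnsemble"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  top <- topology(ens)
  X <- coords(ens)
  meta <- frameMeta(ens)
  nf <- nFrames(ens)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    writeLines(c("REMARK 299 IDPLENS ENSEMBLE",
                 sprintf("REMARK 299 NFRAMES %d", nf)), con)
    writeLines(sprintf("REMARK 299 FRAME %d REPLICA %d TIME_PS %s",
                       seq_len(nf) - 1L, meta$replica,
                       ifelse(is.na(meta$time_ps), "NA",
                              format(meta$time_ps, trim = TRUE))), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        seq_len(nrow(top)),
        ifelse(nchar(top$atom) < 4, paste0(" ", top$atom), top$atom),
        .res3(top$resname), top$resid,
        X[, 1, f], X[, 2, f], X[, 3, f], top$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(nf)) {
      writeLines(as.character(nrow(top)), con)
      writeLines(sprintf("frame %d replica %d time_ps %s",
                         f - 1L, meta$replica[f],
                         ifelse(is.na(meta$time_ps[f]), "NA",
                                format(meta$time_ps[f], trim = TRUE))), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", top$element,
                         X[, 1, f], X[, 2, f], X[, 3, f]), con)
    }
  }
  invisible(path)
}

.res3 <- function(code) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
           Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[code]
  out[is.na(out)] <- "UNK"
  unname(out)
}

.res1 <- function(code3) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- tab[code3]
  out[is.na(out)] <- "X"
  unname(out)
}

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Read an ensemble from multi-model PDB or XYZ
#'
#' @param path input file.
#' @param format "pdb", "xyz" or "auto" (from extension).
#' @param peptide optional \linkS4class{Peptide}; when given and consistent
#'   with the file's atom count, the package's reduced topology (with lumped
#'   side-chain masses) is used instead of per-element masses.
#' @return a \linkS4class{ConformerEnsemble}; replica metadata is taken from
#'   header remarks when present, else a single replica is assumed.
#' @export
readEnsemble <- function(path, format = c("auto", "pdb", "xyz"),
                         peptide = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  lines <- readLines(path)
  if (format == "pdb") out <- .read_pdb(lines) else out <- .read_xyz(lines)
  top <- out$topology
  if (!is.null(peptide)) {
    cand <- .build_topology(peptide)
    if (nrow(cand) != nrow(top))
      stop("peptide topology has ", nrow(cand),
           " atoms but file has ", nrow(top))
    top <- cand
  }
  new("ConformerEnsemble", topology = top, coords = out$coords,
      frameMeta = out$meta)
}

.parse_remark_meta <- function(lines, nf) {
  m <- regmatches(lines, regexec(
    "^REMARK 299 FRAME ([0-9]+) REPLICA ([0-9]+) TIME_PS (\\S+)", lines))
  m <- m[vapply(m, length, 1L) == 4L]
  meta <- data.frame(replica = rep(1L, nf), frame = seq_len(nf) - 1L,
                     time_ps = NA_real_)
  if (length(m)) {
    for (x in m) {
      i <- as.integer(x[2]) + 1L
      if (i >= 1L && i <= nf) {
        meta$replica[i] <- as.integer(x[3])
        meta$time_ps[i] <- suppressWarnings(as.numeric(x[4]))
      }
    }
    for (r in unique(meta$replica))
      meta$frame[meta$replica == r] <- seq_len(sum(meta$replica == r)) - 1L
  }
  meta
}

.read_pdb <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  atom_lines <- grepl("^ATOM ", lines)
  if (!length(model_starts)) {
    blocks <- list(which(atom_lines))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    blocks <- mapply(function(s, e) {
      idx <- seq.int(s, e)
      idx[atom_lines[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  n0 <- length(blocks[[1]])
  for (b in seq_along(blocks))
    if (length(blocks[[b]]) != n0)
      stop("inconsistent atom count in model ", b, ": ",
           length(blocks[[b]]), " vs ", n0)
  first <- lines[blocks[[1]]]
  atom <- trimws(substr(first, 13, 16))
  resname3 <- trimws(substr(first, 18, 20))
  resid <- as.integer(substr(first, 23, 26))
  element <- trimws(substr(first, 77, 78))
  element[!nzchar(element)] <- substr(atom[!nzchar(element)], 1, 1)
  top <- data.frame(atom = atom, resid = resid, resname = .res1(resname3),
                    element = element,
                    mass = unname(.element_mass[element]),
                    stringsAsFactors = FALSE)
  nf <- length(blocks)
  coords <- array(NA_real_, dim = c(n0, 3L, nf))
  for (f in seq_len(nf)) {
    ln <- lines[blocks[[f]]]
    coords[, 1, f] <- as.numeric(substr(ln, 31, 38))
    coords[, 2, f] <- as.numeric(substr(ln, 39, 46))
    coords[, 3, f] <- as.numeric(substr(ln, 47, 54))
  }
  list(topology = top, coords = coords, meta = .parse_remark_meta(lines, nf))
}

.read_xyz <- function(lines) {
  pos <- 1L
  frames <- list()
  meta_rows <- list()
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    comment <- lines[pos + 1L]
    block <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    f <- length(frames) + 1L
    frames[[f]] <- list(
      element = vapply(parts, `[`, "", 1L),
      xyz = t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))))
    m <- regexec("replica ([0-9]+) time_ps (\\S+)", comment)[[1]]
    g <- regmatches(comment, regexec("replica ([0-9]+) time_ps (\\S+)",
                                     comment))[[1]]
    meta_rows[[f]] <- if (length(g) == 3L)
      data.frame(replica = as.integer(g[2]),
                 time_ps = suppressWarnings(as.numeric(g[3])))
    else data.frame(replica = 1L, time_ps = NA_real_)
    pos <- pos + 2L + n
  }
  n0 <- length(frames[[1]]$element)
  for (f in seq_along(frames))
    if (length(frames[[f]]$element) != n0)
      stop("inconsistent atom count in frame ", f)
  element <- frames[[1]]$element
  top <- data.frame(atom = element, resid = 1L, resname = "X",
                    element = element,
                    mass = unname(.element_mass[element]),
                    stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(n0, 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]$xyz
  meta <- do.call(rbind, meta_rows)
  meta$frame <- stats::ave(seq_len(nrow(meta)), meta$replica,
                           FUN = function(i) seq_along(i) - 1L)
  list(topology = top, coords = coords,
       meta = meta[, c("replica", "frame", "time_ps")])
}

#' Discard the start of each replica and concatenate
#'
#' Removes, per replica, every frame with pseudo-time strictly less than the
#' discard horizon (a frame exactly at the horizon is kept), then
#' concatenates survivors in replica order with a fresh 0-based global
#' frame numbering.
#'
#' @param ens a multi-replica \linkS4class{ConformerEnsemble}, or a list of
#'   single-replica ensembles sharing one topology.
#' @param discard_ns equilibration span to drop from each replica, ns.
#' @return the trimmed, concatenated \linkS4class{ConformerEnsemble}.
#' @export
trimAndConcatenate <- function(ens, discard_ns) {
  if (is.list(ens) && !is(ens, "ConformerEnsemble")) {
    tops <- lapply(ens, topology)
    for (i in seq_along(tops))
      if (!identical(dim(tops[[i]]), dim(tops[[1]])))
        stop("replica ", i, " topology differs from replica 1")
    coords <- array(unlist(lapply(ens, coords)),
                    dim = c(nrow(tops[[1]]), 3L,
                            sum(vapply(ens, nFrames, 1L))))
    meta <- do.call(rbind, lapply(seq_along(ens), function(i) {
      m <- frameMeta(ens[[i]])
      m$replica <- i
      m
    }))
    rownames(meta) <- NULL
    ens <- new("ConformerEnsemble", topology = tops[[1]], coords = coords,
               frameMeta = meta)
  }
  stopifnot(is(ens, "ConformerEnsemble"))
  meta <- frameMeta(ens)
  if (any(is.na(meta$time_ps)))
    stop("every replica needs pseudo-time metadata; run emulateProtocol()")
  discard_ps <- discard_ns * 1000
  keep <- logical(nrow(meta))
  for (r in unique(meta$replica)) {
    sel <- meta$replica == r
    if (discard_ps > max(meta$time_ps[sel]))
      stop("discard of ", discard_ns, " ns exceeds the span of replica ", r)
    keep[sel] <- meta$time_ps[sel] >= discard_ps
  }
  out_meta <- meta[keep, , drop = FALSE]
  rownames(out_meta) <- NULL
  new("ConformerEnsemble", topology = topology(ens),
      coords = coords(ens)[, , keep, drop = FALSE], frameMeta = out_meta)
}

#' Write a frame index file (GROMACS NDX convention)
#'
#' One bracketed group-name line, then whitespace-separated 1-based frame
#' numbers, at most 15 per line. In-memory indices are 0-based; the +1 shift
#' happens here and is undone by \code{readIndex}.
#'
#' @param fi a \linkS4class{FrameIndex} or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeIndex <- function(fi, path) {
  if (is(fi, "FrameIndex")) fi <- list(fi)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in fi) {
    writeLines(sprintf("[ %s ]", g@name), con)
    nums <- g@frames + 1L
    if (length(nums)) {
      rows <- split(nums, ceiling(seq_along(nums) / 15))
      writeLines(vapply(rows, paste, "", collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname writeIndex
#' @return `readIndex` returns a named list of \linkS4class{FrameIndex}.
#' @export
readIndex <- function(path) {
  lines <- readLines(path)
  heads <- grep("^\\[", lines)
  if (!length(heads)) stop("no group headers found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    name <- trimws(gsub("[][]", "", lines[heads[i]]))
    body <- lines[seq.int(heads[i] + 1L, bounds[i + 1L] - 1L)]
    nums <- as.integer(unlist(strsplit(trimws(paste(body, collapse = " ")),
                                       "\\s+")))
    nums <- nums[!is.na(nums)]
    out[[name]] <- frameIndex(name, nums - 1L)
  }
  out
}

#' Extract the frames of one group as a sub-ensemble
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param fi a \linkS4class{FrameIndex} with 0-based global frame numbers.
#' @return a \linkS4class{ConformerEnsemble} in index order; coordinates are
#'   copied bit-for-bit.
#' @export
extractGroup <- function(ens, fi) {
  stopifnot(is(ens, "ConformerEnsemble"), is(fi, "FrameIndex"))
  nf <- nFrames(ens)
  if (length(fi@frames) && max(fi@frames) >= nf)
    stop("frame index ", max(fi@frames), " out of range (ensemble has ",
         nf, " frames)")
  sel <- fi@frames + 1L
  meta <- frameMeta(ens)[sel, , drop = FALSE]
  rownames(meta) <- NULL
  new("ConformerEnsemble", topology = topology(ens),
      coords = coords(ens)[, , sel, drop = FALSE], frameMeta = meta)
}
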
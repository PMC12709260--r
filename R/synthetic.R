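#' Configuration for the synthetic conformer generator
#'
#' The generator runs one Markov chain per replica over backbone dihedral
#' space: single-residue (phi, psi) redraws from a Gaussian mixture of
#' Ramachandran basins, hard-sphere clash rejection between non-adjacent
#' heavy atoms, and an optional harmonic Metropolis bias
#' U = rg_spring (Rg - rg_target)^2 in kBT that tunes compaction. States
#' are recorded every `stride` accepted moves, so consecutive frames are
#' autocorrelated — a stand-in for correlated MD output, not for physical
#' kinetics.
#'
#' @param seed integer; replica r uses R stream `seed + r`.
#' @param n_replicas number of independent chains (default 5).
#' @param frames_per_replica recorded frames per replica.
#' @param basin_weights mixture weights over the alphaR, beta, PPII and
#'   alphaL basins; must sum to 1.
#' @param basin_centers 4 x 2 matrix of (phi, psi) basin centers, degrees.
#' @param basin_sigma Gaussian spread around each center, degrees.
#' @param rg_target target radius of gyration in Angstrom, or NA for an
#'   unbiased chain.
#' @param rg_spring bias strength, kBT per Angstrom^2.
#' @param clash_cutoff minimum allowed heavy-atom distance between residues
#'   at least 2 apart, Angstrom.
#' @param stride accepted moves between recorded frames.
#' @param burn_in accepted moves discarded before recording starts.
#' @param max_attempts proposal budget with zero acceptance before the
#'   generator aborts with diagnostics.
#' @return a list of class "GeneratorConfig".
#' @export
generatorConfig <- function(seed = 1L, n_replicas = 5L,
                            frames_per_replica = 2000L,
                            basin_weights = c(alphaR = 0.30, beta = 0.35,
                                              PPII = 0.25, alphaL = 0.10),
                            basin_centers = rbind(alphaR = c(-63, -43),
                                                  beta = c(-120, 130),
                                                  PPII = c(-75, 150),
                                                  alphaL = c(60, 45)),
                            basin_sigma = 15, rg_target = NA_real_,
                            rg_spring = 2.0, clash_cutoff = 2.8,
                            stride = 10L, burn_in = 1000L,
                            max_attempts = 200000L) {
  if (any(basin_weights < 0) || abs(sum(basin_weights) - 1) > 1e-8)
    stop("basin_weights must be non-negative and sum to 1")
  if (frames_per_replica < 1L) stop("frames_per_replica must be >= 1")
  if (clash_cutoff <= 0) stop("clash_cutoff must be positive")
  if (nrow(basin_centers) != length(basin_weights))
    stop("basin_centers must have one (phi, psi) row per weight")
  cfg <- list(seed = as.integer(seed), n_replicas = as.integer(n_replicas),
              frames_per_replica = as.integer(frames_per_replica),
              basin_weights = basin_weights,
              basin_centers = basin_centers, basin_sigma = basin_sigma,
              rg_target = rg_target, rg_spring = rg_spring,
              clash_cutoff = clash_cutoff, stride = as.integer(stride),
              burn_in = as.integer(burn_in),
              max_attempts = as.integer(max_attempts))
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Write / read a generator configuration as YAML
#' @param cfg a GeneratorConfig.
#' @param path file path.
#' @return `readGeneratorConfig` returns a GeneratorConfig.
#' @export
writeGeneratorConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  out <- cfg
  out$basin_centers <- lapply(seq_len(nrow(cfg$basin_centers)), function(i)
    as.numeric(cfg$basin_centers[i, ]))
  names(out$basin_centers) <- rownames(cfg$basin_centers)
  out$basin_weights <- as.list(cfg$basin_weights)
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  centers <- do.call(rbind, raw$basin_centers)
  generatorConfig(seed = raw$seed, n_replicas = raw$n_replicas,
                  frames_per_replica = raw$frames_per_replica,
                  basin_weights = unlist(raw$basin_weights),
                  basin_centers = centers, basin_sigma = raw$basin_sigma,
                  rg_target = if (is.null(raw$rg_target)) NA_real_ else
                    raw$rg_target,
                  rg_spring = raw$rg_spring,
                  clash_cutoff = raw$clash_cutoff, stride = raw$stride,
                  burn_in = raw$burn_in, max_attempts = raw$max_attempts)
}

#' Sample a synthetic multi-replica conformer ensemble
#'
#' Runs the dihedral-space Markov chain described in
#' \code{\link{generatorConfig}} once per replica. Replica r is seeded with
#' `seed + r`, so replicas are mutually independent but the whole ensemble
#' is a deterministic function of the seed.
#'
#' @param p a \linkS4class{Peptide}.
#' @param cfg a GeneratorConfig.
#' @param verbose log one line per replica (seed, acceptance, mean Rg).
#' @return a \linkS4class{ConformerEnsemble}; per-replica acceptance rates
#'   and mean Rg are attached as attribute "generator_log".
#' @export
sampleEnsemble <- function(p, cfg, verbose = FALSE) {
  stopifnot(is(p, "Peptide"), inherits(cfg, "GeneratorConfig"))
  top <- .build_topology(p)
  heavy <- which(top$element != "H")
  reps <- vector("list", cfg$n_replicas)
  log <- data.frame(replica = integer(), seed = integer(),
                    acceptance = numeric(), mean_rg = numeric())
  n_rec <- cfg$frames_per_replica + ceiling(cfg$burn_in / cfg$stride)
  for (r in seq_len(cfg$n_replicas)) {
    set.seed(cfg$seed + r)
    out <- cpp_sample_replica(
      n_frames = n_rec, stride = cfg$stride,
      w = as.numeric(cfg$basin_weights),
      centers_phi_psi = unname(cfg$basin_centers),
      sigma = cfg$basin_sigma,
      rg_target = if (is.na(cfg$rg_target)) 0 else cfg$rg_target,
      rg_spring = cfg$rg_spring, use_rg_bias = !is.na(cfg$rg_target),
      clash_cutoff = cfg$clash_cutoff, has_h = .has_h(p),
      has_cb = .has_cb(p), masses = top$mass, heavy_idx = heavy - 1L,
      heavy_res = top$resid[heavy] - 1L, max_attempts = cfg$max_attempts)
    keep <- seq.int(n_rec - cfg$frames_per_replica + 1L, n_rec)
    reps[[r]] <- out$coords[, , keep, drop = FALSE]
    log <- rbind(log, data.frame(replica = r, seed = cfg$seed + r,
                                 acceptance = out$acceptance,
                                 mean_rg = mean(out$rg[keep])))
    if (verbose)
      message(sprintf("replica %d: seed %d, acceptance %.2f, mean Rg %.2f A",
                      r, cfg$seed + r, out$acceptance, mean(out$rg[keep])))
  }
  coords <- array(unlist(reps), dim = c(nrow(top), 3L,
                                        cfg$n_replicas * cfg$frames_per_replica))
  meta <- data.frame(
    replica = rep(seq_len(cfg$n_replicas), each = cfg$frames_per_replica),
    frame = rep(seq_len(cfg$frames_per_replica) - 1L, cfg$n_replicas),
    time_ps = NA_real_)
  ens <- new("ConformerEnsemble", topology = top, coords = coords,
             frameMeta = meta)
  attr(ens, "generator_log") <- log
  ens
}

#' Assign pseudo-times to frames
#'
#' Emulates a fixed trajectory output interval: within each replica, frame k
#' gets pseudo-time k * time_per_frame_ps. This is bookkeeping for the
#' discard/concatenate stage, not physical time.
#'
#' @param ens a \linkS4class{ConformerEnsemble}.
#' @param time_per_frame_ps positive frame interval in ps.
#' @return the ensemble with frameMeta$time_ps filled.
#' @export
emulateProtocol <- function(ens, time_per_frame_ps) {
  stopifnot(is(ens, "ConformerEnsemble"))
  if (!is.numeric(time_per_frame_ps) || time_per_frame_ps <= 0)
    stop("time_per_frame_ps must be positive")
  meta <- frameMeta(ens)
  meta$time_ps <- meta$frame * time_per_frame_ps
  ens@frameMeta <- meta
  ens
}
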
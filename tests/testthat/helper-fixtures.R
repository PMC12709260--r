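# Shared fixtures, all built in code.

ala_peptide <- function(n) loadPeptide(paste(rep("A", n), collapse = ""))

ideal_helix <- function(n = 12) buildChain(ala_peptide(n), rep(-63, n),
                                           rep(-43, n))

extended_chain <- function(n = 12) buildChain(ala_peptide(n), rep(180, n),
                                              rep(180, n))

# 16-residue antiparallel hairpin: two beta strands around a type II' turn
beta_hairpin <- function() {
  phi <- c(rep(-139, 7), 60, -80, rep(-139, 7))
  psi <- c(rep(135, 7), -120, 0, rep(135, 7))
  buildChain(ala_peptide(16), phi, psi)
}

# minimal bare ensemble from an explicit coordinate array
toy_ensemble <- function(coords_list, element = "C", mass = 12.011) {
  n <- nrow(coords_list[[1]])
  top <- data.frame(atom = paste0("X", seq_len(n)), resid = seq_len(n),
                    resname = "X", element = element, mass = mass,
                    stringsAsFactors = FALSE)
  arr <- array(unlist(coords_list), dim = c(n, 3, length(coords_list)))
  new("ConformerEnsemble", topology = top, coords = arr,
      frameMeta = data.frame(replica = 1L,
                             frame = seq_along(coords_list) - 1L,
                             time_ps = NA_real_))
}

# profile object shorthand
profile <- function(q, I, sigma = NA_real_)
  new("ScatteringProfile", q = q, I = I, sigma = sigma, rgMeta = NA_real_)

# small unbiased synthetic ensemble, memoised per test run
.fix_env <- new.env()
small_ensemble <- function() {
  if (is.null(.fix_env$ens)) {
    cfg <- generatorConfig(seed = 5, n_replicas = 2,
                           frames_per_replica = 120, burn_in = 200)
    .fix_env$ens <- emulateProtocol(sampleEnsemble(aicdPeptide(), cfg), 100)
  }
  .fix_env$ens
}

# basin-midpoint partition of the Ramachandran torus: each rectangle owns
# the full mass of one generator basin (boundaries halfway between basin
# centers), so sampled fractions estimate the mixture weights directly
recovery_regions <- function() {
  list(alphaR = c(-180, 0, -120, 43.5),
       beta = c(-180, -97.5, 43.5, 180),
       PPII = c(-97.5, 0, 43.5, 180),
       alphaL = c(0, 180, -180, 180))
}
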
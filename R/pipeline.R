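#' Configuration for the end-to-end pipeline
#'
#' Physical quantities carry explicit units in their names (trim_ns,
#' cutoff_nm, q in 1/Angstrom) because the analyses mix Angstrom (Rg,
#' scattering) and nm (RMSD, SASA, cluster cutoff) conventions.
#'
#' @param sequence peptide string or FASTA path (default: packaged
#'   35-residue fixture).
#' @param generator a \code{\link{generatorConfig}}; its seed is overridden
#'   by `seed`.
#' @param ensemble_file optional multi-model PDB/XYZ to analyse instead of
#'   generating.
#' @param time_per_frame_ps pseudo-time interval per recorded frame.
#' @param trim_ns per-replica discard horizon.
#' @param rg_bin_width Rg bin width, Angstrom.
#' @param rg_groups integer group labels to analyse in depth (NULL: the
#'   three most populated groups).
#' @param q momentum-transfer grid.
#' @param expt_saxs,expt_cd optional experimental curve paths.
#' @param cd_meta list(pathlength_cm, conc_g_per_L) for experimental CD
#'   conversion.
#' @param tica_lag lag in frames.
#' @param tica_scheme feature scheme, see \code{\link{featurize}}.
#' @param cluster_cutoff_nm GROMOS cutoff.
#' @param cluster_max_frames frame cap for the O(n^2) clustering.
#' @param sasa_stride analyse every k-th frame for SASA (1 = all).
#' @param stages character vector of stages to run (subset of the default).
#' @param seed global seed; every stochastic stage derives from it.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(sequence = NULL, generator = generatorConfig(),
                           ensemble_file = NULL, time_per_frame_ps = 100,
                           trim_ns = 30, rg_bin_width = 1.0,
                           rg_groups = NULL, q = defaultQGrid(),
                           expt_saxs = NULL, expt_cd = NULL,
                           cd_meta = list(pathlength_cm = 0.1,
                                          conc_g_per_L = 0.1),
                           tica_lag = 100L,
                           tica_scheme = "dihedral-sincos",
                           cluster_cutoff_nm = 0.9,
                           cluster_max_frames = 2000L, sasa_stride = 1L,
                           stages = c("generate", "trim", "decompose",
                                      "saxs", "pr", "sasa", "contacts",
                                      "hbonds", "ss", "rama", "jcouple",
                                      "cd", "tica", "fes", "cluster"),
                           seed = 1L) {
  if (is.null(sequence))
    sequence <- system.file("extdata", "aicd35.fasta", package = "idplens")
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage_log <- function(log, name, n_in, n_out) {
  message(sprintf("[%s] frames in: %s, out: %s", name, n_in, n_out))
  rbind(log, data.frame(stage = name, frames_in = n_in, frames_out = n_out))
}

#' Run the full analysis pipeline
#'
#' generate/ingest -> pseudo-time -> trim+concatenate -> Rg decomposition
#' -> per-group scattering, P(r) and optional chi-square -> SASA, contact,
#' H-bond, secondary-structure, Ramachandran and J-coupling observables ->
#' ensemble CD -> tICA and landscapes -> GROMOS clustering. Every table is
#' written under `out_dir` and a manifest records the config, seed,
#' package version and per-stage frame counts. A failing stage stops with
#' its name; artifacts written so far are preserved.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the manifest is `manifest.json` inside.
#' @export
runPipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(cfg$sequence) || !nzchar(cfg$sequence))
    stop("config has no sequence; nothing to analyse")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(stage = character(), frames_in = character(),
                    frames_out = character())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  p <- run_stage("sequence", loadPeptide(cfg$sequence))
  writeResidueProfile(p, file.path(out_dir, "residue_profile.tsv"))

  # --- ensemble ---------------------------------------------------------
  if (!is.null(cfg$ensemble_file)) {
    ens <- run_stage("ingest", readEnsemble(cfg$ensemble_file, peptide = p))
    log <- .stage_log(log, "ingest", "-", nFrames(ens))
  } else {
    gen <- cfg$generator
    gen$seed <- as.integer(cfg$seed)
    ens <- run_stage("generate", sampleEnsemble(p, gen))
    utils::write.table(attr(ens, "generator_log"),
                       file.path(out_dir, "generator_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- .stage_log(log, "generate", "-", nFrames(ens))
  }
  ens <- emulateProtocol(ens, cfg$time_per_frame_ps)
  n0 <- nFrames(ens)
  if ("trim" %in% cfg$stages) {
    ens <- run_stage("trim", trimAndConcatenate(ens, cfg$trim_ns))
    log <- .stage_log(log, "trim", n0, nFrames(ens))
  }

  # --- Rg decomposition -------------------------------------------------
  rg <- radiusOfGyration(ens)
  part <- assignGroups(rg, cfg$rg_bin_width)
  writeRgTable(part, file.path(out_dir, "rg_table.tsv"))
  writeIndex(part@indices, file.path(out_dir, "rg_groups.ndx"))
  rmsd <- rmsdSeries(ens)
  utils::write.table(data.frame(frame = seq_along(rmsd) - 1L, rmsd_nm = rmsd),
                     file.path(out_dir, "rmsd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  kde <- kdeDensity(rmsd)
  utils::write.table(kde, file.path(out_dir, "rmsd_kde.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- .stage_log(log, "decompose", nFrames(ens),
                    length(groupLabels(part)))
  labs <- cfg$rg_groups
  if (is.null(labs)) {
    sizes <- vapply(groupLabels(part),
                    function(l) length(groupIndex(part, l)@frames), 1L)
    labs <- groupLabels(part)[order(sizes, decreasing = TRUE)][
      seq_len(min(3L, length(sizes)))]
    labs <- sort(labs)
  }
  labs <- intersect(labs, groupLabels(part))
  groups <- lapply(labs, function(l) extractGroup(ens, groupIndex(part, l)))
  names(groups) <- labs

  # --- scattering -------------------------------------------------------
  if ("saxs" %in% cfg$stages) {
    profs <- run_stage("saxs", groupProfiles(ens, part, q = cfg$q))
    for (nm in c(as.character(labs), "all"))
      writeScatteringCurve(profs[[nm]],
                           file.path(out_dir, sprintf("saxs_%s.dat", nm)))
    guin <- tryCatch(guinierRg(profs$all), error = function(e) NULL)
    if (!is.null(guin)) {
      utils::write.table(
        data.frame(rg_A = guin$rg, I0 = guin$I0, n_points = guin$n_points),
        file.path(out_dir, "guinier.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      kr <- kratky(profs$all, rg = guin$rg, I0 = guin$I0)
      utils::write.table(kr, file.path(out_dir, "kratky.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cfg$expt_saxs)) {
      expt <- readScatteringCurve(cfg$expt_saxs)
      x2 <- chiSquare(expt, profs$all, scale = "fit")
      utils::write.table(
        data.frame(chi2 = as.numeric(x2),
                   scale_factor = attr(x2, "scale_factor"),
                   n = attr(x2, "n")),
        file.path(out_dir, "chi2.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    log <- .stage_log(log, "saxs", nFrames(ens), length(labs) + 1L)
    if ("pr" %in% cfg$stages) {
      for (nm in c(as.character(labs), "all")) {
        sub <- if (nm == "all") ens else groups[[nm]]
        pd <- run_stage("pr", prDirect(sub))
        dmax <- pd@Dmax
        pri <- run_stage("pr", prIndirect(profs[[nm]], Dmax = dmax,
                                          alpha = 1e-6))
        utils::write.table(data.frame(r = pri@r, P = pri@P),
                           file.path(out_dir, sprintf("pr_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(data.frame(r = pd@r, P = pd@P),
                           file.path(out_dir,
                                     sprintf("pr_direct_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log <- .stage_log(log, "pr", length(labs) + 1L, length(labs) + 1L)
    }
  }

  # --- structural observables ------------------------------------------
  sasa_frames <- seq(1L, nFrames(ens), by = cfg$sasa_stride)
  sr <- NULL
  if ("sasa" %in% cfg$stages) {
    sr <- run_stage("sasa", sasa(ens, frames = sasa_frames))
    sub_part <- assignGroups(rg[sasa_frames], cfg$rg_bin_width)
    ss_sum <- sasaGroupSummary(sr, sub_part)
    utils::write.table(ss_sum$group_totals,
                       file.path(out_dir, "sasa_group_totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ss_sum$per_residue_mean,
                       file.path(out_dir, "sasa_per_residue.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    log <- .stage_log(log, "sasa", length(sasa_frames),
                      nrow(ss_sum$group_totals))
  }
  if ("contacts" %in% cfg$stages) {
    for (nm in names(groups))
      writeContactMap(minCaDistanceMap(groups[[nm]]),
                      file.path(out_dir,
                                sprintf("contact_min_ca_%s.tsv", nm)))
    log <- .stage_log(log, "contacts", length(groups), length(groups))
  }
  if ("hbonds" %in% cfg$stages) {
    for (nm in names(groups))
      writeContactMap(hbondMap(groups[[nm]]),
                      file.path(out_dir, sprintf("hbond_%s.tsv", nm)))
    log <- .stage_log(log, "hbonds", length(groups), length(groups))
  }
  ssa <- NULL
  if ("ss" %in% cfg$stages) {
    ssa <- run_stage("ss", assignSecondaryStructure(ens, part))
    utils::write.table(ssa$probabilities,
                       file.path(out_dir, "ss_probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    utils::write.table(ssa$group_fractions,
                       file.path(out_dir, "ss_group_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    log <- .stage_log(log, "ss", nFrames(ens), nrow(ssa$probabilities))
  }
  if ("rama" %in% cfg$stages) {
    rama <- run_stage("rama", ramachandran(ens))
    utils::write.table(
      data.frame(region = names(rama$fractions),
                 fraction = as.numeric(rama$fractions), n = rama$n),
      file.path(out_dir, "rama_fractions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log <- .stage_log(log, "rama", rama$n, length(rama$fractions))
  }
  if ("jcouple" %in% cfg$stages) {
    jc <- run_stage("jcouple", jCouplings(ens, part = part))
    utils::write.table(jc, file.path(out_dir, "jcouplings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- .stage_log(log, "jcouple", nFrames(ens), nrow(jc))
  }
  if ("cd" %in% cfg$stages && !is.null(ssa)) {
    sim_cd <- run_stage("cd", ensembleCd(ssa))
    writeCdSpectrum(sim_cd, file.path(out_dir, "cd_simulated.tsv"))
    dec <- decomposeCd(sim_cd)
    utils::write.table(
      data.frame(class = names(dec$fractions),
                 fraction = as.numeric(dec$fractions),
                 residual = dec$residual),
      file.path(out_dir, "cd_fractions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log <- .stage_log(log, "cd", nFrames(ens), length(dec$fractions))
  }

  # --- landscapes and clustering ---------------------------------------
  if ("tica" %in% cfg$stages) {
    fs <- featurize(ens, cfg$tica_scheme)
    tm <- run_stage("tica", fitTica(fs, tau = cfg$tica_lag))
    proj <- data.frame(frame = seq_len(nFrames(ens)) - 1L,
                       tic1 = tm$projections[, 1],
                       tic2 = tm$projections[, 2])
    utils::write.table(proj, file.path(out_dir, "tica_projections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = seq_along(tm$eigenvalues),
                 eigenvalue = tm$eigenvalues, lag_frames = tm$tau),
      file.path(out_dir, "tica_eigenvalues.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    log <- .stage_log(log, "tica", nFrames(ens), ncol(tm$projections))
    if ("fes" %in% cfg$stages) {
      fes <- freeEnergySurface(proj$tic1, proj$tic2)
      utils::write.table(fes$F, file.path(out_dir, "fes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      if (!is.null(sr)) {
        sl <- sasaLandscape(proj$tic1[sasa_frames], proj$tic2[sasa_frames],
                            sr$total)
        utils::write.table(sl$mean, file.path(out_dir,
                                              "sasa_landscape.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      log <- .stage_log(log, "fes", nFrames(ens), sum(fes$counts > 0))
    }
  }
  if ("cluster" %in% cfg$stages) {
    cl <- run_stage("cluster",
                    gromosCluster(ens, cutoff_nm = cfg$cluster_cutoff_nm,
                                  max_frames = cfg$cluster_max_frames))
    utils::write.table(
      data.frame(cluster = seq_along(cl$populations),
                 population = cl$populations,
                 center_frame = cl$centers, stride = cl$stride),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log <- .stage_log(log, "cluster", length(cl$frames),
                      length(cl$populations))
  }

  # --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_ser <- lapply(unclass(cfg), function(x)
    if (inherits(x, "GeneratorConfig")) unclass(x) else x)
  cfg_ser$generator$basin_centers <-
    apply(cfg$generator$basin_centers, 1, as.numeric, simplify = FALSE)
  cfg_ser$generator$basin_weights <- as.list(cfg$generator$basin_weights)
  yaml::write_yaml(cfg_ser, cfg_path)
  manifest <- list(
    package = "idplens",
    version = as.character(utils::packageVersion("idplens")),
    seed = cfg$seed,
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summary tables of a completed run
#'
#' Pure function of the run directory: re-reads the written artifacts into
#' one table per figure-style analysis (profiles, scattering, SASA, maps,
#' secondary structure, couplings, landscapes, clusters). Missing
#' artifacts are flagged, not errors.
#'
#' @param run_dir directory produced by \code{\link{runPipeline}}.
#' @return named list of data.frames; attribute "missing" lists absent
#'   artifacts.
#' @export
pipelineReport <- function(run_dir) {
  want <- c(residue_profile = "residue_profile.tsv",
            rg_table = "rg_table.tsv",
            saxs = "saxs_all.dat",
            guinier = "guinier.tsv",
            pr = "pr_all.tsv",
            sasa = "sasa_group_totals.tsv",
            contacts = NA, # per-group files, collected below
            ss = "ss_group_fractions.tsv",
            rama = "rama_fractions.tsv",
            jcouplings = "jcouplings.tsv",
            cd = "cd_fractions.tsv",
            tica = "tica_eigenvalues.tsv",
            clusters = "clusters.tsv")
  out <- list()
  missing <- character()
  for (nm in names(want)) {
    if (nm == "contacts") {
      files <- list.files(run_dir, "^contact_min_ca_.*\\.tsv$",
                          full.names = TRUE)
      if (length(files))
        out$contacts <- stats::setNames(
          lapply(files, utils::read.table, sep = "\t"), basename(files))
      else missing <- c(missing, "contacts")
      next
    }
    path <- file.path(run_dir, want[[nm]])
    if (file.exists(path)) {
      header <- !nm %in% c("saxs")
      out[[nm]] <- utils::read.table(path, header = header, sep = "",
                                     comment.char = "#")
    } else missing <- c(missing, nm)
  }
  if (length(missing))
    warning("incomplete run; missing: ", paste(missing, collapse = ", "))
  attr(out, "missing") <- missing
  out
}
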
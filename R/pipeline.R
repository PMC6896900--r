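#' Read and validate a run configuration
#'
#' Plain-text key-value (YAML) schema:
#' ```
#' variant: canonical | dH3/H4 | dH2A/H2B | dH3'/H4' | dH2A'/H2B'
#' topology: path/to/topology.pdb
#' trajectories: [trial_01.trj, trial_02.trj]
#' sampling_interval: 10        # ps
#' window_start_fraction: 0.5   # latter half
#' cutoff: 10                   # contact cutoff, A
#' n_modes: 2                   # PCA modes for projections/landscape
#' kde_bandwidth: scott         # or a number (kernel sd, A)
#' output: out/dir
#' region_table: optional TSV with columns role, region, from, to
#' chain_map: optional mapping chain -> role
#' ```
#'
#' @param path YAML config file.
#' @return validated RunConfig list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, base_dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg config list (as from YAML).
#' @param base_dir directory relative paths resolve against.
#' @export
validate_run_config <- function(cfg, base_dir = ".") {
  defaults <- list(variant = "canonical", sampling_interval = 10,
                   window_start_fraction = 0.5, cutoff = 10, n_modes = 2,
                   kde_bandwidth = "scott", output = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$variant <- match.arg(cfg$variant, VARIANTS)
  if (is.null(cfg$topology)) stop("config: 'topology' is required")
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  cfg$topology <- resolve(cfg$topology)
  if (!file.exists(cfg$topology))
    stop("config: topology file not found: ", cfg$topology)
  if (is.null(cfg$trajectories) || !length(cfg$trajectories))
    stop("config: at least one trajectory is required")
  cfg$trajectories <- vapply(cfg$trajectories, resolve, character(1))
  missing <- cfg$trajectories[!file.exists(cfg$trajectories)]
  if (length(missing))
    stop("config: trajectory file(s) not found: ",
         paste(missing, collapse = ", "))
  if (cfg$cutoff <= 0) stop("config: cutoff must be positive")
  if (cfg$window_start_fraction < 0 || cfg$window_start_fraction >= 1)
    stop("config: window_start_fraction must be in [0, 1)")
  if (!is.null(cfg$region_table) && is.character(cfg$region_table)) {
    p <- resolve(cfg$region_table)
    # quote = "": primed histone roles (H3') contain apostrophes
    cfg$region_table <- utils::read.table(p, header = TRUE, sep = "\t",
                                          quote = "", stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$region_table)) validate_region_table(cfg$region_table)
  cfg$chain_map <- if (is.null(cfg$chain_map)) default_chain_map()
                   else unlist(cfg$chain_map)
  class(cfg) <- "RunConfig"
  cfg
}

#' Write a region table / config pair that round-trips bit-exactly
#' @param region_table data.frame as [default_region_table()].
#' @param path output TSV path.
#' @export
write_region_table <- function(region_table, path) {
  utils::write.table(region_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                               stage, paste0(..., collapse = " ")))
}

#' Run the full per-variant analysis
#'
#' Stages: read structure and trajectories -> whole-complex alignment ->
#' per-chain RMSD series -> histone-core alignment -> DNA RMSD + C1' RMSF ->
#' essential-dynamics PCA, projections and KDE landscape -> contact
#' frequency matrix -> alpha-helix occupancy. Deterministic for fixed
#' inputs.
#'
#' @param config RunConfig (or path to one).
#' @param verbose log one line per stage.
#' @param helix compute helix occupancy (needs full backbones; skipped
#'   automatically for bead-only topologies).
#' @return `ReportBundle` list with elements `rmsd`, `rmsf`, `modes`,
#'   `projections`, `landscape`, `contacts`, `helix`, `meta`.
#' @export
run_full_analysis <- function(config, verbose = FALSE, helix = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  rt <- if (is.null(config$region_table)) default_region_table()
        else config$region_table
  stage_log(verbose, "read", config$topology)
  st <- read_structure(config$topology, config$chain_map)
  topo <- st$topology
  ens <- read_trajectory(topo, config$trajectories, config$sampling_interval)
  window <- analysis_window(config$window_start_fraction)
  stage_log(verbose, "align(i)", n_atoms(topo), "atoms,",
            length(ens$trials), "trials")
  al1 <- align_ensemble(ens, "whole_complex", region_table = rt)
  rmsd <- rmsd_series(al1)
  stage_log(verbose, "align(ii)")
  al2 <- align_ensemble(ens, "histone_core_only", region_table = rt)
  dna_mask <- make_selection(topo, rt, "dna_c1p")
  rmsd_dna_ii <- rmsd_series(al2, groups = list(DNA_conv_ii = dna_mask))
  stage_log(verbose, "rmsf", length(dna_mask$indices), "nucleotides")
  rmsf <- rmsf_profile(al2, window, dna_mask)
  stage_log(verbose, "pca")
  modes <- compute_modes(al2, window, dna_mask)
  nm <- max(2L, config$n_modes)
  proj <- project_modes(al2, modes, seq_len(min(nm, ncol(modes$eigenvectors))))
  widx <- resolve_window(al2, window)
  win_rows <- rep(FALSE, nrow(proj))
  for (k in seq_along(widx))
    win_rows[proj$trial == k & proj$frame %in% widx[[k]]] <- TRUE
  bw <- if (identical(config$kde_bandwidth, "scott")) NULL
        else as.numeric(config$kde_bandwidth)
  landscape <- estimate_landscape(proj[win_rows, , drop = FALSE],
                                  bandwidth = bw)
  stage_log(verbose, "contacts")
  contacts <- contact_frequency(ens, dna_mask,
                                make_selection(topo, rt, "histone_ca"),
                                cutoff = config$cutoff, window = window)
  helix_tab <- NULL
  has_backbone <- all(c("N", "C", "O") %in% topo$atoms$atom_name)
  do_helix <- if (is.null(helix)) has_backbone else helix
  if (do_helix) {
    stage_log(verbose, "helix")
    helix_tab <- helix_occupancy(ens, window)
  }
  bundle <- list(rmsd = rmsd, rmsd_dna_ii = rmsd_dna_ii, rmsf = rmsf,
                 modes = modes, projections = proj,
                 projections_in_window = win_rows,
                 landscape = landscape, contacts = contacts,
                 helix = helix_tab,
                 meta = list(variant = config$variant,
                             window_start_fraction = config$window_start_fraction,
                             cutoff = config$cutoff,
                             n_trials = length(ens$trials),
                             topology = config$topology))
  class(bundle) <- "ReportBundle"
  if (!is.null(config$output)) write_report_bundle(bundle, config$output)
  bundle
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle for variant", x$meta$variant, "-",
      x$meta$n_trials, "trial(s)\n")
  cat("  mean DNA RMSF:", signif(mean(x$rmsf$rmsf_A), 4), "A;",
      "lambda1:", signif(x$modes$eigenvalues[1], 4), "A^2\n")
  invisible(x)
}

#' Write a report bundle as TSV tables plus a manifest
#'
#' @param bundle ReportBundle.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(bundle$rmsd, "rmsd.tsv"),
    wt(bundle$rmsd_dna_ii, "rmsd_dna_conv_ii.tsv"),
    wt(bundle$rmsf, "rmsf.tsv"),
    wt(data.frame(mode = seq_along(bundle$modes$eigenvalues),
                  eigenvalue_A2 = bundle$modes$eigenvalues),
       "eigenvalues.tsv"),
    wt(export_mode_arrows(bundle$modes, 1), "mode1_arrows.tsv"),
    wt(bundle$projections, "projections.tsv"))
  gr <- expand.grid(s1 = bundle$landscape$s1, s2 = bundle$landscape$s2)
  gr$density <- as.vector(bundle$landscape$density)
  paths <- c(paths, wt(gr, "landscape.tsv"))
  pc <- file.path(dir, "contacts.tsv")
  write_contact_tsv(bundle$contacts, pc)
  paths <- c(paths, pc)
  if (!is.null(bundle$helix)) paths <- c(paths, wt(bundle$helix, "helix.tsv"))
  meta <- bundle$meta
  meta$written <- format(Sys.time())
  manifest <- file.path(dir, "MANIFEST.tsv")
  utils::write.table(
    data.frame(file = basename(paths),
               md5 = vapply(paths, function(p)
                 as.character(tools::md5sum(p)), character(1)),
               variant = meta$variant,
               window_start_fraction = meta$window_start_fraction),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(meta, file.path(dir, "provenance.yaml"))
  invisible(manifest)
}

#' Compare variant bundles against the canonical one
#'
#' @param bundles named list of ReportBundle; one must be for the canonical
#'   variant.
#' @return list with per-variant `contact_difference` matrices (variant -
#'   canonical over shared labels) and an `rmsf_ratio` table.
#' @export
compare_variants <- function(bundles) {
  variants <- vapply(bundles, function(b) b$meta$variant, character(1))
  ic <- which(variants == "canonical")
  if (!length(ic)) stop("compare_variants: no canonical bundle present")
  canon <- bundles[[ic[1]]]
  out <- list(contact_difference = list(), rmsf_ratio = list())
  for (k in seq_along(bundles)) {
    if (k == ic[1]) next
    b <- bundles[[k]]
    nm <- if (!is.null(names(bundles)) && nzchar(names(bundles)[k]))
      names(bundles)[k] else b$meta$variant
    out$contact_difference[[nm]] <- matrix_difference(b$contacts,
                                                      canon$contacts)
    m <- merge(b$rmsf, canon$rmsf, by = c("chain", "residue_index"),
               suffixes = c("", "_canonical"))
    m$ratio <- m$rmsf_A / m$rmsf_A_canonical
    out$rmsf_ratio[[nm]] <- m[order(m$chain, m$residue_index), ]
  }
  out
}
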
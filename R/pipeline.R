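pipeline_defaults <- function() list(
  preset = NULL,            # synthetic preset name, or
  input = NULL,             # path to a trajectory file
  stages = c("generate"),   # any of generate, cluster, diffusion,
                            # undulations, rdf, contacts
  out_dir = NULL,           # output directory (NULL: return only)
  seed = 1L,
  box = NULL,               # optional, for consistency checks
  cutoff = 8.2,             # protein contact cutoff (nm)
  residue_cutoff = 0.7,     # residue contact cutoff (nm)
  grid = 0.5,               # height-field grid (nm)
  n_boot = 1000L,           # bootstrap iterations
  fit_range = c(1, 2000),   # MSD fit range (ns)
  discard_initial = 50,     # equilibration discard (ns)
  dt = 1,                   # frame spacing (ns)
  rdf_r_max = 12, rdf_dr = 0.1, rdf_leaflet = "both",
  residue_range = NULL,     # centroid residue range
  stride = 1L,              # cluster-analysis frame stride
  window = NULL,            # analysis frame window
  n_frames = NULL           # override the preset's trajectory length
)

#' Validate and normalize a pipeline configuration
#'
#' Fills in documented defaults (contact cutoff 8.2 nm, residue cutoff
#' 0.7 nm, grid 0.5 nm, 1000 bootstrap iterations, 1-2000 ns fit range,
#' 50 ns discard), rejects unknown keys with a closest-match suggestion,
#' and runs physical-consistency checks (cutoff versus box minimum-image
#' bound, fit range versus positivity). All violations are reported
#' together.
#'
#' @param config named list of overrides.
#' @return the normalized config (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  problems <- character(0)
  if (length(unknown)) {
    sug <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(defaults))
      if (min(d) <= 3) sprintf(" (did you mean '%s'?)",
                               names(defaults)[which.min(d)]) else ""
    }, "")
    problems <- c(problems,
                  sprintf("unknown key '%s'%s", unknown, sug))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  known_stages <- c("generate", "cluster", "diffusion", "undulations",
                    "rdf", "contacts")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad))
    problems <- c(problems, sprintf("unknown stage '%s'", bad))
  if (!is.null(cfg$box) && cfg$cutoff > min(cfg$box[1:2]) / 2)
    problems <- c(problems, sprintf(
      "cutoff %.2f nm exceeds half the smallest lateral box edge (%.2f nm)",
      cfg$cutoff, min(cfg$box[1:2]) / 2))
  if (cfg$fit_range[1] <= 0 || diff(cfg$fit_range) <= 0)
    problems <- c(problems, "fit_range must be increasing and positive")
  if (cfg$n_boot < 2) problems <- c(problems, "n_boot must be at least 2")
  for (k in c("cutoff", "residue_cutoff", "grid", "dt"))
    if (cfg[[k]] <= 0) problems <- c(problems, sprintf("%s must be positive", k))
  if (length(problems))
    mc_stop(paste0("invalid configuration:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "mc_validation_error")
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on either a named
#' synthetic preset or an input trajectory file: generation, cluster
#' analysis, diffusion analysis (MSD, anomalous fit, alpha profile),
#' undulation spectra, lateral RDF and residue contacts. All randomness
#' flows from `config$seed`, so a rerun with an identical config is
#' identical. Outputs (delimited text tables plus a machine-readable JSON
#' summary embedding the package version and the full normalized config)
#' are written under `config$out_dir` when set.
#'
#' @param config a list accepted by [validate_config()].
#' @return a `run_report` list: `config`, `summary` (fitted parameters and
#'   statistics per stage) and the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  set.seed(cfg$seed)
  results <- list()
  cfg_rec <- unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)]
  cfg_rec$out_dir <- NULL  # a location, not an analysis parameter
  summary <- list(package_version = as.character(utils::packageVersion("memcrowd")),
                  config = cfg_rec)
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) mc_stop(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      "mc_stage_error"))
    message(sprintf("[memcrowd] stage %-12s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  traj <- NULL
  if ("generate" %in% cfg$stages || !is.null(cfg$preset)) {
    traj <- t_stage("generate", {
      preset <- preset_registry(cfg$preset %||% "free-Brownian")
      generate_diffusive_trajectory(preset, n_frames = cfg$n_frames,
                                    seed = cfg$seed)
    })
    results$trajectory <- traj
    summary$generate <- list(preset = cfg$preset %||% "free-Brownian",
                             n_frames = n_frames(traj),
                             n_particles = n_particles(traj))
  } else if (!is.null(cfg$input)) {
    traj <- t_stage("read", read_trajectory(cfg$input))
  }
  if (is.null(traj))
    mc_stop("nothing to analyse: provide 'preset' or 'input'",
            "mc_validation_error")

  if ("cluster" %in% cfg$stages) {
    results$cluster <- t_stage("cluster", {
      cs <- cluster_size_series(traj, cutoff = cfg$cutoff,
                                stride = cfg$stride,
                                residue_range = cfg$residue_range)
      nf <- neighbor_fractions(cs, n_boot = cfg$n_boot, seed = cfg$seed + 1L)
      list(series = cs, neighbor_fractions = nf)
    })
    st <- results$cluster$series$stats
    summary$cluster <- list(
      mean_size_final = st$mean_size[nrow(st)],
      max_size = max(st$max_size),
      neighbor_fractions = results$cluster$neighbor_fractions)
  }

  if ("diffusion" %in% cfg$stages) {
    results$diffusion <- t_stage("diffusion", {
      traj2 <- remove_com_motion(if (traj$wrapped && is.null(traj$unwrapped))
        unwrap(traj) else traj)
      out <- list()
      for (sp in unique(traj$topology$species)) {
        m <- compute_msd(traj2, selection = sp,
                         discard_initial = cfg$discard_initial)
        fit <- fit_anomalous(m, cfg$fit_range[1], cfg$fit_range[2])
        prof <- alpha_profile(m)
        out[[sp]] <- list(msd = m, fit = fit, alpha_profile = prof)
      }
      out
    })
    summary$diffusion <- lapply(results$diffusion, function(r) list(
      D_alpha = r$fit$D_alpha, alpha = r$fit$alpha,
      sd = as.list(r$fit$sd)))
  }

  if ("undulations" %in% cfg$stages) {
    results$undulations <- t_stage("undulations", {
      win <- cfg$window %||% seq_len(n_frames(traj))
      fields <- lapply(win, function(f)
        height_field(traj, frame = f, g = cfg$grid))
      spec <- undulation_spectrum(fields)
      dens <- z_density_profile(traj, window = win)
      list(spectrum = spec, density = dens)
    })
    summary$undulations <- list(
      variance = attr(results$undulations$spectrum, "variance"),
      n_frames = attr(results$undulations$spectrum, "n_frames"))
  }

  if ("rdf" %in% cfg$stages) {
    results$rdf <- t_stage("rdf", lateral_rdf(
      traj, r_max = cfg$rdf_r_max, dr = cfg$rdf_dr,
      leaflet = cfg$rdf_leaflet, window = cfg$window))
    summary$rdf <- list(g_max = max(results$rdf$g),
                        r_at_max = results$rdf$r[which.max(results$rdf$g)])
  }

  if ("contacts" %in% cfg$stages) {
    results$contacts <- t_stage("contacts", residue_contact_frequencies(
      traj, cutoff = cfg$residue_cutoff, window = cfg$window))
    summary$contacts <- list(total = attr(results$contacts, "total"))
  }

  report <- structure(list(config = cfg, summary = summary,
                           results = results), class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  if (!is.null(res$trajectory))
    write_trajectory(res$trajectory, file.path(out_dir, "trajectory.mct"))
  if (!is.null(res$cluster)) {
    utils::write.table(res$cluster$series$stats,
                       file.path(out_dir, "cluster_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$cluster$neighbor_fractions,
                       file.path(out_dir, "neighbor_fractions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$cluster$series$size_label,
                       file.path(out_dir, "cluster_size_labels.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(res$diffusion)) for (sp in names(res$diffusion)) {
    utils::write.table(res$diffusion[[sp]]$msd,
                       file.path(out_dir, sprintf("msd_%s.tsv", sp)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$diffusion[[sp]]$alpha_profile,
                       file.path(out_dir, sprintf("alpha_profile_%s.tsv", sp)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$undulations)) {
    utils::write.table(res$undulations$spectrum,
                       file.path(out_dir, "undulation_spectrum.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$undulations$density,
                       file.path(out_dir, "z_density.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(res$rdf))
    utils::write.table(res$rdf, file.path(out_dir, "rdf.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$contacts))
    utils::write.table(res$contacts, file.path(out_dir, "residue_contacts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report$summary,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    dput(report$summary, file.path(out_dir, "summary.txt"))
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(x$config$stages, collapse = ", "), "\n")
  if (!is.null(x$summary$diffusion)) for (sp in names(x$summary$diffusion))
    cat(sprintf("  %s: D_alpha = %.4g, alpha = %.4g\n", sp,
                x$summary$diffusion[[sp]]$D_alpha,
                x$summary$diffusion[[sp]]$alpha))
  if (!is.null(x$summary$cluster))
    cat(sprintf("  clusters: final mean size %.2f, max %d\n",
                x$summary$cluster$mean_size_final, x$summary$cluster$max_size))
  invisible(x)
}
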
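#' Construct a named synthetic preset
#'
#' A preset bundles everything [generate_diffusive_trajectory()] needs:
#' species with their generalized diffusion coefficients and anomalous
#' exponents, trajectory length, frame spacing, box and seed.
#'
#' @param name preset name.
#' @param species list of [diffusion_spec()] entries.
#' @param n_frames number of frames.
#' @param dt frame spacing (ns).
#' @param box length-3 box (nm).
#' @param seed default RNG seed.
#' @return a `synthetic_preset`.
#' @export
mc_preset <- function(name, species, n_frames = 8192L, dt = 1,
                      box = c(137, 137, 20), seed = 1L) {
  stopifnot(is.list(species),
            all(vapply(species, inherits, TRUE, "diffusion_spec")))
  structure(list(name = name, species = species,
                 n_frames = as.integer(n_frames), dt = dt, box = box,
                 seed = seed),
            class = "synthetic_preset")
}

#' @export
print.synthetic_preset <- function(x, ...) {
  cat(sprintf("<synthetic_preset> '%s': %d frames, dt = %g ns\n",
              x$name, x$n_frames, x$dt))
  for (sp in x$species)
    cat(sprintf("  %-28s D_alpha = %-6g alpha = %-4g n = %d\n",
                sp$species, sp$d_alpha, sp$alpha, sp$n_particles))
  invisible(x)
}

#' Registry of synthetic presets parameterized from published membrane
#' simulations
#'
#' Named generator parameterizations matching the diffusion coefficients
#' reported for coarse-grained Kir2.2 / plasma-membrane systems: pure-PC
#' lipid and protein diffusion, plasma-membrane (PM_s) POPE and protein
#' diffusion, the PIP2+GM3-depleted (noPIP2G_s) POPE value, the
#' cholesterol-depleted (noChol_s) protein value, plus a subdiffusive
#' fractional-Brownian protein preset at the crowding-minimum exponent
#' alpha = 0.5 and a free-Brownian reference. Diffusion coefficients are
#' numeric values on the nm^2/ns^alpha scale, matching the published
#' diffusion tables digit for digit.
#'
#' Lipid presets use 1000 particles and protein presets 500; 8192 frames at
#' 1 ns (16384 for the free-Brownian reference so long lags are resolved).
#'
#' @param name optional single preset name to look up.
#' @return the named `synthetic_preset`, or the full named list when `name`
#'   is `NULL`.
#' @export
preset_registry <- function(name = NULL) {
  reg <- list(
    mc_preset("PC-lipid",
              list(diffusion_spec("PC-lipid", 37, 1, 1000L))),
    mc_preset("PM_s-POPE",
              list(diffusion_spec("POPE-lipid", 10, 1, 1000L))),
    mc_preset("noPIP2G_s-POPE",
              list(diffusion_spec("POPE-lipid", 13, 1, 1000L))),
    mc_preset("PC-protein",
              list(diffusion_spec("protein", 4, 1, 500L))),
    mc_preset("PM_s-protein",
              list(diffusion_spec("protein", 0.4, 1, 500L))),
    mc_preset("noChol_s-protein",
              list(diffusion_spec("protein", 1.1, 1, 500L))),
    mc_preset("crowded-protein-subdiffusive",
              list(diffusion_spec("protein", 1, 0.5, 500L))),
    mc_preset("free-Brownian",
              list(diffusion_spec("protein", 1, 1, 500L)),
              n_frames = 16384L)
  )
  names(reg) <- vapply(reg, `[[`, "", "name")
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    mc_stop(sprintf("unknown preset '%s'; available: %s", name,
                    paste(names(reg), collapse = ", ")),
            "mc_lookup_error")
  reg[[name]]
}
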
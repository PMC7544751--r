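# Analog photon transport with per-region energy-deposition tallies.
# Kerma approximation: energy transferred to secondary electrons is
# deposited at the interaction point; no electron transport.

#' Transport settings
#'
#' @param cutoff_MeV photon energy cutoff; a photon below it deposits its
#'   remaining energy locally. Must lie in [0.001, 0.1] MeV.
#' @param max_crossings abort a history after this many boundary crossings
#'   (guards against geometry leaks).
#' @param rayleigh enable coherent (Rayleigh) scattering. Off by default:
#'   elastic scattering moves no energy and barely perturbs 511 keV photon
#'   paths in this geometry.
#' @param interactions master switch; `FALSE` turns the medium transparent
#'   (useful for geometry-only checks).
#' @return `hd_settings` object.
#' @export
transport_settings <- function(cutoff_MeV = 0.010, max_crossings = 1000,
                               rayleigh = FALSE, interactions = TRUE) {
  if (cutoff_MeV < 0.001 || cutoff_MeV > 0.1)
    stop("cutoff_MeV must lie in [0.001, 0.1]")
  stopifnot(max_crossings > 0)
  structure(list(cutoff_MeV = cutoff_MeV,
                 max_crossings = as.integer(max_crossings),
                 rayleigh = isTRUE(rayleigh),
                 interactions = isTRUE(interactions)),
            class = "hd_settings")
}

#' F-18 syringe source description
#' @param nuclide an `hd_nuclide`.
#' @param region source region name in the scene.
#' @param deterministic_first pin the first decay to the source center.
#' @export
source_f18 <- function(nuclide = nuclide_f18(),
                       region = "syringe_interior",
                       deterministic_first = FALSE) {
  structure(list(type = "decay", nuclide = nuclide, region = region,
                 deterministic_first = deterministic_first),
            class = "hd_source")
}

#' Monoenergetic isotropic point-photon source
#'
#' One photon per history; used for benchmark checks (inverse-square,
#' attenuation) rather than the syringe scenario.
#' @param point emission point (cm).
#' @param energy_MeV photon energy.
#' @export
source_point_photons <- function(point = c(0, 0, 0), energy_MeV = 0.511) {
  structure(list(type = "photon", point = as.numeric(point),
                 energy = energy_MeV), class = "hd_source")
}

.source_cpp <- function(source, scene) {
  if (source$type == "decay") {
    i <- match(source$region, scene$names)
    if (is.na(i)) stop("scene has no region named '", source$region, "'")
    list(type = 0L, region = i,
         deterministic_first = isTRUE(source$deterministic_first),
         beta_fraction = source$nuclide$beta_plus_fraction,
         beta_endpoint = source$nuclide$beta_endpoint_MeV)
  } else {
    list(type = 1L, point = source$point, energy = source$energy)
  }
}

#' Run decay histories and tally energy deposition
#'
#' Samples `n` decay (or single-photon) histories, transports every
#' annihilation photon through the scene, and returns a per-region tally
#' with history-by-history statistics.
#'
#' @param n number of histories (decays for the F-18 source).
#' @param scene an `hd_scene`.
#' @param settings an [transport_settings] object.
#' @param source an [source_f18] or [source_point_photons] object.
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   the run is reproducible.
#' @return `dose_tally` object.
#' @export
run_histories <- function(n, scene, settings = transport_settings(),
                          source = source_f18(), seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    nr <- length(scene$names)
    res <- list(deposit_MeV = numeric(nr), deposit_sq_MeV2 = numeric(nr),
                histories = 0L, n_photons = 0, aborted = 0, exit_MeV = 0,
                emitted_MeV = 0, max_residual_MeV = 0)
  } else {
    res <- cpp_run_histories(as.integer(n), scene$matrix,
                             .mat_tables_cpp(), .source_cpp(source, scene),
                             settings$cutoff_MeV, settings$max_crossings,
                             settings$rayleigh, settings$interactions)
  }
  structure(list(region = scene$names, scoring = scene$scoring,
                 deposit_MeV = res$deposit_MeV,
                 deposit_sq_MeV2 = res$deposit_sq_MeV2,
                 histories = res$histories, n_photons = res$n_photons,
                 aborted = res$aborted, exit_MeV = res$exit_MeV,
                 emitted_MeV = res$emitted_MeV,
                 max_residual_MeV = res$max_residual_MeV),
            class = "dose_tally")
}

#' Merge tallies from independent runs
#' @param ... `dose_tally` objects over the same scene.
#' @return merged `dose_tally`.
#' @export
merge_tallies <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], "dose_tally"))
    ts <- ts[[1]]
  stopifnot(length(ts) >= 1L)
  out <- ts[[1]]
  for (t in ts[-1]) {
    stopifnot(identical(t$region, out$region))
    out$deposit_MeV <- out$deposit_MeV + t$deposit_MeV
    out$deposit_sq_MeV2 <- out$deposit_sq_MeV2 + t$deposit_sq_MeV2
    out$histories <- out$histories + t$histories
    out$n_photons <- out$n_photons + t$n_photons
    out$aborted <- out$aborted + t$aborted
    out$exit_MeV <- out$exit_MeV + t$exit_MeV
    out$emitted_MeV <- out$emitted_MeV + t$emitted_MeV
    out$max_residual_MeV <- max(out$max_residual_MeV, t$max_residual_MeV)
  }
  out
}

# History-by-history standard deviation of the per-region total deposit.
tally_sigma_MeV <- function(tally) {
  n <- tally$histories
  if (n < 2) return(rep(NA_real_, length(tally$region)))
  s <- tally$deposit_MeV
  s2 <- tally$deposit_sq_MeV2
  v <- pmax(0, (s2 - s^2 / n)) * n / (n - 1)
  sqrt(v)
}

#' @export
as.data.frame.dose_tally <- function(x, ...) {
  data.frame(region = x$region, scoring = x$scoring,
             energy_MeV = x$deposit_MeV, sigma_MeV = tally_sigma_MeV(x),
             histories = rep(x$histories, length(x$region)),
             stringsAsFactors = FALSE)
}

#' @export
print.dose_tally <- function(x, ...) {
  cat("<dose_tally>", x$histories, "histories,", x$n_photons, "photons,",
      x$aborted, "aborted\n")
  df <- as.data.frame(x)
  print(df[df$scoring | df$energy_MeV > 0, ], ...)
  invisible(x)
}

#' Transport a single photon
#'
#' Follows one photon until absorption, cutoff or world exit. Mainly a
#' validation surface: the returned interaction count and first-interaction
#' distance support mean-free-path and narrow-beam attenuation checks.
#'
#' @param scene an `hd_scene`.
#' @param position start point (cm), inside the world.
#' @param direction unit direction.
#' @param energy_MeV initial photon energy.
#' @param settings an [transport_settings] object.
#' @return list: per-region deposits (named, MeV), `exit_MeV`,
#'   `n_interactions`, `first_interaction_cm` (-1 when none), `aborted`.
#' @export
transport_photon <- function(scene, position, direction, energy_MeV = 0.511,
                             settings = transport_settings()) {
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-6) stop("direction must be normalized")
  res <- cpp_transport_photon(scene$matrix, .mat_tables_cpp(),
                              as.numeric(position), as.numeric(direction),
                              energy_MeV, settings$cutoff_MeV,
                              settings$max_crossings, settings$rayleigh,
                              settings$interactions)
  dep <- res$deposit_MeV
  names(dep) <- scene$names
  list(deposit_MeV = dep, exit_MeV = res$exit_MeV,
       n_interactions = res$n_interactions,
       first_interaction_cm = res$first_interaction_cm,
       aborted = res$aborted)
}

#' Sample one photon interaction
#'
#' Channel chosen proportional to the channel attenuation coefficients at
#' the photon energy; photoelectric absorbs fully, Compton scatters with
#' Klein-Nishina angle/energy, coherent (if enabled) deflects without
#' energy loss. A photon below the cutoff is absorbed locally.
#'
#' @param energy_MeV photon energy.
#' @param material material name.
#' @param settings an [transport_settings] object.
#' @return list: `deposit_MeV`, `energy_MeV` (scattered photon), `costheta`
#'   (`NA` on absorption), `alive`, `channel`.
#' @export
step_interaction <- function(energy_MeV, material,
                             settings = transport_settings()) {
  if (energy_MeV < settings$cutoff_MeV)
    return(list(deposit_MeV = energy_MeV, energy_MeV = 0, costheta = NA,
                alive = FALSE, channel = "cutoff"))
  mu_pe <- lookup_mu(material, energy_MeV, "photoelectric")
  mu_inc <- lookup_mu(material, energy_MeV, "incoherent")
  mu_coh <- if (settings$rayleigh)
    lookup_mu(material, energy_MeV, "coherent") else 0
  r <- cpp_interact(energy_MeV, mu_pe, mu_inc, mu_coh)
  list(deposit_MeV = r$deposit, energy_MeV = r$energy,
       costheta = r$costheta, alive = r$alive, channel = r$channel)
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#' @param energy_MeV photon energy.
#' @param n number of draws.
#' @return data.frame with `costheta` and scattered energy `energy_MeV`.
#' @export
sample_compton <- function(energy_MeV, n) {
  m <- cpp_sample_kn(energy_MeV, n)
  data.frame(costheta = m[, 1], energy_MeV = m[, 2])
}
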
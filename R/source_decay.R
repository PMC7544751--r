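# F-18 decay source: decay positions in the syringe, beta-plus spectrum,
# positron termination and annihilation-photon pairs.

#' Nuclide specification
#'
#' @param name label.
#' @param half_life_s physical half-life in seconds.
#' @param beta_plus_fraction branching fraction to beta-plus (the remainder
#'   is electron capture, which deposits nothing here).
#' @param beta_endpoint_MeV beta-plus spectrum endpoint energy.
#' @return `hd_nuclide` object.
#' @export
nuclide_spec <- function(name, half_life_s, beta_plus_fraction,
                         beta_endpoint_MeV) {
  stopifnot(half_life_s > 0, beta_plus_fraction >= 0,
            beta_plus_fraction <= 1, beta_endpoint_MeV > 0)
  structure(list(name = name, half_life_s = half_life_s,
                 beta_plus_fraction = beta_plus_fraction,
                 beta_endpoint_MeV = beta_endpoint_MeV),
            class = "hd_nuclide")
}

#' Fluorine-18
#'
#' Half-life 110 min (6600 s); beta-plus branching 0.967 with electron
#' capture remainder; allowed-spectrum endpoint 0.6335 MeV.
#' @export
nuclide_f18 <- function() nuclide_spec("F-18", 6600, 0.967, 0.6335)

#' Handling scenario: activity and exposure time
#'
#' @param activity_Bq source activity (Bq).
#' @param handling_time_s working time with the open source (s).
#' @param decay_correction if `TRUE`, account for decay of the source over
#'   the handling time instead of assuming constant activity.
#' @return `hd_scenario` object.
#' @export
exposure_scenario <- function(activity_Bq, handling_time_s,
                              decay_correction = FALSE) {
  stopifnot(activity_Bq >= 0, handling_time_s >= 0)
  structure(list(activity_Bq = activity_Bq,
                 handling_time_s = handling_time_s,
                 decay_correction = decay_correction),
            class = "hd_scenario")
}

#' Number of decays during a handling scenario
#'
#' Constant-activity mode returns A * t (the reference convention: 300 MBq
#' over 120 s gives 3.6e10 decays). Decay-corrected mode integrates
#' A0 exp(-lambda u) over the handling time: (A0/lambda)(1 - exp(-lambda t)).
#'
#' @param scenario an [exposure_scenario].
#' @param nuclide an `hd_nuclide` (needed for decay correction).
#' @return expected decay count.
#' @export
decays_from_activity <- function(scenario, nuclide = nuclide_f18()) {
  stopifnot(inherits(scenario, "hd_scenario"))
  if (!scenario$decay_correction)
    return(scenario$activity_Bq * scenario$handling_time_s)
  lambda <- log(2) / nuclide$half_life_s
  scenario$activity_Bq / lambda *
    (1 - exp(-lambda * scenario$handling_time_s))
}

#' Sample decay positions inside the source volume
#'
#' Uniform over the syringe-interior (liquid) region. With
#' `deterministic_first = TRUE` the first position is the exact region
#' center, mirroring the reference convention that the first atom sits at
#' the syringe center.
#'
#' @param scene an `hd_scene` containing a region named `region`.
#' @param n number of positions.
#' @param deterministic_first pin the first position to the region center.
#' @param region source region name.
#' @return n x 3 matrix of xyz positions (cm).
#' @export
sample_decay_position <- function(scene, n = 1,
                                  deterministic_first = FALSE,
                                  region = "syringe_interior") {
  i <- match(region, scene$names)
  if (is.na(i)) stop("scene has no region named '", region, "'")
  pts <- cpp_sample_in_shape(scene$matrix[i, ], n)
  if (deterministic_first && n >= 1)
    pts[1, ] <- scene$matrix[i, c("cx", "cy", "cz")]
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Sample positron kinetic energies from the allowed beta-plus spectrum
#'
#' Rejection sampling from N(T) proportional to p E_tot (Q - T)^2 with the
#' Fermi function approximated as 1 (see [beta_spectrum_density]).
#'
#' @param n number of draws.
#' @param nuclide an `hd_nuclide`.
#' @return kinetic energies in MeV, all in (0, endpoint).
#' @export
sample_beta_energy <- function(n, nuclide = nuclide_f18()) {
  cpp_sample_beta(nuclide$beta_endpoint_MeV, n)
}

#' Sample decay events
#'
#' @param scene an `hd_scene`.
#' @param n number of decays.
#' @param nuclide an `hd_nuclide`.
#' @param deterministic_first pin the first decay to the source center.
#' @return data.frame with position, branch (`"beta_plus"` or `"ec"`) and
#'   positron kinetic energy (`NA` for electron capture).
#' @export
sample_decay_events <- function(scene, n, nuclide = nuclide_f18(),
                                deterministic_first = FALSE) {
  pos <- sample_decay_position(scene, n, deterministic_first)
  branch <- ifelse(runif(n) < nuclide$beta_plus_fraction, "beta_plus", "ec")
  energy <- rep(NA_real_, n)
  nb <- sum(branch == "beta_plus")
  if (nb > 0) energy[branch == "beta_plus"] <- sample_beta_energy(nb, nuclide)
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], branch = branch,
             positron_energy_MeV = energy, stringsAsFactors = FALSE)
}

#' Annihilate a positron: back-to-back 511 keV photon pair
#'
#' The positron is terminated at its creation point (local annihilation;
#' its sub-mm to 2 mm range in water is small against the geometry). The
#' pair direction is isotropic; the two photons are exactly antiparallel,
#' 0.511 MeV each. Calling this for an electron-capture event is an error:
#' that branch emits no photons.
#'
#' @param event one row of [sample_decay_events] output (or a list with
#'   `x`, `y`, `z` and `branch`).
#' @return data.frame of two photons: position, direction, energy.
#' @export
annihilate <- function(event) {
  if (!identical(event$branch, "beta_plus"))
    stop("annihilate() requires a beta-plus event; the EC branch emits no photons")
  ct <- runif(1, -1, 1)
  st <- sqrt(1 - ct^2)
  phi <- runif(1, 0, 2 * pi)
  u <- c(st * cos(phi), st * sin(phi), ct)
  data.frame(x = rep(event$x, 2), y = rep(event$y, 2), z = rep(event$z, 2),
             ux = c(u[1], -u[1]), uy = c(u[2], -u[2]), uz = c(u[3], -u[3]),
             energy_MeV = c(.ME_C2, .ME_C2))
}
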
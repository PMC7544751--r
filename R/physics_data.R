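#' @useDynLib handdose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats integrate median rnorm runif sd lm coef setNames approx residuals
#' @importFrom utils read.csv write.csv
NULL

# Electron rest energy (MeV) and MeV -> J.
.ME_C2 <- 0.51099895
.MEV_TO_J <- 1.602176634e-13

#' Define a material
#'
#' A material is a named element mix with a bulk density. Mass fractions must
#' sum to one; density must be positive.
#'
#' @param name label used to reference the material from regions.
#' @param density bulk density in g/cm^3.
#' @param composition named numeric vector of element mass fractions.
#' @param z_over_a effective electrons per atomic mass unit (sum of
#'   w_i * Z_i / A_i over the mix); used to build the incoherent-scattering
#'   channel of the attenuation table.
#' @return an object of class `hd_material`.
#' @export
hd_material <- function(name, density, composition, z_over_a) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("material density must be a single positive number")
  if (length(composition) == 0L || is.null(names(composition)))
    stop("composition must be a non-empty named vector of mass fractions")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 within 1e-6 (got ",
         format(sum(composition)), ")")
  structure(list(name = name, density = density,
                 composition = composition, z_over_a = z_over_a),
            class = "hd_material")
}

#' Built-in material library
#'
#' Air, water, ICRP-style soft tissue (used for all hand regions) and
#' tungsten. Compositions follow the standard reference mixes; the soft
#' tissue entry stands in for skin, which the hand model is filled with
#' uniformly.
#'
#' @return named list of [hd_material] objects.
#' @export
material_library <- function() {
  list(
    air = hd_material("air", 0.0012048,
      c(N = 0.7552, O = 0.2318, Ar = 0.0128, C = 0.0002), 0.4992),
    water = hd_material("water", 1.0,
      c(H = 0.111894, O = 0.888106), 0.55509),
    soft_tissue = hd_material("soft_tissue", 1.09,
      c(H = 0.100, C = 0.204, N = 0.042, O = 0.645, other = 0.009), 0.549),
    tungsten = hd_material("tungsten", 19.3, c(W = 1.0), 0.40250)
  )
}

#' Klein-Nishina total cross-section
#'
#' Total Compton cross-section per electron for a free electron at rest,
#' in barn. `k` below is E / (m_e c^2).
#'
#' @param energy_MeV photon energy in MeV.
#' @return cross-section in barn per electron.
#' @export
kn_total_cross_section <- function(energy_MeV) {
  k <- energy_MeV / .ME_C2
  two_pi_re2 <- 0.49894 # 2 pi r_e^2, barn
  l <- log(1 + 2 * k)
  two_pi_re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - l / k) +
                  l / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

#' Klein-Nishina differential cross-section
#'
#' d(sigma)/d(cos theta) per electron (barn), un-normalised over azimuth.
#' Used as the analytic reference density for goodness-of-fit checks of the
#' Compton angle sampler.
#'
#' @param energy_MeV photon energy in MeV.
#' @param costheta cosine of the scattering angle.
#' @return differential cross-section values (barn per unit cos theta).
#' @export
kn_differential <- function(energy_MeV, costheta) {
  k <- energy_MeV / .ME_C2
  r <- 1 / (1 + k * (1 - costheta)) # E'/E
  pi_re2 <- 0.24947                 # pi r_e^2, barn
  pi_re2 * r^2 * (r + 1 / r - (1 - costheta^2))
}

# Mean fraction of the photon energy transferred to the Compton electron,
# from numerical integration of the KN differential cross-section.
kn_transfer_fraction <- function(energy_MeV) {
  k <- energy_MeV / .ME_C2
  num <- integrate(function(ct) kn_differential(energy_MeV, ct) *
                     (1 - 1 / (1 + k * (1 - ct))), -1, 1,
                   rel.tol = 1e-9)$value
  den <- integrate(function(ct) kn_differential(energy_MeV, ct), -1, 1,
                   rel.tol = 1e-9)$value
  num / den
}

#' Allowed beta-plus spectrum density
#'
#' Unnormalised allowed-shape density N(T) = p E_tot (Q - T)^2 with the
#' Fermi function approximated as 1; T is the positron kinetic energy.
#'
#' @param kinetic_MeV positron kinetic energy (MeV).
#' @param endpoint_MeV spectrum endpoint Q (MeV).
#' @return density values (zero outside (0, Q)).
#' @export
beta_spectrum_density <- function(kinetic_MeV, endpoint_MeV) {
  et <- kinetic_MeV + .ME_C2
  p <- sqrt(pmax(0, et^2 - .ME_C2^2))
  d <- p * et * (endpoint_MeV - kinetic_MeV)^2
  d[kinetic_MeV <= 0 | kinetic_MeV >= endpoint_MeV] <- 0
  d
}

# ---------------------------------------------------------------------------
# Embedded attenuation anchors (mass attenuation, cm^2/g, coherent included
# in `total`).  Standard reference tabulation values on a fixed grid; the
# channel split is reconstructed as: incoherent from the Klein-Nishina
# cross-section times electrons per gram, a small power-law coherent term,
# and photoelectric as the remainder (floored at a tiny positive value).
# mu_en anchors are tabulated for water/air and derived as
# photoelectric + incoherent * KN-transfer-fraction elsewhere.
.atten_anchors <- local({
  e_lowz <- c(0.010, 0.015, 0.020, 0.030, 0.040, 0.050, 0.060, 0.080,
              0.100, 0.150, 0.200, 0.300, 0.400, 0.500, 0.511, 0.600,
              0.800, 1.000)
  water_tot <- c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                 0.1837, 0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.0969,
                 0.0960, 0.0896, 0.0786, 0.0707)
  water_en <- c(4.944, 1.374, 0.5503, 0.1557, 0.0695, 0.0422, 0.0319,
                0.0262, 0.0256, 0.0277, 0.0297, 0.0319, 0.0328, 0.0330,
                0.0330, 0.0329, 0.0321, 0.0309)
  air_tot <- c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875,
               0.1662, 0.1541, 0.1356, 0.1233, 0.1067, 0.0954, 0.0871,
               0.0863, 0.0806, 0.0707, 0.0636)
  air_en <- c(4.742, 1.334, 0.5389, 0.1537, 0.0683, 0.0410, 0.0304,
              0.0241, 0.0233, 0.0250, 0.0268, 0.0287, 0.0295, 0.0297,
              0.0297, 0.0296, 0.0289, 0.0278)
  # Tungsten grid carries the K edge (69.5 keV) as a split node pair.
  e_w <- c(0.010, 0.015, 0.020, 0.030, 0.040, 0.050, 0.060, 0.0695,
           0.0696, 0.080, 0.100, 0.150, 0.200, 0.300, 0.400, 0.500,
           0.511, 0.600, 0.800, 1.000)
  w_tot <- c(96.9, 130.0, 65.7, 22.7, 10.67, 5.95, 3.71, 2.55, 11.23,
             7.81, 4.438, 1.581, 0.7844, 0.3238, 0.1925, 0.1378, 0.1341,
             0.1093, 0.0787, 0.0618)
  list(
    air = list(E = e_lowz, total = air_tot, mu_en = air_en, coh0 = 0.0034),
    water = list(E = e_lowz, total = water_tot, mu_en = water_en,
                 coh0 = 0.0037),
    soft_tissue = list(E = e_lowz, total = water_tot * 0.989,
                       mu_en = water_en * 0.99, coh0 = 0.0037),
    tungsten = list(E = e_w, total = w_tot, mu_en = NULL, coh0 = 0.30)
  )
})

# Insert log-midpoints between anchors (log-log interpolated) to densify the
# grid; interpolation is exact for the added nodes by construction.
.densify <- function(e, y) {
  le <- log(e); ly <- log(y)
  mid_e <- exp((le[-1] + le[-length(le)]) / 2)
  mid_y <- exp((ly[-1] + ly[-length(ly)]) / 2)
  ord <- order(c(e, mid_e))
  list(E = c(e, mid_e)[ord], y = c(y, mid_y)[ord])
}

# Build the full channelised table for one material.  All values mass
# coefficients (cm^2/g); linear coefficients are density * these.
.build_table <- function(anchor, z_over_a) {
  d <- .densify(anchor$E, anchor$total)
  e <- d$E
  total <- d$y
  inc <- vapply(e, kn_total_cross_section, 0) * 0.602214 * z_over_a
  coh <- anchor$coh0 * (0.1 / e)^2
  coh <- pmin(coh, 0.45 * total) # keep the split physical near edges
  pe <- pmax(total - inc - coh, 1e-8)
  total_sum <- pe + inc + coh
  if (!is.null(anchor$mu_en)) {
    den <- .densify(anchor$E, anchor$mu_en)
    mu_en <- den$y
  } else {
    tf <- vapply(e, kn_transfer_fraction, 0)
    mu_en <- pe + inc * tf
  }
  data.frame(energy_MeV = e, photoelectric = pe, incoherent = inc,
             coherent = coh, total = total_sum,
             total_without_coherent = pe + inc, mu_en = mu_en)
}

.handdose_cache <- new.env(parent = emptyenv())

.atten_tables <- function() {
  if (!exists("tables", envir = .handdose_cache)) {
    lib <- material_library()
    tabs <- lapply(names(.atten_anchors), function(nm)
      .build_table(.atten_anchors[[nm]], lib[[nm]]$z_over_a))
    names(tabs) <- names(.atten_anchors)
    assign("tables", tabs, envir = .handdose_cache)
  }
  get("tables", envir = .handdose_cache)
}

#' Attenuation table for a material
#'
#' Energy grid (MeV, ascending, 10 keV to 1 MeV) with mass interaction
#' coefficients per channel (cm^2/g): photoelectric, incoherent (Compton),
#' coherent (Rayleigh), total, total without coherent, and the mass
#' energy-absorption coefficient.
#'
#' @param material material name or [hd_material] object.
#' @return data.frame, one row per grid node.
#' @export
attenuation_table <- function(material) {
  nm <- if (inherits(material, "hd_material")) material$name else material
  tabs <- .atten_tables()
  if (!nm %in% names(tabs))
    stop("unknown material: ", nm)
  tabs[[nm]]
}

.mu_channels <- c("photoelectric", "incoherent", "coherent", "total",
                  "total_without_coherent", "mu_en")

#' Look up a linear attenuation coefficient
#'
#' Log-log interpolation between bracketing grid nodes; exact at nodes.
#'
#' @param material material name or [hd_material].
#' @param energy_MeV photon energy, must lie within the grid span.
#' @param channel one of `r paste(shQuote(handdose:::.mu_channels), collapse = ", ")`.
#' @param quantity `"linear"` for mu in 1/cm (mass coefficient times
#'   density) or `"mass"` for cm^2/g.
#' @return coefficient value(s), vectorised over `energy_MeV`.
#' @export
lookup_mu <- function(material, energy_MeV,
                      channel = "total_without_coherent",
                      quantity = c("linear", "mass")) {
  quantity <- match.arg(quantity)
  nm <- if (inherits(material, "hd_material")) material$name else material
  lib <- material_library()
  if (!nm %in% names(lib)) stop("unknown material: ", nm)
  if (!channel %in% .mu_channels)
    stop("unknown channel: ", channel)
  tab <- attenuation_table(nm)
  e <- tab$energy_MeV
  if (any(energy_MeV < min(e) | energy_MeV > max(e)))
    stop("energy outside attenuation grid span [",
         format(min(e)), ", ", format(max(e)), "] MeV")
  y <- tab[[channel]]
  lx <- log(e); ly <- log(y)
  out <- exp(approx(lx, ly, xout = log(energy_MeV), rule = 1)$y)
  if (quantity == "linear") out <- out * lib[[nm]]$density
  out
}

# Marshalled linear-mu tables (log-log) for the C++ kernel, one entry per
# material in library order.
.mat_tables_cpp <- function() {
  if (!exists("cpp_tabs", envir = .handdose_cache)) {
    lib <- material_library()
    tabs <- lapply(names(lib), function(nm) {
      tab <- attenuation_table(nm)
      rho <- lib[[nm]]$density
      list(logE = log(tab$energy_MeV),
           log_pe = log(tab$photoelectric * rho),
           log_inc = log(tab$incoherent * rho),
           log_coh = log(tab$coherent * rho))
    })
    names(tabs) <- names(lib)
    assign("cpp_tabs", tabs, envir = .handdose_cache)
  }
  get("cpp_tabs", envir = .handdose_cache)
}

#' Compton scattered photon energy
#'
#' Closed-form Compton kinematics: E' = E / (1 + k (1 - cos theta)) with
#' k = E / (m_e c^2).
#'
#' @param energy_MeV incident photon energy.
#' @param costheta cosine of the scattering angle.
#' @return scattered photon energy in MeV.
#' @export
compton_scattered_energy <- function(energy_MeV, costheta) {
  energy_MeV / (1 + energy_MeV / .ME_C2 * (1 - costheta))
}
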
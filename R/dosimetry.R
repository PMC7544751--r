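# Dose pipeline: tallies -> absorbed dose -> dose-vs-decays slope ->
# extrapolation to the handling scenario -> Hp(0.07) -> normalized stats.

#' Absorbed doses from a tally
#'
#' D = deposited energy / region mass for every scoring region. The finger
#' label of a `<finger>_distal` region is the fingertip scoring region used
#' throughout the pipeline.
#'
#' @param tally a `dose_tally`.
#' @param scene the `hd_scene` the tally was produced on.
#' @return data.frame: region, finger (NA for non-fingertip regions),
#'   n_decays, energy_MeV, dose_Gy, sigma_Gy, rel_sigma.
#' @export
dose_from_tally <- function(tally, scene) {
  stopifnot(inherits(tally, "dose_tally"), inherits(scene, "hd_scene"))
  keep <- which(scene$scoring)
  m <- scene$mass_kg[keep]
  if (any(m <= 0)) stop("scoring region with non-positive mass")
  e <- tally$deposit_MeV[keep]
  s <- tally_sigma_MeV(tally)[keep]
  dose <- e * .MEV_TO_J / m
  sig <- s * .MEV_TO_J / m
  reg <- scene$names[keep]
  finger <- ifelse(grepl("_distal$", reg), sub("_distal$", "", reg), NA)
  data.frame(region = reg, finger = finger,
             n_decays = rep(tally$histories, length(reg)),
             energy_MeV = e, dose_Gy = dose, sigma_Gy = sig,
             rel_sigma = ifelse(dose > 0, sig / dose, NA_real_),
             stringsAsFactors = FALSE)
}

#' Simulate the dose-response curve
#'
#' Runs `replicates` independent runs at each decay level, the protocol
#' behind the dose-versus-decays fit (reference protocol: levels 100,
#' 1000, 10000, ... repeated dozens of times and averaged).
#'
#' @param scene an `hd_scene`.
#' @param levels decay counts, ascending.
#' @param replicates independent runs per level.
#' @param settings transport settings.
#' @param source photon/decay source.
#' @param seed optional integer seed applied once before the sweep.
#' @return list with `points` (per replicate fingertip dose points),
#'   `averaged` (replicate-averaged dose per level and finger) and
#'   `merged_tallies` (one merged tally per level, highest level last).
#' @export
simulate_dose_curve <- function(scene, levels = c(100, 1000, 1e4, 1e5),
                                replicates = 20,
                                settings = transport_settings(),
                                source = source_f18(), seed = NULL) {
  stopifnot(all(diff(levels) > 0), all(levels > 0), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  pts <- list()
  merged <- list()
  for (lv in levels) {
    tallies <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      tallies[[r]] <- run_histories(lv, scene, settings, source)
      d <- dose_from_tally(tallies[[r]], scene)
      d <- d[!is.na(d$finger), c("finger", "n_decays", "dose_Gy", "sigma_Gy")]
      d$replicate <- r
      pts[[length(pts) + 1]] <- d
    }
    merged[[as.character(lv)]] <- merge_tallies(tallies)
  }
  points <- do.call(rbind, pts)
  avg <- do.call(rbind, lapply(split(points, list(points$finger,
                                                  points$n_decays)),
    function(g) data.frame(finger = g$finger[1], n_decays = g$n_decays[1],
                           dose_Gy = mean(g$dose_Gy),
                           sigma_Gy = sd(g$dose_Gy) / sqrt(nrow(g)))))
  avg <- avg[order(avg$finger, avg$n_decays), ]
  rownames(avg) <- NULL
  list(points = points, averaged = avg, merged_tallies = merged)
}

#' Fit the dose-versus-decays line for one finger
#'
#' Ordinary least squares of dose on decay count (unweighted, free
#' intercept). Replicate rows at the same level are averaged first.
#'
#' @param points data.frame with `n_decays` and `dose_Gy` (optionally
#'   `finger`, which must then be unique).
#' @return `slope_fit`: finger, slope (Gy/decay), intercept (Gy),
#'   r_squared.
#' @export
fit_dose_response <- function(points) {
  finger <- NA_character_
  if (!is.null(points$finger)) {
    u <- unique(points$finger)
    if (length(u) != 1L)
      stop("fit_dose_response() expects points for a single finger; ",
           "use fit_all_fingers()")
    finger <- u
  }
  agg <- tapply(points$dose_Gy, points$n_decays, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  if (length(x) < 3L || length(unique(x)) < 3L)
    stop("need at least 3 distinct decay levels to fit")
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(finger = finger, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_levels = length(x)),
            class = "slope_fit")
}

#' Fit dose-response lines for every finger
#' @param points data.frame with `finger`, `n_decays`, `dose_Gy` columns
#'   (e.g. `simulate_dose_curve()$points`).
#' @return named list of `slope_fit` objects.
#' @export
fit_all_fingers <- function(points) {
  fits <- lapply(split(points, points$finger), fit_dose_response)
  fits[intersect(.FINGERS, names(fits))]
}

#' Extrapolate a fitted slope to a decay count
#'
#' Dose = slope x decays, reported in mGy. The free intercept is a fit
#' diagnostic and is deliberately not used for the extrapolation.
#'
#' @param fit a `slope_fit`, or a bare slope in Gy/decay.
#' @param n_decays decay count (e.g. from [decays_from_activity]).
#' @return absorbed dose in mGy.
#' @export
extrapolate_dose <- function(fit, n_decays) {
  if (any(n_decays < 0)) stop("n_decays must be non-negative")
  slope <- if (inherits(fit, "slope_fit")) fit$slope else fit
  slope * n_decays * 1000
}

#' Convert absorbed dose to personal dose equivalent Hp(0.07)
#'
#' Hp(0.07) = D x Q with the photon radiation quality factor Q(L) = 1, so
#' the value in mSv numerically equals the absorbed dose in mGy.
#'
#' @param absorbed_dose_mGy absorbed dose in mGy.
#' @param quality_factor Q, must be positive.
#' @return Hp(0.07) in mSv.
#' @export
hp007 <- function(absorbed_dose_mGy, quality_factor = 1) {
  if (quality_factor <= 0) stop("quality factor must be positive")
  if (any(absorbed_dose_mGy < 0)) stop("absorbed dose must be non-negative")
  absorbed_dose_mGy * quality_factor
}

#' Normalized-dose statistics
#'
#' Divides Hp(0.07) values by the handled activity and returns the range,
#' arithmetic mean and median (mid-interpolated for even counts), in
#' mSv/GBq.
#'
#' @param values_mSv Hp(0.07) values.
#' @param activity_GBq handled activity in GBq.
#' @return list: `range` (min, max), `mean`, `median`.
#' @export
normalized_stats <- function(values_mSv, activity_GBq) {
  if (activity_GBq <= 0) stop("activity must be positive")
  if (length(values_mSv) == 0) stop("no values supplied")
  v <- values_mSv / activity_GBq
  list(range = c(min(v), max(v)), mean = mean(v), median = median(v))
}

#' Assemble the per-finger dose report
#'
#' @param fits named list of `slope_fit` objects (or a named numeric vector
#'   of slopes in Gy/decay), one per finger.
#' @param scenario an [exposure_scenario].
#' @param nuclide an `hd_nuclide`.
#' @param quality_factor photon quality factor Q.
#' @return `dose_report` data.frame: finger, slope_Gy_per_decay, r_squared,
#'   dose_mGy, hp007_mSv, normalized_mSv_per_GBq.
#' @export
dose_report <- function(fits, scenario, nuclide = nuclide_f18(),
                        quality_factor = 1) {
  n <- decays_from_activity(scenario, nuclide)
  if (is.numeric(fits)) {
    slopes <- fits
    r2 <- rep(NA_real_, length(fits))
  } else {
    slopes <- vapply(fits, function(f) f$slope, 0)
    r2 <- vapply(fits, function(f) f$r_squared, 0)
  }
  dose <- extrapolate_dose(slopes, n)
  hp <- hp007(dose, quality_factor)
  act_GBq <- scenario$activity_Bq / 1e9
  out <- data.frame(finger = names(slopes), slope_Gy_per_decay = slopes,
                    r_squared = r2, dose_mGy = dose, hp007_mSv = hp,
                    normalized_mSv_per_GBq = hp / act_GBq,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  attr(out, "n_decays") <- n
  class(out) <- c("dose_report", "data.frame")
  out
}

#' @export
print.dose_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$dose_mGy <- round(y$dose_mGy, 3)      # 3 decimals, reporting convention
  y$hp007_mSv <- round(y$hp007_mSv, 3)
  y$normalized_mSv_per_GBq <- round(y$normalized_mSv_per_GBq, 2)
  print(y, ...)
  invisible(x)
}
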
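# Measured-vs-simulated comparison: TLD measurement records, per-finger
# range checks, and synthetic measurement fixtures.

.WORKER_ROLES <- c("nurse", "chemist", "physicist")

#' Load per-finger Hp(0.07) measurement records
#'
#' CSV dialect: comma-separated, dot decimal, mandatory header with columns
#' `worker_role`, `facility`, `finger`, `hp007_mSv`. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of validated records.
#' @export
load_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("worker_role", "finger", "hp007_mSv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("measurement file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$facility)) df$facility <- NA_character_
  if (nrow(df) == 0) return(df[, c("worker_role", "facility", "finger",
                                   "hp007_mSv")])
  bad_finger <- which(!df$finger %in% .FINGERS)
  bad_role <- which(!df$worker_role %in% .WORKER_ROLES)
  bad_dose <- which(!is.finite(df$hp007_mSv) | df$hp007_mSv < 0)
  msgs <- c(
    if (length(bad_finger))
      paste0("unknown finger ", sQuote(df$finger[bad_finger]), " at line ",
             bad_finger + 1L),
    if (length(bad_role))
      paste0("unknown worker_role ", sQuote(df$worker_role[bad_role]),
             " at line ", bad_role + 1L),
    if (length(bad_dose))
      paste0("invalid hp007_mSv at line ", bad_dose + 1L))
  if (length(msgs))
    stop("invalid measurement rows:\n  ", paste(msgs, collapse = "\n  "))
  df[, c("worker_role", "facility", "finger", "hp007_mSv")]
}

#' Compare simulated Hp(0.07) against measured ranges
#'
#' Per finger, the measured minimum and maximum (optionally restricted to
#' one worker role) bracket the simulated value. A simulated value equal to
#' a measured extreme counts as `within`; only a strict excess over the
#' maximum is flagged, with its size.
#'
#' @param simulated named numeric vector of simulated Hp(0.07) in mSv
#'   (names are finger labels), or a `dose_report`.
#' @param measurements data.frame from [load_measurements].
#' @param role_filter optional worker role; `NULL` compares against all.
#' @return `comparison_report` data.frame: finger, simulated_mSv,
#'   measured_min_mSv, measured_max_mSv, status (`within`, `below_min`,
#'   `exceeds_max`), excess_mSv.
#' @export
compare_doses <- function(simulated, measurements, role_filter = NULL) {
  if (inherits(simulated, "dose_report"))
    simulated <- setNames(simulated$hp007_mSv, simulated$finger)
  if (is.null(names(simulated)))
    stop("simulated values must be named by finger")
  m <- measurements
  if (!is.null(role_filter)) m <- m[m$worker_role == role_filter, ]
  rows <- list()
  for (f in names(simulated)) {
    mf <- m[m$finger == f, ]
    if (nrow(mf) == 0) {
      warning("no measurements for finger '", f, "'; omitted")
      next
    }
    lo <- min(mf$hp007_mSv); hi <- max(mf$hp007_mSv)
    s <- unname(simulated[f])
    status <- if (s > hi) "exceeds_max" else if (s < lo) "below_min"
              else "within"
    rows[[f]] <- data.frame(finger = f, simulated_mSv = s,
                            measured_min_mSv = lo, measured_max_mSv = hi,
                            status = status,
                            excess_mSv = if (s > hi) s - hi else 0,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no fingers could be compared; empty report")
    out <- data.frame(finger = character(), simulated_mSv = numeric(),
                      measured_min_mSv = numeric(),
                      measured_max_mSv = numeric(), status = character(),
                      excess_mSv = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Generate a synthetic measurement fixture
#'
#' Emulates a TLD measurement campaign: per worker and finger, values are
#' drawn log-normally around a simulated template with a given log-space
#' standard deviation. Stands in for physical measurements; it inherits the
#' template's geometry bias and carries no calibration error model.
#'
#' @param template named numeric vector of per-finger Hp(0.07) in mSv, or a
#'   `dose_report`.
#' @param n_workers number of synthetic workers.
#' @param spread standard deviation of log-values (> 0); the geometric
#'   standard deviation of the draws is `exp(spread)`.
#' @param roles worker roles to cycle through.
#' @param path when given, the fixture CSV is written there.
#' @return the records data.frame (invisibly when `path` is given).
#' @export
generate_fixture_measurements <- function(template, n_workers = 4,
                                          spread = 0.3,
                                          roles = c("nurse", "chemist"),
                                          path = NULL) {
  if (spread <= 0) stop("spread must be positive")
  if (inherits(template, "dose_report"))
    template <- setNames(template$hp007_mSv, template$finger)
  recs <- do.call(rbind, lapply(seq_len(n_workers), function(w) {
    data.frame(worker_role = roles[(w - 1) %% length(roles) + 1],
               facility = paste0("SYNTH-", w),
               finger = names(template),
               hp007_mSv = unname(template) *
                 exp(rnorm(length(template), 0, spread)),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  if (!is.null(path)) {
    write.csv(recs, path, row.names = FALSE, quote = FALSE)
    return(invisible(recs))
  }
  recs
}

#' Plain-text summary of a comparison report
#' @param object a `comparison_report`.
#' @param ... unused.
#' @export
summary.comparison_report <- function(object, ...) {
  lines <- vapply(seq_len(nrow(object)), function(i) {
    r <- object[i, ]
    sprintf("%-7s simulated %.3f mSv, measured %.3f-%.3f mSv: %s%s",
            r$finger, r$simulated_mSv, r$measured_min_mSv,
            r$measured_max_mSv, r$status,
            if (r$status == "exceeds_max")
              sprintf(" (excess %.3f mSv)", r$excess_mSv) else "")
  }, "")
  paste(lines, collapse = "\n")
}
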
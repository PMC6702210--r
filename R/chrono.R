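#' Read a radiocarbon calibration curve
#'
#' Accepts the standard ".14c" column layout: comment lines starting with
#' `#`, then comma- or whitespace-separated columns whose first three are
#' calendar age (cal BP), conventional radiocarbon age (BP) and the curve
#' standard deviation (years). The calendar grid must be strictly
#' monotone; values between knots are linearly interpolated.
#'
#' @param path File path.
#' @return Tibble: `cal_bp`, `c14_bp`, `sigma`, sorted by `cal_bp`.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", head(lines, 5)))) "," else ""
  df <- read.table(text = lines, sep = sep, header = FALSE,
                   strip.white = TRUE)[, 1:3]
  names(df) <- c("cal_bp", "c14_bp", "sigma")
  df <- df[order(df$cal_bp), ]
  if (anyDuplicated(df$cal_bp)) abort("calibration curve calendar grid must be strictly monotone")
  if (any(df$sigma < 0)) abort("curve sigma must be non-negative")
  tibble::as_tibble(df)
}

#' Calibrate a radiocarbon measurement
#'
#' Computes the posterior over calendar years on a 1-year grid under a
#' uniform calendar prior:
#' posterior(t) is proportional to
#' exp(-(m - mu(t))^2 / (2 (sigma^2 + sigma_curve(t)^2))),
#' normalized to unit mass. The reported interval set is the smallest
#' density-threshold region holding at least `hpd_mass` (default 95.4%)
#' of the posterior; endpoints are converted to calendar years CE
#' (CE = 1950 - cal BP) and rounded to the nearest 5 years, matching the
#' usual reporting convention. Intervals abutting the recent end of the
#' curve are flagged open-ended.
#'
#' @param age_bp Measured radiocarbon age, BP.
#' @param sigma Measurement standard deviation, years.
#' @param curve Calibration curve tibble (`cal_bp`, `c14_bp`, `sigma`).
#' @param hpd_mass Posterior mass of the interval set.
#' @param round_to Endpoint rounding, years (0 disables).
#' @param sample Sample name used in error messages.
#' @return An object of class `calibrated_date`: `density` (tibble
#'   `cal_bp`, `year_ce`, `density`), `intervals` (tibble `from`, `to`,
#'   `open_ended`, years CE), and the inputs.
#' @export
calibrate_c14 <- function(age_bp, sigma, curve, hpd_mass = 0.954,
                          round_to = 5, sample = "sample") {
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  mu <- approx(curve$cal_bp, curve$c14_bp, xout = grid)$y
  sc <- approx(curve$cal_bp, curve$sigma, xout = grid)$y
  s <- sqrt(sigma^2 + sc^2)
  if (all(abs(age_bp - mu) > 5 * s)) {
    abort(sprintf("measurement for '%s' does not overlap the calibration curve at +-5 sigma",
                  sample))
  }
  dens <- dnorm(age_bp, mu, s)
  dens <- dens / sum(dens)
  # smallest HPD set: take grid years in decreasing density order
  ord <- order(dens, decreasing = TRUE)
  k <- which(cumsum(dens[ord]) >= hpd_mass)[1]
  in_hpd <- logical(length(grid))
  in_hpd[ord[seq_len(k)]] <- TRUE
  runs <- rle(in_hpd)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- which(runs$values)
  intervals <- tibble::tibble(
    from_bp = grid[ends[iv]],   # larger cal BP = older bound
    to_bp = grid[starts[iv]]
  )
  recent_edge <- min(grid)
  rnd <- function(x) if (round_to > 0) round(x / round_to) * round_to else x
  intervals <- tibble::tibble(
    from = rnd(1950 - intervals$from_bp),
    to = rnd(1950 - intervals$to_bp),
    open_ended = intervals$to_bp <= recent_edge
  )
  intervals <- intervals[order(intervals$from), ]
  structure(list(
    density = tibble::tibble(cal_bp = grid, year_ce = 1950 - grid,
                             density = dens),
    intervals = intervals,
    age_bp = age_bp, sigma = sigma, hpd_mass = hpd_mass, sample = sample
  ), class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  iv <- paste(sprintf("%d-%s CE", x$intervals$from,
                      ifelse(x$intervals$open_ended, "...",
                             as.character(x$intervals$to))),
              collapse = ", ")
  cat(sprintf("<calibrated_date> %s: %.0f +- %.0f BP -> %s (%.1f%%)\n",
              x$sample, x$age_bp, x$sigma, iv, 100 * x$hpd_mass))
  invisible(x)
}

#' Tidy a calibrated date into its interval set
#'
#' @param x A `calibrated_date`.
#' @param ... Unused.
#' @return Tibble: `sample`, `from`, `to`, `open_ended` (years CE).
#' @export
tidy.calibrated_date <- function(x, ...) {
  dplyr::mutate(x$intervals, sample = x$sample, .before = 1)
}

#' Calibrate a table of radiocarbon measurements
#'
#' @param radiocarbon Tibble: `sample`, `age_bp`, `sigma`.
#' @param curve Calibration curve tibble.
#' @param ... Passed to [calibrate_c14()].
#' @return Tibble of HPD intervals: `sample`, `from`, `to`, `open_ended`.
#' @export
calibrate_dates <- function(radiocarbon, curve, ...) {
  purrr::pmap_dfr(radiocarbon[c("sample", "age_bp", "sigma")],
                  function(sample, age_bp, sigma) {
                    tidy(calibrate_c14(age_bp, sigma, curve, sample = sample, ...))
                  })
}

#' Minimum number of depositional events
#'
#' The smallest number of calendar points such that every dated
#' individual's interval contains at least one point (interval piercing),
#' found by the greedy sweep over right endpoints, which is optimal for
#' intervals. Open-ended intervals are treated as extending to
#' `recent_limit`. Also returns the witness points, an assignment of each
#' interval to its witness, and the pairwise overlap matrix.
#'
#' @param intervals Tibble: `from`, `to`, optional `open_ended` and
#'   `sample`. `to` may be NA for open-ended rows.
#' @param recent_limit Upper bound substituted for open-ended intervals
#'   (default 1950, the radiocarbon present).
#' @return List of class `event_count`: `n_events`, `witnesses`,
#'   `assignment` (tibble `sample`, `from`, `to`, `event`), `overlap`
#'   (logical matrix).
#' @export
minimum_events <- function(intervals, recent_limit = 1950) {
  stopifnot(nrow(intervals) >= 1)
  iv <- tibble::as_tibble(intervals)
  if (!"sample" %in% names(iv)) iv$sample <- paste0("i", seq_len(nrow(iv)))
  open <- if ("open_ended" %in% names(iv)) iv$open_ended %in% TRUE else
    is.na(iv$to)
  iv$to[open | is.na(iv$to)] <- recent_limit
  if (any(iv$from > iv$to)) abort("interval with from > to")
  ord <- order(iv$to, iv$from)
  witnesses <- numeric(0)
  event <- integer(nrow(iv))
  current <- -Inf
  for (i in ord) {
    if (iv$from[i] > current) {
      current <- iv$to[i]
      witnesses <- c(witnesses, current)
    }
    event[i] <- length(witnesses)
  }
  ov <- outer(iv$from, iv$to, "<=") & t(outer(iv$from, iv$to, "<="))
  dimnames(ov) <- list(iv$sample, iv$sample)
  structure(list(n_events = length(witnesses), witnesses = witnesses,
                 assignment = tibble::tibble(sample = iv$sample,
                                             from = iv$from, to = iv$to,
                                             event = event),
                 overlap = ov),
            class = "event_count")
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("<event_count> minimum %d depositional event(s); witnesses: %s\n",
              x$n_events, paste(x$witnesses, collapse = ", ")))
  invisible(x)
}

#' Parse printed calibrated-interval strings
#'
#' Understands forms like `"890-982 CE"` (hyphen or en dash), open-ended
#' `"1656-... CE"`, and missing `".."`/empty.
#'
#' @param x Character vector.
#' @return Tibble: `from`, `to`, `open_ended` (NA rows for missing).
#' @export
parse_cal_interval <- function(x) {
  x <- trimws(gsub("CE", "", x))
  x <- gsub("–|—", "-", x)
  purrr::map_dfr(x, function(s) {
    if (is.na(s) || s == "" || s == "..") {
      return(tibble::tibble(from = NA_real_, to = NA_real_, open_ended = NA))
    }
    parts <- trimws(strsplit(s, "-")[[1]])
    from <- as.numeric(parts[1])
    open <- length(parts) < 2 || parts[2] %in% c("", "...", "…")
    tibble::tibble(from = from,
                   to = if (open) NA_real_ else as.numeric(parts[2]),
                   open_ended = open)
  })
}
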
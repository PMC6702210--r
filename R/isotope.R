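#' Merge replicate isotope measurements
#'
#' One row per sample: the arithmetic mean per analyte across laboratories
#' (the standard plotting rule when multiple measurements exist), with the
#' replicate count and spread retained. Replicates more than 2 permil apart
#' trigger a warning but are still averaged.
#'
#' @param records Tibble: `sample`, `lab`, `d13c`, `d15n` (values in permil;
#'   d13C vs VPDB, d15N vs ambient air). Values far outside collagen-
#'   plausible ranges (d13C in \[-35, 0\], d15N in \[-5, 25\]) draw a
#'   warning.
#' @return Tibble: `sample`, `d13c`, `d15n`, `n_labs`, `d13c_spread`,
#'   `d15n_spread`.
#' @export
merge_replicates <- function(records) {
  out13 <- records$d13c[!is.na(records$d13c)]
  out15 <- records$d15n[!is.na(records$d15n)]
  if (any(out13 < -35 | out13 > 0) || any(out15 < -5 | out15 > 25)) {
    warn("isotope value(s) outside plausible collagen range")
  }
  spread <- function(x) if (sum(!is.na(x)) > 1) diff(range(x, na.rm = TRUE)) else 0
  out <- records |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      d13c_spread = spread(.data$d13c),
      d15n_spread = spread(.data$d15n),
      n_labs = dplyr::n_distinct(.data$lab),
      d13c = mean(.data$d13c, na.rm = TRUE),
      d15n = mean(.data$d15n, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select("sample", "d13c", "d15n", "n_labs",
                  "d13c_spread", "d15n_spread") |>
    dplyr::mutate(d13c = ifelse(is.nan(.data$d13c), NA_real_, .data$d13c),
                  d15n = ifelse(is.nan(.data$d15n), NA_real_, .data$d15n))
  if (any(out$d13c_spread > 2 | out$d15n_spread > 2, na.rm = TRUE)) {
    warn("replicate measurements more than 2 permil apart; averaging anyway")
  }
  out
}

#' Two-sided Mann-Whitney test
#'
#' U is computed by pairwise comparison with 0.5 credit for ties. With no
#' ties and min(n) <= 25 the p-value is exact (from the null distribution
#' of U); otherwise a tie-corrected normal approximation with continuity
#' correction is used, and the method is recorded.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch; NULL
#'   decides by the rule above.
#' @return One-row tibble: `u`, `p`, `method`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  use_exact <- exact %||% (!has_ties && min(n1, n2) <= 25)
  if (use_exact && has_ties) {
    abort("exact p-values are unavailable with ties")
  }
  if (use_exact) {
    # two-sided exact p: double the smaller tail of the null distribution of U
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      # every observation tied: no evidence against the null
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * pnorm(-abs(z)), 1)
    }
    method <- "normal_tie_corrected"
  }
  tibble::tibble(u = u, p = p, method = method, n_a = n1, n_b = n2)
}

#' Classify diet along the C3/C4 axis
#'
#' Bulk collagen d13C reflects the photosynthetic pathway of dietary
#' plants: strongly negative values indicate C3 staples (wheat, barley,
#' rice), higher values an increasing C4 (e.g. millet) contribution.
#' Boundaries belong to the upper class; d15N is carried alongside as a
#' trophic annotation, unclassified.
#'
#' @param d13c Numeric vector, permil vs VPDB.
#' @param cutoffs Two increasing cutoffs: below the first is "C3", below
#'   the second "mixed C3/C4", at or above it "C4-influenced".
#' @return Character vector of diet classes ("unclassified" for NA).
#' @export
classify_diet <- function(d13c, cutoffs = c(-18, -14)) {
  dplyr::case_when(
    is.na(d13c) ~ "unclassified",
    d13c < cutoffs[1] ~ "C3",
    d13c < cutoffs[2] ~ "mixed C3/C4",
    TRUE ~ "C4-influenced"
  )
}
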
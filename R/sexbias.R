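#' Per-sample ancestry proportion from PC coordinates
#'
#' Rescales each sample's position along the axis between two reference
#' centroids (e.g. a West-Eurasian-related and a South-Asian-related
#' anchor) to a \[0, 1\] proportion: the scalar projection of the sample
#' onto the centroid axis, clamped. An admixture-model alternative is to
#' use `alpha` from [admixture_weights()] per sample; either can feed
#' [sex_permutation_test()].
#'
#' @param coords Tibble with `sample` and PC columns (from
#'   [lsq_project()]). Samples with undefined coordinates are excluded
#'   with a message.
#' @param ref_low,ref_high Numeric PC vectors of the centroids mapping to
#'   proportion 0 and 1.
#' @return Tibble: `sample`, `proportion`, `method`.
#' @export
ancestry_proportion <- function(coords, ref_low, ref_high) {
  pc_cols <- grep("^PC", names(coords), value = TRUE)
  X <- as.matrix(coords[pc_cols])
  ok <- complete.cases(X)
  if (any(!ok)) {
    inform(sprintf("excluding %d sample(s) with undefined coordinates: %s",
                   sum(!ok), paste(coords$sample[!ok], collapse = ", ")))
  }
  axis <- ref_high - ref_low
  t <- as.vector(sweep(X[ok, , drop = FALSE], 2, ref_low) %*% axis) / sum(axis^2)
  tibble::tibble(sample = coords$sample[ok],
                 proportion = pmin(pmax(t, 0), 1),
                 method = "rescaled_pc")
}

#' Permutation test for sex-biased ancestry
#'
#' Tests whether mean ancestry proportion differs between genetic females
#' and males within a group. The statistic is mean(female) - mean(male);
#' sex labels are permuted across individuals, and the two-sided p-value
#' uses the add-one correction (#\{|delta_perm| >= |delta_obs|\} + 1) /
#' (n_perm + 1), which avoids reporting p = 0 from Monte-Carlo noise.
#'
#' @param table Tibble with `sex` ("M"/"F"; others dropped) and
#'   `proportion`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-row tibble: `delta`, `p`, `n_perm`, `n_female`, `n_male`.
#' @export
sex_permutation_test <- function(table, n_perm = 9999, seed = 1) {
  table <- table[table$sex %in% c("M", "F"), , drop = FALSE]
  nf <- sum(table$sex == "F"); nm <- sum(table$sex == "M")
  if (nf == 0 || nm == 0) abort("both sexes must be present")
  if (nf < 2 || nm < 2) {
    warn("fewer than 2 individuals in one sex; the permutation null is coarse")
  }
  x <- table$proportion
  is_f <- table$sex == "F"
  delta <- mean(x[is_f]) - mean(x[!is_f])
  n <- length(x)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pf <- sample.int(n, nf)
      mean(x[pf]) - mean(x[-pf])
    }, 0)
  })
  p <- (sum(abs(perm) >= abs(delta) - 1e-12) + 1) / (n_perm + 1)
  tibble::tibble(delta = delta, p = p, n_perm = n_perm,
                 n_female = nf, n_male = nm)
}
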
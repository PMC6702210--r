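# --- block jackknife machinery -------------------------------------------

# Per-SNP jackknife block ids: 5 Mb physical blocks per chromosome when
# positions exist, else contiguous SNP-count blocks (~n/100 SNPs each).
block_ids <- function(snp, block_bp = 5e6, n_blocks = 100) {
  if (!is.null(snp$pos) && !any(is.na(snp$pos))) {
    key <- paste(snp$chrom, floor(snp$pos / block_bp))
  } else {
    key <- ceiling(seq_len(nrow(snp)) / ceiling(nrow(snp) / n_blocks))
  }
  match(key, unique(key))
}

# Weighted delete-one-block jackknife (Busing-style) for a scalar estimate.
# theta: full estimate; theta_j: delete-block estimates; m: block weights.
jackknife_se <- function(theta, theta_j, m) {
  keep <- !is.na(theta_j) & m > 0
  theta_j <- theta_j[keep]; m <- m[keep]
  g <- length(theta_j)
  if (g < 2) return(list(est = theta, se = NA_real_, n_blocks = g))
  n <- sum(m)
  h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * theta_j)
  tau <- h * theta - (h - 1) * theta_j
  v <- sum((tau - theta_J)^2 / (h - 1)) / g
  list(est = theta, se = sqrt(v), n_blocks = g)
}

# Matrix analogue: columns of `theta_j` are delete-block estimate vectors.
jackknife_cov <- function(theta, theta_j, m) {
  g <- ncol(theta_j)
  n <- sum(m)
  h <- n / m
  theta_J <- g * theta - as.vector(theta_j %*% (1 - m / n))
  V <- matrix(0, length(theta), length(theta))
  for (j in seq_len(g)) {
    tau <- h[j] * theta - (h[j] - 1) * theta_j[, j]
    d <- tau - theta_J
    V <- V + outer(d, d) / (h[j] - 1)
  }
  V / g
}

fstat_row <- function(stat, pops, estimate, se, n_blocks, n_snps) {
  tibble::tibble(stat = stat, pops = paste(pops, collapse = ","),
                 estimate = estimate, se = se,
                 z = ifelse(!is.na(se) && se > 0, estimate / se, NA_real_),
                 n_blocks = n_blocks, n_snps = n_snps)
}

# --- PCA ------------------------------------------------------------------

#' Principal component analysis of a reference panel
#'
#' Genotypes are centered by the per-SNP mean call and scaled by
#' sqrt(p(1-p)) with p the mean call; missing entries are mean-imputed
#' (zero after centering). Monomorphic SNPs are dropped with a message.
#' The component sign is fixed so the largest-magnitude SNP loading is
#' positive, making repeated runs byte-identical.
#'
#' @param g A [geno_matrix()].
#' @param n_components Number of components to retain.
#' @return An object of class `ref_pca`: SNP loadings, eigenvalues,
#'   per-SNP means and scales, and in-sample `scores`.
#' @export
reference_pca <- function(g, n_components = 2) {
  X <- g$calls
  n_called <- colSums(!is.na(X))
  if (any(n_called == 0)) abort("panel contains fully-missing SNPs")
  p <- colMeans(X, na.rm = TRUE)
  keep <- p > 0 & p < 1
  if (any(!keep)) {
    inform(sprintf("dropping %d monomorphic SNPs", sum(!keep)))
  }
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  if (n_components > min(dim(X))) abort("n_components exceeds matrix rank")
  sc <- sqrt(p * (1 - p))
  Z <- sweep(sweep(X, 2, p), 2, sc, "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = n_components, nv = n_components)
  V <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    s <- sign(V[which.max(abs(V[, k])), k])
    V[, k] <- V[, k] * s
    scores[, k] <- scores[, k] * s
  }
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    loadings = `rownames<-`(V, colnames(X)),
    eigenvalues = sv$d[seq_len(n_components)]^2 / (nrow(X) - 1),
    means = p, scales = sc, snp_ids = colnames(X),
    scores = dplyr::bind_cols(
      tibble::tibble(sample = rownames(X), pop = g$ind$pop),
      tibble::as_tibble(scores)
    )
  ), class = "ref_pca")
}

#' @export
print.ref_pca <- function(x, ...) {
  cat(sprintf("<ref_pca> %d SNPs, %d components; eigenvalues %s\n",
              length(x$snp_ids), ncol(x$loadings),
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' Least-squares projection onto a reference PCA
#'
#' Projects samples (typically low-coverage, high-missingness) onto an
#' existing basis: coordinates minimize the squared reconstruction error
#' over each sample's non-missing SNPs only, the standard approach for
#' projecting ancient samples without shrinking them to the origin.
#'
#' @param g A [geno_matrix()] of samples to project.
#' @param basis A [reference_pca()] result.
#' @param min_snps Minimum non-missing basis SNPs; below it the sample's
#'   coordinates are undefined (NA) and flagged.
#' @return Tibble: `sample`, `n_obs`, `projected`, PC columns.
#' @export
lsq_project <- function(g, basis, min_snps = 5000) {
  idx <- match(basis$snp_ids, colnames(g$calls))
  k <- ncol(basis$loadings)
  res <- lapply(seq_len(nrow(g$calls)), function(i) {
    gi <- g$calls[i, idx]
    obs <- which(!is.na(gi))
    if (length(obs) < min_snps) {
      return(c(n_obs = length(obs), rep(NA_real_, k)))
    }
    z <- (gi[obs] - basis$means[obs]) / basis$scales[obs]
    L <- basis$loadings[obs, , drop = FALSE]
    G <- crossprod(L)
    coords <- tryCatch(solve(G, crossprod(L, z)),
                       error = function(e) MASS::ginv(G) %*% crossprod(L, z))
    c(n_obs = length(obs), as.vector(coords))
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(sample = rownames(g$calls),
                        n_obs = as.integer(m[, 1]),
                        projected = !is.na(m[, 2]))
  coords <- m[, -1, drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(out, tibble::as_tibble(coords))
}

#' Assign samples to ancestry groups in PC space
#'
#' Nearest-centroid assignment when reference centroids are given
#' (ties go to the lowest-index centroid, with a message); otherwise
#' k-medoids clustering (deterministic for fixed input). Singleton groups
#' are permitted.
#'
#' @param coords Tibble with `sample` and PC columns (rows with NA
#'   coordinates are returned unassigned).
#' @param centroids Tibble with `group` and the same PC columns, or NULL.
#' @param k Number of clusters when `centroids` is NULL.
#' @return Tibble: `sample`, `group`.
#' @export
assign_groups <- function(coords, centroids = NULL, k = NULL) {
  pc_cols <- grep("^PC", names(coords), value = TRUE)
  X <- as.matrix(coords[pc_cols])
  ok <- complete.cases(X)
  group <- rep(NA_character_, nrow(coords))
  if (!is.null(centroids)) {
    C <- as.matrix(centroids[pc_cols])
    d <- outer(rowSums(X[ok, , drop = FALSE]^2), rowSums(C^2), "+") -
      2 * X[ok, , drop = FALSE] %*% t(C)
    tie <- apply(d, 1, function(r) sum(r == min(r)) > 1)
    if (any(tie)) inform(sprintf("%d sample(s) equidistant; lowest-index centroid used",
                                 sum(tie)))
    group[ok] <- centroids$group[apply(d, 1, which.min)]
  } else {
    if (is.null(k)) abort("supply `centroids` or `k`")
    if (k > sum(ok)) abort("k exceeds the number of samples with coordinates")
    fit <- cluster::pam(X[ok, , drop = FALSE], k = k, pamonce = 5)
    group[ok] <- paste0("G", fit$clustering)
  }
  tibble::tibble(sample = coords$sample, group = group)
}

# --- F_ST and f4 ----------------------------------------------------------

# Per-SNP allele frequencies and call counts for several populations.
freq_table <- function(g, pops) {
  out <- lapply(pops, function(p) pop_freqs(g, p))
  names(out) <- pops
  out
}

#' Pairwise Hudson F_ST with block jackknife
#'
#' Ratio-of-averages Hudson estimator with within-population variance
#' estimated treating calls as haploid draws (the appropriate "inbreed"
#' correction for pseudo-haploid data, where within-individual
#' heterozygosity is unobservable): per SNP the numerator is
#' (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1) and the denominator
#' pA(1-pB) + pB(1-pA); both are summed over SNPs before dividing.
#' Standard errors come from a weighted block jackknife.
#'
#' @param g A [geno_matrix()].
#' @param pop_a,pop_b Population labels (each needs >= 2 samples).
#' @param block_bp Physical jackknife block size.
#' @return A one-row tibble: `stat`, `pops`, `estimate`, `se`, `z`,
#'   `n_blocks`, `n_snps`.
#' @export
fst_pairwise <- function(g, pop_a, pop_b, block_bp = 5e6) {
  for (p in c(pop_a, pop_b)) {
    if (sum(g$ind$pop == p) < 2) {
      abort(sprintf("population '%s' needs at least 2 samples", p))
    }
  }
  fa <- pop_freqs(g, pop_a); fb <- pop_freqs(g, pop_b)
  ok <- fa$n >= 2 & fb$n >= 2
  pa <- fa$p[ok]; pb <- fb$p[ok]
  na <- fa$n[ok]; nb <- fb$n[ok]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  blocks <- block_ids(g$snp)[ok]
  ns <- tapply(num, blocks, sum); ds <- tapply(den, blocks, sum)
  ms <- tapply(num, blocks, length)
  theta <- sum(num) / sum(den)
  theta_j <- (sum(num) - ns) / (sum(den) - ds)
  jk <- jackknife_se(theta, theta_j, as.vector(ms))
  fstat_row("fst", c(pop_a, pop_b), jk$est, jk$se, jk$n_blocks, sum(ok))
}

# Core f4 computation shared by f4_stat / cladality / admixture:
# per-quad totals and per-block sums using every SNP where the quad's own
# four populations are all called ("allsnps" semantics).
f4_core <- function(g, quads, block_bp = 5e6) {
  pops <- unique(unlist(quads))
  ft <- freq_table(g, pops)
  blocks <- block_ids(g$snp, block_bp)
  n_blocks <- max(blocks)
  lapply(quads, function(q) {
    pA <- ft[[q[1]]]; pB <- ft[[q[2]]]; pC <- ft[[q[3]]]; pD <- ft[[q[4]]]
    ok <- pA$n >= 1 & pB$n >= 1 & pC$n >= 1 & pD$n >= 1
    d <- (pA$p - pB$p) * (pC$p - pD$p)
    d[!ok] <- 0
    s_b <- vapply(seq_len(n_blocks), function(b) sum(d[ok & blocks == b]), 0)
    m_b <- vapply(seq_len(n_blocks), function(b) sum(ok & blocks == b), 0)
    list(total = sum(d[ok]), n = sum(ok), block_sum = s_b, block_n = m_b)
  })
}

#' f4-statistic with block jackknife
#'
#' The mean over usable SNPs of (pA - pB)(pC - pD); its expectation is zero
#' when (A, B) and (C, D) are symmetric pairs (treeness), so the Z score
#' tests symmetry. Each statistic uses every SNP at which its own four
#' populations have at least one call.
#'
#' @param g A [geno_matrix()].
#' @param a,b,c,d Population labels.
#' @param block_bp Physical jackknife block size.
#' @return A one-row tibble like [fst_pairwise()].
#' @export
f4_stat <- function(g, a, b, c, d, block_bp = 5e6) {
  core <- f4_core(g, list(c(a, b, c, d)), block_bp)[[1]]
  if (core$n == 0) abort("no SNPs usable for this f4 (all-missing pops?)")
  theta <- core$total / core$n
  theta_j <- (core$total - core$block_sum) / (core$n - core$block_n)
  jk <- jackknife_se(theta, theta_j, core$block_n)
  fstat_row("f4", c(a, b, c, d), jk$est, jk$se, jk$n_blocks, core$n)
}

# Full + delete-block estimate matrix for a list of quads.
f4_vector <- function(g, quads, block_bp = 5e6) {
  cores <- f4_core(g, quads, block_bp)
  est <- vapply(cores, function(x) x$total / x$n, 0)
  n_blocks <- length(cores[[1]]$block_sum)
  loo <- vapply(cores, function(x) {
    (x$total - x$block_sum) / pmax(x$n - x$block_n, 1)
  }, numeric(n_blocks))
  m <- vapply(seq_len(n_blocks), function(b) {
    max(vapply(cores, function(x) x$block_n[b], 0))
  }, 0)
  keep <- m > 0
  list(est = est, loo = t(loo)[, keep, drop = FALSE], m = m[keep],
       n_snps = min(vapply(cores, function(x) x$n, 0)))
}

#' Cladality (rank-0) test from f4-statistics
#'
#' Tests whether `target` and `candidate` form a clade relative to a set of
#' right (outgroup) populations: if they do, every
#' f4(target, candidate; O_i, O_j) has expectation zero. The statistics for
#' a spanning set of right-population pairs are combined with their block-
#' jackknife covariance into a Hotelling-style chi-square statistic.
#'
#' @param g A [geno_matrix()].
#' @param target,candidate Population labels.
#' @param right_pops At least two right populations.
#' @param block_bp Jackknife block size.
#' @param alpha Significance level for the clade verdict.
#' @return Tibble: `statistic`, `dof`, `p`, `clade`.
#' @export
cladality_test <- function(g, target, candidate, right_pops,
                           block_bp = 5e6, alpha = 0.05) {
  if (length(right_pops) < 2) abort("need at least two right populations")
  quads <- lapply(right_pops[-1], function(o) {
    c(target, candidate, right_pops[1], o)
  })
  fv <- f4_vector(g, quads, block_bp)
  V <- jackknife_cov(fv$est, fv$loo, fv$m)
  sol <- tryCatch(list(Vi = solve(V), dof = length(fv$est)),
                  error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol$Vi))) {
    warn("singular f4 covariance; using pseudo-inverse with reduced dof")
    Vi <- MASS::ginv(V)
    dof <- qr(V)$rank
  } else {
    Vi <- sol$Vi
    dof <- sol$dof
  }
  stat <- as.numeric(t(fv$est) %*% Vi %*% fv$est)
  p <- pchisq(stat, dof, lower.tail = FALSE)
  tibble::tibble(statistic = stat, dof = dof, p = p, clade = p > alpha)
}

#' Two-way admixture proportions from f4-statistics
#'
#' Models `target` as alpha * source1 + (1 - alpha) * source2: alpha
#' minimizes the generalized least-squares distance between
#' f4(target, O_ref; O_i, O_j) and the same statistics for the sources,
#' over all pairs of the remaining right populations. Standard errors come
#' from delete-block re-estimation. Sources that are themselves cladal
#' with respect to the right set give no leverage and raise an error.
#'
#' @param g A [geno_matrix()].
#' @param target,source1,source2 Population labels.
#' @param right_pops At least three right populations (the first is the
#'   reference outgroup).
#' @param block_bp Jackknife block size.
#' @return Tibble: `alpha`, `se`, `n_stats`, `boundary`.
#' @export
admixture_weights <- function(g, target, source1, source2, right_pops,
                              block_bp = 5e6) {
  if (length(right_pops) < 3) abort("need at least three right populations")
  o_ref <- right_pops[1]
  others <- right_pops[-1]
  prs <- combn(others, 2)
  mk <- function(p) {
    lapply(seq_len(ncol(prs)), function(j) c(p, o_ref, prs[1, j], prs[2, j]))
  }
  quads <- c(mk(target), mk(source1), mk(source2))
  fv <- f4_vector(g, quads, block_bp)
  K <- ncol(prs)
  iy <- seq_len(K); ia <- K + iy; ib <- 2 * K + iy
  V <- jackknife_cov(fv$est, fv$loo, fv$m)
  Wy <- MASS::ginv(V[iy, iy, drop = FALSE])
  e_ab <- fv$est[ia] - fv$est[ib]
  V_ab <- V[ia, ia] + V[ib, ib] - V[ia, ib] - V[ib, ia]
  t_ab <- as.numeric(t(e_ab) %*% MASS::ginv(V_ab) %*% e_ab)
  if (pchisq(t_ab, K, lower.tail = FALSE) > 0.05) {
    abort("source populations are cladal with respect to the right set; choose more distinct sources")
  }
  alpha_of <- function(y, a, b) {
    num <- as.numeric(t(y - b) %*% Wy %*% (a - b))
    den <- as.numeric(t(a - b) %*% Wy %*% (a - b))
    num / den
  }
  alpha <- alpha_of(fv$est[iy], fv$est[ia], fv$est[ib])
  alpha_j <- vapply(seq_len(ncol(fv$loo)), function(j) {
    alpha_of(fv$loo[iy, j], fv$loo[ia, j], fv$loo[ib, j])
  }, 0)
  jk <- jackknife_se(alpha, alpha_j, fv$m)
  boundary <- alpha < 0 || alpha > 1
  if (boundary) warn("admixture proportion clamped to [0, 1]")
  tibble::tibble(alpha = min(max(alpha, 0), 1), se = jk$se,
                 n_stats = K, boundary = boundary)
}

# --- kinship --------------------------------------------------------------

#' Pairwise relatedness scan from allele mismatch rates
#'
#' For each sample pair, the mismatch rate over jointly-called SNPs is
#' normalized by the cohort median (the unrelated baseline, following
#' pairwise-mismatch kinship conventions for pseudo-haploid data) and
#' classified by normalized-rate cutoffs. Pairs with too few overlapping
#' calls are reported as "insufficient_data".
#'
#' @param g A [geno_matrix()].
#' @param min_overlap Minimum jointly-called SNPs per pair.
#' @param cutoffs Named increasing cutoffs on the normalized mismatch rate
#'   for `identical`, `first_degree`, `second_degree`, `third_degree`;
#'   above the last cutoff a pair is `unrelated`.
#' @return Tibble: `sample_a`, `sample_b`, `n_overlap`, `mismatch`,
#'   `normalized`, `relationship`.
#' @export
kinship_scan <- function(g, min_overlap = 5000,
                         cutoffs = c(identical = 0.625, first_degree = 0.8125,
                                     second_degree = 0.90625,
                                     third_degree = 0.953)) {
  n <- nrow(g$calls)
  if (n < 2) {
    return(tibble::tibble(sample_a = character(), sample_b = character(),
                          n_overlap = integer(), mismatch = double(),
                          normalized = double(), relationship = character()))
  }
  A <- (g$calls == 1L); A[is.na(A)] <- FALSE
  B <- (g$calls == 0L); B[is.na(B)] <- FALSE
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  overlap <- tcrossprod(A + B)
  mism <- tcrossprod(A, B) + tcrossprod(B, A)
  pr <- t(combn(n, 2))
  ov <- overlap[pr]
  mr <- mism[pr] / ov
  usable <- ov >= min_overlap
  baseline <- median(mr[usable])
  norm <- mr / baseline
  cls <- rep("unrelated", length(mr))
  for (nm in rev(names(cutoffs))) cls[norm < cutoffs[[nm]]] <- nm
  cls[!usable] <- "insufficient_data"
  tibble::tibble(sample_a = rownames(g$calls)[pr[, 1]],
                 sample_b = rownames(g$calls)[pr[, 2]],
                 n_overlap = as.integer(ov), mismatch = mr,
                 normalized = norm, relationship = cls)
}
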
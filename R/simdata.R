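#' Balding-Nichols population model
#'
#' Describes K source populations drifting independently from a shared
#' ancestral allele-frequency pool. Drift is parameterized by a per-pair
#' target F_ST; under the Balding-Nichols model with per-population drift
#' F_k, the expected Hudson F_ST between populations a and b is
#' (F_a + F_b) / 2, so a scalar `fst` gives every pair that F_ST exactly.
#'
#' @param n_pops Number of populations (>= 1).
#' @param fst Either a scalar pairwise F_ST target (all pairs equal) or a
#'   symmetric `n_pops x n_pops` matrix with zero diagonal, entries in
#'   \[0, 1). A matrix is converted to per-population drift coefficients by
#'   least squares on F_ab = (F_a + F_b) / 2.
#' @param n_snps Number of SNPs (>= 1).
#' @param freq_range Interval in (0, 1) from which ancestral frequencies are
#'   drawn uniformly.
#' @param pop_names Optional population names (default "Pop1", ...).
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_pops, fst, n_snps,
                             freq_range = c(0.05, 0.95),
                             pop_names = NULL) {
  stopifnot(n_pops >= 1, n_snps >= 1)
  if (freq_range[1] <= 0 || freq_range[2] >= 1 || freq_range[1] > freq_range[2]) {
    abort("`freq_range` must be an interval inside (0, 1)")
  }
  if (is.matrix(fst)) {
    if (nrow(fst) != n_pops || ncol(fst) != n_pops) {
      abort("`fst` matrix must be n_pops x n_pops")
    }
    if (any(abs(fst - t(fst)) > 1e-12) || any(diag(fst) != 0)) {
      abort("`fst` matrix must be symmetric with zero diagonal")
    }
    if (any(fst < 0 | fst >= 1)) abort("`fst` entries must lie in [0, 1)")
    if (n_pops == 1) {
      drift <- 0
    } else if (n_pops == 2) {
      drift <- rep(fst[1, 2], 2)
    } else {
      # solve F_a + F_b = 2 * fst_ab in least squares
      pairs <- t(combn(n_pops, 2))
      A <- matrix(0, nrow(pairs), n_pops)
      A[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
      A[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
      drift <- as.vector(qr.solve(A, 2 * fst[pairs]))
      drift <- pmin(pmax(drift, 0), 0.999)
    }
    fst_matrix <- fst
  } else {
    if (fst < 0 || fst >= 1) abort("`fst` must lie in [0, 1)")
    drift <- rep(fst, n_pops)
    fst_matrix <- matrix(fst, n_pops, n_pops)
    diag(fst_matrix) <- 0
  }
  pop_names <- pop_names %||% paste0("Pop", seq_len(n_pops))
  structure(
    list(n_pops = n_pops, fst_matrix = fst_matrix, drift = drift,
         n_snps = n_snps, freq_range = freq_range, pop_names = pop_names),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d populations, %d SNPs, drift F = %s\n",
              x$n_pops, x$n_snps,
              paste(signif(x$drift, 3), collapse = "/")))
  invisible(x)
}

#' Simulate a pseudo-haploid reference panel
#'
#' Draws ancestral frequencies p ~ Uniform(`freq_range`) per SNP, then
#' population frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F) (Balding-
#' Nichols; F = 0 gives the ancestral frequency exactly), and finally one
#' haploid call per sample per SNP. SNPs are laid out on 22 autosomes so
#' that physical-position jackknife blocks are meaningful.
#'
#' @param model A [population_model()].
#' @param n_per_pop Samples per population (scalar or vector).
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A [geno_matrix()]. The true per-population allele frequencies are
#'   attached as attribute `"true_freqs"` (SNPs x populations matrix).
#' @export
sim_genotype_panel <- function(model, n_per_pop, seed = 1) {
  stopifnot(inherits(model, "population_model"))
  n_per_pop <- rep(n_per_pop, length.out = model$n_pops)
  with_seed(seed, {
    L <- model$n_snps
    p0 <- runif(L, model$freq_range[1], model$freq_range[2])
    freqs <- matrix(NA_real_, L, model$n_pops)
    for (k in seq_len(model$n_pops)) {
      f <- model$drift[k]
      if (f == 0) {
        freqs[, k] <- p0
      } else {
        freqs[, k] <- rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      }
    }
    n_tot <- sum(n_per_pop)
    calls <- matrix(NA_integer_, n_tot, L)
    pop <- rep(model$pop_names, n_per_pop)
    for (i in seq_len(n_tot)) {
      k <- match(pop[i], model$pop_names)
      calls[i, ] <- rbinom(L, 1L, freqs[, k])
    }
    chrom <- rep(1:22, length.out = 22)[
      pmin(22, ceiling(seq_len(L) / ceiling(L / 22)))]
    pos <- unlist(lapply(split(seq_len(L), chrom), function(ix) {
      seq_along(ix) * 50000L
    }), use.names = FALSE)
    ind <- tibble::tibble(
      id = sprintf("%s_%d", pop, unlist(lapply(n_per_pop, seq_len))),
      sex = "U", pop = pop
    )
    snp <- tibble::tibble(
      id = sprintf("snp%06d", seq_len(L)),
      chrom = as.character(chrom), pos = pos, ref = "A", alt = "G"
    )
    g <- geno_matrix(calls, ind, snp)
    attr(g, "true_freqs") <- freqs
    g
  })
}

#' Simulate a tree-structured panel with optional admixed populations
#'
#' Extends the exchangeable Balding-Nichols model with a fixed nested
#' topology that gives f4-statistics leverage: from the ancestral pool,
#' two internal lineages A and B drift by `drift`; S1 and O3 then drift
#' from A by `drift2`, S2 and O4 from B, and O1, O2 drift directly from
#' the ancestral pool. Additional populations can be declared as gene-pool
#' mixtures of the base populations (e.g. `list(Target = c(S1 = 0.8,
#' S2 = 0.2))`), whose per-SNP frequencies are the weighted average of the
#' source frequencies -- the structure that two-way admixture estimation
#' assumes.
#'
#' @param n_snps SNP count.
#' @param n_per_pop Samples per population (applies to every population).
#' @param drift Drift of the internal lineages and plain outgroups.
#' @param drift2 Terminal drift of S1/O3/S2/O4.
#' @param mixtures Named list of named weight vectors over base
#'   populations.
#' @param freq_range Ancestral frequency range.
#' @param seed Integer seed.
#' @return A [geno_matrix()] with populations O1, O2, O3, O4, S1, S2 and
#'   any mixtures; true per-population frequencies attached as attribute
#'   `"true_freqs"`.
#' @export
sim_structured_panel <- function(n_snps, n_per_pop = 15,
                                 drift = 0.1, drift2 = 0.05,
                                 mixtures = list(),
                                 freq_range = c(0.05, 0.95), seed = 1) {
  bn <- function(p, f) {
    if (f == 0) p else rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  with_seed(seed, {
    p0 <- runif(n_snps, freq_range[1], freq_range[2])
    pA <- bn(p0, drift); pB <- bn(p0, drift)
    freqs <- cbind(
      O1 = bn(p0, drift), O2 = bn(p0, drift),
      O3 = bn(pA, drift2), O4 = bn(pB, drift2),
      S1 = bn(pA, drift2), S2 = bn(pB, drift2)
    )
    for (nm in names(mixtures)) {
      w <- mixtures[[nm]]
      if (!all(names(w) %in% colnames(freqs))) {
        abort("mixture weights must name base populations")
      }
      freqs <- cbind(freqs, freqs[, names(w), drop = FALSE] %*% (w / sum(w)))
      colnames(freqs)[ncol(freqs)] <- nm
    }
    pops <- colnames(freqs)
    calls <- matrix(NA_integer_, length(pops) * n_per_pop, n_snps)
    pop <- rep(pops, each = n_per_pop)
    for (i in seq_len(nrow(calls))) {
      calls[i, ] <- rbinom(n_snps, 1L, freqs[, pop[i]])
    }
    chrom <- rep(1:22, length.out = 22)[
      pmin(22, ceiling(seq_len(n_snps) / ceiling(n_snps / 22)))]
    pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix) {
      seq_along(ix) * 50000L
    }), use.names = FALSE)
    g <- geno_matrix(
      calls,
      ind = tibble::tibble(
        id = sprintf("%s_%d", pop, rep(seq_len(n_per_pop), length(pops))),
        sex = "U", pop = pop),
      snp = tibble::tibble(id = sprintf("snp%06d", seq_len(n_snps)),
                           chrom = as.character(chrom), pos = pos,
                           ref = "A", alt = "G")
    )
    attr(g, "true_freqs") <- freqs
    g
  })
}

#' Build a cohort specification
#'
#' One row per sample: the truth table that drives read, marker, isotope and
#' radiocarbon simulation. Defaults mirror the design of the assemblage the
#' package models: three ancestry groups of 23, 14 and 1 individuals, mean
#' coverage about 0.5x within the observed 0.026-1.547x range, terminal
#' damage rates near 5%, low contamination, and two depositional clusters of
#' calendar ages about 1000 years apart (~800 CE and ~1800 CE).
#'
#' @param n_per_group Samples per ancestry group.
#' @param groups Group (population) names.
#' @param coverage_range Coverage range; per-sample coverage is drawn
#'   log-uniformly inside it.
#' @param damage_rate,contamination Per-sample rates (recycled).
#' @param year_means,year_sd Calendar-year cluster means (years CE, one per
#'   group) and within-cluster standard deviation.
#' @param d13c_means,d15n_means Group mean isotope values (permil).
#' @param prop_male Proportion of genetic males.
#' @param seed Integer seed.
#' @return A tibble with one row per sample.
#' @export
sim_cohort <- function(n_per_group = c(23, 14, 1),
                       groups = paste0("Pop", seq_along(n_per_group)),
                       coverage_range = c(0.026, 1.547),
                       damage_rate = 0.05,
                       contamination = 0.005,
                       year_means = c(800, 1800, 1800)[seq_along(n_per_group)],
                       year_sd = 50,
                       d13c_means = c(-16, -19.1, -19.2)[seq_along(n_per_group)],
                       d15n_means = c(9.2, 10, 10)[seq_along(n_per_group)],
                       prop_male = 0.6,
                       seed = 1) {
  check_fraction(damage_rate, "damage_rate")
  check_fraction(contamination, "contamination")
  stopifnot(all(coverage_range > 0))
  with_seed(seed, {
    n <- sum(n_per_group)
    pop <- rep(groups, n_per_group)
    tibble::tibble(
      sample = sprintf("S%03d", seq_len(n)),
      population = pop,
      sex = ifelse(runif(n) < prop_male, "M", "F"),
      coverage = exp(runif(n, log(coverage_range[1]), log(coverage_range[2]))),
      damage_rate = rep(damage_rate, length.out = n),
      contamination = rep(contamination, length.out = n),
      calendar_year = round(rnorm(n, rep(year_means, n_per_group), year_sd)),
      d13c_mean = rep(d13c_means, n_per_group),
      d15n_mean = rep(d15n_means, n_per_group)
    )
  })
}

# Random read-id barcodes; duplicates of a read share the barcode.
.barcodes <- function(n) sprintf("bc%07d", sample.int(9999999L, n, replace = TRUE))

#' Simulate per-sample read observations
#'
#' Generates the tabular pileup that the QC stage consumes. Per autosomal
#' SNP the read count is Poisson(coverage); SNP-overlapping reads place the
#' SNP at least two bases from either read end (damage in partial-UDG-style
#' libraries is confined to terminal bases, which the caller trims anyway).
#' Separate flanking reads carry the 5'-terminal base signal used for damage
#' estimation: their terminal reference base is C with probability 0.25 and
#' is read as T with probability `damage_rate`. Mitochondrial reads are
#' drawn from a shared consensus sequence with a designated contaminant
#' haplotype mixed in at each sample's contamination rate; X/Y reads follow
#' the sample's true sex (one X and one Y in males, two X and no Y in
#' females). A fraction of reads is duplicated with degraded base
#' qualities.
#'
#' @param cohort A cohort tibble from [sim_cohort()].
#' @param panel A [geno_matrix()] whose populations cover the cohort's.
#' @param read_length Read length in bp.
#' @param duplicate_rate Fraction of reads re-emitted as duplicates.
#' @param n_flank_sites Number of terminal-signal sites per sample.
#' @param mt_depth Mean mitochondrial read depth per site.
#' @param n_mt_sites,n_x_sites,n_y_sites Numbers of mitochondrial, X and Y
#'   sites simulated.
#' @param n_contaminant_diffs Positions at which the mitochondrial
#'   contaminant differs from the consensus.
#' @param base_error Per-base sequencing error rate.
#' @param low_qual_rate Fraction of observations with failing base/mapping
#'   quality (exercises the filters).
#' @param seed Integer seed.
#' @return A list of class `read_sim`: `pileup` (the observation tibble),
#'   `x_panel` (known X polymorphisms: pos, major, minor, maf),
#'   `mt_consensus` and `mt_contaminant` (tibbles of pos, base).
#' @export
sim_reads <- function(cohort, panel,
                      read_length = 50,
                      duplicate_rate = 0.1,
                      n_flank_sites = 2000,
                      mt_depth = 20,
                      n_mt_sites = 300,
                      n_x_sites = 4000,
                      n_y_sites = 4000,
                      n_contaminant_diffs = 40,
                      base_error = 0.002,
                      low_qual_rate = 0.05,
                      seed = 1) {
  if (nrow(cohort) == 0) {
    return(structure(list(pileup = empty_pileup(), x_panel = NULL,
                          mt_consensus = NULL, mt_contaminant = NULL),
                     class = "read_sim"))
  }
  missing_pop <- setdiff(cohort$population, panel$ind$pop)
  if (length(missing_pop) > 0) {
    abort(sprintf("cohort populations absent from panel: %s",
                  paste(missing_pop, collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    # shared references
    mt_pos <- sort(sample.int(16569L, n_mt_sites))
    mt_cons <- sample(bases, n_mt_sites, replace = TRUE)
    mt_cont <- mt_cons
    flip <- sample.int(n_mt_sites, min(n_contaminant_diffs, n_mt_sites))
    mt_cont[flip] <- vapply(mt_cons[flip], function(b) sample(setdiff(bases, b), 1), "")
    x_pos <- sort(sample.int(154000000L, n_x_sites))
    x_major <- sample(bases, n_x_sites, replace = TRUE)
    x_minor <- vapply(x_major, function(b) sample(setdiff(bases, b), 1), "")
    x_maf <- ifelse(seq_len(n_x_sites) %% 2 == 0, 0, runif(n_x_sites, 0.1, 0.5))
    # contaminant nuclear haplotype: drawn from the first panel population
    cont_freq <- pop_freqs(panel, panel$ind$pop[1])$p
    cont_hap <- rbinom(length(cont_freq), 1L, ifelse(is.na(cont_freq), 0.5, cont_freq))
    cont_x <- rbinom(n_x_sites, 1L, x_maf)  # 1 = minor allele

    per_sample <- lapply(seq_len(nrow(cohort)), function(i) {
      set.seed(sub_seed(seed, i))
      smp <- cohort[i, ]
      sample_reads(smp, panel, cont_hap,
                   mt_pos, mt_cons, mt_cont, mt_depth,
                   x_pos, x_major, x_minor, x_maf, cont_x,
                   n_y_sites, n_flank_sites, read_length,
                   base_error, low_qual_rate, bases)
    })
    pileup <- dplyr::bind_rows(per_sample)
    # duplicate injection: re-emit a fraction of reads with lower quality
    if (duplicate_rate > 0 && nrow(pileup) > 0) {
      dup <- pileup[runif(nrow(pileup)) < duplicate_rate, , drop = FALSE]
      if (nrow(dup) > 0) {
        dup$baseq <- pmax(dup$baseq - 5L, 2L)
        pileup <- dplyr::bind_rows(pileup, dup)
      }
    }
    structure(list(
      pileup = pileup,
      x_panel = tibble::tibble(pos = x_pos, major = x_major,
                               minor = x_minor, maf = x_maf),
      mt_consensus = tibble::tibble(pos = mt_pos, base = mt_cons),
      mt_contaminant = tibble::tibble(pos = mt_pos, base = mt_cont)
    ), class = "read_sim")
  })
}

empty_pileup <- function() {
  tibble::tibble(sample = character(), chrom = character(), pos = integer(),
                 read_start = integer(), read_end = integer(),
                 orientation = character(), barcode = character(),
                 base = character(), ref = character(),
                 baseq = integer(), mapq = integer())
}

# One sample's reads; RNG state is set by the caller.
sample_reads <- function(smp, panel, cont_hap,
                         mt_pos, mt_cons, mt_cont, mt_depth,
                         x_pos, x_major, x_minor, x_maf, cont_x,
                         n_y_sites, n_flank_sites, read_length,
                         base_error, low_qual_rate, bases) {
  L <- read_length
  quals <- function(n) {
    q <- sample(25:40, n, replace = TRUE)
    low <- runif(n) < low_qual_rate
    q[low] <- sample(5:19, sum(low), replace = TRUE)
    as.integer(q)
  }
  mapqs <- function(n) {
    m <- rep(37L, n)
    low <- runif(n) < low_qual_rate
    m[low] <- sample(0:9, sum(low), replace = TRUE)
    as.integer(m)
  }
  maybe_err <- function(b, rate = base_error) {
    e <- runif(length(b)) < rate
    if (any(e)) {
      b[e] <- vapply(b[e], function(x) sample(setdiff(bases, x), 1), "")
    }
    b
  }
  out <- list()

  # --- autosomal SNP-overlapping reads ---
  hap <- panel$calls[match(smp$sample, panel$ind$id), ]
  if (is.na(match(smp$sample, panel$ind$id))) {
    # cohort sample not in panel: draw a haplotype from its population's freqs
    fr <- pop_freqs(panel, smp$population)$p
    hap <- rbinom(length(fr), 1L, ifelse(is.na(fr), 0.5, fr))
  }
  depth <- rpois(ncol(panel$calls), smp$coverage)
  idx <- rep(seq_along(depth), depth)
  if (length(idx) > 0) {
    pos <- panel$snp$pos[idx]
    offset <- sample(2:(L - 3), length(idx), replace = TRUE)
    allele <- hap[idx]
    contam <- runif(length(idx)) < smp$contamination
    allele[contam] <- cont_hap[idx][contam]
    base <- ifelse(allele == 1L, panel$snp$alt[idx], panel$snp$ref[idx])
    out$auto <- tibble::tibble(
      sample = smp$sample, chrom = panel$snp$chrom[idx], pos = pos,
      read_start = pos - offset, read_end = pos - offset + L - 1L,
      orientation = sample(c("+", "-"), length(idx), replace = TRUE),
      barcode = .barcodes(length(idx)),
      base = maybe_err(base), ref = panel$snp$ref[idx],
      baseq = quals(length(idx)), mapq = mapqs(length(idx))
    )
  }

  # --- terminal-signal (flanking) reads: 5' base carries the damage signal ---
  fdepth <- rpois(n_flank_sites, smp$coverage)
  fidx <- rep(seq_len(n_flank_sites), fdepth)
  if (length(fidx) > 0) {
    fpos <- 250000000L + fidx * 100L
    fref <- sample(bases, length(fidx), replace = TRUE,
                   prob = c(0.3, 0.25, 0.2, 0.25))
    fbase <- fref
    dmg <- fref == "C" & runif(length(fidx)) < smp$damage_rate
    fbase[dmg] <- "T"
    ori <- sample(c("+", "-"), length(fidx), replace = TRUE)
    out$flank <- tibble::tibble(
      sample = smp$sample, chrom = "1", pos = fpos,
      read_start = ifelse(ori == "+", fpos, fpos - L + 1L),
      read_end = ifelse(ori == "+", fpos + L - 1L, fpos),
      orientation = ori, barcode = .barcodes(length(fidx)),
      base = fbase, ref = fref,
      baseq = quals(length(fidx)), mapq = mapqs(length(fidx))
    )
  }

  # --- mitochondrial reads ---
  mdepth <- rpois(length(mt_pos), mt_depth)
  midx <- rep(seq_along(mt_pos), mdepth)
  if (length(midx) > 0) {
    from_cont <- runif(length(midx)) < smp$contamination
    mbase <- ifelse(from_cont, mt_cont[midx], mt_cons[midx])
    mpos <- mt_pos[midx]
    moff <- sample(2:(L - 3), length(midx), replace = TRUE)
    out$mt <- tibble::tibble(
      sample = smp$sample, chrom = "MT", pos = mpos,
      read_start = mpos - moff, read_end = mpos - moff + L - 1L,
      orientation = "+", barcode = .barcodes(length(midx)),
      base = maybe_err(mbase, 0.005), ref = mt_cons[midx],
      baseq = quals(length(midx)), mapq = 37L
    )
  }

  # --- X chromosome ---
  x_cov <- if (smp$sex == "M") smp$coverage / 2 else smp$coverage
  xdepth <- rpois(length(x_pos), x_cov)
  xidx <- rep(seq_along(x_pos), xdepth)
  if (length(xidx) > 0) {
    # endogenous haplotypes carry the panel major allele; the contaminant
    # carries minor alleles at the panel frequencies (the structure the
    # moments contamination estimator measures)
    carried <- rep(0L, length(xidx))
    contam <- runif(length(xidx)) < smp$contamination
    carried[contam] <- cont_x[xidx][contam]
    xbase <- ifelse(carried == 1L, x_minor[xidx], x_major[xidx])
    xp <- x_pos[xidx]
    xoff <- sample(2:(L - 3), length(xidx), replace = TRUE)
    out$x <- tibble::tibble(
      sample = smp$sample, chrom = "X", pos = xp,
      read_start = xp - xoff, read_end = xp - xoff + L - 1L,
      orientation = "+", barcode = .barcodes(length(xidx)),
      base = maybe_err(xbase), ref = x_major[xidx],
      baseq = quals(length(xidx)), mapq = mapqs(length(xidx))
    )
  }

  # --- Y chromosome (trace mismapping only, for females) ---
  y_rate <- if (smp$sex == "M") smp$coverage / 2 else 0
  ydepth <- rpois(n_y_sites, y_rate)
  yidx <- rep(seq_len(n_y_sites), ydepth)
  if (length(yidx) > 0) {
    yp <- 2000000L + yidx * 1000L
    yoff <- sample(2:(L - 3), length(yidx), replace = TRUE)
    out$y <- tibble::tibble(
      sample = smp$sample, chrom = "Y", pos = yp,
      read_start = yp - yoff, read_end = yp - yoff + L - 1L,
      orientation = "+", barcode = .barcodes(length(yidx)),
      base = "A", ref = "A",
      baseq = quals(length(yidx)), mapq = mapqs(length(yidx))
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate uniparental lineage markers
#'
#' Assigns each sample a true leaf haplogroup on the given mitochondrial and
#' Y trees, then emits (i) a per-sample mitochondrial mutation list equal to
#' the defining positions on the root-to-leaf path plus optional private
#' noise positions, and (ii) per-sample Y marker observations: derived on
#' the path, ancestral off the path, with transition markers flipped to the
#' wrong state at rate `y_error_rate` (emulating residual damage). Females
#' receive no Y observations.
#'
#' @param cohort Cohort tibble (columns `sample`, `sex`; optional
#'   `mt_leaf` / `y_leaf` columns pin the true leaves).
#' @param mt_tree,y_tree [haplo_tree()] objects.
#' @param noise Expected number of private (off-path) mitochondrial noise
#'   positions per sample.
#' @param y_error_rate Probability that an observed transition marker is
#'   flipped (derived <-> ancestral).
#' @param y_missing_rate Fraction of Y markers unobserved.
#' @param seed Integer seed.
#' @return A list with `mt` (tibble: sample, true_leaf, mutations
#'   comma-string) and `y` (tibble: sample, true_leaf, pos, state,
#'   is_transition).
#' @export
sim_lineage_markers <- function(cohort, mt_tree, y_tree,
                                noise = 0, y_error_rate = 0,
                                y_missing_rate = 0, seed = 1) {
  stopifnot(inherits(mt_tree, "haplo_tree"), inherits(y_tree, "haplo_tree"))
  with_seed(seed, {
    mt_leaves <- haplo_leaves(mt_tree)
    y_leaves <- haplo_leaves(y_tree)
    n <- nrow(cohort)
    mt_leaf <- if ("mt_leaf" %in% names(cohort)) cohort$mt_leaf else
      sample(mt_leaves, n, replace = TRUE)
    y_leaf <- if ("y_leaf" %in% names(cohort)) cohort$y_leaf else
      sample(y_leaves, n, replace = TRUE)
    mt <- lapply(seq_len(n), function(i) {
      path <- haplo_path(mt_tree, mt_leaf[i])
      muts <- path$pos
      if (noise > 0) {
        k <- rpois(1, noise)
        if (k > 0) {
          extra <- sample(setdiff(1:16569, muts), k)
          muts <- c(muts, extra)
        }
      }
      tibble::tibble(sample = cohort$sample[i], true_leaf = mt_leaf[i],
                     mutations = paste(sort(muts), collapse = ","))
    })
    y <- lapply(seq_len(n), function(i) {
      if (cohort$sex[i] != "M") return(NULL)
      markers <- haplo_markers(y_tree)
      onpath <- markers$node %in% haplo_path_nodes(y_tree, y_leaf[i])
      state <- ifelse(onpath, "derived", "ancestral")
      flip <- markers$is_transition & runif(nrow(markers)) < y_error_rate
      state[flip] <- ifelse(state[flip] == "derived", "ancestral", "derived")
      miss <- runif(nrow(markers)) < y_missing_rate
      state[miss] <- "missing"
      tibble::tibble(sample = cohort$sample[i], true_leaf = y_leaf[i],
                     pos = markers$pos, state = state,
                     is_transition = markers$is_transition)
    })
    list(mt = dplyr::bind_rows(mt), y = dplyr::bind_rows(y))
  })
}

#' Simulate isotope measurements and radiocarbon determinations
#'
#' Isotope values are Normal(group mean, `sigma_iso`) per analyte, with an
#' optional duplicate measurement from a second laboratory. Radiocarbon
#' measurements are Normal(mu_curve(true calendar year),
#' sqrt(sigma_c14^2 + sigma_curve^2)).
#'
#' @param cohort Cohort tibble (columns `sample`, `calendar_year`,
#'   `d13c_mean`, `d15n_mean`).
#' @param curve Calibration-curve tibble (`cal_bp`, `c14_bp`, `sigma`).
#' @param sigma_iso Measurement standard deviation, permil.
#' @param sigma_c14 Laboratory measurement error, 14C years.
#' @param duplicate_lab_rate Probability a sample is measured at a second
#'   laboratory.
#' @param seed Integer seed.
#' @return A list with `isotopes` (sample, lab, d13c, d15n) and
#'   `radiocarbon` (sample, age_bp, sigma).
#' @export
sim_isotopes_dates <- function(cohort, curve,
                               sigma_iso = 0.2, sigma_c14 = 25,
                               duplicate_lab_rate = 0, seed = 1) {
  cal_bp <- 1950 - cohort$calendar_year
  bad <- cal_bp < min(curve$cal_bp) | cal_bp > max(curve$cal_bp)
  if (any(bad)) {
    abort(sprintf("calendar year outside calibration-curve domain for sample(s): %s",
                  paste(cohort$sample[bad], collapse = ", ")))
  }
  with_seed(seed, {
    n <- nrow(cohort)
    iso <- tibble::tibble(
      sample = cohort$sample, lab = "lab1",
      d13c = rnorm(n, cohort$d13c_mean, sigma_iso),
      d15n = rnorm(n, cohort$d15n_mean, sigma_iso)
    )
    dup <- runif(n) < duplicate_lab_rate
    if (any(dup)) {
      iso2 <- tibble::tibble(
        sample = cohort$sample[dup], lab = "lab2",
        d13c = rnorm(sum(dup), cohort$d13c_mean[dup], sigma_iso),
        d15n = rnorm(sum(dup), cohort$d15n_mean[dup], sigma_iso)
      )
      iso <- dplyr::bind_rows(iso, iso2)
    }
    mu <- approx(curve$cal_bp, curve$c14_bp, xout = cal_bp)$y
    sc <- approx(curve$cal_bp, curve$sigma, xout = cal_bp)$y
    rc <- tibble::tibble(
      sample = cohort$sample,
      age_bp = rnorm(n, mu, sqrt(sigma_c14^2 + sc^2)),
      sigma = sigma_c14
    )
    list(isotopes = iso, radiocarbon = rc)
  })
}

#' Synthetic calibration curve
#'
#' A linear calendar-to-radiocarbon mapping with an optional sinusoidal
#' wiggle, for testing calibration without external curve data.
#'
#' @param from,to Calendar range, cal BP.
#' @param step Grid step, years.
#' @param sigma Curve standard deviation, years.
#' @param wiggle_amplitude,wiggle_period Amplitude (14C years) and period
#'   (calendar years) of the superimposed wiggle.
#' @return A tibble with `cal_bp`, `c14_bp`, `sigma`.
#' @export
sim_calibration_curve <- function(from = 0, to = 3000, step = 5, sigma = 15,
                                  wiggle_amplitude = 0, wiggle_period = 500) {
  cal_bp <- seq(from, to, by = step)
  tibble::tibble(
    cal_bp = cal_bp,
    c14_bp = cal_bp + wiggle_amplitude * sin(2 * pi * cal_bp / wiggle_period),
    sigma = sigma
  )
}
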
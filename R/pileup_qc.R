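#' Remove duplicate reads from a pileup
#'
#' Observations sharing (sample, chrom, read start, read end, orientation,
#' barcode) are considered copies of one molecule; the copy with the highest
#' summed base quality survives, ties broken by input order.
#'
#' @param obs Pileup tibble (columns `sample`, `chrom`, `pos`, `read_start`,
#'   `read_end`, `orientation`, `barcode`, `base`, `baseq`, `mapq`, ...).
#' @return The deduplicated tibble, in first-seen key order.
#' @export
dedupe_reads <- function(obs) {
  if (nrow(obs) == 0) return(obs)
  obs |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$read_start,
                    .data$read_end, .data$orientation, .data$barcode) |>
    dplyr::arrange(dplyr::desc(.data$baseq), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Pseudo-haploid genotype calling
#'
#' Applies the standard ancient-DNA filters -- mapping quality >= 10, base
#' quality >= 20, and at least two bases from either read end -- then at
#' each covered SNP picks one surviving observation uniformly at random
#' (seeded) as the haploid call. Bases matching neither panel allele are
#' missing.
#'
#' @param obs Deduplicated pileup tibble.
#' @param snp SNP table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param seed Integer seed for the random read draw.
#' @param min_mapq,min_baseq,end_trim Filter thresholds.
#' @param samples Optional character vector fixing the sample set (and row
#'   order) of the output; defaults to the samples present in `obs`.
#' @return A [geno_matrix()] (sex and population set to "U").
#' @export
call_pseudohaploid <- function(obs, snp, seed = 1,
                               min_mapq = 10, min_baseq = 20, end_trim = 2,
                               samples = NULL) {
  samples <- samples %||% unique(obs$sample)
  keep <- obs$mapq >= min_mapq & obs$baseq >= min_baseq &
    (obs$pos - obs$read_start) >= end_trim &
    (obs$read_end - obs$pos) >= end_trim
  f <- obs[keep, c("sample", "chrom", "pos", "base")] |>
    dplyr::inner_join(snp, by = c("chrom", "pos"))
  calls <- matrix(NA_integer_, length(samples), nrow(snp),
                  dimnames = list(samples, snp$id))
  if (nrow(f) > 0) {
    picked <- with_seed(seed, {
      f |>
        dplyr::mutate(.u = runif(dplyr::n())) |>
        dplyr::group_by(.data$sample, .data$id) |>
        dplyr::arrange(.data$.u, .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
    })
    call <- ifelse(picked$base == picked$ref, 0L,
                   ifelse(picked$base == picked$alt, 1L, NA_integer_))
    ok <- !is.na(call) & picked$sample %in% samples
    calls[cbind(match(picked$sample[ok], samples),
                match(picked$id[ok], snp$id))] <- call[ok]
  }
  geno_matrix(calls,
              ind = tibble::tibble(id = samples, sex = "U", pop = "U"),
              snp = snp)
}

#' Terminal C-to-T damage rate
#'
#' The authenticity signal of post-mortem deamination: among observations
#' whose 5'-terminal base overlies a reference C, the fraction read as T.
#' Forward reads are terminal at `read_start`, reverse reads at `read_end`.
#'
#' @param obs Pileup tibble with a `ref` column.
#' @return A tibble with one row per sample: `sample`, `n_terminal_c`,
#'   `damage_rate` (`NA` with zero informative observations).
#' @export
estimate_damage <- function(obs) {
  term <- obs |>
    dplyr::filter((.data$orientation == "+" & .data$pos == .data$read_start) |
                    (.data$orientation == "-" & .data$pos == .data$read_end),
                  .data$ref == "C")
  out <- term |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_terminal_c = dplyr::n(),
                     damage_rate = mean(.data$base == "T"), .groups = "drop")
  all_samples <- unique(obs$sample)
  missing <- setdiff(all_samples, out$sample)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(sample = missing, n_terminal_c = 0L, damage_rate = NA_real_)
    )
  }
  out[match(all_samples, out$sample), ]
}

#' Mitochondrial consensus match rate
#'
#' A two-component read-likelihood mixture preserving the decision variable
#' of consensus-based contamination screens: the consensus is the majority
#' base per covered mitochondrial position; each read is scored under the
#' consensus and under the best-matching contaminant haplotype with a
#' symmetric error rate `epsilon`, and the authentic proportion is the
#' maximum-likelihood mixture weight found by grid search on \[0, 1\].
#'
#' @param obs_mt Mitochondrial pileup observations (chrom "MT").
#' @param contaminants A tibble of contaminant haplotypes (`hap`, `pos`,
#'   `base`), or NULL for none (match rate then driven by sequencing error
#'   alone, reported as the MLE against a consensus-equal contaminant).
#' @param epsilon Symmetric per-base error rate.
#' @param min_reads Minimum mitochondrial reads per sample; below it the
#'   match rate is undefined.
#' @param grid_step Grid resolution for the mixture-weight search.
#' @return A tibble: `sample`, `n_reads`, `match_rate`, `consensus`
#'   (list-column of pos/base tibbles).
#' @export
mt_consensus_match <- function(obs_mt, contaminants = NULL, epsilon = 0.01,
                               min_reads = 100, grid_step = 0.001) {
  obs_mt <- dplyr::filter(obs_mt, .data$chrom == "MT")
  alphas <- seq(0, 1, by = grid_step)
  res <- obs_mt |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_map(function(df, key) {
      cons <- df |>
        dplyr::count(.data$pos, .data$base) |>
        dplyr::group_by(.data$pos) |>
        dplyr::arrange(dplyr::desc(.data$n), .data$base, .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup() |>
        dplyr::select("pos", "base")
      n_reads <- nrow(df)
      if (n_reads < min_reads) {
        return(tibble::tibble(sample = key$sample, n_reads = n_reads,
                              match_rate = NA_real_,
                              consensus = list(cons)))
      }
      cons_base <- cons$base[match(df$pos, cons$pos)]
      p_auth <- ifelse(df$base == cons_base, 1 - epsilon, epsilon / 3)
      best <- -Inf; best_alpha <- 1
      hap_ids <- if (is.null(contaminants)) character(0) else
        unique(contaminants$hap)
      if (length(hap_ids) == 0) {
        # no contaminant differences: likelihood flat in alpha; report MLE 1
        best_alpha <- 1
      }
      for (h in hap_ids) {
        hp <- contaminants[contaminants$hap == h, ]
        hb <- hp$base[match(df$pos, hp$pos)]
        hb <- ifelse(is.na(hb), cons_base, hb)
        p_cont <- ifelse(df$base == hb, 1 - epsilon, epsilon / 3)
        ll <- vapply(alphas, function(a) {
          sum(log(a * p_auth + (1 - a) * p_cont))
        }, 0)
        if (max(ll) > best) {
          best <- max(ll)
          best_alpha <- alphas[which.max(ll)]
        }
      }
      tibble::tibble(sample = key$sample, n_reads = n_reads,
                     match_rate = best_alpha, consensus = list(cons))
    }) |>
    dplyr::bind_rows()
  res
}

#' X-chromosome contamination in males
#'
#' Males carry one X chromosome, so apparent heterozygosity on X measures
#' contamination. A two-estimate method of moments: the base error rate is
#' estimated from sites invariant in the polymorphism panel, and the
#' contamination fraction solves
#' observed minor-allele rate = error / 3 + c * mean(panel MAF)
#' at polymorphic sites (an error hits the specific minor base a third of
#' the time), clamped to \[0, 1\]. Undefined (NA) for samples
#' covering 200 or fewer panel SNPs; apply it to genetic males only.
#'
#' @param obs_x X-chromosome pileup observations.
#' @param x_panel Known X polymorphisms: `pos`, `major`, `minor`, `maf`
#'   (maf 0 marks invariant sites).
#' @param min_snps Minimum distinct covered panel SNPs (exclusive bound).
#' @return Tibble: `sample`, `n_snps_x`, `error_rate`, `x_contamination`.
#' @export
estimate_x_contamination <- function(obs_x, x_panel, min_snps = 200) {
  obs_x <- dplyr::filter(obs_x, .data$chrom == "X") |>
    dplyr::inner_join(x_panel, by = "pos")
  obs_x |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_map(function(df, key) {
      n_cov <- dplyr::n_distinct(df$pos)
      if (n_cov <= min_snps) {
        return(tibble::tibble(sample = key$sample, n_snps_x = n_cov,
                              error_rate = NA_real_,
                              x_contamination = NA_real_))
      }
      inv <- df[df$maf == 0, ]
      pol <- df[df$maf > 0, ]
      e_hat <- if (nrow(inv) > 0) mean(inv$base != inv$major) else 0
      r <- mean(pol$base == pol$minor)
      c_hat <- (r - e_hat / 3) / mean(pol$maf)
      tibble::tibble(sample = key$sample, n_snps_x = n_cov,
                     error_rate = e_hat,
                     x_contamination = min(max(c_hat, 0), 1))
    }) |>
    dplyr::bind_rows()
}

#' Genetic sex from the X/Y alignment ratio
#'
#' R_y = #Y / (#X + #Y) over sex-chromosome observations; males carry one X
#' and one Y, females two X and no Y, so R_y separates the sexes cleanly at
#' ancient-DNA coverages.
#'
#' @param obs Pileup tibble.
#' @param min_obs Minimum sex-chromosome observations; below it the call is
#'   "U" (undetermined).
#' @param male_min,female_max R_y thresholds for the male and female calls.
#' @return Tibble: `sample`, `n_x`, `n_y`, `r_y`, `sex` ("M"/"F"/"U").
#' @export
determine_sex <- function(obs, min_obs = 100, male_min = 0.3, female_max = 0.05) {
  obs |>
    dplyr::filter(.data$chrom %in% c("X", "Y")) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_x = sum(.data$chrom == "X"),
                     n_y = sum(.data$chrom == "Y"), .groups = "drop") |>
    dplyr::mutate(
      r_y = .data$n_y / (.data$n_x + .data$n_y),
      sex = dplyr::case_when(
        .data$n_x + .data$n_y < min_obs ~ "U",
        .data$r_y >= male_min ~ "M",
        .data$r_y <= female_max ~ "F",
        TRUE ~ "U"
      )
    )
}

#' Apply the three ancient-DNA authenticity tests
#'
#' A sample passes when (1) the mitochondrial consensus match rate is at
#' least 97%, (2) the terminal C-to-T damage rate is at least 3% (the
#' minimum expected for authentic partial-UDG material), and (3) the
#' X-chromosome contamination estimate, where defined, is at most 1.5%.
#' Thresholds are inclusive; every failing test is listed as a reason.
#'
#' @param qc Tibble with columns `sample`, `mt_match_rate`, `damage_rate`,
#'   `x_contamination` (NA where undefined).
#' @param min_match,min_damage,max_x_contamination Gate thresholds.
#' @return `qc` with `pass` (logical) and `reasons` (comma string, "" when
#'   passing) appended.
#' @export
authenticity_gate <- function(qc, min_match = 0.97, min_damage = 0.03,
                              max_x_contamination = 0.015) {
  fail_mt <- !is.na(qc$mt_match_rate) & qc$mt_match_rate < min_match
  fail_dmg <- !is.na(qc$damage_rate) & qc$damage_rate < min_damage
  fail_x <- !is.na(qc$x_contamination) & qc$x_contamination > max_x_contamination
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "mt_match", if (b) "damage", if (c) "x_contamination"),
          collapse = ",")
  }, fail_mt, fail_dmg, fail_x)
  dplyr::mutate(qc, pass = !(fail_mt | fail_dmg | fail_x),
                reasons = unname(reasons))
}

#' Per-sample QC summary from a read simulation or pileup
#'
#' Convenience wrapper running deduplication, damage estimation, the
#' mitochondrial match-rate mixture, sexing, X contamination (males only)
#' and coverage accounting, then the authenticity gate.
#'
#' @param obs Pileup tibble (raw; deduplicated internally).
#' @param snp Autosomal SNP table used for coverage and SNP counting.
#' @param x_panel Known X polymorphisms (see
#'   [estimate_x_contamination()]), or NULL to skip that test.
#' @param contaminants Mitochondrial contaminant haplotypes (`hap`, `pos`,
#'   `base`), or NULL.
#' @param ... Threshold arguments passed to [authenticity_gate()].
#' @return A tibble, one row per sample, with QC metrics, `sex`, `pass` and
#'   `reasons`.
#' @export
sample_qc <- function(obs, snp, x_panel = NULL, contaminants = NULL, ...) {
  obs <- dedupe_reads(obs)
  samples <- unique(obs$sample)
  auto <- dplyr::semi_join(obs, snp, by = c("chrom", "pos"))
  covr <- auto |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(mean_coverage = dplyr::n() / nrow(snp),
                     n_snps = dplyr::n_distinct(.data$chrom, .data$pos),
                     .groups = "drop")
  dmg <- estimate_damage(obs)
  mt <- mt_consensus_match(obs, contaminants)
  sex <- determine_sex(obs)
  out <- tibble::tibble(sample = samples) |>
    dplyr::left_join(covr, by = "sample") |>
    dplyr::left_join(dmg[c("sample", "n_terminal_c", "damage_rate")], by = "sample") |>
    dplyr::left_join(
      dplyr::rename(mt[c("sample", "n_reads", "match_rate")],
                    n_mt_reads = "n_reads", mt_match_rate = "match_rate"),
      by = "sample") |>
    dplyr::left_join(sex[c("sample", "r_y", "sex")], by = "sample")
  if (!is.null(x_panel)) {
    xc <- estimate_x_contamination(obs, x_panel)
    out <- dplyr::left_join(out, xc[c("sample", "n_snps_x", "x_contamination")],
                            by = "sample")
    # the X test is only meaningful in males
    out$x_contamination[is.na(out$sex) | out$sex != "M"] <- NA_real_
  } else {
    out$x_contamination <- NA_real_
  }
  out$mean_coverage[is.na(out$mean_coverage)] <- 0
  out$n_snps[is.na(out$n_snps)] <- 0L
  authenticity_gate(out, ...)
}
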
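#' Packaged assemblage tables
#'
#' `roopkund_dossier()` returns the per-individual dossier of the 38
#' genotyped Roopkund Lake individuals (QC metrics, genetic sex, uniparental
#' haplogroups, ancestry group, calibrated date interval in years CE, and
#' stable-isotope values; replicate isotope measurements from a second
#' laboratory appear as `*_alt` columns). `roopkund_mt_panel()` returns the
#' 71-row multiplex-PCR mitochondrial panel (per-individual mutation
#' positions relative to the rCRS and the haplogroup determined from them),
#' and `roopkund_mt_tree()` the packaged haplogroup tree built from those
#' lineages.
#'
#' @return A tibble (`roopkund_dossier`, `roopkund_mt_panel`) or a
#'   [haplo_tree()] (`roopkund_mt_tree`).
#' @export
roopkund_dossier <- function() {
  readr::read_tsv(system.file("extdata", "roopkund_individuals.tsv",
                              package = "multiproxy"),
                  show_col_types = FALSE)
}

#' @rdname roopkund_dossier
#' @export
roopkund_mt_panel <- function() {
  readr::read_tsv(system.file("extdata", "roopkund_mt_panel.tsv",
                              package = "multiproxy"),
                  show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname roopkund_dossier
#' @export
roopkund_mt_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "roopkund_mt_tree.tsv",
                                   package = "multiproxy"))
}

#' Summarize a per-sample dossier
#'
#' Computes the assemblage-level quantities of interest: coverage and SNP
#' means and ranges, sex and group counts, the dated-sample count, the
#' two-sided Mann-Whitney comparison of merged d13C between the two largest
#' groups, and the minimum number of depositional events (overall and per
#' group) from the calibrated intervals.
#'
#' @param dossier Tibble with columns `sample_id` (or `sample`), `group`,
#'   `sex`, `coverage`, `n_snps`, `d13c` (optional `d13c_alt` replicate),
#'   `cal_from`, `cal_to`, `cal_open`.
#' @return A list of class `dossier_summary`.
#' @export
summarize_dossier <- function(dossier) {
  d <- dossier
  if (!"sample" %in% names(d) && "sample_id" %in% names(d)) {
    d$sample <- d$sample_id
  }
  stopifnot(nrow(d) > 0)
  d13c <- if ("d13c_alt" %in% names(d)) {
    rowMeans(cbind(d$d13c, d$d13c_alt), na.rm = TRUE)
  } else d$d13c
  d13c[is.nan(d13c)] <- NA_real_
  groups <- sort(table(d$group), decreasing = TRUE)
  mw <- NULL
  if (length(groups) >= 2) {
    ga <- names(groups)[1]; gb <- names(groups)[2]
    xa <- d13c[d$group == ga & !is.na(d13c)]
    xb <- d13c[d$group == gb & !is.na(d13c)]
    if (length(xa) > 0 && length(xb) > 0) {
      mw <- dplyr::mutate(mann_whitney(xa, xb), group_a = ga, group_b = gb)
    }
  }
  dated <- !is.na(d$cal_from)
  iv <- tibble::tibble(sample = d$sample[dated], from = d$cal_from[dated],
                       to = d$cal_to[dated],
                       open_ended = d$cal_open[dated] %in% TRUE,
                       group = d$group[dated])
  events_all <- if (nrow(iv) > 0) minimum_events(iv) else NULL
  events_by_group <- purrr::map(split(iv, iv$group), minimum_events)
  structure(list(
    n_samples = nrow(d),
    coverage = c(mean = mean(d$coverage), min = min(d$coverage),
                 max = max(d$coverage)),
    n_snps = c(mean = mean(d$n_snps), min = min(d$n_snps), max = max(d$n_snps)),
    sex_counts = table(d$sex),
    group_counts = groups,
    n_dated = sum(dated),
    mann_whitney_d13c = mw,
    events_overall = events_all,
    events_by_group = events_by_group
  ), class = "dossier_summary")
}

#' @export
print.dossier_summary <- function(x, ...) {
  cat(sprintf("<dossier_summary> %d individuals\n", x$n_samples))
  cat(sprintf("  coverage %.2fx (range %.3f-%.3f); SNPs %.0f (range %d-%d)\n",
              x$coverage["mean"], x$coverage["min"], x$coverage["max"],
              x$n_snps["mean"], x$n_snps["min"], x$n_snps["max"]))
  cat("  sex:", paste(names(x$sex_counts), x$sex_counts, sep = "=",
                      collapse = " "), "\n")
  cat("  groups:", paste(names(x$group_counts), x$group_counts, sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  dated: %d\n", x$n_dated))
  if (!is.null(x$mann_whitney_d13c)) {
    cat(sprintf("  d13C Mann-Whitney %s vs %s: U = %.1f, p = %.3g (%s)\n",
                x$mann_whitney_d13c$group_a, x$mann_whitney_d13c$group_b,
                x$mann_whitney_d13c$u, x$mann_whitney_d13c$p,
                x$mann_whitney_d13c$method))
  }
  if (!is.null(x$events_overall)) {
    cat(sprintf("  minimum depositional events: %d overall (%s)\n",
                x$events_overall$n_events,
                paste(vapply(names(x$events_by_group), function(g) {
                  sprintf("%s: %d", g, x$events_by_group[[g]]$n_events)
                }, ""), collapse = ", ")))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run, with the authenticity,
#' sexing, caution, HPD and diet thresholds at their standard defaults.
#'
#' @param n_per_group,groups Cohort design (defaults: three ancestry groups
#'   of 23, 14 and 1).
#' @param fst Pairwise F_ST between the source populations.
#' @param n_snps,n_ref_per_pop Panel size.
#' @param n_mt_sites,mt_depth,n_flank_sites Read-simulation sizes.
#' @param min_project_snps Minimum non-missing SNPs for PCA projection.
#' @param thresholds Named list: `min_match`, `min_damage`,
#'   `max_x_contamination`, `caution_snps`, `hpd_mass`, `sex_male_min`,
#'   `sex_female_max`, `diet_cutoffs`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides passed to [sim_cohort()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = c(23, 14, 1),
                            groups = c("GroupA", "GroupB", "GroupC"),
                            fst = 0.08,
                            n_snps = 4000, n_ref_per_pop = 20,
                            n_mt_sites = 150, mt_depth = 10,
                            n_flank_sites = 1500,
                            min_project_snps = 50,
                            thresholds = list(),
                            seed = 1, ...) {
  th <- utils::modifyList(list(
    min_match = 0.97, min_damage = 0.03, max_x_contamination = 0.015,
    caution_snps = 1e5, hpd_mass = 0.954,
    sex_male_min = 0.3, sex_female_max = 0.05,
    diet_cutoffs = c(-18, -14)
  ), thresholds)
  structure(list(n_per_group = n_per_group, groups = groups, fst = fst,
                 n_snps = n_snps, n_ref_per_pop = n_ref_per_pop,
                 n_mt_sites = n_mt_sites, mt_depth = mt_depth,
                 n_flank_sites = n_flank_sites,
                 min_project_snps = min_project_snps,
                 thresholds = th, seed = seed,
                 cohort_args = list(...)),
            class = "pipeline_config")
}

#' Run the multi-proxy pipeline on a synthetic cohort
#'
#' Simulates a cohort under the configured study design and runs every
#' stage in order: read QC and authenticity gating, pseudo-haploid calling,
#' PCA projection and group assignment, sex-bias permutation testing within
#' the largest group, isotope merging and group comparison, radiocarbon
#' calibration and the minimum-events analysis. Samples failing a stage are
#' carried through with flags, never dropped.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `dossier` (one row per
#'   sample), `summary` ([summarize_dossier()] output), `report`
#'   (thresholds and seeds echoed), and `truth` (the simulated cohort).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  seed <- config$seed

  model <- population_model(length(config$groups), config$fst, config$n_snps,
                            pop_names = config$groups)
  panel <- sim_genotype_panel(model, config$n_ref_per_pop,
                              seed = sub_seed(seed, 1))
  cohort <- do.call(sim_cohort, c(
    list(n_per_group = config$n_per_group, groups = config$groups,
         seed = sub_seed(seed, 2)),
    config$cohort_args
  ))
  sim <- sim_reads(cohort, panel, n_mt_sites = config$n_mt_sites,
                   mt_depth = config$mt_depth,
                   n_flank_sites = config$n_flank_sites,
                   seed = sub_seed(seed, 3))
  contam <- dplyr::mutate(sim$mt_contaminant, hap = "contaminant1")
  qc <- sample_qc(sim$pileup, panel$snp, x_panel = sim$x_panel,
                  contaminants = contam,
                  min_match = th$min_match, min_damage = th$min_damage,
                  max_x_contamination = th$max_x_contamination)
  geno <- call_pseudohaploid(dedupe_reads(sim$pileup), panel$snp,
                             seed = sub_seed(seed, 4),
                             samples = cohort$sample)
  basis <- reference_pca(panel, 2)
  proj <- lsq_project(geno, basis, min_snps = config$min_project_snps)
  centroids <- basis$scores |>
    dplyr::group_by(group = .data$pop) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop")
  grp <- assign_groups(proj, centroids = centroids)

  # sex-biased ancestry within the largest group
  main_group <- names(sort(table(grp$group), decreasing = TRUE))[1]
  axis_groups <- centroids$group[1:2]
  prop <- ancestry_proportion(
    proj,
    ref_low = as.numeric(centroids[centroids$group == axis_groups[1],
                                   startsWith(names(centroids), "PC")]),
    ref_high = as.numeric(centroids[centroids$group == axis_groups[2],
                                    startsWith(names(centroids), "PC")])
  )
  sb_table <- prop |>
    dplyr::inner_join(grp, by = "sample") |>
    dplyr::inner_join(qc[c("sample", "sex")], by = "sample") |>
    dplyr::filter(.data$group == main_group)
  sexbias <- if (sum(sb_table$sex == "M") >= 2 && sum(sb_table$sex == "F") >= 2) {
    sex_permutation_test(sb_table, n_perm = 999, seed = sub_seed(seed, 5))
  } else NULL

  curve <- sim_calibration_curve(from = 0, to = 2500, sigma = 10)
  iso <- sim_isotopes_dates(cohort, curve, duplicate_lab_rate = 0.3,
                            seed = sub_seed(seed, 6))
  merged <- merge_replicates(iso$isotopes)
  cal <- calibrate_dates(iso$radiocarbon, curve, hpd_mass = th$hpd_mass)
  # one row per sample: the spanning HPD envelope for multi-modal dates
  cal1 <- cal |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(cal_from = min(.data$from),
                     cal_to = max(.data$to),
                     cal_open = any(.data$open_ended), .groups = "drop")

  dossier <- tibble::tibble(sample = cohort$sample) |>
    dplyr::left_join(qc, by = "sample") |>
    dplyr::rename(coverage = "mean_coverage") |>
    dplyr::left_join(grp, by = "sample") |>
    dplyr::left_join(merged[c("sample", "d13c", "d15n")], by = "sample") |>
    dplyr::left_join(cal1, by = "sample") |>
    dplyr::mutate(diet_class = classify_diet(.data$d13c, th$diet_cutoffs))

  summary <- summarize_dossier(dossier)
  structure(list(
    dossier = dossier,
    summary = summary,
    sexbias = sexbias,
    report = list(config = config, thresholds = th, seed = seed,
                  stage_seeds = setNames(vapply(1:6, sub_seed, 0L, seed = seed),
                                         c("panel", "cohort", "reads", "calls",
                                           "sexbias", "isotopes"))),
    truth = cohort
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}
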
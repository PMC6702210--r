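test_that("deduplication keeps the highest-quality copy per molecule key", {
  # two identical-key reads, quals 30 and 20 -> retain the qual-30 read
  obs <- dplyr::bind_rows(pileup_row(baseq = 20, base = "C"),
                          pileup_row(baseq = 30, base = "A"))
  dd <- dedupe_reads(obs)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$baseq, 30)

  # keys differing only in the library barcode are distinct molecules
  obs2 <- dplyr::bind_rows(pileup_row(barcode = "bc1"),
                           pileup_row(barcode = "bc2"))
  expect_equal(nrow(dedupe_reads(obs2)), 2)

  # quality ties break by input order
  obs3 <- dplyr::bind_rows(pileup_row(base = "G", baseq = 30),
                           pileup_row(base = "T", baseq = 30))
  expect_equal(dedupe_reads(obs3)$base, "G")
})

test_that("random duplicate injection dedupes to the distinct-key count", {
  set.seed(42)
  n <- 500
  base <- tibble::tibble(
    sample = "s1", chrom = "1",
    pos = as.integer(sample.int(1e6, n)),
    orientation = sample(c("+", "-"), n, TRUE),
    barcode = sprintf("bc%03d", sample.int(50, n, TRUE)),
    base = sample(c("A", "C", "G", "T"), n, TRUE),
    ref = "A", baseq = 30L, mapq = 37L
  )
  base$read_start <- base$pos - 10L
  base$read_end <- base$pos + 30L
  dups <- base[runif(n) < 0.3, ]
  shuffled <- dplyr::slice_sample(dplyr::bind_rows(base, dups),
                                  prop = 1)
  key <- paste(shuffled$sample, shuffled$chrom, shuffled$read_start,
               shuffled$read_end, shuffled$orientation, shuffled$barcode)
  expect_equal(nrow(dedupe_reads(shuffled)), length(unique(key)))
})

test_that("dedupe and quality filtering commute when duplicates share qualities", {
  set.seed(1)
  n <- 300
  obs <- tibble::tibble(
    sample = "s1", chrom = "1", pos = as.integer(sample.int(1e5, n)),
    orientation = "+",
    barcode = sprintf("bc%02d", sample.int(10, n, TRUE)),
    base = "A", ref = "A",
    baseq = as.integer(sample(c(10L, 30L), n, TRUE)),
    mapq = as.integer(sample(c(5L, 37L), n, TRUE))
  )
  obs$read_start <- obs$pos - 10L
  obs$read_end <- obs$pos + 30L
  dup_idx <- runif(n) < 0.4
  obs <- dplyr::bind_rows(obs, obs[dup_idx, ])  # exact copies: same qualities
  filt <- function(x) x[x$mapq >= 10 & x$baseq >= 20, ]
  a <- dedupe_reads(filt(obs))
  b <- filt(dedupe_reads(obs))
  expect_equal(dplyr::arrange(a, pos, barcode), dplyr::arrange(b, pos, barcode))
})

test_that("pseudo-haploid calling filters and samples reads as specified", {
  snp <- tibble::tibble(id = "rs1", chrom = "1", pos = 1000L,
                        ref = "A", alt = "G")
  # single passing read carrying the reference allele -> call 0
  g <- call_pseudohaploid(pileup_row(base = "A"), snp, seed = 1)
  expect_identical(unname(g$calls[1, 1]), 0L)

  # an observation one base from the read end is excluded
  g2 <- call_pseudohaploid(pileup_row(base = "A", read_start = 999L), snp, seed = 1)
  expect_identical(unname(g2$calls[1, 1]), NA_integer_)

  # mapq and baseq filters
  expect_identical(unname(call_pseudohaploid(
    pileup_row(mapq = 9L), snp, seed = 1)$calls[1, 1]), NA_integer_)
  expect_identical(unname(call_pseudohaploid(
    pileup_row(baseq = 19L), snp, seed = 1)$calls[1, 1]), NA_integer_)

  # a base matching neither panel allele is missing
  g3 <- call_pseudohaploid(pileup_row(base = "T"), snp, seed = 1)
  expect_identical(unname(g3$calls[1, 1]), NA_integer_)
})

test_that("the random read draw is uniform over passing reads", {
  snp <- tibble::tibble(id = "rs1", chrom = "1", pos = 1000L,
                        ref = "A", alt = "G")
  obs <- dplyr::bind_rows(
    pileup_row(base = "A", barcode = "b1"),
    pileup_row(base = "A", barcode = "b2"),
    pileup_row(base = "A", barcode = "b3"),
    pileup_row(base = "G", barcode = "b4")
  )
  # binomial oracle: alt-call frequency 1/4 over seeded replicates
  n_rep <- 2000
  alt <- vapply(seq_len(n_rep), function(s) {
    call_pseudohaploid(obs, snp, seed = s)$calls[1, 1] == 1L
  }, TRUE)
  se <- sqrt(0.25 * 0.75 / n_rep)
  expect_lt(abs(mean(alt) - 0.25), 3 * se)
  # and the call is reproducible under a fixed seed
  expect_identical(call_pseudohaploid(obs, snp, seed = 7)$calls,
                   call_pseudohaploid(obs, snp, seed = 7)$calls)
})

test_that("damage estimation flags samples without informative sites", {
  obs <- pileup_row(ref = "A")  # no terminal C reference
  dmg <- estimate_damage(obs)
  expect_true(is.na(dmg$damage_rate))
  expect_identical(dmg$n_terminal_c, 0L)
})

test_that("mitochondrial match rate recovers a simulated 10% contamination", {
  cohort <- sim_cohort(n_per_group = c(3, 0, 0), contamination = 0.10, seed = 1)
  cohort$coverage <- 1
  m <- population_model(1, 0.1, 100, pop_names = "Pop1")
  panel <- sim_genotype_panel(m, 3, seed = 2)
  sim <- sim_reads(cohort, panel, mt_depth = 25, seed = 3)
  mm <- mt_consensus_match(sim$pileup,
                           dplyr::mutate(sim$mt_contaminant, hap = "c1"))
  expect_lt(abs(mean(mm$match_rate) - 0.90), 0.02)

  # pure consensus reads give match rate 1
  pure <- tibble::tibble(sample = "s", chrom = "MT", pos = rep(1:200, 2),
                         read_start = rep(1:200, 2) - 10L,
                         read_end = rep(1:200, 2) + 30L,
                         orientation = "+",
                         barcode = sprintf("b%03d", 1:400),
                         base = "A", ref = "A", baseq = 30L, mapq = 37L)
  expect_equal(mt_consensus_match(pure, NULL)$match_rate, 1)

  # fewer than 100 mitochondrial reads: undefined
  few <- pure[1:50, ]
  expect_true(is.na(mt_consensus_match(few, NULL)$match_rate))
})

test_that("X contamination is recovered in males and undefined below 200 SNPs", {
  cohort <- sim_cohort(n_per_group = c(2, 0, 0), contamination = 0.02,
                       prop_male = 1, seed = 4)
  cohort$coverage <- 3
  m <- population_model(1, 0.1, 100, pop_names = "Pop1")
  panel <- sim_genotype_panel(m, 2, seed = 5)
  sim <- sim_reads(cohort, panel, n_x_sites = 20000, seed = 6)
  xc <- estimate_x_contamination(sim$pileup, sim$x_panel)
  expect_true(all(xc$x_contamination >= 0.015 & xc$x_contamination <= 0.025))

  # zero minor-allele observations -> exactly 0
  clean <- tibble::tibble(sample = "s", chrom = "X",
                          pos = sim$x_panel$pos[1:300],
                          read_start = sim$x_panel$pos[1:300] - 10L,
                          read_end = sim$x_panel$pos[1:300] + 30L,
                          orientation = "+", barcode = sprintf("b%03d", 1:300),
                          base = sim$x_panel$major[1:300],
                          ref = sim$x_panel$major[1:300],
                          baseq = 30L, mapq = 37L)
  expect_equal(estimate_x_contamination(clean, sim$x_panel)$x_contamination, 0)

  # 150 covered SNPs: undefined, not a failure
  small <- clean[1:150, ]
  expect_true(is.na(estimate_x_contamination(small, sim$x_panel)$x_contamination))
})

test_that("sex determination follows the R_y thresholds", {
  mk <- function(nx, ny) dplyr::bind_rows(
    if (nx > 0) pileup_row(chrom = "X")[rep(1, nx), ],
    if (ny > 0) pileup_row(chrom = "Y")[rep(1, ny), ]
  )
  expect_equal(determine_sex(mk(500, 0))$sex, "F")
  expect_equal(determine_sex(mk(500, 500))$sex, "M")
  expect_equal(determine_sex(mk(850, 150))$sex, "U")   # R_y = 0.15
  expect_equal(determine_sex(mk(50, 0))$sex, "U")      # below min_obs

  # simulated sexes are recovered at moderate coverage
  cohort <- sim_cohort(n_per_group = c(6, 0, 0), seed = 7)
  cohort$coverage <- 0.5
  m <- population_model(1, 0.1, 100, pop_names = "Pop1")
  panel <- sim_genotype_panel(m, 6, seed = 8)
  sim <- sim_reads(cohort, panel, seed = 9)
  sx <- determine_sex(sim$pileup)
  expect_equal(sx$sex[match(cohort$sample, sx$sample)], cohort$sex)
})

test_that("the authenticity gate applies the three thresholds inclusively", {
  qc <- tibble::tibble(
    sample = c("pass", "mt_fail", "dmg_fail", "boundary"),
    mt_match_rate = c(0.996, 0.95, 0.999, 0.97),
    damage_rate = c(0.071, 0.05, 0.025, 0.03),
    x_contamination = c(0.004, NA, NA, 0.015)
  )
  g <- authenticity_gate(qc)
  expect_equal(g$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(g$reasons[2], "mt_match")
  expect_equal(g$reasons[3], "damage")
  expect_equal(g$reasons[4], "")
})

test_that("clean well-damaged samples pass the gate at a high rate", {
  cohort <- sim_cohort(n_per_group = c(12, 0, 0), contamination = 0,
                       damage_rate = 0.05, seed = 10)
  cohort$coverage <- pmax(cohort$coverage, 0.3)
  m <- population_model(1, 0.1, 500, pop_names = "Pop1")
  panel <- sim_genotype_panel(m, 12, seed = 11)
  sim <- sim_reads(cohort, panel, n_flank_sites = 4000, mt_depth = 15, seed = 12)
  qc <- sample_qc(sim$pileup, panel$snp, x_panel = sim$x_panel,
                  contaminants = dplyr::mutate(sim$mt_contaminant, hap = "c1"))
  expect_true(all(qc$pass))
})
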
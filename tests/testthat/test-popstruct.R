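test_that("reference PCA separates drifted populations and is deterministic", {
  m <- population_model(2, 0.1, 5000)
  g <- sim_genotype_panel(m, 15, seed = 51)
  b1 <- reference_pca(g, 2)
  b2 <- reference_pca(g, 2)
  expect_identical(b1$loadings, b2$loadings)   # sign convention fixes runs
  pc1 <- b1$scores$PC1
  expect_true(max(pc1[b1$scores$pop == "Pop1"]) <
                min(pc1[b1$scores$pop == "Pop2"]) ||
              max(pc1[b1$scores$pop == "Pop2"]) <
                min(pc1[b1$scores$pop == "Pop1"]))
})

test_that("degenerate panels carry no variance beyond the leading structure", {
  # identical samples make every SNP monomorphic: all are dropped and no
  # component can be extracted
  calls <- matrix(rep(c(0L, 1L), length.out = 100), nrow = 8, ncol = 100,
                  byrow = TRUE)
  g <- geno_matrix(calls,
                   ind = tibble::tibble(id = paste0("s", 1:8), sex = "U",
                                        pop = "P"),
                   snp = tibble::tibble(id = paste0("v", 1:100), chrom = "1",
                                        pos = 1:100 * 1000L, ref = "A",
                                        alt = "G"))
  expect_error(suppressMessages(reference_pca(g, 2)), "rank")

  # one divergent sample: a single direction carries all the variance
  calls[8, 1:50] <- 1L - calls[8, 1:50]
  g2 <- geno_matrix(calls, g$ind, g$snp)
  b <- suppressMessages(reference_pca(g2, 2))
  expect_lt(b$eigenvalues[2] / b$eigenvalues[1], 1e-10)
})

test_that("projection reproduces in-sample coordinates and handles missingness", {
  m <- population_model(2, 0.1, 4000)
  g <- sim_genotype_panel(m, 10, seed = 52)
  basis <- reference_pca(g, 2)
  proj <- lsq_project(g, basis, min_snps = 100)
  # complete data: projection equals the in-sample PCA coordinates
  expect_lt(max(abs(proj$PC1 - basis$scores$PC1)), 1e-8)
  expect_lt(max(abs(proj$PC2 - basis$scores$PC2)), 1e-8)

  # 50% missingness barely moves a fresh Pop1 draw relative to its own
  # complete-data projection (out-of-sample scores shrink toward the
  # origin at n << p, so the in-sample centroid is not the reference)
  fr <- attr(g, "true_freqs")
  set.seed(53)
  probes <- t(vapply(1:10, function(i) {
    rbinom(ncol(g$calls), 1L, fr[, 1])
  }, integer(ncol(g$calls))))
  masked <- probes
  masked[matrix(runif(length(masked)) < 0.5, nrow(masked))] <- NA_integer_
  mk <- function(calls, tag) geno_matrix(
    calls,
    ind = tibble::tibble(id = paste0(tag, 1:10), sex = "U", pop = "Pop1"),
    snp = g$snp)
  full <- lsq_project(mk(probes, "p"), basis, min_snps = 100)
  half <- lsq_project(mk(masked, "p"), basis, min_snps = 100)
  cen1 <- mean(basis$scores$PC1[basis$scores$pop == "Pop1"])
  cen2 <- mean(basis$scores$PC1[basis$scores$pop == "Pop2"])
  gap <- abs(cen1 - cen2)
  expect_lt(max(abs(half$PC1 - full$PC1)), 0.1 * gap)
  # and every masked probe still falls on its own population's side
  side1 <- sign(cen1 - cen2)
  expect_true(all(sign(half$PC1 - (cen1 + cen2) / 2) == side1))

  # an all-missing sample is flagged undefined
  g3 <- geno_matrix(rbind(g$calls, rep(NA_integer_, ncol(g$calls))),
                    dplyr::bind_rows(g$ind,
                                     tibble::tibble(id = "void", sex = "U",
                                                    pop = "Pop1")),
                    g$snp)
  proj3 <- lsq_project(g3, basis, min_snps = 100)
  expect_false(proj3$projected[proj3$sample == "void"])
  expect_true(is.na(proj3$PC1[proj3$sample == "void"]))
})

test_that("group assignment recovers simulated clusters", {
  m <- population_model(3, 0.12, 4000)
  g <- sim_genotype_panel(m, 12, seed = 54)
  basis <- reference_pca(g, 2)
  # k-medoids partition matches the truth up to relabeling
  grp <- assign_groups(basis$scores, k = 3)
  expect_equal(adjusted_rand(grp$group, g$ind$pop), 1)
  # k = 1: everything in one group
  grp1 <- assign_groups(basis$scores, k = 1)
  expect_equal(length(unique(grp1$group)), 1)
  expect_error(assign_groups(basis$scores[1:2, ], k = 5), "exceeds")

  # nearest-centroid ties go to the lowest-index centroid
  coords <- tibble::tibble(sample = "s", PC1 = 0, PC2 = 0)
  cents <- tibble::tibble(group = c("L", "R"), PC1 = c(-1, 1), PC2 = 0)
  expect_message(ga <- assign_groups(coords, centroids = cents),
                 "equidistant")
  expect_equal(ga$group, "L")
})

test_that("F_ST behaves at the boundary cases", {
  m <- population_model(1, 0, 8000, pop_names = "P")
  g <- sim_genotype_panel(m, 20, seed = 55)
  # random split of one population: estimate 0 within 2 jackknife SE
  g$ind$pop[11:20] <- "Q"
  f <- fst_pairwise(g, "P", "Q")
  expect_lt(abs(f$estimate), 2 * f$se)

  # fixed differences at all SNPs -> 1
  calls <- rbind(matrix(0L, 4, 200), matrix(1L, 4, 200))
  gf <- geno_matrix(calls,
                    ind = tibble::tibble(id = paste0("s", 1:8), sex = "U",
                                         pop = rep(c("A", "B"), each = 4)),
                    snp = tibble::tibble(id = paste0("v", 1:200), chrom = "1",
                                         pos = 1:200 * 1000L, ref = "A",
                                         alt = "G"))
  expect_equal(fst_pairwise(gf, "A", "B")$estimate, 1)

  expect_error(fst_pairwise(g, "P", "missingpop"), "missingpop")
})

test_that("F_ST of random splits stays within 2 SE across seeds", {
  for (s in 1:20) {
    m <- population_model(1, 0, 3000, pop_names = "P")
    g <- sim_genotype_panel(m, 16, seed = 500 + s)
    g$ind$pop[9:16] <- "Q"
    f <- fst_pairwise(g, "P", "Q")
    expect_lt(abs(f$estimate), 2.5 * f$se)
  }
})

test_that("f4 algebraic identities hold exactly", {
  m <- population_model(5, 0.1, 2000,
                        pop_names = c("A", "B", "C", "D", "E"))
  g <- sim_genotype_panel(m, 8, seed = 56)
  # f4(A, A; C, D) = 0 exactly
  expect_equal(f4_stat(g, "A", "A", "C", "D")$estimate, 0)
  # swapping the first pair flips the sign exactly
  f_ab <- f4_stat(g, "A", "B", "C", "D")
  f_ba <- f4_stat(g, "B", "A", "C", "D")
  expect_equal(f_ab$estimate, -f_ba$estimate)
  # linearity on identical SNP sets (complete data):
  # f4(A,B;C,D) + f4(A,B;D,E) = f4(A,B;C,E)
  lhs <- f4_stat(g, "A", "B", "C", "D")$estimate +
    f4_stat(g, "A", "B", "D", "E")$estimate
  rhs <- f4_stat(g, "A", "B", "C", "E")$estimate
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("f4 is null-calibrated under an unadmixed tree", {
  # tree ((S1,O3),(S2,O4)): f4(S1,O3; S2,O4) has expectation 0
  z <- vapply(1:60, function(i) {
    g <- sim_structured_panel(3000, n_per_pop = 8, seed = 600 + i)
    f4_stat(g, "S1", "O3", "S2", "O4")$z
  }, 0)
  expect_gte(mean(abs(z) < 3), 0.95)
})

test_that("a single right pair reduces the cladality test to a squared Z", {
  g <- sim_structured_panel(4000, n_per_pop = 8, seed = 57)
  f <- f4_stat(g, "S1", "S2", "O1", "O2")
  ct <- cladality_test(g, "S1", "S2", c("O1", "O2"))
  expect_equal(ct$statistic, f$z^2, tolerance = 1e-6)
  expect_equal(ct$dof, 1)
})

test_that("kinship scan separates duplicates, relatives and unrelated pairs", {
  m <- population_model(1, 0, 20000, pop_names = "P")
  g <- sim_genotype_panel(m, 12, seed = 58)
  fr <- attr(g, "true_freqs")
  set.seed(59)
  # duplicate of sample 1 (same genotypes) and a parent-offspring pair:
  # the child shares one allele per locus, here emulated by copying the
  # parent call at half the loci
  dup <- g$calls[1, ]
  child <- g$calls[2, ]
  swap <- runif(ncol(g$calls)) < 0.5
  child[swap] <- rbinom(sum(swap), 1L, fr[swap, 1])
  g2 <- geno_matrix(rbind(g$calls, dup, child),
                    dplyr::bind_rows(g$ind,
                                     tibble::tibble(id = c("dup1", "child2"),
                                                    sex = "U", pop = "P")),
                    g$snp)
  kin <- kinship_scan(g2, min_overlap = 5000)
  dup_pair <- kin[kin$sample_a == "P_1" & kin$sample_b == "dup1", ]
  expect_true(dup_pair$relationship %in% c("identical", "first_degree"))
  rel_pair <- kin[kin$sample_a == "P_2" & kin$sample_b == "child2", ]
  expect_true(rel_pair$relationship != "unrelated")

  # mismatch ordering: same-individual < parent-offspring < unrelated
  unrelated <- kin[!(kin$sample_a %in% c("P_1", "P_2", "dup1", "child2")) &
                     !(kin$sample_b %in% c("P_1", "P_2", "dup1", "child2")), ]
  expect_lt(dup_pair$mismatch, rel_pair$mismatch)
  expect_lt(rel_pair$mismatch, mean(unrelated$mismatch))

  # a panmictic cohort has no flagged pairs
  base <- kinship_scan(g, min_overlap = 5000)
  expect_true(all(base$relationship == "unrelated"))

  # insufficient overlap is reported as such
  g3 <- g
  g3$calls[1, 101:ncol(g3$calls)] <- NA_integer_
  kin3 <- kinship_scan(g3, min_overlap = 5000)
  expect_true(all(kin3$relationship[kin3$sample_a == "P_1"] ==
                    "insufficient_data"))
})
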
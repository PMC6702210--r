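test_that("tree loading validates structure", {
  # duplicate defining position on one root-to-leaf path is rejected
  bad <- data.frame(node = c("r", "a", "b"), parent = c(NA, "r", "a"),
                    mutations = c("", "100", "200,100"))
  expect_error(haplo_tree(bad), "recurs")
  # the same position on different branches is fine
  ok <- data.frame(node = c("r", "a", "b"), parent = c(NA, "r", "r"),
                   mutations = c("", "100", "100,200"))
  expect_s3_class(haplo_tree(ok), "haplo_tree")
  expect_error(haplo_tree(data.frame(node = c("a", "a"),
                                     parent = c(NA, "a"),
                                     mutations = "")), "unique")
  expect_error(haplo_tree(data.frame(node = c("a", "b"),
                                     parent = c(NA, NA),
                                     mutations = "")), "root")
})

test_that("mtDNA assignment matches printed lineages and handles edge cases", {
  tree <- roopkund_mt_tree()
  # the M3 lineage defined by 15043 + 16126
  expect_equal(assign_mt_haplogroup(c(15043, 16126), tree)$haplogroup, "M3")
  # empty mutation list -> root (rCRS-like)
  expect_equal(assign_mt_haplogroup(integer(0), tree)$node, "rCRS")
  expect_error(assign_mt_haplogroup(c(20000), tree), "16569")
})

test_that("mtDNA scoring equals the exhaustive all-node oracle", {
  tree <- random_haplo_tree(50, seed = 21, max_pos = 16569L)
  all_pos <- unlist(lapply(tree$paths, function(p) p$pos))
  set.seed(22)
  for (i in 1:25) {
    obs <- sample(c(sample(all_pos, 3), sample.int(16569L, 2)))
    got <- assign_mt_haplogroup(obs, tree)
    sc <- exhaustive_mt_scores(tree, obs)
    if (all(vapply(tree$nodes$node, function(nd) {
      sum(tree$paths[[nd]]$pos %in% obs) == 0
    }, TRUE))) {
      expect_equal(got$node, tree$root)
    } else {
      cand <- names(sc)[sc == max(sc)]
      depth <- tree$nodes$depth[match(cand, tree$nodes$node)]
      expect_equal(got$score, max(sc))
      expect_true(got$node %in% cand[depth == min(depth)])
    }
  }
})

test_that("unobserved path positions outside the assayed set are not penalized", {
  tr <- haplo_tree(data.frame(node = c("r", "a", "b"),
                              parent = c(NA, "r", "a"),
                              mutations = c("", "100", "200,300")))
  # 200/300 unobserved: with full penalty node a wins
  expect_equal(assign_mt_haplogroup(100, tr)$node, "a")
  # but if the assay only covered position 100, b ties a and the
  # shallower node is kept
  expect_equal(assign_mt_haplogroup(100, tr, assayed = c(100))$node, "a")
})

test_that("Y assignment recovers exact paths and weights transitions at 1/3", {
  tr <- haplo_tree(data.frame(
    node = c("root", "P", "X", "Y"),
    parent = c(NA, "root", "P", "P"),
    mutations = c("",
                  "A1000G,C2000A",       # transition + transversion support
                  "A3000G,C3500A",       # transition marker + transversion
                  "C4000G,C4500A")
  ))
  # observations derived along the path to X except its transition marker;
  # Y contradicted by its transversion marker instead
  obs <- tibble::tibble(
    pos = c(1000, 2000, 3000, 3500, 4000, 4500),
    state = c("derived", "derived", "ancestral", "derived",
              "ancestral", "derived")
  )
  res <- assign_y_haplogroup(obs, tr)
  # hand-computed: X = 4/3 - 1/3 + 1 = 2; Y = 4/3 - 1 + 1 = 4/3; P = 4/3
  expect_equal(res$node, "X")
  expect_equal(res$score, 2)

  # an exactly-derived path with ancestral elsewhere recovers the leaf
  obs2 <- tibble::tibble(pos = c(1000, 2000, 3000, 3500, 4000, 4500),
                         state = c("derived", "derived", "derived", "derived",
                                   "ancestral", "ancestral"))
  expect_equal(assign_y_haplogroup(obs2, tr)$node, "X")

  # no informative observations -> not callable
  obs3 <- tibble::tibble(pos = c(1000), state = "missing")
  expect_false(assign_y_haplogroup(obs3, tr)$callable)

  # caution flag tracks the autosomal SNP count
  expect_true(assign_y_haplogroup(obs2, tr, n_snps_total = 50278)$caution)
  expect_false(assign_y_haplogroup(obs2, tr, n_snps_total = 150000)$caution)
})

test_that("adding an unobserved subtree never changes an assignment", {
  tr <- random_haplo_tree(30, seed = 31)
  markers <- do.call(rbind, lapply(tr$paths, function(p) p))
  set.seed(32)
  obs <- tibble::tibble(pos = sample(unique(markers$pos), 10),
                        state = sample(c("derived", "ancestral"), 10, TRUE))
  before <- assign_y_haplogroup(obs, tr)
  # graft a new subtree with fresh positions under a random node
  df <- data.frame(node = tr$nodes$node, parent = tr$nodes$parent,
                   mutations = vapply(tr$nodes$node, function(nd) {
                     mu <- tr$paths[[nd]]
                     mu <- mu[mu$node == nd, ]
                     paste(sprintf("%s%d%s", mu$anc, mu$pos, mu$der),
                           collapse = ",")
                   }, ""))
  df$parent[df$parent == ""] <- NA
  df2 <- rbind(df, data.frame(node = c("Z1", "Z2"),
                              parent = c(df$node[5], "Z1"),
                              mutations = c("A99000001C", "G99000002T")))
  after <- assign_y_haplogroup(obs, haplo_tree(df2))
  expect_equal(after$node, before$node)
  expect_equal(after$score, before$score)
})

test_that("simulated lineages round-trip through both callers", {
  yt <- random_haplo_tree(40, seed = 41)
  mt <- random_haplo_tree(25, seed = 42, max_pos = 16569L)
  cohort <- sim_cohort(n_per_group = c(60, 0, 0), prop_male = 1, seed = 43)
  lm <- sim_lineage_markers(cohort, mt, yt, y_error_rate = 0, seed = 44)
  y_calls <- vapply(split(lm$y, lm$y$sample), function(df) {
    assign_y_haplogroup(df, yt)$node
  }, "")
  y_truth <- vapply(split(lm$y, lm$y$sample), function(df) df$true_leaf[1], "")
  expect_equal(mean(y_calls == y_truth), 1)
  mt_calls <- vapply(seq_len(nrow(lm$mt)), function(i) {
    assign_mt_haplogroup(lm$mt$mutations[i], mt)$node
  }, "")
  expect_equal(mean(mt_calls == lm$mt$true_leaf), 1)

  # females yield no Y observations and are therefore not callable
  cohort_f <- sim_cohort(n_per_group = c(5, 0, 0), prop_male = 0, seed = 45)
  lm_f <- sim_lineage_markers(cohort_f, mt, yt, seed = 46)
  expect_equal(nrow(lm_f$y), 0)
})
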
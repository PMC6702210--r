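# Shared helpers: independent oracles and small generators used across tests.

# Random allele-annotated haplogroup tree with globally unique positions.
random_haplo_tree <- function(n_nodes, seed, n_mut = 2, max_pos = 50000000L) {
  set.seed(seed)
  nodes <- c("root", sprintf("N%03d", seq_len(n_nodes - 1)))
  parent <- c(NA, vapply(2:n_nodes, function(i) nodes[sample.int(i - 1, 1)], ""))
  pool <- sample.int(max_pos, (n_nodes - 1) * n_mut + 10)
  k <- 0
  muts <- c("", vapply(seq_len(n_nodes - 1) + 1, function(i) {
    m <- sample.int(n_mut, 1)
    pos <- pool[(k + 1):(k + m)]
    k <<- k + m
    anc <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
    paste0(anc, pos, der, collapse = ",")
  }, ""))
  haplo_tree(data.frame(node = nodes, parent = parent, mutations = muts))
}

# Exhaustive per-node weighted Y score (independent of the BFS path).
exhaustive_y_scores <- function(tree, obs, transition_weight = 1 / 3) {
  vapply(tree$nodes$node, function(nd) {
    path <- tree$paths[[nd]]
    s <- 0
    for (j in seq_len(nrow(path))) {
      o <- obs[obs$pos == path$pos[j], ]
      if (nrow(o) == 0 || o$state[1] == "missing") next
      w <- if (isTRUE(path$is_transition[j])) transition_weight else 1
      s <- s + if (o$state[1] == "derived") w else -w
    }
    s
  }, 0)
}

# Exhaustive per-node mt score (brute-force analogue of the caller).
exhaustive_mt_scores <- function(tree, mutations, lambda = 1) {
  vapply(tree$nodes$node, function(nd) {
    p <- tree$paths[[nd]]$pos
    sum(p %in% mutations) - lambda * sum(!(p %in% mutations))
  }, 0)
}

# Brute-force minimum interval piercing over right-endpoint subsets.
brute_force_piercing <- function(from, to) {
  pts <- sort(unique(to))
  n <- length(from)
  for (k in seq_along(pts)) {
    subsets <- utils::combn(pts, k, simplify = FALSE)
    for (s in subsets) {
      covered <- vapply(seq_len(n), function(i) {
        any(s >= from[i] & s <= to[i])
      }, TRUE)
      if (all(covered)) return(k)
    }
  }
  length(pts)
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# Small deterministic pileup row constructor.
pileup_row <- function(sample = "s1", chrom = "1", pos = 1000L,
                       read_start = pos - 10L, read_end = pos + 30L,
                       orientation = "+", barcode = "bc1", base = "A",
                       ref = "A", baseq = 30L, mapq = 37L) {
  tibble::tibble(sample = sample, chrom = chrom, pos = as.integer(pos),
                 read_start = as.integer(read_start),
                 read_end = as.integer(read_end),
                 orientation = orientation, barcode = barcode, base = base,
                 ref = ref, baseq = as.integer(baseq),
                 mapq = as.integer(mapq))
}
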
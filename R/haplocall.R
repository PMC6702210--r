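#' Mutation-annotated haplogroup tree
#'
#' A rooted tree whose edges carry defining mutations. Construct from a
#' data frame with columns `node`, `parent` (NA for the root), optional
#' `haplogroup` (display label; defaults to the node id) and `mutations`
#' (comma-separated tokens, each either a bare 1-based position such as
#' `"15043"` or an allele-annotated `"C15043T"`). Transitions (A<->G,
#' C<->T) are flagged from the alleles where given.
#'
#' A position may recur in different parts of the tree, but not twice on
#' one root-to-leaf path; such trees are rejected at load.
#'
#' @param df Data frame as described above.
#' @return An object of class `haplo_tree`.
#' @export
haplo_tree <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("node", "parent") %in% names(df))) {
    abort("tree table needs `node` and `parent` columns")
  }
  if (!"haplogroup" %in% names(df)) df$haplogroup <- df$node
  if (!"mutations" %in% names(df)) df$mutations <- ""
  if (anyDuplicated(df$node)) abort("node names must be unique")
  root <- df$node[is.na(df$parent) | df$parent == ""]
  if (length(root) != 1) abort("tree must have exactly one root")
  known <- c(root, df$node)
  if (!all(df$parent[!is.na(df$parent) & df$parent != ""] %in% df$node)) {
    abort("every parent must be a defined node")
  }
  muts <- lapply(df$mutations, parse_mutations)
  names(muts) <- df$node
  # depth + path computation (iterate until stable; tree is finite)
  parent <- setNames(ifelse(is.na(df$parent), "", df$parent), df$node)
  depth <- setNames(rep(NA_integer_, nrow(df)), df$node)
  depth[root] <- 0L
  repeat {
    todo <- names(depth)[is.na(depth)]
    if (length(todo) == 0) break
    ready <- todo[!is.na(depth[parent[todo]])]
    if (length(ready) == 0) abort("tree contains a cycle or orphan nodes")
    depth[ready] <- depth[parent[ready]] + 1L
  }
  paths <- vector("list", nrow(df))
  names(paths) <- df$node
  for (nd in df$node[order(depth)]) {
    p <- parent[nd]
    above <- if (p == "" || is.na(p)) NULL else paths[[p]]
    own <- muts[[nd]]
    if (!is.null(own) && nrow(own) > 0) own$node <- nd
    path <- dplyr::bind_rows(above, own)
    if (anyDuplicated(path$pos)) {
      abort(sprintf("position %s recurs on the path to node '%s'",
                    paste(path$pos[duplicated(path$pos)], collapse = ","), nd))
    }
    paths[[nd]] <- path
  }
  structure(list(nodes = tibble::tibble(node = df$node, parent = parent,
                                        haplogroup = df$haplogroup,
                                        depth = unname(depth[df$node])),
                 root = root, paths = paths),
            class = "haplo_tree")
}

parse_mutations <- function(s) {
  if (is.na(s) || s == "") {
    return(tibble::tibble(pos = integer(), anc = character(),
                          der = character(), is_transition = logical(),
                          node = character()))
  }
  tok <- trimws(strsplit(s, ",")[[1]])
  tok <- tok[tok != ""]
  m <- regmatches(tok, regexec("^([ACGT]?)([0-9]+)([ACGT]?)$", tok))
  bad <- vapply(m, length, 0L) == 0
  if (any(bad)) abort(sprintf("cannot parse mutation token(s): %s",
                              paste(tok[bad], collapse = ", ")))
  anc <- vapply(m, `[`, "", 2)
  pos <- as.integer(vapply(m, `[`, "", 3))
  der <- vapply(m, `[`, "", 4)
  ts <- ifelse(anc != "" & der != "",
               paste0(anc, der) %in% c("AG", "GA", "CT", "TC"), NA)
  tibble::tibble(pos = pos,
                 anc = ifelse(anc == "", NA_character_, anc),
                 der = ifelse(der == "", NA_character_, der),
                 is_transition = ts, node = NA_character_)
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf("<haplo_tree> %d nodes (root '%s'), %d leaves, max depth %d\n",
              nrow(x$nodes), x$root, length(haplo_leaves(x)),
              max(x$nodes$depth)))
  invisible(x)
}

#' Read a haplogroup tree from a TSV file
#'
#' @param path TSV with columns `node`, `parent`, optional `haplogroup`,
#'   `mutations` (see [haplo_tree()]).
#' @return A `haplo_tree`.
#' @export
read_haplogroup_tree <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  haplo_tree(df)
}

#' @rdname haplo_tree
#' @param tree A `haplo_tree`.
#' @export
haplo_leaves <- function(tree) {
  setdiff(tree$nodes$node, tree$nodes$parent)
}

# Nodes on the root-to-node path (inclusive).
haplo_path_nodes <- function(tree, node) {
  out <- character(0)
  cur <- node
  while (!is.na(cur) && cur != "") {
    out <- c(cur, out)
    cur <- tree$nodes$parent[match(cur, tree$nodes$node)]
  }
  out
}

# Defining mutations on the root-to-node path.
haplo_path <- function(tree, node) {
  tree$paths[[node]]
}

# All defining markers on the tree with their carrying node.
haplo_markers <- function(tree) {
  deepest <- tree$nodes$node[which.max(tree$nodes$depth)]
  dplyr::bind_rows(lapply(tree$nodes$node, function(nd) {
    mu <- tree$paths[[nd]]
    mu[mu$node == nd, , drop = FALSE]
  })) |>
    dplyr::distinct(.data$pos, .keep_all = TRUE)
}

#' Assign a mitochondrial haplogroup from a mutation list
#'
#' Scores every node of the tree against the observed mutation positions:
#' score = |observed and on-path| - lambda * |on-path but unobserved|,
#' where positions outside an explicit `assayed` set are never penalized
#' (a multiplex panel covers few positions, so unobserved does not mean
#' absent). The maximal-score node wins; ties go to the shallower node,
#' then to tree order. An everywhere-empty intersection returns the root
#' (an rCRS-like sequence).
#'
#' @param mutations Integer vector of observed mutation positions (1-based,
#'   1..16569), or a comma-separated string.
#' @param tree A [haplo_tree()].
#' @param lambda Penalty weight for expected-but-unobserved path mutations.
#' @param assayed Optional integer vector: the positions the assay could
#'   have observed. Path positions outside it are not penalized.
#' @return A one-row tibble: `haplogroup`, `node`, `score`, `n_matched`,
#'   `n_penalized`.
#' @export
assign_mt_haplogroup <- function(mutations, tree, lambda = 1, assayed = NULL) {
  if (nrow(tree$nodes) == 0) abort("empty tree")
  if (is.character(mutations)) {
    mutations <- as.integer(strsplit(paste(mutations, collapse = ","), ",")[[1]])
  }
  mutations <- unique(mutations[!is.na(mutations)])
  if (length(mutations) > 0 && any(mutations < 1 | mutations > 16569)) {
    abort("mutation positions must lie in [1, 16569]")
  }
  stats <- lapply(tree$nodes$node, function(nd) {
    p <- tree$paths[[nd]]$pos
    matched <- sum(p %in% mutations)
    pen_set <- setdiff(p, mutations)
    if (!is.null(assayed)) pen_set <- intersect(pen_set, assayed)
    c(matched = matched, penalized = length(pen_set))
  })
  matched <- vapply(stats, `[[`, 0, "matched")
  penal <- vapply(stats, `[[`, 0, "penalized")
  score <- matched - lambda * penal
  if (all(matched == 0)) {
    i <- match(tree$root, tree$nodes$node)
  } else {
    cand <- which(score == max(score))
    cand <- cand[order(tree$nodes$depth[cand], cand)]
    i <- cand[1]
  }
  tibble::tibble(haplogroup = tree$nodes$haplogroup[i],
                 node = tree$nodes$node[i],
                 score = score[i], n_matched = matched[i],
                 n_penalized = penal[i])
}

#' Assign a Y-chromosome haplogroup by damage-aware tree search
#'
#' Breadth-first search of the Y tree accumulating per-node weighted
#' support: each defining marker on the root-to-node path contributes
#' +w when observed derived and -w when observed ancestral (a mismatch),
#' with w = 1/3 for transitions and 1 for transversions -- post-mortem
#' deamination mimics transitions, so they carry a third of the weight.
#' Missing markers contribute nothing; derived observations off the
#' accepted path are ignored by default (set `penalize_offpath_derived`
#' to subtract their weight instead). The maximal-score node is reported;
#' ties go to the shallower node. Calls from samples with fewer than
#' `caution_snps` autosomal SNPs carry a caution flag.
#'
#' @param obs Marker observations: tibble with `pos`, `state` (one of
#'   "derived", "ancestral", "missing") and optionally `is_transition`
#'   (used where the tree lacks allele annotations).
#' @param tree A [haplo_tree()].
#' @param transition_weight Weight of transition markers relative to
#'   transversions.
#' @param n_snps_total Autosomal SNP count of the sample (for the caution
#'   flag); NA suppresses the flag.
#' @param caution_snps Caution threshold on `n_snps_total`.
#' @param penalize_offpath_derived Also penalize derived observations not on
#'   the candidate path.
#' @return One-row tibble: `haplogroup`, `node`, `score`, `caution`,
#'   `callable`.
#' @export
assign_y_haplogroup <- function(obs, tree, transition_weight = 1 / 3,
                                n_snps_total = NA, caution_snps = 1e5,
                                penalize_offpath_derived = FALSE) {
  obs <- obs[obs$state %in% c("derived", "ancestral"), , drop = FALSE]
  markers <- haplo_markers(tree)
  obs <- obs[obs$pos %in% markers$pos, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(tibble::tibble(haplogroup = NA_character_, node = NA_character_,
                          score = NA_real_, caution = NA, callable = FALSE))
  }
  ts_tree <- markers$is_transition[match(obs$pos, markers$pos)]
  ts <- ifelse(!is.na(ts_tree), ts_tree,
               if ("is_transition" %in% names(obs)) obs$is_transition else FALSE)
  w <- ifelse(ts %in% TRUE, transition_weight, 1)
  sgn <- ifelse(obs$state == "derived", 1, -1)
  contrib <- setNames(w * sgn, obs$pos)
  total_derived_w <- sum(w[obs$state == "derived"])

  # breadth-first accumulation: node score = parent score + edge markers
  nodes <- tree$nodes
  score <- setNames(rep(NA_real_, nrow(nodes)), nodes$node)
  score[tree$root] <- node_edge_score(tree, tree$root, contrib)
  queue <- tree$root
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- nodes$node[nodes$parent == cur]
    for (k in kids) {
      score[k] <- score[cur] + node_edge_score(tree, k, contrib)
      queue <- c(queue, k)
    }
  }
  if (penalize_offpath_derived) {
    # subtract the weight of derived observations not on each path
    onpath_derived <- vapply(nodes$node, function(nd) {
      p <- as.character(tree$paths[[nd]]$pos)
      sum(pmax(contrib[intersect(p, names(contrib))], 0))
    }, 0)
    score <- score - (total_derived_w - onpath_derived)
  }
  cand <- which(score == max(score))
  cand <- cand[order(nodes$depth[cand], cand)]
  i <- cand[1]
  tibble::tibble(haplogroup = nodes$haplogroup[i], node = nodes$node[i],
                 score = unname(score[i]),
                 caution = if (is.na(n_snps_total)) NA else
                   n_snps_total < caution_snps,
                 callable = TRUE)
}

node_edge_score <- function(tree, node, contrib) {
  mu <- tree$paths[[node]]
  mu <- mu[mu$node == node, , drop = FALSE]
  p <- as.character(mu$pos)
  sum(contrib[intersect(p, names(contrib))])
}

#' Call mitochondrial haplogroups for a panel table
#'
#' Maps [assign_mt_haplogroup()] over a table of per-individual mutation
#' lists (the layout of a multiplex-PCR mitochondrial panel).
#'
#' @param panel Tibble with a `mutations` column (comma-separated
#'   positions; NA rows yield NA calls) and any id columns. Positions
#'   outside the mitochondrial coordinate range (1..16569) -- which occur
#'   as typographic slips in published position lists -- are dropped with
#'   a message.
#' @param tree A [haplo_tree()].
#' @param ... Passed to [assign_mt_haplogroup()].
#' @return `panel` with `called_haplogroup` and `call_score` appended.
#' @export
call_mt_panel <- function(panel, tree, ...) {
  calls <- purrr::map(panel$mutations, function(m) {
    if (is.na(m) || m == "") {
      return(tibble::tibble(haplogroup = NA_character_, score = NA_real_))
    }
    pos <- as.integer(strsplit(m, ",")[[1]])
    bad <- pos < 1 | pos > 16569
    if (any(bad)) {
      inform(sprintf("dropping out-of-range mitochondrial position(s): %s",
                     paste(pos[bad], collapse = ",")))
      pos <- pos[!bad]
    }
    assign_mt_haplogroup(pos, tree, ...)[c("haplogroup", "score")]
  })
  dplyr::mutate(panel,
                called_haplogroup = purrr::map_chr(calls, "haplogroup"),
                call_score = purrr::map_dbl(calls, "score"))
}
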
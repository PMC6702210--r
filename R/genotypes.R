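#' Pseudo-haploid genotype matrix
#'
#' A light container for pseudo-haploid calls: a samples-by-SNPs integer
#' matrix with values 0 (reference/ancestral allele), 1 (alternate allele)
#' or `NA` (missing), together with per-sample metadata (`ind`) and per-SNP
#' metadata (`snp`). This is the in-memory analogue of an EIGENSTRAT-dialect
#' fileset and the common currency of all population-structure functions.
#'
#' @param calls Integer matrix (samples x SNPs) with entries in \{0, 1, NA\}.
#'   Row names are sample ids, column names SNP ids.
#' @param ind Tibble with columns `id`, `sex`, `pop` (one row per sample).
#' @param snp Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, ind, snp) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, NA_integer_))) {
    abort("genotype calls must be 0, 1 or NA")
  }
  ind <- tibble::as_tibble(ind)
  snp <- tibble::as_tibble(snp)
  if (nrow(ind) != nrow(calls)) abort("`ind` must have one row per sample")
  if (nrow(snp) != ncol(calls)) abort("`snp` must have one row per SNP")
  if (anyDuplicated(snp$id)) abort("SNP ids must be unique")
  if (anyDuplicated(ind$id)) abort("sample ids must be unique")
  rownames(calls) <- ind$id
  colnames(calls) <- snp$id
  structure(list(calls = calls, ind = ind, snp = snp), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  cat("populations:", paste(unique(x$ind$pop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Tidy a genotype matrix into long form
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per non-missing call: `sample`, `pop`,
#'   `snp`, `call`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  idx <- which(!is.na(x$calls), arr.ind = TRUE)
  tibble::tibble(
    sample = rownames(x$calls)[idx[, 1]],
    pop = x$ind$pop[idx[, 1]],
    snp = colnames(x$calls)[idx[, 2]],
    call = x$calls[idx]
  )
}

# Per-SNP alternate-allele frequencies and call counts for one population.
pop_freqs <- function(g, pop) {
  rows <- which(g$ind$pop == pop)
  if (length(rows) == 0) abort(sprintf("population '%s' not found", pop))
  m <- g$calls[rows, , drop = FALSE]
  n <- colSums(!is.na(m))
  s <- colSums(m, na.rm = TRUE)
  list(p = ifelse(n > 0, s / n, NA_real_), n = n)
}

#' Write a genotype matrix as EIGENSTRAT-dialect files
#'
#' Writes `<prefix>.geno` (one line per SNP, one character per sample:
#' 0/1/9 in the haploid dialect), `<prefix>.snp` (id, chrom, genetic
#' position, physical position, ref, alt) and `<prefix>.ind`
#' (id, sex, population).
#'
#' @param g A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(g, prefix) {
  codes <- t(g$calls)
  codes[is.na(codes)] <- 9L
  lines <- apply(codes, 1, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- g$snp
  write.table(
    data.frame(snp$id, snp$chrom, 0, snp$pos, snp$ref, snp$alt),
    paste0(prefix, ".snp"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(
    data.frame(g$ind$id, g$ind$sex, g$ind$pop),
    paste0(prefix, ".ind"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read EIGENSTRAT-dialect files into a genotype matrix
#'
#' @param prefix Path prefix of a `.geno`/`.snp`/`.ind` fileset written by
#'   [write_eigenstrat()] (haploid 0/1/9 coding).
#' @return A [geno_matrix()].
#' @export
read_eigenstrat <- function(prefix) {
  lines <- readLines(paste0(prefix, ".geno"))
  snp <- read.table(paste0(prefix, ".snp"), sep = "\t",
                    col.names = c("id", "chrom", "gpos", "pos", "ref", "alt"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  ind <- read.table(paste0(prefix, ".ind"), sep = "\t",
                    col.names = c("id", "sex", "pop"),
                    colClasses = "character")
  m <- matrix(
    as.integer(unlist(strsplit(lines, ""), use.names = FALSE)),
    nrow = length(lines), byrow = TRUE
  )
  m[m == 9L] <- NA_integer_
  geno_matrix(t(m),
              ind = tibble::as_tibble(ind),
              snp = tibble::as_tibble(snp[c("id", "chrom", "pos", "ref", "alt")]))
}

#' @importFrom utils write.table read.table
NULL
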
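# GWAS TF prioritization: a trait's per-TAD SNP counts are compared with
# each TF's relative TAD-wise abundance (per-TAD peak count over the TF's
# mean per-TAD count). TFscore is the dot product; the cosine similarity
# normalizes it, and significance comes from a one-sided permutation of
# the SNP-count vector across TADs with BH correction over TFs.

#' Relative TAD-wise abundance of a TF
#'
#' @param counts numeric vector of per-TAD peak counts for one TF (with
#'   multiple samples, average the counts before calling).
#' @return counts divided by their mean; the output always has mean 1.
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- mean(counts)
  if (m == 0) stop("all-zero peak counts")
  counts / m
}

#' TFscore and cosine similarity between a trait and a TF
#'
#' @param snp_counts per-TAD SNP counts of the trait.
#' @param abundance per-TAD relative abundance of the TF
#'   (\code{\link{relative_abundance}}), same TAD order.
#' @return list with \code{tfscore} (dot product) and \code{cosine}.
#' @export
trait_tf_score <- function(snp_counts, abundance) {
  if (length(snp_counts) != length(abundance))
    stop("vectors must have equal length")
  n1 <- sqrt(sum(snp_counts^2)); n2 <- sqrt(sum(abundance^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm vector")
  s <- sum(snp_counts * abundance)
  list(tfscore = s, cosine = s / (n1 * n2))
}

#' Permutation significance of trait-TF cosine similarities
#'
#' The null distribution permutes the SNP-count vector across TADs (the
#' same permutations are applied against every TF). One-sided p-values
#' use the add-one rule p = (1 + #{null >= observed}) / (1 + n_perm), are
#' BH-adjusted across TFs, and flagged significant below \code{p_flag}
#' (raw p, matching a fixed figure-style threshold).
#'
#' @param snp_counts per-TAD SNP counts of one trait.
#' @param abundance_matrix TADs x TFs matrix of relative abundances.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed; required for reproducibility.
#' @param p_flag raw-p flag threshold (default 0.001).
#' @return data.frame with one row per TF: \code{tf}, \code{cosine},
#'   \code{p}, \code{p_adj} (BH), \code{significant}.
#' @export
permutation_significance <- function(snp_counts, abundance_matrix,
                                     n_perm = 10000L, seed,
                                     p_flag = 0.001) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  abundance_matrix <- as.matrix(abundance_matrix)
  if (length(snp_counts) != nrow(abundance_matrix))
    stop("snp_counts length must equal the number of TADs")
  norms <- sqrt(colSums(abundance_matrix^2))
  snorm <- sqrt(sum(snp_counts^2))
  if (snorm == 0 || any(norms == 0)) stop("zero-norm vector")
  obs <- as.vector(snp_counts %*% abundance_matrix) / (snorm * norms)
  set.seed(seed)
  n_tads <- length(snp_counts)
  perm <- matrix(0, n_perm, n_tads)
  for (b in seq_len(n_perm))
    perm[b, ] <- snp_counts[sample.int(n_tads)]
  null_cos <- sweep(perm %*% abundance_matrix, 2, snorm * norms, "/")
  exceed <- colSums(null_cos >= matrix(obs, n_perm, ncol(abundance_matrix),
                                       byrow = TRUE))
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(tf = colnames(abundance_matrix), cosine = obs, p = p,
             p_adj = stats::p.adjust(p, "BH"),
             significant = p < p_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}
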
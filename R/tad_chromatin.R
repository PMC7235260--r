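# TAD chromatin state from H3K27ac: per-TAD mean signal, per-sample
# z-transformation, biclustering of TADs x samples, and calling of A-type
# (consistently strong) and B-type (consistently weak) TADs.

#' Base-pair-weighted mean coverage per TAD
#'
#' Averages a bedGraph-like coverage track over each TAD; bases covered by
#' no interval count as signal 0, so the denominator is always the full
#' TAD length.
#'
#' @param coverage data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open, non-overlapping within the track) and
#'   \code{value}.
#' @param tads TAD data.frame (\code{tad_id}, \code{chrom}, \code{start},
#'   \code{end}).
#' @return named numeric vector of per-TAD means (TAD order preserved).
#' @export
tad_mean_signal <- function(coverage, tads) {
  .check_tads_disjoint(tads)
  known <- unique(tads$chrom)
  drop <- !(coverage$chrom %in% known)
  if (any(drop)) {
    message("ignoring ", sum(drop),
            " coverage interval(s) on chromosomes without TADs")
    coverage <- coverage[!drop, , drop = FALSE]
  }
  out <- stats::setNames(numeric(nrow(tads)), tads$tad_id)
  if (nrow(coverage) == 0) return(out)
  cov_gr <- GenomicRanges::GRanges(
    coverage$chrom, IRanges::IRanges(coverage$start + 1L, coverage$end))
  tad_gr <- GenomicRanges::GRanges(
    tads$chrom, IRanges::IRanges(tads$start + 1L, tads$end))
  hits <- GenomicRanges::findOverlaps(cov_gr, tad_gr)
  if (length(hits) > 0) {
    ov <- IRanges::pintersect(cov_gr[S4Vectors::queryHits(hits)],
                              tad_gr[S4Vectors::subjectHits(hits)])
    contrib <- IRanges::width(ov) *
      coverage$value[S4Vectors::queryHits(hits)]
    sums <- rowsum(contrib, S4Vectors::subjectHits(hits))
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out / (tads$end - tads$start)
}

#' Standardize each sample column of a TAD signal matrix
#'
#' Each sample (column) is z-transformed to mean 0, standard deviation 1 so
#' that samples with different sequencing depth become comparable.
#'
#' @param m TADs x samples numeric matrix.
#' @param sd_type \code{"population"} (divide by n; default) or
#'   \code{"sample"} (n - 1).
#' @return z-transformed matrix of the same shape.
#' @export
sample_z_transform <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 TADs")
  mu <- colMeans(m)
  cen <- sweep(m, 2, mu)
  denom <- if (sd_type == "population") nrow(m) else nrow(m) - 1L
  s <- sqrt(colSums(cen^2) / denom)
  if (any(s == 0))
    stop("constant signal in sample(s): ",
         paste(colnames(m)[s == 0], collapse = ", "))
  sweep(cen, 2, s, "/")
}

#' Hierarchically bicluster a TAD signal matrix
#'
#' Clusters TADs (rows) and samples (columns) independently by
#' hierarchical clustering and cuts each tree into \code{k} groups. TAD
#' cluster labels are re-numbered by ascending mean signal, so cluster 1
#' is always the weakest and cluster \code{k} the strongest.
#'
#' @param m TADs x samples matrix (typically z-transformed).
#' @param k number of clusters for both dimensions (default 10).
#' @param method linkage for \code{\link[stats]{hclust}} (default
#'   \code{"average"}).
#' @param metric distance for \code{\link[stats]{dist}} (default
#'   \code{"euclidean"}).
#' @return object of class \code{tad_clustering}: list with
#'   \code{tad_cluster} (named integer vector, 1 = weakest),
#'   \code{sample_cluster}, \code{cluster_means} (mean signal per TAD
#'   cluster), and \code{k}.
#' @export
bicluster <- function(m, k = 10L, method = "average", metric = "euclidean") {
  m <- as.matrix(m)
  if (k < 2) stop("k must be >= 2")
  if (k > min(dim(m))) stop("k exceeds matrix dimensions")
  rowcl <- stats::cutree(stats::hclust(stats::dist(m, metric), method), k)
  colcl <- stats::cutree(stats::hclust(stats::dist(t(m), metric), method), k)
  raw_means <- tapply(rowMeans(m), rowcl, mean)
  # relabel so cluster index increases with mean signal
  rank_of <- rank(raw_means, ties.method = "first")
  new_lab <- stats::setNames(rank_of, names(raw_means))
  tad_cluster <- stats::setNames(as.integer(new_lab[as.character(rowcl)]),
                                 rownames(m))
  cluster_means <- tapply(rowMeans(m), tad_cluster, mean)
  structure(list(tad_cluster = tad_cluster,
                 sample_cluster = stats::setNames(as.integer(colcl),
                                                  colnames(m)),
                 cluster_means = cluster_means, k = as.integer(k)),
            class = "tad_clustering")
}

#' Call A-type and B-type TADs from a clustering
#'
#' B-type TADs are the members of the weakest-mean cluster and A-type TADs
#' those of the strongest-mean cluster; TADs in intermediate clusters carry
#' no type. Optionally the \code{merge} arguments take the weakest /
#' strongest \code{n} clusters instead of exactly one.
#'
#' @param clustering a \code{\link{bicluster}} result.
#' @param merge_low,merge_high number of extreme clusters to merge into
#'   the B-type and A-type calls (default 1 each).
#' @return list with character vectors \code{a_type} and \code{b_type}
#'   (disjoint TAD id sets).
#' @export
call_ab_types <- function(clustering, merge_low = 1L, merge_high = 1L) {
  stopifnot(inherits(clustering, "tad_clustering"))
  k <- clustering$k
  if (merge_low + merge_high > k)
    stop("merged extremes exceed the number of clusters")
  cl <- clustering$tad_cluster
  b <- names(cl)[cl <= merge_low]
  a <- names(cl)[cl > k - merge_high]
  list(a_type = a, b_type = b)
}

#' Differentially active TADs between two sample groups
#'
#' Per TAD, a two-sided Welch t-test compares the signal between the two
#' groups; a TAD is predominant in the group with the higher mean when the
#' p-value passes the cutoff.
#'
#' @param m TADs x samples signal matrix.
#' @param group1,group2 character vectors of column names (>= 2 each).
#' @param p_cut significance cutoff (default 1e-10, suited to the large
#'   sample-per-group settings this contrast is designed for; relax for
#'   small synthetic cohorts).
#' @return list with \code{group1_predominant}, \code{group2_predominant}
#'   (TAD id vectors) and a per-TAD data.frame \code{table} (means, t, p).
#' @export
differential_tads <- function(m, group1, group2, p_cut = 1e-10) {
  m <- as.matrix(m)
  if (length(group1) < 2 || length(group2) < 2)
    stop("both groups need >= 2 samples")
  if (!all(c(group1, group2) %in% colnames(m)))
    stop("group sample ids must be matrix columns")
  x1 <- m[, group1, drop = FALSE]; x2 <- m[, group2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  n1 <- length(group1); n2 <- length(group2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  tab <- data.frame(tad_id = rownames(m), mean1 = m1, mean2 = m2,
                    t = tstat, p = p, stringsAsFactors = FALSE)
  list(group1_predominant = rownames(m)[m1 > m2 & p < p_cut],
       group2_predominant = rownames(m)[m2 > m1 & p < p_cut],
       table = tab)
}
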
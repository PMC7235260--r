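# TF occupancy per TAD: peak density (peaks/kb), relative-occupancy
# z-scores computed per TAD across TFs, target-TAD calls, and the
# descriptive statistics built on them (expression trend over target TADs,
# tissue coefficient of variation, autoregulation index).

#' Peak density of a sample in each TAD
#'
#' Counts peak representative points falling in each TAD and divides by
#' the TAD length in kb.
#'
#' @param ps a \code{\link{peak_set}} (filtered per the top-N rule when
#'   comparing samples).
#' @param tads TAD data.frame.
#' @param use_summit passed to \code{\link{peak_representative_point}}.
#' @return named numeric vector of densities (peaks/kb) over TADs.
#' @export
peak_density <- function(ps, tads, use_summit = FALSE) {
  stopifnot(inherits(ps, "peak_set"))
  pt <- peak_representative_point(ps, use_summit = use_summit)
  tad <- assign_to_tads(ps$peaks$chrom, pt, tads)
  counts <- table(factor(tad, levels = tads$tad_id))
  dens <- as.numeric(counts) / ((tads$end - tads$start) / 1000)
  stats::setNames(dens, tads$tad_id)
}

#' Relative TF occupancy z-scores per TAD
#'
#' For each TAD (row), standardizes the binding densities across TF
#' samples: z = (density - mean across TFs) / sd across TFs. A high z for
#' TF i in TAD j means TAD j is more densely bound by TF i than by the
#' other TFs. Rows with zero spread across TFs are set to \code{NA} with a
#' warning.
#'
#' @param density TADs x TF-samples matrix of peak densities
#'   (\code{\link{peak_density}} columns).
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return z-score matrix of the same shape (rows of \code{NA} where the
#'   across-TF sd is zero).
#' @export
tad_zscores <- function(density, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  density <- as.matrix(density)
  if (ncol(density) < 3) stop("need at least 3 TF samples")
  mu <- rowMeans(density)
  cen <- density - mu
  denom <- if (sd_type == "population") ncol(density) else ncol(density) - 1L
  s <- sqrt(rowSums(cen^2) / denom)
  z <- cen / s
  if (any(s == 0)) {
    warning(sum(s == 0), " TAD(s) with zero density spread across TFs; ",
            "z rows set to NA")
    z[s == 0, ] <- NA_real_
  }
  z
}

#' Call the target TADs of a TF
#'
#' Target TADs are those where the TF's relative occupancy z-score is at
#' least \code{threshold} (boundary inclusive).
#'
#' @param z z-score matrix from \code{\link{tad_zscores}}.
#' @param tf column name of the TF sample.
#' @param threshold z cutoff (default 1).
#' @return character vector of target TAD ids.
#' @export
call_target_tads <- function(z, tf, threshold = 1) {
  if (!(tf %in% colnames(z))) stop("TF column not found: ", tf)
  v <- z[, tf]
  rownames(z)[!is.na(v) & v >= threshold]
}

#' Trend between TF expression and target-TAD activity across cell lines
#'
#' Correlates the TF's expression with the across-target-TAD mean of a
#' per-TAD quantity (H3K27ac signal or mean gene expression), over cell
#' lines.
#'
#' @param tf_expr named numeric vector of TF expression per cell line.
#' @param tad_values TADs x cell-lines matrix of the per-TAD quantity;
#'   columns must cover the cell lines of \code{tf_expr}.
#' @param target_tads character vector of the TF's target TAD ids.
#' @return list with \code{r} (Pearson), \code{p}, \code{n} cell lines.
#' @export
target_tad_trend <- function(tf_expr, tad_values, target_tads) {
  if (length(tf_expr) < 3) stop("need at least 3 cell lines")
  if (length(target_tads) == 0) stop("no target TADs supplied")
  cells <- names(tf_expr)
  if (!all(cells %in% colnames(tad_values)))
    stop("tad_values must have a column per cell line")
  v <- colMeans(tad_values[target_tads, cells, drop = FALSE])
  if (stats::sd(v) == 0 || stats::sd(tf_expr) == 0)
    stop("constant vector; trend undefined")
  ct <- stats::cor.test(tf_expr, v)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cells))
}

#' Autoregulation index of a TF
#'
#' The TF's relative-occupancy z-score in the TAD that contains its own
#' gene; a value of at least \code{threshold} flags the TF as bound near
#' its own locus more densely than other TFs (auto-regulatory pattern).
#'
#' @param z z-score matrix (\code{\link{tad_zscores}}).
#' @param tf column name of the TF sample.
#' @param tf_gene gene id of the TF's own gene.
#' @param layout a \code{\link{genome_layout}} giving the gene's TAD.
#' @param threshold flag cutoff (default 1).
#' @return list with \code{tad_id}, \code{z} and \code{flagged}; all
#'   \code{NA}/\code{FALSE} when the gene is unmapped or the z row is
#'   degenerate.
#' @export
autoregulation_index <- function(z, tf, tf_gene, layout, threshold = 1) {
  g <- layout$genes[layout$genes$gene_id == tf_gene, , drop = FALSE]
  if (nrow(g) != 1) stop("tf_gene not in layout: ", tf_gene)
  if (is.na(g$tad_id))
    return(list(tad_id = NA_character_, z = NA_real_, flagged = FALSE))
  zv <- z[g$tad_id, tf]
  list(tad_id = g$tad_id, z = unname(zv),
       flagged = !is.na(zv) && zv >= threshold)
}

#' Coefficient of variation of expression across tissues
#'
#' @param x numeric vector of per-tissue expression (>= 2 tissues).
#' @return sd(x)/mean(x), or \code{NA} when the mean is not positive.
#' @export
tissue_cv <- function(x) {
  if (length(x) < 2) stop("need at least 2 tissues")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(x) / m
}
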
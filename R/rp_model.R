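# Regulatory potential: each peak k of a TF contributes 2^(-x_k / delta)
# (exponential kernel) or max(x_k, 1)^lambda (power-law kernel) to a gene,
# where x_k is the unsigned bp distance from the peak's representative
# point to the gene TSS, and only peaks inside the gene's TAD count.

#' Specify a regulatory-potential decay kernel
#'
#' @param kind \code{"exponential"} (half-distance parameter \code{delta},
#'   bp: the distance at which a binding site's modeled effect is halved)
#'   or \code{"powerlaw"} (dimensionless exponent \code{lambda}, negative
#'   for decay).
#' @param delta exponential half-distance in bp (> 0).
#' @param lambda power-law exponent (< 0 unless \code{force = TRUE}).
#' @param force allow a non-negative \code{lambda}.
#' @return object of class \code{decay_spec}.
#' @export
decay_spec <- function(kind = c("exponential", "powerlaw"),
                       delta = NULL, lambda = NULL, force = FALSE) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (is.null(delta) || !is.finite(delta) || delta <= 0)
      stop("exponential kernel requires delta > 0")
    spec <- list(kind = kind, delta = delta)
  } else {
    if (is.null(lambda) || !is.finite(lambda))
      stop("powerlaw kernel requires a finite lambda")
    if (lambda >= 0 && !force)
      stop("powerlaw exponent should be negative (use force = TRUE to override)")
    spec <- list(kind = kind, lambda = lambda)
  }
  structure(spec, class = "decay_spec")
}

#' @export
print.decay_spec <- function(x, ...) {
  if (x$kind == "exponential")
    cat("decay_spec: exponential, delta =", x$delta, "bp\n")
  else
    cat("decay_spec: power-law, lambda =", x$lambda, "\n")
  invisible(x)
}

#' Precompute gene-peak distance pairs within TADs
#'
#' Builds, once per (peak set, layout) pair, the sparse list of
#' (gene, |peak point - TSS|) distances over all peaks sharing the gene's
#' TAD. Scoring the same peak set under many decay parameters (as the
#' grid searches do) then reduces to re-weighting these distances.
#'
#' @param ps a \code{\link{peak_set}}.
#' @param layout a \code{\link{genome_layout}}.
#' @param use_summit passed to \code{\link{peak_representative_point}}.
#' @return object of class \code{rp_index}: list with \code{gene_ids}
#'   (mapped genes, layout order), \code{excluded} (unmapped gene ids),
#'   \code{gene_idx} and \code{dist} (parallel vectors of in-TAD pairs).
#' @export
rp_index <- function(ps, layout, use_summit = FALSE) {
  stopifnot(inherits(ps, "peak_set"), inherits(layout, "genome_layout"))
  genes <- layout$genes
  mapped <- !is.na(genes$tad_id)
  gene_ids <- genes$gene_id[mapped]
  pt <- peak_representative_point(ps, use_summit = use_summit)
  peak_tad <- assign_to_tads(ps$peaks$chrom, pt, layout$tads)
  in_tad <- !is.na(peak_tad)
  gi <- integer(0); dd <- numeric(0)
  if (any(in_tad) && length(gene_ids) > 0) {
    pt_by_tad <- split(pt[in_tad], peak_tad[in_tad])
    g_tad <- genes$tad_id[mapped]
    g_tss <- genes$tss[mapped]
    use <- g_tad %in% names(pt_by_tad)
    if (any(use)) {
      idx <- which(use)
      np <- lengths(pt_by_tad)[g_tad[idx]]
      gi <- rep.int(idx, np)
      peak_pos <- unlist(pt_by_tad[g_tad[idx]], use.names = FALSE)
      dd <- abs(peak_pos - rep.int(g_tss[idx], np))
    }
  }
  structure(list(gene_ids = gene_ids,
                 excluded = genes$gene_id[!mapped],
                 gene_idx = gi, dist = dd,
                 tf_id = ps$tf_id, sample_id = ps$sample_id),
            class = "rp_index")
}

# weight a distance vector under a kernel
.rp_weights <- function(dist, decay) {
  if (decay$kind == "exponential") 2^(-dist / decay$delta)
  else pmax(dist, 1)^decay$lambda
}

#' Regulatory-potential scores for all mapped genes of one sample
#'
#' @param index an \code{\link{rp_index}}.
#' @param decay a \code{\link{decay_spec}}.
#' @return named numeric vector over mapped genes; 0 for genes without any
#'   peak in their TAD.
#' @export
rp_column <- function(index, decay) {
  stopifnot(inherits(index, "rp_index"), inherits(decay, "decay_spec"))
  out <- numeric(length(index$gene_ids))
  if (length(index$gene_idx) > 0) {
    w <- .rp_weights(index$dist, decay)
    s <- rowsum(w, index$gene_idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  names(out) <- index$gene_ids
  out
}

#' Regulatory potential of a TF on one gene
#'
#' Sums the decay-weighted contributions of all peaks lying in the gene's
#' TAD. Returns \code{NA} (defined-absent, distinct from a score of 0) for
#' a gene whose TSS is in no TAD.
#'
#' @inheritParams rp_index
#' @param gene_id a single gene identifier present in the layout.
#' @param decay a \code{\link{decay_spec}}.
#' @return numeric score (>= 0), or \code{NA} for an unmapped gene.
#' @export
rp_score <- function(ps, gene_id, layout, decay, use_summit = FALSE) {
  g <- layout$genes[layout$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("gene not in layout: ", gene_id)
  if (is.na(g$tad_id)) return(NA_real_)
  pt <- peak_representative_point(ps, use_summit = use_summit)
  peak_tad <- assign_to_tads(ps$peaks$chrom, pt, layout$tads)
  x <- abs(pt[!is.na(peak_tad) & peak_tad == g$tad_id] - g$tss)
  sum(.rp_weights(x, decay))
}

#' Regulatory-potential matrix over genes and samples
#'
#' @param peaksets list of \code{\link{peak_set}} objects.
#' @param layout a \code{\link{genome_layout}}.
#' @param decay a \code{\link{decay_spec}}.
#' @param gene_subset optional character vector restricting rows to a set
#'   of mapped genes (e.g. genes in one TAD type).
#' @return matrix (genes x samples) with attributes \code{decay} and
#'   \code{excluded} (unmapped gene ids).
#' @export
rp_matrix <- function(peaksets, layout, decay, gene_subset = NULL) {
  if (length(peaksets) < 1) stop("need at least one peak set")
  idx <- lapply(peaksets, rp_index, layout = layout)
  cols <- lapply(idx, rp_column, decay = decay)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(peaksets, function(p)
    paste(p$tf_id, p$sample_id, sep = "."), "")
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stop("gene_subset is empty")
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing) > 0)
      stop("gene_subset contains unmapped or unknown genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    m <- m[gene_subset, , drop = FALSE]
  }
  attr(m, "decay") <- decay
  attr(m, "excluded") <- idx[[1]]$excluded
  m
}

#' Distance from a gene TSS to its nearest in-TAD peak
#'
#' Baseline alternative to the decay-weighted score: the minimum unsigned
#' distance from the TSS to any peak in the gene's TAD.
#'
#' @inheritParams rp_score
#' @return bp distance, or \code{NA} when the gene is unmapped or its TAD
#'   holds no peak.
#' @export
nearest_peak_distance <- function(ps, gene_id, layout, use_summit = FALSE) {
  g <- layout$genes[layout$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("gene not in layout: ", gene_id)
  if (is.na(g$tad_id)) return(NA_real_)
  pt <- peak_representative_point(ps, use_summit = use_summit)
  peak_tad <- assign_to_tads(ps$peaks$chrom, pt, layout$tads)
  x <- abs(pt[!is.na(peak_tad) & peak_tad == g$tad_id] - g$tss)
  if (length(x) == 0) NA_real_ else min(x)
}
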
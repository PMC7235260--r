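# eQTL-TSS distance contrasts between TAD classes/tissues, and Hi-C
# contact-frequency decay with genomic distance fitted as a power law
# within a TAD set.

#' Filter an eQTL table on association p-value
#'
#' @param eqtls data.frame with at least \code{p}; typically also
#'   \code{chrom}, \code{pos}, \code{gene_id}, \code{tss}, \code{tissue}.
#' @param p_max retention threshold, boundary inclusive (default 1e-5).
#' @return the retained rows with a derived \code{distance} column
#'   (|pos - tss|) when both coordinates are present.
#' @export
filter_eqtls <- function(eqtls, p_max = 1e-5) {
  if (!("p" %in% names(eqtls))) stop("eQTL table must have a p column")
  out <- eqtls[eqtls$p <= p_max, , drop = FALSE]
  if (nrow(out) == 0) warning("no eQTL pairs pass p <= ", p_max)
  if (all(c("pos", "tss") %in% names(out)))
    out$distance <- abs(out$pos - out$tss)
  rownames(out) <- NULL
  out
}

#' Compare eQTL-TSS distances between A-type and B-type TADs
#'
#' Pairs are classified by the TAD containing the gene TSS; a two-sided
#' t-test compares log10(distance + 1) between the B-type and A-type
#' groups (the t statistic is invariant to the logarithm base).
#'
#' @param eqtls filtered eQTL table with \code{gene_id} and
#'   \code{distance} columns.
#' @param gene_to_tad named character vector mapping gene id to TAD id.
#' @param a_type,b_type character vectors of TAD ids per class.
#' @return list with \code{t}, \code{p}, \code{median_a}, \code{median_b}
#'   (bp medians per class) and the group sizes.
#' @export
compare_distances_ab <- function(eqtls, gene_to_tad, a_type, b_type) {
  tad <- gene_to_tad[eqtls$gene_id]
  da <- eqtls$distance[tad %in% a_type]
  db <- eqtls$distance[tad %in% b_type]
  if (length(da) < 2 || length(db) < 2)
    stop("need >= 2 eQTL pairs in each TAD class")
  tt <- stats::t.test(log10(db + 1), log10(da + 1))
  list(t = unname(tt$statistic), p = tt$p.value,
       median_a = stats::median(da), median_b = stats::median(db),
       n_a = length(da), n_b = length(db))
}

#' Compare eQTL-TSS distances between two tissues within predominant TADs
#'
#' Within each tissue-predominant TAD set (from
#' \code{\link{differential_tads}}), the log distances of eQTLs measured
#' in the two tissues are compared by a two-sided t-test, reporting which
#' tissue has the shorter distances.
#'
#' @param eqtls1,eqtls2 filtered eQTL tables for tissue 1 and tissue 2
#'   (with \code{gene_id} and \code{distance}).
#' @param gene_to_tad named mapping gene id to TAD id.
#' @param predominant named list of TAD-id vectors (one element per
#'   predominant set, e.g. \code{list(tissue1_active = ...,
#'   tissue2_active = ...)}).
#' @return data.frame with one row per usable TAD set: \code{set},
#'   \code{t}, \code{p}, medians per tissue, and \code{shorter_in}
#'   (which tissue's distances are shorter). Sets with fewer than 2 pairs
#'   in either tissue are skipped with a warning.
#' @export
compare_distances_tissue_pair <- function(eqtls1, eqtls2, gene_to_tad,
                                          predominant) {
  rows <- list()
  for (nm in names(predominant)) {
    tset <- predominant[[nm]]
    d1 <- eqtls1$distance[gene_to_tad[eqtls1$gene_id] %in% tset]
    d2 <- eqtls2$distance[gene_to_tad[eqtls2$gene_id] %in% tset]
    if (length(d1) < 2 || length(d2) < 2) {
      warning("TAD set '", nm, "' has < 2 pairs in a tissue; skipped")
      next
    }
    tt <- stats::t.test(log10(d1 + 1), log10(d2 + 1))
    rows[[nm]] <- data.frame(
      set = nm, t = unname(tt$statistic), p = tt$p.value,
      median_tissue1 = stats::median(d1), median_tissue2 = stats::median(d2),
      shorter_in = if (stats::median(d1) < stats::median(d2))
        "tissue1" else "tissue2",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(set = character(), t = numeric(), p = numeric(),
                      median_tissue1 = numeric(), median_tissue2 = numeric(),
                      shorter_in = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average intra-TAD contact frequency as a function of distance
#'
#' For each genomic separation d (a multiple of the bin size), F(d) is the
#' sum of observed contact counts over intra-TAD bin pairs at that
#' separation divided by the number of possible intra-TAD pairs at that
#' separation -- pairs with zero observed counts contribute to the
#' denominator.
#'
#' @param contacts data.frame with \code{chrom}, \code{bin1_start},
#'   \code{bin2_start} (bp, bin left edges), \code{count}.
#' @param tads TAD data.frame; only pairs with both bins inside one TAD of
#'   this set are used.
#' @param bin_size bin width in bp.
#' @return object of class \code{contact_curve}: data.frame with
#'   \code{d} (bp, bin-midpoint separation), \code{F}, \code{n_possible},
#'   \code{n_observed}.
#' @export
contact_curve <- function(contacts, tads, bin_size) {
  if (nrow(tads) == 0) stop("empty TAD set")
  .check_tads_disjoint(tads)
  # possible pairs: bins fully inside a TAD
  sep_counts <- list()
  possible <- integer(0)
  for (i in seq_len(nrow(tads))) {
    first_bin <- ceiling(tads$start[i] / bin_size)
    last_bin <- floor(tads$end[i] / bin_size) - 1L
    nb <- last_bin - first_bin + 1L
    if (nb < 2) next
    seps <- seq_len(nb - 1L)
    for (s in seps) {
      key <- as.character(s)
      possible[key] <- (if (is.na(possible[key])) 0L else possible[key]) +
        (nb - s)
    }
  }
  if (length(possible) == 0) stop("no TAD holds two bins at this bin size")
  # observed: map both bins to TADs, keep pairs sharing one TAD
  mid1 <- contacts$bin1_start + bin_size %/% 2
  mid2 <- contacts$bin2_start + bin_size %/% 2
  t1 <- assign_to_tads(contacts$chrom, mid1, tads)
  t2 <- assign_to_tads(contacts$chrom, mid2, tads)
  keep <- !is.na(t1) & !is.na(t2) & t1 == t2 &
    contacts$bin1_start != contacts$bin2_start
  sep <- abs(contacts$bin2_start[keep] - contacts$bin1_start[keep]) %/%
    bin_size
  obs_sum <- tapply(contacts$count[keep], sep, sum)
  obs_n <- table(sep)
  seps <- sort(as.integer(names(possible)))
  Fd <- vapply(seps, function(s) {
    k <- as.character(s)
    tot <- if (k %in% names(obs_sum)) obs_sum[[k]] else 0
    tot / possible[[k]]
  }, 0)
  out <- data.frame(d = seps * bin_size, F = Fd,
                    n_possible = as.integer(possible[as.character(seps)]),
                    n_observed = as.integer(
                      ifelse(as.character(seps) %in% names(obs_n),
                             obs_n[as.character(seps)], 0L)))
  class(out) <- c("contact_curve", "data.frame")
  attr(out, "bin_size") <- bin_size
  out
}

#' Fit a power-law decay to a contact curve
#'
#' Ordinary least squares of log F on log d over the requested distance
#' range; the slope is the decay exponent.
#'
#' @param curve a \code{\link{contact_curve}} (or data.frame with \code{d}
#'   and \code{F}).
#' @param d_range length-2 numeric range of distances to fit (inclusive);
#'   default the full curve.
#' @return list with \code{lambda} (slope), \code{intercept} (log F at
#'   log d = 0) and \code{n_bins} used.
#' @export
fit_powerlaw <- function(curve, d_range = NULL) {
  d <- curve$d; Fv <- curve$F
  if (!is.null(d_range)) {
    keep <- d >= d_range[1] & d <= d_range[2]
    d <- d[keep]; Fv <- Fv[keep]
  }
  use <- Fv > 0
  if (sum(use) < 3) stop("need >= 3 bins with positive F in the range")
  fit <- stats::lm(log(Fv[use]) ~ log(d[use]))
  list(lambda = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_bins = sum(use))
}
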
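# Inference of TF-specific regulatory decay distances (delta*). Two routes:
#  - perturbation: delta* maximizes the KS separation between the RP scores
#    of perturbation-derived DE genes and all other genes;
#  - expression cohort: per-gene TF-gene expression correlations gamma_hat
#    (the MLE of the regulatory effect under a standardized linear model)
#    are compared with RP(delta) columns; delta* maximizes |Pearson rho|
#    (linear concordance) or the distance correlation (nonlinear).

#' Geometric grid of candidate decay distances
#'
#' @param n_points number of grid points (>= 2); default 33.
#' @param min_bp,max_bp grid endpoints in bp; default 100 bp to 4,000 kb.
#' @return strictly increasing numeric vector (a geometric progression
#'   including both endpoints) of class \code{delta_grid}.
#' @export
default_grid <- function(n_points = 33L, min_bp = 100, max_bp = 4e6) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (min_bp <= 0 || max_bp <= min_bp) stop("need 0 < min_bp < max_bp")
  g <- exp(seq(log(min_bp), log(max_bp), length.out = n_points))
  g[1] <- min_bp; g[n_points] <- max_bp
  structure(g, class = "delta_grid")
}

#' Derive a differential-expression gene set from a perturbation table
#'
#' @param tbl data.frame with columns \code{gene}, \code{log2FC}, \code{p}.
#' @param lfc_min absolute log2 fold-change threshold (strict; default 1).
#' @param p_max p-value threshold (strict; default 0.01).
#' @param direction \code{"both"} (default), \code{"down"} or \code{"up"};
#'   e.g. down-regulated genes after a knockdown.
#' @return object of class \code{de_gene_set}: list with \code{genes},
#'   \code{direction} and the thresholds used.
#' @export
derive_de_genes <- function(tbl, lfc_min = 1, p_max = 0.01,
                            direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  req <- c("gene", "log2FC", "p")
  if (!all(req %in% names(tbl)))
    stop("perturbation table must have columns: ", paste(req, collapse = ", "))
  keep <- abs(tbl$log2FC) > lfc_min & tbl$p < p_max
  keep <- keep & switch(direction,
                        both = TRUE,
                        down = tbl$log2FC < 0,
                        up = tbl$log2FC > 0)
  genes <- unique(tbl$gene[keep])
  if (length(genes) == 0)
    stop("no genes pass |log2FC| > ", lfc_min, " and p < ", p_max,
         "; review thresholds")
  structure(list(genes = genes, direction = direction,
                 lfc_min = lfc_min, p_max = p_max),
            class = "de_gene_set")
}

#' Kolmogorov-Smirnov separation of DE genes by RP score
#'
#' Two-sample two-sided KS statistic between the RP scores of the DE genes
#' and those of all remaining scored genes.
#'
#' @param scores named numeric vector of per-gene RP scores.
#' @param de a \code{\link{de_gene_set}} or character vector of gene ids
#'   (must be a strict subset of the scored genes).
#' @param alternative passed to \code{\link[stats]{ks.test}}; default
#'   two-sided.
#' @return list with \code{statistic} and \code{p}.
#' @export
ks_separation <- function(scores, de, alternative = "two.sided") {
  if (inherits(de, "de_gene_set")) de <- de$genes
  if (is.null(names(scores))) stop("scores must be a named vector")
  de_scores <- scores[names(scores) %in% de]
  other <- scores[!(names(scores) %in% de)]
  if (length(de_scores) == 0 || length(other) == 0)
    stop("both DE and non-DE groups must be non-empty")
  kt <- suppressWarnings(
    stats::ks.test(de_scores, other, alternative = alternative))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

.decay_curve <- function(grid, statistic, method, extra = list()) {
  stopifnot(length(grid) == length(statistic), all(is.finite(statistic)))
  best <- which.max(statistic)  # which.max takes the first (smallest delta) tie
  structure(c(list(grid = as.numeric(grid), statistic = statistic,
                   delta_star = as.numeric(grid)[best],
                   stat_max = statistic[best], method = method),
              extra),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("decay_curve (", x$method, "): ", length(x$grid),
      " grid points, delta* = ", signif(x$delta_star, 4), " bp, max stat = ",
      signif(x$stat_max, 4), "\n", sep = "")
  invisible(x)
}

#' Infer a decay distance from a TF perturbation experiment
#'
#' Scans the decay grid; at each delta the KS separation between DE-gene
#' and non-DE-gene RP scores is computed, and delta* is the grid value with
#' the largest KS statistic (ties resolved to the smallest delta).
#'
#' @param ps a \code{\link{peak_set}} (or a precomputed
#'   \code{\link{rp_index}}).
#' @param layout a \code{\link{genome_layout}} (ignored when \code{ps} is
#'   already an index).
#' @param de a \code{\link{de_gene_set}}.
#' @param grid a \code{\link{default_grid}}-style vector of deltas.
#' @return a \code{decay_curve} with per-delta KS statistics and p-values.
#' @export
infer_delta_perturbation <- function(ps, layout, de, grid = default_grid()) {
  if (length(grid) < 2) stop("grid needs at least 2 points")
  index <- if (inherits(ps, "rp_index")) ps else rp_index(ps, layout)
  stat <- numeric(length(grid)); pv <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sc <- rp_column(index, decay_spec("exponential", delta = grid[i]))
    ks <- ks_separation(sc, de)
    stat[i] <- ks$statistic; pv[i] <- ks$p
  }
  .decay_curve(grid, stat, "perturbation-ks", list(p = pv))
}

#' Normalize an expression matrix for correlation analysis
#'
#' Applies the cohort normalization used before computing TF-gene
#' expression correlations: \code{log2(x + 1)} on RPKM-like values,
#' quantile normalization across samples (all samples share the pooled
#' sorted-value reference), then gene-wise mean centering.
#'
#' @param raw genes x samples numeric matrix of non-negative values.
#' @return normalized matrix with attribute \code{normalization} set to
#'   \code{"log-quantile-centered"}.
#' @export
normalize_expression <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 2) stop("need at least 2 samples")
  if (anyNA(raw) || any(raw < 0))
    stop("expression values must be non-negative and complete")
  if (anyDuplicated(rownames(raw)) || anyDuplicated(colnames(raw)))
    stop("row and column labels must be unique")
  x <- log2(raw + 1)
  x <- limma::normalizeQuantiles(x)
  x <- x - rowMeans(x)
  attr(x, "normalization") <- "log-quantile-centered"
  x
}

#' Per-gene expression correlation with a TF
#'
#' Pearson correlation between the TF's expression row and every other
#' gene's row. Under the standardized linear regulatory model this
#' correlation is the maximum-likelihood estimator of the per-gene
#' regulatory effect, so the profile doubles as the gamma-hat vector of
#' the concordance step.
#'
#' @param expr normalized genes x samples matrix
#'   (\code{\link{normalize_expression}}).
#' @param tf_gene row name of the TF's own gene.
#' @return object of class \code{correlation_profile}: list with
#'   \code{tf_gene}, \code{gamma} (named vector over the other genes;
#'   \code{NA} for zero-variance genes) and \code{n_samples}.
#' @export
correlation_profile <- function(expr, tf_gene) {
  if (!(tf_gene %in% rownames(expr))) stop("tf_gene not in matrix")
  if (ncol(expr) < 3) stop("need at least 3 samples")
  tf <- expr[tf_gene, ]
  if (stats::sd(tf) == 0) stop("TF expression row is constant")
  others <- expr[setdiff(rownames(expr), tf_gene), , drop = FALSE]
  g <- suppressWarnings(as.vector(stats::cor(t(others), tf)))
  names(g) <- rownames(others)
  structure(list(tf_gene = tf_gene, gamma = g, n_samples = ncol(expr)),
            class = "correlation_profile")
}

#' Linear concordance between expression effects and RP scores
#'
#' Pearson correlation between the per-gene expression effect estimates
#' gamma-hat and the RP column at one delta, with the closed-form OLS
#' intercept, slope and residual variance (1/n form) of the linear link
#' gamma-hat = alpha + beta * RP + eps.
#'
#' @param gamma named numeric vector of per-gene effects (a
#'   \code{correlation_profile}'s \code{gamma}, or the object itself).
#' @param rp named numeric vector of RP scores over the same genes.
#' @return list with \code{rho}, \code{alpha}, \code{beta}, \code{sigma2},
#'   \code{n} (genes used after pairwise NA removal).
#' @export
concordance_linear <- function(gamma, rp) {
  if (inherits(gamma, "correlation_profile")) gamma <- gamma$gamma
  common <- intersect(names(gamma), names(rp))
  g <- gamma[common]; r <- rp[common]
  ok <- is.finite(g) & is.finite(r)
  g <- g[ok]; r <- r[ok]
  if (length(g) < 3) stop("need at least 3 genes with both values")
  if (stats::sd(g) == 0 || stats::sd(r) == 0)
    stop("zero variance in gamma or RP vector")
  beta <- sum((g - mean(g)) * (r - mean(r))) / sum((r - mean(r))^2)
  alpha <- mean(g) - beta * mean(r)
  resid <- g - alpha - beta * r
  list(rho = stats::cor(g, r), alpha = alpha, beta = beta,
       sigma2 = mean(resid^2), n = length(g))
}

#' Distance correlation
#'
#' Szekely-Rizzo distance correlation between two numeric vectors, from
#' double-centered pairwise-distance matrices. Zero if and only if the
#' variables are independent (in the population), making it the nonlinear
#' concordance statistic of the grid search.
#'
#' @param x,y numeric vectors of equal length (>= 2), no NAs.
#' @return dCor in [0, 1].
#' @export
dcor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  A <- .dcenter(abs(outer(x, x, "-")))
  B <- .dcenter(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A); dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(dcov2 / sqrt(dvarx * dvary))
}

.dcenter <- function(d) {
  d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
}

# internal: dCor of y against a fixed pre-centered matrix B (for grid scans)
.dcor_fixedB <- function(x, B, dvary) {
  A <- .dcenter(abs(outer(x, x, "-")))
  dvarx <- mean(A * A)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(mean(A * B) / sqrt(dvarx * dvary))
}

#' Nonlinear concordance via distance correlation
#'
#' @inheritParams concordance_linear
#' @return dCor value in [0, 1].
#' @export
concordance_dcor <- function(gamma, rp) {
  if (inherits(gamma, "correlation_profile")) gamma <- gamma$gamma
  common <- intersect(names(gamma), names(rp))
  g <- gamma[common]; r <- rp[common]
  ok <- is.finite(g) & is.finite(r)
  g <- g[ok]; r <- r[ok]
  if (length(g) < 3) stop("need at least 3 genes with both values")
  if (stats::sd(g) == 0 || stats::sd(r) == 0)
    stop("zero variance in gamma or RP vector")
  dcor(r, g)
}

#' Grid search for the decay distance from an expression cohort
#'
#' For each candidate delta the RP column is computed and compared with
#' the per-gene expression effects gamma-hat; delta* is the grid argmax of
#' |Pearson rho| (\code{method = "linear"}) or of the distance correlation
#' (\code{method = "dcor"}), with ties resolved to the smallest delta. The
#' TF's own gene is excluded to avoid trivial self-correlation.
#'
#' @param ps a \code{\link{peak_set}} or \code{\link{rp_index}}.
#' @param layout a \code{\link{genome_layout}} (ignored for an index).
#' @param profile a \code{\link{correlation_profile}}.
#' @param grid candidate deltas (bp), strictly increasing, >= 2 points.
#' @param method \code{"linear"} or \code{"dcor"}.
#' @param gene_subset optional character vector restricting the genes used
#'   (e.g. genes of one TAD type); the intersection with scored genes is
#'   taken.
#' @return a \code{decay_curve}; for the linear method the per-delta
#'   signed rho, slope and residual variance are included, and
#'   \code{sign_at_max} records the sign of rho at delta*.
#' @export
delta_grid_search <- function(ps, layout, profile, grid = default_grid(),
                              method = c("linear", "dcor"),
                              gene_subset = NULL) {
  method <- match.arg(method)
  if (length(grid) < 2) stop("grid needs at least 2 points")
  stopifnot(inherits(profile, "correlation_profile"))
  index <- if (inherits(ps, "rp_index")) ps else rp_index(ps, layout)
  gamma <- profile$gamma
  genes <- setdiff(intersect(index$gene_ids, names(gamma)), profile$tf_gene)
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  gamma <- gamma[genes]
  ok <- is.finite(gamma)
  gamma <- gamma[ok]; genes <- genes[ok]
  if (length(genes) < 3) stop("fewer than 3 usable genes")
  pos <- match(genes, index$gene_ids)
  keep_pairs <- index$gene_idx %in% pos
  sub_idx <- structure(list(gene_ids = index$gene_ids,
                            excluded = index$excluded,
                            gene_idx = index$gene_idx[keep_pairs],
                            dist = index$dist[keep_pairs]),
                       class = "rp_index")
  if (method == "dcor") {
    B <- .dcenter(abs(outer(gamma, gamma, "-")))
    dvary <- mean(B * B)
  }
  stat <- numeric(length(grid))
  rho <- beta <- sigma2 <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    rp_all <- rp_column(sub_idx, decay_spec("exponential", delta = grid[i]))
    r <- rp_all[pos]
    if (stats::sd(r) == 0) { stat[i] <- 0; next }
    if (method == "linear") {
      cl <- concordance_linear(gamma, stats::setNames(r, genes))
      rho[i] <- cl$rho; beta[i] <- cl$beta; sigma2[i] <- cl$sigma2
      stat[i] <- abs(cl$rho)
    } else {
      stat[i] <- .dcor_fixedB(r, B, dvary)
    }
  }
  extra <- list(n_genes = length(genes),
                tf_id = index$tf_id, sample_id = index$sample_id)
  if (method == "linear") {
    extra$rho <- rho; extra$beta <- beta; extra$sigma2 <- sigma2
  }
  curve <- .decay_curve(grid, stat, paste0("expr-", method), extra)
  if (method == "linear")
    curve$sign_at_max <- sign(rho[which.max(stat)])
  curve
}

#' Aggregate per-sample decay curves into a TF-level estimate
#'
#' A sample qualifies when its concordance curve exceeds the qualification
#' threshold somewhere on the grid. With at least \code{min_qualified}
#' qualified samples the curves are averaged pointwise; if the averaged
#' maximum also exceeds the threshold, delta* is the argmax of the mean
#' curve. Otherwise no estimate is returned (a valid outcome, not an
#' error).
#'
#' @param curves list of \code{decay_curve}s for one TF (same grid).
#' @param threshold qualification level for the concordance statistic
#'   (default 0.1).
#' @param min_qualified minimum number of qualified samples (default 2).
#' @param subset optional label (e.g. \code{"A-type"}, \code{"B-type"}, a
#'   tissue) carried into the estimate.
#' @return object of class \code{tf_delta_estimate}: list with
#'   \code{tf_id}, \code{delta_star} (\code{NA} when no estimate),
#'   \code{class} (short-range/long-range), \code{stat_max},
#'   \code{qualified} (sample ids), \code{mean_curve}, \code{subset}.
#' @export
aggregate_tf_delta <- function(curves, threshold = 0.1, min_qualified = 2L,
                               subset = NA_character_) {
  if (length(curves) < 1) stop("need at least one curve")
  grid <- curves[[1]]$grid
  for (cv in curves)
    if (!isTRUE(all.equal(cv$grid, grid)))
      stop("curves must share one grid")
  qual <- vapply(curves, function(cv) max(cv$statistic) > threshold, TRUE)
  tf_id <- curves[[1]]$tf_id %||% NA_character_
  est <- list(tf_id = tf_id, delta_star = NA_real_, class = NA_character_,
              stat_max = NA_real_,
              qualified = vapply(curves[qual], function(cv)
                cv$sample_id %||% NA_character_, ""),
              mean_curve = NULL, subset = subset,
              n_samples = length(curves), n_qualified = sum(qual))
  if (sum(qual) >= min_qualified) {
    mean_stat <- rowMeans(vapply(curves[qual], function(cv) cv$statistic,
                                 numeric(length(grid))))
    est$mean_curve <- .decay_curve(grid, mean_stat, "aggregated")
    if (max(mean_stat) > threshold) {
      est$delta_star <- est$mean_curve$delta_star
      est$stat_max <- est$mean_curve$stat_max
      est$class <- classify_range(est$delta_star)
    }
  }
  structure(est, class = "tf_delta_estimate")
}

#' @export
print.tf_delta_estimate <- function(x, ...) {
  if (is.na(x$delta_star))
    cat("tf_delta_estimate:", x$tf_id, "- no estimate (",
        x$n_qualified, "of", x$n_samples, "samples qualified )\n")
  else
    cat("tf_delta_estimate:", x$tf_id, "- delta* =",
        signif(x$delta_star, 4), "bp (", x$class, "),",
        x$n_qualified, "qualified samples\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a decay distance as short- or long-range
#'
#' Short-range covers 100 bp to 3 kb (boundary inclusive); anything above
#' 3 kb is long-range.
#'
#' @param delta_star decay distance in bp.
#' @return \code{"short-range"} or \code{"long-range"}.
#' @export
classify_range <- function(delta_star) {
  if (is.na(delta_star)) return(NA_character_)
  if (delta_star > 3000) "long-range" else "short-range"
}

#' Decay-distance inference restricted to a gene subset
#'
#' Runs the expression-cohort grid search using only the genes of a
#' designated subset (a TAD type or a tissue-specific TAD set), yielding
#' subset-labeled estimates such as delta^A and delta^B.
#'
#' @inheritParams delta_grid_search
#' @param subset_genes character vector of gene ids defining the subset.
#' @param subset_label label stored on the returned estimate.
#' @param min_genes refuse (with a warning, returning \code{NULL}) when
#'   fewer than this many usable genes remain (default 30).
#' @return a \code{decay_curve} with a \code{subset} field, or \code{NULL}
#'   when the subset is too small.
#' @export
delta_by_subset <- function(ps, layout, profile, grid = default_grid(),
                            method = c("linear", "dcor"),
                            subset_genes, subset_label = "subset",
                            min_genes = 30L) {
  method <- match.arg(method)
  if (length(subset_genes) == 0) stop("subset_genes is empty")
  index <- if (inherits(ps, "rp_index")) ps else rp_index(ps, layout)
  usable <- setdiff(intersect(index$gene_ids, subset_genes), profile$tf_gene)
  usable <- usable[is.finite(profile$gamma[usable])]
  if (length(usable) < min_genes) {
    warning("only ", length(usable), " usable genes in subset '",
            subset_label, "' (< ", min_genes, "); refusing to estimate")
    return(NULL)
  }
  curve <- delta_grid_search(index, layout, profile, grid, method,
                             gene_subset = subset_genes)
  curve$subset <- subset_label
  curve
}
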
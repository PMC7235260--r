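# Pioneer-factor-like test: does the focal TF's motif become more enriched
# in OTHER TFs' ChIP-seq peaks as the focal TF's expression rises across
# cell lines? Enrichment values are summarized per cell line, binarized at
# their mean, and regressed on focal-TF expression by logistic regression.

#' Summarize motif enrichment per cell line
#'
#' From a table of focal-motif enrichment ratios in other TFs' peak sets
#' (one row per ChIP-seq sample), rows of the focal TF itself are dropped,
#' redundant (TF, cell line) duplicates are averaged, and the median over
#' the deduplicated TFs is taken per cell line.
#'
#' @param table data.frame with columns \code{tf_id}, \code{cell_line},
#'   \code{enrichment} (> 0).
#' @param focal_tf the focal TF whose motif was scanned; its own rows are
#'   excluded.
#' @return named numeric vector: median enrichment y per cell line.
#' @export
summarize_enrichment <- function(table, focal_tf) {
  req <- c("tf_id", "cell_line", "enrichment")
  if (!all(req %in% names(table)))
    stop("enrichment table must have columns: ", paste(req, collapse = ", "))
  if (any(table$enrichment <= 0)) stop("enrichment ratios must be > 0")
  tbl <- table[table$tf_id != focal_tf, , drop = FALSE]
  if (nrow(tbl) == 0) stop("no non-focal rows in enrichment table")
  dedup <- stats::aggregate(enrichment ~ tf_id + cell_line, data = tbl,
                            FUN = mean)
  y <- tapply(dedup$enrichment, dedup$cell_line, stats::median)
  stats::setNames(as.numeric(y), names(y))
}

#' Logistic test for pioneer-factor-like behavior
#'
#' Binarizes the per-cell-line enrichment summaries at their mean
#' (y* = 1 when y >= mean(y)), fits the logistic regression y* ~ x on the
#' focal TF's expression by IRLS, and calls the TF pioneer-factor-like
#' when the Wald p-value of the slope is below \code{alpha}. Complete
#' separation is detected and reported as status \code{"separated"}
#' (with the slope sign) instead of a spurious p-value.
#'
#' @param y named numeric vector of per-cell-line enrichment summaries
#'   (\code{\link{summarize_enrichment}}).
#' @param x named numeric vector of focal-TF expression per cell line
#'   (names matching \code{y}).
#' @param alpha significance level (default 0.05).
#' @return object of class \code{pioneer_result}: list with \code{y},
#'   \code{y_star}, \code{x}, \code{slope}, \code{p}, \code{status}
#'   (\code{"ok"} or \code{"separated"}) and \code{pioneer_like}.
#' @export
pioneer_test <- function(y, x, alpha = 0.05) {
  common <- intersect(names(y), names(x))
  if (length(common) < 6) stop("need at least 6 cell lines with both values")
  y <- y[common]; x <- x[common]
  if (stats::sd(x) == 0) stop("focal TF expression does not vary")
  y_star <- as.integer(y >= mean(y))
  if (all(y_star == y_star[1]))
    stop("degenerate response: all binarized values identical")
  fit <- suppressWarnings(
    stats::glm(y_star ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  p <- co["x", "Pr(>|z|)"]
  # complete separation: IRLS walks to huge coefficients with fitted
  # probabilities pinned at 0/1
  sep <- !fit$converged || abs(slope) > 50 ||
    all(abs(fit$fitted.values - y_star) < 1e-8)
  status <- if (sep) "separated" else "ok"
  structure(list(y = y, y_star = stats::setNames(y_star, common), x = x,
                 y_bar = mean(y), slope = slope,
                 p = if (sep) NA_real_ else p, status = status,
                 pioneer_like = !sep && p < alpha),
            class = "pioneer_result")
}

#' @export
print.pioneer_result <- function(x, ...) {
  cat("pioneer_result:", length(x$y), "cell lines; slope =",
      signif(x$slope, 3),
      if (x$status == "separated") "(complete separation)"
      else paste0("p = ", signif(x$p, 3)),
      "->", if (isTRUE(x$pioneer_like)) "pioneer-factor-like"
      else "not pioneer-like", "\n")
  invisible(x)
}
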
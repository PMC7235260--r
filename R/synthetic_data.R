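# Synthetic data with planted ground truth for every downstream stage:
# genomes (TADs + genes with A/B activity classes), ChIP-seq peak sets
# whose TSS displacements follow the exponential RP kernel at a planted
# decay distance, expression cohorts with a linear TF->gene link through
# RP, perturbation DE tables, H3K27ac TAD signal, eQTL tables, Hi-C-style
# binned contacts, and trait SNP sets. Every generator is a pure function
# of its arguments and seed.

#' Bundle of simulation defaults
#'
#' Collects the default study conditions used across the generators: a
#' 50-TAD genome with 600 genes split over A/B activity classes, 200
#' expression samples at noise sd 0.5, a 33-point decay grid, and the
#' thresholds of the inference stages. Individual generators take the
#' same parameters explicitly; this bundle exists for the pipeline runner.
#'
#' @param seed integer seed (mandatory).
#' @param ... overrides for any default element.
#' @return named list of class \code{sim_config}.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = seed,
    n_tads = 50L, tad_len_range = c(4e5, 1e6), tads_per_chrom = 10L,
    gap = 5e4, frac_b = 0.5, n_genes = 600L, b_density_ratio = 0.4,
    n_tfs = 1L, delta_true = 1e4, n_peaks = 600L, frac_background = 0.2,
    concentration = 10, peak_width = 200L,
    n_samples = 200L, sigma = 0.5, target_concordance = 0.4,
    n_de = 100L,
    h3k27ac_samples = 20L, h3k27ac_separation = 5, h3k27ac_noise = 1,
    eqtl_mu_a = 4.0, eqtl_mu_b = 4.5, eqtl_sdlog = 0.5,
    eqtl_n_per_class = 500L,
    contact_lambda = -0.8, contact_bin = 2e4, contact_c0 = 25,
    snp_factor = 10, n_snps = 200L,
    grid_points = 33L, qualification = 0.1, z_threshold = 1,
    de_lfc_min = 1, de_p_max = 0.01, eqtl_p_max = 1e-5,
    diff_tad_p = 1e-10, gwas_p_flag = 0.001, n_perm = 10000L,
    peak_cap = 20000L, peak_min = 0L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Simulate a genome layout with planted TAD activity classes
#'
#' Lays non-overlapping TADs end-to-end (with gaps) on synthetic
#' chromosomes, labels a fraction as B-type (inactive) and the rest as
#' A-type (active), and places genes uniformly within TADs with B-type
#' TADs receiving proportionally fewer genes (lower gene density, as seen
#' for inactive chromatin).
#'
#' @param n_tads number of TADs.
#' @param tad_len_range length-2 range of TAD lengths (bp), sampled
#'   uniformly.
#' @param tads_per_chrom TADs per synthetic chromosome.
#' @param gap bp between consecutive TADs.
#' @param frac_b fraction of TADs labeled B-type.
#' @param n_genes total genes, allocated to TADs with weight
#'   length x density (B density scaled by \code{b_density_ratio}).
#' @param b_density_ratio B:A gene-density ratio (< 1).
#' @param seed integer seed.
#' @return a \code{\link{genome_layout}} with attribute \code{truth}: list
#'   with \code{a_type}, \code{b_type} (TAD ids) and \code{gene_class}
#'   (named A/B label per gene).
#' @export
make_genome <- function(n_tads = 50L, tad_len_range = c(4e5, 1e6),
                        tads_per_chrom = 10L, gap = 5e4, frac_b = 0.5,
                        n_genes = 600L, b_density_ratio = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genes < 1) stop("n_genes must be positive")
  set.seed(seed)
  lens <- round(stats::runif(n_tads, tad_len_range[1], tad_len_range[2]))
  chrom_idx <- (seq_len(n_tads) - 1L) %/% tads_per_chrom + 1L
  chrom <- paste0("chrS", chrom_idx)
  start <- integer(n_tads)
  for (ci in unique(chrom_idx)) {
    sel <- which(chrom_idx == ci)
    start[sel] <- cumsum(c(gap, lens[sel][-length(sel)] + gap))
  }
  tads <- data.frame(tad_id = sprintf("tad%03d", seq_len(n_tads)),
                     chrom = chrom, start = start, end = start + lens,
                     stringsAsFactors = FALSE)
  n_b <- round(frac_b * n_tads)
  b_ids <- sample(tads$tad_id, n_b)
  is_b <- tads$tad_id %in% b_ids
  w <- lens * ifelse(is_b, b_density_ratio, 1)
  alloc <- as.vector(stats::rmultinom(1, n_genes, w))
  gi <- rep(seq_len(n_tads), alloc)
  tss <- tads$start[gi] +
    floor(stats::runif(n_genes) * (tads$end[gi] - tads$start[gi]))
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      chrom = tads$chrom[gi], tss = as.integer(tss),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  layout <- genome_layout(genes, tads)
  gene_class <- ifelse(layout$genes$tad_id %in% b_ids, "B", "A")
  attr(layout, "truth") <- list(
    a_type = tads$tad_id[!is_b], b_type = tads$tad_id[is_b],
    gene_class = stats::setNames(gene_class, layout$genes$gene_id))
  layout
}

# per-gene planted decay distance: scalar, or c(A=..., B=...) resolved
# through the layout's planted classes
.gene_deltas <- function(layout, delta_true) {
  genes <- layout$genes$gene_id
  if (length(delta_true) == 1 && is.null(names(delta_true)))
    return(stats::setNames(rep(as.numeric(delta_true), length(genes)),
                           genes))
  truth <- attr(layout, "truth")
  if (is.null(truth))
    stop("per-class delta_true requires a layout with planted classes")
  cl <- truth$gene_class[genes]
  stats::setNames(as.numeric(delta_true[cl]), genes)
}

#' Simulate a TF ChIP-seq peak set with a planted decay distance
#'
#' Signal peaks are centered at displacements from gene TSSs drawn from a
#' two-sided exponential with density proportional to 2^(-|x|/delta), so
#' the planted displacement kernel matches the RP scoring kernel at
#' \code{delta_true}. A fraction of background peaks is placed uniformly
#' within TADs. When \code{target_tads} is given, genes and background in
#' those TADs are favored \code{concentration}-fold.
#'
#' @param layout a \code{\link{genome_layout}} (from
#'   \code{\link{make_genome}} when per-class deltas are used).
#' @param tf_id,sample_id identifiers for the emitted peak set.
#' @param delta_true planted decay distance (bp): a scalar, or a named
#'   vector \code{c(A = ..., B = ...)} for class-specific kernels.
#' @param n_peaks total peaks.
#' @param frac_background fraction placed uniformly rather than around
#'   TSSs.
#' @param target_tads optional TAD ids where placement is concentrated.
#' @param concentration fold-weighting of target TADs.
#' @param peak_width peak interval width (bp).
#' @param seed integer seed.
#' @return a \code{\link{peak_set}} with lognormal intensities; attribute
#'   \code{truth} records the planted parameters.
#' @export
make_peaks <- function(layout, tf_id = "TF1", sample_id = "s1",
                       delta_true = 1e4, n_peaks = 600L,
                       frac_background = 0.2, target_tads = NULL,
                       concentration = 1, peak_width = 200L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  genes <- layout$genes[!is.na(layout$genes$tad_id), , drop = FALSE]
  tads <- layout$tads
  deltas <- .gene_deltas(layout, delta_true)[genes$gene_id]
  n_bg <- round(frac_background * n_peaks)
  n_sig <- n_peaks - n_bg
  g_w <- rep(1, nrow(genes))
  t_w <- tads$end - tads$start
  if (!is.null(target_tads)) {
    g_w[genes$tad_id %in% target_tads] <- concentration
    t_w[tads$tad_id %in% target_tads] <-
      t_w[tads$tad_id %in% target_tads] * concentration
  }
  pick <- sample(nrow(genes), n_sig, replace = TRUE, prob = g_w)
  disp <- sample(c(-1, 1), n_sig, replace = TRUE) *
    stats::rexp(n_sig, rate = log(2) / deltas[pick])
  centers <- genes$tss[pick] + round(disp)
  chroms <- genes$chrom[pick]
  if (n_bg > 0) {
    bt <- sample(nrow(tads), n_bg, replace = TRUE, prob = t_w)
    centers <- c(centers,
                 tads$start[bt] + floor(stats::runif(n_bg) *
                                          (tads$end[bt] - tads$start[bt])))
    chroms <- c(chroms, tads$chrom[bt])
  }
  centers <- pmax(centers, peak_width %/% 2)
  half <- peak_width %/% 2
  peaks <- data.frame(chrom = chroms,
                      start = as.integer(centers - half),
                      end = as.integer(centers - half + peak_width),
                      intensity = stats::rlnorm(length(centers), 3, 1),
                      stringsAsFactors = FALSE)
  ps <- peak_set(tf_id, sample_id, peaks)
  attr(ps, "truth") <- list(delta_true = delta_true,
                            target_tads = target_tads,
                            concentration = concentration)
  ps
}

#' Simulate an expression cohort linked to RP at a planted decay distance
#'
#' The TF's expression per sample is standard normal; every other gene j
#' follows gamma_j * E_tf + noise with gamma_j = beta * R_j(delta_true),
#' where R is the exponential RP score of the supplied peak set. Values
#' are then pushed onto a positive RPKM-like scale through a fixed
#' monotone transform (2^(z + per-gene baseline) - so the full
#' normalization path of \code{\link{normalize_expression}} is exercised).
#'
#' When \code{beta} is \code{NULL} it is calibrated deterministically from
#' the planted RP vector so that the expected concordance
#' |cor(gamma_hat, R)| at delta_true is approximately
#' \code{target_concordance} given \code{n_samples} and \code{sigma}
#' (the per-gene correlation estimates carry sampling noise of sd about
#' 1/sqrt(n)).
#'
#' @param layout a \code{\link{genome_layout}}.
#' @param ps the TF's \code{\link{peak_set}}.
#' @param delta_true planted decay distance (scalar or \code{c(A=,B=)}).
#' @param tf_gene gene id serving as the TF's own gene (its row carries
#'   the TF expression).
#' @param n_samples cohort size.
#' @param sigma residual noise sd on the standardized scale.
#' @param beta linear effect scale; \code{NULL} (default) calibrates to
#'   \code{target_concordance}.
#' @param target_concordance desired concordance maximum (default 0.4).
#' @param seed integer seed.
#' @return genes x samples matrix of positive RPKM-like values with
#'   attribute \code{truth} (planted delta, beta, gamma vector).
#' @export
make_expression <- function(layout, ps, delta_true = 1e4, tf_gene,
                            n_samples = 200L, sigma = 0.5, beta = NULL,
                            target_concordance = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma <= 0) stop("sigma must be positive")
  set.seed(seed)
  index <- rp_index(ps, layout)
  deltas <- .gene_deltas(layout, delta_true)
  # per-gene RP at the planted (possibly class-specific) decay distance
  R <- numeric(length(index$gene_ids))
  names(R) <- index$gene_ids
  if (length(index$gene_idx) > 0) {
    d_per_pair <- deltas[index$gene_ids[index$gene_idx]]
    w <- 2^(-index$dist / d_per_pair)
    s <- rowsum(w, index$gene_idx)
    R[as.integer(rownames(s))] <- s[, 1]
  }
  if (!(tf_gene %in% names(R)))
    stop("tf_gene must be a mapped gene: ", tf_gene)
  if (is.null(beta)) {
    sdR <- stats::sd(R[names(R) != tf_gene])
    if (sdR == 0) stop("RP vector is constant; cannot calibrate beta")
    c2 <- target_concordance^2
    beta <- sigma * sqrt(c2 / (n_samples * (1 - c2))) / sdR
  }
  gamma <- beta * R
  e_tf <- stats::rnorm(n_samples)
  z <- outer(gamma, e_tf) +
    matrix(stats::rnorm(length(R) * n_samples, sd = sigma),
           length(R), n_samples)
  z[tf_gene, ] <- e_tf
  baseline <- stats::runif(length(R), 2, 8)
  raw <- 2^(z + baseline)
  rownames(raw) <- names(R)
  colnames(raw) <- sprintf("smp%03d", seq_len(n_samples))
  attr(raw, "truth") <- list(delta_true = delta_true, beta = beta,
                             sigma = sigma, gamma = gamma,
                             tf_gene = tf_gene)
  raw
}

#' Simulate a TF perturbation DE table with a planted decay distance
#'
#' DE genes are sampled (without replacement) with probability
#' proportional to the RP score at the planted decay distance, so genes
#' strongly bound at the planted range are preferentially perturbed. The
#' emitted table is consistent with the default thresholds of
#' \code{\link{derive_de_genes}}: DE rows get |log2FC| > 1 and p < 0.01,
#' other rows fall outside both thresholds.
#'
#' @param layout a \code{\link{genome_layout}}.
#' @param ps the TF's \code{\link{peak_set}}.
#' @param delta_true planted decay distance (scalar or \code{c(A=,B=)}).
#' @param n_de number of DE genes (> 0).
#' @param seed integer seed.
#' @return data.frame with \code{gene}, \code{log2FC}, \code{p} and
#'   attribute \code{truth} (DE gene ids, planted delta).
#' @export
make_perturbation <- function(layout, ps, delta_true = 1e4, n_de = 100L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_de < 1) stop("n_de must be positive")
  set.seed(seed)
  index <- rp_index(ps, layout)
  deltas <- .gene_deltas(layout, delta_true)
  R <- numeric(length(index$gene_ids))
  names(R) <- index$gene_ids
  if (length(index$gene_idx) > 0) {
    d_per_pair <- deltas[index$gene_ids[index$gene_idx]]
    s <- rowsum(2^(-index$dist / d_per_pair), index$gene_idx)
    R[as.integer(rownames(s))] <- s[, 1]
  }
  if (n_de >= length(R)) stop("n_de must be smaller than the gene count")
  if (sum(R > 0) < n_de)
    stop("fewer genes with positive RP than n_de")
  de <- sample(names(R), n_de, prob = R)
  n <- length(R)
  is_de <- names(R) %in% de
  tbl <- data.frame(
    gene = names(R),
    log2FC = ifelse(is_de,
                    sample(c(-1, 1), n, replace = TRUE) *
                      (1 + stats::rexp(n, 1)),
                    stats::runif(n, -0.8, 0.8)),
    p = ifelse(is_de, 10^stats::runif(n, -6, -2.1),
               stats::runif(n, 0.02, 1)),
    stringsAsFactors = FALSE)
  attr(tbl, "truth") <- list(de_genes = de, delta_true = delta_true)
  tbl
}

#' Simulate per-TAD H3K27ac signal with planted activity classes
#'
#' Signal = class mean + per-sample offset + Gaussian noise, with the
#' A-class mean above the B-class mean by \code{separation} noise sds.
#'
#' @param layout a \code{\link{make_genome}} layout (planted classes).
#' @param n_samples number of H3K27ac samples.
#' @param separation between-class mean difference in units of
#'   \code{noise_sd}.
#' @param noise_sd within-class noise sd.
#' @param sample_effect_sd sd of the per-sample additive offset.
#' @param seed integer seed.
#' @return TADs x samples matrix with attribute \code{truth} (class
#'   labels).
#' @export
make_h3k27ac <- function(layout, n_samples = 20L, separation = 5,
                         noise_sd = 1, sample_effect_sd = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  truth <- attr(layout, "truth")
  if (is.null(truth)) stop("layout must carry planted classes")
  set.seed(seed)
  tad_ids <- layout$tads$tad_id
  class_mean <- ifelse(tad_ids %in% truth$a_type, separation * noise_sd, 0)
  samp <- stats::rnorm(n_samples, sd = sample_effect_sd)
  m <- outer(class_mean, samp, "+") +
    matrix(stats::rnorm(length(tad_ids) * n_samples, sd = noise_sd),
           length(tad_ids), n_samples)
  rownames(m) <- tad_ids
  colnames(m) <- sprintf("k27_%02d", seq_len(n_samples))
  attr(m, "truth") <- list(a_type = truth$a_type, b_type = truth$b_type)
  m
}

#' Simulate an eQTL table with class-specific distance distributions
#'
#' Distances are log10-normal with class-specific location (B-type TADs
#' drawn with the larger mu mirror the longer regulatory reach of
#' inactive chromatin); p-values all pass the default retention filter.
#'
#' @param layout a \code{\link{make_genome}} layout.
#' @param mu_a,mu_b log10 distance means for genes in A-/B-type TADs.
#' @param sdlog log10 distance sd.
#' @param n_per_class eQTL pairs sampled per class.
#' @param tissue tissue label written on every row.
#' @param seed integer seed.
#' @return data.frame (\code{chrom}, \code{pos}, \code{gene_id},
#'   \code{tss}, \code{p}, \code{tissue}) with attribute \code{truth}.
#' @export
make_eqtls <- function(layout, mu_a = 4.0, mu_b = 4.5, sdlog = 0.5,
                       n_per_class = 500L, tissue = "synthetic", seed) {
  if (missing(seed)) stop("seed is mandatory")
  truth <- attr(layout, "truth")
  if (is.null(truth)) stop("layout must carry planted classes")
  set.seed(seed)
  genes <- layout$genes[!is.na(layout$genes$tad_id), , drop = FALSE]
  cls <- truth$gene_class[genes$gene_id]
  rows <- lapply(c(A = "A", B = "B"), function(cl) {
    pool <- which(cls == cl)
    if (length(pool) == 0) stop("no genes in class ", cl)
    gi <- sample(pool, n_per_class, replace = TRUE)
    mu <- if (cl == "A") mu_a else mu_b
    dist <- pmax(1, round(10^stats::rnorm(n_per_class, mu, sdlog)))
    side <- sample(c(-1, 1), n_per_class, replace = TRUE)
    data.frame(chrom = genes$chrom[gi],
               pos = pmax(0L, as.integer(genes$tss[gi] + side * dist)),
               gene_id = genes$gene_id[gi], tss = genes$tss[gi],
               p = 10^stats::runif(n_per_class, -10, -5),
               tissue = tissue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(mu_a = mu_a, mu_b = mu_b, sdlog = sdlog)
  out
}

#' Simulate binned intra-TAD contacts with planted power-law decay
#'
#' For every pair of bins lying inside one TAD, the expected count is
#' c0 * (d / bin_size)^lambda (d = bin-separation distance) and the
#' observed count is Poisson. \code{lambda} may be a scalar or
#' \code{c(A = ..., B = ...)} for class-specific decay.
#'
#' @param layout a \code{\link{make_genome}} layout.
#' @param lambda planted decay exponent(s), negative.
#' @param bin_size bin width (bp).
#' @param c0 expected count per pair at one-bin separation.
#' @param seed integer seed.
#' @return data.frame (\code{chrom}, \code{bin1_start}, \code{bin2_start},
#'   \code{count}) of non-zero pairs, with attribute \code{truth}.
#' @export
make_contacts <- function(layout, lambda = -0.8, bin_size = 2e4, c0 = 25,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(lambda >= 0)) stop("lambda must be negative")
  set.seed(seed)
  tads <- layout$tads
  truth <- attr(layout, "truth")
  lam_of <- function(tid) {
    if (length(lambda) == 1 && is.null(names(lambda)))
      return(as.numeric(lambda))
    if (is.null(truth)) stop("per-class lambda requires planted classes")
    if (tid %in% truth$b_type) lambda[["B"]] else lambda[["A"]]
  }
  out <- vector("list", nrow(tads))
  for (i in seq_len(nrow(tads))) {
    first_bin <- ceiling(tads$start[i] / bin_size)
    last_bin <- floor(tads$end[i] / bin_size) - 1L
    nb <- last_bin - first_bin + 1L
    if (nb < 2) next
    pr <- utils::combn(nb, 2)
    b1 <- (first_bin + pr[1, ] - 1L) * bin_size
    b2 <- (first_bin + pr[2, ] - 1L) * bin_size
    sep <- (b2 - b1) / bin_size
    mu <- c0 * sep^lam_of(tads$tad_id[i])
    cnt <- stats::rpois(length(mu), mu)
    keep <- cnt > 0
    out[[i]] <- data.frame(chrom = tads$chrom[i], bin1_start = b1[keep],
                           bin2_start = b2[keep], count = cnt[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  attr(res, "truth") <- list(lambda = lambda, bin_size = bin_size, c0 = c0)
  res
}

#' Simulate trait-associated SNPs enriched in one TF's target TADs
#'
#' Each SNP picks a TAD with probability proportional to
#' 1 + factor * [TAD in the enriched TF's target set], then a uniform
#' position inside it.
#'
#' @param layout a \code{\link{genome_layout}}.
#' @param target_tads TAD ids of the planted-enriched TF.
#' @param factor enrichment factor (0 for uniform null placement).
#' @param n_snps number of SNPs.
#' @param trait trait label.
#' @param seed integer seed.
#' @return data.frame (\code{trait}, \code{chrom}, \code{pos}) with
#'   attribute \code{truth}.
#' @export
make_snps <- function(layout, target_tads = character(), factor = 10,
                      n_snps = 200L, trait = "syntrait", seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  tads <- layout$tads
  w <- 1 + factor * (tads$tad_id %in% target_tads)
  ti <- sample(nrow(tads), n_snps, replace = TRUE, prob = w)
  pos <- tads$start[ti] +
    floor(stats::runif(n_snps) * (tads$end[ti] - tads$start[ti]))
  out <- data.frame(trait = trait, chrom = tads$chrom[ti],
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  attr(out, "truth") <- list(target_tads = target_tads, factor = factor)
  out
}
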
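# End-to-end orchestration of the synthetic-data pipeline: simulate a
# genome and TF data, score RP, infer the decay distance by both routes,
# classify TAD chromatin, call target TADs, and run the downstream eQTL /
# contact / GWAS analyses, writing TSV outputs with provenance headers.

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order (simulate -> rp -> delta ->
#' tads -> occupancy -> downstream) from a \code{\link{sim_config}} (or a
#' YAML file holding one), writing per-stage TSVs and a machine-readable
#' run report into \code{out_dir}. Stage toggles allow skipping the
#' downstream analyses; enabling a stage whose prerequisite is disabled
#' fails before execution.
#'
#' @param config a \code{sim_config}, a plain list of its fields, or the
#'   path of a YAML file containing them (\code{seed} mandatory).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run; default all of
#'   \code{c("simulate", "rp", "delta", "tads", "occupancy",
#'   "downstream")}.
#' @return invisibly, the run report data.frame (stage, status, outputs);
#'   also written as \code{report.tsv}.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "rp", "delta", "tads",
                                    "occupancy", "downstream")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  deps <- list(simulate = character(), rp = "simulate",
               delta = "rp", tads = "simulate",
               occupancy = c("simulate", "tads"),
               downstream = c("simulate", "tads", "occupancy"))
  stages <- match.arg(stages, names(deps), several.ok = TRUE)
  for (st in stages) {
    miss <- setdiff(deps[[st]], stages)
    if (length(miss) > 0)
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(miss, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  report <- list()
  note <- function(stage, outputs) {
    report[[stage]] <<- data.frame(stage = stage, status = "ok",
                                   outputs = paste(outputs, collapse = ","),
                                   stringsAsFactors = FALSE)
    message("[cisrange] stage ", stage, ": ok")
  }
  cfg <- config
  env <- new.env()

  if ("simulate" %in% stages) {
    env$layout <- make_genome(cfg$n_tads, cfg$tad_len_range,
                              cfg$tads_per_chrom, cfg$gap, cfg$frac_b,
                              cfg$n_genes, cfg$b_density_ratio,
                              seed = cfg$seed)
    env$ps <- make_peaks(env$layout, "TF1", "s1", cfg$delta_true,
                         cfg$n_peaks, cfg$frac_background,
                         seed = cfg$seed + 1L)
    env$ps <- filter_peaks(env$ps, cap = cfg$peak_cap,
                           min_peaks = cfg$peak_min)
    truth <- attr(env$layout, "truth")
    write_intervals(env$layout$tads[, c("chrom", "start", "end")],
                    file.path(out_dir, "tads.bed"),
                    comment = "synthetic TADs")
    write_intervals(env$ps$peaks, file.path(out_dir, "peaks.bed"),
                    comment = "synthetic TF peaks")
    .write_tsv(data.frame(tad_id = env$layout$tads$tad_id,
                          class = ifelse(env$layout$tads$tad_id %in%
                                           truth$b_type, "B", "A")),
               file.path(out_dir, "ground_truth_tads.tsv"),
               "planted TAD activity classes")
    note("simulate", c("tads.bed", "peaks.bed", "ground_truth_tads.tsv"))
  }
  if ("rp" %in% stages) {
    env$index <- rp_index(env$ps, env$layout)
    rp <- rp_column(env$index,
                    decay_spec("exponential",
                               delta = unname(cfg$delta_true[1])))
    .write_tsv(data.frame(gene_id = names(rp), rp = rp),
               file.path(out_dir, "rp_scores.tsv"),
               sprintf("exponential RP, delta = %g bp",
                       unname(cfg$delta_true[1])))
    note("rp", "rp_scores.tsv")
  }
  if ("delta" %in% stages) {
    grid <- default_grid(cfg$grid_points)
    tf_gene <- env$layout$genes$gene_id[
      which(!is.na(env$layout$genes$tad_id))[1]]
    expr <- make_expression(env$layout, env$ps, cfg$delta_true, tf_gene,
                            cfg$n_samples, cfg$sigma,
                            target_concordance = cfg$target_concordance,
                            seed = cfg$seed + 2L)
    norm <- normalize_expression(expr)
    prof <- correlation_profile(norm, tf_gene)
    curve <- delta_grid_search(env$index, env$layout, prof, grid, "linear")
    pert <- make_perturbation(env$layout, env$ps, cfg$delta_true,
                              cfg$n_de, seed = cfg$seed + 3L)
    de <- derive_de_genes(pert, cfg$de_lfc_min, cfg$de_p_max)
    kcurve <- infer_delta_perturbation(env$index, env$layout, de, grid)
    env$delta_expr <- curve$delta_star
    .write_tsv(data.frame(delta = grid, expr_stat = curve$statistic,
                          ks_stat = kcurve$statistic),
               file.path(out_dir, "decay_curves.tsv"),
               c(sprintf("expression-route delta* = %g bp (%s)",
                         curve$delta_star,
                         classify_range(curve$delta_star)),
                 sprintf("perturbation-route delta* = %g bp",
                         kcurve$delta_star)))
    note("delta", "decay_curves.tsv")
  }
  if ("tads" %in% stages) {
    sig <- make_h3k27ac(env$layout, cfg$h3k27ac_samples,
                        cfg$h3k27ac_separation, cfg$h3k27ac_noise,
                        seed = cfg$seed + 4L)
    z <- sample_z_transform(sig)
    cl <- bicluster(z, k = 2)
    env$ab <- call_ab_types(cl)
    .write_tsv(data.frame(
      tad_id = names(cl$tad_cluster), cluster = cl$tad_cluster,
      type = ifelse(names(cl$tad_cluster) %in% env$ab$a_type, "A",
                    ifelse(names(cl$tad_cluster) %in% env$ab$b_type,
                           "B", "none"))),
      file.path(out_dir, "tad_classes.tsv"),
      "H3K27ac biclustering and A/B-type calls")
    note("tads", "tad_classes.tsv")
  }
  if ("occupancy" %in% stages) {
    # a small panel of TFs so across-TF z-scores are defined
    panel <- lapply(1:5, function(i)
      make_peaks(env$layout, paste0("TF", i), "s1", cfg$delta_true,
                 cfg$n_peaks, cfg$frac_background,
                 target_tads = if (i == 1)
                   utils::head(env$layout$tads$tad_id, 5) else NULL,
                 concentration = if (i == 1) cfg$concentration else 1,
                 seed = cfg$seed + 10L + i))
    dens <- vapply(panel, peak_density, numeric(nrow(env$layout$tads)),
                   tads = env$layout$tads)
    colnames(dens) <- paste0("TF", 1:5)
    env$z <- suppressWarnings(tad_zscores(dens))
    targets <- call_target_tads(env$z, "TF1", cfg$z_threshold)
    zdf <- cbind(data.frame(tad_id = rownames(env$z)),
                 as.data.frame(env$z))
    .write_tsv(zdf, file.path(out_dir, "tad_zscores.tsv"),
               "relative TF occupancy z-scores")
    .write_tsv(data.frame(tad_id = targets),
               file.path(out_dir, "target_tads_TF1.tsv"),
               sprintf("z >= %g", cfg$z_threshold))
    env$panel <- panel
    note("occupancy", c("tad_zscores.tsv", "target_tads_TF1.tsv"))
  }
  if ("downstream" %in% stages) {
    eq <- filter_eqtls(make_eqtls(env$layout, cfg$eqtl_mu_a,
                                  cfg$eqtl_mu_b, cfg$eqtl_sdlog,
                                  cfg$eqtl_n_per_class,
                                  seed = cfg$seed + 20L),
                       cfg$eqtl_p_max)
    truth <- attr(env$layout, "truth")
    g2t <- stats::setNames(env$layout$genes$tad_id,
                           env$layout$genes$gene_id)
    abcmp <- compare_distances_ab(eq, g2t, truth$a_type, truth$b_type)
    contacts <- make_contacts(env$layout, cfg$contact_lambda,
                              cfg$contact_bin, cfg$contact_c0,
                              seed = cfg$seed + 21L)
    curve <- contact_curve(contacts, env$layout$tads, cfg$contact_bin)
    pw <- fit_powerlaw(curve,
                       d_range = c(cfg$contact_bin, 10 * cfg$contact_bin))
    tf1_targets <- attr(env$panel[[1]], "truth")$target_tads
    snps <- make_snps(env$layout, tf1_targets, cfg$snp_factor,
                      cfg$n_snps, seed = cfg$seed + 22L)
    snp_tad <- assign_to_tads(snps$chrom, snps$pos, env$layout$tads)
    snp_counts <- as.integer(table(factor(snp_tad,
                                          levels = env$layout$tads$tad_id)))
    ab_mat <- vapply(env$panel, function(p) {
      d <- peak_density(p, env$layout$tads) *
        (env$layout$tads$end - env$layout$tads$start) / 1000
      relative_abundance(d)
    }, numeric(nrow(env$layout$tads)))
    colnames(ab_mat) <- paste0("TF", 1:5)
    gw <- permutation_significance(snp_counts, ab_mat,
                                   n_perm = cfg$n_perm,
                                   seed = cfg$seed + 23L,
                                   p_flag = cfg$gwas_p_flag)
    .write_tsv(gw, file.path(out_dir, "gwas_scores.tsv"),
               "trait-TF cosine similarity with permutation p")
    .write_tsv(data.frame(quantity = c("eqtl_t", "eqtl_p",
                                       "eqtl_median_a", "eqtl_median_b",
                                       "hic_lambda"),
                          value = c(abcmp$t, abcmp$p, abcmp$median_a,
                                    abcmp$median_b, pw$lambda)),
               file.path(out_dir, "downstream_summary.tsv"),
               "eQTL distance contrast and contact-decay fit")
    note("downstream", c("gwas_scores.tsv", "downstream_summary.tsv"))
  }
  rep_df <- do.call(rbind, report[stages[stages %in% names(report)]])
  rownames(rep_df) <- NULL
  .write_tsv(rep_df, file.path(out_dir, "report.tsv"),
             "pipeline run report")
  invisible(rep_df)
}
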
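test_that("delta grid is geometric over the default span", {
  g2 <- default_grid(2)
  expect_equal(as.numeric(g2), c(100, 4e6))
  g <- default_grid(33)
  ratios <- g[-1] / g[-length(g)]
  expect_lt(diff(range(ratios)), 1e-9)
  expect_true(all(g >= 100 & g <= 4e6))
  expect_error(default_grid(1), ">= 2")
})

test_that("DE derivation applies strict thresholds and direction", {
  tbl <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FC = c(1.5, 1.0, -2, 3),
                    p = c(0.001, 0.001, 0.005, 0.5))
  de <- derive_de_genes(tbl)
  expect_setequal(de$genes, c("a", "c"))  # b fails strict |lfc|>1, d fails p
  down <- derive_de_genes(tbl, direction = "down")
  expect_equal(down$genes, "c")
  expect_error(derive_de_genes(data.frame(gene = "a", log2FC = 0.1,
                                          p = 0.5)), "threshold")
})

test_that("KS separation matches the brute-force ECDF sup-difference", {
  x <- stats::setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_equal(ks_separation(x, c("g1", "g2"),
                             alternative = "two.sided")$statistic,
               brute_ks(c(1, 2), c(3, 4)))
  # identical distributions -> 0; disjoint supports -> 1
  same <- stats::setNames(rep(c(1, 2), 10), paste0("g", 1:20))
  expect_equal(ks_separation(same, paste0("g", 1:10))$statistic, 0)
  split <- stats::setNames(c(1:10, 101:110), paste0("g", 1:20))
  expect_equal(ks_separation(split, paste0("g", 11:20))$statistic, 1)
  set.seed(42)
  sc <- stats::setNames(runif(550), paste0("g", 1:550))
  de <- paste0("g", sample(550, 50))
  expect_equal(ks_separation(sc, de)$statistic,
               brute_ks(sc[de], sc[setdiff(names(sc), de)]),
               tolerance = 1e-12)
  expect_error(ks_separation(sc, paste0("g", 1:550)), "non-empty")
})

test_that("perturbation argmax finds planted short and long ranges", {
  lay <- tiny_layout()
  grid <- default_grid(17)
  # short-range construction: DE genes have a peak within 500 bp of the
  # TSS, other genes none nearby
  set.seed(3)
  near <- tiny_peaks(c(-300L, 200L, 400L))           # near g1 (t1)
  far_bg <- tiny_peaks(c(60000L, 70000L, 80000L))    # far from g1, near no TSS
  ps <- peak_set("TF", "s", rbind(near$peaks, far_bg$peaks))
  cv <- infer_delta_perturbation(ps, lay, structure(
    list(genes = "g1"), class = "de_gene_set"), grid)
  expect_lte(cv$delta_star, grid[4])
  # long-range construction: DE genes are those best bound at ~50 kb
  lay_l <- make_genome(seed = 181)
  ps_l <- make_peaks(lay_l, delta_true = 5e4, seed = 182)
  r50 <- rp_column(rp_index(ps_l, lay_l),
                   decay_spec("exponential", delta = 5e4))
  de_l <- names(sort(r50, decreasing = TRUE))[1:100]
  cv_long <- infer_delta_perturbation(ps_l, lay_l, structure(
    list(genes = de_l), class = "de_gene_set"), grid)
  expect_gte(cv_long$delta_star, 10000)
  # constant curve -> tie broken to the smallest delta
  one <- tiny_peaks(10000L)
  cv_tie <- infer_delta_perturbation(one, lay, structure(
    list(genes = "g2"), class = "de_gene_set"), grid)
  expect_equal(cv_tie$delta_star, grid[1])
})

test_that("normalization equalizes sample distributions and centers genes", {
  set.seed(8)
  raw <- matrix(2^runif(300, 0, 10), 50, 6,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  norm <- normalize_expression(raw)
  expect_equal(unname(rowMeans(norm)), rep(0, 50), tolerance = 1e-10)
  # two samples that are permutations of each other share sorted values
  raw2 <- raw
  raw2[, 2] <- raw2[sample(50), 1]
  q <- limma::normalizeQuantiles(log2(raw2 + 1))
  expect_equal(unname(sort(q[, 1])), unname(sort(q[, 2])),
               tolerance = 1e-10)
  # constant gene row (identical columns, so ranks are stable) -> zeros
  raw3 <- matrix(rep(2^seq(1, 5, length.out = 50), 6), 50, 6,
                 dimnames = dimnames(raw))
  expect_equal(unname(normalize_expression(raw3)[1, ]), rep(0, 6),
               tolerance = 1e-10)
  expect_error(normalize_expression(raw[, 1, drop = FALSE]), "2 samples")
})

test_that("correlation profile is the standardized-OLS slope (MLE identity)", {
  set.seed(12)
  expr <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  expr["g2", ] <- expr["g1", ]
  expr["g3", ] <- -expr["g1", ]
  prof <- correlation_profile(expr, "g1")
  expect_equal(unname(prof$gamma["g2"]), 1)
  expect_equal(unname(prof$gamma["g3"]), -1)
  # Pearson equals OLS slope after standardizing both variables
  for (g in c("g4", "g5", "g6")) {
    zx <- scale(expr["g1", ])[, 1]; zy <- scale(expr[g, ])[, 1]
    slope <- sum(zx * zy) / sum(zx^2)
    # population-vs-sample scaling cancels in the ratio
    expect_equal(unname(prof$gamma[g]), slope, tolerance = 1e-12)
  }
  expr["g7", ] <- 3
  prof2 <- correlation_profile(expr, "g1")
  expect_true(is.na(prof2$gamma["g7"]))
  expr["g1", ] <- 1
  expect_error(correlation_profile(expr, "g1"), "constant")
})

test_that("linear concordance returns exact OLS on a noiseless relation", {
  set.seed(13)
  r <- stats::setNames(runif(100), paste0("g", 1:100))
  g <- 0.3 + 0.2 * r
  cl <- concordance_linear(g, r)
  expect_equal(cl$rho, 1)
  expect_equal(cl$beta, 0.2, tolerance = 1e-12)
  expect_equal(cl$alpha, 0.3, tolerance = 1e-12)
  expect_equal(cl$sigma2, 0, tolerance = 1e-20)
  # brute-force covariance formulas on a noisy fixture
  gn <- g + rnorm(100, sd = 0.1)
  cl2 <- concordance_linear(gn, r)
  sxy <- sum((gn - mean(gn)) * (r - mean(r)))
  expect_equal(cl2$beta, sxy / sum((r - mean(r))^2), tolerance = 1e-12)
  expect_equal(cl2$rho,
               sxy / sqrt(sum((gn - mean(gn))^2) * sum((r - mean(r))^2)),
               tolerance = 1e-12)
  # independence -> small |rho|
  perm <- stats::setNames(sample(gn), names(gn))
  expect_lt(abs(concordance_linear(perm, r)$rho), 0.3)
  expect_error(concordance_linear(stats::setNames(rep(1, 100), names(r)),
                                  r), "variance")
})

test_that("distance correlation matches its definition and bounds", {
  set.seed(14)
  x <- rnorm(20); y <- 2 * x
  expect_equal(dcor(x, y), 1, tolerance = 1e-10)
  expect_equal(dcor(x, x), 1, tolerance = 1e-12)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(dcor(a, b), brute_dcor(a, b), tolerance = 1e-10)
  expect_lt(dcor(rnorm(30), rnorm(30)), 0.5)
  nl <- a^2  # nonlinear dependence still detected
  expect_gt(dcor(a, nl), 0.3)
})

test_that("grid search recovers a planted delta and is sign-invariant", {
  set.seed(15)
  lay <- make_genome(seed = 151)
  ps <- make_peaks(lay, delta_true = 1e4, seed = 152)
  idx <- rp_index(ps, lay)
  grid <- default_grid(33)
  tfg <- lay$genes$gene_id[1]
  expr <- make_expression(lay, ps, 1e4, tfg, seed = 153)
  prof <- correlation_profile(normalize_expression(expr), tfg)
  cv <- delta_grid_search(idx, lay, prof, grid, "linear")
  expect_lte(grid_step_apart(grid, cv$delta_star, 1e4), 1)
  # repressor-like: flipping gamma leaves |rho| and delta* unchanged
  flip <- prof
  flip$gamma <- -flip$gamma
  cv_f <- delta_grid_search(idx, lay, flip, grid, "linear")
  expect_equal(cv_f$delta_star, cv$delta_star)
  expect_equal(cv_f$statistic, cv$statistic, tolerance = 1e-12)
  # gene/sample order invariance of the statistic curve
  o <- sample(length(prof$gamma))
  prof_perm <- prof
  prof_perm$gamma <- prof$gamma[o]
  cv_p <- delta_grid_search(idx, lay, prof_perm, grid, "linear")
  expect_equal(cv_p$statistic, cv$statistic, tolerance = 1e-12)
  expect_error(delta_grid_search(idx, lay, prof, grid[1], "linear"),
               "2 points")
})

test_that("aggregation applies the qualification and averaging rules", {
  grid <- default_grid(9)
  mk_curve <- function(stats, sample_id)
    structure(list(grid = as.numeric(grid), statistic = stats,
                   delta_star = grid[which.max(stats)],
                   stat_max = max(stats), method = "expr-linear",
                   tf_id = "TF1", sample_id = sample_id),
              class = "decay_curve")
  low <- mk_curve(rep(0.05, 9), "s1")
  est <- aggregate_tf_delta(list(low))
  expect_true(is.na(est$delta_star))
  expect_equal(est$n_qualified, 0)
  # two qualified samples peaking at adjacent grid points
  c1 <- mk_curve(c(0.02, 0.05, 0.1, 0.3, 0.2, 0.1, 0.05, 0.02, 0.01), "s1")
  c2 <- mk_curve(c(0.02, 0.05, 0.1, 0.2, 0.32, 0.1, 0.05, 0.02, 0.01), "s2")
  est2 <- aggregate_tf_delta(list(c1, c2, low))
  expect_equal(est2$n_qualified, 2)
  mean_curve <- (c1$statistic + c2$statistic) / 2
  expect_equal(est2$delta_star, grid[which.max(mean_curve)])
  # identical curves: aggregate equals the per-sample argmax
  est3 <- aggregate_tf_delta(list(c1, c1))
  expect_equal(est3$delta_star, c1$delta_star)
})

test_that("range classification uses the 3 kb boundary inclusively", {
  expect_equal(classify_range(1000), "short-range")
  expect_equal(classify_range(3000), "short-range")
  expect_equal(classify_range(47000), "long-range")
})

test_that("subset-restricted estimates use only their own genes", {
  set.seed(17)
  lay <- make_genome(seed = 171)
  tr <- attr(lay, "truth")
  ps <- make_peaks(lay, delta_true = 1e4, seed = 172)
  idx <- rp_index(ps, lay)
  grid <- default_grid(17)
  tfg <- lay$genes$gene_id[1]
  expr <- make_expression(lay, ps, 1e4, tfg, seed = 173)
  prof <- correlation_profile(normalize_expression(expr), tfg)
  all_genes <- names(prof$gamma)
  # subset = all genes equals the unrestricted search
  full <- delta_grid_search(idx, lay, prof, grid, "linear")
  sub_all <- delta_by_subset(idx, lay, prof, grid, "linear",
                             all_genes, "all")
  expect_equal(sub_all$statistic, full$statistic, tolerance = 1e-12)
  # locality: perturbing gamma outside the subset leaves the estimate
  ga <- names(tr$gene_class)[tr$gene_class == "A"]
  gb <- setdiff(all_genes, ga)
  sub_a <- delta_by_subset(idx, lay, prof, grid, "linear", ga, "A-type")
  prof2 <- prof
  prof2$gamma[gb] <- sample(prof2$gamma[gb])
  sub_a2 <- delta_by_subset(idx, lay, prof2, grid, "linear", ga, "A-type")
  expect_equal(sub_a2$statistic, sub_a$statistic, tolerance = 1e-12)
  # tiny subset refused
  expect_warning(
    out <- delta_by_subset(idx, lay, prof, grid, "linear",
                           all_genes[1:5], "tiny"),
    "refusing")
  expect_null(out)
})
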
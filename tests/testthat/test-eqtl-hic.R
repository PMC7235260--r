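test_that("eQTL filter is boundary inclusive and derives distances", {
  eq <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   gene_id = c("a", "b", "c"), tss = c(50L, 150L, 250L),
                   p = c(1e-6, 1e-4, 1e-5), tissue = "t")
  out <- filter_eqtls(eq)
  expect_equal(out$gene_id, c("a", "c"))  # p = 1e-5 retained exactly
  expect_equal(out$distance, c(50, 50))
  expect_warning(filter_eqtls(eq, p_max = 1e-20), "no eQTL")
})

test_that("A/B distance contrast detects a planted lognormal shift", {
  lay <- make_genome(seed = 611)
  tr <- attr(lay, "truth")
  g2t <- stats::setNames(lay$genes$tad_id, lay$genes$gene_id)
  eq <- filter_eqtls(make_eqtls(lay, seed = 612))
  res <- compare_distances_ab(eq, g2t, tr$a_type, tr$b_type)
  expect_lt(res$p, 0.01)
  expect_gt(res$median_b, res$median_a)
  # invariance to the logarithm base: t from log10 equals t from ln
  da <- eq$distance[g2t[eq$gene_id] %in% tr$a_type]
  db <- eq$distance[g2t[eq$gene_id] %in% tr$b_type]
  t_ln <- stats::t.test(log(db + 1), log(da + 1))$statistic
  expect_equal(res$t, unname(t_ln), tolerance = 1e-10)
  # distance 0 tolerated through the +1 offset
  eq0 <- eq
  eq0$distance[1] <- 0
  expect_no_error(compare_distances_ab(eq0, g2t, tr$a_type, tr$b_type))
})

test_that("tissue-pair contrast localizes shorter distances correctly", {
  lay <- make_genome(seed = 621)
  g2t <- stats::setNames(lay$genes$tad_id, lay$genes$gene_id)
  sets <- list(lung_active = lay$tads$tad_id[1:25],
               blood_active = lay$tads$tad_id[26:50])
  # in each predominant set, the matching tissue has shorter distances
  mk <- function(mu_by_set, seed) {
    e <- make_eqtls(lay, mu_a = 4.2, mu_b = 4.2, seed = seed)
    on1 <- g2t[e$gene_id] %in% sets$lung_active
    d <- ifelse(on1, 10^rnorm(nrow(e), mu_by_set[1], 0.3),
                10^rnorm(nrow(e), mu_by_set[2], 0.3))
    e$pos <- as.integer(e$tss + round(d))
    filter_eqtls(e)
  }
  set.seed(1)
  eq_lung <- mk(c(3.8, 4.6), 622)   # lung eQTLs short in lung-active TADs
  eq_blood <- mk(c(4.6, 3.8), 623)
  res <- compare_distances_tissue_pair(eq_lung, eq_blood, g2t, sets)
  expect_equal(nrow(res), 2)
  expect_equal(res$shorter_in[res$set == "lung_active"], "tissue1")
  expect_equal(res$shorter_in[res$set == "blood_active"], "tissue2")
  expect_true(all(res$p < 0.01))
  # swapping the tissues swaps the conclusions
  res_sw <- compare_distances_tissue_pair(eq_blood, eq_lung, g2t, sets)
  expect_equal(res_sw$shorter_in[res_sw$set == "lung_active"], "tissue2")
  # insufficient sets are skipped with a warning
  sets$empty <- "no_such_tad"
  expect_warning(
    res3 <- compare_distances_tissue_pair(eq_lung, eq_blood, g2t, sets),
    "skipped")
  expect_equal(nrow(res3), 2)
})

test_that("contact curve divides by possible intra-TAD pairs", {
  tads <- data.frame(tad_id = "t1", chrom = "chr1", start = 0L,
                     end = 40L, stringsAsFactors = FALSE)
  contacts <- data.frame(chrom = "chr1", bin1_start = c(0L, 20L),
                         bin2_start = c(10L, 30L), count = c(3, 5))
  cc <- contact_curve(contacts, tads, 10)
  expect_equal(cc$F[cc$d == 10], 8 / 3)  # 3 possible pairs at sep 1
  expect_equal(cc$F[cc$d == 30], 0)      # zero observed still in curve
  # all-zero counts -> all-zero curve
  cc0 <- contact_curve(contacts[0, ], tads, 10)
  expect_true(all(cc0$F == 0))
  # brute-force pair enumeration on a random fixture
  lay <- make_genome(n_tads = 6, seed = 631)
  ct <- make_contacts(lay, -0.8, bin_size = 5e4, c0 = 5, seed = 632)
  curve <- contact_curve(ct, lay$tads, 5e4)
  for (d in curve$d[1:3]) {
    tot <- 0; poss <- 0
    for (i in seq_len(nrow(lay$tads))) {
      fb <- ceiling(lay$tads$start[i] / 5e4)
      lb <- floor(lay$tads$end[i] / 5e4) - 1
      nb <- lb - fb + 1
      s <- d / 5e4
      if (nb > s) poss <- poss + (nb - s)
    }
    sel <- ct$bin2_start - ct$bin1_start == d
    # count only intra-TAD pairs
    t1 <- assign_to_tads(ct$chrom[sel], ct$bin1_start[sel] + 25000,
                         lay$tads)
    t2 <- assign_to_tads(ct$chrom[sel], ct$bin2_start[sel] + 25000,
                         lay$tads)
    tot <- sum(ct$count[sel][!is.na(t1) & !is.na(t2) & t1 == t2])
    expect_equal(curve$F[curve$d == d], tot / poss, tolerance = 1e-12)
  }
})

test_that("power-law fits recover exact and planted exponents", {
  d <- c(1e4, 2e4, 4e4, 8e4, 1.6e5)
  curve <- data.frame(d = d, F = 3 * d^-0.8)
  fit <- fit_powerlaw(curve)
  expect_equal(fit$lambda, -0.8, tolerance = 1e-10)
  # doubling the coefficient changes the intercept, not the slope
  fit2 <- fit_powerlaw(data.frame(d = d, F = 6 * d^-0.8))
  expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-10)
  expect_gt(fit2$intercept, fit$intercept)
  expect_error(fit_powerlaw(data.frame(d = d[1:2], F = c(1, 2))), "3 bins")
  # Poisson-noised recovery at high depth
  lay <- make_genome(seed = 641)
  ct <- make_contacts(lay, -0.8, bin_size = 2e4, c0 = 25, seed = 642)
  curve2 <- contact_curve(ct, lay$tads, 2e4)
  fit3 <- fit_powerlaw(curve2, d_range = c(2e4, 2e5))
  expect_lt(abs(fit3$lambda + 0.8), 0.05)
})

test_that("restricted contact curves combine by pair-count weights", {
  lay <- make_genome(n_tads = 10, seed = 651)
  ct <- make_contacts(lay, -0.6, bin_size = 5e4, c0 = 10, seed = 652)
  set1 <- lay$tads[1:5, ]; set2 <- lay$tads[6:10, ]
  c1 <- contact_curve(ct, set1, 5e4)
  c2 <- contact_curve(ct, set2, 5e4)
  cu <- contact_curve(ct, lay$tads, 5e4)
  for (d in intersect(c1$d, c2$d)) {
    n1 <- c1$n_possible[c1$d == d]; n2 <- c2$n_possible[c2$d == d]
    f1 <- c1$F[c1$d == d]; f2 <- c2$F[c2$d == d]
    expect_equal(cu$F[cu$d == d], (n1 * f1 + n2 * f2) / (n1 + n2),
                 tolerance = 1e-12)
  }
})
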
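test_that("TAD mean signal is base-pair weighted with uncovered bases as 0", {
  tads <- data.frame(tad_id = c("t1", "t2"), chrom = "chr1",
                     start = c(0L, 1000L), end = c(1000L, 3000L),
                     stringsAsFactors = FALSE)
  const <- data.frame(chrom = "chr1", start = 0L, end = 1000L, value = 2)
  expect_equal(unname(tad_mean_signal(const, tads)["t1"]), 2)
  half <- data.frame(chrom = "chr1", start = 0L, end = 500L, value = 4)
  expect_equal(unname(tad_mean_signal(half, tads)["t1"]), 2)
  # per-base brute force on random piecewise coverage
  set.seed(9)
  bk <- sort(sample(0:2999, 30))
  cov <- data.frame(chrom = "chr1",
                    start = bk, end = c(bk[-1], 3000L),
                    value = round(runif(30, 0, 5), 2))
  cov <- cov[cov$end > cov$start, ]
  got <- tad_mean_signal(cov, tads)
  base <- numeric(3000)
  for (i in seq_len(nrow(cov)))
    base[(cov$start[i] + 1):cov$end[i]] <- cov$value[i]
  expect_equal(unname(got["t1"]), mean(base[1:1000]), tolerance = 1e-9)
  expect_equal(unname(got["t2"]), mean(base[1001:3000]), tolerance = 1e-9)
  # unknown chromosome ignored with a note
  expect_message(tad_mean_signal(data.frame(chrom = "chrX", start = 0L,
                                            end = 10L, value = 1), tads),
                 "ignoring")
})

test_that("sample z-transform standardizes columns and is idempotent", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(10, 30, 20))
  rownames(m) <- paste0("t", 1:3)
  z <- sample_z_transform(m)
  expect_equal(unname(z[, "s1"]),
               (c(1, 2, 3) - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(sample_z_transform(z), z, tolerance = 1e-12)
  m2 <- m; m2[, 2] <- 7
  expect_error(sample_z_transform(m2), "s2")
})

test_that("biclustering recovers planted blocks and orders by signal", {
  set.seed(23)
  m <- rbind(matrix(rnorm(30 * 8, 5), 30, 8),
             matrix(rnorm(20 * 8, 0), 20, 8))
  rownames(m) <- paste0("t", 1:50); colnames(m) <- paste0("s", 1:8)
  cl <- bicluster(m, k = 2)
  expect_equal(sort(unique(cl$tad_cluster)), 1:2)
  # cluster 1 is the weakest: the planted low block
  expect_setequal(names(cl$tad_cluster)[cl$tad_cluster == 1],
                  paste0("t", 31:50))
  expect_equal(mclust::adjustedRandIndex(
    cl$tad_cluster, rep(1:2, c(30, 20))), 1)
  # relabeling TAD ids does not change the partition
  m_perm <- m
  rownames(m_perm) <- paste0("x", 1:50)
  cl2 <- bicluster(m_perm, k = 2)
  expect_equal(unname(cl2$tad_cluster), unname(cl$tad_cluster))
  # k groups are all non-empty
  cl10 <- bicluster(matrix(rnorm(50 * 12), 50, 12,
                           dimnames = list(paste0("t", 1:50),
                                           paste0("s", 1:12))), k = 10)
  expect_equal(length(unique(cl10$tad_cluster)), 10)
  expect_error(bicluster(m, k = 1), "k must be")
})

test_that("A/B calls take the extreme clusters and stay disjoint", {
  set.seed(24)
  m <- rbind(matrix(rnorm(10 * 6, -6), 10, 6),
             matrix(rnorm(10 * 6, 0), 10, 6),
             matrix(rnorm(10 * 6, 6), 10, 6))
  rownames(m) <- paste0("t", 1:30); colnames(m) <- paste0("s", 1:6)
  cl <- bicluster(m, k = 3)
  ab <- call_ab_types(cl)
  expect_setequal(ab$b_type, paste0("t", 1:10))
  expect_setequal(ab$a_type, paste0("t", 21:30))
  expect_length(intersect(ab$a_type, ab$b_type), 0)
  # middle cluster members carry no label
  expect_length(union(ab$a_type, ab$b_type), 20)
  # merging extremes widens the calls
  ab2 <- call_ab_types(cl, merge_low = 2)
  expect_setequal(ab2$b_type, paste0("t", 1:20))
})

test_that("differential TADs detect planted shifts symmetrically", {
  set.seed(25)
  m <- matrix(rnorm(40 * 16), 40, 16,
              dimnames = list(paste0("t", 1:40), paste0("s", 1:16)))
  g1 <- paste0("s", 1:8); g2 <- paste0("s", 9:16)
  m[1:5, g1] <- m[1:5, g1] + 3  # 3-sd shift toward group 1
  res <- differential_tads(m, g1, g2, p_cut = 0.01)
  expect_true(all(paste0("t", 1:5) %in% res$group1_predominant))
  # swapping groups swaps the sets
  res_sw <- differential_tads(m, g2, g1, p_cut = 0.01)
  expect_setequal(res_sw$group2_predominant, res$group1_predominant)
  expect_setequal(res_sw$group1_predominant, res$group2_predominant)
  # identical group means -> not flagged
  m2 <- m; m2[10, g1] <- m2[10, g2]
  res2 <- differential_tads(m2, g1, g2, p_cut = 0.01)
  expect_false("t10" %in% c(res2$group1_predominant,
                            res2$group2_predominant))
  # p_cut = 1 assigns every non-tied TAD to one side
  res_all <- differential_tads(m, g1, g2, p_cut = 1)
  expect_equal(sort(c(res_all$group1_predominant,
                      res_all$group2_predominant)),
               sort(rownames(m)[res_all$table$p < 1]))
})
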
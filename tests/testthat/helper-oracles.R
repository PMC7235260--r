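# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus tiny deterministic fixtures. Oracles are written
# as plain loops over definitions, sharing no code with the package paths
# they validate.

# brute-force point-in-interval scan over all TADs
brute_assign <- function(chrom, pos, tads) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(tads))) {
      if (tads$chrom[j] == chrom[i] &&
          pos[i] >= tads$start[j] && pos[i] < tads$end[j]) {
        out[i] <- tads$tad_id[j]
        break
      }
    }
  }
  out
}

# brute-force RP: double loop over genes and peaks
brute_rp <- function(ps, layout, delta = NULL, lambda = NULL) {
  genes <- layout$genes
  pt <- floor((ps$peaks$start + ps$peaks$end) / 2)
  ptad <- brute_assign(ps$peaks$chrom, pt, layout$tads)
  out <- rep(NA_real_, nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    if (is.na(genes$tad_id[i])) next
    s <- 0
    for (k in seq_along(pt)) {
      if (!is.na(ptad[k]) && ptad[k] == genes$tad_id[i]) {
        x <- abs(pt[k] - genes$tss[i])
        s <- s + if (!is.null(delta)) 2^(-x / delta)
                 else max(x, 1)^lambda
      }
    }
    out[i] <- s
  }
  out
}

# brute-force two-sample KS: sup over pooled points of ECDF difference
brute_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# brute-force distance correlation from first principles
brute_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j]); b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  sqrt(dcov2 / sqrt((sum(A * A) / n^2) * (sum(B * B) / n^2)))
}

# a small fixed layout: 3 TADs on 2 chromosomes, 6 genes
tiny_layout <- function() {
  tads <- data.frame(tad_id = c("t1", "t2", "t3"),
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(0L, 200000L, 0L),
                     end = c(100000L, 300000L, 150000L),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = paste0("g", 1:6),
                      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2",
                                "chr1"),
                      tss = c(10000L, 50000L, 250000L, 20000L, 140000L,
                              150000L),  # g6 falls between TADs
                      strand = c("+", "-", "+", "+", "-", "+"),
                      stringsAsFactors = FALSE)
  suppressMessages(genome_layout(genes, tads))
}

# peaks at known distances from g1 (tss 10000) inside t1
tiny_peaks <- function(xs, chrom = "chr1", tss = 10000L, width = 200L) {
  centers <- tss + xs
  peak_set("TFX", "sx",
           data.frame(chrom = chrom, start = centers - width %/% 2,
                      end = centers - width %/% 2 + width,
                      intensity = seq_along(xs) + 0.5,
                      stringsAsFactors = FALSE))
}

grid_step_apart <- function(grid, a, b) {
  abs(which.min(abs(log(grid) - log(a))) -
        which.min(abs(log(grid) - log(b))))
}
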
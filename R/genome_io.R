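# Coordinate convention: BED-style 0-based half-open [start, end) everywhere
# internally; conversion to the 1-based closed convention of GenomicRanges
# happens only inside the overlap helpers.

#' Construct a genome layout of genes and TADs
#'
#' Bundles a gene annotation (one TSS per gene) with a set of topologically
#' associating domains (TADs) and assigns every gene to the TAD containing
#' its TSS. Genes whose TSS falls in no TAD remain in the layout but are
#' marked unmapped; downstream regulatory-potential scoring skips them and
#' reports them as excluded rather than silently dropping them.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss} (0-based bp) and \code{strand}.
#' @param tads data.frame with columns \code{tad_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open). TADs on one chromosome
#'   must not overlap.
#' @return An object of class \code{genome_layout}: a list with elements
#'   \code{genes} (with an added \code{tad_id} column, \code{NA} when
#'   unmapped) and \code{tads}.
#' @export
genome_layout <- function(genes, tads) {
  req_g <- c("gene_id", "chrom", "tss", "strand")
  req_t <- c("tad_id", "chrom", "start", "end")
  if (!all(req_g %in% names(genes)))
    stop("genes must have columns: ", paste(req_g, collapse = ", "))
  if (!all(req_t %in% names(tads)))
    stop("tads must have columns: ", paste(req_t, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene annotation")
  if (anyDuplicated(tads$tad_id))
    stop("duplicate tad_id")
  if (any(tads$end <= tads$start))
    stop("TAD intervals must satisfy start < end")
  .check_tads_disjoint(tads)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  tads <- as.data.frame(tads, stringsAsFactors = FALSE)
  genes$tad_id <- assign_to_tads(genes$chrom, genes$tss, tads)
  n_unmapped <- sum(is.na(genes$tad_id))
  if (n_unmapped > 0)
    message(n_unmapped, " gene(s) have a TSS outside every TAD; ",
            "kept unmapped")
  structure(list(genes = genes, tads = tads), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$genes), "genes (",
      sum(!is.na(x$genes$tad_id)), "mapped ),",
      nrow(x$tads), "TADs on",
      length(unique(x$tads$chrom)), "chromosome(s)\n")
  invisible(x)
}

.check_tads_disjoint <- function(tads) {
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, , drop = FALSE]
    o <- order(t$start)
    if (any(t$end[o][-nrow(t)] > t$start[o][-1]))
      stop("overlapping TADs on chromosome ", ch)
  }
  invisible(TRUE)
}

#' Construct a ChIP-seq peak set
#'
#' @param tf_id TF identifier.
#' @param sample_id sample identifier (one ChIP-seq experiment).
#' @param peaks data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and optionally \code{intensity} (the
#'   peak-caller score used for top-N filtering) and \code{summit} (absolute
#'   bp position of the peak summit).
#' @return Object of class \code{peak_set}.
#' @export
peak_set <- function(tf_id, sample_id, peaks) {
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks must have columns chrom, start, end")
  if (any(peaks$end <= peaks$start))
    stop("peak intervals must satisfy start < end")
  structure(list(tf_id = tf_id, sample_id = sample_id,
                 peaks = as.data.frame(peaks, stringsAsFactors = FALSE),
                 discarded = FALSE),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", x$tf_id, "/", x$sample_id, "-", nrow(x$peaks), "peaks",
      if (isTRUE(x$discarded)) "(flagged discarded)" else "", "\n")
  invisible(x)
}

#' Read a BED-like interval file
#'
#' Reads tab-separated intervals (0-based half-open), rejecting malformed
#' records with the offending line number. For \code{kind = "peak"} the BED
#' score column (column 5, or column 4 when only four columns are present)
#' is taken as the peak intensity.
#'
#' @param path file path; lines starting with \code{#} are skipped.
#' @param kind one of \code{"tad"}, \code{"peak"}, \code{"snp"}; controls
#'   which optional columns are interpreted.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}, plus
#'   \code{name} and \code{intensity} where available.
#' @export
read_intervals <- function(path, kind = c("tad", "peak", "snp")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED record (fewer than 3 fields) at line ",
         lineno[which(nf < 3)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("non-integer coordinates at line ", lineno[which(bad)[1]])
  if (any(end <= start))
    stop("end <= start at line ", lineno[which(end <= start)[1]])
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (max(nf) >= 4)
    out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (kind == "peak") {
    score_col <- if (max(nf) >= 5) 5L else if (max(nf) >= 4) 4L else NA_integer_
    if (!is.na(score_col)) {
      sc <- suppressWarnings(as.numeric(vapply(
        fields, function(f) if (length(f) >= score_col) f[[score_col]] else NA_character_, "")))
      out$intensity <- sc
    }
  }
  out
}

#' Write intervals as BED
#'
#' Emits tab-separated BED records preceded by \code{#}-prefixed provenance
#' comments, so the file round-trips through \code{\link{read_intervals}}.
#'
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{name}, \code{intensity}.
#' @param path output path.
#' @param comment optional character vector of provenance lines.
#' @export
write_intervals <- function(intervals, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) cols <- c(cols, list(intervals$name))
  if (!is.null(intervals$intensity)) {
    if (is.null(intervals$name)) cols <- c(cols, list("."))
    cols <- c(cols, list(intervals$intensity))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated file with a header containing \code{gene_id},
#' \code{chrom}, \code{start}, \code{end}, \code{strand} (0-based half-open
#' gene body). The TSS is \code{start} for \code{+}-strand genes and
#' \code{end - 1} for \code{-}-strand genes.
#'
#' @param path file path.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{strand} suitable for \code{\link{genome_layout}}.
#' @export
read_gene_annotation <- function(path) {
  tbl <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(tbl)))
    stop("gene annotation must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tbl$gene_id))
    stop("duplicate gene_id: ",
         tbl$gene_id[anyDuplicated(tbl$gene_id)])
  if (!all(tbl$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(setdiff(unique(tbl$strand), c("+", "-")), collapse = ", "))
  data.frame(gene_id = tbl$gene_id, chrom = tbl$chrom,
             tss = ifelse(tbl$strand == "+", tbl$start, tbl$end - 1L),
             strand = tbl$strand, stringsAsFactors = FALSE)
}

#' Assign genomic points to TADs
#'
#' Maps each point to the unique TAD whose half-open interval contains it,
#' or \code{NA} when the point lies in no TAD.
#'
#' @param chrom character vector of chromosomes.
#' @param pos integer vector of 0-based positions, same length.
#' @param tads TAD data.frame (\code{tad_id}, \code{chrom}, \code{start},
#'   \code{end}); validated for disjointness.
#' @return character vector of \code{tad_id} (\code{NA} if unassigned).
#' @export
assign_to_tads <- function(chrom, pos, tads) {
  .check_tads_disjoint(tads)
  if (length(chrom) != length(pos))
    stop("chrom and pos must have equal length")
  out <- rep(NA_character_, length(pos))
  if (length(pos) == 0 || nrow(tads) == 0) return(out)
  # 0-based half-open -> 1-based closed for GRanges
  tad_gr <- GenomicRanges::GRanges(
    tads$chrom, IRanges::IRanges(tads$start + 1L, tads$end))
  pt_gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  # chromosomes absent from the TAD set simply yield unmapped points
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pt_gr, tad_gr))
  out[S4Vectors::queryHits(hits)] <- tads$tad_id[S4Vectors::subjectHits(hits)]
  out
}

#' Apply the top-N peak-count filter to a sample
#'
#' Samples with fewer than \code{min_peaks} peaks are flagged discarded;
#' otherwise exactly the \code{cap} highest-intensity peaks are retained.
#' Ties at the cutoff are broken deterministically by (intensity
#' descending, chrom, start). The default cap of 20,000 reflects the
#' convention of using only the strongest peaks so that occupancy is
#' comparable across ChIP-seq samples; smaller caps (e.g. 10,000) support
#' robustness checks and synthetic runs.
#'
#' @param ps a \code{\link{peak_set}} with an \code{intensity} column.
#' @param cap number of peaks to retain (default 20000).
#' @param min_peaks minimum peak count below which the sample is flagged
#'   discarded (default equal to \code{cap}).
#' @return the filtered \code{peak_set}; \code{$discarded} is \code{TRUE}
#'   when the sample fails the minimum.
#' @export
filter_peaks <- function(ps, cap = 20000L, min_peaks = cap) {
  stopifnot(inherits(ps, "peak_set"))
  if (is.null(ps$peaks$intensity) || anyNA(ps$peaks$intensity))
    stop("filter_peaks requires an intensity for every peak")
  if (nrow(ps$peaks) < min_peaks) {
    ps$discarded <- TRUE
    return(ps)
  }
  if (nrow(ps$peaks) > cap) {
    o <- order(-ps$peaks$intensity, ps$peaks$chrom, ps$peaks$start)
    ps$peaks <- ps$peaks[o[seq_len(cap)], , drop = FALSE]
    rownames(ps$peaks) <- NULL
  }
  ps
}

#' Representative point of each peak
#'
#' The distance term of the regulatory-potential kernel needs one
#' coordinate per peak. The interval midpoint \code{floor((start+end)/2)}
#' is used by default; when the peak table carries a \code{summit} column
#' and \code{use_summit = TRUE} the summit is used instead.
#'
#' @param peaks peak data.frame (or a \code{peak_set}).
#' @param use_summit take the \code{summit} column when present.
#' @return integer vector of 0-based positions.
#' @export
peak_representative_point <- function(peaks, use_summit = FALSE) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  if (use_summit && !is.null(peaks$summit))
    return(as.integer(peaks$summit))
  as.integer(floor((peaks$start + peaks$end) / 2))
}
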
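# True autozygosity (ROH) and IBD from founder-segment identity.
#
# Both operations take the founder-segment table emitted by
# simulate_admixture() ($founder_segments) or individual_segments():
# columns sample, hap, chrom, start, end, founder. Two segments are IBD when
# they descend from the same founder haplotype (equal founder key).

# split a founder-segment table into per-(sample, chrom, hap) tilings
.seg_index <- function(seg) {
  split(seq_len(nrow(seg)),
        paste(seg$sample, seg$chrom, seg$hap, sep = "\r"), drop = TRUE)
}

# key of the segment covering each query position (0-based) of one tiling
.key_at <- function(ends, keys, pos) keys[findInterval(pos, ends) + 1L]

# maximal intervals where two tilings of the same chromosome carry equal keys
.shared_intervals <- function(e1, k1, e2, k2) {
  cuts <- sort(unique(c(e1, e2)))
  starts <- c(0L, cuts[-length(cuts)])
  same <- .key_at(e1, k1, starts) == .key_at(e2, k2, starts)
  if (!any(same)) return(NULL)
  r <- rle(same)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  ok <- which(r$values)
  cbind(start = starts[lo[ok]], end = cuts[hi[ok]])
}

#' True runs of homozygosity from founder-segment identity
#'
#' ROH arise when both homologs of an individual are inherited identical by
#' descent from a common ancestor; with founder-segment tracking this is
#' exact: a position is autozygous when haplotypes 0 and 1 carry the same
#' founder key. Reports maximal autozygous intervals as ROH with genetic
#' lengths from the map. Individuals carrying a single haplotype on a
#' chromosome (male X) contribute no ROH there.
#'
#' @param seg founder-segment table (`sample`, `hap`, `chrom`, `start`,
#'   `end`, `founder`), e.g. `simulate_admixture(...)$founder_segments`.
#' @param map a [genetic_map()].
#' @return ROH rows of a segment table (see [read_segments()] for columns).
#' @export
autozygosity_truth <- function(seg, map) {
  stop_if_not_cols(seg, c("sample", "hap", "chrom", "start", "end", "founder"),
                   "founder-segment table")
  idx <- .seg_index(seg)
  out <- list()
  h0 <- idx[grepl("\r0$", names(idx))]
  for (nm in names(h0)) {
    nm1 <- sub("\r0$", "\r1", nm)
    j1 <- idx[[nm1]]
    if (is.null(j1)) next
    i0 <- h0[[nm]]
    iv <- .shared_intervals(seg$end[i0], seg$founder[i0],
                            seg$end[j1], seg$founder[j1])
    if (is.null(iv)) next
    out[[length(out) + 1L]] <- data.frame(
      sample1 = seg$sample[i0[1]], chrom = seg$chrom[i0[1]],
      start = iv[, "start"], end = iv[, "end"], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), sample1 = character(0),
                      hap1 = integer(0), sample2 = character(0),
                      hap2 = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0), cM = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  data.frame(kind = "ROH", sample1 = res$sample1, hap1 = NA_integer_,
             sample2 = NA_character_, hap2 = NA_integer_, chrom = res$chrom,
             start = res$start, end = res$end,
             cM = interval_cm(map, res$chrom, res$start, res$end),
             class = NA_character_, stringsAsFactors = FALSE)
}

#' True IBD segments from founder-segment identity
#'
#' For each requested pair of individuals and each homolog pair, reports the
#' maximal intervals descending from the same founder haplotype. Pair count
#' is quadratic in the sample, so either pass an explicit `pairs` table or
#' rely on `max_pairs` subsampling (uniform, uses the current RNG).
#'
#' @inheritParams autozygosity_truth
#' @param pairs optional data frame with columns `sample1`, `sample2`; when
#'   `NULL`, all unordered pairs of samples present in `seg` are used.
#' @param max_pairs cap on the number of pairs examined.
#' @return IBD rows of a segment table.
#' @export
ibd_truth <- function(seg, map, pairs = NULL, max_pairs = 5000) {
  stop_if_not_cols(seg, c("sample", "hap", "chrom", "start", "end", "founder"),
                   "founder-segment table")
  ids <- unique(seg$sample)
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least two samples for IBD")
    cmb <- utils::combn(ids, 2)
    pairs <- data.frame(sample1 = cmb[1, ], sample2 = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    stop_if_not_cols(pairs, c("sample1", "sample2"), "pair table")
    bad <- setdiff(c(pairs$sample1, pairs$sample2), ids)
    if (length(bad)) {
      stop(sprintf("pair table names unknown sample(s): %s",
                   paste(head(bad, 3), collapse = ", ")))
    }
  }
  if (nrow(pairs) > max_pairs) {
    pairs <- pairs[sort(sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
  }
  # per-sample, per-chrom, per-hap tilings
  idx <- .seg_index(seg)
  chroms <- intersect(map$chrom, unique(seg$chrom))
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    s1 <- pairs$sample1[p]; s2 <- pairs$sample2[p]
    for (ch in chroms) {
      for (ha in 0:1) {
        i1 <- idx[[paste(s1, ch, ha, sep = "\r")]]
        if (is.null(i1)) next
        for (hb in 0:1) {
          i2 <- idx[[paste(s2, ch, hb, sep = "\r")]]
          if (is.null(i2)) next
          iv <- .shared_intervals(seg$end[i1], seg$founder[i1],
                                  seg$end[i2], seg$founder[i2])
          if (is.null(iv)) next
          out[[length(out) + 1L]] <- data.frame(
            sample1 = s1, hap1 = ha, sample2 = s2, hap2 = hb, chrom = ch,
            start = iv[, "start"], end = iv[, "end"],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), sample1 = character(0),
                      hap1 = integer(0), sample2 = character(0),
                      hap2 = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0), cM = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  data.frame(kind = "IBD", sample1 = res$sample1, hap1 = res$hap1,
             sample2 = res$sample2, hap2 = res$hap2, chrom = res$chrom,
             start = res$start, end = res$end,
             cM = interval_cm(map, res$chrom, res$start, res$end),
             class = NA_character_, stringsAsFactors = FALSE)
}
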
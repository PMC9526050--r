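# Pairwise IBD totals, relatedness networks, and an IBD-based kinship proxy.

#' Pairwise total IBD after a minimum-length filter
#'
#' Drops IBD segments shorter than `min_cm` (short segments are hard to
#' detect reliably, hence the conventional 5 cM floor) and sums the
#' remaining genetic length per unordered sample pair over all homolog
#' pairs and chromosomes.
#'
#' @param ibd segment table with IBD rows (columns `sample1`, `sample2`,
#'   `cM`; see [ibd_truth()] / [read_segments()]).
#' @param min_cm minimum segment length retained, in cM (default 5).
#' @return data frame `sample1`, `sample2` (lexicographically ordered within
#'   pair), `total_cm`, `n_segments`. Pairs sharing nothing are absent.
#' @export
pairwise_ibd_totals <- function(ibd, min_cm = 5) {
  stop_if_not_cols(ibd, c("sample1", "sample2", "cM"), "IBD table")
  ibd <- ibd[!is.na(ibd$sample2) & ibd$cM >= min_cm, , drop = FALSE]
  if (!nrow(ibd)) {
    return(data.frame(sample1 = character(0), sample2 = character(0),
                      total_cm = numeric(0), n_segments = integer(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(ibd$sample1, ibd$sample2)
  b <- pmax(ibd$sample1, ibd$sample2)
  key <- paste(a, b, sep = "\r")
  tot <- rowsum(ibd$cM, key)
  cnt <- rowsum(rep(1L, nrow(ibd)), key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  out <- data.frame(sample1 = parts[, 1], sample2 = parts[, 2],
                    total_cm = tot[, 1], n_segments = as.integer(cnt[, 1]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$sample1, out$sample2), , drop = FALSE]
}

#' Relatedness network edges from IBD totals
#'
#' Edges connect pairs whose total IBD exceeds either an absolute threshold
#' (`edge_cm`, e.g. the 150 cM convention for close relatives) or the
#' `(1 - top_quantile)` quantile of the nonzero totals (e.g.
#' `top_quantile = 0.03` keeps the top 3% of the distribution, as a count:
#' `ceiling(top_quantile * n)` edges, ties broken deterministically).
#' Supplying both thresholds is ambiguous and refused.
#'
#' @param totals data frame from [pairwise_ibd_totals()].
#' @param edge_cm absolute threshold in cM (default 150; set `NULL` to use
#'   `top_quantile`).
#' @param top_quantile optional fraction of top pairs to keep.
#' @return edge list with `sample1`, `sample2`, `total_cm` and
#'   log10-transformed `weight`.
#' @export
ibd_network <- function(totals, edge_cm = 150, top_quantile = NULL) {
  stop_if_not_cols(totals, c("sample1", "sample2", "total_cm"), "IBD totals")
  if (!is.null(edge_cm) && !is.null(top_quantile)) {
    stop("supply either edge_cm or top_quantile, not both")
  }
  if (is.null(edge_cm) && is.null(top_quantile)) {
    stop("one of edge_cm or top_quantile is required")
  }
  tot <- totals[totals$total_cm > 0, , drop = FALSE]
  if (!nrow(tot)) {
    edges <- tot
  } else if (!is.null(edge_cm)) {
    edges <- tot[tot$total_cm > edge_cm, , drop = FALSE]
  } else {
    k <- ceiling(top_quantile * nrow(tot))
    ord <- order(-tot$total_cm, tot$sample1, tot$sample2)
    edges <- tot[ord[seq_len(k)], , drop = FALSE]
  }
  edges <- edges[, c("sample1", "sample2", "total_cm")]
  edges$weight <- log10(edges$total_cm)
  rownames(edges) <- NULL
  edges
}

#' IBD-segment kinship proxy
#'
#' Kinship approximated as the shared genetic length summed over the four
#' homolog pairs, divided by four times the total autosomal map length:
#' parent-offspring and full-sib pairs are expected near 0.25, halving with
#' each additional meiosis separating the pair. Requires homolog-resolved
#' IBD (truth or calls); X segments are excluded.
#'
#' @param ibd homolog-resolved IBD segment table (e.g. [ibd_truth()]).
#' @param map a [genetic_map()] whose autosomal genetic length sets the
#'   denominator.
#' @param min_cm optional minimum segment length (default 0: truth segments
#'   need no detection floor).
#' @return data frame `sample1`, `sample2`, `kinship`.
#' @export
kinship_proxy <- function(ibd, map, min_cm = 0) {
  L <- map_total_cm(map, "autosomes")
  if (L <= 0) stop("map has no autosomal length")
  xchr <- map$chrom[map$is_X]
  ibd <- ibd[!(ibd$chrom %in% xchr), , drop = FALSE]
  tot <- pairwise_ibd_totals(ibd, min_cm = min_cm)
  data.frame(sample1 = tot$sample1, sample2 = tot$sample2,
             kinship = tot$total_cm / (4 * L), stringsAsFactors = FALSE)
}
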
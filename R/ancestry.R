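# Global ancestry proportions, population summaries, local ancestry
# disequilibrium (LAD) in genomic windows, and the paired X-vs-autosome test.

#' Per-sample global S1 ancestry proportion
#'
#' Proportion of S1 ancestry as S1 genetic length divided by total genetic
#' length in scope (cM-weighted). On the X, females contribute two haplotypes
#' and males one, so the denominator follows the haplotypes actually present.
#'
#' @param tracts validated local-ancestry tract table.
#' @param map a [genetic_map()].
#' @param scope `"autosomes"` or `"X"`.
#' @return data frame with columns `sample`, `prop`.
#' @export
global_ancestry <- function(tracts, map, scope = c("autosomes", "X")) {
  scope <- match.arg(scope)
  keep_chr <- if (scope == "X") map$chrom[map$is_X] else map$chrom[!map$is_X]
  if (!length(keep_chr)) stop(sprintf("map has no chromosomes in scope '%s'", scope))
  tr <- tracts[tracts$chrom %in% keep_chr, , drop = FALSE]
  if (!nrow(tr)) {
    return(data.frame(sample = character(0), prop = numeric(0)))
  }
  cm <- interval_cm(map, tr$chrom, tr$start, tr$end)
  tot <- rowsum(cm, tr$sample)
  s1 <- rowsum(cm * (tr$ancestry == "S1"), tr$sample)
  data.frame(sample = rownames(tot), prop = s1[, 1] / tot[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-population ancestry summaries
#'
#' @param proportions data frame from [global_ancestry()] (columns `sample`,
#'   `prop`).
#' @param samples sample metadata with `sample` and `population` columns.
#' @return one row per population: n, mean, sd, median, quartiles.
#' @export
population_summary <- function(proportions, samples) {
  stop_if_not_cols(proportions, c("sample", "prop"), "proportions")
  stop_if_not_cols(samples, c("sample", "population"), "samples")
  pop <- samples$population[match(proportions$sample, samples$sample)]
  if (anyNA(pop)) stop("proportions contain samples absent from metadata")
  sp <- split(proportions$prop, pop)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    v <- sp[[p]]
    data.frame(population = p, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               median = median(v),
               q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# S1 indicator for every haplotype of `tracts` (one chromosome) at positions
# `pos`; returns matrix haplotypes x positions, with haplotype labels.
.ancestry_indicator <- function(tr, pos, length_bp) {
  hap_id <- paste(tr$sample, tr$hap, sep = "\r")
  new <- !duplicated(hap_id)
  hap_lab <- hap_id[new]
  hidx <- match(hap_id, hap_lab)
  # global-coordinate trick: shift every haplotype into its own [h*L, (h+1)*L)
  L <- as.numeric(length_bp)
  gends <- sort((hidx - 1) * L + tr$end)
  ganc <- (tr$ancestry == "S1")[order((hidx - 1) * L + tr$end)]
  q <- as.vector(outer((seq_along(hap_lab) - 1) * L, as.numeric(pos), "+"))
  ind <- ganc[findInterval(q, gends) + 1L]
  matrix(as.numeric(ind), nrow = length(hap_lab), ncol = length(pos),
         dimnames = list(hap_lab, NULL))
}

#' Local ancestry disequilibrium in overlapping windows
#'
#' Places anchor pairs at the start and end of windows of `window_mb`
#' megabases; successive window starts are `window_mb - overlap_mb` apart
#' (the default reading of windows "overlapping by 1 Mb"; set `step_mb` to
#' override, e.g. `step_mb = 1` for the sliding reading). Trailing incomplete
#' windows are dropped. At each anchor pair the LAD value is the Pearson
#' correlation, across all haplotypes, of the S1 indicator at the two
#' positions (the end anchor is queried just inside the boundary);
#' covariance is also reported for diagnostics. Anchor pairs with zero
#' variance at either position are dropped and counted in the
#' `"dropped_zero_variance"` attribute. X chromosomes are excluded.
#'
#' @param tracts validated tract table (at least `min_hap` haplotypes).
#' @param map a [genetic_map()].
#' @param window_mb window span in Mb (default 10).
#' @param overlap_mb overlap between successive windows in Mb (default 1).
#' @param step_mb optional explicit step between window starts in Mb;
#'   overrides `window_mb - overlap_mb`.
#' @param min_hap minimum number of haplotypes required (default 20).
#' @return data frame (`chrom`, `anchor1_bp`, `anchor2_bp`, `dist_cm`,
#'   `lad_corr`, `lad_cov`, `n_hap`) with attributes `mean_lad` and
#'   `dropped_zero_variance`.
#' @export
lad_windows <- function(tracts, map, window_mb = 10, overlap_mb = 1,
                        step_mb = NULL, min_hap = 20) {
  step_mb <- step_mb %||% (window_mb - overlap_mb)
  if (step_mb <= 0 || window_mb <= 0) stop("window and step must be positive")
  autos <- map[!map$is_X, , drop = FALSE]
  rows <- list()
  dropped <- 0L
  for (cc in seq_len(nrow(autos))) {
    L <- autos$length_bp[cc]
    w <- window_mb * 1e6
    if (L < w) next
    starts <- seq(0, L - w, by = step_mb * 1e6)
    if (!length(starts)) next
    tr <- tracts[tracts$chrom == autos$chrom[cc], , drop = FALSE]
    if (!nrow(tr)) next
    a1 <- starts
    a2 <- starts + w
    pos <- unique(c(a1, pmin(a2, L) - 1)) # end anchor just inside boundary
    ind <- .ancestry_indicator(tr, pos, L)
    if (nrow(ind) < min_hap) {
      stop(sprintf("need at least %d haplotypes, found %d", min_hap, nrow(ind)))
    }
    i1 <- match(a1, pos)
    i2 <- match(pmin(a2, L) - 1, pos)
    for (k in seq_along(a1)) {
      x <- ind[, i1[k]]; y <- ind[, i2[k]]
      if (var(x) == 0 || var(y) == 0) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = autos$chrom[cc], anchor1_bp = a1[k], anchor2_bp = a2[k],
        dist_cm = (a2[k] - a1[k]) * autos$cm_per_mb[cc] / 1e6,
        lad_corr = cor(x, y), lad_cov = cov(x, y), n_hap = nrow(ind),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no complete window on any autosome")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_lad") <- mean(out$lad_corr)
  attr(out, "dropped_zero_variance") <- dropped
  out
}

#' Paired X-versus-autosome ancestry test
#'
#' Two-sided Wilcoxon signed-rank test of per-sample X ancestry against
#' autosomal ancestry (normal approximation with continuity correction;
#' zero differences dropped). Requires at least 6 informative pairs.
#'
#' @param auto,x data frames from [global_ancestry()] for the two scopes, or
#'   plain numeric vectors already paired by sample.
#' @return list with `statistic` (V, the signed-rank statistic of `x`
#'   against `auto`), `p_value`, `n_informative`, and the two means.
#' @export
x_vs_auto_test <- function(auto, x) {
  if (is.data.frame(auto)) {
    m <- match(x$sample, auto$sample)
    if (anyNA(m)) stop("X and autosomal tables must cover the same samples")
    av <- auto$prop[m]; xv <- x$prop
  } else {
    av <- auto; xv <- x
    if (length(av) != length(xv)) stop("paired vectors must have equal length")
  }
  informative <- sum(xv != av, na.rm = TRUE)
  if (informative < 6) {
    stop("fewer than 6 informative (non-tied) pairs; test refused")
  }
  wt <- suppressWarnings(
    wilcox.test(xv, av, paired = TRUE, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_informative = informative, mean_x = mean(xv), mean_auto = mean(av))
}
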
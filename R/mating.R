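# Parental-ancestry decomposition and the ancestry-assortative mating test.
#
# Each phased haplotype of an offspring is one parental gamete, so the S1
# genetic fraction of a haplotype on one chromosome is a moment estimate of
# the transmitting parent's ancestry. Chromosomes are analyzed independently
# to avoid matching haplotypes across chromosomes (phasing does not link
# them), and the per-chromosome Pearson correlations between the two
# parental estimates are summarized by their median.

#' Estimate parental ancestries from phased tracts
#'
#' Moment estimator: for each sample and autosome, `a1` and `a2` are the S1
#' genetic fractions of haplotypes 0 and 1 (each phased haplotype is one
#' parental gamete). Parent labels are arbitrary.
#'
#' @param tracts validated local-ancestry tract table.
#' @param map a [genetic_map()]; X chromosomes are excluded.
#' @return data frame with columns `sample`, `chrom`, `a1`, `a2`; samples
#'   missing a haplotype on a chromosome are dropped.
#' @export
parental_ancestry <- function(tracts, map) {
  autos <- map$chrom[!map$is_X]
  tr <- tracts[tracts$chrom %in% autos, , drop = FALSE]
  if (!nrow(tr)) stop("no autosomal tracts")
  key <- paste(tr$sample, tr$chrom, tr$hap, sep = "\r")
  cm <- interval_cm(map, tr$chrom, tr$start, tr$end)
  tot <- rowsum(cm, key)
  s1 <- rowsum(cm * (tr$ancestry == "S1"), key)
  frac <- s1[, 1] / tot[, 1]
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  df <- data.frame(sample = parts[, 1], chrom = parts[, 2],
                   hap = as.integer(parts[, 3]), frac = frac,
                   row.names = NULL, stringsAsFactors = FALSE)
  w <- stats::reshape(df, direction = "wide", idvar = c("sample", "chrom"),
                      timevar = "hap")
  names(w) <- sub("^frac\\.0$", "a1", names(w))
  names(w) <- sub("^frac\\.1$", "a2", names(w))
  if (!all(c("a1", "a2") %in% names(w))) stop("missing haplotype on every chromosome")
  w <- w[!is.na(w$a1) & !is.na(w$a2), c("sample", "chrom", "a1", "a2")]
  rownames(w) <- NULL
  w
}

# symmetrized Pearson R on {(a1,a2)} U {(a2,a1)}
.sym_cor <- function(a1, a2) {
  x <- c(a1, a2); y <- c(a2, a1)
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Spousal ancestry correlation from parental estimates
#'
#' Per-chromosome Pearson R between the two parental ancestry estimates,
#' computed by default on the symmetrized set `{(a1, a2)} U {(a2, a1)}`
#' (parent labels are arbitrary; symmetrization removes label-order noise).
#' The median across chromosomes is reported as the population's assortment
#' strength — the value to pass to [fit_generations()] as `rho`. Chromosomes
#' with fewer than `min_n` individuals or zero variance are skipped with a
#' warning.
#'
#' @param pairs data frame from [parental_ancestry()].
#' @param symmetrize use the symmetrized correlation (default TRUE); when
#'   FALSE, the as-labeled ordered correlation is computed.
#' @param min_n minimum individuals per chromosome (default 10).
#' @return list with `per_chrom` (chrom, n, r), `median_r`.
#' @export
assortment_correlation <- function(pairs, symmetrize = TRUE, min_n = 10) {
  stop_if_not_cols(pairs, c("sample", "chrom", "a1", "a2"), "parental pairs")
  sp <- split(pairs, pairs$chrom)
  rows <- lapply(names(sp), function(ch) {
    d <- sp[[ch]]
    if (nrow(d) < min_n) {
      warning(sprintf("chromosome %s skipped: fewer than %d individuals",
                      ch, min_n))
      return(NULL)
    }
    r <- if (symmetrize) .sym_cor(d$a1, d$a2) else {
      if (var(d$a1) == 0 || var(d$a2) == 0) NA_real_ else cor(d$a1, d$a2)
    }
    if (is.na(r)) {
      warning(sprintf("chromosome %s skipped: zero variance", ch))
      return(NULL)
    }
    data.frame(chrom = ch, n = nrow(d), r = r, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || !nrow(rows)) stop("no usable chromosome")
  list(per_chrom = rows, median_r = median(rows$r))
}

#' Permutation null for the assortment correlation
#'
#' Random-mating null: each shuffle draws one permutation of the
#' individuals and re-pairs every individual's `a1` haplotypes with the
#' partner's `a2` haplotypes within each chromosome, then the
#' median-across-chromosomes symmetrized R is recomputed. The empirical
#' two-sided p-value is `(1 + #{|R_perm| >= |R_obs|}) / (1 + B)`.
#' Deterministic given `seed`.
#'
#' The permutation is drawn at the individual level (one shuffle applied to
#' all chromosomes) rather than independently per chromosome: a sample's
#' chromosomes share its two parents, so per-chromosome R values are
#' strongly dependent, and independent per-chromosome shuffles shrink the
#' null spread of the median far below its true sampling variation
#' (grossly anti-conservative in simulation).
#'
#' The test assumes no first-degree relatives among the samples (the usual
#' hygiene for cohort genotype data): full sibs duplicate the identical
#' parental link, which no row-level permutation can emulate, and their
#' presence inflates the type-I error. Deduplicate sibships upstream.
#'
#' @inheritParams assortment_correlation
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return an `assortment_test` list: `per_chrom`, `median_r`, `B`, `p`,
#'   `seed`, `perm_medians`.
#' @export
permutation_null <- function(pairs, B = 1000, seed = 1, symmetrize = TRUE,
                             min_n = 10) {
  if (B < 100) stop("B must be >= 100")
  obs <- assortment_correlation(pairs, symmetrize = symmetrize, min_n = min_n)
  keep <- pairs$chrom %in% obs$per_chrom$chrom
  d <- pairs[keep, , drop = FALSE]
  ids <- unique(d$sample)
  n_ind <- length(ids)
  sp <- split(d, d$chrom)
  perm_mat <- with_seed(seed, {
    Pi <- vapply(seq_len(B), function(b) sample.int(n_ind), integer(n_ind))
    stats_by_chrom <- lapply(sp, function(dc) {
      n <- nrow(dc)
      a1 <- dc$a1
      # a2 indexed by master individual; rows whose permuted partner is
      # absent on this chromosome fall back to themselves (complete data
      # never hits this)
      a2_by_ind <- rep(NA_real_, n_ind)
      a2_by_ind[match(dc$sample, ids)] <- dc$a2
      pos <- match(dc$sample, ids)
      partner <- matrix(Pi[pos, ], nrow = n)
      A2P <- matrix(a2_by_ind[partner], nrow = n)
      miss <- is.na(A2P)
      if (any(miss)) A2P[miss] <- dc$a2[row(A2P)[miss]]
      if (symmetrize) {
        # symmetrized r: only sum(a1 * a2perm) varies across shuffles
        mu <- mean(c(a1, dc$a2))
        den <- sum((c(a1, dc$a2) - mu)^2)
        (2 * colSums(a1 * A2P) - 2 * n * mu^2) / den
      } else {
        v1 <- sum((a1 - mean(a1))^2)
        sweep2 <- colSums(A2P)
        num <- colSums(a1 * A2P) - mean(a1) * sweep2
        den <- sqrt(v1 * (colSums(A2P^2) - sweep2^2 / n))
        num / den
      }
    })
    do.call(rbind, stats_by_chrom)
  })
  perm_medians <- apply(perm_mat, 2, median)
  p <- (1 + sum(abs(perm_medians) >= abs(obs$median_r))) / (1 + B)
  structure(list(per_chrom = obs$per_chrom, median_r = obs$median_r,
                 B = B, p = p, seed = seed, perm_medians = perm_medians),
            class = "assortment_test")
}

#' @export
print.assortment_test <- function(x, ...) {
  cat(sprintf(
    "ancestry assortment: median R = %.4f over %d chromosomes; permutation p = %.4g (B = %d)\n",
    x$median_r, nrow(x$per_chrom), x$p, x$B))
  invisible(x)
}

#' One-call assortment test from tracts
#'
#' Convenience wrapper: [parental_ancestry()] then [permutation_null()].
#'
#' @inheritParams parental_ancestry
#' @inheritParams permutation_null
#' @return an `assortment_test` (see [permutation_null()]).
#' @export
assortment_test <- function(tracts, map, B = 1000, seed = 1,
                            symmetrize = TRUE, min_n = 10) {
  permutation_null(parental_ancestry(tracts, map), B = B, seed = seed,
                   symmetrize = symmetrize, min_n = min_n)
}
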
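# ROH length classification and summaries.
#
# Two classification schemes: a fixed boundary from the 100/m-cM rule (mean
# IBD segment length for common ancestors a given number of generations
# back) and a 3-component Gaussian mixture on log10 segment length (the
# small / medium / long convention for ROH in worldwide populations).

#' Shorter/long ROH boundary implied by the 100/m-cM rule
#'
#' A common ancestor `g` generations back separates the two lineages by
#' `m = 2g` meioses, and a time depth of m meioses gives a mean IBD segment
#' length of `100/m` cM; converting genetic to physical length at `rate`
#' cM/Mb gives the boundary. Common ancestors within the past 20 generations
#' give segments of about 2.5 Mb or longer at the 1 cM/Mb baseline.
#'
#' @param g generations to the common ancestor (>= 1).
#' @param rate recombination rate in cM/Mb (default 1).
#' @return boundary in Mb.
#' @export
#' @examples
#' boundary_from_generations(20) # 2.5 Mb
boundary_from_generations <- function(g, rate = 1) {
  if (any(g < 1)) stop("g must be >= 1")
  m <- 2 * g
  (100 / m) / rate
}

# one-dimensional k-component Gaussian mixture by EM, k-means init
.gmm1d <- function(x, k = 3, restarts = 20, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- suppressWarnings(kmeans(x, centers = k, nstart = 1, iter.max = 50))
    mu <- as.numeric(km$centers)
    sg <- vapply(seq_len(k), function(j) {
      v <- x[km$cluster == j]
      max(sd(v), diff(range(x)) / (20 * k), 1e-4)
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * dnorm(x, mu[j], sg[j]), numeric(n))
      rs <- rowSums(dens)
      rs[rs < 1e-300] <- 1e-300
      ll <- sum(log(rs))
      resp <- dens / rs
      nk <- colSums(resp)
      if (any(nk < 1e-8)) break # empty component; abandon this restart
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      sg <- pmax(sg, 1e-4)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, w = w, mu = mu, sigma = sg)
    }
  }
  ord <- order(best$mu)
  list(ll = best$ll, w = best$w[ord], mu = best$mu[ord],
       sigma = best$sigma[ord])
}

# boundary between two adjacent ordered Gaussian components: the density
# intersection between the means, falling back to the midpoint when the
# components overlap so heavily that no intersection lies between them
.gmm_boundary <- function(w1, m1, s1, w2, m2, s2) {
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 / w2) + log(s2 / s1)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside)) inside[1] else (m1 + m2) / 2
}

#' Classify ROH segments by length
#'
#' Two schemes. `"gmm3"` fits a 3-component Gaussian mixture to log10
#' physical length (EM with k-means initialization, `restarts` restarts,
#' deterministic under `seed`) and places class boundaries at the density
#' intersections of adjacent ordered components, labeling segments A
#' (small), B (medium), C (long). `"fixed"` applies a single shorter/long
#' boundary in Mb, e.g. from [boundary_from_generations()], labeling
#' segments `shorter` / `long`.
#'
#' @param segments segment table with ROH rows (columns `chrom`, `start`,
#'   `end` at least).
#' @param scheme `"fixed"` or `"gmm3"`.
#' @param boundary_mb fixed-scheme boundary in Mb (required for `"fixed"`).
#' @param restarts EM restarts for `"gmm3"` (default 20).
#' @param seed RNG seed for the k-means initializations (default 1); the
#'   caller's RNG state is left untouched.
#' @return a `roh_classification` list: `scheme`, `boundaries_bp`
#'   (increasing), `segments` (input with `class` filled), and for gmm3 the
#'   `components` diagnostics (weights, means and sds on log10 bp).
#' @export
classify_roh <- function(segments, scheme = c("fixed", "gmm3"),
                         boundary_mb = NULL, restarts = 20, seed = 1) {
  scheme <- match.arg(scheme)
  stop_if_not_cols(segments, c("start", "end"), "segment table")
  len <- as.numeric(segments$end - segments$start)
  if (any(len <= 0)) stop("segment lengths must be positive")
  if (scheme == "fixed") {
    if (is.null(boundary_mb)) stop("fixed scheme needs boundary_mb")
    bnd <- boundary_mb * 1e6
    segments$class <- ifelse(len >= bnd, "long", "shorter")
    out <- list(scheme = "fixed", boundaries_bp = bnd, segments = segments)
  } else {
    if (length(len) < 50) {
      stop("gmm3 needs at least 50 segments; use the fixed scheme")
    }
    lx <- log10(len)
    if (length(unique(lx)) < 3 || sd(lx) < 1e-6) {
      stop("degenerate length distribution; use the fixed scheme")
    }
    fit <- with_seed(seed, .gmm1d(lx, k = 3, restarts = restarts))
    b12 <- .gmm_boundary(fit$w[1], fit$mu[1], fit$sigma[1],
                         fit$w[2], fit$mu[2], fit$sigma[2])
    b23 <- .gmm_boundary(fit$w[2], fit$mu[2], fit$sigma[2],
                         fit$w[3], fit$mu[3], fit$sigma[3])
    bnd <- 10^c(b12, b23)
    segments$class <- cut(len, c(0, bnd, Inf), labels = c("A", "B", "C"))
    segments$class <- as.character(segments$class)
    out <- list(scheme = "gmm3", boundaries_bp = bnd, segments = segments,
                components = data.frame(weight = fit$w, mean_log10 = fit$mu,
                                        sd_log10 = fit$sigma))
  }
  class(out) <- "roh_classification"
  out
}

#' @export
print.roh_classification <- function(x, ...) {
  cat(sprintf("ROH classification (%s): boundaries at %s bp; %d segments\n",
              x$scheme,
              paste(format(round(x$boundaries_bp)), collapse = ", "),
              nrow(x$segments)))
  print(table(x$segments$class))
  invisible(x)
}

#' Per-individual ROH totals, ancestry correlations and population tests
#'
#' Sums ROH genetic length per individual, overall and per length class
#' (classes always partition the total exactly). When per-sample S1 ancestry
#' proportions are supplied, Pearson correlations of each total against
#' ancestry are reported; when population labels are supplied, pairwise
#' Mann-Whitney U tests compare the per-individual totals between
#' populations (exact below 20 per group without ties, otherwise normal
#' approximation with continuity and tie correction, as wilcox.test does).
#'
#' @param classification a [classify_roh()] result (or a segment table with
#'   a `class` column).
#' @param ancestry optional data frame (`sample`, `prop`) from
#'   [global_ancestry()]. Samples listed there but free of ROH enter with
#'   total 0.
#' @param samples optional metadata with `sample` and `population`.
#' @return a list: `per_individual` (totals in cM, one column per class),
#'   `correlations` (class, r, p, n), `population_tests` (pairwise
#'   Mann-Whitney), `per_population` summary of total ROH.
#' @export
roh_summaries <- function(classification, ancestry = NULL, samples = NULL) {
  seg <- if (inherits(classification, "roh_classification")) {
    classification$segments
  } else {
    classification
  }
  stop_if_not_cols(seg, c("sample1", "cM", "class"), "classified ROH table")
  ids <- unique(c(seg$sample1, ancestry$sample, samples$sample))
  classes <- sort(unique(seg$class))
  per <- data.frame(sample = ids, total = 0, stringsAsFactors = FALSE)
  tot <- rowsum(seg$cM, seg$sample1)
  per$total[match(rownames(tot), per$sample)] <- tot[, 1]
  for (cl in classes) {
    v <- numeric(length(ids))
    sub <- seg[seg$class == cl, , drop = FALSE]
    if (nrow(sub)) {
      t2 <- rowsum(sub$cM, sub$sample1)
      v[match(rownames(t2), per$sample)] <- t2[, 1]
    }
    per[[cl]] <- v
  }
  out <- list(per_individual = per)
  if (!is.null(ancestry)) {
    m <- match(per$sample, ancestry$sample)
    anc <- ancestry$prop[m]
    ok <- !is.na(anc)
    if (sum(ok) < 3) stop("fewer than 3 individuals with ancestry values")
    out$correlations <- do.call(rbind, lapply(c("total", classes), function(cl) {
      v <- per[[cl]][ok]
      if (sd(v) == 0) {
        return(data.frame(class = cl, r = NA_real_, p = NA_real_,
                          n = sum(ok), stringsAsFactors = FALSE))
      }
      ct <- cor.test(v, anc[ok])
      data.frame(class = cl, r = unname(ct$estimate), p = ct$p.value,
                 n = sum(ok), stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(samples)) {
    pop <- samples$population[match(per$sample, samples$sample)]
    keep <- !is.na(pop)
    pops <- sort(unique(pop[keep]))
    out$per_population <- population_summary(
      data.frame(sample = per$sample[keep], prop = per$total[keep]),
      samples)
    if (length(pops) >= 2) {
      cmb <- utils::combn(pops, 2)
      out$population_tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
        a <- per$total[keep][pop[keep] == cmb[1, j]]
        b <- per$total[keep][pop[keep] == cmb[2, j]]
        wt <- suppressWarnings(mann_whitney_u(a, b))
        data.frame(pop1 = cmb[1, j], pop2 = cmb[2, j], U = wt$statistic,
                   p = wt$p_value, stringsAsFactors = FALSE)
      }))
    }
  }
  out
}

#' Mann-Whitney U test wrapper
#'
#' Two-sided by default; exact enumeration when both groups have fewer than
#' 20 observations and no ties, otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param a,b numeric samples.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic` (U) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  exact <- length(a) < 20 && length(b) < 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Ancestry switches inside ROH
#'
#' Counts local-ancestry breakpoints strictly inside each ROH, on either
#' haplotype of the carrier, deduplicated at identical positions (within an
#' autozygous segment the two homologs are copies, so shared breakpoints
#' count once). Reports per-segment counts and switches/Mb, per-class
#' fractions with at least one switch, and a Mann-Whitney comparison of
#' switch rates between classes.
#'
#' @param roh classified ROH table (columns `sample1`, `chrom`, `start`,
#'   `end`, `class`) or a [classify_roh()] result.
#' @param tracts the local-ancestry tract table of the same samples and
#'   coordinates.
#' @return list with `per_segment` (input plus `n_switches`,
#'   `switches_per_mb`), `by_class` (n, fraction with a switch, mean and sd
#'   of switches/Mb), and `class_test` (pairwise Mann-Whitney on
#'   switches/Mb).
#' @export
ancestry_switches_in_roh <- function(roh, tracts) {
  if (inherits(roh, "roh_classification")) roh <- roh$segments
  stop_if_not_cols(roh, c("sample1", "chrom", "start", "end", "class"),
                   "ROH table")
  stop_if_not_cols(tracts, c("sample", "hap", "chrom", "start", "end",
                             "ancestry"), "tract table")
  # switch positions: interior tract boundaries, per sample and chromosome,
  # both haplotypes pooled and deduplicated
  tr <- tracts[order(tracts$sample, tracts$chrom, tracts$hap, tracts$start), ]
  grp <- paste(tr$sample, tr$chrom, tr$hap, sep = "\r")
  interior <- tr$end[-nrow(tr)][grp[-nrow(tr)] == grp[-1]]
  g2 <- paste(tr$sample, tr$chrom, sep = "\r")[-nrow(tr)][grp[-nrow(tr)] == grp[-1]]
  sw <- split(interior, g2)
  sw <- lapply(sw, function(v) sort(unique(v)))
  key <- paste(roh$sample1, roh$chrom, sep = "\r")
  n_sw <- vapply(seq_len(nrow(roh)), function(i) {
    J <- sw[[key[i]]]
    if (is.null(J)) return(0L)
    # strictly inside: start < position < end
    findInterval(roh$end[i] - 0.5, J) - findInterval(roh$start[i] + 0.5, J)
  }, integer(1))
  roh$n_switches <- n_sw
  roh$switches_per_mb <- n_sw / ((roh$end - roh$start) / 1e6)
  by_class <- do.call(rbind, lapply(split(roh, roh$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d),
               frac_with_switch = mean(d$n_switches > 0),
               mean_per_mb = mean(d$switches_per_mb),
               sd_per_mb = sd(d$switches_per_mb),
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  class_test <- NULL
  cls <- sort(unique(roh$class))
  if (length(cls) >= 2) {
    cmb <- utils::combn(cls, 2)
    class_test <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- roh$switches_per_mb[roh$class == cmb[1, j]]
      b <- roh$switches_per_mb[roh$class == cmb[2, j]]
      wt <- mann_whitney_u(a, b)
      data.frame(class1 = cmb[1, j], class2 = cmb[2, j], U = wt$statistic,
                 p = wt$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(per_segment = roh, by_class = by_class, class_test = class_test)
}
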
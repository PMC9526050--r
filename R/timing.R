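# Admixture dating from the decay of local ancestry disequilibrium (LAD).
#
# The model couples mean ancestry H_t and the within-haplotype two-locus
# ancestry association D_t under constant migration m (split between the two
# sources in proportion H0 so mean ancestry stays stationary), assortative
# mating strength rho, and recombination fraction c. The cross-homolog
# ancestry coupling is approximated as rho * D_t, which is exact in both
# limits (rho = 0: random-mating decay (1-c)^g; rho = 1: no decay) and is
# validated against the forward simulator rather than assumed.

#' Expected LAD after g post-founding generations
#'
#' Runs the coupled recursion with migrant inflow `m1 = m * h0` from source 1
#' and `m2 = m * (1 - h0)` from source 2 (resident fraction `h = 1 - m`):
#' \deqn{H_{t+1} = m_1 + h H_t}
#' \deqn{E[Z_1 Z_2]_{t+1} = m_1 + h (H_t^2 + D_t (1 - c (1 - \rho)))}
#' \deqn{D_{t+1} = E[Z_1 Z_2]_{t+1} - H_{t+1}^2}
#' initialized at the founding state \eqn{H_0 = h_0},
#' \eqn{D_0 = h_0 (1 - h_0)} (intact migrant haplotypes, LAD = 1), and
#' returns the correlation-scale value
#' \eqn{D_g / (H_g (1 - H_g))}. With `m = 0` this reduces exactly to the
#' closed form \eqn{(1 - c (1 - \rho))^g}.
#'
#' `g` counts post-founding meiosis rounds: the founding cohort itself (g =
#' 0) has LAD 1.
#'
#' @param c recombination fraction(s) between the two loci, in `(0, 0.5]`.
#' @param g generations since founding (>= 1).
#' @param rho assortative-mating strength in `[0, 1]`.
#' @param m migration rate per generation in `[0, 1)`.
#' @param h0 founding S1 ancestry proportion in `(0, 1)`.
#' @return expected LAD correlation, vectorized over `c`.
#' @export
#' @examples
#' expected_lad(c = 0.1, g = 10, rho = 0, m = 0) # 0.9^10
expected_lad <- function(c, g, rho, m = 0, h0 = 0.65) {
  if (any(c <= 0) || any(c > 0.5)) stop("c must lie in (0, 0.5]")
  if (g < 1 || g != round(g)) stop("g must be a positive integer")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (m < 0 || m >= 1) stop("m must lie in [0, 1)")
  if (h0 <= 0 || h0 >= 1) stop("h0 must lie in (0, 1)")
  m1 <- m * h0
  h <- 1 - m
  H <- h0
  D <- rep(h0 * (1 - h0), length(c))
  fac <- 1 - c * (1 - rho)
  for (t in seq_len(g)) {
    Hn <- m1 + h * H
    Ez <- m1 + h * (H^2 + D * fac)
    D <- Ez - Hn^2
    H <- Hn
  }
  D / (H * (1 - H))
}

#' Fit the number of admixture generations to windowed LAD
#'
#' Integer grid fit: for each g on the grid, the sum of squared differences
#' between observed per-window LAD and [expected_lad()] at the window's
#' recombination fraction (Haldane map function,
#' `c = (1 - exp(-2 d)) / 2` with d in Morgans) is computed; the best g
#' minimizes the SSE, ties broken toward smaller g. A warning is issued when
#' the best g sits on the grid boundary. Note the fitted g counts
#' post-founding meiosis rounds (see [expected_lad()]), so a population
#' founded G generations ago is expected to fit near G - 1.
#'
#' @param lad a window table from [lad_windows()] (columns `lad_corr` and
#'   `dist_cm`), or a numeric vector of LAD values with `dist_cm` supplied.
#' @param rho,m,h0 model parameters assumed during the fit.
#' @param g_min,g_max integer grid bounds (defaults 5 and 25).
#' @param dist_cm genetic distances (cM) when `lad` is a plain vector.
#' @param n_boot optional number of bootstrap resamples over windows for a
#'   percentile interval on the best g (0 = none). Uses the current RNG.
#' @return a `timing_fit` list: `grid` (g, SSE), `best_g`, `settings`, and
#'   optionally `boot_ci`.
#' @export
fit_generations <- function(lad, rho = 0, m = 0, h0 = 0.65,
                            g_min = 5, g_max = 25, dist_cm = NULL,
                            n_boot = 0) {
  if (is.data.frame(lad)) {
    stop_if_not_cols(lad, c("lad_corr", "dist_cm"), "LAD window table")
    vals <- lad$lad_corr
    dist_cm <- lad$dist_cm
  } else {
    vals <- as.numeric(lad)
    if (is.null(dist_cm)) stop("dist_cm is required when lad is a vector")
  }
  if (!length(vals)) stop("empty window set")
  if (length(dist_cm) != length(vals)) stop("lad and dist_cm lengths differ")
  d <- dist_cm / 100                      # Morgans
  cfrac <- (1 - exp(-2 * d)) / 2          # Haldane, no interference
  gs <- seq.int(g_min, g_max)
  # which.min takes the first minimum, so ties break toward smaller g
  sse <- vapply(gs, function(g) {
    sum((vals - expected_lad(cfrac, g, rho, m, h0))^2)
  }, numeric(1))
  best <- gs[which.min(sse)]
  if (best %in% c(g_min, g_max)) {
    warning(sprintf("best g = %d sits on the grid boundary [%d, %d]",
                    best, g_min, g_max))
  }
  out <- list(grid = data.frame(g = gs, sse = sse), best_g = best,
              settings = list(rho = rho, m = m, h0 = h0,
                              g_min = g_min, g_max = g_max,
                              n_windows = length(vals)))
  if (n_boot > 0) {
    bg <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(length(vals), replace = TRUE)
      sseb <- vapply(gs, function(g) {
        sum((vals[j] - expected_lad(cfrac[j], g, rho, m, h0))^2)
      }, numeric(1))
      gs[which.min(sseb)]
    }, numeric(1))
    out$boot_ci <- unname(quantile(bg, c(0.025, 0.975)))
  }
  class(out) <- "timing_fit"
  out
}

#' @export
print.timing_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "LAD timing fit: best g = %d (grid %d..%d; rho = %.3g, m = %.3g, h0 = %.3g, %d windows)\n",
    x$best_g, s$g_min, s$g_max, s$rho, s$m, s$h0, s$n_windows))
  if (!is.null(x$boot_ci)) {
    cat(sprintf("  bootstrap 95%% interval over windows: [%g, %g]\n",
                x$boot_ci[1], x$boot_ci[2]))
  }
  invisible(x)
}

#' Monte-Carlo reference LAD curve from the forward simulator
#'
#' Validation engine for [expected_lad()]: simulates `reps` independent
#' populations with matched parameters (`g` post-founding generations, i.e.
#' `G = g + 1` cohorts; migration `m` split `m * h0` / `m * (1 - h0)`
#' between the sources for both sexes) and returns the per-window mean LAD
#' with its Monte-Carlo standard error.
#'
#' @inheritParams expected_lad
#' @param map a [genetic_map()].
#' @param N diploid population size per generation.
#' @param reps replicate count (>= 5).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param ... passed to [lad_windows()].
#' @return list with the window table of the first replicate's layout
#'   (`windows`: mean and SE of `lad_corr` across replicates) and
#'   `mean_lad` / `se_mean_lad` of the per-replicate mean.
#' @export
simulate_lad_reference <- function(g, rho = 0, m = 0, h0 = 0.65, map,
                                   N = 1000, reps = 20, seed = 1, ...) {
  if (reps < 5) stop("reps must be >= 5")
  G <- as.integer(g) + 1L
  # founding row carries the h0 split; later rows the migration inflow
  sch <- contribution_schedule(G,
                               s1f = c(h0, rep(m * h0, G - 1L)),
                               s1m = c(h0, rep(m * h0, G - 1L)),
                               s2f = c(1 - h0, rep(m * (1 - h0), G - 1L)),
                               s2m = c(1 - h0, rep(m * (1 - h0), G - 1L)))
  per_rep <- vector("list", reps)
  means <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_admixture(sim_config(map, G = G, N = N, schedule = sch,
                                         rho = rho, seed = seed + r))
    lw <- lad_windows(sim$tracts, map, ...)
    per_rep[[r]] <- lw$lad_corr
    means[r] <- mean(lw$lad_corr)
    if (r == 1) layout <- lw[, c("chrom", "anchor1_bp", "anchor2_bp", "dist_cm")]
  }
  nw <- min(lengths(per_rep))
  mat <- vapply(per_rep, function(v) v[seq_len(nw)], numeric(nw))
  layout <- layout[seq_len(nw), , drop = FALSE]
  layout$lad_mean <- rowMeans(mat)
  layout$lad_se <- apply(mat, 1, sd) / sqrt(reps)
  list(windows = layout, mean_lad = mean(means),
       se_mean_lad = sd(means) / sqrt(reps))
}

#' Convert admixture generations to calendar years
#'
#' Uses the conventional 20-30 year range of human generation times with a
#' 25-year point estimate.
#'
#' @param g generations (>= 0).
#' @param anchor_year calendar year of the sampled generation.
#' @return list with `point` (25-year generation time) and `interval`
#'   (earliest = 30-year, latest = 20-year generation time).
#' @export
#' @examples
#' generations_to_years(10, anchor_year = 2010) # point 1760, [1710, 1810]
generations_to_years <- function(g, anchor_year) {
  if (any(g < 0)) stop("g must be non-negative")
  list(point = anchor_year - 25 * g,
       interval = c(anchor_year - 30 * g, anchor_year - 20 * g))
}
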
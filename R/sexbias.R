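# Constant-admixture expectations for autosomal and X-chromosome ancestry
# under sex-specific source contributions, and the grid search that inverts
# them from observed ancestry.

#' Expected autosomal and X ancestry under constant sex-specific admixture
#'
#' Recursions with hybrid fractions `hf = 1 - s1f - s2f`,
#' `hm = 1 - s1m - s2m`:
#' autosomes \eqn{H_g = \frac12 (s1f + hf H_{g-1}) + \frac12 (s1m + hm H_{g-1})};
#' X in females
#' \eqn{HXf_g = \frac12 (s1f + hf\, HXf_{g-1}) + \frac12 (s1m + hm\, HXm_{g-1})};
#' X in males \eqn{HXm_g = s1f + hf\, HXf_{g-1}} (sons draw their X from
#' mothers only). The founding generation (g = 1) uses the source-only
#' splits `s1f/(s1f+s2f)` and `s1m/(s1m+s2m)`. The pooled X value weights
#' X-chromosome dosage: `(2 pf HXf_G + (1 - pf) HXm_G) / (1 + pf)` with `pf`
#' the proportion of females in the sample.
#'
#' All arguments are vectorized over parameter sets.
#'
#' @param s1f,s1m,s2f,s2m per-generation contribution fractions (mothers /
#'   fathers from source 1 / source 2); `s1f + s2f <= 1`, `s1m + s2m <= 1`,
#'   and each sex needs a positive source contribution at founding.
#' @param G number of generations (g = 1 is the founding generation).
#' @param pf proportion of females in the sample (default 0.5).
#' @return list with `H_auto`, `H_X` (pooled), `H_Xf`, `H_Xm`.
#' @export
#' @examples
#' # all mothers source 1, all fathers source 2, one generation:
#' expected_hx_ha(1, 0, 0, 1, G = 1, pf = 0.5) # H_auto 0.5, H_X 2/3
expected_hx_ha <- function(s1f, s1m, s2f, s2m, G, pf = 0.5) {
  n <- max(length(s1f), length(s1m), length(s2f), length(s2m))
  s1f <- rep_len(s1f, n); s1m <- rep_len(s1m, n)
  s2f <- rep_len(s2f, n); s2m <- rep_len(s2m, n)
  if (G < 1 || G != round(G)) stop("G must be a positive integer")
  hf <- 1 - s1f - s2f
  hm <- 1 - s1m - s2m
  if (any(hf < -1e-12) || any(hm < -1e-12)) {
    stop("negative hybrid fraction: contributions exceed 1")
  }
  denf <- s1f + s2f
  denm <- s1m + s2m
  if (any(denf <= 0) || any(denm <= 0)) {
    stop("founding requires positive source contributions for each sex")
  }
  H <- (s1f / denf + s1m / denm) / 2
  HXf <- H
  HXm <- s1f / denf
  if (G > 1) {
    for (g in 2:G) {
      Hn <- 0.5 * (s1f + hf * H) + 0.5 * (s1m + hm * H)
      HXfn <- 0.5 * (s1f + hf * HXf) + 0.5 * (s1m + hm * HXm)
      HXmn <- s1f + hf * HXf
      H <- Hn; HXf <- HXfn; HXm <- HXmn
    }
  }
  list(H_auto = H, H_X = (2 * pf * HXf + (1 - pf) * HXm) / (1 + pf),
       H_Xf = HXf, H_Xm = HXm)
}

#' Precompute the sex-bias expectation lattice
#'
#' Enumerates every feasible `(s1f, s1m, s2f, s2m)` on the increment lattice
#' (sums per sex at most 1 and positive, so founding is defined) and runs
#' [expected_hx_ha()] once. Reusable across observations with the same `G`
#' and increment, which is how replicate grid searches stay cheap.
#'
#' @param G generations of constant admixture.
#' @param increment lattice spacing (default 0.02).
#' @return data frame of parameter sets with `H_auto`, `H_Xf`, `H_Xm`.
#' @export
sexbias_expect_grid <- function(G, increment = 0.02) {
  v <- seq(0, 1, by = increment)
  fem <- expand.grid(s1f = v, s2f = v)
  fem <- fem[fem$s1f + fem$s2f <= 1 + 1e-9 & fem$s1f + fem$s2f > 0, ]
  mal <- expand.grid(s1m = v, s2m = v)
  mal <- mal[mal$s1m + mal$s2m <= 1 + 1e-9 & mal$s1m + mal$s2m > 0, ]
  grid <- cbind(fem[rep(seq_len(nrow(fem)), times = nrow(mal)), ],
                mal[rep(seq_len(nrow(mal)), each = nrow(fem)), ])
  rownames(grid) <- NULL
  ex <- expected_hx_ha(grid$s1f, grid$s1m, grid$s2f, grid$s2m, G = G, pf = 0.5)
  grid$H_auto <- ex$H_auto
  grid$H_Xf <- ex$H_Xf
  grid$H_Xm <- ex$H_Xm
  grid
}

#' Grid search for sex-specific contributions
#'
#' Compares observed autosomal and pooled-X S1 ancestry with the
#' constant-admixture expectations over the full constrained lattice and
#' retains the parameter sets with the smallest Euclidean distances
#' \eqn{\sqrt{(H_{auto}-obs_{auto})^2 + (H_X-obs_X)^2}}. The retained count
#' is `ceiling(keep * lattice size)`; ties at the cutoff break by
#' lexicographic parameter order, so results are deterministic. Female
#' fractions `f1 = s1f/(s1f+s1m)` and `f2 = s2f/(s2f+s2m)` summarize the
#' retained sets (sets with undefined fractions are excluded from the
#' medians).
#'
#' @param obs_auto,obs_x observed mean S1 ancestry on autosomes and X
#'   (pooled over sexes with X dosage), both in (0, 1).
#' @param pf proportion of females among sampled individuals.
#' @param G generations of constant admixture (default 20).
#' @param increment lattice spacing (default 0.02).
#' @param keep retained fraction of the feasible lattice (default 0.001,
#'   i.e. the 0.1% closest parameter sets).
#' @param grid optional precomputed [sexbias_expect_grid()] for this `G` and
#'   `increment`.
#' @return a `sexbias_grid` list: `retained` (parameter sets, distances,
#'   `f1`, `f2`), `median_f1`, `median_f2`, `settings`.
#' @export
sexbias_grid <- function(obs_auto, obs_x, pf = 0.5, G = 20, increment = 0.02,
                         keep = 0.001, grid = NULL) {
  if (obs_auto <= 0 || obs_auto >= 1 || obs_x <= 0 || obs_x >= 1) {
    stop("observed ancestries must lie in (0, 1)")
  }
  if (is.null(grid)) grid <- sexbias_expect_grid(G, increment)
  hx <- (2 * pf * grid$H_Xf + (1 - pf) * grid$H_Xm) / (1 + pf)
  dist <- sqrt((grid$H_auto - obs_auto)^2 + (hx - obs_x)^2)
  n_keep <- ceiling(keep * nrow(grid))
  ord <- order(dist, grid$s1f, grid$s1m, grid$s2f, grid$s2m)
  sel <- ord[seq_len(n_keep)]
  ret <- grid[sel, c("s1f", "s1m", "s2f", "s2m")]
  ret$H_auto <- grid$H_auto[sel]
  ret$H_X <- hx[sel]
  ret$dist <- dist[sel]
  ret$f1 <- female_fraction(ret$s1f, ret$s1m)
  ret$f2 <- female_fraction(ret$s2f, ret$s2m)
  rownames(ret) <- NULL
  structure(list(retained = ret,
                 median_f1 = median(ret$f1, na.rm = TRUE),
                 median_f2 = median(ret$f2, na.rm = TRUE),
                 settings = list(obs_auto = obs_auto, obs_x = obs_x, pf = pf,
                                 G = G, increment = increment, keep = keep,
                                 n_grid = nrow(grid), n_keep = n_keep)),
            class = "sexbias_grid")
}

#' @export
print.sexbias_grid <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "sex-bias grid: kept %d / %d parameter sets (%.2g%%); median f1 = %.3f, median f2 = %.3f\n",
    s$n_keep, s$n_grid, 100 * s$keep, x$median_f1, x$median_f2))
  cat(sprintf("  observed H_auto = %.4f, H_X = %.4f, pf = %.3f, G = %d\n",
              s$obs_auto, s$obs_x, s$pf, s$G))
  invisible(x)
}

#' Female fraction of a source's total contribution
#'
#' `f = s_f / (s_f + s_m)`: the fraction of a source population's genetic
#' contribution that entered through females. Undefined (NA) when both
#' contributions are zero; such sets are excluded from summaries.
#'
#' @param s_f,s_m female and male contribution fractions of one source.
#' @return numeric vector in `[0, 1]` (NA where undefined).
#' @export
#' @examples
#' female_fraction(0.2, 0.1) # 2/3
female_fraction <- function(s_f, s_m) {
  tot <- s_f + s_m
  out <- ifelse(tot > 0, s_f / tot, NA_real_)
  out
}
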
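# Forward-in-time simulator of a two-source admixed population.
#
# Internal haplotype representation ("pool", one per chromosome): ragged
# arrays ends/keys with 0-based offsets `off` (length n_hap + 1). Individual
# i owns haplotype rows 2i-1 and 2i (1-based); on the X, males carry rows
# 2i-1 only (row 2i is empty). Every founder haplotype gets a unique integer
# key; ancestry of a segment is the source of its founder.

#' Per-generation sex-specific source contributions
#'
#' Builds the contribution schedule of the constant-admixture model: each
#' generation, a fraction `s1f` of mothers are new source-1 migrant females,
#' `s2f` new source-2 migrant females, and the rest (`hf = 1 - s1f - s2f`)
#' resident females of the previous generation; `s1m`, `s2m`, `hm` likewise
#' for fathers. Arguments are recycled to length `G`, so scalars give a
#' constant schedule.
#'
#' The founding generation (t = 1) is built from sources only: its row is
#' renormalized to the source-only splits `s1f/(s1f+s2f)` and
#' `s1m/(s1m+s2m)`.
#'
#' @param G number of generations (the founding generation is t = 1).
#' @param s1f,s1m,s2f,s2m contribution fractions in `[0,1]`, recycled to
#'   length `G`; per generation `s1f + s2f <= 1` and `s1m + s2m <= 1`.
#' @return a `contribution_schedule` data frame with columns `s1f`, `s1m`,
#'   `s2f`, `s2m`, `hf`, `hm`.
#' @export
#' @examples
#' contribution_schedule(20, s1f = 0.1, s1m = 0, s2f = 0, s2m = 0.05)
contribution_schedule <- function(G, s1f, s1m, s2f, s2m) {
  G <- as.integer(G)
  if (G < 1) stop("G must be >= 1")
  s1f <- rep_len(s1f, G); s1m <- rep_len(s1m, G)
  s2f <- rep_len(s2f, G); s2m <- rep_len(s2m, G)
  all_s <- c(s1f, s1m, s2f, s2m)
  if (any(all_s < 0) || any(all_s > 1)) stop("contributions must lie in [0,1]")
  if (s1f[1] + s2f[1] <= 0 || s1m[1] + s2m[1] <= 0) {
    stop("founding generation needs source contributions for both sexes")
  }
  # founding generation has no hybrids: renormalize row 1 to source-only splits
  fsum <- s1f[1] + s2f[1]
  s1f[1] <- s1f[1] / fsum; s2f[1] <- s2f[1] / fsum
  msum <- s1m[1] + s2m[1]
  s1m[1] <- s1m[1] / msum; s2m[1] <- s2m[1] / msum
  if (any(s1f + s2f > 1 + 1e-12) || any(s1m + s2m > 1 + 1e-12)) {
    stop("infeasible schedule: s1 + s2 exceeds 1 (negative hybrid fraction)")
  }
  out <- data.frame(s1f = s1f, s1m = s1m, s2f = s2f, s2m = s2m,
                    hf = pmax(0, 1 - s1f - s2f), hm = pmax(0, 1 - s1m - s2m))
  class(out) <- c("contribution_schedule", "data.frame")
  out
}

#' Configuration for the forward simulator
#'
#' @param map a [genetic_map()] (autosomes, optionally one X).
#' @param G generations to simulate; generation 1 is the founding cohort,
#'   built entirely from source migrants (so `G` cohorts involve `G - 1`
#'   post-founding meiosis rounds).
#' @param N diploid population size per generation; a scalar or a length-`G`
#'   vector (e.g. a founding bottleneck `c(10, 300, 300, ...)`).
#' @param schedule a [contribution_schedule()]; the default mirrors a
#'   female-biased source-1 / male-biased source-2 constant inflow.
#' @param rho target spousal correlation of genome-wide (autosomal,
#'   cM-weighted) S1 ancestry, in `[0, 1)`; see [mate_assortative()].
#' @param sex_ratio probability an offspring is female (default 0.5).
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   outputs.
#' @param population population label attached to emitted samples.
#' @param sample_n optionally emit only this many individuals (sampled
#'   without replacement) from the final generation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(map, G = 20, N = 500,
                       schedule = contribution_schedule(G, 0.10, 0, 0, 0.05),
                       rho = 0, sex_ratio = 0.5, seed, population = "pop1",
                       sample_n = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(map, "genetic_map"))
  G <- as.integer(G)
  if (G < 1) stop("G must be >= 1")
  N <- rep_len(as.integer(N), G)
  if (any(N < 4)) stop("N too small for pairing (need N >= 4)")
  if (max(N) < 20) stop("population too small (need max N >= 20)")
  if (!inherits(schedule, "contribution_schedule") || nrow(schedule) != G) {
    stop("schedule must be a contribution_schedule with G rows")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (!is.null(sample_n)) sample_n <- as.integer(sample_n)
  structure(list(map = map, G = G, N = N, schedule = schedule, rho = rho,
                 sex_ratio = sex_ratio, seed = as.integer(seed),
                 population = population, sample_n = sample_n),
            class = "sim_config")
}

#' Assortative pairing of parent pools by ancestry rank matching
#'
#' Forms monogamous pairs whose realized Pearson correlation of spousal
#' ancestries approximates `rho`. Ranks of each pool's ancestries are
#' perturbed with Gaussian noise and pairs are formed by matching sorted
#' noisy ranks; the noise scale is calibrated by bisection so the realized
#' correlation lands within about `tol` of `rho` (guaranteed only for pools
#' of 500+ with ancestry variance above 0.005). `rho = 0` is plain random
#' pairing. Uses the current RNG state.
#'
#' @param maternal,paternal equal-length numeric vectors of genome-wide S1
#'   ancestries of the two parent pools.
#' @param rho target spousal ancestry correlation in `[0, 1)`.
#' @param tol calibration tolerance on the realized correlation.
#' @param max_iter bisection iterations.
#' @return list with `pairing` (index into `paternal` for each mother),
#'   `realized_r` (NA when either pool is degenerate) and `sigma` (noise
#'   scale used).
#' @export
mate_assortative <- function(maternal, paternal, rho, tol = 0.05,
                             max_iter = 25) {
  n <- length(maternal)
  if (n == 0 || length(paternal) != n) {
    stop("parent pools must be non-empty and of equal length")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  vm <- if (n > 1) var(maternal) else 0
  vf <- if (n > 1) var(paternal) else 0
  if (rho == 0 || n < 4 || vm == 0 || vf == 0) {
    perm <- sample.int(n)
    r <- if (n > 2 && vm > 0 && vf > 0) cor(maternal, paternal[perm]) else NA_real_
    return(list(pairing = perm, realized_r = r, sigma = Inf))
  }
  pair_at <- function(sigma) {
    sm <- rank(maternal, ties.method = "first") + rnorm(n, 0, sigma * n)
    sf <- rank(paternal, ties.method = "first") + rnorm(n, 0, sigma * n)
    perm <- integer(n)
    perm[order(sm)] <- order(sf)
    perm
  }
  eval_at <- function(sigma) {
    perm <- pair_at(sigma)
    list(perm = perm, r = cor(maternal, paternal[perm]))
  }
  lo <- 0; hi <- 4
  best <- eval_at(0); best_sig <- 0
  if (best$r <= rho) {                      # even perfect matching undershoots
    return(list(pairing = best$perm, realized_r = best$r, sigma = 0))
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cand <- eval_at(mid)
    if (abs(cand$r - rho) < abs(best$r - rho)) {
      best <- cand; best_sig <- mid
    }
    if (abs(best$r - rho) <= tol / 2) break
    if (cand$r > rho) lo <- mid else hi <- mid
  }
  list(pairing = best$perm, realized_r = best$r, sigma = best_sig)
}

#' Single meiosis on one chromosome
#'
#' Crossover count is Poisson in the chromosome's genetic length (Morgans),
#' positions uniform in genetic distance, alternating parental origin from a
#' fair random start; no interference. Founder segments are cut consistently.
#' A `NULL` second haplotype (male X) is transmitted intact.
#'
#' @param hap0,hap1 parental haplotypes as data frames with columns `end`
#'   (increasing, last equal to `length_bp`) and `key` (integer founder key);
#'   segment i covers `[previous end, end)`. `hap1 = NULL` copies `hap0`.
#' @param length_bp chromosome physical length.
#' @param cm_per_mb constant recombination rate.
#' @return gamete data frame (`start`, `end`, `key`) with attribute
#'   `"crossovers"`.
#' @export
meiosis_gamete <- function(hap0, hap1 = NULL, length_bp, cm_per_mb = 1) {
  check_hap <- function(h) {
    stop_if_not_cols(h, c("end", "key"), "haplotype")
    if (is.unsorted(h$end, strictly = TRUE) ||
        h$end[length(h$end)] != length_bp) {
      stop("haplotype must tile [0, length_bp) with increasing ends")
    }
  }
  check_hap(hap0)
  if (!is.null(hap1)) check_hap(hap1)
  ends <- c(hap0$end, if (!is.null(hap1)) hap1$end)
  keys <- c(hap0$key, if (!is.null(hap1)) hap1$key)
  off <- as.integer(cumsum(c(0L, nrow(hap0), if (!is.null(hap1)) nrow(hap1))))
  res <- gamete_batch_cpp(as.integer(ends), as.integer(keys), off,
                          hapA = 0L,
                          hapB = if (is.null(hap1)) -1L else 1L,
                          length_bp = length_bp,
                          morgans = length_bp * cm_per_mb / 1e8)
  out <- data.frame(start = c(0L, res$ends[-length(res$ends)]),
                    end = res$ends, key = res$keys)
  attr(out, "crossovers") <- res$nxo[1]
  out
}

# categorical draw per slot: 1 = S1 migrant, 2 = S2 migrant, 0 = resident
draw_types <- function(n, p1, p2) {
  u <- runif(n)
  ifelse(u < p1, 1L, ifelse(u < p1 + p2, 2L, 0L))
}

empty_pool <- function() list(ends = integer(0), keys = integer(0), off = 0L)

# interleave maternal gametes (one per individual) and paternal gametes
# (given for individuals `pat_for`, in that order) into a 2-slot-per-
# individual pool
interleave_pool <- function(matP, patP, pat_for, N) {
  lenA <- diff(matP$off)
  len1 <- integer(N)
  lB <- integer(0)
  if (length(pat_for)) {
    lB <- diff(patP$off)
    len1[pat_for] <- lB
  }
  lens <- as.integer(rbind(lenA, len1))
  off <- c(0L, cumsum(lens))
  total <- off[length(off)]
  ends <- integer(total); keys <- integer(total)
  destA <- rep.int(off[seq.int(1L, 2L * N, by = 2L)], lenA) + sequence(lenA)
  ends[destA] <- matP$ends; keys[destA] <- matP$keys
  if (length(pat_for)) {
    destB <- rep.int(off[2L * pat_for], lB) + sequence(lB)
    ends[destB] <- patP$ends; keys[destB] <- patP$keys
  }
  list(ends = ends, keys = keys, off = as.integer(off))
}

# summed bp per individual over segments satisfying `mask` (NULL = all)
pool_bp_by_ind <- function(pool, n_ind, mask = NULL) {
  lens <- diff(pool$off)
  out <- numeric(n_ind)
  if (!length(pool$ends)) return(out)
  ends <- pool$ends
  starts <- c(0L, ends[-length(ends)])
  first <- pool$off[-length(pool$off)][lens > 0L] + 1L
  starts[first] <- 0L
  seglen <- as.numeric(ends - starts)
  nh <- length(lens)
  ind <- (rep.int(seq_len(nh), lens) + 1L) %/% 2L
  if (!is.null(mask)) {
    seglen <- seglen[mask]; ind <- ind[mask]
  }
  if (length(ind)) {
    add <- rowsum(seglen, ind)
    out[as.integer(rownames(add))] <- add[, 1]
  }
  out
}

#' Simulate an admixed population forward in time
#'
#' Runs `G` non-overlapping generations. To produce generation t, `N[t] %/% 2`
#' couples are formed: each mother slot is a new source-1 migrant female with
#' probability `s1f[t]`, a new source-2 migrant female with probability
#' `s2f[t]`, and otherwise a resident female drawn uniformly with replacement
#' from generation t-1 (fathers likewise with `s1m`, `s2m`). Migrants carry
#' fresh founder keys and single-ancestry haplotypes and enter the pool
#' before assortative pairing, so strong `rho` preferentially pairs
#' same-source migrants. Pairs are formed by [mate_assortative()]; offspring
#' are assigned to couples uniformly (multinomial family sizes) and receive
#' one recombinant gamete per parent per autosome. On the X, sons receive a
#' recombinant maternal X only; daughters receive a recombinant maternal X
#' and the father's X intact.
#'
#' @param config a [sim_config()].
#' @return an `admix_sim` list: `tracts` (local-ancestry tract table for the
#'   final generation), `samples` (metadata), `founder_segments`
#'   (per-haplotype founder-segment tiling, the ground truth for ROH/IBD),
#'   and `truth` with the pedigree of the final generation (`parents`),
#'   spousal pairs with true ancestries for every generation (`pairs`),
#'   founder sources (`founders`), per-individual true autosomal and X
#'   ancestry (`ancestry`) and the realized spousal correlation per
#'   generation (`realized_rho`).
#' @export
#' @examples
#' map <- example_map(scale = 0.05)
#' sim <- simulate_admixture(sim_config(map, G = 3, N = 30, seed = 1))
#' head(sim$tracts)
simulate_admixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- config$map
  set.seed(config$seed)
  nchr <- nrow(map)
  Lbp <- as.integer(map$length_bp)
  morg <- map$length_bp * map$cm_per_mb / 1e8
  isX <- map$is_X
  auto_idx <- which(!isX)
  x_idx <- which(isX)
  auto_cm <- sum(map$length_cM[!isX])
  rate_cm <- map$cm_per_mb / 1e6      # cM per bp
  G <- config$G
  sched <- config$schedule

  founder_src <- integer(0)
  cur <- NULL
  pairs_list <- vector("list", G)
  realized_rho <- rep(NA_real_, G)

  for (t in seq_len(G)) {
    Nt <- config$N[t]
    Ct <- max(2L, Nt %/% 2L)
    s1f <- sched$s1f[t]; s2f <- sched$s2f[t]
    s1m <- sched$s1m[t]; s2m <- sched$s2m[t]

    mtype <- draw_types(Ct, s1f, s2f)
    ftype <- draw_types(Ct, s1m, s2m)
    if (t == 1L && (any(mtype == 0L) || any(ftype == 0L))) {
      # schedule row 1 is source-only by construction; guard anyway
      stop("founding generation must be built from source migrants only")
    }
    res_m <- which(mtype == 0L)
    res_f <- which(ftype == 0L)
    mig_m <- which(mtype != 0L)
    mig_f <- which(ftype != 0L)
    Mprev <- if (t == 1L) 0L else cur$n

    # resident draws (uniform with replacement, by sex)
    m_res_idx <- f_res_idx <- integer(0)
    if (length(res_m)) {
      fem <- which(cur$sex == "F")
      if (!length(fem)) stop("no resident females available for mating")
      m_res_idx <- sample(fem, length(res_m), replace = TRUE)
    }
    if (length(res_f)) {
      mal <- which(cur$sex == "M")
      if (!length(mal)) stop("no resident males available for mating")
      f_res_idx <- sample(mal, length(res_f), replace = TRUE)
    }

    # fresh founder keys: two per migrant (one per haplotype), mothers first
    nmigM <- length(mig_m); nmigF <- length(mig_f)
    k0 <- length(founder_src)
    founder_src <- c(founder_src,
                     rep(mtype[mig_m], each = 2L),
                     rep(ftype[mig_f], each = 2L))

    # slot-level entity rows in the extended pool (1-based haplotype rows)
    m_ent <- integer(Ct); f_ent <- integer(Ct)
    m_ent[res_m] <- m_res_idx
    m_ent[mig_m] <- Mprev + seq_len(nmigM)
    f_ent[res_f] <- f_res_idx
    f_ent[mig_f] <- Mprev + nmigM + seq_len(nmigF)

    # true ancestries of the parent slots (autosomal, cM-weighted)
    m_anc <- numeric(Ct); f_anc <- numeric(Ct)
    m_ancx <- numeric(Ct); f_ancx <- numeric(Ct)
    if (length(res_m)) {
      m_anc[res_m] <- cur$anc[m_res_idx]
      m_ancx[res_m] <- cur$ancx[m_res_idx]
    }
    if (length(res_f)) {
      f_anc[res_f] <- cur$anc[f_res_idx]
      f_ancx[res_f] <- cur$ancx[f_res_idx]
    }
    m_anc[mig_m] <- m_ancx[mig_m] <- as.numeric(mtype[mig_m] == 1L)
    f_anc[mig_f] <- f_ancx[mig_f] <- as.numeric(ftype[mig_f] == 1L)

    m_id <- character(Ct); f_id <- character(Ct)
    if (length(res_m)) m_id[res_m] <- cur$ids[m_res_idx]
    if (length(res_f)) f_id[res_f] <- cur$ids[f_res_idx]
    m_id[mig_m] <- sprintf("G%02d_MF%03d", t, seq_len(nmigM))
    f_id[mig_f] <- sprintf("G%02d_MM%03d", t, seq_len(nmigF))

    # assortative pairing: permute father slots
    pairing <- mate_assortative(m_anc, f_anc, config$rho)
    perm <- pairing$pairing
    realized_rho[t] <- pairing$realized_r
    f_ent <- f_ent[perm]; f_anc <- f_anc[perm]
    f_ancx <- f_ancx[perm]; f_id <- f_id[perm]
    pairs_list[[t]] <- data.frame(
      gen = t, couple = seq_len(Ct), mother = m_id, father = f_id,
      mother_anc = m_anc, father_anc = f_anc, stringsAsFactors = FALSE)

    # offspring
    cid <- sample.int(Ct, Nt, replace = TRUE)
    sexF <- runif(Nt) < config$sex_ratio
    sex_new <- ifelse(sexF, "F", "M")
    ids_new <- sprintf("G%02d_I%04d", t, seq_len(Nt))
    daughters <- which(sexF)

    new_pools <- vector("list", nchr)
    for (cc in seq_len(nchr)) {
      pool <- if (t == 1L) empty_pool() else cur$pools[[cc]]
      # append migrant haplotypes (mothers, then fathers)
      nmig <- nmigM + nmigF
      if (nmig > 0L) {
        mig_keys0 <- k0 + 2L * (seq_len(nmig) - 1L) + 1L
        mig_keys1 <- mig_keys0 + 1L
        male_mig <- c(rep(FALSE, nmigM), rep(TRUE, nmigF))
        # on the X, male migrants carry haplotype 0 only
        hap1_len <- if (isX[cc]) as.integer(!male_mig) else rep(1L, nmig)
        lens_add <- as.integer(rbind(1L, hap1_len))
        ends_add <- integer(sum(lens_add))
        keys_add <- integer(sum(lens_add))
        pos <- cumsum(lens_add)
        h0_at <- pos - lens_add + 1L
        h0_rows <- seq.int(1L, 2L * nmig, by = 2L)
        ends_add[h0_at[h0_rows]] <- Lbp[cc]
        keys_add[h0_at[h0_rows]] <- mig_keys0
        has1 <- which(hap1_len == 1L)
        if (length(has1)) {
          ends_add[pos[2L * has1]] <- Lbp[cc]
          keys_add[pos[2L * has1]] <- mig_keys1[has1]
        }
        base <- pool$off[length(pool$off)]
        pool <- list(ends = c(pool$ends, ends_add),
                     keys = c(pool$keys, keys_add),
                     off = c(pool$off, base + cumsum(lens_add)))
      }
      # maternal gametes for all offspring
      mo <- m_ent[cid]
      mat <- gamete_batch_cpp(pool$ends, pool$keys, as.integer(pool$off),
                              hapA = 2L * mo - 2L, hapB = 2L * mo - 1L,
                              length_bp = Lbp[cc], morgans = morg[cc])
      if (!isX[cc]) {
        fa <- f_ent[cid]
        pat <- gamete_batch_cpp(pool$ends, pool$keys, as.integer(pool$off),
                                hapA = 2L * fa - 2L, hapB = 2L * fa - 1L,
                                length_bp = Lbp[cc], morgans = morg[cc])
        new_pools[[cc]] <- interleave_pool(mat, pat, seq_len(Nt), Nt)
      } else {
        if (length(daughters)) {
          fa <- f_ent[cid[daughters]]
          pat <- gamete_batch_cpp(pool$ends, pool$keys, as.integer(pool$off),
                                  hapA = 2L * fa - 2L,
                                  hapB = rep(-1L, length(daughters)),
                                  length_bp = Lbp[cc], morgans = morg[cc])
        } else {
          pat <- list(ends = integer(0), keys = integer(0), off = 0L)
        }
        new_pools[[cc]] <- interleave_pool(mat, pat, daughters, Nt)
      }
    }

    # true ancestries of the new cohort (child = mean of transmitted gametes)
    src_is_s1 <- founder_src == 1L
    anc_cm <- numeric(Nt)
    for (cc in auto_idx) {
      p <- new_pools[[cc]]
      anc_cm <- anc_cm +
        pool_bp_by_ind(p, Nt, mask = src_is_s1[p$keys]) * rate_cm[cc]
    }
    anc <- anc_cm / (2 * auto_cm)
    ancx <- rep(NA_real_, Nt)
    if (length(x_idx)) {
      cc <- x_idx
      p <- new_pools[[cc]]
      xnum <- pool_bp_by_ind(p, Nt, mask = src_is_s1[p$keys]) * rate_cm[cc]
      xden <- ifelse(sexF, 2, 1) * map$length_cM[cc]
      ancx <- xnum / xden
    }

    cur <- list(n = Nt, ids = ids_new, sex = sex_new, anc = anc, ancx = ancx,
                pools = new_pools,
                mother = m_id[cid], father = f_id[cid],
                mother_anc = m_anc[cid], father_anc = f_anc[cid])
  }

  # emission (optionally subsampled)
  keep <- seq_len(cur$n)
  if (!is.null(config$sample_n) && config$sample_n < cur$n) {
    keep <- sort(sample.int(cur$n, config$sample_n))
  }
  src_is_s1 <- founder_src == 1L
  seg <- pools_to_segments(cur$pools, cur$ids, map)
  seg <- seg[seg$sample %in% cur$ids[keep], , drop = FALSE]
  rownames(seg) <- NULL
  tracts <- merge_to_tracts(seg, src_is_s1)

  samples <- data.frame(
    sample = cur$ids[keep], sex = cur$sex[keep],
    population = config$population, generation = G,
    mother = cur$mother[keep], father = cur$father[keep],
    stringsAsFactors = FALSE)

  truth <- list(
    parents = data.frame(sample = cur$ids[keep],
                         mother = cur$mother[keep], father = cur$father[keep],
                         mother_anc = cur$mother_anc[keep],
                         father_anc = cur$father_anc[keep],
                         stringsAsFactors = FALSE),
    pairs = do.call(rbind, pairs_list),
    founders = data.frame(key = seq_along(founder_src),
                          source = c("S1", "S2")[founder_src]),
    ancestry = data.frame(sample = cur$ids[keep], sex = cur$sex[keep],
                          anc_auto = cur$anc[keep], anc_x = cur$ancx[keep],
                          stringsAsFactors = FALSE),
    realized_rho = realized_rho)

  structure(list(tracts = tracts, samples = samples, founder_segments = seg,
                 truth = truth, map = map, config = config),
            class = "admix_sim")
}

# pool list -> founder-segment data frame (sample, hap, chrom, start, end,
# founder)
pools_to_segments <- function(pools, ids, map) {
  out <- vector("list", length(pools))
  for (cc in seq_along(pools)) {
    p <- pools[[cc]]
    lens <- diff(p$off)
    if (!sum(lens)) next
    ends <- p$ends
    starts <- c(0L, ends[-length(ends)])
    first <- p$off[-length(p$off)][lens > 0L] + 1L
    starts[first] <- 0L
    nh <- length(lens)
    hap_row <- rep.int(seq_len(nh), lens)
    ind <- (hap_row + 1L) %/% 2L
    out[[cc]] <- data.frame(
      sample = ids[ind], hap = (hap_row - 1L) %% 2L,
      chrom = map$chrom[cc], start = starts, end = ends, founder = p$keys,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

# founder segments -> merged local-ancestry tracts
merge_to_tracts <- function(seg, src_is_s1) {
  if (is.null(seg) || nrow(seg) == 0) {
    return(data.frame(sample = character(0), hap = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), ancestry = character(0)))
  }
  lab <- ifelse(src_is_s1[seg$founder], "S1", "S2")
  hap_id <- paste(seg$sample, seg$hap, seg$chrom, sep = "\r")
  n <- nrow(seg)
  new_run <- c(TRUE, hap_id[-1] != hap_id[-n] | lab[-1] != lab[-n])
  run <- cumsum(new_run)
  firsts <- which(new_run)
  lasts <- c(firsts[-1] - 1L, n)
  data.frame(sample = seg$sample[firsts], hap = seg$hap[firsts],
             chrom = seg$chrom[firsts], start = seg$start[firsts],
             end = seg$end[lasts], ancestry = lab[firsts],
             stringsAsFactors = FALSE)
}

#' Hand-built pedigrees: founders and crosses
#'
#' A small harness for constructing explicit pedigrees on top of the same
#' meiosis engine as [simulate_admixture()], used for pedigree expectations
#' (parent-offspring and sib IBD, autozygosity under consanguineous mating).
#' `founder_individual()` creates an unrelated founder whose two haplotypes
#' carry the given founder keys on every chromosome; `cross()` produces one
#' offspring (selfing is permitted for testing). `individual_segments()`
#' flattens individuals into the founder-segment table understood by
#' [autozygosity_truth()] and [ibd_truth()].
#'
#' @param map a [genetic_map()].
#' @param sex `"F"` or `"M"`.
#' @param keys two distinct integer founder keys (haplotype 0 and 1).
#' @param source source label (`"S1"`/`"S2"`) recorded for both keys.
#' @return `founder_individual()` / `cross()`: a `sim_individual`;
#'   `individual_segments()`: a founder-segment data frame.
#' @export
founder_individual <- function(map, sex = "F", keys, source = "S1") {
  stopifnot(inherits(map, "genetic_map"), sex %in% c("F", "M"),
            length(keys) == 2, keys[1] != keys[2])
  haps <- lapply(seq_len(nrow(map)), function(cc) {
    h0 <- data.frame(end = as.integer(map$length_bp[cc]),
                     key = as.integer(keys[1]))
    h1 <- if (map$is_X[cc] && sex == "M") NULL else {
      data.frame(end = as.integer(map$length_bp[cc]),
                 key = as.integer(keys[2]))
    }
    list(h0 = h0, h1 = h1)
  })
  structure(list(sex = sex, haps = haps,
                 keys = as.integer(keys), source = source),
            class = "sim_individual")
}

#' @rdname founder_individual
#' @param mother,father `sim_individual` parents (mother female, father male;
#'   `mother` and `father` may be the same individual, i.e. selfing, which is
#'   only sensible in test harnesses).
#' @export
cross <- function(mother, father, map, sex = "F") {
  stopifnot(inherits(mother, "sim_individual"),
            inherits(father, "sim_individual"), sex %in% c("F", "M"))
  haps <- lapply(seq_len(nrow(map)), function(cc) {
    L <- map$length_bp[cc]
    r <- map$cm_per_mb[cc]
    mh <- mother$haps[[cc]]
    h0 <- meiosis_gamete(mh$h0, mh$h1, L, r)[, c("end", "key")]
    h1 <- NULL
    if (map$is_X[cc]) {
      if (sex == "F") h1 <- father$haps[[cc]]$h0 # father's X intact
    } else {
      fh <- father$haps[[cc]]
      h1 <- meiosis_gamete(fh$h0, fh$h1, L, r)[, c("end", "key")]
    }
    list(h0 = h0, h1 = h1)
  })
  structure(list(sex = sex, haps = haps, keys = NA_integer_, source = NA),
            class = "sim_individual")
}

#' @rdname founder_individual
#' @param individuals named list of `sim_individual` objects; names become
#'   sample ids.
#' @export
individual_segments <- function(individuals, map) {
  stopifnot(length(names(individuals)) == length(individuals))
  rows <- list()
  for (id in names(individuals)) {
    ind <- individuals[[id]]
    for (cc in seq_len(nrow(map))) {
      for (h in 0:1) {
        hp <- if (h == 0) ind$haps[[cc]]$h0 else ind$haps[[cc]]$h1
        if (is.null(hp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample = id, hap = h, chrom = map$chrom[cc],
          start = c(0L, hp$end[-nrow(hp)]), end = hp$end, founder = hp$key,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
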
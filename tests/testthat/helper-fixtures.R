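# shared fixtures and a lazy cache for expensive simulations

small_map <- function(n = 2, mb = 100, include_x = FALSE, rate = 1) {
  chrom <- paste0("chr", seq_len(n))
  len <- rep(mb * 1e6, n)
  isx <- rep(FALSE, n)
  if (include_x) {
    chrom <- c(chrom, "chrX")
    len <- c(len, mb * 1e6)
    isx <- c(isx, TRUE)
  }
  genetic_map(chrom, len, cm_per_mb = rate, is_X = isx)
}

# one-row-per-haplotype tract table from a compact spec list:
# list(list(sample=, hap=, chrom=, breaks=c(...), anc=c("S1","S2",...)), ...)
tracts_from_spec <- function(spec, map) {
  rows <- lapply(spec, function(s) {
    L <- map$length_bp[match(s$chrom, map$chrom)]
    ends <- c(s$breaks, L)
    data.frame(sample = s$sample, hap = s$hap, chrom = s$chrom,
               start = c(0, s$breaks), end = ends, ancestry = s$anc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# memoized heavy objects shared across test files (alphabetical order means
# test-acceptance usually pays the cost)
.cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, builder(), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

# drop all but one child per parental couple: the study population excludes
# first-degree relatives, and full sibs duplicate the identical parent link,
# which no row-level permutation can emulate
drop_sibs <- function(sim) {
  keep <- sim$samples$sample[!duplicated(paste(sim$samples$mother,
                                               sim$samples$father))]
  sim$tracts[sim$tracts$sample %in% keep, , drop = FALSE]
}

# null / assorted parental-pair datasets for the permutation-test
# calibration (criterion-level settings: N = 500, B = 1000)
null_assort_pvalues <- function() {
  cache_get("null_assort_pvalues", function() {
    map <- example_map(scale = 0.25, include_x = FALSE)
    sch <- contribution_schedule(10, 0.05, 0.05, 0.05, 0.05)
    vapply(seq_len(200), function(r) {
      sim <- simulate_admixture(sim_config(map, G = 10, N = 500,
                                           schedule = sch, rho = 0,
                                           seed = 40000 + r))
      permutation_null(parental_ancestry(drop_sibs(sim), map),
                       B = 1000, seed = r)$p
    }, numeric(1))
  })
}
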
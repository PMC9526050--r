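test_that("global ancestry is the cM-weighted S1 fraction", {
  map <- small_map(1, mb = 100)
  all_s1 <- tracts_from_spec(list(
    list(sample = "s1", hap = 0, chrom = "chr1", breaks = NULL, anc = "S1"),
    list(sample = "s1", hap = 1, chrom = "chr1", breaks = NULL, anc = "S1")),
    map)
  expect_equal(global_ancestry(all_s1, map)$prop, 1)

  half <- tracts_from_spec(list(
    list(sample = "s1", hap = 0, chrom = "chr1", breaks = NULL, anc = "S1"),
    list(sample = "s1", hap = 1, chrom = "chr1", breaks = NULL, anc = "S2")),
    map)
  expect_equal(global_ancestry(half, map)$prop, 0.5)

  # 30 of 100 Mb on hap0 plus 50 of 100 Mb on hap1 -> (30 + 50) / 200 = 0.40
  mix <- tracts_from_spec(list(
    list(sample = "s1", hap = 0, chrom = "chr1", breaks = 3e7,
         anc = c("S1", "S2")),
    list(sample = "s1", hap = 1, chrom = "chr1", breaks = 5e7,
         anc = c("S1", "S2"))), map)
  expect_equal(global_ancestry(mix, map)$prop, 0.40)
})

test_that("population summaries cover the trivial cases", {
  s <- data.frame(sample = c("a", "b", "c"), sex = "F",
                  population = c("p1", "p2", "p2"), generation = 1L,
                  mother = NA, father = NA)
  p <- data.frame(sample = c("a", "b", "c"), prop = c(0.7, 0.4, 0.6))
  out <- population_summary(p, s)
  expect_equal(out$mean[out$population == "p1"], 0.7)
  expect_equal(out$median[out$population == "p1"], 0.7)
  expect_equal(out$mean[out$population == "p2"], 0.5)
})

test_that("lad_corr matches hand-computed Pearson values and window layout", {
  # 25-Mb chromosome, 10-Mb windows overlapping 1 Mb -> anchors (0,10), (9,19)
  map <- small_map(1, mb = 25)
  specs <- list()
  # 4 haplotypes; ancestry constant per haplotype at the anchor positions:
  # (1,1), (1,1), (0,0), (0,0) at pair 1 -> r = 1
  haps <- list(c("S1"), c("S1"), c("S2"), c("S2"))
  for (i in seq_along(haps)) {
    specs[[i]] <- list(sample = paste0("s", ceiling(i / 2)), hap = (i + 1) %% 2,
                       chrom = "chr1", breaks = NULL, anc = haps[[i]])
  }
  tr <- tracts_from_spec(specs, map)
  lw <- lad_windows(tr, map, window_mb = 10, overlap_mb = 1, min_hap = 4)
  expect_equal(nrow(lw), 2)
  expect_equal(lw$anchor1_bp, c(0, 9e6))
  expect_equal(lw$anchor2_bp, c(1e7, 1.9e7))
  expect_equal(lw$lad_corr, c(1, 1))
  expect_equal(lw$dist_cm, c(10, 10))

  # first window: indicators (1,1), (0,0), (1,0), (0,1) -> r = 0 by hand;
  # second window sits beyond the breakpoints -> all haplotypes coupled, r = 1
  specs2 <- list(
    list(sample = "a", hap = 0, chrom = "chr1", breaks = NULL, anc = "S1"),
    list(sample = "a", hap = 1, chrom = "chr1", breaks = NULL, anc = "S2"),
    list(sample = "b", hap = 0, chrom = "chr1", breaks = 5e6,
         anc = c("S1", "S2")),
    list(sample = "b", hap = 1, chrom = "chr1", breaks = 5e6,
         anc = c("S2", "S1")))
  tr2 <- tracts_from_spec(specs2, map)
  lw2 <- lad_windows(tr2, map, window_mb = 10, overlap_mb = 1, min_hap = 4)
  expect_equal(lw2$lad_corr, c(0, 1))
})

test_that("lad_corr is invariant to swapping the ancestry labels", {
  map <- small_map(2, mb = 40)
  sim <- simulate_admixture(sim_config(map, G = 6, N = 100, seed = 31))
  lw <- lad_windows(sim$tracts, map)
  flipped <- sim$tracts
  flipped$ancestry <- ifelse(flipped$ancestry == "S1", "S2", "S1")
  lw2 <- lad_windows(flipped, map)
  expect_equal(lw$lad_corr, lw2$lad_corr, tolerance = 1e-12)
})

test_that("a founding pulse population has LAD = 1 everywhere", {
  map <- small_map(2, mb = 40)
  sch <- contribution_schedule(1, 0.6, 0.6, 0.4, 0.4)
  sim <- simulate_admixture(sim_config(map, G = 1, N = 200, schedule = sch,
                                       seed = 32))
  lw <- lad_windows(sim$tracts, map)
  expect_true(all(abs(lw$lad_corr - 1) < 1e-9))
})

test_that("X-vs-autosome signed-rank test: rank arithmetic and refusals", {
  auto <- data.frame(sample = paste0("s", 1:50),
                     prop = seq(0.3, 0.8, length.out = 50))
  x <- auto
  x$prop <- x$prop + 0.1
  res <- x_vs_auto_test(auto, x)
  expect_equal(res$statistic, 50 * 51 / 2) # every pair positive: full rank sum
  expect_lt(res$p_value, 1e-8)
  expect_equal(res$n_informative, 50)
  expect_error(x_vs_auto_test(auto, auto), "informative")
  expect_error(x_vs_auto_test(auto$prop[1:5], auto$prop[1:5] + 1), "informative")
})
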
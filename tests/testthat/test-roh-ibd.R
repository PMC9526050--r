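test_that("the 100/m-cM boundary rule", {
  expect_equal(boundary_from_generations(20), 2.5)
  expect_equal(boundary_from_generations(10), 5.0)
  expect_equal(boundary_from_generations(50), 1.0)
  # strictly decreasing in g; rate rescales linearly
  g <- 1:60
  expect_true(all(diff(boundary_from_generations(g)) < 0))
  expect_equal(boundary_from_generations(20, rate = 2), 1.25)
  expect_error(boundary_from_generations(0), "g must")
})

test_that("fixed-boundary classification labels shorter/long", {
  map <- small_map(1, mb = 100)
  seg <- data.frame(kind = "ROH", sample1 = "s1", hap1 = NA, sample2 = NA,
                    hap2 = NA, chrom = "chr1",
                    start = c(0L, 1e7), end = c(5e5, 1e7 + 3e6),
                    cM = c(0.5, 3), class = NA)
  cls <- classify_roh(seg, "fixed", boundary_mb = 2.5)
  expect_equal(cls$segments$class, c("shorter", "long"))
  expect_error(classify_roh(seg, "fixed"), "boundary_mb")
})

test_that("gmm3 recovers well-separated mixture components", {
  set.seed(90)
  # three log-normal clusters with modes near 0.1, 0.5 and 2 Mb
  comp <- rep(1:3, each = 1000)
  lens <- round(10^(rnorm(3000, mean = rep(c(5, 5.7, 6.3), each = 1000),
                          sd = 0.08)))
  seg <- data.frame(sample1 = "s", chrom = "chr1", start = 0L,
                    end = lens, class = NA)
  cls <- classify_roh(seg, "gmm3", seed = 2)
  b <- cls$boundaries_bp
  expect_true(b[1] > 1e5 && b[1] < 10^5.7)
  expect_true(b[2] > 10^5.7 && b[2] < 10^6.3)
  recovered <- mean(c("A", "B", "C")[comp] == cls$segments$class)
  expect_gte(recovered, 0.95)

  # unit rescaling (bp -> kb) rescales the boundaries by the same factor
  seg_kb <- seg
  seg_kb$end <- seg$end * 1000L
  cls_kb <- classify_roh(seg_kb, "gmm3", seed = 2)
  expect_equal(cls_kb$boundaries_bp / cls$boundaries_bp, c(1000, 1000),
               tolerance = 1e-6)

  expect_error(classify_roh(seg[1:20, ], "gmm3"), "at least 50")
  same <- seg
  same$end <- 1e6L
  expect_error(classify_roh(same, "gmm3"), "degenerate")
})

test_that("per-individual summaries: totals, conservation, correlations", {
  map <- small_map(1, mb = 100)
  seg <- data.frame(kind = "ROH",
                    sample1 = c("a", "a", "b"), hap1 = NA, sample2 = NA,
                    hap2 = NA, chrom = "chr1",
                    start = c(0, 2e6, 0), end = c(1e6, 3e6, 4e6),
                    cM = c(1, 1, 4), class = c("shorter", "shorter", "long"))
  out <- roh_summaries(seg,
                       ancestry = data.frame(sample = c("a", "b", "c"),
                                             prop = c(0.5, 0.7, 0.6)),
                       samples = data.frame(sample = c("a", "b", "c"),
                                            population = c("p1", "p1", "p2")))
  per <- out$per_individual
  expect_equal(per$total[per$sample == "a"], 2)
  expect_equal(per$total[per$sample == "c"], 0) # ROH-free individual included
  expect_equal(per$total, per$shorter + per$long) # classes partition total
  expect_equal(nrow(out$population_tests), 1)
})

test_that("ancestry switches inside ROH are counted strictly and deduplicated", {
  map <- small_map(1, mb = 100)
  # ROH spanning exactly one breakpoint shared by both haplotypes at 1 Mb
  tr <- tracts_from_spec(list(
    list(sample = "a", hap = 0, chrom = "chr1", breaks = 1e6,
         anc = c("S1", "S2")),
    list(sample = "a", hap = 1, chrom = "chr1", breaks = 1e6,
         anc = c("S1", "S2"))), map)
  roh <- data.frame(sample1 = "a", chrom = "chr1", start = 0L, end = 2e6,
                    cM = 2, class = "long")
  res <- ancestry_switches_in_roh(roh, tr)
  expect_equal(res$per_segment$n_switches, 1) # deduplicated across homologs
  expect_equal(res$per_segment$switches_per_mb, 0.5)

  # ROH fully inside one tract: no switches; boundary-touching not counted
  roh2 <- data.frame(sample1 = "a", chrom = "chr1",
                     start = c(2e6, 0), end = c(5e6, 1e6),
                     cM = c(3, 1), class = c("long", "shorter"))
  res2 <- ancestry_switches_in_roh(roh2, tr)
  expect_equal(res2$per_segment$n_switches, c(0, 0))
})

test_that("IBD totals filter then sum; networks threshold or take quantiles", {
  ibd <- data.frame(kind = "IBD", sample1 = c("a", "a"), hap1 = 0,
                    sample2 = c("b", "b"), hap2 = 0, chrom = "chr1",
                    start = c(0, 1e7), end = c(4e6, 1.6e7),
                    cM = c(4, 6), class = NA)
  tot <- pairwise_ibd_totals(ibd, min_cm = 5)
  expect_equal(tot$total_cm, 6) # the 4-cM segment is filtered out
  expect_equal(nrow(pairwise_ibd_totals(ibd[0, ], 5)), 0)

  totals <- data.frame(sample1 = paste0("s", 1:100), sample2 = "z",
                       total_cm = seq(2, 200, by = 2))
  expect_equal(nrow(ibd_network(totals, edge_cm = 150)), 25)
  expect_equal(nrow(ibd_network(data.frame(sample1 = c("a", "b"),
                                           sample2 = c("b", "c"),
                                           total_cm = c(100, 200)),
                                edge_cm = 150)), 1)
  top <- ibd_network(totals, edge_cm = NULL, top_quantile = 0.03)
  expect_equal(nrow(top), 3)
  expect_equal(sort(top$total_cm, decreasing = TRUE), c(200, 198, 196))
  expect_error(ibd_network(totals, edge_cm = 150, top_quantile = 0.03),
               "not both")
})

test_that("pedigree expectations: parent-offspring and unrelated pairs", {
  map <- example_map(scale = 0.5, include_x = FALSE)
  set.seed(91)
  mo <- founder_individual(map, "F", c(1, 2))
  fa <- founder_individual(map, "M", c(3, 4))
  kid <- cross(mo, fa, map, "F")
  seg <- individual_segments(list(mo = mo, fa = fa, kid = kid), map)

  # two fresh founders share nothing
  none <- ibd_truth(seg, map, pairs = data.frame(sample1 = "mo", sample2 = "fa"))
  expect_equal(nrow(none), 0)

  # parent-offspring: the transmitted gamete tiles one full genome length
  po <- ibd_truth(seg, map, pairs = data.frame(sample1 = "mo", sample2 = "kid"))
  expect_equal(sum(po$cM), map_total <- sum(map$length_cM), tolerance = 1e-9)
  kin <- kinship_proxy(po, map)
  expect_equal(kin$kinship, 0.25, tolerance = 1e-9)

  # offspring of two unrelated founders has zero ROH
  expect_equal(nrow(autozygosity_truth(seg, map)), 0)
})

test_that("kinship proxy halves per extra meiosis (grandparent ~ 0.125)", {
  map <- example_map(scale = 0.5, include_x = FALSE)
  set.seed(92)
  ks <- vapply(1:10, function(r) {
    gm <- founder_individual(map, "F", c(1, 2))
    gf <- founder_individual(map, "M", c(3, 4))
    mo <- cross(gm, gf, map, "F")
    fa <- founder_individual(map, "M", c(5, 6))
    kid <- cross(mo, fa, map, "M")
    seg <- individual_segments(list(gm = gm, kid = kid), map)
    ib <- ibd_truth(seg, map,
                    pairs = data.frame(sample1 = "gm", sample2 = "kid"))
    kinship_proxy(ib, map)$kinship
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.125), 0.02)
})
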
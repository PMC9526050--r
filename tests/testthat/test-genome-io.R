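test_that("genetic map enforces its invariants", {
  expect_error(genetic_map(c("a", "a"), c(1e6, 2e6)), "unique")
  expect_error(genetic_map("a", 0), "positive")
  expect_error(genetic_map(c("a", "b"), c(1e6, 1e6), is_X = c(TRUE, TRUE)),
               "at most one X")
  m <- genetic_map("chr1", 2.5e6, cm_per_mb = 1)
  expect_equal(m$length_cM, 2.5)
  expect_equal(admixisle:::interval_cm(m, "chr1", 0, 2.5e6), 2.5)
})

test_that("tract tiling violations are caught with coordinates", {
  map <- small_map(1, mb = 100)
  ok <- tracts_from_spec(list(
    list(sample = "s1", hap = 0, chrom = "chr1", breaks = numeric(0),
         anc = "S1")), map)
  expect_silent(validate_tracts(ok, map))

  gap <- data.frame(sample = "s1", hap = 0, chrom = "chr1",
                    start = c(0, 6e7), end = c(5e7, 1e8),
                    ancestry = c("S1", "S2"))
  expect_error(validate_tracts(gap, map), "expected start 50000000")

  short <- data.frame(sample = "s1", hap = 0, chrom = "chr1",
                      start = 0, end = 9e7, ancestry = "S1")
  expect_error(validate_tracts(short, map), "chromosome length")

  unknown <- data.frame(sample = "s1", hap = 0, chrom = "chrZ",
                        start = 0, end = 1e8, ancestry = "S1")
  expect_error(validate_tracts(unknown, map), "unknown chromosome")
})

test_that("tract write/read round-trips bit-exactly, including simulator output", {
  map <- small_map(2, mb = 80)
  one <- tracts_from_spec(list(
    list(sample = "s1", hap = 0, chrom = "chr1", breaks = numeric(0),
         anc = "S1"),
    list(sample = "s1", hap = 1, chrom = "chr1", breaks = 4e7,
         anc = c("S2", "S1"))), map)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracts(one, f, map)
  expect_equal(read_tracts(f, map), validate_tracts(one, map),
               ignore_attr = TRUE)

  # empty set -> header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tracts(one[0, ], f2)
  lines <- readLines(f2)
  expect_length(lines[!startsWith(lines, "#")], 1)

  # a 500-sample simulated set round-trips identically and byte-stably
  simmap <- example_map(scale = 0.05)
  sim <- simulate_admixture(sim_config(simmap, G = 4, N = 500, seed = 42))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_tracts(sim$tracts, f3, simmap)
  back <- read_tracts(f3, simmap)
  expect_equal(back, validate_tracts(sim$tracts, simmap), ignore_attr = TRUE)
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_tracts(back, f4, simmap)
  expect_identical(readLines(f3), readLines(f4))
})

test_that("segment io recomputes cM from the map and rejects bad rows", {
  map <- small_map(1, mb = 100)
  seg <- data.frame(kind = "ROH", sample1 = "s1", hap1 = NA_integer_,
                    sample2 = NA_character_, hap2 = NA_integer_,
                    chrom = "chr1", start = 0L, end = 2500000L,
                    cM = NA_real_, class = NA_character_)
  out <- validate_segments(seg, map)
  expect_equal(out$cM, 2.5)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_segments(out, f, map)
  back <- read_segments(f, map)
  expect_equal(back$cM, 2.5)
  expect_equal(back$start, 0L)

  bad <- out
  bad$kind <- "IBD" # partner missing
  expect_error(validate_segments(bad, map), "sample2")
  neg <- out
  neg$end <- 0L
  expect_error(validate_segments(neg, map), "negative or empty")
})

test_that("IBD truth tables round-trip through segment files", {
  map <- small_map(2, mb = 60)
  set.seed(7)
  f1 <- founder_individual(map, "F", c(1, 2))
  f2 <- founder_individual(map, "M", c(3, 4))
  kid <- cross(f1, f2, map, sex = "F")
  seg <- individual_segments(list(p = f1, k = kid), map)
  ibd <- ibd_truth(seg, map)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_segments(ibd, f, map)
  back <- read_segments(f, map)
  ord <- order(back$hap1, back$hap2, back$chrom, back$start)
  ibd_ord <- order(ibd$hap1, ibd$hap2, ibd$chrom, ibd$start)
  expect_equal(back[ord, c("sample1", "hap1", "sample2", "hap2", "start", "end")],
               ibd[ibd_ord, c("sample1", "hap1", "sample2", "hap2", "start", "end")],
               ignore_attr = TRUE)
})

test_that("sample table io validates sex and uniqueness", {
  s <- data.frame(sample = c("a", "b"), sex = c("F", "M"),
                  population = "p1", generation = 3L,
                  mother = c(NA, "a"), father = c(NA, NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(s, f)
  back <- read_samples(f)
  expect_equal(back$sample, c("a", "b"))
  expect_equal(back$mother, c(NA, "a"))
  s2 <- s; s2$sex[1] <- "X"
  expect_error(validate_samples(s2), "sex")
  s3 <- s; s3$sample <- c("a", "a")
  expect_error(validate_samples(s3), "unique")
})
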
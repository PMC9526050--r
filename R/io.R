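# Readers, writers and validators for the tract/segment/sample tables.
#
# All files are UTF-8, LF, tab-delimited with a header line; lines starting
# with '#' are comments. Coordinates are 0-based, half-open everywhere.

TRACT_COLS <- c("sample", "hap", "chrom", "start", "end", "ancestry")
SEGMENT_COLS <- c("kind", "sample1", "hap1", "sample2", "hap2",
                  "chrom", "start", "end", "cM", "class")
SAMPLE_COLS <- c("sample", "sex", "population", "generation", "mother", "father")

#' Validate a local-ancestry tract table
#'
#' Checks that per (sample, haplotype, chromosome) the tracts are
#' non-overlapping, sorted, and tile `[0, length_bp)` exactly, and that
#' ancestry labels are `S1`/`S2`. Errors name the sample, haplotype,
#' chromosome and offending position.
#'
#' @param tracts data frame with columns `sample`, `hap` (0/1), `chrom`,
#'   `start`, `end`, `ancestry`.
#' @param map a [genetic_map()] covering every chromosome named.
#' @return the tract table, invisibly, ordered by (sample, hap, chrom, start).
#' @export
validate_tracts <- function(tracts, map) {
  stop_if_not_cols(tracts, TRACT_COLS, "tract table")
  if (nrow(tracts) == 0) return(invisible(tracts))
  if (!all(tracts$hap %in% c(0L, 1L))) stop("haplotype must be 0 or 1")
  if (!all(tracts$ancestry %in% c("S1", "S2"))) {
    stop("ancestry labels must be 'S1' or 'S2'")
  }
  mi <- map_row(map, tracts$chrom)
  ord <- order(tracts$sample, tracts$hap, match(tracts$chrom, map$chrom),
               tracts$start)
  tracts <- tracts[ord, , drop = FALSE]
  mi <- mi[ord]
  grp <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  new <- !duplicated(grp)
  # within-group predecessor end; for group heads it must equal 0
  prev_end <- c(0, tracts$end[-nrow(tracts)])
  prev_end[new] <- 0
  bad <- which(tracts$start != prev_end)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "tract tiling violated for sample %s hap %d %s: expected start %d, found %d (gap or overlap)",
      tracts$sample[b], tracts$hap[b], tracts$chrom[b],
      as.integer(prev_end[b]), as.integer(tracts$start[b])))
  }
  if (any(tracts$end <= tracts$start)) {
    b <- which(tracts$end <= tracts$start)[1]
    stop(sprintf("empty or negative tract for sample %s hap %d %s at %d",
                 tracts$sample[b], tracts$hap[b], tracts$chrom[b],
                 as.integer(tracts$start[b])))
  }
  last <- c(!duplicated(grp, fromLast = TRUE))
  short <- which(last & tracts$end != map$length_bp[mi])
  if (length(short)) {
    b <- short[1]
    stop(sprintf(
      "tract tiling violated for sample %s hap %d %s: ends at %d, chromosome length is %d",
      tracts$sample[b], tracts$hap[b], tracts$chrom[b],
      as.integer(tracts$end[b]), as.integer(map$length_bp[mi[b]])))
  }
  rownames(tracts) <- NULL
  invisible(tracts)
}

#' Read local-ancestry tracts
#'
#' @param path tab-delimited file with header
#'   `sample hap chrom start end ancestry`.
#' @param map a [genetic_map()]; the tiling invariant is enforced on read.
#' @return validated tract data frame ordered by (sample, hap, chrom, start).
#' @export
read_tracts <- function(path, map) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", chrom = "character"))
  stop_if_not_cols(df, TRACT_COLS, "tract file")
  df$hap <- as.integer(df$hap)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  out <- validate_tracts(df[TRACT_COLS], map)
  out
}

#' Write local-ancestry tracts
#'
#' Rows are written in deterministic (sample, hap, chrom, start) order so that
#' write/read round-trips are byte-stable.
#'
#' @param tracts validated tract table.
#' @param path output path.
#' @param map optional [genetic_map()]; when supplied the table is validated
#'   before writing and chromosome order follows the map.
#' @export
write_tracts <- function(tracts, path, map = NULL) {
  stop_if_not_cols(tracts, TRACT_COLS, "tract table")
  if (!is.null(map)) {
    tracts <- validate_tracts(tracts, map)
    corder <- match(tracts$chrom, map$chrom)
  } else {
    corder <- tracts$chrom
  }
  ord <- order(tracts$sample, tracts$hap, corder, tracts$start)
  .write_table(tracts[ord, TRACT_COLS, drop = FALSE], path,
               "# local ancestry tracts; coordinates 0-based, half-open")
}

#' Read an ROH/IBD segment table
#'
#' ROH rows have blank partner fields (written as `.`); IBD rows require
#' `sample2`. Genetic lengths are recomputed from the map when absent and
#' checked for consistency otherwise.
#'
#' @param path tab-delimited file with header
#'   `kind sample1 hap1 sample2 hap2 chrom start end cM class`.
#' @param map a [genetic_map()].
#' @return segment data frame.
#' @export
read_segments <- function(path, map) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = c("NA", "."),
                   colClasses = c(sample1 = "character", chrom = "character"))
  stop_if_not_cols(df, SEGMENT_COLS, "segment file")
  df$sample2 <- as.character(df$sample2)
  df$class <- as.character(df$class)
  validate_segments(df[SEGMENT_COLS], map)
}

#' Validate (and complete) an ROH/IBD segment table
#'
#' @inheritParams read_segments
#' @param segments segment data frame (see [read_segments()] for columns).
#' @return the table with `cM` filled from the map where missing.
#' @export
validate_segments <- function(segments, map) {
  stop_if_not_cols(segments, SEGMENT_COLS, "segment table")
  if (nrow(segments) == 0) return(segments)
  if (!all(segments$kind %in% c("ROH", "IBD"))) {
    stop("segment kind must be 'ROH' or 'IBD'")
  }
  if (any(segments$end <= segments$start)) {
    b <- which(segments$end <= segments$start)[1]
    stop(sprintf("negative or empty segment at %s:%d-%d",
                 segments$chrom[b], as.integer(segments$start[b]),
                 as.integer(segments$end[b])))
  }
  ibd <- segments$kind == "IBD"
  if (any(ibd & (is.na(segments$sample2) | segments$sample2 == ""))) {
    stop("IBD rows must name sample2")
  }
  if (any(!ibd & !is.na(segments$sample2))) {
    stop("ROH rows must leave partner fields blank")
  }
  cm <- interval_cm(map, segments$chrom, segments$start, segments$end)
  fill <- is.na(segments$cM)
  segments$cM[fill] <- cm[fill]
  if (any(abs(segments$cM - cm) > 1e-6)) {
    stop("cM column disagrees with map-derived genetic length")
  }
  rownames(segments) <- NULL
  segments
}

#' Write an ROH/IBD segment table
#'
#' @inheritParams validate_segments
#' @param path output path.
#' @export
write_segments <- function(segments, path, map = NULL) {
  stop_if_not_cols(segments, SEGMENT_COLS, "segment table")
  if (!is.null(map)) segments <- validate_segments(segments, map)
  ord <- order(segments$kind, segments$sample1, segments$sample2,
               segments$chrom, segments$start)
  out <- segments[ord, SEGMENT_COLS, drop = FALSE]
  out$cM <- formatC(out$cM, format = "g", digits = 10)
  .write_table(out, path,
               "# ROH/IBD segments; coordinates 0-based, half-open")
}

#' Read / write the sample metadata table
#'
#' Columns: `sample sex population generation mother father` with sex in
#' `{F, M}`; unknown parents are blank (`.`).
#'
#' @param path file path.
#' @return sample data frame.
#' @export
read_samples <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = c("NA", "."),
                   colClasses = c(sample = "character"))
  stop_if_not_cols(df, SAMPLE_COLS, "sample file")
  validate_samples(df[SAMPLE_COLS])
}

#' @rdname read_samples
#' @param samples sample data frame.
#' @export
validate_samples <- function(samples) {
  stop_if_not_cols(samples, SAMPLE_COLS, "sample table")
  if (anyDuplicated(samples$sample)) stop("sample ids must be unique")
  if (!all(samples$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  rownames(samples) <- NULL
  samples
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  ord <- order(samples$sample)
  .write_table(samples[ord, SAMPLE_COLS, drop = FALSE], path,
               "# sample metadata")
}

.write_table <- function(df, path, header_comment) {
  con <- file(path, open = "wb") # wb => LF endings on every platform
  on.exit(close(con))
  writeLines(header_comment, con, sep = "\n")
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]][is.na(df[[j]])] <- "."
  }
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ".", eol = "\n"))
  invisible(path)
}
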
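#' Build a genome model with constant per-chromosome recombination rates
#'
#' A genetic map is a data frame with one row per chromosome and a constant
#' cM/Mb rate per chromosome (default 1 cM/Mb, the commonly applied baseline).
#' Genetic length of any interval is `(end_bp - start_bp) * cm_per_mb / 1e6`,
#' exactly. Per-interval recombination maps are a declared extension point and
#' are not implemented.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length_bp positive integer physical lengths in bp.
#' @param cm_per_mb constant recombination rate per chromosome, cM per Mb
#'   (recycled; default 1).
#' @param is_X logical flag per chromosome; at most one X is allowed. The X is
#'   carried as two haplotypes by females and one (haplotype 0) by males.
#' @return a `genetic_map` data frame with columns `chrom`, `length_bp`,
#'   `cm_per_mb`, `is_X`, `length_cM`.
#' @export
#' @examples
#' genetic_map("chr1", 1e8)
genetic_map <- function(chrom, length_bp, cm_per_mb = 1, is_X = FALSE) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length_bp <- as.numeric(length_bp)
  cm_per_mb <- rep_len(as.numeric(cm_per_mb), length(chrom))
  is_X <- rep_len(as.logical(is_X), length(chrom))
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("chromosome lengths must be strictly positive")
  }
  if (any(cm_per_mb <= 0)) stop("recombination rates must be strictly positive")
  if (sum(is_X) > 1) stop("at most one X chromosome is allowed")
  map <- data.frame(
    chrom = chrom,
    length_bp = length_bp,
    cm_per_mb = cm_per_mb,
    is_X = is_X,
    length_cM = length_bp * cm_per_mb / 1e6,
    stringsAsFactors = FALSE
  )
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Human-like 22-autosome + X map at 1 cM/Mb
#'
#' Chromosome physical lengths approximate the human karyotype (GRCh37 scale,
#' rounded to the Mb). `scale` shrinks every chromosome proportionally, which
#' is how the test suite and examples keep forward simulations fast; genetic
#' lengths shrink with it, so expectations that depend only on cM distances
#' are unchanged in form.
#'
#' @param scale multiplicative factor applied to all physical lengths.
#' @param include_x include the X chromosome (default TRUE).
#' @param cm_per_mb constant recombination rate (default 1 cM/Mb).
#' @return a [genetic_map()].
#' @export
example_map <- function(scale = 1, include_x = TRUE, cm_per_mb = 1) {
  auto_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
               115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  chrom <- paste0("chr", seq_along(auto_mb))
  len <- auto_mb * 1e6
  isx <- rep(FALSE, length(auto_mb))
  if (include_x) {
    chrom <- c(chrom, "chrX")
    len <- c(len, 155e6)
    isx <- c(isx, TRUE)
  }
  genetic_map(chrom, round(len * scale), cm_per_mb = cm_per_mb, is_X = isx)
}

# total genetic length (cM) of a scope of the map
map_total_cm <- function(map, scope = c("autosomes", "X", "all")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
    autosomes = !map$is_X,
    X = map$is_X,
    all = rep(TRUE, nrow(map))
  )
  if (!any(keep)) stop(sprintf("map has no chromosomes in scope '%s'", scope))
  sum(map$length_cM[keep])
}

# map lookup helpers
map_row <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (anyNA(i)) {
    stop(sprintf("unknown chromosome(s): %s",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  i
}

# genetic length in cM of intervals on the map (constant per-chromosome rate)
interval_cm <- function(map, chrom, start_bp, end_bp) {
  i <- map_row(map, chrom)
  (end_bp - start_bp) * map$cm_per_mb[i] / 1e6
}
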
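# Internal coordinate helpers.
#
# All intervals in this package are 0-based, half-open [start, end) --
# the BED convention.  GenomicRanges/IRanges are 1-based closed, so the
# conversion is start + 1 on the left edge only; overlap semantics
# (>= 1 shared base) are preserved exactly.

#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.frame(chrom, start, end) [0-based half-open] -> GRanges
.as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$end < df$start))
    stop("interval end < start")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# GRanges -> data.frame(chrom, start, end) [0-based half-open]
.from_granges0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# midpoint of a 0-based half-open interval
.midpoint <- function(start, end) as.integer(floor((start + end) / 2))
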
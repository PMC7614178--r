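# Shared low-level helpers: reverse complement, interval containers and
# conversions between the BED-convention data frames used throughout the
# package and the IRanges/GenomicRanges objects used for interval arithmetic.
# Coordinates are 0-based half-open everywhere; conversion to the 1-based
# closed convention happens only at the GFF/GRanges boundary.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement preserving case; `N`/`n` map to themselves.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}` (any case).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtNn", "TGCAtgcaNn", x))
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention): `length = end - start`.
#'
#' @param seq_id character, sequence names.
#' @param start,end integer bp, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(seq_id = character(), start = integer(),
                              end = integer(), strand = ".") {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(seq_id = rep_len(as.character(seq_id), n),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Construct a table of repeat intervals
#'
#' A called or annotated repeat: a genomic interval plus a score (mean k-mer
#' count of the call) and a TE classification (`"UNANNOTATED"` until the
#' annotation step assigns one).
#'
#' @inheritParams genomic_intervals
#' @param score non-negative numeric.
#' @param te_class character classification, e.g. `"LTR/Gypsy"`.
#' @return data.frame with columns `seq_id`, `start`, `end`, `score`,
#'   `te_class`, `strand`.
#' @export
repeat_intervals <- function(seq_id = character(), start = integer(),
                             end = integer(), score = 0,
                             te_class = "UNANNOTATED", strand = ".") {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(seq_id = rep_len(as.character(seq_id), n),
                   start = as.numeric(start), end = as.numeric(end),
                   score = rep_len(as.numeric(score), n),
                   te_class = rep_len(as.character(te_class), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  if (any(df$score < 0)) stop("interval scores must be non-negative")
  df
}

validate_intervals <- function(df, chrom_lengths = NULL) {
  stopifnot(is.data.frame(df),
            all(c("seq_id", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$seq_id]
    if (anyNA(len)) {
      stop("interval on unknown sequence: ",
           paste(unique(df$seq_id[is.na(len)]), collapse = ", "))
    }
    if (any(df$end > len)) stop("interval end exceeds sequence length")
  }
  invisible(df)
}

# BED-convention data frame -> GRanges (1-based closed internally).
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(df$seq_id,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

# GRanges -> BED-convention data frame.
as_bed_df <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = s, stringsAsFactors = FALSE)
}

# Merge intervals closer than or equal to `merge_dist` bp, per seq_id.
merge_bed_df <- function(df, merge_dist = 0) {
  if (nrow(df) == 0) return(df[, c("seq_id", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges0(df), ignore.strand = TRUE,
                              min.gapwidth = merge_dist + 1L)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  as_bed_df(gr)[, c("seq_id", "start", "end")]
}

total_interval_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

has_overlaps_within <- function(df) {
  if (nrow(df) < 2) return(FALSE)
  gr <- as_granges0(df)
  any(IRanges::overlapsAny(gr, drop.self = TRUE, ignore.strand = TRUE))
}

# Open a (possibly gzip-compressed) text connection for reading.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt")
  else file(path, open = "rt")
}

genome_lengths <- function(genomes) {
  vapply(genomes, nchar, numeric(1))
}
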
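# Interval plumbing. The package-wide coordinate contract is 0-based,
# half-open [start, end) on every user-facing data.frame (BED-native).
# GRanges (1-based, closed) is used only internally, through the two
# converters below, for overlap and distance machinery.

#' Construct an interval table
#'
#' Creates the canonical 0-based half-open interval `data.frame` used across
#' the package (`chrom`, `start`, `end`, optional `strand` and `name`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; 0-based half-open, `start < end`.
#' @param strand Optional `"+"`/`"-"` vector.
#' @param name Optional label vector.
#' @return A `data.frame` with one row per interval.
#' @export
intervals <- function(chrom, start, end, strand = NULL, name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the 0-based half-open invariants: `0 <= start < end`, and
#' `end <= chromosome length` when lengths are supplied.
#'
#' @param x Interval `data.frame`.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x, chrom_lengths = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 0)) stop("interval start < 0")
  if (any(x$start >= x$end)) stop("empty or inverted interval (start >= end)")
  if ("strand" %in% names(x) &&
      !all(x$strand %in% c("+", "-", NA_character_)))
    stop("strand must be '+', '-' or NA")
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
    if (any(x$end > chrom_lengths[x$chrom]))
      stop("interval extends past chromosome end")
  }
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (internal)
as_granges0 <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand; s[is.na(s)] <- "*"; s
  } else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

# GRanges -> 0-based half-open data.frame (internal)
as_intervals0 <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- ifelse(s == "*", NA_character_, s)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

# Hits between two 0-based interval tables (any-overlap, >= 1 bp),
# returned as a two-column index data.frame.
overlap_pairs <- function(query, subject) {
  h <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject),
                                   ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}

# Number of subject intervals overlapping each query interval.
overlap_counts <- function(query, subject) {
  GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject),
                               ignore.strand = TRUE)
}

# Gap distance (bp) from each query interval to the nearest subject interval
# on the same chromosome; 0 when overlapping or adjacent, NA when the
# chromosome carries no subject interval.
nearest_distance <- function(query, subject) {
  qg <- as_granges0(query); sg <- as_granges0(subject)
  d <- rep(NA_real_, nrow(query))
  h <- GenomicRanges::distanceToNearest(qg, sg, ignore.strand = TRUE)
  d[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
  d
}

#' Tile a genome into fixed-width windows
#'
#' Per chromosome, produces windows `[0,w), [w,2w), ...` with a final
#' truncated window covering the remainder, as used for ChIC-seq/ATAC-seq
#' quantification (500 bp default elsewhere in the package).
#'
#' @param chrom_lengths Named vector of chromosome lengths, or a genome
#'   object accepted by [genome_lengths()].
#' @param width Window width in bp (>= 1).
#' @return Interval `data.frame` with a `width` attribute.
#' @export
tile_genome <- function(chrom_lengths, width = 500) {
  stopifnot(width >= 1)
  chrom_lengths <- genome_lengths(chrom_lengths)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(width), len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "width") <- as.integer(width)
  out
}

# Two window tables must describe the same tiling.
check_same_tiling <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom & a$start == b$start & a$end == b$end))
    stop("window tilings differ")
  invisible(TRUE)
}

#' Chromosome lengths of a genome object
#'
#' @param genome Named character vector of sequences (as returned by
#'   [read_fasta()]) or an already-named numeric vector of lengths.
#' @return Named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.character(genome)) {
    setNames(nchar(genome), names(genome))
  } else {
    stopifnot(!is.null(names(genome)))
    setNames(as.integer(genome), names(genome))
  }
}
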
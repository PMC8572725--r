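# Readers/writers for the standard formats the pipeline touches. FASTA goes
# through Biostrings, BED and GFF3 through rtracklayer; coordinates are
# converted to the package's 0-based half-open contract at this boundary.

#' Read a genome FASTA
#'
#' Sequences are upper-cased and restricted to the `{A,C,G,T,N}` alphabet;
#' duplicate headers are rejected. Header descriptions after the first
#' whitespace are dropped.
#'
#' @param path FASTA file.
#' @return Named character vector, one upper-case sequence per chromosome.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate sequence name(s) in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nm
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) stop("non-ACGTN characters in sequence(s): ",
                     paste(nm[bad], collapse = ", "))
  out
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene models
#'
#' Two dialects are supported. `"tsv"` is the package's native table with
#' columns `gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated, 0-based half-open). `"gff3"` reads exon features
#' (1-based inclusive, converted here) and groups them by the `gene_id`
#' attribute, falling back to `Parent`.
#'
#' The TSS is always derived from the strand: the minimal exon start on `+`,
#' the maximal exon end on `-`. Exons must be disjoint; overlapping exons,
#' unknown strands and (when `chrom_lengths` is given) out-of-bounds exons
#' are errors.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param chrom_lengths Optional named lengths for bounds checking.
#' @return A `gene_models` object: list with `genes` (gene_id, chrom, strand,
#'   tss, span_start, span_end) and `exons` (gene_id, chrom, start, end).
#' @export
read_gene_models <- function(path, dialect = c("tsv", "gff3"),
                             chrom_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "exon_starts", "exon_ends")
    if (!all(need %in% names(tab)))
      stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    ex <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      s <- as.integer(strsplit(tab$exon_starts[i], ",")[[1]])
      e <- as.integer(strsplit(tab$exon_ends[i], ",")[[1]])
      if (length(s) != length(e)) stop("exon_starts/exon_ends length mismatch")
      data.frame(gene_id = tab$gene_id[i], chrom = tab$chrom[i],
                 start = s, end = e, strand = tab$strand[i],
                 stringsAsFactors = FALSE)
    }))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0) stop("no exon features in GFF3: ", path)
    mc <- S4Vectors::mcols(gr)
    gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
           else if ("Parent" %in% names(mc))
             vapply(mc$Parent, function(p) as.character(p)[1], character(1))
           else stop("GFF3 exons need a gene_id or Parent attribute")
    ex <- data.frame(gene_id = gid,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  }
  gene_models(ex, chrom_lengths = chrom_lengths)
}

#' Build gene models from an exon table
#'
#' @param exons `data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open exons).
#' @param chrom_lengths Optional named lengths for bounds checking.
#' @return A `gene_models` object (see [read_gene_models()]).
#' @export
gene_models <- function(exons, chrom_lengths = NULL) {
  if (!all(exons$strand %in% c("+", "-")))
    stop("unknown strand value(s): ",
         paste(setdiff(unique(exons$strand), c("+", "-")), collapse = ", "))
  validate_intervals(exons, chrom_lengths)
  exons <- exons[order(exons$gene_id, exons$start), ]
  by_gene <- split(exons, exons$gene_id)
  genes <- do.call(rbind, lapply(by_gene, function(e) {
    if (length(unique(e$chrom)) != 1 || length(unique(e$strand)) != 1)
      stop("gene ", e$gene_id[1], " spans multiple chromosomes or strands")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", e$gene_id[1])
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1],
               tss = if (e$strand[1] == "+") min(e$start) else max(e$end),
               span_start = min(e$start), span_end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons[, c("gene_id", "chrom",
                                                  "start", "end")]),
            class = "gene_models")
}

#' Write gene models in the native TSV dialect
#'
#' @param models `gene_models` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  ex <- split(models$exons, models$exons$gene_id)
  g <- models$genes
  tab <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    exon_starts = vapply(ex[g$gene_id], function(e)
      paste(e$start, collapse = ","), character(1)),
    exon_ends = vapply(ex[g$gene_id], function(e)
      paste(e$end, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position-weight-matrix library
#'
#' Plain-text format: one block per motif, a header line
#' `>motif_id TF1,TF2,...` followed by exactly four rows labelled
#' `A`, `C`, `G`, `T`, each with L tab- or space-separated weights. The
#' maximum obtainable score (sum over columns of column maxima) is
#' precomputed; an all-zero matrix is accepted with a warning.
#'
#' @param path PWM library file.
#' @return List of `pwm` objects: `id`, `tf_names`, `weights` (4 x L matrix,
#'   rows A,C,G,T), `max_score`.
#' @export
read_pwm_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif blocks (\">\" headers) in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    hdr <- strsplit(sub("^>\\s*", "", block[1]), "\\s+")[[1]]
    id <- hdr[1]
    tf_names <- if (length(hdr) > 1)
      strsplit(paste(hdr[-1], collapse = " "), ",")[[1]] else id
    body <- block[-1]
    if (length(body) != 4)
      stop("motif ", id, ": expected 4 weight rows, got ", length(body))
    parsed <- lapply(body, function(l) strsplit(trimws(l), "[\t ]+")[[1]])
    labels <- toupper(vapply(parsed, `[`, character(1), 1))
    if (!identical(sort(labels), c("A", "C", "G", "T")))
      stop("motif ", id, ": rows must be labelled A, C, G, T")
    w <- do.call(rbind, lapply(parsed, function(p) as.numeric(p[-1])))
    rownames(w) <- labels
    w <- w[c("A", "C", "G", "T"), , drop = FALSE]
    if (ncol(w) < 1) stop("motif ", id, ": zero-length matrix")
    pwm(id = id, tf_names = trimws(tf_names), weights = w)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  pwms
}

#' Construct a PWM object
#'
#' @param id Motif identifier.
#' @param tf_names Character vector of TF names the motif maps to (a motif
#'   may serve several TFs).
#' @param weights 4 x L numeric matrix with rows A, C, G, T.
#' @return A `pwm` object with precomputed `max_score`.
#' @export
pwm <- function(id, tf_names, weights) {
  stopifnot(is.matrix(weights), nrow(weights) == 4, ncol(weights) >= 1,
            length(tf_names) >= 1)
  rownames(weights) <- c("A", "C", "G", "T")
  max_score <- sum(apply(weights, 2, max))
  if (max_score <= 0) warning("motif ", id, ": max obtainable score is ",
                              max_score)
  structure(list(id = id, tf_names = tf_names, weights = weights,
                 max_score = max_score), class = "pwm")
}

#' Write a PWM library
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm_set <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", paste(p$tf_names, collapse = ",")), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste(c(b, format(p$weights[b, ], trim = TRUE)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read intervals from a BED file
#'
#' @param path BED file (0-based half-open, as BED natively is).
#' @return Interval `data.frame` (`chrom`, `start`, `end`, and `name`,
#'   `score`, `strand` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as_intervals0(gr)
  validate_intervals(df)
  df
}

#' Write intervals to a BED file
#'
#' @param x Interval `data.frame`; optional `name`, `score`, `strand`
#'   columns are carried into BED fields.
#' @param path Output file.
#' @param chrom_lengths Optional named lengths; out-of-bounds intervals error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom_lengths = NULL) {
  validate_intervals(x, chrom_lengths)
  has <- c(name = "name" %in% names(x), score = "score" %in% names(x),
           strand = "strand" %in% names(x))
  cols <- list(x$chrom, x$start, x$end)
  if (any(has)) cols <- c(cols, list(if (has["name"]) x$name else "."))
  if (has["score"] || has["strand"])
    cols <- c(cols, list(if (has["score"]) x$score else 0))
  if (has["strand"])
    cols <- c(cols, list(ifelse(is.na(x$strand), ".", x$strand)))
  df <- data.frame(cols, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count table
#'
#' @param path TSV with row ids in the first column and one column per sample.
#' @return Integer matrix with row and column names.
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative entries in count table")
  m
}

#' Write a count table
#'
#' @param m Matrix with row and column names.
#' @param path Output file.
#' @param id_col Name for the row-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
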
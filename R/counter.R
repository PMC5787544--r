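# Classification of aligned small-RNA reads into per-length isomiR counts.
#
# Reads overlapping a mature-miRNA locus on the same strand are binned by
# two strand-aware coordinates: the 5' offset of the read start from the
# locus's canonical 5' end, and the read length measured from that canonical
# 5' end (so a read with offset 0 and length 21 is the 21 nt templated
# 3'-isomiR). Internally all coordinates are 0-based half-open; GFF3 input
# (1-based closed) is converted on read, BED is native.

#' Read mature-miRNA loci from GFF3 or BED
#'
#' The locus name is taken from the BED name column, or from the `Name`
#' (falling back to `ID`) attribute of GFF3 records. Width must be a
#' plausible mature-miRNA length (15-30 nt) and the strand must be `+` or
#' `-`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file; format inferred from the
#'   extension.
#' @return A [GenomicRanges::GRanges] with a `mirna_name` metadata column.
#' @export
read_loci <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- if (ext %in% c("gff", "gff3")) {
    g <- rtracklayer::import(path, format = "gff3")
    nm <- if ("Name" %in% names(S4Vectors::mcols(g))) g$Name else g$ID
    S4Vectors::mcols(g) <- NULL
    g$mirna_name <- as.character(nm)
    g
  } else if (ext == "bed") {
    g <- rtracklayer::import(path, format = "bed")
    nm <- g$name
    S4Vectors::mcols(g) <- NULL
    g$mirna_name <- as.character(nm)
    g
  } else stop("unsupported locus format: .", ext, call. = FALSE)
  if (any(is.na(g$mirna_name)) || any(!nzchar(g$mirna_name)))
    stop("every locus needs a name", call. = FALSE)
  bad_strand <- which(!as.character(BiocGenerics::strand(gr)) %in% c("+", "-"))
  if (length(bad_strand))
    stop("locus ", gr$mirna_name[bad_strand[1L]],
         " (record ", bad_strand[1L], ") has no strand", call. = FALSE)
  w <- BiocGenerics::width(gr)
  bad_w <- which(w < 15L | w > 30L)
  if (length(bad_w))
    stop(sprintf("locus %s (record %d) has implausible width %d nt",
                 gr$mirna_name[bad_w[1L]], bad_w[1L], w[bad_w[1L]]),
         call. = FALSE)
  gr
}

#' Read small-RNA alignments from SAM or BED
#'
#' BED input may carry per-interval collapsed counts in the score column
#' (0 or NA scores count as 1 read). SAM input is converted and read via
#' Rsamtools; unmapped records are dropped and each mapped record counts
#' once.
#'
#' @param path `.bed` or `.sam` file.
#' @return A `GRanges` with a `read_count` metadata column.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    counts <- gr$score
    if (is.null(counts)) counts <- rep(1, length(gr))
    counts[is.na(counts) | counts == 0] <- 1
    S4Vectors::mcols(gr) <- NULL
    gr$read_count <- as.numeric(counts)
    return(gr)
  }
  if (ext %in% c("sam", "bam")) {
    bam <- if (ext == "sam") {
      Rsamtools::asBam(path, file.path(tempdir(),
                                       paste0("aln-", basename(path))),
                       overwrite = TRUE, indexDestination = FALSE)
    } else path
    res <- Rsamtools::scanBam(
      bam,
      param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "qwidth", "strand", "flag"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1L]]
    keep <- !is.na(res$pos)
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(res$rname)[keep],
      ranges = IRanges::IRanges(start = res$pos[keep],
                                width = res$qwidth[keep]),
      strand = as.character(res$strand)[keep])
    gr$read_count <- rep(1, length(gr))
    return(gr)
  }
  stop("unsupported alignment format: .", ext, call. = FALSE)
}

#' Classify aligned reads into isomiR count bins
#'
#' Each read is compared against every same-strand locus it overlaps by at
#' least `min_overlap` of the read's length; among candidates it is assigned
#' to the single nearest locus (smallest absolute 5' offset, ties broken by
#' locus order) so no read is counted twice. Binning is by
#' `(mirna_name, five_prime_offset, length)` where both coordinates are
#' measured from the locus's canonical 5' end, strand-aware. Reads matching
#' no locus contribute only to the mapped total.
#'
#' @param alignments `GRanges` with optional `read_count` column, or a path
#'   accepted by [read_alignments()].
#' @param loci `GRanges` with `mirna_name`, or a path accepted by
#'   [read_loci()].
#' @param min_overlap Minimum overlapping fraction of the read length
#'   (default 0.75).
#' @return data.frame of class `isomir_counts` with columns `mirna`,
#'   `offset5p`, `length`, `raw_count`; attributes `total_mapped` (sum of
#'   all read counts) and `classified` (reads assigned to a locus).
#' @export
classify_reads <- function(alignments, loci, min_overlap = 0.75) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (is.character(loci)) loci <- read_loci(loci)
  counts <- alignments$read_count
  if (is.null(counts)) counts <- rep(1, length(alignments))
  total_mapped <- sum(counts)
  empty <- data.frame(mirna = character(), offset5p = integer(),
                      length = integer(), raw_count = numeric(),
                      stringsAsFactors = FALSE)
  if (length(alignments) == 0L || length(loci) == 0L) {
    attr(empty, "total_mapped") <- total_mapped
    attr(empty, "classified") <- 0
    class(empty) <- c("isomir_counts", "data.frame")
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(alignments, loci)
  if (length(hits) == 0L) {
    attr(empty, "total_mapped") <- total_mapped
    attr(empty, "classified") <- 0
    class(empty) <- c("isomir_counts", "data.frame")
    return(empty)
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  r <- alignments[qi]
  l <- loci[si]
  same_strand <- as.character(BiocGenerics::strand(r)) ==
    as.character(BiocGenerics::strand(l))
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(r), IRanges::ranges(l)))
  frac_ok <- ov / BiocGenerics::width(r) >= min_overlap
  keep <- same_strand & frac_ok
  qi <- qi[keep]; si <- si[keep]; r <- r[keep]; l <- l[keep]
  if (length(qi) == 0L) {
    attr(empty, "total_mapped") <- total_mapped
    attr(empty, "classified") <- 0
    class(empty) <- c("isomir_counts", "data.frame")
    return(empty)
  }
  plus <- as.character(BiocGenerics::strand(l)) == "+"
  offset5p <- ifelse(plus,
                     BiocGenerics::start(r) - BiocGenerics::start(l),
                     BiocGenerics::end(l) - BiocGenerics::end(r))
  len5p <- ifelse(plus,
                  BiocGenerics::end(r) - BiocGenerics::start(l) + 1L,
                  BiocGenerics::end(l) - BiocGenerics::start(r) + 1L)
  # one locus per read: nearest canonical 5' end, then locus order
  ord <- order(qi, abs(offset5p), si)
  first <- !duplicated(qi[ord])
  sel <- ord[first]
  df <- data.frame(mirna = l$mirna_name[sel],
                   offset5p = as.integer(offset5p[sel]),
                   length = as.integer(len5p[sel]),
                   raw_count = counts[qi[sel]],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(raw_count ~ mirna + offset5p + length, df, sum)
  agg <- agg[order(agg$mirna, agg$offset5p, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "total_mapped") <- total_mapped
  attr(agg, "classified") <- sum(df$raw_count)
  class(agg) <- c("isomir_counts", "data.frame")
  agg
}

#' Add reads-per-million normalization to a count table
#'
#' `rpm = raw_count * 1e6 / total_mapped_reads`. The default denominator is
#' all mapped reads of the sample (the table's `total_mapped` attribute);
#' pass `total_mapped_reads` to use another convention, e.g. miRNA-assigned
#' reads only.
#'
#' @param table An `isomir_counts` data.frame.
#' @param total_mapped_reads Denominator; defaults to the table's
#'   `total_mapped` attribute.
#' @return The table with an `rpm` column added.
#' @export
add_rpm <- function(table, total_mapped_reads = attr(table, "total_mapped")) {
  if (is.null(total_mapped_reads) || is.na(total_mapped_reads) ||
      total_mapped_reads <= 0)
    stop("total mapped reads must be > 0", call. = FALSE)
  table$rpm <- table$raw_count * 1e6 / total_mapped_reads
  table
}

#' Normalize counts to a reference small RNA
#'
#' Expresses counts per `per` reads of a reference gene (e.g. a snoRNA),
#' the normalization used for targeted small-RNA sequencing where a global
#' mapped total is not meaningful.
#'
#' @param table An `isomir_counts` data.frame.
#' @param reference_counts Read count of the reference gene in the same
#'   sample (> 0).
#' @param per Reference scale (default 100).
#' @return The table with a `ref_normalized` column added.
#' @export
normalize_to_reference <- function(table, reference_counts, per = 100) {
  if (is.na(reference_counts) || reference_counts <= 0)
    stop("reference counts must be > 0", call. = FALSE)
  table$ref_normalized <- table$raw_count * per / reference_counts
  table
}

#' Per-length isomiR proportions at the canonical 5' end
#'
#' Restricts a count table to `offset5p == 0` rows of one miRNA (the
#' templated 3'-isomiR series) and returns the per-length proportions.
#'
#' @param table An `isomir_counts` data.frame.
#' @param mirna miRNA name.
#' @return Named numeric vector of proportions, names = lengths.
#' @export
length_proportions <- function(table, mirna) {
  rows <- table[table$mirna == mirna & table$offset5p == 0L, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no canonical-5' rows for ", mirna, call. = FALSE)
  stats::setNames(rows$raw_count / sum(rows$raw_count),
                  as.character(rows$length))
}

#' Write an isomiR count table as TSV
#'
#' @param table An `isomir_counts` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isomir_counts <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
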
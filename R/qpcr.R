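# Cq-table ingestion and relative-quantification arithmetic.
#
# Quantification cycles (Cq) are log2-scale template measurements: one PCR
# cycle corresponds to a factor of two. All derived quantities here are the
# standard transforms 2^-dCq (relative amplification against a reference
# Cq) and 2^-ddCq (fold change against a reference gene and a control
# condition). "Undetermined" wells (no threshold crossing) are a first-class
# sentinel, represented as NA internally.

.CQ_MAX <- 45

#' Construct a Cq record
#'
#' One (sample, primer, condition) combination with its technical-replicate
#' quantification cycles. `NA` encodes an undetermined well.
#'
#' @param sample,primer,condition Identifiers (condition e.g. `"NT"` or
#'   `"IFN-b"`).
#' @param replicate_cqs Numeric vector (>= 1 value); each in `(0, 45]` or
#'   `NA` for undetermined.
#' @return Object of class `cq_record`.
#' @export
cq_record <- function(sample, primer, condition = "NT", replicate_cqs) {
  if (length(replicate_cqs) < 1L)
    stop("at least one replicate Cq required", call. = FALSE)
  replicate_cqs <- as.numeric(replicate_cqs)
  num <- replicate_cqs[!is.na(replicate_cqs)]
  if (any(num <= 0 | num > .CQ_MAX))
    stop("numeric Cq values must lie in (0, ", .CQ_MAX, "]", call. = FALSE)
  structure(
    list(sample = sample, primer = primer, condition = condition,
         replicate_cqs = replicate_cqs),
    class = "cq_record"
  )
}

#' Mean quantification cycle of a record
#'
#' Technical replicates are averaged on the Cq (log) scale. A record whose
#' replicates are all undetermined has an undetermined mean (`NA`).
#'
#' @param record A [cq_record()] or numeric vector of replicate Cqs.
#' @return Mean Cq (cycles), or `NA` if all replicates are undetermined.
#' @export
#' @examples
#' mean_cq(cq_record("s1", "F222-21", "NT", c(20, 21)))
mean_cq <- function(record) {
  cqs <- if (inherits(record, "cq_record")) record$replicate_cqs else
    as.numeric(record)
  if (length(cqs) < 1L) stop("empty replicate list", call. = FALSE)
  if (all(is.na(cqs))) return(NA_real_)
  mean(cqs, na.rm = TRUE)
}

#' Relative amplification from a Cq difference
#'
#' `percent = 100 * 2^(reference_cq - cq)`. An undetermined `cq` maps to 0%
#' (and is flagged below threshold); an undetermined reference is an error.
#' `below_threshold` marks values under 0.1%, the annotation used for
#' effectively unamplified pairs.
#'
#' @param cq Measured Cq (cycles) or `NA` (undetermined).
#' @param reference_cq Reference Cq the value is expressed against.
#' @return List with `percent` and `below_threshold`.
#' @export
#' @examples
#' relative_amplification(21, 20)   # 50%
relative_amplification <- function(cq, reference_cq) {
  if (is.na(reference_cq))
    stop("reference Cq is undetermined", call. = FALSE)
  if (is.na(cq))
    return(list(percent = 0, below_threshold = TRUE))
  pct <- 100 * 2^(reference_cq - cq)
  list(percent = pct, below_threshold = pct < 0.1)
}

#' Fold change by the 2^-ddCq method
#'
#' `2^-((Cq_target,treated - Cq_ref,treated) - (Cq_target,control -
#' Cq_ref,control))`, the standard reference-gene-normalised fold change of
#' the target between two conditions. Adding a constant to all four Cqs
#' (e.g. an input-amount shift) leaves the value unchanged.
#'
#' @param target_treated,target_control Mean Cqs of the target assay in the
#'   two conditions.
#' @param reference_treated,reference_control Mean Cqs of the reference
#'   gene (e.g. U6) in the two conditions.
#' @return The fold change (dimensionless, > 0).
#' @export
#' @examples
#' fold_change_ddcq(24, 25, 19, 18)  # ddCq = -2 -> 4
fold_change_ddcq <- function(target_treated, target_control,
                             reference_treated, reference_control) {
  vals <- c(target_treated, target_control, reference_treated,
            reference_control)
  if (any(is.na(vals)))
    stop("all four mean Cqs must be determined", call. = FALSE)
  ddcq <- (target_treated - reference_treated) -
    (target_control - reference_control)
  2^(-ddcq)
}

#' Row-normalize an efficiency or percentage matrix
#'
#' Scales each row so that its reference entry reads 100%, the per-template
#' normalization of cross-amplification heat maps. Values below 0.1 are
#' flagged `#`; `clip` limits the display at 100.
#'
#' @param mat Numeric matrix (rows = templates / conditions).
#' @param reference_cols Integer or character vector, one reference column
#'   per row (recycled if length 1).
#' @param clip Clip at 100 (default `FALSE`).
#' @return List with `percent` matrix and `flag` character matrix.
#' @export
normalize_rows <- function(mat, reference_cols, clip = FALSE) {
  mat <- as.matrix(mat)
  if (is.character(reference_cols))
    reference_cols <- match(reference_cols, colnames(mat))
  reference_cols <- rep_len(as.integer(reference_cols), nrow(mat))
  if (any(is.na(reference_cols)))
    stop("unknown reference column", call. = FALSE)
  ref <- mat[cbind(seq_len(nrow(mat)), reference_cols)]
  if (any(is.na(ref)) || any(ref <= 0))
    stop("each row's reference entry must be positive", call. = FALSE)
  percent <- 100 * mat / ref
  flag <- matrix(ifelse(percent < 0.1, "#", ""), nrow(mat),
                 dimnames = dimnames(mat))
  if (clip) percent <- pmin(percent, 100)
  list(percent = percent, flag = flag)
}

#' Read a Cq table (CSV/TSV)
#'
#' Expected header: `sample, primer, condition, cq1, cq2, ...` (any number
#' of replicate columns; `condition` optional). `Undetermined`, `NA` and
#' empty cells parse as the undetermined sentinel. The separator is taken
#' from the extension (`.csv` comma, otherwise tab) unless given.
#'
#' @param path Input file.
#' @param sep Field separator, or `NULL` to infer from the extension.
#' @return List of [cq_record()]s, in row order.
#' @export
read_cq_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) return(list())
  cols <- tolower(names(df))
  need <- c("sample", "primer")
  if (!all(need %in% cols))
    stop("Cq table must have 'sample' and 'primer' columns", call. = FALSE)
  cq_cols <- grep("^cq", cols)
  if (!length(cq_cols))
    stop("Cq table has no cq columns (cq1, cq2, ...)", call. = FALSE)
  cond_col <- match("condition", cols)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    raw <- unlist(df[i, cq_cols], use.names = FALSE)
    raw <- trimws(raw)
    vals <- suppressWarnings(as.numeric(raw))
    undet <- toupper(raw) %in% c("UNDETERMINED", "NA", "")
    if (any(is.na(vals) & !undet))
      stop(sprintf("line %d: unparseable Cq value '%s'", i + 1L,
                   raw[which(is.na(vals) & !undet)[1L]]), call. = FALSE)
    vals[undet] <- NA_real_
    vals <- vals[raw != ""]  # empty cells are absent replicates, not wells
    rec <- tryCatch(
      cq_record(df[i, match("sample", cols)], df[i, match("primer", cols)],
                if (!is.na(cond_col)) df[i, cond_col] else "NT",
                vals),
      error = function(e)
        stop(sprintf("line %d: %s", i + 1L, conditionMessage(e)),
             call. = FALSE))
    out[[i]] <- rec
  }
  out
}

#' Write Cq records back to a table
#'
#' @param records List of [cq_record()]s.
#' @param path Output file; extension selects CSV vs TSV.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nrep <- max(vapply(records, function(r) length(r$replicate_cqs),
                     integer(1L)), 0L)
  rows <- lapply(records, function(r) {
    cqs <- r$replicate_cqs
    length(cqs) <- nrep
    cqt <- ifelse(is.na(cqs), "Undetermined", format(cqs))
    c(sample = r$sample, primer = r$primer, condition = r$condition,
      stats::setNames(cqt, paste0("cq", seq_len(nrep))))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
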
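# Isoform-targeted forward-primer design for polyadenylation RT-qPCR.
#
# A forward primer for a templated 3'-isomiR of length L is the DNA of the
# family prefix of length L, optionally extended with a short 3' adenosine
# run (the "A-tail"). Because the polyadenylation step appends poly(A) to
# every template before reverse transcription, a tailed primer base-pairs
# into the poly(A)-derived region of cDNAs from isoforms of length <= L but
# mismatches the genuine 3' bases of longer isoforms, suppressing their
# amplification.

#' Construct an isoform-targeted forward primer
#'
#' @param family A [mirna_family()].
#' @param target_length Length (nt) of the targeted templated isoform; must
#'   not exceed the family reference length.
#' @param a_tail Number of adenosines appended at the 3' end (0, 2, 4 or 5
#'   in routine use; any non-negative count accepted).
#' @param stem Optional short name used in the primer identifier; defaults
#'   to the family's `stem` attribute, else the family name with a `miR-`
#'   prefix dropped.
#' @return Object of class `forward_primer` with fields `name`, `core`,
#'   `a_tail`, `target_length`, `family` and the full `sequence`
#'   (`core` followed by the A-tail).
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' design_forward_primer(fam, 21, a_tail = 4)
design_forward_primer <- function(family, target_length, a_tail = 0L,
                                  stem = NULL) {
  stopifnot(inherits(family, "mirna_family"))
  target_length <- as.integer(target_length)
  a_tail <- as.integer(a_tail)
  ref_len <- nchar(family$reference_sequence)
  if (target_length < 1L || target_length > ref_len)
    stop(sprintf("target_length %d outside [1, %d] for family '%s'",
                 target_length, ref_len, family$name), call. = FALSE)
  if (a_tail < 0L) stop("a_tail must be >= 0", call. = FALSE)
  if (is.null(stem)) {
    stem <- attr(family, "stem")
    if (is.null(stem)) stem <- sub("^miR-", "", family$name)
  }
  core <- rna_to_dna(substr(family$reference_sequence, 1L, target_length))
  name <- sprintf("F%s-%d", stem, target_length)
  if (a_tail > 0L) name <- sprintf("%s-%dA", name, a_tail)
  structure(
    list(name = name, core = core,
         sequence = paste0(core, strrep("A", a_tail)),
         a_tail = a_tail, target_length = target_length,
         family = family$name),
    class = "forward_primer"
  )
}

#' Wrap an arbitrary DNA string as a forward primer
#'
#' Escape hatch for primers not derivable from a family reference (e.g. a
#' published primer being re-analysed). `a_tail` is inferred as the trailing
#' adenosine run unless given.
#'
#' @param name Identifier.
#' @param sequence Full primer DNA, 5'->3'.
#' @param a_tail 3' A-tail length; `NA` (default) infers the trailing A run.
#' @return A `forward_primer`.
#' @export
forward_primer <- function(name, sequence, a_tail = NA) {
  seq <- dna(sequence)
  if (is.na(a_tail)) {
    m <- regmatches(seq, regexpr("A*$", seq))
    a_tail <- nchar(m)
  }
  a_tail <- as.integer(a_tail)
  core <- substr(seq, 1L, nchar(seq) - a_tail)
  structure(
    list(name = name, core = core, sequence = seq, a_tail = a_tail,
         target_length = nchar(core), family = NA_character_),
    class = "forward_primer"
  )
}

#' @export
print.forward_primer <- function(x, ...) {
  tail_txt <- if (x$a_tail > 0) sprintf(" + %dA tail", x$a_tail) else ""
  cat(sprintf("<forward_primer> %s  (%d nt target%s)\n  5'-%s-3'\n",
              x$name, x$target_length, tail_txt, x$sequence))
  invisible(x)
}

#' Adenosine content immediately 3' of a target prefix
#'
#' The discriminating power of an A-tailed primer comes from the mismatch
#' between its tail and the template bases just downstream of the targeted
#' prefix. If those bases are themselves A-rich, the tail partly pairs and
#' blocking is weakened. This computes the adenosine fraction of the
#' `window` reference bases immediately 3' of position `target_length`;
#' positions past the reference end are poly(A)-tail positions and count
#' as A.
#'
#' @param family A [mirna_family()].
#' @param target_length Targeted isoform length.
#' @param window Number of downstream bases inspected (default 4, matching
#'   the 4A tail).
#' @param warn_at Fraction at or above which an `A_RICH_3P_CONTEXT` warning
#'   is raised (default 0.5).
#' @return List with `fraction` and `warning` (the warning code or `NULL`).
#'   No warning is raised when `target_length` equals the reference length:
#'   there is no longer isoform left to discriminate.
#' @export
a_rich_context <- function(family, target_length, window = 4L,
                           warn_at = 0.5) {
  stopifnot(inherits(family, "mirna_family"), window >= 1L)
  target_length <- as.integer(target_length)
  ref <- family$reference_sequence
  ref_len <- nchar(ref)
  if (target_length > ref_len)
    stop("target_length exceeds reference length", call. = FALSE)
  pos <- seq.int(target_length + 1L, target_length + window)
  bases <- ifelse(pos <= ref_len,
                  substring(ref, pos, pos),
                  "A")  # poly(A) tail
  frac <- mean(bases == "A")
  warning_code <- NULL
  if (frac >= warn_at && target_length < ref_len)
    warning_code <- "A_RICH_3P_CONTEXT"
  list(fraction = frac, warning = warning_code)
}

#' Recommend an A-tail for a target isoform length
#'
#' Encodes the design rule arising from the assay's selectivity behaviour:
#' primers for short isoforms (19-21 nt) should carry the 4A tail; primers
#' for long isoforms (23 nt and above) should be unmodified, since tailing a
#' long primer lets its A-run pair with the poly(A) of shorter isoforms and
#' *increases* their off-target amplification. 22 nt targets behave like
#' short ones and get the tail together with an `AMBIGUOUS_LENGTH_22`
#' warning. The A-rich 3'-context check is always run and its warning
#' attached.
#'
#' @inheritParams a_rich_context
#' @return Object of class `design_recommendation` with `target_length`,
#'   `recommended_tail` (0 or 4), `rationale` and `warnings` (character
#'   vector, possibly empty).
#' @export
recommend_design <- function(family, target_length, window = 4L,
                             warn_at = 0.5) {
  target_length <- as.integer(target_length)
  if (target_length <= 21L) {
    tail <- 4L
    rationale <- "short target (<=21 nt): 4A tail suppresses longer isoforms"
    warnings <- character()
  } else if (target_length == 22L) {
    tail <- 4L
    rationale <- "22 nt target treated as short; selectivity gain is smaller"
    warnings <- "AMBIGUOUS_LENGTH_22"
  } else {
    tail <- 0L
    rationale <- paste0("long target (>=23 nt): unmodified primer; a tail ",
                        "would pair with poly(A) of shorter isoforms")
    warnings <- character()
  }
  ctx <- a_rich_context(family, target_length, window = window,
                        warn_at = warn_at)
  if (!is.null(ctx$warning) && tail > 0L)
    warnings <- c(warnings, ctx$warning)
  structure(
    list(target_length = target_length, recommended_tail = tail,
         rationale = rationale, warnings = warnings,
         a_rich_fraction = ctx$fraction),
    class = "design_recommendation"
  )
}

#' @export
print.design_recommendation <- function(x, ...) {
  cat(sprintf("<design_recommendation> %d nt target -> tail %dA\n  %s\n",
              x$target_length, x$recommended_tail, x$rationale))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Primer melting temperature
#'
#' `"wallace"` (default) is the Wallace rule 2(A+T) + 4(G+C) degrees C,
#' adequate for the short primers used here. `"nn"` is a nearest-neighbour
#' estimate using unified dinucleotide thermodynamic parameters
#' (dH kcal/mol, dS cal/(mol K)) with a simple 50 mM monovalent salt
#' correction -- useful for comparing primers of different length.
#'
#' @param primer A `forward_primer` or a DNA string.
#' @param method `"wallace"` or `"nn"`.
#' @param part `"full"` (core + tail, default) or `"core"`.
#' @param primer_conc Primer concentration (M), nearest-neighbour method
#'   only.
#' @param na_conc Monovalent cation concentration (M), nearest-neighbour
#'   method only.
#' @return Temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AAAA")          # 8
#' melting_temperature("GGCC")          # 16
melting_temperature <- function(primer, method = c("wallace", "nn"),
                                part = c("full", "core"),
                                primer_conc = 2.5e-7, na_conc = 0.05) {
  method <- match.arg(method)
  part <- match.arg(part)
  seq <- if (inherits(primer, "forward_primer")) {
    if (part == "core") primer$core else primer$sequence
  } else dna(primer)
  if (!nzchar(seq)) stop("empty sequence has no melting temperature",
                         call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (method == "wallace") {
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  }
  # unified nearest-neighbour parameters (two-state duplex model)
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  canon <- function(d) {
    if (d %in% names(dH)) d else
      paste(rev(chartr("ACGT", "TGCA", strsplit(d, "")[[1L]])), collapse = "")
  }
  if (length(chars) < 2L)
    stop("nearest-neighbour Tm needs at least 2 bases", call. = FALSE)
  dints <- vapply(seq_len(length(chars) - 1L), function(i)
    canon(paste0(chars[i], chars[i + 1L])), character(1L))
  h <- sum(dH[dints]) + 0.2               # initiation
  s <- sum(dS[dints]) - 5.7
  ends <- chars[c(1L, length(chars))]
  h <- h + 2.2 * sum(ends %in% c("A", "T"))
  s <- s + 6.9 * sum(ends %in% c("A", "T"))
  tm_k <- (h * 1000) / (s + 1.987 * log(primer_conc / 4))
  tm_k + 16.6 * log10(na_conc) - 273.15
}

#' Design a primer panel across isoform lengths
#'
#' One primer per requested length. With `tail = "auto"` each primer's
#' A-tail follows [recommend_design()]; a fixed number applies that tail to
#' every primer.
#'
#' @param family A [mirna_family()].
#' @param lengths Integer vector of target lengths.
#' @param tail `"auto"` or a fixed tail count (0, 2, 4, 5, ...).
#' @param tm_method Passed to [melting_temperature()].
#' @return data.frame of class `primer_panel`: `name`, `sequence`,
#'   `target_length`, `a_tail`, `tm_full`, `tm_core`, `warnings`
#'   (comma-separated, empty string if none).
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' design_panel(fam, 21:25)
design_panel <- function(family, lengths, tail = "auto",
                         tm_method = "wallace") {
  lengths <- as.integer(lengths)
  rows <- lapply(lengths, function(L) {
    rec <- recommend_design(family, L)
    at <- if (identical(tail, "auto")) rec$recommended_tail
          else as.integer(tail)
    p <- design_forward_primer(family, L, a_tail = at)
    data.frame(
      name = p$name, sequence = p$sequence, target_length = L,
      a_tail = at,
      tm_full = melting_temperature(p, method = tm_method, part = "full"),
      tm_core = melting_temperature(p, method = tm_method, part = "core"),
      warnings = paste(rec$warnings, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), sequence = character(),
               target_length = integer(), a_tail = integer(),
               tm_full = numeric(), tm_core = numeric(),
               warnings = character(), stringsAsFactors = FALSE)
  class(out) <- c("primer_panel", "data.frame")
  out
}

#' Convert panel rows back to forward_primer objects
#'
#' @param panel A `primer_panel` data.frame.
#' @return List of `forward_primer` objects.
#' @export
panel_primers <- function(panel) {
  lapply(seq_len(nrow(panel)), function(i)
    forward_primer(panel$name[i], panel$sequence[i],
                   a_tail = panel$a_tail[i]))
}
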
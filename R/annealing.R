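# Sequence-level model of forward-primer annealing to a polyadenylated,
# reverse-transcribed template.
#
# After poly(A) tailing and oligo-dT-primed reverse transcription, the cDNA
# of a template RNA is the antisense copy of (sense RNA + poly(A)). The
# forward primer hybridises to that cDNA, so primer-vs-cDNA complementarity
# is exactly primer-vs-(sense DNA + A-run) identity. The model therefore
# compares the primer, anchored with its 5' end at template position 1 (all
# assay primers share the family's canonical 5' start), against the
# A-extended sense template, position by position.
#
# Amplification requires a paired primer 3' terminus: 5'->3' polymerases
# cannot extend a primer whose terminal bases are unpaired. The empirical
# rules encoded here are (i) two or more consecutive terminal mismatches
# block amplification; (ii) a heavily mismatched 3'-terminal window (3+ of
# the last 4 bases) blocks; (iii) a single terminal mismatch, or 2 window
# mismatches, reduce; (iv) a sufficient fraction of internal mismatches
# reduces (short primers discriminate central mismatches, long ones do not);
# (v) otherwise the pair amplifies.

#' Build a poly(A)-extended sense template
#'
#' @param x RNA string or a named element of [table1_rnas()]; a
#'   `mirna_family` is accepted and contributes its reference sequence.
#' @param tail_length Number of modelled poly(A) positions appended
#'   (default 10). Classifications are invariant once the tail covers the
#'   primer's overhang: `tail_length >= a_tail + window` suffices.
#' @param name Template identifier; defaults to the deparsed input or the
#'   family name.
#' @return Object of class `sense_template` with `name`, `core` (sense DNA)
#'   and the extended `sequence`.
#' @export
#' @examples
#' extend_template("AGCUACAUCUGGCUACUGGGU", tail_length = 4)
extend_template <- function(x, tail_length = 10L, name = NULL) {
  if (inherits(x, "mirna_family")) {
    if (is.null(name)) name <- x$name
    x <- x$reference_sequence
  }
  if (is.null(name)) name <- "template"
  tail_length <- as.integer(tail_length)
  if (tail_length < 0L) stop("tail_length must be >= 0", call. = FALSE)
  core <- rna_to_dna(x)
  structure(
    list(name = name, core = core, tail_length = tail_length,
         sequence = paste0(core, strrep("A", tail_length))),
    class = "sense_template"
  )
}

#' @export
print.sense_template <- function(x, ...) {
  cat(sprintf("<sense_template> %s  (%d nt core + %d A)\n  5'-%s-3'\n",
              x$name, nchar(x$core), x$tail_length, x$sequence))
  invisible(x)
}

#' Efficiency rules for annealing classification
#'
#' The model's decision thresholds and the per-class relative efficiencies.
#' Classes are qualitative; the efficiencies are a calibrated mapping used
#' by the simulator and matrix views, chosen so that `blocked` pairs fall
#' under a 0.1% relative-amplification annotation threshold and `reduced`
#' pairs sit in the regime of 60-90% amplification decreases.
#'
#' @param window_size 3'-terminal window inspected for mismatches
#'   (default 4).
#' @param eff_amplified,eff_reduced,eff_blocked Relative efficiencies per
#'   class; must satisfy `0 <= eff_blocked < eff_reduced <= eff_amplified
#'   <= 1` and `eff_blocked < 0.001`.
#' @param internal_fraction_threshold Internal mismatch fraction (over the
#'   whole primer length) at or above which amplification is reduced
#'   (default 0.09: 2 central mismatches reduce a 22 nt primer but not a
#'   27 nt one).
#' @return Object of class `efficiency_rules`.
#' @export
efficiency_rules <- function(window_size = 4L, eff_amplified = 1.0,
                             eff_reduced = 0.1, eff_blocked = 5e-4,
                             internal_fraction_threshold = 0.09) {
  stopifnot(window_size >= 1L,
            eff_blocked >= 0, eff_blocked < eff_reduced,
            eff_reduced < eff_amplified, eff_amplified <= 1)
  if (eff_blocked >= 0.001)
    stop("eff_blocked must be < 0.001 (below the '<0.1%' annotation)",
         call. = FALSE)
  structure(
    list(window_size = as.integer(window_size),
         eff_amplified = eff_amplified, eff_reduced = eff_reduced,
         eff_blocked = eff_blocked,
         internal_fraction_threshold = internal_fraction_threshold),
    class = "efficiency_rules"
  )
}

#' @export
print.efficiency_rules <- function(x, ...) {
  cat(sprintf(paste0("<efficiency_rules> window %d nt; eff ",
                     "amplified/reduced/blocked = %g/%g/%g; internal ",
                     "fraction threshold %g\n"),
              x$window_size, x$eff_amplified, x$eff_reduced, x$eff_blocked,
              x$internal_fraction_threshold))
  invisible(x)
}

#' Annealing profile of a primer against an extended template
#'
#' Position-wise identity with the primer 5' end anchored at template
#' position 1. Summaries: `terminal_mismatch_run` (consecutive mismatches
#' ending at the primer 3' terminus), `window_mismatches` (mismatches among
#' the 3'-terminal `window` primer bases) and `internal_mismatches`
#' (mismatches 5' of that window), with `internal_fraction` =
#' internal mismatches / primer length.
#'
#' @param primer A `forward_primer` (or DNA string).
#' @param template A `sense_template` (or RNA string, extended with the
#'   default tail).
#' @param window 3'-terminal window size (default 4).
#' @return Object of class `annealing_profile`.
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' p <- design_forward_primer(fam, 21, a_tail = 4)
#' t21 <- extend_template("AGCUACAUCUGGCUACUGGGU", name = "miR-222-21 nt")
#' anneal_profile(p, t21)
anneal_profile <- function(primer, template, window = 4L) {
  if (!inherits(primer, "forward_primer"))
    primer <- forward_primer("primer", primer)
  if (!inherits(template, "sense_template"))
    template <- extend_template(template)
  pseq <- strsplit(primer$sequence, "", fixed = TRUE)[[1L]]
  tseq <- strsplit(template$sequence, "", fixed = TRUE)[[1L]]
  n <- length(pseq)
  if (n > length(tseq))
    stop(sprintf("primer %s (%d nt) extends past template %s (%d nt incl. tail)",
                 primer$name, n, template$name, length(tseq)), call. = FALSE)
  match_vector <- pseq == tseq[seq_len(n)]
  window <- min(as.integer(window), n)
  mism <- !match_vector
  run <- 0L
  for (i in rev(seq_len(n))) {
    if (mism[i]) run <- run + 1L else break
  }
  win_idx <- seq.int(n - window + 1L, n)
  window_mismatches <- sum(mism[win_idx])
  internal_mismatches <- sum(mism[-win_idx])
  structure(
    list(primer_name = primer$name, template_name = template$name,
         match_vector = match_vector,
         terminal_mismatch_run = run,
         window_size = window,
         window_mismatches = window_mismatches,
         internal_mismatches = internal_mismatches,
         internal_fraction = internal_mismatches / n,
         primer_length = n),
    class = "annealing_profile"
  )
}

#' @export
print.annealing_profile <- function(x, ...) {
  cat(sprintf("<annealing_profile> %s vs %s\n", x$primer_name,
              x$template_name))
  cat("  ", paste(ifelse(x$match_vector, "|", "x"), collapse = ""), "\n",
      sep = "")
  cat(sprintf("  terminal run %d; window (%d nt) mismatches %d; internal %d (fraction %.3f)\n",
              x$terminal_mismatch_run, x$window_size, x$window_mismatches,
              x$internal_mismatches, x$internal_fraction))
  invisible(x)
}

#' Classify an annealing profile
#'
#' Decision cascade: (1) terminal mismatch run >= 2 -> `blocked`;
#' (2) window mismatches >= 3 -> `blocked`; (3) terminal run of exactly 1 or
#' 2 window mismatches -> `reduced`; (4) internal mismatch fraction at or
#' above the threshold -> `reduced`; (5) otherwise `amplified`. The class is
#' mapped to a relative efficiency via `rules`.
#'
#' @param profile An [anneal_profile()] result.
#' @param rules An [efficiency_rules()] object.
#' @return List with `class` (`"amplified"`, `"reduced"` or `"blocked"`)
#'   and `efficiency`.
#' @export
classify_annealing <- function(profile, rules = efficiency_rules()) {
  stopifnot(inherits(profile, "annealing_profile"),
            inherits(rules, "efficiency_rules"))
  cls <-
    if (profile$terminal_mismatch_run >= 2L) "blocked"
    else if (profile$window_mismatches >= 3L) "blocked"
    else if (profile$terminal_mismatch_run == 1L ||
             profile$window_mismatches == 2L) "reduced"
    else if (profile$internal_fraction >=
             rules$internal_fraction_threshold) "reduced"
    else "amplified"
  eff <- switch(cls, amplified = rules$eff_amplified,
                reduced = rules$eff_reduced, blocked = rules$eff_blocked)
  list(class = cls, efficiency = eff)
}

#' Predict amplification of one primer/template pair
#'
#' Convenience wrapper: profile then classify.
#'
#' @inheritParams anneal_profile
#' @param rules An [efficiency_rules()].
#' @return List with `class`, `efficiency` and the `profile`.
#' @export
predict_amplification <- function(primer, template,
                                  rules = efficiency_rules()) {
  prof <- anneal_profile(primer, template, window = rules$window_size)
  c(classify_annealing(prof, rules), list(profile = prof))
}

#' Cross-amplification matrix of a primer panel against templates
#'
#' Computes the predicted class and efficiency for every primer x template
#' pair, plus a row-normalized percentage view in the layout of a
#' per-template heat map: rows are templates, columns primers, and each row
#' is scaled to 100% at its on-target primer (the primer whose target length
#' equals the template core length, unless `reference_primers` names one per
#' row). Cells below 0.1% are flagged `#`.
#'
#' @param primers List of `forward_primer` objects (or named character
#'   vector of primer DNA).
#' @param templates List of `sense_template` objects (or named character
#'   vector of RNA sequences, extended with the default tail).
#' @param rules An [efficiency_rules()].
#' @param reference_primers Optional character vector, one primer name per
#'   template row, overriding the on-target match.
#' @param clip Clip the normalized view at 100 (the heat-map display rule);
#'   default `TRUE`.
#' @return Object of class `cross_amplification`: a list with matrices
#'   `class`, `efficiency`, `percent` (row-normalized), `flag` (`"#"` where
#'   percent < 0.1).
#' @export
cross_amplification_matrix <- function(primers, templates,
                                       rules = efficiency_rules(),
                                       reference_primers = NULL,
                                       clip = TRUE) {
  if (is.character(primers))
    primers <- lapply(names(primers), function(n)
      forward_primer(n, primers[[n]]))
  if (is.character(templates))
    templates <- lapply(names(templates), function(n)
      extend_template(templates[[n]], name = n))
  if (!length(primers) || !length(templates))
    stop("need at least one primer and one template", call. = FALSE)
  pn <- vapply(primers, `[[`, character(1L), "name")
  tn <- vapply(templates, `[[`, character(1L), "name")
  eff <- matrix(NA_real_, length(templates), length(primers),
                dimnames = list(template = tn, primer = pn))
  cls <- matrix(NA_character_, length(templates), length(primers),
                dimnames = dimnames(eff))
  for (i in seq_along(templates)) {
    for (j in seq_along(primers)) {
      res <- predict_amplification(primers[[j]], templates[[i]], rules)
      eff[i, j] <- res$efficiency
      cls[i, j] <- res$class
    }
  }
  # per-row reference: explicit, else the on-target primer for the row
  ref_idx <- integer(length(templates))
  for (i in seq_along(templates)) {
    if (!is.null(reference_primers)) {
      ref_idx[i] <- match(reference_primers[i], pn)
    } else {
      core_len <- nchar(templates[[i]]$core)
      tl <- vapply(primers, `[[`, integer(1L), "target_length")
      at <- vapply(primers, `[[`, integer(1L), "a_tail")
      hit <- which(tl == core_len)
      if (length(hit) > 1L) hit <- hit[order(at[hit])][1L]  # prefer untailed
      ref_idx[i] <- if (length(hit)) hit else NA_integer_
    }
    if (is.na(ref_idx[i]))
      stop(sprintf("no on-target primer for template '%s'; supply reference_primers",
                   tn[i]), call. = FALSE)
  }
  ref_eff <- eff[cbind(seq_along(templates), ref_idx)]
  if (any(ref_eff <= 0))
    stop("reference efficiency is zero for at least one row", call. = FALSE)
  percent <- 100 * eff / ref_eff
  flag <- matrix(ifelse(percent < 0.1, "#", ""), nrow(percent),
                 dimnames = dimnames(eff))
  if (clip) percent <- pmin(percent, 100)
  structure(
    list(class = cls, efficiency = eff, percent = percent, flag = flag,
         reference_primer = pn[ref_idx], rules = rules),
    class = "cross_amplification"
  )
}

#' @export
print.cross_amplification <- function(x, digits = 3, ...) {
  cat("<cross_amplification>", nrow(x$class), "templates x",
      ncol(x$class), "primers\n")
  shown <- matrix(paste0(format(round(x$percent, 1)), ifelse(x$flag == "#", " #", "")),
                  nrow(x$percent), dimnames = dimnames(x$percent))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Heat-map display of a cross-amplification matrix
#'
#' Base-graphics image of the row-normalized percentages (white = not
#' amplified, red = 100% or more), with `#` marking cells below 0.1%.
#'
#' @param x A `cross_amplification` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cross_amplification <- function(x, ...) {
  m <- x$percent
  op <- graphics::par(mar = c(6, 7, 2, 2))
  on.exit(graphics::par(op))
  pal <- grDevices::colorRampPalette(c("white", "red"))(100)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(0, 100), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  fl <- x$flag[rev(seq_len(nrow(m))), , drop = FALSE]
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (fl[i, j] == "#") graphics::text(j, i, "#", cex = 0.8)
  invisible(x)
}

#' Write a cross-amplification matrix as TSV
#'
#' Long format: template, primer, class, efficiency, percent, flag.
#'
#' @param x A `cross_amplification` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cross_amplification <- function(x, path) {
  long <- expand.grid(template = rownames(x$class),
                      primer = colnames(x$class),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$class <- as.vector(x$class)
  long$efficiency <- as.vector(x$efficiency)
  long$percent <- as.vector(x$percent)
  long$flag <- as.vector(x$flag)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
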
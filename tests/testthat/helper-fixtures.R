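# Shared fixtures built in code.

fams <- fixture_families()
rnas <- table1_rnas()
primers <- table2_primers()

# All panel primers regenerable from a panel RNA reference: everything but
# the two MySEQ sequencing primers and the three miR-199a primers (whose
# reference RNA is not part of the synthetic panel).
regenerable_primer_names <- function() {
  unlist(lapply(names(fams), function(fn) {
    stem <- attr(fams[[fn]], "stem")
    grep(sprintf("^F%s-[0-9]+(-[0-9]A)?$", stem), names(primers),
         value = TRUE)
  }), use.names = FALSE)
}

# Parse "F<stem>-<len>[-<k>A]" into its components relative to a family.
parse_primer_name <- function(nm, stem) {
  rest <- sub(sprintf("^F%s-", stem), "", nm)
  parts <- strsplit(rest, "-", fixed = TRUE)[[1L]]
  list(target_length = as.integer(parts[1L]),
       a_tail = if (length(parts) > 1L)
         as.integer(sub("A$", "", parts[2L])) else 0L)
}

# A single-locus GRanges for simulations and counting tests.
make_locus <- function(name = "miR-222", chrom = "chr1", start = 1001L,
                       len = 25L, strand = "+") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, width = len),
                               strand = strand)
  gr$mirna_name <- name
  gr
}

# Mirror a GRanges through a genome of length G (reverse-complement world).
mirror_granges <- function(gr, genome_length) {
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  new_start <- genome_length - e + 1L
  new_end <- genome_length - s + 1L
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(new_start, new_end),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "+", "-", "+"))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# Independent brute-force classifier used as oracle in the annealing tests:
# re-derives the class from the raw match vector alone, written as plain
# rule lookups with no shared code path with classify_annealing().
oracle_class <- function(primer_seq, template_seq, window = 4L,
                         internal_threshold = 0.09) {
  p <- strsplit(primer_seq, "")[[1L]]
  t <- strsplit(template_seq, "")[[1L]][seq_along(p)]
  mism <- p != t
  n <- length(p)
  run <- 0L
  i <- n
  while (i >= 1L && mism[i]) { run <- run + 1L; i <- i - 1L }
  w <- min(window, n)
  wm <- sum(mism[(n - w + 1L):n])
  im <- sum(mism) - wm
  if (run >= 2L) return("blocked")
  if (wm >= 3L) return("blocked")
  if (run == 1L || wm == 2L) return("reduced")
  if (im / n >= internal_threshold) return("reduced")
  "amplified"
}

eff_of <- function(class, rules = efficiency_rules()) {
  switch(class, amplified = rules$eff_amplified,
         reduced = rules$eff_reduced, blocked = rules$eff_blocked)
}
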
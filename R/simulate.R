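# Seeded generators of isomiR read sets and Cq tables.
#
# The read generator emulates the isomiR stoichiometry seen in fibroblast
# small RNA-seq: within a family, >22 nt isoforms are roughly an order of
# magnitude more abundant than the 20-22 nt ones, and type-I interferon
# stimulation depletes the long isoforms while mildly inducing the short
# ones. The Cq generator pushes per-isoform abundances through the
# annealing model's efficiency matrix, so a primer's signal is the
# efficiency-weighted sum over all isoforms it cross-amplifies -- the
# mechanism by which abundant long isoforms mask changes in rare short ones.

#' Simulation configuration
#'
#' @param total_reads Reads to draw per read-set simulation.
#' @param seed Integer seed; mandatory for stochastic runs.
#' @param cq_intercept Cq at unit signal (cycles, default 35).
#' @param cq_noise_sd SD of Gaussian Cq noise per replicate (cycles,
#'   default 0.15, a typical technical-duplicate scatter).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(total_reads = 1e5, seed = NULL, cq_intercept = 35,
                       cq_noise_sd = 0.15) {
  stopifnot(total_reads > 0)
  structure(
    list(total_reads = total_reads, seed = seed,
         cq_intercept = cq_intercept, cq_noise_sd = cq_noise_sd),
    class = "sim_config"
  )
}

#' Build an isomiR stoichiometry profile
#'
#' @param family Family name.
#' @param abundances Named numeric vector: names are isoform lengths (nt),
#'   values are abundances in arbitrary linear units (>= 0, not all zero).
#' @param condition Condition label (default `"NT"`).
#' @return Object of class `stoichiometry_profile`.
#' @export
stoichiometry_profile <- function(family, abundances, condition = "NT") {
  abundances <- stats::setNames(as.numeric(abundances), names(abundances))
  if (any(abundances < 0) || all(abundances == 0))
    stop("abundances must be >= 0 and not all zero", call. = FALSE)
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("abundances must be named by isoform length", call. = FALSE)
  structure(
    list(family = family, abundances = abundances, condition = condition),
    class = "stoichiometry_profile"
  )
}

#' @export
print.stoichiometry_profile <- function(x, ...) {
  cat(sprintf("<stoichiometry_profile> %s [%s]\n", x$family, x$condition))
  print(x$abundances)
  invisible(x)
}

#' Default untreated / interferon-shifted stoichiometry profiles
#'
#' The untreated (NT) profile covers isoform lengths from
#' `max(19, reference - 4)` up to the family reference length, with
#' abundance `long_abundance` (default 10) for isoforms >= 23 nt and
#' `short_abundance` (default 1) for shorter ones -- the order-of-magnitude
#' gap between long and short isoforms. The IFN profile scales the long
#' isoforms by `ifn_long_scale` (default 0.3, depletion) and the short ones
#' by `ifn_short_scale` (default 1.5, mild induction).
#'
#' @param family A [mirna_family()] with reference >= 24 nt.
#' @param short_abundance,long_abundance NT abundances for <=22 nt and
#'   >=23 nt isoforms.
#' @param ifn_short_scale,ifn_long_scale IFN condition scale factors.
#' @param lengths Isoform lengths modelled; default
#'   `max(19, ref-4) .. ref`.
#' @return List with elements `NT` and `IFN`, each a
#'   [stoichiometry_profile()].
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' default_profiles(fam)$NT
default_profiles <- function(family, short_abundance = 1,
                             long_abundance = 10, ifn_short_scale = 1.5,
                             ifn_long_scale = 0.3, lengths = NULL) {
  stopifnot(inherits(family, "mirna_family"))
  ref_len <- nchar(family$reference_sequence)
  if (ref_len < 24L)
    stop("family reference must be >= 24 nt for the default profiles",
         call. = FALSE)
  if (is.null(lengths)) lengths <- seq.int(max(19L, ref_len - 4L), ref_len)
  is_long <- lengths >= 23L
  nt <- ifelse(is_long, long_abundance, short_abundance)
  ifn <- nt * ifelse(is_long, ifn_long_scale, ifn_short_scale)
  list(
    NT = stoichiometry_profile(family$name,
                               stats::setNames(nt, lengths), "NT"),
    IFN = stoichiometry_profile(family$name,
                                stats::setNames(ifn, lengths), "IFN")
  )
}

#' Simulate an aligned isomiR read set
#'
#' Draws `config$total_reads` reads multinomially over the profile's
#' isoform lengths (probabilities proportional to abundances) and places
#' each at the family locus with 5' offset 0 and the drawn length,
#' strand-aware. In `exact` mode counts are the rounded expected values
#' (largest-remainder apportionment, so they sum to the total) and no
#' randomness is used.
#'
#' @param profile A [stoichiometry_profile()].
#' @param loci `GRanges` with `mirna_name` (see [read_loci()]); the locus
#'   whose name equals the profile family is used.
#' @param config A [sim_config()]; `seed` required unless `exact`.
#' @param exact Logical; use expected counts instead of sampling.
#' @return `GRanges` of collapsed reads with a `read_count` column;
#'   attribute `total_mapped` equals `config$total_reads`.
#' @export
simulate_reads <- function(profile, loci, config = sim_config(),
                           exact = FALSE) {
  stopifnot(inherits(profile, "stoichiometry_profile"))
  if (is.character(loci)) loci <- read_loci(loci)
  li <- which(loci$mirna_name == profile$family)
  if (!length(li))
    stop("no locus named '", profile$family, "'", call. = FALSE)
  locus <- loci[li[1L]]
  ab <- profile$abundances
  p <- ab / sum(ab)
  n <- config$total_reads
  counts <- if (exact) {
    expected <- n * p
    base <- floor(expected)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(expected - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base
  } else {
    if (is.null(config$seed))
      stop("stochastic simulation requires a seed", call. = FALSE)
    set.seed(config$seed)
    as.numeric(stats::rmultinom(1L, n, p))
  }
  lens <- as.integer(names(ab))
  plus <- as.character(BiocGenerics::strand(locus)) == "+"
  starts <- if (plus) rep(BiocGenerics::start(locus), length(lens))
            else BiocGenerics::end(locus) - lens + 1L
  ends <- if (plus) BiocGenerics::start(locus) + lens - 1L
          else rep(BiocGenerics::end(locus), length(lens))
  keep <- counts > 0
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(locus)),
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    strand = as.character(BiocGenerics::strand(locus)))
  gr$read_count <- counts[keep]
  attr(gr, "total_mapped") <- n
  gr
}

#' Write simulated reads as BED
#'
#' Collapsed intervals with the read count in the score column, compatible
#' with [read_alignments()].
#'
#' @param reads `GRanges` from [simulate_reads()].
#' @param path Output `.bed` file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    start = BiocGenerics::start(reads) - 1L,  # BED is 0-based half-open
    end = BiocGenerics::end(reads),
    name = sprintf("read%d", seq_along(reads)),
    score = reads$read_count,
    strand = as.character(BiocGenerics::strand(reads)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a Cq table through the annealing model
#'
#' For each primer and condition, the qPCR signal is the sum over the
#' profile's isoforms of abundance times the primer's predicted relative
#' efficiency on that isoform's poly(A)-extended template:
#' `Cq = cq_intercept - log2(signal) + N(0, cq_noise_sd)` per technical
#' replicate. A zero signal yields an undetermined Cq. A constant-abundance
#' reference assay (`reference_name`, e.g. U6) is appended per condition
#' for 2^-ddCq normalization.
#'
#' @param profiles List of [stoichiometry_profile()]s (one per condition)
#'   for a single family.
#' @param family The [mirna_family()] the profiles refer to (provides the
#'   isoform sequences).
#' @param primers List of `forward_primer` objects.
#' @param rules An [efficiency_rules()].
#' @param config A [sim_config()]; `seed` required when `cq_noise_sd > 0`.
#' @param replicates Technical replicates per well (default 2).
#' @param reference_name Name of the constant reference assay (default
#'   `"U6"`); set `NULL` to omit.
#' @param reference_abundance Abundance of the reference in every condition
#'   (default 1).
#' @param tail_length Modelled template poly(A) length (default 10).
#' @return List of [cq_record()]s (sample = condition label).
#' @export
simulate_cq <- function(profiles, family, primers,
                        rules = efficiency_rules(),
                        config = sim_config(), replicates = 2L,
                        reference_name = "U6", reference_abundance = 1,
                        tail_length = 10L) {
  stopifnot(inherits(family, "mirna_family"))
  if (inherits(profiles, "stoichiometry_profile")) profiles <- list(profiles)
  noisy <- config$cq_noise_sd > 0
  if (noisy) {
    if (is.null(config$seed))
      stop("noisy Cq simulation requires a seed", call. = FALSE)
    set.seed(config$seed)
  }
  out <- list()
  for (prof in profiles) {
    lens <- as.integer(names(prof$abundances))
    isoforms <- enumerate_isoforms(family, lens)
    templates <- lapply(seq_len(nrow(isoforms)), function(i)
      extend_template(isoforms$sequence[i], tail_length = tail_length,
                      name = isoforms$name[i]))
    for (p in primers) {
      effs <- vapply(templates, function(tmpl)
        predict_amplification(p, tmpl, rules)$efficiency, numeric(1L))
      signal <- sum(prof$abundances * effs)
      cqs <- if (signal <= 0) rep(NA_real_, replicates) else {
        base <- config$cq_intercept - log2(signal)
        if (noisy) base + stats::rnorm(replicates, 0, config$cq_noise_sd)
        else rep(base, replicates)
      }
      cqs[!is.na(cqs) & cqs > 45] <- NA_real_  # never crosses threshold
      out[[length(out) + 1L]] <-
        cq_record(prof$condition, p$name, prof$condition, cqs)
    }
    if (!is.null(reference_name)) {
      base <- config$cq_intercept - log2(reference_abundance)
      cqs <- if (noisy) base + stats::rnorm(replicates, 0, config$cq_noise_sd)
             else rep(base, replicates)
      out[[length(out) + 1L]] <-
        cq_record(prof$condition, reference_name, prof$condition, cqs)
    }
  }
  out
}
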
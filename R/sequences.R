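# Strict alphabets. Inputs are case-insensitive; canonical storage is
# uppercase. RNA rejects T, DNA rejects U -- mixing the two alphabets in one
# string is always an error that names the first offending position.

.check_alphabet <- function(x, alphabet, label) {
  if (length(x) != 1L || !is.character(x) || is.na(x))
    stop(label, " sequence must be a single non-NA character string",
         call. = FALSE)
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    stop(sprintf("invalid %s base '%s' at position %d (alphabet: %s)",
                 label, chars[bad[1L]], bad[1L],
                 paste(alphabet, collapse = "")),
         call. = FALSE)
  x
}

#' Validate an RNA sequence
#'
#' Uppercases and checks that `x` contains only A, C, G, U. `T` is rejected:
#' RNA and DNA strings are kept in separate strict alphabets throughout the
#' package.
#'
#' @param x Character scalar, 5'->3'.
#' @return The validated uppercase string.
#' @export
#' @examples
#' rna("agcuacaucuggcuacuGGGU")
rna <- function(x) .check_alphabet(x, c("A", "C", "G", "U"), "RNA")

#' Validate a DNA sequence
#'
#' Uppercases and checks that `x` contains only A, C, G, T (`U` rejected).
#'
#' @param x Character scalar, 5'->3'.
#' @return The validated uppercase string.
#' @export
dna <- function(x) .check_alphabet(x, c("A", "C", "G", "T"), "DNA")

#' Convert an RNA sequence to its DNA equivalent
#'
#' U -> T substitution, position by position; length is preserved. This is
#' the correspondence between a synthetic RNA and the forward primer that
#' matches it.
#'
#' @param x RNA string (validated with [rna()]).
#' @return DNA string of the same length.
#' @export
#' @examples
#' rna_to_dna("AGCUACAUCUGGCUACUGGGU")
rna_to_dna <- function(x) {
  if (identical(x, "")) return("")
  chartr("U", "T", rna(x))
}

#' Convert a DNA sequence to its RNA equivalent (T -> U)
#'
#' @param x DNA string.
#' @return RNA string.
#' @export
dna_to_rna <- function(x) {
  if (identical(x, "")) return("")
  chartr("T", "U", dna(x))
}

#' Reverse complement of a DNA sequence
#'
#' @param x DNA string.
#' @return The Watson-Crick reverse complement.
#' @export
#' @examples
#' reverse_complement("AAAA")
reverse_complement <- function(x) {
  if (identical(x, "")) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna(x))))
}

#' Define a miRNA family by its longest templated 3'-isoform
#'
#' A family is anchored at its canonical 5' end (position 1); every templated
#' 3'-isomiR is a prefix of `reference_sequence`, which should be the longest
#' isoform under consideration. Non-templated 3' additions (e.g.
#' mono-uridylation) are outside this representation and cannot be expressed.
#'
#' @param name Family identifier (e.g. `"miR-222"`).
#' @param reference_sequence RNA string, 18-30 nt, canonical 5' end first.
#' @param species Optional species tag (e.g. `"hsa"`).
#' @return An object of class `mirna_family`.
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' fam
mirna_family <- function(name, reference_sequence, species = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- rna(reference_sequence)
  n <- nchar(seq)
  if (n < 18L || n > 30L)
    stop("reference sequence must be 18-30 nt, got ", n, " nt", call. = FALSE)
  structure(
    list(name = name, reference_sequence = seq, species = species),
    class = "mirna_family"
  )
}

#' @export
print.mirna_family <- function(x, ...) {
  cat(sprintf("<mirna_family> %s  (%d nt reference)\n  5'-%s-3'\n",
              x$name, nchar(x$reference_sequence), x$reference_sequence))
  invisible(x)
}

#' @export
length.mirna_family <- function(x) nchar(x$reference_sequence)

#' Enumerate templated 3'-isoforms of a family
#'
#' Each requested length yields the prefix of the family reference of that
#' length, named `<family>-<length>nt` after the convention used for
#' synthetic isomiR panels.
#'
#' @param family A [mirna_family()].
#' @param lengths Integer vector of isoform lengths, each in
#'   `[18, length(reference)]`.
#' @return A data.frame with columns `name`, `family`, `length`, `sequence`,
#'   of class `isomir_set`.
#' @export
#' @examples
#' fam <- mirna_family("miR-222", "AGCUACAUCUGGCUACUGGGUCUCU")
#' enumerate_isoforms(fam, 21:25)
enumerate_isoforms <- function(family, lengths) {
  stopifnot(inherits(family, "mirna_family"))
  lengths <- as.integer(lengths)
  ref_len <- nchar(family$reference_sequence)
  if (length(lengths) &&
      (any(lengths < 18L) || any(lengths > ref_len)))
    stop(sprintf("isoform lengths must lie in [18, %d] for family '%s'",
                 ref_len, family$name), call. = FALSE)
  out <- data.frame(
    name = sprintf("%s-%dnt", family$name, lengths),
    family = rep(family$name, length(lengths)),
    length = lengths,
    sequence = substr(rep(family$reference_sequence, length(lengths)),
                      1L, lengths),
    stringsAsFactors = FALSE
  )
  class(out) <- c("isomir_set", "data.frame")
  out
}

# ---- FASTA I/O -------------------------------------------------------------

.record_alphabet <- function(seq) {
  chars <- unique(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  has_u <- "U" %in% chars
  has_t <- "T" %in% chars
  if (has_u && has_t) return("mixed")
  unknown <- setdiff(chars, c("A", "C", "G", "T", "U"))
  if (length(unknown)) return("unknown")
  if (has_u) "RNA" else "DNA"
}

#' Read a FASTA file, auto-detecting RNA vs DNA per record
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; each record is then
#' classified as RNA or DNA from its letters (a record with neither U nor T is
#' reported as DNA). A record mixing U and T, or containing letters outside
#' the two alphabets, is a parse error.
#'
#' @param path FASTA file.
#' @return A data.frame with columns `name`, `sequence`, `alphabet`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L)
    return(data.frame(name = character(), sequence = character(),
                      alphabet = character(), stringsAsFactors = FALSE))
  seqs <- toupper(as.character(recs))
  # keep only the first token of the header, as mature-miRNA FASTAs carry
  # accession + description after the ID
  nms <- vapply(strsplit(names(recs), "[ \t]"), `[[`, character(1L), 1L)
  alph <- vapply(seqs, .record_alphabet, character(1L), USE.NAMES = FALSE)
  bad <- which(alph %in% c("mixed", "unknown"))
  if (length(bad))
    stop(sprintf("record '%s' (#%d) has %s alphabet", nms[bad[1L]], bad[1L],
                 alph[bad[1L]]), call. = FALSE)
  data.frame(name = nms, sequence = unname(seqs), alphabet = alph,
             stringsAsFactors = FALSE)
}

#' Write named sequences to FASTA
#'
#' @param records Either a data.frame with `name` and `sequence` columns or a
#'   named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.data.frame(records)) {
    seqs <- records$sequence
    names(seqs) <- records$name
  } else seqs <- records
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Fraction of mature miRNAs longer than a length threshold
#'
#' Computes, over a mature-miRNA FASTA (miRBase-style headers,
#' `hsa-miR-...`), the proportion of records whose sequence length exceeds
#' `threshold` nucleotides, after restricting to one species by header
#' prefix. By default each accession counts once; `distinct = "sequence"`
#' collapses identical mature sequences first.
#'
#' @param mature_records data.frame from [read_fasta()] (or any data.frame
#'   with `name` and `sequence`).
#' @param species_prefix Header prefix selecting the species, e.g. `"hsa-"`.
#' @param threshold Length threshold in nt; records strictly longer are
#'   counted.
#' @param distinct `"accession"` (default) or `"sequence"`.
#' @return Fraction in `[0, 1]`.
#' @export
mature_length_fraction <- function(mature_records, species_prefix,
                                   threshold = 22L,
                                   distinct = c("accession", "sequence")) {
  distinct <- match.arg(distinct)
  keep <- startsWith(mature_records$name, species_prefix)
  recs <- mature_records[keep, , drop = FALSE]
  if (nrow(recs) == 0L)
    stop("no records left after filtering on prefix '", species_prefix, "'",
         call. = FALSE)
  if (distinct == "sequence")
    recs <- recs[!duplicated(recs$sequence), , drop = FALSE]
  mean(nchar(recs$sequence) > threshold)
}
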
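# Bundled assay sequences: the synthetic RNA panel and the forward primers of
# the published 4A-modification study, under their original names. These are
# the ground truth the design and annealing rules are checked against.

#' Synthetic RNA panel
#'
#' The fifteen single-stranded synthetic RNAs of the assay-validation panel:
#' the miR-221-3p and miR-222-3p templated 3'-isoform series, seven unrelated
#' 25-27 nt RNAs (RNA#1-#7) and a two-central-mismatch variant of RNA#7.
#' Returned 5'->3' in the RNA alphabet.
#'
#' @return Named character vector of RNA sequences.
#' @export
#' @examples
#' table1_rnas()[["miR-222-21 nt"]]
table1_rnas <- function() {
  c(
    "miR-221-20 nt" = "AGCUACAUUGUCUGCUGGGU",
    "miR-221-23 nt" = "AGCUACAUUGUCUGCUGGGUUUC",
    "miR-222-21 nt" = "AGCUACAUCUGGCUACUGGGU",
    "miR-222-22 nt" = "AGCUACAUCUGGCUACUGGGUC",
    "miR-222-23 nt" = "AGCUACAUCUGGCUACUGGGUCU",
    "miR-222-24 nt" = "AGCUACAUCUGGCUACUGGGUCUC",
    "miR-222-25 nt" = "AGCUACAUCUGGCUACUGGGUCUCU",
    "RNA#1"         = "GAAGGAGGGUGACCUGAUAAACCAA",
    "RNA#2"         = "ACUCCUUCAUUCUCCCUUUCAAAGGCU",
    "RNA#3"         = "GAGGUUUAGGUAUCGAAGUUGGGUCAA",
    "RNA#4"         = "CAGAACAAAGGCAUCGUUGGAGUUCAG",
    "RNA#5"         = "AGUAUCUCAACAGCUAAUUUGGCUGCG",
    "RNA#6"         = "GAAGGAGGGUGACCUGAUAGGUUAC",
    "RNA#7"         = "AGCAGCUAUCAGGUCACCCUCCUUCUU",
    "RNA#7-MIS"     = "AGCAGCUAUCAGGUAAACCUCCUUCUU"
  )
}

#' Forward primer panel
#'
#' The forty-one DNA forward primers used with the synthetic RNA panel,
#' including the 2A/4A/5A 3'-extended variants and the two targeted-sequencing
#' (MySEQ) primers, under their original names.
#'
#' @return Named character vector of DNA sequences.
#' @export
table2_primers <- function() {
  c(
    "F222-25"     = "AGCTACATCTGGCTACTGGGTCTCT",
    "F222-24"     = "AGCTACATCTGGCTACTGGGTCTC",
    "F222-23"     = "AGCTACATCTGGCTACTGGGTCT",
    "F222-22"     = "AGCTACATCTGGCTACTGGGTC",
    "F222-21"     = "AGCTACATCTGGCTACTGGGT",
    "F221-23"     = "AGCTACATTGTCTGCTGGGTTTC",
    "F221-20"     = "AGCTACATTGTCTGCTGGGT",
    "F221-20-4A"  = "AGCTACATTGTCTGCTGGGTAAAA",
    "F222-21-2A"  = "AGCTACATCTGGCTACTGGGTAA",
    "F222-21-5A"  = "AGCTACATCTGGCTACTGGGTAAAAA",
    "F1-25"       = "GAAGGAGGGTGACCTGATAAACCAA",
    "F1-21"       = "GAAGGAGGGTGACCTGATAAA",
    "F1-21-4A"    = "GAAGGAGGGTGACCTGATAAAAAAA",
    "F222-25-4A"  = "AGCTACATCTGGCTACTGGGTCTCTAAAA",
    "F222-24-4A"  = "AGCTACATCTGGCTACTGGGTCTCAAAA",
    "F222-23-4A"  = "AGCTACATCTGGCTACTGGGTCTAAAA",
    "F222-22-4A"  = "AGCTACATCTGGCTACTGGGTCAAAA",
    "F222-21-4A"  = "AGCTACATCTGGCTACTGGGTAAAA",
    "F199a-20"    = "CCCAGTGTTCAGACTACCTG",
    "F199a-20-4A" = "CCCAGTGTTCAGACTACCTGAAAA",
    "F199a-23"    = "CCCAGTGTTCAGACTACCTGTTC",
    "F2-27"       = "ACTCCTTCATTCTCCCTTTCAAAGGCT",
    "F2-22"       = "ACTCCTTCATTCTCCCTTTCAA",
    "F2-22-4A"    = "ACTCCTTCATTCTCCCTTTCAAAAAA",
    "F3-27"       = "GAGGTTTAGGTATCGAAGTTGGGTCAA",
    "F3-22"       = "GAGGTTTAGGTATCGAAGTTGG",
    "F3-22-4A"    = "GAGGTTTAGGTATCGAAGTTGGAAAA",
    "F4-27"       = "CAGAACAAAGGCATCGTTGGAGTTCAG",
    "F4-22"       = "CAGAACAAAGGCATCGTTGGAG",
    "F4-22-4A"    = "CAGAACAAAGGCATCGTTGGAGAAAA",
    "F5-27"       = "AGTATCTCAACAGCTAATTTGGCTGCG",
    "F5-22"       = "AGTATCTCAACAGCTAATTTGG",
    "F5-22-4A"    = "AGTATCTCAACAGCTAATTTGGAAAA",
    "F6-25"       = "GAAGGAGGGTGACCTGATAGGTTAC",
    "F6-21"       = "GAAGGAGGGTGACCTGATAGG",
    "F6-21-4A"    = "GAAGGAGGGTGACCTGATAGGAAAA",
    "F7-27"       = "AGCAGCTATCAGGTCACCCTCCTTCTT",
    "F7-22"       = "AGCAGCTATCAGGTCACCCTCC",
    "F7-22-4A"    = "AGCAGCTATCAGGTCACCCTCCAAAA",
    "F7MIS-27"    = "AGCAGCTATCAGGTAAACCTCCTTCTT",
    "F7MIS-22"    = "AGCAGCTATCAGGTAAACCTCC",
    "F7MIS-22-4A" = "AGCAGCTATCAGGTAAACCTCCAAAA",
    "miR-221-3p MySEQ"  = "CCTACACGACGCTCTTCCGATCTAGCTACATTGTCTGCTGGG",
    "snoRNA-202 MySEQ"  = "CCTACACGACGCTCTTCCGATCTGCTGTACTGACTTGATGAAAGTAC"
  )
}

#' Assay families derivable from the synthetic RNA panel
#'
#' Builds one [mirna_family()] per panel RNA whose longest variant serves as
#' the family reference: miR-221 (23 nt), miR-222 (25 nt) and RNA#1-#7 plus
#' RNA#7-MIS, each treated as its own single-reference "family". The short
#' primer naming in the panel maps each family to a primer stem (`F222`,
#' `F1`, `F7MIS`, ...), returned in the `stem` attribute.
#'
#' @return Named list of `mirna_family` objects; each carries a `stem`
#'   attribute used by the panel naming convention.
#' @export
fixture_families <- function() {
  rnas <- table1_rnas()
  defs <- list(
    "miR-221"   = list(ref = "miR-221-23 nt", stem = "221"),
    "miR-222"   = list(ref = "miR-222-25 nt", stem = "222"),
    "RNA#1"     = list(ref = "RNA#1",     stem = "1"),
    "RNA#2"     = list(ref = "RNA#2",     stem = "2"),
    "RNA#3"     = list(ref = "RNA#3",     stem = "3"),
    "RNA#4"     = list(ref = "RNA#4",     stem = "4"),
    "RNA#5"     = list(ref = "RNA#5",     stem = "5"),
    "RNA#6"     = list(ref = "RNA#6",     stem = "6"),
    "RNA#7"     = list(ref = "RNA#7",     stem = "7"),
    "RNA#7-MIS" = list(ref = "RNA#7-MIS", stem = "7MIS")
  )
  out <- lapply(names(defs), function(nm) {
    fam <- mirna_family(nm, rnas[[defs[[nm]]$ref]])
    attr(fam, "stem") <- defs[[nm]]$stem
    fam
  })
  names(out) <- names(defs)
  out
}

#' Write the bundled assay sequences to FASTA/TSV files
#'
#' Dumps the synthetic RNA panel to `rnas.fasta`, the primer panel to
#' `primers.fasta` and a combined TSV (`fixtures.tsv` with name, type,
#' length, sequence) into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_fixture_files <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rnas <- table1_rnas()
  primers <- table2_primers()
  f1 <- file.path(dir, "rnas.fasta")
  f2 <- file.path(dir, "primers.fasta")
  f3 <- file.path(dir, "fixtures.tsv")
  write_fasta(rnas, f1)
  write_fasta(primers, f2)
  tab <- rbind(
    data.frame(name = names(rnas), type = "synthetic_rna",
               length = nchar(rnas), sequence = unname(rnas)),
    data.frame(name = names(primers), type = "forward_primer",
               length = nchar(primers), sequence = unname(primers))
  )
  utils::write.table(tab, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
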
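# Deterministic toy fixtures for tests and demos: a two-contig FASTA, a VCF
# exercising every filter path (strand collapse, non-PASS, multiallelic,
# indel, N-context), a BED restriction, and a small synthetic signature
# matrix. All hand-designed; expected tallies live in the manifest.

.FIXTURE_CHR1 <- "ACTCAGATANCTTAC"  # 15 bp
.FIXTURE_CHR2 <- "ACGTACGT"         # 8 bp, the worked trinucleotide example

#' Write the package's toy fixture set
#'
#' Generates, deterministically, a small FASTA (with .fai index), a somatic
#' VCF, a BED file, a 4-signature synthetic matrix and a manifest of
#' hand-computed expected values. The VCF records exercise: a plain
#' pyrimidine-reference SNV, a purine-reference SNV (strand collapse onto
#' the reverse complement), a non-PASS record, an N-context record, a
#' multiallelic record and an insertion.
#'
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a named list of the file paths plus the manifest
#'   data.frame.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("directory not writable: ", out_dir)
  paths <- list(
    fasta = file.path(out_dir, "toy.fa"),
    vcf = file.path(out_dir, "toy.vcf"),
    bed = file.path(out_dir, "toy.bed"),
    signatures = file.path(out_dir, "toy_signatures_synthetic.tsv"),
    manifest = file.path(out_dir, "manifest.tsv"))

  writeLines(c(">chr1", .FIXTURE_CHR1, ">chr2", .FIXTURE_CHR2), paths$fasta)
  Rsamtools::indexFa(paths$fasta)

  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=15>",
    "##contig=<ID=chr2,length=8>",
    "##FILTER=<ID=q10,Description=\"Low quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    # ACT context -> A[C>G]T
    "chr1\t2\t.\tC\tG\t50\tPASS\t.",
    # TCA context -> T[C>T]A
    "chr1\t4\t.\tC\tT\t50\tPASS\t.",
    # purine ref, AGA context -> revcomp TCT, channel T[C>A]T
    "chr1\t6\t.\tG\tT\t50\tPASS\t.",
    # ATA context, non-PASS -> accepted only when FILTER is ignored
    "chr1\t8\t.\tT\tG\t10\tq10\t.",
    # NCT context -> skipped (ambiguous)
    "chr1\t11\t.\tC\tA\t50\tPASS\t.",
    # multiallelic -> skipped under the default policy
    "chr1\t13\t.\tT\tA,G\t50\tPASS\t.",
    # insertion -> always skipped (non-SNV)
    "chr1\t14\t.\tA\tAT\t50\tPASS\t.")
  writeLines(vcf_lines, paths$vcf)

  # 0-based half-open [1,4) on chr2 = central positions 2..4 (1-based)
  writeLines("chr2\t1\t4", paths$bed)

  write_signature_matrix(orthogonal_signatures(4), paths$signatures)

  manifest <- data.frame(
    key = c("accepted_default", "accepted_pass_only",
            "channel_ACgT", "channel_TCtA", "channel_TCaT", "channel_ATgA",
            "bed_count_ACG", "bed_count_GTA",
            "chr2_whole_ACG", "chr2_whole_GTA"),
    value = c(4, 3, 1, 1, 1, 1, 1, 2, 4, 2),
    note = c("records accepted with the default policy",
             "records accepted with require_pass",
             "A[C>G]T count", "T[C>T]A count",
             "T[C>A]T count (strand collapse of AGA, G>T)",
             "A[T>G]A count (non-PASS record)",
             "ACG contexts with BED [1,4) on chr2",
             "GTA contexts with BED [1,4) on chr2",
             "ACG contexts on whole chr2", "GTA contexts on whole chr2"),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(manifest_table = manifest)))
}
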
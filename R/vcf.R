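#' Filtering policy for VCF-derived catalogues
#'
#' Controls which VCF records enter a mutational catalogue. Non-SNV records
#' (indels, MNVs, symbolic alleles) are always skipped; that switch cannot
#' be disabled because the 96-channel model is defined on single-base
#' substitutions only.
#'
#' @param require_pass If \code{TRUE}, only records whose FILTER field is
#'   \code{PASS} or \code{.} are accepted. Default \code{FALSE}: FILTER
#'   semantics vary between callers, so by default every record is
#'   considered and the decision is left upstream.
#' @param skip_multiallelic If \code{TRUE} (default) records with more than
#'   one ALT allele are skipped; if \code{FALSE} they are decomposed and
#'   each SNV allele contributes one count.
#' @param skip_ambiguous_context If \code{TRUE} (default) records whose
#'   reference trinucleotide contains non-ACGT letters (or lies at a contig
#'   edge with a missing flank) are skipped with a warning; if \code{FALSE}
#'   such records raise an error.
#' @return A list of class \code{"vcf_filter_policy"}.
#' @export
vcf_filter_policy <- function(require_pass = FALSE, skip_multiallelic = TRUE,
                              skip_ambiguous_context = TRUE) {
  structure(list(require_pass = isTRUE(require_pass),
                 skip_multiallelic = isTRUE(skip_multiallelic),
                 skip_non_snv = TRUE,
                 skip_ambiguous_context = isTRUE(skip_ambiguous_context)),
            class = "vcf_filter_policy")
}

#' Build a 96-channel mutational catalogue from a somatic VCF
#'
#' Each accepted biallelic SNV contributes one count to exactly one channel.
#' The reference trinucleotide around each variant is looked up in the
#' indexed FASTA; when the reference base is a purine, both the trinucleotide
#' and the substitution are reverse-complemented onto the pyrimidine-centered
#' channel. Soft-masked (lowercase) reference bases are uppercased before
#' the lookup. Genotypes are ignored: the catalogue is built from record
#' sites, one catalogue per file.
#'
#' @param vcf Path to a VCF file (plain or bgzipped).
#' @param reference Path to a FASTA file with a \code{.fai} index.
#' @param policy A \code{\link{vcf_filter_policy}}.
#' @param sample_id Sample name for the catalogue column; defaults to the
#'   VCF file name without extension.
#' @return A 96 x 1 catalogue matrix of counts. Attribute
#'   \code{"provenance"} records the source file, the policy, the accepted
#'   count and per-reason skip counts.
#' @seealso \code{\link{write_catalogue_table}}
#' @export
vcf_to_catalogue <- function(vcf, reference, policy = vcf_filter_policy(),
                             sample_id = NULL) {
  if (!file.exists(vcf)) stop("VCF file not found: ", vcf)
  if (!file.exists(reference)) stop("reference FASTA not found: ", reference)
  fai <- paste0(reference, ".fai")
  if (!file.exists(fai))
    stop("missing FASTA index (expected ", fai, "); create it with ",
         "Rsamtools::indexFa() or `samtools faidx`")
  stopifnot(inherits(policy, "vcf_filter_policy"))
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(vcf))

  v <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  gr <- SummarizedExperiment::rowRanges(v)
  ref_al <- as.character(VariantAnnotation::ref(v))
  alt_list <- VariantAnnotation::alt(v)
  filt <- VariantAnnotation::filt(v)

  fa <- Rsamtools::FaFile(reference)
  idx <- Rsamtools::scanFaIndex(fa)
  seqlens <- stats::setNames(GenomicRanges::width(idx),
                             as.character(GenomicRanges::seqnames(idx)))

  skipped <- c(non_pass = 0L, multiallelic = 0L, non_snv = 0L,
               ambiguous_context = 0L)
  labels <- character(0)

  n_rec <- length(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  unknown <- setdiff(unique(chroms), names(seqlens))
  if (length(unknown) > 0L)
    stop("VCF contig(s) absent from the reference FASTA: ",
         paste(unknown, collapse = ", "))

  for (i in seq_len(n_rec)) {
    if (policy$require_pass && !(filt[i] %in% c("PASS", "."))) {
      skipped["non_pass"] <- skipped["non_pass"] + 1L
      next
    }
    alts <- as.character(alt_list[[i]])
    if (length(alts) > 1L && policy$skip_multiallelic) {
      skipped["multiallelic"] <- skipped["multiallelic"] + 1L
      next
    }
    ref <- toupper(ref_al[i])
    snv_alts <- alts[nchar(alts) == 1L & toupper(alts) %in% .BASES &
                       toupper(alts) != ref]
    if (nchar(ref) != 1L || !(ref %in% .BASES) || length(snv_alts) == 0L) {
      skipped["non_snv"] <- skipped["non_snv"] + 1L
      next
    }
    pos <- starts[i]
    chrom <- chroms[i]
    # verify the VCF REF against the reference sequence before anything else
    base_rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    fasta_base <- toupper(as.character(Biostrings::getSeq(fa, base_rng)))
    if (fasta_base != ref)
      stop("REF mismatch at ", chrom, ":", pos, " (VCF says ", ref,
           ", FASTA says ", fasta_base,
           "): coordinate system or reference build disagreement")
    if (pos == 1L || pos == seqlens[[chrom]]) {
      ctx <- NA_character_  # flank missing at contig edge
    } else {
      rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos - 1L, pos + 1L))
      ctx <- toupper(as.character(Biostrings::getSeq(fa, rng)))
    }
    for (alt in toupper(snv_alts)) {
      chan <- if (is.na(ctx)) NA_character_ else .canonical_channel(ref, alt, ctx)
      if (is.na(chan)) {
        if (!policy$skip_ambiguous_context)
          stop("ambiguous trinucleotide context at ", chrom, ":", pos)
        warning("skipping record at ", chrom, ":", pos,
                ": trinucleotide context unavailable or contains non-ACGT letters",
                call. = FALSE)
        skipped["ambiguous_context"] <- skipped["ambiguous_context"] + 1L
      } else {
        labels <- c(labels, chan)
      }
    }
  }

  m <- matrix(0, nrow = 96L, ncol = 1L,
              dimnames = list(mut_channel_labels(), sample_id))
  if (length(labels) > 0L) {
    tab <- table(labels)
    m[names(tab), 1L] <- as.numeric(tab)
  }
  attr(m, "provenance") <- list(
    source = vcf, reference = reference, policy = unclass(policy),
    records = n_rec, accepted = length(labels), skipped = skipped)
  m
}
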
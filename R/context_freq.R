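# Trinucleotide frequency objects: a numeric vector of 32 strand-collapsed
# counts named by pyrimidine-centered context, class "trinuc_freq", with a
# "source_label" attribute. Frequencies are derived on demand by dividing by
# the total.

.as_trinuc_freq <- function(counts, source_label = "") {
  ctx <- trinuc_contexts()
  if (is.null(names(counts)) && length(counts) == 32L) names(counts) <- ctx
  if (!setequal(names(counts), ctx))
    stop("trinucleotide counts must be keyed by the 32 pyrimidine-centered ",
         "contexts; mismatched keys: ",
         paste(utils::head(c(setdiff(names(counts), ctx), setdiff(ctx, names(counts))), 5),
               collapse = ", "))
  counts <- counts[ctx]
  if (any(counts < 0)) stop("trinucleotide counts must be non-negative")
  structure(as.numeric(counts), names = ctx, source_label = source_label,
            class = "trinuc_freq")
}

#' Trinucleotide frequencies of a count vector
#'
#' @param x A \code{trinuc_freq} object or a named vector of 32 collapsed
#'   trinucleotide counts.
#' @return Numeric vector of 32 frequencies summing to 1 (all zero for an
#'   all-zero input).
#' @export
trinuc_frequencies <- function(x) {
  x <- .as_trinuc_freq(unclass(x), attr(x, "source_label") %||% "")
  tot <- sum(x)
  out <- as.numeric(x)
  names(out) <- names(x)
  if (tot > 0) out / tot else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count strand-collapsed trinucleotides in a reference or region set
#'
#' Counts every position whose central base lies inside the (merged) regions
#' and whose two flanking bases exist and are A/C/G/T; flanking bases may
#' extend one base pair beyond a region boundary into the reference.
#' Purine-centered trinucleotides are counted toward their reverse
#' complement, yielding the 32 collapsed pyrimidine-centered contexts. With
#' no regions, the whole of every sequence is counted.
#'
#' @param reference Path to an indexed FASTA file, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param regions Optional region set: a \code{GenomicRanges::GRanges}, or a
#'   path to a BED file (0-based half-open). Overlapping intervals are
#'   merged before counting.
#' @param source_label Free-text tag recorded on the result.
#' @return A \code{trinuc_freq} object: 32 named counts.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' count_trinucleotides(ref)  # ACG: 4, GTA: 2
count_trinucleotides <- function(reference, regions = NULL, source_label = NULL) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference FASTA not found: ", reference)
    label <- source_label %||% basename(reference)
    seqs <- Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (methods::is(reference, "DNAStringSet")) {
    seqs <- reference
    label <- source_label %||% "DNAStringSet"
  } else {
    stop("reference must be a FASTA path or a DNAStringSet")
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))

  if (!is.null(regions)) {
    if (is.character(regions)) {
      if (!file.exists(regions)) stop("BED file not found: ", regions)
      gr <- rtracklayer::import(regions, format = "BED")
    } else if (methods::is(regions, "GRanges")) {
      gr <- regions
    } else {
      stop("regions must be a BED path or a GRanges")
    }
    if (length(gr) == 0L) stop("empty region set")
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), names(seqs))
    if (length(bad) > 0L)
      stop("region chromosome(s) absent from the reference: ",
           paste(bad, collapse = ", "))
    gr <- GenomicRanges::reduce(gr)
    # widen by one base each side so each region position gets its 3-mer;
    # clip at contig bounds (edge positions then lack a flank and drop out)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    starts <- pmax(GenomicRanges::start(gr) - 1L, 1L)
    ends <- pmin(GenomicRanges::end(gr) + 1L,
                 Biostrings::width(seqs)[match(chroms, names(seqs))])
    windows <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
      as.character(Biostrings::subseq(seqs[[chroms[i]]], starts[i], ends[i]))
    }, character(1)))
    seqs <- windows
  }

  counts_all <- Biostrings::trinucleotideFrequency(seqs)
  raw <- colSums(counts_all)
  out <- .collapse_trinuc(raw)
  if (sum(out) == 0)
    warning("no valid (ACGT-only) trinucleotide contexts found", call. = FALSE)
  .as_trinuc_freq(out, source_label = label %||% "")
}

#' Read / write a 32-row trinucleotide count table
#'
#' The table is tab-separated with a \code{Context} column of collapsed
#' pyrimidine-centered trinucleotides and one or more count columns; when
#' several count columns are present (e.g. \code{Genome} and \code{Exome}),
#' a named list of \code{trinuc_freq} objects is returned.
#'
#' @param path Path to the TSV file.
#' @return A \code{trinuc_freq} object, or a named list of them when the
#'   table has several count columns.
#' @export
read_trinuc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ctx_col <- intersect(c("Context", "Cotext", "context"), colnames(tab))
  if (length(ctx_col) == 0L) ctx_col <- colnames(tab)[1L]
  ctx <- as.character(tab[[ctx_col[1L]]])
  value_cols <- setdiff(colnames(tab), ctx_col[1L])
  out <- lapply(value_cols, function(cn) {
    .as_trinuc_freq(stats::setNames(as.numeric(tab[[cn]]), ctx),
                    source_label = cn)
  })
  names(out) <- value_cols
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname read_trinuc_table
#' @param f A \code{trinuc_freq} object or named list of them.
#' @param path Output path.
#' @export
write_trinuc_table <- function(f, path) {
  if (inherits(f, "trinuc_freq")) f <- list(Count = f)
  f <- lapply(f, function(x) .as_trinuc_freq(unclass(x)))
  tab <- data.frame(Context = trinuc_contexts(),
                    do.call(cbind, lapply(f, as.numeric)),
                    check.names = FALSE)
  colnames(tab) <- c("Context", names(f))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# per-channel scaling ratios for re-baselining; channels sharing a context
# share one ratio
.context_ratios <- function(values, f_source, f_target, invert_ratios = FALSE) {
  fs <- trinuc_frequencies(f_source)
  ft <- trinuc_frequencies(f_target)
  if (sum(unclass(f_source)) <= 0 || sum(unclass(f_target)) <= 0)
    stop("both trinucleotide frequency sets must have positive totals")
  ctx <- channel_contexts()
  needs <- rowSums(values > 0) > 0
  zero_src <- fs[ctx] == 0 & needs
  if (any(zero_src))
    stop("zero source frequency for context(s) with observed mass: ",
         paste(unique(ctx[zero_src]), collapse = ", "))
  ratio <- ifelse(fs[ctx] > 0, ft[ctx] / fs[ctx], 0)
  if (invert_ratios) ratio <- ifelse(ratio > 0, 1 / ratio, 0)
  unname(ratio)
}

#' Re-scale a mutational catalogue to a different trinucleotide baseline
#'
#' To express a catalogue observed on baseline A (e.g. an exome capture) on
#' baseline B (e.g. the whole genome), each channel is multiplied by the
#' ratio of target to source context frequency, f_B(c)/f_A(c), and the
#' result is converted to frequencies. Expected channel counts are
#' proportional to context availability, so dividing by the source
#' availability and multiplying by the target availability puts the
#' catalogue on the footing on which genome-wide signature matrices are
#' defined. Set \code{invert_ratios = TRUE} to apply the reciprocal ratios
#' instead (for comparing the two conventions).
#'
#' @param m Catalogue matrix (96 x S) or a single 96-vector; counts or
#'   frequencies.
#' @param f_source Trinucleotide frequencies of the regions the catalogue
#'   was observed on.
#' @param f_target Trinucleotide frequencies of the baseline to map onto.
#' @param invert_ratios Use f_source/f_target instead of f_target/f_source.
#' @return A 96 x S matrix of frequencies (columns sum to 1).
#' @export
normalize_catalogue <- function(m, f_source, f_target, invert_ratios = FALSE) {
  m <- .as_catalogue_matrix(m)
  ratio <- .context_ratios(m, f_source, f_target, invert_ratios)
  scaled <- m * ratio
  totals <- colSums(scaled)
  if (any(totals == 0 & colSums(m) > 0))
    stop("normalization annihilated a non-empty catalogue (all ratios zero)")
  sweep(scaled, 2L, ifelse(totals > 0, totals, 1), "/")
}

#' Re-scale a signature matrix to a different trinucleotide baseline
#'
#' Applies the same per-channel ratios as \code{\link{normalize_catalogue}}
#' to every signature column independently and renormalizes each column to
#' sum 1. Use it to map genome-referenced signatures onto an exome capture
#' baseline (source = genome, target = exome) so they can be fitted against
#' un-normalized exome catalogues.
#'
#' @inheritParams normalize_catalogue
#' @param P 96 x N signature matrix.
#' @param baseline Baseline tag for the result; defaults to the target's
#'   source label.
#' @return A 96 x N column-stochastic matrix with updated \code{baseline}
#'   attribute.
#' @export
normalize_signatures <- function(P, f_source, f_target, invert_ratios = FALSE,
                                 baseline = NULL) {
  P <- .validate_signature_matrix(P)
  ratio <- .context_ratios(P, f_source, f_target, invert_ratios)
  scaled <- P * ratio
  totals <- colSums(scaled)
  if (any(totals == 0))
    stop("normalization annihilated signature(s): ",
         paste(colnames(P)[totals == 0], collapse = ", "))
  out <- sweep(scaled, 2L, totals, "/")
  attr(out, "baseline") <- baseline %||%
    (attr(f_target, "source_label") %||% "re-scaled")
  out
}
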
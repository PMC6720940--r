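.BASES <- c("A", "C", "G", "T")
.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical labels of the 96 single-base-substitution channels
#'
#' Channels are pyrimidine-centered: the six substitution classes
#' \code{C>A, C>G, C>T, T>A, T>C, T>G} in that order, and within each class
#' the 5' then the 3' flanking base each in order \code{A, C, G, T}. Index 1
#' (0 in zero-based terms) is \code{"A[C>A]A"} and index 96 is
#' \code{"T[T>G]T"}.
#'
#' @return Character vector of length 96 in canonical order.
#' @export
#' @examples
#' head(mut_channel_labels())
mut_channel_labels <- function() {
  labels <- character(96)
  i <- 1L
  for (sub in .SUBSTITUTIONS) {
    ref <- substr(sub, 1L, 1L)
    alt <- substr(sub, 3L, 3L)
    for (five in .BASES) {
      for (three in .BASES) {
        labels[i] <- paste0(five, "[", sub, "]", three)
        i <- i + 1L
      }
    }
  }
  labels
}

#' Trinucleotide context of each of the 96 channels
#'
#' @return Character vector of length 96: the pyrimidine-centered reference
#'   trinucleotide (5' flank, reference base, 3' flank) of each channel in
#'   canonical order. Each of the 32 collapsed contexts appears three times
#'   (once per substitution class of its central base).
#' @export
channel_contexts <- function() {
  labels <- mut_channel_labels()
  paste0(substr(labels, 1L, 1L), substr(labels, 3L, 3L), substr(labels, 7L, 7L))
}

#' The 32 strand-collapsed trinucleotide contexts
#'
#' @return Character vector of length 32: all trinucleotides with a central
#'   pyrimidine (C or T), central-C contexts first, flanks each in order
#'   A, C, G, T.
#' @export
trinuc_contexts <- function() {
  out <- character(32)
  i <- 1L
  for (central in c("C", "T")) {
    for (five in .BASES) {
      for (three in .BASES) {
        out[i] <- paste0(five, central, three)
        i <- i + 1L
      }
    }
  }
  out
}

#' Parse a channel label of the form "X[R>A]Y"
#'
#' @param label Character vector of channel labels such as \code{"T[C>T]A"}.
#' @return A data.frame with one row per label and columns
#'   \code{substitution}, \code{five_prime}, \code{three_prime},
#'   \code{index} (zero-based, 0--95) and \code{label}.
#' @details The central reference base must be a pyrimidine (C or T);
#'   purine-centered labels are rejected rather than silently
#'   reverse-complemented, since file row labels are expected to already be
#'   strand-collapsed.
#' @export
#' @examples
#' parse_channel_label("A[C>A]A")$index  # 0
#' parse_channel_label("T[T>G]T")$index  # 95
parse_channel_label <- function(label) {
  stopifnot(is.character(label), length(label) >= 1L)
  ok <- grepl("^[ACGT]\\[[ACGT]>[ACGT]\\][ACGT]$", label)
  if (!all(ok)) {
    stop("malformed channel label(s): ", paste(label[!ok], collapse = ", "),
         " (expected form \"X[R>A]Y\" with single A/C/G/T bases)")
  }
  five <- substr(label, 1L, 1L)
  ref <- substr(label, 3L, 3L)
  alt <- substr(label, 5L, 5L)
  three <- substr(label, 7L, 7L)
  bad_ref <- !(ref %in% c("C", "T"))
  if (any(bad_ref)) {
    stop("central reference base must be a pyrimidine (C or T) in: ",
         paste(label[bad_ref], collapse = ", "))
  }
  bad_alt <- alt == ref
  if (any(bad_alt)) {
    stop("alternate base equals the reference base in: ",
         paste(label[bad_alt], collapse = ", "))
  }
  sub <- paste0(ref, ">", alt)
  sub_idx <- match(sub, .SUBSTITUTIONS) - 1L
  five_idx <- match(five, .BASES) - 1L
  three_idx <- match(three, .BASES) - 1L
  data.frame(
    substitution = sub,
    five_prime = five,
    three_prime = three,
    index = 16L * sub_idx + 4L * five_idx + three_idx,
    label = label,
    stringsAsFactors = FALSE
  )
}

# reverse complement of a character vector of DNA strings (ACGT only)
.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(.COMPLEMENT[b])), collapse = "")
  }, character(1))
}

# map an observed (ref, alt, trinucleotide) triple to its canonical channel
# label, reverse-complementing when ref is a purine; returns NA for contexts
# containing non-ACGT letters
.canonical_channel <- function(ref, alt, context) {
  if (!grepl("^[ACGT]{3}$", context)) return(NA_character_)
  if (ref %in% c("G", "A")) {
    ref <- unname(.COMPLEMENT[ref])
    alt <- unname(.COMPLEMENT[alt])
    context <- .revcomp(context)
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}

# collapse a named count vector over arbitrary trinucleotides onto the 32
# pyrimidine-centered contexts
.collapse_trinuc <- function(counts) {
  ctx <- trinuc_contexts()
  out <- stats::setNames(numeric(32), ctx)
  keep <- grepl("^[ACGT]{3}$", names(counts))
  counts <- counts[keep]
  if (length(counts) == 0L) return(out)
  key <- names(counts)
  purine <- substr(key, 2L, 2L) %in% c("A", "G")
  key[purine] <- .revcomp(key[purine])
  agg <- tapply(as.numeric(counts), key, sum)
  out[names(agg)] <- agg
  out
}
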
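# Signature matrices: 96 x N column-stochastic numeric matrices in canonical
# channel order, colnames = signature names. An attribute "baseline" records
# the trinucleotide baseline the probabilities refer to (free text, e.g.
# "GRCh37 whole genome").

.COLSUM_TOL <- 1e-4  # COSMIC files carry rounded values

.validate_signature_matrix <- function(P, tol = .COLSUM_TOL) {
  P <- as.matrix(P)
  if (nrow(P) != 96L) stop("signature matrix must have 96 channel rows, got ", nrow(P))
  if (ncol(P) < 1L) stop("signature matrix needs at least one signature column")
  if (is.null(colnames(P))) colnames(P) <- paste0("Signature_", seq_len(ncol(P)))
  if (anyDuplicated(colnames(P))) stop("duplicate signature names")
  if (any(P < 0)) {
    bad <- colnames(P)[apply(P < 0, 2, any)]
    stop("negative entries in signature(s): ", paste(bad, collapse = ", "))
  }
  cs <- colSums(P)
  off <- abs(cs - 1) > tol
  if (any(off)) {
    stop("signature column sum(s) outside 1 +/- ", tol, ": ",
         paste(sprintf("%s (%.6g)", colnames(P)[off], cs[off]), collapse = ", "))
  }
  storage.mode(P) <- "double"
  P
}

#' Read a mutational signature matrix
#'
#' Supports the COSMIC v2 dialect (columns \code{Substitution Type},
#' \code{Trinucleotide}, \code{Somatic Mutation Type}, then one column per
#' signature), the COSMIC v3 SBS dialect (a \code{Type} or
#' \code{MutationType} label column of \code{"X[R>A]Y"} labels, then one
#' column per signature), and a plain matrix dialect (first column channel
#' labels, remaining columns signatures; the format
#' \code{write_signature_matrix} produces).
#'
#' Rows are reordered to the canonical channel order regardless of file
#' order, and every column sum is validated against 1 (tolerance 1e-4, since
#' published files carry rounded probabilities).
#'
#' @param path Path to a tab-separated signature file.
#' @param dialect One of \code{"cosmic_v2"}, \code{"cosmic_v3_sbs"},
#'   \code{"plain_matrix"}.
#' @param baseline Free-text trinucleotide baseline tag stored on the result
#'   (COSMIC signatures refer to the GRCh37 whole genome).
#' @return A 96 x N matrix with attribute \code{baseline}.
#' @export
read_signature_matrix <- function(path,
                                  dialect = c("plain_matrix", "cosmic_v2",
                                              "cosmic_v3_sbs"),
                                  baseline = "GRCh37 whole genome") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "cosmic_v2") {
    needed <- c("Substitution Type", "Trinucleotide", "Somatic Mutation Type")
    if (!all(needed %in% colnames(tab)))
      stop("cosmic_v2 dialect requires columns: ", paste(needed, collapse = ", "))
    labels <- as.character(tab[["Somatic Mutation Type"]])
    sig_cols <- setdiff(colnames(tab), needed)
    # COSMIC v2 downloads sometimes carry trailing empty columns
    keep <- vapply(tab[sig_cols], function(x) !all(is.na(x)), logical(1))
    sig_cols <- sig_cols[keep]
    P <- as.matrix(tab[, sig_cols, drop = FALSE])
  } else {
    label_col <- intersect(c("Type", "MutationType", "Somatic Mutation Type"),
                           colnames(tab))
    if (dialect == "cosmic_v3_sbs" && length(label_col) == 0L)
      stop("cosmic_v3_sbs dialect requires a 'Type' or 'MutationType' column")
    if (length(label_col) > 0L) {
      labels <- as.character(tab[[label_col[1L]]])
      P <- as.matrix(tab[, setdiff(colnames(tab), label_col), drop = FALSE])
    } else {
      labels <- as.character(tab[[1L]])
      P <- as.matrix(tab[, -1L, drop = FALSE])
    }
  }
  parse_channel_label(labels)
  if (anyDuplicated(labels))
    stop("duplicate channel rows: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(P) <- labels
  canonical <- mut_channel_labels()
  missing <- setdiff(canonical, labels)
  if (length(missing) > 0L)
    stop("missing channel rows: ", paste(utils::head(missing, 5), collapse = ", "))
  P <- P[canonical, , drop = FALSE]
  P <- .validate_signature_matrix(P)
  attr(P, "baseline") <- baseline
  P
}

#' Write a signature matrix in the plain dialect
#'
#' @param P 96 x N signature matrix.
#' @param path Output path.
#' @return Invisibly, the validated matrix.
#' @export
write_signature_matrix <- function(P, path) {
  P <- .validate_signature_matrix(P)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Type", colnames(P)), collapse = "\t"), con)
  body <- apply(P, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 15), collapse = "\t"))
  writeLines(paste(mut_channel_labels(), body, sep = "\t"), con)
  invisible(P)
}
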
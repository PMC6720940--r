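# Mutational catalogues are stored as plain numeric matrices: 96 rows in
# canonical channel order (rownames = channel labels), one column per sample.
# This is the shape the field's catalogue TSVs use and what every other
# function in the package consumes.

.as_catalogue_matrix <- function(m) {
  labels <- mut_channel_labels()
  if (is.numeric(m) && is.null(dim(m))) {
    m <- matrix(m, ncol = 1L, dimnames = list(names(m), "sample_1"))
  }
  m <- as.matrix(m)
  if (nrow(m) != 96L) {
    stop("a mutational catalogue must have exactly 96 channel rows, got ",
         nrow(m))
  }
  if (is.null(rownames(m))) {
    rownames(m) <- labels
  } else {
    if (anyDuplicated(rownames(m)))
      stop("duplicate channel rows: ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
    missing <- setdiff(labels, rownames(m))
    if (length(missing) > 0L)
      stop("missing channel rows: ", paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...")
    m <- m[labels, , drop = FALSE]
  }
  if (any(m < 0)) stop("catalogue entries must be non-negative")
  storage.mode(m) <- "double"
  m
}

#' Read a 96-row mutational catalogue table
#'
#' Reads a tab-separated table with channel labels (\code{"X[R>A]Y"}) in the
#' first column and one column of counts or frequencies per sample. Rows are
#' reordered to the canonical channel order regardless of file order; lines
#' starting with \code{#} (provenance headers) are skipped.
#'
#' @param path Path to the TSV file.
#' @return A 96 x S numeric matrix, rownames in canonical channel order,
#'   colnames the sample identifiers.
#' @export
read_catalogue_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("catalogue table needs a label column and at least one sample column")
  labels <- as.character(tab[[1L]])
  parse_channel_label(labels)  # validates label syntax
  if (anyDuplicated(labels))
    stop("duplicate channel rows: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  missing <- setdiff(mut_channel_labels(), labels)
  if (length(missing) > 0L)
    stop("missing channel rows: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- labels
  .as_catalogue_matrix(m)
}

#' Write catalogues to a 96-row TSV table
#'
#' @param m Catalogue matrix (96 x S) or a single 96-vector.
#' @param path Output path.
#' @param provenance Optional character vector written as \code{#}-prefixed
#'   header lines before the table.
#' @return Invisibly, the normalized matrix that was written.
#' @export
write_catalogue_table <- function(m, path, provenance = NULL) {
  m <- .as_catalogue_matrix(m)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("Somatic Mutation Type", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 15), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(m)
}

#' Convert a catalogue of counts to frequencies
#'
#' @param m Catalogue matrix or 96-vector.
#' @return Matrix of the same shape with each column divided by its total;
#'   all-zero columns stay zero.
#' @export
catalogue_to_frequencies <- function(m) {
  m <- .as_catalogue_matrix(m)
  totals <- colSums(m)
  out <- sweep(m, 2L, ifelse(totals > 0, totals, 1), "/")
  out
}
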
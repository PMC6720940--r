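# Bootstrap resampling of a catalogue: each re-sample redraws the n observed
# mutations with replacement from the 96 channels with probabilities m/n,
# i.e. a multinomial draw of the original size. Resampling channels is
# equivalent to resampling the individual mutations, and the catalogue is
# sufficient for the channel-level model.

#' Bootstrap re-samples of a mutational catalogue
#'
#' @param m A single catalogue of counts (96-vector or 96 x 1 matrix) with
#'   positive total.
#' @param R Number of re-samples (the package default, used throughout the
#'   validation experiments, is 1000).
#' @param seed Integer seed; the whole set of re-samples is a deterministic
#'   function of it.
#' @return A 96 x R matrix of counts; every column sums to the original
#'   total.
#' @export
bootstrap_catalogues <- function(m, R = 1000L, seed = NULL) {
  m <- .as_catalogue_matrix(m)
  if (ncol(m) != 1L) stop("bootstrap_catalogues takes a single catalogue")
  n <- sum(m)
  if (n == 0) stop("cannot bootstrap a zero-total catalogue")
  if (abs(n - round(n)) > 1e-9)
    stop("catalogue must be on the counts scale (integer total)")
  if (n < .low_count_threshold)
    warning("mutational catalogue size below ", .low_count_threshold,
            "; bootstrap intervals will be wide and unstable", call. = FALSE)
  stopifnot(R >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- stats::rmultinom(R, size = round(n), prob = m[, 1L] / n)
  rownames(out) <- rownames(m)
  colnames(out) <- paste0(colnames(m)[1L], "_bs", seq_len(R))
  storage.mode(out) <- "double"
  out
}

#' Bootstrap summary of signature exposures for one sample
#'
#' Fits the original catalogue and \code{R} bootstrap re-samples, and
#' summarizes the per-signature distribution of the re-sampled exposures by
#' minimum, quartiles and maximum, alongside the original point estimate.
#'
#' @inheritParams bootstrap_catalogues
#' @param P 96 x N signature matrix.
#' @param constraint_mode Passed to \code{\link{estimate_exposure}}.
#' @return A data.frame of class \code{"exposure_summary"} with one row per
#'   signature and columns \code{signature}, \code{original}, \code{min},
#'   \code{q1}, \code{median}, \code{q3}, \code{max}; attributes
#'   \code{sample_id}, \code{R}, \code{seed}, \code{constraint_mode}.
#'   Quartiles use linear interpolation between order statistics
#'   (\code{quantile} type 7).
#' @seealso \code{\link{plot_exposure_summary}}
#' @export
summarize_exposures <- function(m, P, R = 1000L, seed = NULL,
                                constraint_mode = c("simplex", "nonneg")) {
  constraint_mode <- match.arg(constraint_mode)
  m <- .as_catalogue_matrix(m)
  if (ncol(m) != 1L) stop("summarize_exposures takes a single catalogue")
  P <- .validate_signature_matrix(P)
  bs <- bootstrap_catalogues(m, R = R, seed = seed)
  fit0 <- suppressWarnings(estimate_exposure(m, P, constraint_mode))
  fits <- suppressWarnings(estimate_exposure(bs, P, constraint_mode))
  q <- apply(fits$proportions, 2L, stats::quantile,
             probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  out <- data.frame(signature = colnames(P),
                    original = as.numeric(fit0$proportions[1L, ]),
                    min = q[1L, ], q1 = q[2L, ], median = q[3L, ],
                    q3 = q[4L, ], max = q[5L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- colnames(m)[1L]
  attr(out, "R") <- as.integer(R)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "constraint_mode") <- constraint_mode
  class(out) <- c("exposure_summary", "data.frame")
  out
}

#' Plot a bootstrap exposure summary
#'
#' Box-and-whisker style display of the bootstrapped exposure distribution
#' per signature (min, quartiles, max), with a star marking the point
#' estimate from the original catalogue.
#'
#' @param x An \code{exposure_summary}.
#' @param ... Passed to \code{\link[graphics]{bxp}}.
#' @export
plot_exposure_summary <- function(x, ...) {
  stopifnot(inherits(x, "exposure_summary"))
  stats_mat <- t(as.matrix(x[, c("min", "q1", "median", "q3", "max")]))
  z <- list(stats = stats_mat, n = rep(attr(x, "R"), nrow(x)),
            conf = NULL, out = numeric(0), names = x$signature)
  graphics::bxp(z, las = 2, ylab = "estimated exposure",
                main = paste0("Bootstrapped exposures: ", attr(x, "sample_id"),
                              " (R = ", attr(x, "R"), ")"), ...)
  graphics::points(seq_len(nrow(x)), x$original, pch = 8, col = "red")
  invisible(x)
}

#' Write a bootstrap exposure summary as TSV
#'
#' @param x An \code{exposure_summary}.
#' @param path Output path.
#' @param provenance Optional \code{#}-prefixed header lines.
#' @export
write_exposure_summary <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "exposure_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(paste0("sample: ", attr(x, "sample_id")),
              paste0("R: ", attr(x, "R")),
              paste0("seed: ", attr(x, "seed")), provenance)
  writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
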
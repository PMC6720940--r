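# Synthetic catalogue generation. Catalogues are multinomial draws either
# from a weighted mixture of signature profiles (the accuracy experiments)
# or from a "null" distribution proportional to genomic trinucleotide
# availability (absence of process-specific signal).

.as_cohort <- function(catalogues, truth_weights, n_mutations, seed, tag) {
  structure(list(catalogues = catalogues, truth_weights = truth_weights,
                 n_mutations = as.integer(n_mutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 generator_tag = tag),
            class = "sim_cohort")
}

#' Simulate mutational catalogues from a signature mixture
#'
#' Draws each catalogue as an independent multinomial sample of
#' \code{n_mutations} mutations from the channel distribution
#' \code{q = P \%*\% w}, where \code{w} are the mixture weights. The
#' validation experiments in this package use five signatures at weight 0.2
#' each and 1000 mutations per catalogue.
#'
#' @param P 96 x N signature matrix.
#' @param weights Named numeric vector of mixture weights over a subset of
#'   \code{colnames(P)} (or a full-length vector in column order);
#'   non-negative, summing to 1.
#' @param n_mutations Mutations per catalogue (default 1000).
#' @param n_samples Number of catalogues (default 1).
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return A \code{"sim_cohort"}: list with \code{catalogues} (96 x
#'   n_samples counts matrix), \code{truth_weights} (length-N vector over
#'   all signatures of P), \code{n_mutations}, \code{seed},
#'   \code{generator_tag}.
#' @export
#' @examples
#' P <- orthogonal_signatures(6)
#' co <- create_mut_catalogues(P, c(S1 = 0.5, S4 = 0.5), 1000, 3, seed = 1)
#' colSums(co$catalogues)
create_mut_catalogues <- function(P, weights, n_mutations = 1000L,
                                  n_samples = 1L, seed = NULL) {
  P <- .validate_profile_matrix(P)
  N <- ncol(P)
  w <- numeric(N)
  names(w) <- colnames(P)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), colnames(P))
    if (length(unknown) > 0L)
      stop("weights reference unknown signature(s): ",
           paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
  } else {
    if (length(weights) != N)
      stop("unnamed weights must have one entry per signature column")
    w[] <- weights
  }
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  stopifnot(n_mutations >= 1L, n_samples >= 1L)
  q <- as.numeric(P %*% w)
  q <- q / sum(q)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cat_mat <- stats::rmultinom(n_samples, size = n_mutations, prob = q)
  rownames(cat_mat) <- rownames(P)
  colnames(cat_mat) <- paste0("sim_", seq_len(n_samples))
  storage.mode(cat_mat) <- "double"
  .as_cohort(cat_mat, w, n_mutations, seed, "signature-mixture")
}

#' Simulate null catalogues from trinucleotide availability
#'
#' Draws catalogues whose channel probabilities are proportional to the
#' trinucleotide context frequencies of a reference region set, with the
#' three substitution classes of each context equally likely (a
#' maximum-entropy split: the null carries no mutational-process signal, so
#' no substitution class is preferred within a context). Such catalogues
#' represent the absence of any mutational process beyond sequence
#' availability.
#'
#' @param f A \code{trinuc_freq} object (or named 32-vector of counts).
#' @inheritParams create_mut_catalogues
#' @return A \code{"sim_cohort"} with \code{generator_tag}
#'   \code{"null-frequency"} and all-zero \code{truth_weights}.
#' @export
null_catalogues <- function(f, n_mutations = 1000L, n_samples = 1L,
                            seed = NULL) {
  freqs <- trinuc_frequencies(f)
  if (sum(freqs) == 0) stop("all-zero trinucleotide frequencies")
  q <- freqs[channel_contexts()] / 3
  q <- as.numeric(q / sum(q))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cat_mat <- stats::rmultinom(n_samples, size = n_mutations, prob = q)
  rownames(cat_mat) <- mut_channel_labels()
  colnames(cat_mat) <- paste0("null_", seq_len(n_samples))
  storage.mode(cat_mat) <- "double"
  .as_cohort(cat_mat, NULL, n_mutations, seed, "null-frequency")
}

#' Mean squared exposure-recovery error versus catalogue size
#'
#' For each catalogue size, simulates \code{replicates} catalogues from the
#' given mixture, refits exposures against the full signature matrix, and
#' averages the sum of squared errors between the true mixture weights and
#' the estimated proportions (over all signatures, so exposures assigned to
#' absent signatures count toward the error).
#'
#' @param P 96 x N signature matrix.
#' @param weights Mixture weights as in \code{\link{create_mut_catalogues}}.
#' @param sizes Integer vector of catalogue sizes (mutations per catalogue).
#' @param replicates Catalogues per size (default 100).
#' @param seed Integer seed governing the whole experiment.
#' @param constraint_mode Passed to \code{\link{estimate_exposure}}.
#' @return data.frame with columns \code{size}, \code{mean_sse},
#'   \code{replicates}, \code{seed}.
#' @export
prediction_error_curve <- function(P, weights, sizes, replicates = 100L,
                                   seed = NULL,
                                   constraint_mode = c("simplex", "nonneg")) {
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(all(sizes >= 1))
  P <- .validate_profile_matrix(P)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # derive one sub-seed per size so each size block is reproducible
  sub_seeds <- sample.int(.Machine$integer.max, length(sizes))
  mean_sse <- vapply(seq_along(sizes), function(i) {
    co <- create_mut_catalogues(P, weights, n_mutations = sizes[i],
                                n_samples = replicates, seed = sub_seeds[i])
    fit <- suppressWarnings(
      estimate_exposure(co$catalogues, P, constraint_mode))
    err <- sweep(fit$proportions, 2L, co$truth_weights, "-")
    mean(rowSums(err^2))
  }, numeric(1))
  data.frame(size = as.integer(sizes), mean_sse = mean_sse,
             replicates = as.integer(replicates),
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Deterministic orthogonal synthetic signatures
#'
#' Builds \code{n} signatures with mutually disjoint channel support: the 96
#' channels are split into \code{n} consecutive blocks and each signature is
#' uniform on its block. Useful as a best-case reference in accuracy
#' experiments (orthogonal signatures make the refit problem well
#' conditioned).
#'
#' @param n Number of signatures (2--96).
#' @return 96 x n column-stochastic matrix with names \code{S1..Sn}.
#' @export
orthogonal_signatures <- function(n) {
  stopifnot(n >= 2L, n <= 96L)
  P <- matrix(0, 96L, n, dimnames = list(mut_channel_labels(),
                                         paste0("S", seq_len(n))))
  bounds <- floor(seq(0L, 96L, length.out = n + 1L))
  for (j in seq_len(n)) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    P[idx, j] <- 1 / length(idx)
  }
  P
}

#' Random synthetic signature matrix
#'
#' Draws each signature column from a symmetric Dirichlet distribution over
#' the 96 channels. Low concentration gives spiky, well-separated profiles;
#' high concentration gives flat, mutually similar ones (mimicking the
#' redundancy of published signature sets).
#'
#' @param n Number of signatures.
#' @param concentration Dirichlet concentration parameter (default 0.5:
#'   moderately spiky, resembling real substitution signatures).
#' @param seed Integer seed.
#' @return 96 x n column-stochastic matrix with names \code{S1..Sn}. The
#'   matrix is synthetic: profiles do not correspond to any published
#'   signature set.
#' @export
synthetic_signature_matrix <- function(n, concentration = 0.5, seed = NULL) {
  stopifnot(n >= 1L, concentration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- matrix(stats::rgamma(96L * n, shape = concentration), 96L, n)
  # guard against an all-tiny column at very low concentration
  g[g < 1e-300] <- 1e-300
  P <- sweep(g, 2L, colSums(g), "/")
  dimnames(P) <- list(mut_channel_labels(), paste0("S", seq_len(n)))
  P
}

#' Write a simulated cohort to disk
#'
#' @param cohort A \code{"sim_cohort"}.
#' @param catalogue_path Output TSV path for the catalogues.
#' @param weights_path Optional output TSV path for the truth weights.
#' @export
write_cohort <- function(cohort, catalogue_path, weights_path = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  prov <- c(paste0("generator: ", cohort$generator_tag),
            paste0("n_mutations: ", cohort$n_mutations),
            paste0("seed: ", cohort$seed))
  write_catalogue_table(cohort$catalogues, catalogue_path, provenance = prov)
  if (!is.null(weights_path) && !is.null(cohort$truth_weights)) {
    utils::write.table(
      data.frame(signature = names(cohort$truth_weights),
                 weight = as.numeric(cohort$truth_weights)),
      weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}
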
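# Constrained least-squares core. The refit problem
#   e = argmin || m - P e ||_2   s.t. e >= 0  (and optionally sum(e) = 1)
# is solved by active-set iteration (Lawson-Hanson for the pure non-negative
# case, the same scheme with the simplex equality folded into the KKT system
# otherwise). Problems here are tiny (96 channels, tens of signatures), so
# the emphasis is on exact KKT termination, not speed.

.low_count_threshold <- 125

.clip_tol <- 1e-10   # solver negatives below this are clipped to zero
.kkt_tol <- 1e-10    # dual feasibility tolerance

# validate a profile matrix of arbitrary feature count (the fitting and
# simulation code is not tied to the 96 channels: toy problems and
# extended-feature signatures are legitimate inputs)
.validate_profile_matrix <- function(P, tol = .COLSUM_TOL) {
  P <- as.matrix(P)
  if (ncol(P) < 1L) stop("signature matrix needs at least one column")
  if (is.null(colnames(P))) colnames(P) <- paste0("S", seq_len(ncol(P)))
  if (any(P < 0)) stop("negative entries in the signature matrix")
  cs <- colSums(P)
  if (any(abs(cs - 1) > tol))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(P)[abs(cs - 1) > tol], collapse = ", "))
  storage.mode(P) <- "double"
  P
}

# align a catalogue matrix with a profile matrix (rows may be in any order
# when both carry feature names)
.conform_catalogue <- function(m, P) {
  if (is.numeric(m) && is.null(dim(m)))
    m <- matrix(m, ncol = 1L, dimnames = list(names(m), "sample_1"))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != nrow(P))
    stop("catalogue/matrix channel mismatch: ", nrow(m), " vs ", nrow(P),
         " rows")
  if (!is.null(rownames(m)) && !is.null(rownames(P))) {
    if (!setequal(rownames(m), rownames(P)))
      stop("catalogue/matrix channel mismatch: row names disagree")
    m <- m[rownames(P), , drop = FALSE]
  }
  if (any(m < 0)) stop("catalogue entries must be non-negative")
  if (is.null(colnames(m))) colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  m
}

# least squares on the passive set; ridge fallback for collinear columns
.ls_passive <- function(A, b) {
  s <- tryCatch(qr.coef(qr(A), b), error = function(e) NULL)
  if (is.null(s) || anyNA(s)) {
    G <- crossprod(A) + diag(1e-12, ncol(A))
    s <- solve(G, crossprod(A, b))
  }
  as.numeric(s)
}

# Lawson-Hanson non-negative least squares
.solve_nnls <- function(A, b, max_iter = 30L * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(A, b))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > .kkt_tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- .ls_passive(A[, passive, drop = FALSE], b)
      if (all(s[passive] > 0)) {
        x <- s
        break
      }
      viol <- passive & s <= 0
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive[passive & x <= .clip_tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

# least squares on the unit simplex: min ||b - A e||, sum(e) = 1, e >= 0
.solve_simplex_ls <- function(A, b, max_iter = 30L * ncol(A)) {
  n <- ncol(A)
  if (n == 1L) return(1)
  # start from the best single-signature vertex
  obj1 <- vapply(seq_len(n), function(j) sum((b - A[, j])^2), numeric(1))
  x <- numeric(n)
  x[which.min(obj1)] <- 1
  passive <- x > 0

  solve_kkt <- function(F) {
    Af <- A[, F, drop = FALSE]
    Q <- crossprod(Af)
    k <- ncol(Af)
    K <- rbind(cbind(Q, 1), c(rep(1, k), 0))
    rhs <- c(as.numeric(crossprod(Af, b)), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) {
      K[seq_len(k), seq_len(k)] <- Q + diag(1e-12, k)
      sol <- solve(K, rhs)
    }
    sol
  }

  for (iter in seq_len(max_iter)) {
    # inner loop: restore primal feasibility on the passive set
    repeat {
      sol <- solve_kkt(passive)
      s <- numeric(n)
      s[passive] <- sol[seq_len(sum(passive))]
      if (all(s[passive] >= -.clip_tol)) {
        x <- pmax(s, 0)
        x[!passive] <- 0
        lambda <- sol[sum(passive) + 1L]
        break
      }
      viol <- passive & s < 0
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      drop <- passive & x <= .clip_tol & s < 0
      if (!any(drop)) drop <- passive & x <= .clip_tol
      passive[drop] <- FALSE
      x[!passive] <- 0
      if (sum(passive) == 0L) {  # numerical corner: restart from a vertex
        passive[which.min(obj1)] <- TRUE
        x[] <- 0
        x[passive] <- 1
      }
    }
    # outer loop: dual feasibility. Stationarity gives g + lambda*1 = mu,
    # with mu the multipliers of the bound constraints (mu = 0 on the
    # passive set, mu >= 0 required elsewhere).
    g <- as.numeric(crossprod(A, A %*% x - b))
    mu <- g + lambda
    mu[passive] <- 0
    if (all(mu >= -.kkt_tol)) break
    passive[which.min(mu)] <- TRUE
  }
  x / sum(x)
}

#' Estimate signature exposures by constrained quadratic programming
#'
#' Solves, per sample, the refit problem: minimize the Euclidean distance
#' between the observed catalogue (as frequencies) and its reconstruction
#' \code{P \%*\% e}, subject to non-negative exposures. In the default
#' \code{"simplex"} mode the exposures are additionally constrained to sum
#' to 1, so they are directly the proportions of the mutational load
#' attributed to each signature; in \code{"nonneg"} mode only non-negativity
#' is imposed and proportions are obtained by renormalizing the raw weights.
#'
#' @param catalogues A 96 x S catalogue matrix or a single 96-vector, in
#'   counts or frequencies (counts are converted internally).
#' @param P 96 x N column-stochastic signature matrix.
#' @param constraint_mode \code{"simplex"} (default) or \code{"nonneg"}.
#' @return An object of class \code{"exposure_fit"}: a list with elements
#'   \code{proportions} (S x N matrix), \code{raw_weights} (S x N),
#'   \code{residual_norm} (length S: \eqn{\|m_{freq} - P e\|_2} at the
#'   solution, with e the proportions), \code{constraint_mode},
#'   \code{sample_ids} and \code{signature_names}.
#' @details Catalogues with a count total below 125 trigger a warning:
#'   below a few hundred mutations the 96 channels are too sparsely
#'   populated for a stable refit. Solver negatives above \code{-1e-10}
#'   are clipped to zero and the solution renormalized.
#' @export
#' @examples
#' P <- orthogonal_signatures(4)
#' m <- 250 * P[, 2]
#' fit <- estimate_exposure(m, P)
#' round(fit$proportions, 3)
estimate_exposure <- function(catalogues, P,
                              constraint_mode = c("simplex", "nonneg")) {
  constraint_mode <- match.arg(constraint_mode)
  P <- .validate_profile_matrix(P)
  m <- .conform_catalogue(catalogues, P)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("catalogue total is zero for sample(s): ",
         paste(colnames(m)[totals == 0] %||% which(totals == 0), collapse = ", "))
  low <- totals < .low_count_threshold & abs(totals - 1) > 1e-9
  if (any(low))
    warning("mutational catalogue size below ", .low_count_threshold,
            " for sample(s): ",
            paste(colnames(m)[low] %||% which(low), collapse = ", "),
            "; exposure estimates will be unstable", call. = FALSE)
  mf <- sweep(m, 2L, totals, "/")
  S <- ncol(mf)
  N <- ncol(P)
  raw <- matrix(0, S, N, dimnames = list(colnames(mf), colnames(P)))
  for (s in seq_len(S)) {
    b <- mf[, s]
    e <- if (constraint_mode == "simplex") .solve_simplex_ls(P, b)
         else .solve_nnls(P, b)
    e[e < .clip_tol] <- 0
    raw[s, ] <- e
  }
  rs <- rowSums(raw)
  prop <- sweep(raw, 1L, ifelse(rs > 0, rs, 1), "/")
  prop[rs == 0, ] <- 0
  resid <- vapply(seq_len(S), function(s) {
    sqrt(sum((mf[, s] - P %*% prop[s, ])^2))
  }, numeric(1))
  structure(list(proportions = prop, raw_weights = raw,
                 residual_norm = stats::setNames(resid, colnames(mf)),
                 constraint_mode = constraint_mode,
                 sample_ids = colnames(mf), signature_names = colnames(P)),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposure fit (", x$constraint_mode, " mode): ",
      length(x$sample_ids), " sample(s) x ", length(x$signature_names),
      " signature(s)\n", sep = "")
  show <- utils::head(cbind(round(x$proportions, 4),
                            residual = round(x$residual_norm, 4)), 10)
  print(show)
  invisible(x)
}

#' Reconstruct a catalogue from exposures
#'
#' @param m Observed 96-vector (counts or frequencies) the residual is
#'   computed against.
#' @param P 96 x N signature matrix.
#' @param e Exposure vector of length N.
#' @return List with \code{reconstruction} (the 96-vector \code{P e}) and
#'   \code{residual_norm} (\eqn{\|m - P e\|_2}).
#' @export
reconstruct <- function(m, P, e) {
  P <- as.matrix(P)
  if (length(m) != nrow(P)) stop("catalogue/matrix dimension mismatch")
  if (length(e) != ncol(P)) stop("exposure/matrix dimension mismatch")
  rec <- as.numeric(P %*% e)
  names(rec) <- rownames(P)
  list(reconstruction = rec, residual_norm = sqrt(sum((m - rec)^2)))
}

#' Pairwise cosine similarity of signature columns
#'
#' @param P 96 x N matrix with no zero columns.
#' @return N x N symmetric matrix; diagonal 1, entries in [0, 1] for
#'   non-negative columns.
#' @export
cosine_similarity_matrix <- function(P) {
  P <- as.matrix(P)
  norms <- sqrt(colSums(P^2))
  if (any(norms == 0))
    stop("zero column(s): ", paste(colnames(P)[norms == 0] %||%
                                     which(norms == 0), collapse = ", "))
  S <- crossprod(P) / outer(norms, norms)
  S[S > 1] <- 1  # guard rounding
  diag(S) <- 1
  S
}

#' Leave-one-out reconstruction stability of signatures
#'
#' For each signature, fits its profile as if it were a catalogue against
#' the remaining signatures (non-negative mode) and reports the cosine
#' similarity between the profile and its best reconstruction. Signatures
#' whose profile is nearly expressible by the others (similarity close to 1)
#' carry little independent information, and their exposure estimates are
#' correspondingly unstable.
#'
#' @param P 96 x N signature matrix with N >= 2.
#' @return Named numeric vector of per-signature similarities; 0 when the
#'   best reconstruction is the zero vector.
#' @export
reconstruction_stability <- function(P) {
  P <- .validate_profile_matrix(P)
  N <- ncol(P)
  if (N < 2L) stop("need at least two signatures")
  out <- vapply(seq_len(N), function(j) {
    rest <- P[, -j, drop = FALSE]
    e <- .solve_nnls(rest, P[, j])
    rec <- as.numeric(rest %*% e)
    nr <- sqrt(sum(rec^2))
    if (nr == 0) return(0)
    sum(P[, j] * rec) / (sqrt(sum(P[, j]^2)) * nr)
  }, numeric(1))
  stats::setNames(out, colnames(P))
}

#' Write an exposure table
#'
#' Samples x signatures proportions plus the per-sample residual norm, as a
#' tab-separated file.
#'
#' @param fit An \code{exposure_fit}.
#' @param path Output path.
#' @param provenance Optional \code{#}-prefixed header lines.
#' @export
write_exposure_table <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "exposure_fit"))
  tab <- data.frame(Sample = fit$sample_ids, fit$proportions,
                    Residual = fit$residual_norm, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
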
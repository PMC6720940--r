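# Independent oracles used against the package implementation. These stay
# deliberately naive: enumeration, direct arithmetic, no shared code with
# the solver under test.

# objective of the refit problem at a candidate exposure vector
ls_objective <- function(A, b, w) sum((b - as.numeric(A %*% w))^2)

# brute-force minimum over the simplex grid with components that are
# multiples of `step` (k = 2 or 3 signatures)
grid_simplex_min <- function(A, b, step = 1e-3) {
  k <- ncol(A)
  M <- round(1 / step)
  if (k == 2L) {
    w1 <- seq(0L, M) / M
    W <- rbind(w1, 1 - w1)
  } else if (k == 3L) {
    i <- rep.int(0:M, M + 1 - 0:M)
    j <- unlist(lapply(0:M, function(a) 0:(M - a)))
    W <- rbind(i / M, j / M, 1 - (i + j) / M)
  } else {
    stop("grid oracle supports 2 or 3 signatures")
  }
  resid <- b - A %*% W
  min(colSums(resid^2))
}

# uniform draws from the unit simplex (Dirichlet(1,...,1))
runif_simplex <- function(n, k) {
  g <- matrix(stats::rexp(n * k), k, n)
  sweep(g, 2L, colSums(g), "/")
}

# naive strand-collapsed trinucleotide tally by substring enumeration;
# centers restricted to `centers` (1-based) when given
enum_trinuc <- function(seq_str, centers = NULL) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  n <- nchar(seq_str)
  if (is.null(centers)) centers <- seq_len(n)
  centers <- centers[centers >= 2 & centers <= n - 1]
  out <- list()
  for (p in centers) {
    tri <- substr(seq_str, p - 1, p + 1)
    if (!grepl("^[ACGT]{3}$", tri)) next
    if (substr(tri, 2, 2) %in% c("A", "G")) tri <- rc(tri)
    out[[tri]] <- (out[[tri]] %||% 0) + 1
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# random small refit instances (channels x signatures), column-stochastic
random_instance <- function(channels, signatures) {
  A <- matrix(stats::runif(channels * signatures), channels, signatures)
  A <- sweep(A, 2L, colSums(A), "/")
  w <- as.numeric(runif_simplex(1L, signatures))
  b <- as.numeric(A %*% w) + stats::rnorm(channels, sd = 0.02)
  b <- pmax(b, 0)
  if (sum(b) == 0) b[1] <- 1
  b <- b / sum(b)
  list(A = A, b = b)
}

# a tiny 96-channel test matrix shared across files
toy_signatures <- function(n = 5, concentration = 0.3, seed = 42) {
  synthetic_signature_matrix(n, concentration = concentration, seed = seed)
}

as_cat <- function(v, id = "s1") {
  matrix(v, 96L, 1L, dimnames = list(mut_channel_labels(), id))
}

write_toy_vcf <- function(path, records, contigs = c(chr1 = 15L)) {
  head <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
            "##FILTER=<ID=q10,Description=\"Low quality\">",
            paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", sep = "\t"))
  writeLines(c(head, records), path)
  path
}

write_toy_fasta <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  Rsamtools::indexFa(path)
  path
}
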
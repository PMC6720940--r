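test_that("an exactly representable catalogue is recovered with zero residual", {
  P <- toy_signatures(5, seed = 2)
  m <- 1000 * P[, 3]
  fit <- estimate_exposure(as_cat(m), P)
  expect_equal(unname(fit$proportions[1, ]), c(0, 0, 1, 0, 0), tolerance = 1e-9)
  expect_lt(fit$residual_norm[[1]], 1e-9)
  # same in nonneg mode
  fit2 <- estimate_exposure(as_cat(m), P, constraint_mode = "nonneg")
  expect_equal(unname(fit2$proportions[1, 3]), 1, tolerance = 1e-9)
})

test_that("solver matches the brute-force simplex grid on 4-channel toy problems", {
  set.seed(101)
  for (i in 1:10) {
    inst <- random_instance(4, 2)
    grid_opt <- grid_simplex_min(inst$A, inst$b, step = 1e-3)
    fit <- estimate_exposure(inst$b, inst$A)
    obj <- ls_objective(inst$A, inst$b, as.numeric(fit$proportions[1, ]))
    expect_lte(obj, grid_opt + 1e-6)
    # and the grid's argmin is within one step of the solver's (L-inf)
    w1 <- seq(0, 1, by = 1e-3)
    objs <- colSums((inst$b - inst$A %*% rbind(w1, 1 - w1))^2)
    expect_lt(abs(w1[which.min(objs)] - fit$proportions[1, 1]), 1e-3 + 1e-9)
  }
})

test_that("solver optimality on random instances: never beaten by 10,000 feasible candidates", {
  set.seed(7)
  for (rep in 1:8) {
    P <- synthetic_signature_matrix(6, concentration = 0.4, seed = 100 + rep)
    w <- as.numeric(runif_simplex(1, 6))
    b <- pmax(as.numeric(P %*% w) + rnorm(96, sd = 0.003), 0)
    b <- b / sum(b)
    fit <- estimate_exposure(as_cat(b), P)
    sol <- as.numeric(fit$proportions[1, ])
    obj_sol <- ls_objective(P, b, sol)
    cand <- runif_simplex(5000, 6)
    # plus local perturbations of the solution, projected back to the simplex
    pert <- abs(sweep(matrix(rnorm(6 * 5000, sd = 0.01), 6), 1, sol, "+"))
    pert <- sweep(pert, 2, colSums(pert), "/")
    cand <- cbind(cand, pert)
    objs <- colSums((b - P %*% cand)^2)
    expect_gte(min(objs), obj_sol - 1e-9)
  }
})

test_that("exposures are invariant to rescaling the input counts", {
  P <- toy_signatures(5, seed = 3)
  set.seed(14)
  m <- as_cat(rpois(96, 15) + 1)
  f1 <- estimate_exposure(m, P)
  f2 <- estimate_exposure(997.3 * m, P)
  expect_equal(f1$proportions, f2$proportions, tolerance = 1e-9)
})

test_that("simplex-mode residual is never below nonneg-mode residual", {
  set.seed(77)
  P <- toy_signatures(6, seed = 9)
  for (i in 1:5) {
    m <- as_cat(rpois(96, 10) + 1)
    # residual at the actual minimizer of each mode's objective
    b <- m[, 1] / sum(m)
    e_simplex <- estimate_exposure(m, P)$proportions[1, ]
    e_nonneg <- estimate_exposure(m, P, "nonneg")$raw_weights[1, ]
    r_simplex <- sqrt(sum((b - P %*% e_simplex)^2))
    r_nonneg <- sqrt(sum((b - P %*% e_nonneg)^2))
    expect_gte(r_simplex, r_nonneg - 1e-9)
  }
})

test_that("zero-total catalogues and dimension mismatches are errors; low counts warn", {
  P <- toy_signatures(3)
  expect_error(estimate_exposure(as_cat(numeric(96)), P), "total is zero")
  m <- as_cat(numeric(96))
  m[1:4, 1] <- c(30, 30, 30, 30)  # total 120 < 125
  expect_warning(estimate_exposure(m, P), "below 125")
  m2 <- as_cat(numeric(96))
  m2[1:4, 1] <- 50
  expect_silent(estimate_exposure(m2, P))
})

test_that("reconstruct returns P e and its residual", {
  P <- toy_signatures(4, seed = 5)
  m <- as.numeric(P[, 1])
  z <- reconstruct(m, P, c(0, 0, 0, 0))
  expect_equal(z$reconstruction, rep(0, 96), ignore_attr = TRUE)
  expect_equal(z$residual_norm, sqrt(sum(m^2)))
  one <- reconstruct(m, P, c(1, 0, 0, 0))
  expect_equal(unname(one$reconstruction), unname(m))
  expect_equal(one$residual_norm, 0)
  # random instance vs direct multiply oracle
  set.seed(6)
  e <- runif(4)
  direct <- as.numeric(P %*% e)
  r <- reconstruct(m, P, e)
  expect_equal(unname(r$reconstruction), direct)
  expect_equal(r$residual_norm, sqrt(sum((m - direct)^2)))
  expect_error(reconstruct(m[1:10], P, e), "dimension mismatch")
})

test_that("cosine similarity matrix: hand case, bounds, zero-column error", {
  # 2-channel hand case: (1,0) vs normalized (1,1) -> 1/sqrt(2)
  A <- cbind(a = c(1, 0), b = c(1, 1) / sqrt(2))
  S <- cosine_similarity_matrix(A)
  expect_equal(unname(S["a", "b"]), 1 / sqrt(2))
  expect_equal(unname(diag(S)), c(1, 1))
  P <- toy_signatures(5, seed = 30)
  S2 <- cosine_similarity_matrix(P)
  expect_true(all(S2 >= 0 & S2 <= 1))
  expect_equal(S2, t(S2))
  # identical columns -> 1; disjoint supports -> 0
  O <- orthogonal_signatures(4)
  SO <- cosine_similarity_matrix(cbind(O, dup = O[, 1]))
  expect_equal(unname(SO["S1", "dup"]), 1)
  expect_equal(unname(SO["S1", "S2"]), 0)
  Z <- P
  Z[, 2] <- 0
  expect_error(cosine_similarity_matrix(Z), "zero column")
})

test_that("leave-one-out reconstruction stability: duplicates 1, disjoint 0", {
  O <- orthogonal_signatures(4)
  expect_equal(unname(reconstruction_stability(O)), rep(0, 4))
  D <- cbind(O[, 1:3], S4 = O[, 1])
  rs <- reconstruction_stability(D)
  expect_equal(unname(rs[c("S1", "S4")]), c(1, 1), tolerance = 1e-9)
  expect_error(reconstruction_stability(O[, 1, drop = FALSE]), "at least two")
})

test_that("exposure tables are written with proportions and residuals", {
  dir <- withr::local_tempdir()
  P <- toy_signatures(3, seed = 4)
  m <- cbind(as_cat(100 * P[, 1] + 1, "a"), as_cat(50 * P[, 2] + 2, "b"))
  fit <- suppressWarnings(estimate_exposure(m, P))
  path <- file.path(dir, "exp.tsv")
  write_exposure_table(fit, path, provenance = "demo")
  tab <- read.delim(path, comment.char = "#", check.names = FALSE)
  expect_equal(tab$Sample, c("a", "b"))
  expect_equal(as.numeric(tab[1, c("S1", "S2", "S3")]),
               unname(fit$proportions[1, ]), tolerance = 1e-12)
})
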
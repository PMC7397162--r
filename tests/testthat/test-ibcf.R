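test_that("standardization uses observed-cell means and population SD", {
  std <- standardize_phenotypes(worked_phenotypes())
  expect_lt(max(abs(std$params$mu - c(1.63, 2.50, 1.94, 2.75))), 0.00501)
  expect_lt(max(abs(std$params$sigma - c(0.28, 0.40, 0.27, 0.31))), 0.00501)
  z <- ibcfgs:::pheno_matrix(std$z)
  expect_equal(round(z["4", "A"], 2), 1.34)
  # observed columns of Z have mean ~0 and population SD ~1
  for (j in colnames(z)) {
    x <- z[!is.na(z[, j]), j]
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-10)
  }
})

test_that("standardizing an already-standard column is a no-op", {
  x <- c(-1.2, -0.3, 0.1, 1.4)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  p <- tibble::tibble(line = sprintf("L%d", 1:4), A = x, B = rnorm(4))
  std <- standardize_phenotypes(p)
  expect_equal(std$params$mu[1], 0)
  expect_equal(std$params$sigma[1], 1)
  expect_equal(std$z$A, x)
})

test_that("constant columns are rejected by name", {
  p <- tibble::tibble(line = sprintf("L%d", 1:4), A = rnorm(4), B = rep(2, 4))
  expect_error(standardize_phenotypes(p), "B")
})

test_that("similarity matches a brute-force pairwise Pearson oracle", {
  m <- random_pheno(6, 3, n_miss = 3, seed = 11)
  sim <- similarity_matrix(ibcfgs:::matrix_to_pheno(m))
  for (j in 1:3) {
    for (k in 1:3) {
      both <- !is.na(m[, j]) & !is.na(m[, k])
      expected <- if (sum(both) >= 2) cor(m[both, j], m[both, k]) else 0
      expect_equal(sim$w[j, k], expected, tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(sim$w))
  expect_equal(diag(sim$w), setNames(rep(1, 3), colnames(m)))
})

test_that("degenerate similarity pairs are flagged, not fatal", {
  p <- tibble::tibble(
    line = sprintf("L%d", 1:4),
    A = c(1, 2, NA, NA), B = c(NA, NA, 1, 2), C = c(1, 2, 3, 4)
  )
  sim <- similarity_matrix(p)
  expect_false(sim$defined["A", "B"])  # zero complete pairs
  expect_equal(sim$w["A", "B"], 0)
  expect_equal(sim$w["A", "C"], 1)     # duplicated shape -> 1
  p2 <- tibble::tibble(line = sprintf("L%d", 1:4),
                       A = c(1, 2, 3, 4), B = -c(1, 2, 3, 4))
  expect_equal(similarity_matrix(p2)$w["A", "B"], -1)
})

test_that("the worked example's four imputations reproduce at 2 decimals", {
  fit <- ibcf_impute(worked_phenotypes(), similarity = worked_similarity())
  cells <- dplyr::arrange(tidy(fit), line)
  expect_equal(cells$item, c("A", "B", "C", "D"))
  expect_equal(round(cells$y_hat, 2), c(1.97, 2.86, 1.92, 2.77))
  expect_equal(round(cells$z_hat, 2), c(1.22, 0.90, -0.08, 0.07))
  expect_false(any(cells$flagged))
  # observed cells pass through untouched
  expect_equal(fit$predictions$B[-2], worked_phenotypes()$B[-2])
})

test_that("prediction equals the literal formula transcription", {
  m <- random_pheno(8, 5, n_miss = 6, seed = 3)
  fit <- ibcf_impute(ibcfgs:::matrix_to_pheno(m))
  for (r in seq_len(nrow(fit$cells))) {
    cell <- fit$cells[r, ]
    i <- match(cell$line, rownames(m))
    J <- match(cell$item, colnames(m))
    expect_equal(cell$y_hat, oracle_ibcf_cell(m, i, J), tolerance = 1e-12)
  }
})

test_that("equal positive weights reduce prediction to the neighbor mean", {
  m <- random_pheno(6, 4, n_miss = 0, seed = 5)
  m[2, 1] <- NA
  w <- matrix(0.5, 4, 4, dimnames = list(colnames(m), colnames(m)))
  diag(w) <- 1
  fit <- ibcf_impute(ibcfgs:::matrix_to_pheno(m),
                     similarity = ibcfgs:::new_similarity(w))
  z <- ibcfgs:::pheno_matrix(standardize_phenotypes(
    ibcfgs:::matrix_to_pheno(m))$z)
  expect_equal(fit$cells$z_hat, mean(z[2, 2:4]))
})

test_that("zero weights fall back to the item mean with a flag", {
  m <- random_pheno(6, 3, n_miss = 0, seed = 6)
  m[1, 1] <- NA
  w <- diag(3)
  dimnames(w) <- list(colnames(m), colnames(m))
  fit <- ibcf_impute(ibcfgs:::matrix_to_pheno(m),
                     similarity = ibcfgs:::new_similarity(w))
  expect_true(fit$cells$flagged)
  expect_equal(fit$cells$y_hat, mean(m[-1, 1]))
})

test_that("a line with nothing observed is flagged, not fatal", {
  m <- random_pheno(5, 3, n_miss = 0, seed = 7)
  m[3, ] <- NA
  fit <- ibcf_impute(ibcfgs:::matrix_to_pheno(m))
  cells <- dplyr::filter(fit$cells, line == rownames(m)[3])
  expect_equal(nrow(cells), 3L)
  expect_true(all(cells$flagged))
})

test_that("top_k = 1 uses only the most similar observed item", {
  m <- random_pheno(10, 4, n_miss = 0, seed = 8)
  m[1, 1] <- NA
  fit_all <- ibcf_impute(ibcfgs:::matrix_to_pheno(m))
  fit_1 <- ibcf_impute(ibcfgs:::matrix_to_pheno(m), top_k = 1)
  w <- fit_all$similarity$w
  best <- which.max(abs(w[1, 2:4])) + 1L
  z <- ibcfgs:::pheno_matrix(standardize_phenotypes(
    ibcfgs:::matrix_to_pheno(m))$z)
  expect_equal(fit_1$cells$z_hat, sign(w[1, best]) * z[1, best])
})

test_that("prediction is affine-equivariant in the target column", {
  m <- random_pheno(9, 4, n_miss = 4, seed = 9)
  fit1 <- ibcf_impute(ibcfgs:::matrix_to_pheno(m))
  a <- 2.5
  b <- -7
  m2 <- m
  m2[, 2] <- a * m[, 2] + b
  fit2 <- ibcf_impute(ibcfgs:::matrix_to_pheno(m2))
  c1 <- dplyr::arrange(fit1$cells, line, item)
  c2 <- dplyr::arrange(fit2$cells, line, item)
  idx <- c1$item == colnames(m)[2]
  expect_equal(c2$y_hat[idx], a * c1$y_hat[idx] + b, tolerance = 1e-10)
  expect_equal(c2$y_hat[!idx], c1$y_hat[!idx], tolerance = 1e-10)
  expect_equal(c2$z_hat, c1$z_hat, tolerance = 1e-10)
})

test_that("predictions are invariant to line and item order", {
  m <- random_pheno(9, 4, n_miss = 4, seed = 10)
  base <- dplyr::arrange(ibcf_impute(ibcfgs:::matrix_to_pheno(m))$cells,
                         line, item)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  shuf <- dplyr::arrange(ibcf_impute(ibcfgs:::matrix_to_pheno(perm))$cells,
                         line, item)
  expect_equal(as.data.frame(shuf), as.data.frame(base), tolerance = 1e-12)
})

test_that("standardized predictions are bounded by the neighbor extrema", {
  for (s in 1:5) {
    m <- random_pheno(10, 6, n_miss = 8, seed = 100 + s)
    fit <- ibcf_impute(ibcfgs:::matrix_to_pheno(m))
    z <- ibcfgs:::pheno_matrix(standardize_phenotypes(
      ibcfgs:::matrix_to_pheno(m))$z)
    for (r in which(!fit$cells$flagged)) {
      i <- match(fit$cells$line[r], rownames(m))
      zmax <- max(abs(z[i, !is.na(m[i, ])]))
      expect_lte(abs(fit$cells$z_hat[r]), zmax + 1e-12)
    }
  }
})

test_that("similarity files round-trip and feed prediction verbatim", {
  sim <- worked_similarity()
  f <- tempfile(fileext = ".csv")
  write_similarity(sim, f)
  sim2 <- read_similarity(f)
  expect_equal(sim2$w, sim$w)
  expect_equal(sim2$items, c("A", "B", "C", "D"))
})
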
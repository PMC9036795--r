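test_that("correction matrix is identity without derivatization atoms", {
  frag <- fragment_spec("bare", "C3", 3)
  M <- correction_matrix(frag, K = 3)
  expect_equal(unname(M), diag(4))
})

test_that("silicon columns carry the natural Si distribution", {
  frag <- fragment_spec("si1", "C2Si", 2)
  M <- correction_matrix(frag)
  expect_equal(unname(M[1:3, 1]), c(0.92223, 0.04685, 0.03092),
               tolerance = 1e-6)
  # a second Si self-convolves the distribution
  frag2 <- fragment_spec("si2", "C2Si2", 2)
  M2 <- correction_matrix(frag2)
  si <- natural_abundance_table()$Si
  self <- convolve(si, rev(si), type = "open")
  expect_equal(unname(M2[seq_along(self), 1]), self, tolerance = 1e-12)
})

test_that("correction columns sum to one minus a small truncated tail", {
  # heavily silylated fragments (up to 7 Si) push ~1% of spectral mass past
  # n + 4 shifts; the truncation bound reflects that
  for (frag in synthetic_fragments()) {
    M <- correction_matrix(frag) # K = n + 4
    sums <- colSums(M)
    expect_true(all(sums <= 1 + 1e-12))
    expect_true(all(1 - sums < 0.02))
  }
  # with a generous truncation the tail becomes negligible
  M <- correction_matrix(synthetic_fragments()$PG6, K = 20)
  expect_lt(1 - colSums(M)[1], 1e-6)
})

test_that("NNLS correction inverts the forward convolution", {
  frag <- fragment_spec("G6P", "C26H65NO9PSi6", 6)
  M <- correction_matrix(frag)
  x <- c(0.05, 0.60, 0.20, 0.10, 0.03, 0.01, 0.01)
  raw <- as.numeric(M %*% x)
  cc <- correct_cid(raw, frag)
  expect_lt(max(abs(cc$areas - x)), 1e-8)
  expect_equal(cc$ra, 100 * x / sum(x), tolerance = 1e-6)
  # reconvolving the corrected areas reproduces the raw vector
  expect_lt(max(abs(M %*% cc$areas - raw)), cc$residual_norm + 1e-8)
})

test_that("fully natural data corrects to the natural backbone binomial", {
  # the correction removes derivatization isotopes only: an unlabeled
  # metabolite keeps its backbone carbons at natural 13C abundance
  for (frag in synthetic_fragments()[c("G6P", "X5P", "PG3")]) {
    n <- frag$n_backbone_carbons
    backbone <- stats::dbinom(0:n, n, 0.0107)
    M <- correction_matrix(frag)
    raw <- as.numeric(M %*% backbone)
    cc <- correct_cid(raw, frag)
    expect_equal(cc$ra, 100 * backbone, tolerance = 1e-6)
  }
})

test_that("correction of column 0 gives a pure unlabeled backbone", {
  frag <- fragment_spec("X5P", "C19H50NO8PSi4", 5)
  M <- correction_matrix(frag)
  cc <- correct_cid(M[, 1], frag)
  expect_equal(cc$ra, c(100, rep(0, 5)), tolerance = 1e-6)
})

test_that("correction tolerates measurement noise", {
  set.seed(19)
  for (nm in c("X5P", "PG3")) {
    frag <- synthetic_fragments()[[nm]]
    n <- frag$n_backbone_carbons
    x <- stats::dbinom(0:n, n, 0.3)
    M <- correction_matrix(frag)
    clean <- as.numeric(M %*% x)
    worst <- 0
    for (i in 1:100) {
      raw <- pmax(clean + rnorm(length(clean), 0, 0.005 * max(clean)), 0)
      cc <- correct_cid(raw, frag)
      worst <- max(worst, max(abs(cc$ra - 100 * x)))
    }
    # 0.5%-of-max Gaussian noise stays close after deconvolution; larger
    # fragments amplify noise slightly more
    expect_lt(worst, if (n <= 5) 1 else 2)
  }
})

test_that("correct_cid rejects degenerate input", {
  frag <- fragment_spec("m", "C3Si", 3)
  expect_error(correct_cid(rep(0, 8), frag), "zero total area")
  expect_error(correct_cid(c(-1, 1, 1, 1), frag), "negative")
  expect_error(correct_cid(c(1, 1), frag), "shorter")
})

test_that("relative abundances implement the percent normalization", {
  expect_equal(relative_abundance(c(1, 1, 2)), c(25, 25, 50))
  expect_equal(relative_abundance(5), 100)
  x <- c(2, 3, 7, 1)
  expect_equal(relative_abundance(x), relative_abundance(10 * x))
  expect_equal(sum(relative_abundance(runif(6))), 100)
  expect_error(relative_abundance(c(0, 0)), "zero")
  expect_error(relative_abundance(c(-1, 2)), "negative")
})

test_that("Pascal QC expects binomial(n, 1/2) rows", {
  expect_equal(qc_pascal(c(25, 50, 25), 2)$expected, c(25, 50, 25))
  q3 <- qc_pascal(c(12.5, 37.5, 37.5, 12.5), 3)
  expect_equal(q3$expected, c(12.5, 37.5, 37.5, 12.5))
  expect_equal(q3$max_abs_dev, 0)
  expect_true(q3$pass)
  off <- qc_pascal(c(50, 30, 15, 5), 3, threshold = 5)
  expect_false(off$pass)
  expect_error(qc_pascal(c(1, 1), 3), "length")
})

test_that("formula parsing handles multi-letter elements and counts", {
  counts <- parse_formula("C26H65NO9PSi6")
  expect_equal(counts[["C"]], 26L)
  expect_equal(counts[["Si"]], 6L)
  expect_equal(counts[["N"]], 1L)
  expect_error(fragment_spec("x", "H2O", 1), "carbon")
  expect_error(fragment_spec("x", "C2H5", 3), "n_backbone_carbons")
})
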
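test_that("matrix CSV round-trips and allele names normalize", {
  mats <- test_matrices(2)
  dir <- write_matrix_dir(mats)
  reread <- load_pssm(file.path(dir, "DRB1_99_01.csv"))
  expect_equal(reread$allele, "DRB1*99:01")
  expect_equal(reread$matrix, mats[[1]]$matrix, tolerance = 1e-10)

  expect_equal(normalize_allele("DRB1*0101"), "DRB1*01:01")
  expect_equal(normalize_allele("hla-drb1*0901"), "DRB1*09:01")
  expect_equal(normalize_allele("DRB1*01:01"), "DRB1*01:01")
  expect_error(normalize_allele("DRB1*1"), "unrecognized")
})

test_that("malformed matrix files are rejected with a useful message", {
  m <- matrix(0, 9, 20, dimnames = list(NULL, amino_alphabet()))
  f <- tempfile(fileext = ".csv")
  writeLines(c("# allele=DRB1*01:01",
               paste(amino_alphabet(), collapse = ","),
               rep(paste(rep("0", 20), collapse = ","), 8)), f)
  expect_error(load_pssm(f), "expected 9 positions")

  writeLines(c("# allele=DRB1*01:01",
               paste(amino_alphabet(), collapse = ","),
               rep(paste(rep("0", 20), collapse = ","), 8),
               paste(c("x", rep("0", 19)), collapse = ",")), f)
  expect_error(load_pssm(f), "non-numeric")

  expect_error(pssm("DRB1*01:01", m[1:8, ]), "9 positions")
})

test_that("JSON matrix dialect loads", {
  mats <- test_matrices(1)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(allele = "DRB1*0407",
                            matrix = lapply(1:9, function(k)
                              unname(mats[[1]]$matrix[k, ]))),
                       f, auto_unbox = TRUE, digits = NA)
  p <- load_pssm(f)
  expect_equal(p$allele, "DRB1*04:07")
  expect_equal(p$matrix, mats[[1]]$matrix, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("null moments: constant matrix is degenerate, single position matches enumeration", {
  m <- matrix(3, 9, 20, dimnames = list(NULL, amino_alphabet()))
  p <- pssm("DRB1*01:01", m)
  nm <- null_moments(p)
  expect_equal(nm$mu, 27)
  expect_equal(nm$sigma, 0)
  expect_true(nm$degenerate)
  expect_error(zscore(5, nm), "degenerate")

  # one informative position: brute-force enumeration over the 20 residues
  m2 <- matrix(1, 9, 20, dimnames = list(NULL, amino_alphabet()))
  vals <- seq(-2, 2, length.out = 20)
  m2[4, ] <- vals
  nm2 <- null_moments(pssm("DRB1*01:01", m2))
  expect_equal(nm2$mu, 8 + mean(vals))
  expect_equal(nm2$sigma, sqrt(mean(vals^2) - mean(vals)^2))
})

test_that("null moments match a Monte-Carlo oracle for a random matrix", {
  p <- test_matrices(1, seed = 7)[[1]]
  nm <- null_moments(p)
  set.seed(11)
  n <- 1e6
  idx <- matrix(sample.int(20, 9 * n, replace = TRUE), ncol = 9)
  raw <- numeric(n)
  for (k in 1:9) raw <- raw + p$matrix[k, ][idx[, k]]
  se_mean <- stats::sd(raw) / sqrt(n)
  expect_lt(abs(mean(raw) - nm$mu), 3 * se_mean)
  se_sd <- stats::sd(raw) / sqrt(2 * n)
  expect_lt(abs(stats::sd(raw) - nm$sigma), 3 * se_sd)
})

test_that("9-mer scoring sums the indexed entries", {
  p <- test_matrices(1)[[1]]
  pep <- "ACDEFGHIK"
  manual <- sum(vapply(1:9, function(k)
    p$matrix[k, substr(pep, k, k)], 0))
  expect_equal(score_ninemer(p, pep), manual)

  zero <- pssm("DRB1*01:01", matrix(0, 9, 20, dimnames = list(NULL, amino_alphabet())))
  expect_equal(score_ninemer(zero, "AAAAAAAAA"), 0)
  ind <- matrix(0, 9, 20, dimnames = list(NULL, amino_alphabet()))
  ind[, "A"] <- 1
  expect_equal(score_ninemer(pssm("DRB1*01:01", ind), "AAAAAAAAA"), 9)

  expect_error(score_ninemer(p, "ACDE"), "exactly 9")
  expect_error(score_ninemer(p, "ACDEFGHIX"), "unknown residue")
})

test_that("z-scores center and scale, and standardize background 9-mers", {
  p <- test_matrices(1, seed = 3)[[1]]
  nm <- null_moments(p)
  expect_equal(zscore(nm$mu, nm), 0)
  expect_equal(zscore(nm$mu + 1.64 * nm$sigma, nm), 1.64)

  set.seed(5)
  n <- 1e5
  idx <- matrix(sample.int(20, 9 * n, replace = TRUE), ncol = 9)
  raw <- numeric(n)
  for (k in 1:9) raw <- raw + p$matrix[k, ][idx[, k]]
  z <- zscore(raw, nm)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(stats::sd(z) - 1), 0.01)
})

test_that("hit classification is inclusive at both cutoffs and monotone", {
  t <- hit_thresholds()
  expect_equal(classify_hit(1.64, t), "hit")
  expect_equal(classify_hit(1.30, t), "likely")
  expect_equal(classify_hit(1.28, t), "likely")
  expect_equal(classify_hit(0, t), "none")
  zs <- sort(stats::rnorm(200, sd = 2))
  lev <- match(classify_hit(zs, t), c("none", "likely", "hit"))
  expect_true(all(diff(lev) >= 0))
  expect_error(hit_thresholds(hit = 1, likely = 2), "below")
})
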
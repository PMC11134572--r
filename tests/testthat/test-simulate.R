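test_that("matrix generation is seed-deterministic and non-degenerate", {
  a <- generate_pssm_set(3, seed = 5)
  b <- generate_pssm_set(3, seed = 5)
  expect_identical(lapply(a, `[[`, "matrix"), lapply(b, `[[`, "matrix"))
  for (p in a) expect_false(null_moments(p)$degenerate)
  expect_equal(names(a), sprintf("DRB1*99:%02d", 1:3))
})

test_that("random 9-mers hit at roughly the normal upper-tail rate", {
  mats <- generate_pssm_set(4, seed = 61)
  pr <- generate_random_protein(2000, seed = 62)
  g <- scan_protein(pr, mats)
  rate <- mean(g$hit_class == "hit")
  n <- length(g$hit_class)
  p0 <- stats::pnorm(-1.64)
  # frames overlap, so allow a generous multiple of the binomial SE
  expect_lt(abs(rate - p0), 6 * sqrt(p0 * (1 - p0) / n))
})

test_that("planted epitopes are recovered exactly and Tregitope plants mask them", {
  mats <- generate_pssm_set(4, seed = 71)
  sp <- sim_spec(seed = 9, protein_length = 180,
                 planted_epitopes = data.frame(
                   allele = c("DRB1*99:01", "DRB1*99:03", "DRB1*99:01"),
                   position = c(15L, 60L, 130L), target_z = 2),
                 planted_tregitopes = data.frame(id = "TRG_A", start = 12L,
                                                 length = 15L))
  pl <- plant_protein(sp, mats)
  g <- scan_protein(pl$protein, mats, registry = pl$registry)
  # every planted cell is a hit; nothing else reaches the likely tier
  cells <- which(g$z >= g$thresholds$likely, arr.ind = TRUE)
  expect_equal(nrow(cells), 3)
  found <- data.frame(allele = g$alleles[cells[, 2]], frame = cells[, 1])
  expect_equal(found[order(found$frame), ],
               pl$truth[order(pl$truth$frame), c("allele", "frame")],
               ignore_attr = TRUE)
  expect_true(all(g$z[cbind(pl$truth$frame, match(pl$truth$allele, g$alleles))] >= 2))
  # the Tregitope span covers the first plant: adjusted < raw
  expect_true(g$masked[15])
  rep <- protein_score(g)
  expect_lt(rep$adjusted_score, rep$raw_score)

  # empty plant list: no cell anywhere reaches the likely tier
  sp0 <- sim_spec(seed = 10, protein_length = 120)
  g0 <- scan_protein(plant_protein(sp0, mats)$protein, mats)
  expect_equal(sum(g0$z >= g0$thresholds$likely), 0)
})

test_that("a Tregitope planted over every hit drops adjusted to the zero-hit floor", {
  mats <- generate_pssm_set(3, seed = 81)
  sp <- sim_spec(seed = 12, protein_length = 140,
                 planted_epitopes = data.frame(allele = "DRB1*99:02",
                                               position = 50L, target_z = 2.2),
                 planted_tregitopes = data.frame(id = "TRG", start = 47L,
                                                 length = 16L))
  pl <- plant_protein(sp, mats)
  g <- scan_protein(pl$protein, mats, registry = pl$registry)
  rep <- protein_score(g)
  expect_equal(rep$adjusted_score, -null_cell_expectation(1.64) * 1000)
  expect_gt(rep$raw_score, rep$adjusted_score)
})

test_that("generators round-trip through the on-disk dialects", {
  mats <- generate_pssm_set(2, seed = 91)
  dir <- write_matrix_dir(mats)
  reread <- lapply(sort(list.files(dir, full.names = TRUE)), load_pssm)
  expect_equal(lapply(reread, `[[`, "matrix"),
               unname(lapply(mats, `[[`, "matrix")), tolerance = 1e-10)

  pr <- generate_random_protein(50, seed = 92, id = "roundtrip")
  fa <- tempfile(fileext = ".fasta")
  write_proteins(list(pr), fa)
  back <- read_proteins(fa)
  expect_equal(back$roundtrip$sequence, pr$sequence)
})

test_that("population tables honor the spec exactly; differential structure is controlled", {
  alleles <- sprintf("DRB1*99:%02d", 1:4)
  base <- stats::setNames(rep(0.05, 4), alleles)
  hi <- base; hi[1] <- 0.30
  lo <- base; lo[1] <- 0.01
  sp <- sim_spec(seed = 3, populations = list(
    list(label = "A", total_n = 1000, carrier = hi),
    list(label = "B", total_n = 1000, carrier = lo)))
  tabs <- generate_population_tables(sp)
  expect_equal(unname(tabs$A$carrier["DRB1*99:01"]), 0.30)
  # only the shifted allele's homozygote clears both 5% floors:
  # 0.30^2 - 0.01^2 = 0.0899
  dp <- differential_pairs(tabs$A, tabs$B, alleles)
  expect_equal(nrow(dp), 1)
  expect_equal(dp$allele_a, "DRB1*99:01")
  expect_equal(dp$allele_b, "DRB1*99:01")
  expect_equal(dp$diff, 0.30^2 - 0.01^2)
  # identical specs: no differential pairs
  sp2 <- sim_spec(seed = 3, populations = list(
    list(label = "A", total_n = 1000, carrier = hi),
    list(label = "B", total_n = 1000, carrier = hi)))
  t2 <- generate_population_tables(sp2)
  expect_equal(nrow(differential_pairs(t2$A, t2$B, alleles)), 0)
})

test_that("paired-score generation is seed-deterministic with the stated shift", {
  a <- generate_paired_scores(50, delta = 0.7, seed = 4)
  b <- generate_paired_scores(50, delta = 0.7, seed = 4)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  big <- generate_paired_scores(20000, delta = 0.7, seed = 6)
  expect_equal(mean(big$x - big$y), 0.7, tolerance = 0.05)
})
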
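test_that("scanning produces L-8 frames and errors on bad input", {
  mats <- test_matrices(3)
  pr <- generate_random_protein(100, seed = 1)
  g <- scan_protein(pr, mats)
  expect_equal(length(g$frames), 92)
  expect_equal(dim(g$z), c(92, 3))
  expect_equal(length(g$frames) * length(g$alleles), 276)

  g1 <- scan_protein(generate_random_protein(9, seed = 2), mats)
  expect_equal(length(g1$frames), 1)

  expect_error(scan_protein(protein_record("x", "ACDEFGHI"), mats), "too short")
  expect_error(protein_record("x", "ACDEFGHIB"), "unknown residue")
})

test_that("grid z-values agree with per-9-mer scoring", {
  mats <- test_matrices(2)
  pr <- generate_random_protein(40, seed = 9)
  g <- scan_protein(pr, mats)
  nm <- null_moments(mats[[2]])
  for (f in c(1, 13, 32)) {
    pep <- substr(pr$sequence, f, f + 8)
    expect_equal(unname(g$z[f, 2]), zscore(score_ninemer(mats[[2]], pep), nm))
  }
})

test_that("Tregitope spans: exact matches, merging, containment masking", {
  reg <- tregitope_registry(c("T1", "T2"), c("AAAAACCCCC", "CCCCCDDDDD"))
  pr <- protein_record("p", paste0(strrep("G", 20), "AAAAACCCCCDDDDD", strrep("G", 20)))
  spans <- find_tregitope_spans(pr, reg)
  # overlapping matches merge into one maximal run
  expect_equal(nrow(spans), 1)
  expect_equal(spans$start, 21)
  expect_equal(spans$end, 35)

  # absent peptide -> empty
  expect_equal(nrow(find_tregitope_spans(
    protein_record("q", strrep("G", 30)), reg)), 0)

  # protein identical to a registry peptide -> full-length span
  pr2 <- protein_record("r", "AAAAACCCCC")
  s2 <- find_tregitope_spans(pr2, reg)
  expect_equal(c(s2$start, s2$end), c(1, 10))

  # only frames fully inside the span are masked
  mats <- test_matrices(1)
  g <- scan_protein(pr, mats, registry = reg)
  masked_frames <- which(g$masked)
  expect_equal(masked_frames, 21:27)  # 9-mers within [21, 35]
})

test_that("protein score closed forms: zero-hit floor and uniform threshold grid", {
  e0 <- null_cell_expectation(1.64)
  expect_equal(e0, stats::dnorm(1.64))

  z0 <- matrix(0, 50, 4)
  rep0 <- protein_score(make_grid(z0))
  expect_equal(rep0$raw_score, -e0 * 1000)
  expect_equal(rep0$raw_score, -103.9611, tolerance = 1e-4)

  z1 <- matrix(1.64, 50, 4)
  rep1 <- protein_score(make_grid(z1))
  expect_equal(rep1$raw_score, (1.64 - e0) * 1000)
})

test_that("masking all hits drops the adjusted score to the zero-hit floor", {
  z <- matrix(0, 30, 2)
  z[10, 1] <- 2.5; z[11, 2] <- 3.0
  masked <- rep(FALSE, 30); masked[10:11] <- TRUE
  rep <- protein_score(make_grid(z, masked = masked))
  expect_equal(rep$adjusted_score, -null_cell_expectation(1.64) * 1000)
  expect_gt(rep$raw_score, rep$adjusted_score)
})

test_that("adjusted <= raw on random proteins; equality iff no hit frame masked", {
  mats <- test_matrices(2, seed = 5)
  for (s in 1:25) {
    pr <- generate_random_protein(120, seed = 1000 + s)
    # registry built from the protein's own 12-mer, present in half the cases
    reg <- if (s %% 2 == 0) {
      tregitope_registry("T", substr(pr$sequence, 30, 44))
    } else NULL
    g <- scan_protein(pr, mats, registry = reg)
    rep <- protein_score(g)
    expect_lte(rep$adjusted_score, rep$raw_score + 1e-12)
    masked_hit <- any(g$masked & apply(g$hit_class == "hit", 1, any))
    expect_equal(isTRUE(all.equal(rep$adjusted_score, rep$raw_score)),
                 !masked_hit)
  }
})

test_that("score is invariant under duplicating the allele panel", {
  mats <- test_matrices(2, seed = 21)
  pr <- generate_random_protein(150, seed = 3)
  # copies of both matrices under fresh names: O and A scale equally
  dups <- list(pssm("DRB1*98:01", mats[[1]]$matrix),
               pssm("DRB1*98:02", mats[[2]]$matrix))
  s2 <- protein_score(scan_protein(pr, mats))
  s4 <- protein_score(scan_protein(pr, c(mats, dups)))
  expect_equal(s4$raw_score, s2$raw_score, tolerance = 1e-12)
  expect_equal(s4$adjusted_score, s2$adjusted_score, tolerance = 1e-12)
  # single-allele set: duplicating that allele is also exactly neutral
  s1 <- protein_score(scan_protein(pr, mats[1]))
  s1d <- protein_score(scan_protein(pr, list(mats[[1]], dups[[1]])))
  expect_equal(s1d$raw_score, s1$raw_score, tolerance = 1e-12)
})

test_that("appending hit-free sequence dilutes the score toward the floor", {
  mats <- test_matrices(1, seed = 31)
  sp <- sim_spec(seed = 8, protein_length = 120,
                 planted_epitopes = data.frame(allele = "DRB1*99:01",
                                               position = 40L, target_z = 2.5))
  pl <- plant_protein(sp, mats)
  base <- protein_score(scan_protein(pl$protein, mats))$raw_score
  floor <- -null_cell_expectation(1.64) * 1000
  expect_gt(base, floor)
  # lengthening with a hit-free tail (planted spec, longer, same single plant)
  sp2 <- sim_spec(seed = 8, protein_length = 240,
                  planted_epitopes = data.frame(allele = "DRB1*99:01",
                                                position = 40L, target_z = 2.5))
  longer <- protein_score(scan_protein(plant_protein(sp2, mats)$protein, mats))$raw_score
  expect_lt(longer, base)
  expect_gt(longer, floor)
})

test_that("reference annotations are metadata, not recomputed values", {
  ann <- reference_annotations()
  expect_false(ann$recomputable)
  expect_lt(ann$secreted_median, ann$human_proteome_median)
})
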
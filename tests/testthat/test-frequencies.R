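test_that("study aggregation is the sample-size-weighted mean", {
  s1 <- study_sample("P", "a", 100, c("DRB1*01:01" = 0.10))
  s2 <- study_sample("P", "b", 300, c("DRB1*01:01" = 0.20))
  tab <- aggregate_frequencies(list(s1, s2), "P")
  expect_equal(unname(tab$carrier["DRB1*01:01"]), 0.175)
  expect_equal(tab$total_n, 400)

  # single study passes through
  expect_equal(unname(aggregate_frequencies(list(s1), "P")$carrier["DRB1*01:01"]), 0.10)

  # unreported alleles count as zero in the non-reporting study
  s3 <- study_sample("P", "c", 100, c("DRB1*02:01" = 0.50))
  tab2 <- aggregate_frequencies(list(s1, s3), "P")
  expect_equal(unname(tab2$carrier["DRB1*01:01"]), 0.05)
  # ... unless renormalization over reporting studies is requested
  tab3 <- aggregate_frequencies(list(s1, s3), "P", renormalize = TRUE)
  expect_equal(unname(tab3$carrier["DRB1*01:01"]), 0.10)

  expect_error(aggregate_frequencies(list(s1), "Q"), "no study samples")
})

test_that("aggregation is invariant under splitting a study in half", {
  whole <- study_sample("P", "w", 200, c("DRB1*04:05" = 0.3, "DRB1*09:01" = 0.1))
  half1 <- study_sample("P", "h1", 100, c("DRB1*04:05" = 0.3, "DRB1*09:01" = 0.1))
  half2 <- study_sample("P", "h2", 100, c("DRB1*04:05" = 0.3, "DRB1*09:01" = 0.1))
  expect_equal(aggregate_frequencies(list(whole), "P")$carrier,
               aggregate_frequencies(list(half1, half2), "P")$carrier)
})

test_that("panel filter keeps alleles strictly above the floor in any population", {
  t1 <- frequency_table("A", c("DRB1*01:01" = 0.005, "DRB1*04:10" = 0.038,
                               "DRB1*02:01" = 0.010), 100)
  t2 <- frequency_table("B", c("DRB1*01:01" = 0.005, "DRB1*04:10" = 0.0009,
                               "DRB1*02:01" = 0.009), 100)
  panel <- filter_panel(list(t1, t2))
  expect_true("DRB1*04:10" %in% panel)       # rare in B, common in A
  expect_false("DRB1*01:01" %in% panel)      # below floor everywhere
  expect_false("DRB1*02:01" %in% panel)      # exactly 1%: strict inequality
})

test_that("carrier/allele frequency conversion inverts Hardy-Weinberg carriage", {
  expect_equal(carrier_to_allele_freq(0), 0)
  expect_equal(carrier_to_allele_freq(0.75), 0.5)
  expect_equal(carrier_to_allele_freq(0.2877), 1 - sqrt(0.7123))
  p <- seq(0, 1, by = 0.05)
  expect_equal(carrier_to_allele_freq(1 - (1 - p)^2), p)
  expect_error(carrier_to_allele_freq(1.2), "\\[0, 1\\]")
})

test_that("joint probability is the carrier product, symmetric and monotone", {
  tabs <- drb1_reference_frequencies()
  jp <- joint_probability(tabs$Japanese, allele_pair("DRB1*09:01", "DRB1*09:01"))
  expect_equal(jp, 0.2877^2)
  ca <- joint_probability(tabs$Caucasian, allele_pair("DRB1*03:01", "DRB1*07:01"))
  expect_equal(ca, 0.2904 * 0.2405)
  expect_equal(ca, joint_probability(tabs$Caucasian, allele_pair("DRB1*07:01", "DRB1*03:01")))
  # absent allele contributes zero
  expect_equal(joint_probability(tabs$Japanese,
                                 allele_pair("DRB1*01:01", "DRB1*97:97")), 0)
  # monotone in each carrier fraction
  lo <- frequency_table("L", c("DRB1*01:01" = 0.1, "DRB1*02:01" = 0.2), 10)
  hi <- frequency_table("H", c("DRB1*01:01" = 0.3, "DRB1*02:01" = 0.2), 10)
  pr <- allele_pair("DRB1*01:01", "DRB1*02:01")
  expect_lt(joint_probability(lo, pr), joint_probability(hi, pr))
})

test_that("differential pairs on the packaged table reproduce the 3 + 6 split", {
  tabs <- drb1_reference_frequencies()
  panel <- filter_panel(tabs)
  expect_equal(length(panel), 26)
  dp <- differential_pairs(tabs$Japanese, tabs$Caucasian, panel)
  expect_equal(nrow(dp), 9)
  expect_equal(sum(dp$dominant == "Caucasian"), 3)
  expect_equal(sum(dp$dominant == "Japanese"), 6)
  jp_set <- unique(unlist(dp[dp$dominant == "Japanese", c("allele_a", "allele_b")]))
  ca_set <- unique(unlist(dp[dp$dominant == "Caucasian", c("allele_a", "allele_b")]))
  expect_setequal(jp_set, c("DRB1*09:01", "DRB1*04:05", "DRB1*15:02"))
  expect_setequal(ca_set, c("DRB1*03:01", "DRB1*07:01"))
  # sorted by absolute difference, descending
  expect_true(all(diff(abs(dp$diff)) <= 0))
})

test_that("identical populations yield no differential pairs", {
  tabs <- drb1_reference_frequencies()
  dp <- differential_pairs(tabs$Japanese, tabs$Japanese, filter_panel(tabs))
  expect_equal(nrow(dp), 0)
  expect_error(differential_pairs(tabs$Japanese, tabs$Caucasian, character(0)),
               "empty")
})

test_that("study CSV and frequency CSV round-trip", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("population,study_id,sample_size,allele,carrier_percent",
               "P,a,100,DRB1*01:01,10",
               "P,a,100,DRB1*09:01,25",
               "P,b,300,DRB1*01:01,20"), f)
  samples <- read_study_samples(f)
  expect_length(samples, 2)
  tab <- aggregate_frequencies(samples, "P")
  expect_equal(unname(tab$carrier["DRB1*01:01"]), 0.175)
  expect_equal(unname(tab$carrier["DRB1*09:01"]), 0.0625)

  out <- tempfile(fileext = ".csv")
  write_frequency_tables(list(tab), out)
  back <- drb1_reference_frequencies(path = out, total_n = c(P = 400))
  expect_equal(unname(back$P$carrier["DRB1*01:01"]), 0.175, tolerance = 1e-4)
})
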
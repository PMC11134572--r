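#' Construct a study sample of carrier frequencies
#'
#' One population study: the fraction of typed individuals carrying each
#' HLA-DRB1 allele ("carrier" frequency, not gene-copy frequency).
#'
#' @param population Population label (free text).
#' @param study_id Study identifier.
#' @param sample_size Number of individuals typed (> 0).
#' @param carrier Named numeric vector, allele -> carrier fraction in [0, 1].
#' @return List of class `itemrisk_study`.
#' @export
study_sample <- function(population, study_id, sample_size, carrier) {
  if (sample_size <= 0) stop("sample_size must be > 0")
  if (any(carrier < 0 | carrier > 1)) stop("carrier fractions must be in [0, 1]")
  names(carrier) <- normalize_allele(names(carrier))
  structure(list(population = as.character(population),
                 study_id = as.character(study_id),
                 sample_size = as.numeric(sample_size),
                 carrier = carrier),
            class = "itemrisk_study")
}

#' Read study samples from CSV
#'
#' Long format with columns `population,study_id,sample_size,allele,
#' carrier_percent`; percentages on the 0-100 scale as printed in source
#' tables (fractions are used internally).
#'
#' @param path CSV file.
#' @return List of [study_sample()] objects.
#' @export
read_study_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("population", "study_id", "sample_size", "allele", "carrier_percent")
  if (!all(need %in% names(df))) {
    stop("study CSV must have columns ", paste(need, collapse = ","), ": ", path)
  }
  keys <- unique(df[, c("population", "study_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$population == keys$population[i] & df$study_id == keys$study_id[i], ]
    study_sample(keys$population[i], keys$study_id[i], sub$sample_size[1],
                 stats::setNames(sub$carrier_percent / 100, sub$allele))
  })
}

#' Construct a population frequency table
#'
#' @param population Population label.
#' @param carrier Named numeric vector, allele -> aggregated carrier fraction.
#' @param total_n Summed sample size behind the aggregation.
#' @return List of class `itemrisk_freq_table`.
#' @export
frequency_table <- function(population, carrier, total_n) {
  if (any(carrier < 0 | carrier > 1)) stop("carrier fractions must be in [0, 1]")
  names(carrier) <- normalize_allele(names(carrier))
  carrier <- carrier[order(names(carrier))]
  structure(list(population = as.character(population), carrier = carrier,
                 total_n = as.numeric(total_n)),
            class = "itemrisk_freq_table")
}

#' @export
print.itemrisk_freq_table <- function(x, ...) {
  cat("Frequency table:", x$population, "(", length(x$carrier), "alleles, n =",
      x$total_n, ")\n")
  invisible(x)
}

#' Aggregate multi-study carrier frequencies for one population
#'
#' Sample-size-weighted mean of each allele's carrier fraction over the
#' population's studies. An allele unreported by a contributing study counts
#' as 0 in that study (set `renormalize = TRUE` to instead average only over
#' the studies that report the allele).
#'
#' @param samples List of [study_sample()] objects.
#' @param population Population label to aggregate.
#' @param renormalize Average over reporting studies only?
#' @return A [frequency_table()].
#' @export
aggregate_frequencies <- function(samples, population, renormalize = FALSE) {
  sel <- Filter(function(s) s$population == population, samples)
  if (!length(sel)) stop("no study samples for population '", population, "'")
  alleles <- sort(unique(unlist(lapply(sel, function(s) names(s$carrier)))))
  total_n <- sum(vapply(sel, function(s) s$sample_size, 0))
  carrier <- vapply(alleles, function(a) {
    num <- 0; den <- 0
    for (s in sel) {
      reported <- a %in% names(s$carrier)
      if (reported) num <- num + s$sample_size * s$carrier[[a]]
      if (reported || !renormalize) den <- den + s$sample_size
    }
    if (den == 0) 0 else num / den
  }, 0)
  frequency_table(population, carrier, total_n)
}

#' Select the allele panel above a frequency floor
#'
#' Alleles whose carrier frequency strictly exceeds `min_freq` in at least
#' one of the supplied population tables.
#'
#' @param tables List of [frequency_table()] objects.
#' @param min_freq Frequency floor as a fraction (default 0.01, i.e. 1%).
#' @return Sorted character vector of allele names.
#' @export
filter_panel <- function(tables, min_freq = 0.01) {
  if (!(min_freq > 0 && min_freq < 1)) stop("min_freq must be in (0, 1)")
  keep <- character(0)
  for (tab in tables) {
    keep <- union(keep, names(tab$carrier)[tab$carrier > min_freq])
  }
  sort(keep)
}

#' Convert carrier frequency to allele (gene-copy) frequency
#'
#' Under Hardy-Weinberg equilibrium the fraction of individuals carrying at
#' least one copy is `P = 1 - (1 - p)^2`, so `p = 1 - sqrt(1 - P)`.
#'
#' @param P Carrier fraction(s) in [0, 1].
#' @return Allele frequency(ies).
#' @export
carrier_to_allele_freq <- function(P) {
  if (any(P < 0 | P > 1)) stop("carrier fraction must be in [0, 1]")
  1 - sqrt(1 - P)
}

#' Canonical unordered allele pair
#'
#' @param allele_a,allele_b Allele names; `allele_a == allele_b` denotes a
#'   homozygous pair.
#' @return Character vector of length 2 in canonical (sorted) order, class
#'   `itemrisk_pair`.
#' @export
allele_pair <- function(allele_a, allele_b) {
  p <- sort(normalize_allele(c(allele_a, allele_b)))
  structure(p, class = "itemrisk_pair")
}

#' Joint carrier probability of an allele pair
#'
#' Probability that an individual carries both alleles of the pair, modeled
#' as the product of the two carrier fractions (independent carriage); a
#' homozygous pair gives the square. Alleles absent from the table
#' contribute probability 0.
#'
#' @param table A [frequency_table()].
#' @param pair An [allele_pair()].
#' @return Joint probability in [0, 1].
#' @export
joint_probability <- function(table, pair) {
  stopifnot(inherits(table, "itemrisk_freq_table"))
  p <- function(a) if (a %in% names(table$carrier)) table$carrier[[a]] else 0
  p(pair[1]) * p(pair[2])
}

#' Allele pairs with differential joint probability between two populations
#'
#' Enumerates all unordered pairs (including homozygous) over the panel and
#' keeps those whose joint carrier probability exceeds `jp_min` in at least
#' one population AND whose between-population absolute difference exceeds
#' `diff_min` (both strict). Each retained pair is labeled with its dominant
#' population (the larger joint probability); results sort by |diff|
#' descending.
#'
#' @param table_a,table_b Two [frequency_table()] objects.
#' @param panel Character vector of alleles (e.g. from [filter_panel()]).
#' @param jp_min Joint-probability floor (default 0.05).
#' @param diff_min Absolute-difference floor (default 0.05).
#' @return Data.frame with columns `allele_a`, `allele_b`, `jp_a`, `jp_b`,
#'   `diff` (jp_a - jp_b), `dominant`.
#' @export
differential_pairs <- function(table_a, table_b, panel,
                               jp_min = 0.05, diff_min = 0.05) {
  if (!length(panel)) stop("empty allele panel")
  panel <- sort(normalize_allele(panel))
  k <- length(panel)
  rows <- vector("list", k * (k + 1) / 2)
  n <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pr <- allele_pair(panel[i], panel[j])
      ja <- joint_probability(table_a, pr)
      jb <- joint_probability(table_b, pr)
      if (max(ja, jb) > jp_min && abs(ja - jb) > diff_min) {
        n <- n + 1
        rows[[n]] <- data.frame(
          allele_a = pr[1], allele_b = pr[2], jp_a = ja, jp_b = jb,
          diff = ja - jb,
          dominant = if (ja >= jb) table_a$population else table_b$population,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0) {
    return(data.frame(allele_a = character(0), allele_b = character(0),
                      jp_a = numeric(0), jp_b = numeric(0),
                      diff = numeric(0), dominant = character(0)))
  }
  out <- do.call(rbind, rows[seq_len(n)])
  out[order(-abs(out$diff)), , drop = FALSE]
}

#' Packaged HLA-DRB1 carrier frequencies for two reference populations
#'
#' Aggregated carrier frequencies ("% of individuals that have the allele")
#' of 26 HLA-DRB1 alleles in Japanese and Caucasian reference populations,
#' compiled from multi-study allele-frequency data. Only alleles above 1%
#' carrier frequency in at least one population are included. The per-study
#' sample sizes behind the aggregation are not part of the table; the
#' `total_n` attached here (5000 Japanese, 20000 Caucasian) is a
#' representative aggregate size used only by the resampling stage.
#'
#' @param path Optional path to a two-population frequency CSV with columns
#'   `allele,<pop1>,<pop2>` (percent scale); defaults to the packaged table.
#' @param total_n Named numeric vector of aggregate sample sizes per
#'   population column.
#' @return Named list of two [frequency_table()] objects.
#' @export
drb1_reference_frequencies <- function(path = NULL,
                                       total_n = c(Japanese = 5000, Caucasian = 20000)) {
  if (is.null(path)) {
    path <- system.file("extdata", "drb1_carrier_frequencies.csv",
                        package = "itemrisk", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1] != "allele") stop("first column must be 'allele': ", path)
  pops <- names(df)[-1]
  out <- lapply(pops, function(p) {
    n <- if (p %in% names(total_n)) total_n[[p]] else 10000
    frequency_table(p, stats::setNames(df[[p]] / 100, df$allele), n)
  })
  names(out) <- pops
  out
}

#' Write a set of frequency tables as a two-population CSV
#'
#' @param tables Named list of [frequency_table()] objects sharing alleles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tables <- function(tables, path) {
  alleles <- sort(unique(unlist(lapply(tables, function(t) names(t$carrier)))))
  df <- data.frame(allele = alleles, stringsAsFactors = FALSE)
  for (tab in tables) {
    col <- vapply(alleles, function(a)
      if (a %in% names(tab$carrier)) tab$carrier[[a]] * 100 else 0, 0)
    df[[tab$population]] <- sprintf("%.2f", col)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
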
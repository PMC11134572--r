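#' Allele weight vector
#'
#' Nonnegative per-allele weights, typically carrier frequencies restricted
#' to a panel. Normalization to unit sum makes weighted scores comparable
#' across populations with different panel coverage.
#'
#' @param weights Named nonnegative numeric vector, allele -> weight.
#' @param normalize Rescale to sum to 1 (default TRUE)?
#' @return Named numeric vector of class `itemrisk_weights`.
#' @export
weight_vector <- function(weights, normalize = TRUE) {
  if (is.null(names(weights))) stop("weights must be named by allele")
  names(weights) <- normalize_allele(names(weights))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  if (normalize) weights <- weights / sum(weights)
  structure(weights, class = "itemrisk_weights")
}

#' Frequency-weighted protein score
#'
#' The frequency-weighted analogue of [protein_score()]: with F frames,
#' per-allele observed hit-Z content o_a, and weights w_a normalized to unit
#' sum, the score is `(sum_a w_a o_a / F - e0) * 1000`. With uniform weights
#' over exactly the grid's allele set this reduces to the unweighted score.
#'
#' @param grid An `itemrisk_grid`.
#' @param weights A [weight_vector()] (or named vector); alleles must be a
#'   subset of the grid's alleles with at least one positive weight.
#' @param adjusted Use Tregitope-adjusted content?
#' @return Numeric score.
#' @export
weighted_protein_score <- function(grid, weights, adjusted = FALSE) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  if (!inherits(weights, "itemrisk_weights")) weights <- weight_vector(weights)
  common <- intersect(names(weights), grid$alleles)
  if (!length(common) || sum(weights[common]) <= 0) {
    stop("weights have no positive overlap with the grid's alleles")
  }
  w <- weights[common] / sum(weights[common])
  o <- allele_content(grid, adjusted = adjusted)[common]
  F <- length(grid$frames)
  e0 <- null_cell_expectation(grid$thresholds$hit)
  (sum(w * o) / F - e0) * 1000
}

# Deterministic per-index substream seed; shared across populations so
# resample i of two populations uses common random numbers (pairable).
substream_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(index) * 1000003
  as.integer(s %% 2147483629 + 1)
}

#' Parametric bootstrap resample of a frequency table
#'
#' For each panel allele, draws a carrier count from
#' `Binomial(total_n, carrier)` and divides by `total_n`, emulating the
#' sampling noise of a frequency survey of the table's aggregate size.
#' Deterministic given `seed`; alleles are visited in canonical sorted
#' order.
#'
#' @param table A [frequency_table()] with `total_n > 0`.
#' @param panel Alleles to resample (default: all alleles in the table).
#' @param seed Integer seed.
#' @return A [frequency_table()] over `panel`.
#' @export
resample_frequency_table <- function(table, panel = names(table$carrier), seed) {
  stopifnot(inherits(table, "itemrisk_freq_table"))
  if (table$total_n <= 0) stop("table total_n must be > 0 to resample")
  panel <- sort(normalize_allele(panel))
  p <- vapply(panel, function(a)
    if (a %in% names(table$carrier)) table$carrier[[a]] else 0, 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- stats::rbinom(length(p), size = round(table$total_n), prob = p)
  frequency_table(table$population,
                  stats::setNames(counts / round(table$total_n), panel),
                  table$total_n)
}

#' Resampled frequency-weighted score distribution for one population
#'
#' Draws `n_resamples` parametric-bootstrap frequency tables, weights the
#' grid's per-allele epitope content by each resample's carrier fractions
#' (restricted to the panel and renormalized), and summarizes the resulting
#' score distribution. Resample i uses a per-index substream of `seed`, so
#' two populations run with the same `seed` are paired by resample index
#' (common random numbers), supporting a paired test downstream.
#'
#' @param grid An `itemrisk_grid`.
#' @param table A [frequency_table()].
#' @param panel Allele panel (must intersect the grid's alleles).
#' @param n_resamples Number of resamples (default 100).
#' @param seed Integer seed.
#' @param adjusted Use Tregitope-adjusted content?
#' @return List of class `itemrisk_score_dist` with `protein_id`,
#'   `population`, `scores`, `median`, `q1`, `q3`, `n_resamples`, `seed`.
#' @export
population_score_distribution <- function(grid, table, panel,
                                          n_resamples = 100, seed = 1,
                                          adjusted = FALSE) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  scores <- vapply(seq_len(n_resamples), function(i) {
    rt <- resample_frequency_table(table, panel, substream_seed(seed, i))
    w <- rt$carrier
    if (sum(w) <= 0) {
      # degenerate resample (all zero counts): fall back to uniform panel weights
      w <- stats::setNames(rep(1, length(panel)), sort(normalize_allele(panel)))
    }
    weighted_protein_score(grid, weight_vector(w), adjusted = adjusted)
  }, 0)
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(protein_id = grid$protein_id, population = table$population,
         scores = scores, q1 = qs[1], median = qs[2], q3 = qs[3],
         n_resamples = n_resamples, seed = seed, adjusted = adjusted),
    class = "itemrisk_score_dist"
  )
}

#' @export
print.itemrisk_score_dist <- function(x, ...) {
  cat(sprintf("%s / %s: median %.2f [Q1 %.2f, Q3 %.2f] over %d resamples%s\n",
              x$protein_id, x$population, x$median, x$q1, x$q3, x$n_resamples,
              if (x$adjusted) " (Tregitope-adjusted)" else ""))
  invisible(x)
}
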
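#' Individual (allele-pair) epitope measure
#'
#' The protein score restricted to the two HLA-DRB1 alleles an individual
#' carries: for a heterozygous pair {a, b} the score is
#' `(o_a + o_b - 2 F e0) / (2 F) * 1000`; a homozygous pair counts the
#' allele once, `(o_a - F e0) / F * 1000`, which equals the single-allele
#' protein score (duplicating both numerator and denominator would give the
#' same value).
#'
#' @param grid An `itemrisk_grid`.
#' @param pair An [allele_pair()] (or length-2 character vector); both
#'   alleles must be in the grid.
#' @param adjusted Use Tregitope-adjusted content?
#' @return Numeric score.
#' @export
item_score <- function(grid, pair, adjusted = FALSE) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  pair <- allele_pair(pair[1], pair[2])
  missing <- setdiff(unique(unclass(pair)), grid$alleles)
  if (length(missing)) {
    stop("allele(s) absent from grid: ", paste(missing, collapse = ", "))
  }
  o <- allele_content(grid, adjusted = adjusted)
  F <- length(grid$frames)
  e0 <- null_cell_expectation(grid$thresholds$hit)
  alleles <- unique(unclass(pair))
  k <- length(alleles)
  (sum(o[alleles]) - k * F * e0) / (k * F) * 1000
}

#' All-pairs distribution of individual scores for one protein
#'
#' Computes raw and Tregitope-adjusted scores for every unordered allele
#' pair over the panel (including homozygous pairs): k alleles give
#' k(k+1)/2 pairs. Quartile boundaries use linear interpolation (type 7) on
#' the adjusted scores.
#'
#' @param grid An `itemrisk_grid`.
#' @param panel Allele panel, a subset of the grid's alleles.
#' @return List of class `itemrisk_item_dist` with `protein_id`, `results`
#'   (data.frame: allele_a, allele_b, raw_item, adjusted_item), and
#'   `q1`, `median`, `q3` of the adjusted scores.
#' @export
item_distribution <- function(grid, panel = grid$alleles) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  if (!length(panel)) stop("empty allele panel")
  panel <- sort(normalize_allele(panel))
  missing <- setdiff(panel, grid$alleles)
  if (length(missing)) {
    stop("panel allele(s) absent from grid: ", paste(missing, collapse = ", "))
  }
  o_raw <- allele_content(grid, adjusted = FALSE)
  o_adj <- allele_content(grid, adjusted = TRUE)
  F <- length(grid$frames)
  e0 <- null_cell_expectation(grid$thresholds$hit)
  k <- length(panel)
  ia <- unlist(lapply(seq_len(k), function(i) rep(i, k - i + 1)))
  ib <- unlist(lapply(seq_len(k), function(i) i:k))
  pair_score <- function(o) {
    ifelse(ia == ib,
           (o[panel[ia]] - F * e0) / F * 1000,
           (o[panel[ia]] + o[panel[ib]] - 2 * F * e0) / (2 * F) * 1000)
  }
  results <- data.frame(
    allele_a = panel[ia], allele_b = panel[ib],
    raw_item = as.numeric(pair_score(o_raw)),
    adjusted_item = as.numeric(pair_score(o_adj)),
    stringsAsFactors = FALSE
  )
  qs <- stats::quantile(results$adjusted_item, c(0.25, 0.5, 0.75),
                        names = FALSE, type = 7)
  structure(
    list(protein_id = grid$protein_id, results = results,
         q1 = qs[1], median = qs[2], q3 = qs[3]),
    class = "itemrisk_item_dist"
  )
}

#' @export
print.itemrisk_item_dist <- function(x, ...) {
  cat(sprintf("%s: %d allele pairs; adjusted-score quartiles %.2f / %.2f / %.2f\n",
              x$protein_id, nrow(x$results), x$q1, x$median, x$q3))
  invisible(x)
}

#' Quartile placement of one allele pair
#'
#' Places a pair's Tregitope-adjusted score within the all-pairs
#' distribution: 1 = bottom quartile (score <= Q1), 2 = (Q1, median],
#' 3 = (median, Q3], 4 = top quartile (> Q3). Boundary scores fall to the
#' lower quartile.
#'
#' @param dist An `itemrisk_item_dist`.
#' @param pair An [allele_pair()] (or length-2 character vector).
#' @return Integer in 1..4.
#' @export
pair_quartile <- function(dist, pair) {
  stopifnot(inherits(dist, "itemrisk_item_dist"))
  pair <- allele_pair(pair[1], pair[2])
  row <- dist$results$allele_a == pair[1] & dist$results$allele_b == pair[2]
  if (!any(row)) stop("pair ", pair[1], "/", pair[2], " not in distribution")
  s <- dist$results$adjusted_item[which(row)[1]]
  if (s <= dist$q1) 1L
  else if (s <= dist$median) 2L
  else if (s <= dist$q3) 3L
  else 4L
}
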
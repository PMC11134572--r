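#' Paired score samples
#'
#' Two populations' resampled score vectors, paired by resample index.
#'
#' @param x,y Equal-length numeric vectors.
#' @param label Optional label (e.g. the protein id).
#' @return List of class `itemrisk_paired`.
#' @export
paired_samples <- function(x, y, label = "") {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must be equal-length vectors of length >= 1")
  }
  structure(list(label = as.character(label), x = as.numeric(x), y = as.numeric(y)),
            class = "itemrisk_paired")
}

# Signed-rank sums after dropping zero differences.
signed_rank_sums <- function(d) {
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero; test is degenerate")
  r <- rank(abs(d))
  list(w_plus = sum(r[d > 0]), w_minus = sum(r[d < 0]),
       n = length(d), ties = anyDuplicated(abs(d)) > 0)
}

#' Wilcoxon signed-rank test on paired samples
#'
#' Two-sided paired test of the score distributions. Zero differences are
#' dropped (standard convention). The exact null distribution is used for
#' n <= 25 without ties; otherwise a normal approximation with tie and
#' continuity correction. The statistic reported is W+ (the positive-rank
#' sum), alongside W-.
#'
#' @param s An [paired_samples()] object.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return List of class `itemrisk_test` with `label`, `w_plus`, `w_minus`,
#'   `n`, `p_value`, `effect_r` (matched-pairs rank-biserial), `mode`.
#' @export
wilcoxon_signed_rank <- function(s, mode = c("auto", "exact", "normal")) {
  stopifnot(inherits(s, "itemrisk_paired"))
  mode <- match.arg(mode)
  d <- s$x - s$y
  sr <- signed_rank_sums(d)
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = sr$n <= 25 && !sr$ties)
  ht <- suppressWarnings(
    stats::wilcox.test(s$x, s$y, paired = TRUE, exact = use_exact,
                       correct = TRUE, alternative = "two.sided")
  )
  structure(
    list(label = s$label, w_plus = sr$w_plus, w_minus = sr$w_minus,
         n = sr$n, p_value = ht$p.value,
         effect_r = (sr$w_plus - sr$w_minus) / (sr$w_plus + sr$w_minus),
         mode = if (use_exact) "exact" else "normal"),
    class = "itemrisk_test"
  )
}

#' @export
print.itemrisk_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank%s: W+ = %g, W- = %g, n = %d, p = %.4g (%s), r = %.3f\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$w_plus, x$w_minus, x$n, x$p_value, x$mode, x$effect_r))
  invisible(x)
}

#' Adjust p-values for multiple comparisons
#'
#' The six canonical adjustment approaches; each dominates the raw p-value
#' and is capped at 1.
#'
#' @param ps Numeric vector of p-values in [0, 1].
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`, `"hommel"`,
#'   `"BH"`, `"BY"`, or `"all"` for a matrix of every method.
#' @return Adjusted vector, or a matrix (one column per method) for
#'   `method = "all"`.
#' @export
adjust_pvalues <- function(ps, method = "all") {
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  methods <- c("bonferroni", "holm", "hochberg", "hommel", "BH", "BY")
  if (identical(method, "all")) {
    return(vapply(methods, function(m) stats::p.adjust(ps, method = m),
                  numeric(length(ps))))
  }
  if (!method %in% methods) {
    stop("unknown adjustment method '", method, "'; expected one of: ",
         paste(methods, collapse = ", "))
  }
  stats::p.adjust(ps, method = method)
}

#' Matched-pairs rank-biserial correlation
#'
#' Effect size for the paired signed-rank comparison:
#' `r = (W+ - W-) / (W+ + W-)`, in [-1, 1]; the sign follows the direction
#' of `x - y`.
#'
#' @param s A [paired_samples()] object.
#' @return Numeric effect size.
#' @export
rank_biserial <- function(s) {
  stopifnot(inherits(s, "itemrisk_paired"))
  sr <- signed_rank_sums(s$x - s$y)
  (sr$w_plus - sr$w_minus) / (sr$w_plus + sr$w_minus)
}

#' Shipped effect-size interpretation schemes
#'
#' Editable threshold tables mapping |r| to a categorical label. Each scheme
#' is a data.frame with columns `threshold` (lower bound, inclusive) and
#' `label`, sorted ascending; |r| falls in the highest bin whose threshold
#' it meets.
#'
#' @return Named list of scheme data.frames.
#' @export
effect_size_schemes <- function() {
  list(
    cohen = data.frame(
      threshold = c(0, 0.1, 0.3, 0.5),
      label = c("negligible", "small", "medium", "large"),
      stringsAsFactors = FALSE),
    evans = data.frame(
      threshold = c(0, 0.2, 0.4, 0.6, 0.8),
      label = c("very weak", "weak", "moderate", "strong", "very strong"),
      stringsAsFactors = FALSE)
  )
}

#' Categorical interpretation of an effect size
#'
#' @param r Effect size in [-1, 1] (magnitude is interpreted).
#' @param scheme Scheme name from [effect_size_schemes()], or a custom
#'   data.frame with columns `threshold` and `label`.
#' @return Character label.
#' @export
interpret_effect <- function(r, scheme = "cohen") {
  if (is.character(scheme)) {
    schemes <- effect_size_schemes()
    if (!scheme %in% names(schemes)) {
      stop("unknown effect-size scheme '", scheme, "'; shipped: ",
           paste(names(schemes), collapse = ", "))
    }
    scheme <- schemes[[scheme]]
  }
  stopifnot(all(c("threshold", "label") %in% names(scheme)))
  a <- abs(r)
  if (a > 1 + 1e-12) stop("effect size magnitude must be <= 1")
  scheme <- scheme[order(scheme$threshold), ]
  scheme$label[max(which(a >= scheme$threshold))]
}

#' Construct an ATA study record
#'
#' One reported anti-therapeutic-antibody (ATA) rate for a biologic.
#'
#' @param biologic Biologic name.
#' @param study_id Study identifier.
#' @param participants Number of participants (> 0).
#' @param ata_rate Reported ATA rate as a fraction in [0, 1].
#' @param monotherapy Was the rate observed under monotherapy?
#' @param excluded Exclude this study from aggregation?
#' @param reason Free-text exclusion reason.
#' @return List of class `itemrisk_ata_study`.
#' @export
ata_study <- function(biologic, study_id, participants, ata_rate,
                      monotherapy = TRUE, excluded = FALSE, reason = "") {
  if (participants <= 0) stop("participants must be > 0")
  if (ata_rate < 0 || ata_rate > 1) stop("ata_rate must be in [0, 1]")
  structure(list(biologic = as.character(biologic),
                 study_id = as.character(study_id),
                 participants = as.numeric(participants),
                 ata_rate = as.numeric(ata_rate),
                 monotherapy = isTRUE(monotherapy),
                 excluded = isTRUE(excluded), reason = as.character(reason)),
            class = "itemrisk_ata_study")
}

#' Read ATA study records from CSV
#'
#' Columns: `biologic,study_id,n,ata_percent,monotherapy,excluded,reason`
#' (percent on the 0-100 scale).
#'
#' @param path CSV file.
#' @return List of [ata_study()] objects.
#' @export
read_ata_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("biologic", "study_id", "n", "ata_percent")
  if (!all(need %in% names(df))) {
    stop("ATA CSV must have columns ", paste(need, collapse = ","), ": ", path)
  }
  if (is.null(df$monotherapy)) df$monotherapy <- TRUE
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$reason)) df$reason <- ""
  lapply(seq_len(nrow(df)), function(i)
    ata_study(df$biologic[i], df$study_id[i], df$n[i], df$ata_percent[i] / 100,
              as.logical(df$monotherapy[i]), as.logical(df$excluded[i]),
              df$reason[i]))
}

#' Participant-weighted aggregate ATA rate
#'
#' Average reported rate over non-excluded studies, weighted by the number
#' of study participants. With `monotherapy_only = TRUE`, rates observed
#' under concomitant medication are also dropped.
#'
#' @param studies List of [ata_study()] objects (one biologic).
#' @param monotherapy_only Restrict to monotherapy rates?
#' @return Aggregate rate as a fraction.
#' @export
aggregate_ata_rate <- function(studies, monotherapy_only = FALSE) {
  keep <- Filter(function(s) !s$excluded && (!monotherapy_only || s$monotherapy),
                 studies)
  if (!length(keep)) stop("no studies remain after exclusion filters")
  n <- vapply(keep, function(s) s$participants, 0)
  r <- vapply(keep, function(s) s$ata_rate, 0)
  sum(n * r) / sum(n)
}

#' Compare two population score distributions for one protein
#'
#' Pairs the two distributions by resample index, runs the signed-rank
#' test, and reports descriptive medians plus the rank-biserial effect size
#' with its categorical interpretation. Multiplicity adjustment across
#' proteins is applied separately with [adjust_pvalues()].
#'
#' @param dist_a,dist_b `itemrisk_score_dist` objects for the same protein.
#' @param scheme Effect-size interpretation scheme (see [interpret_effect()]).
#' @return One-row data.frame: protein, populations, medians, W+, W-, p,
#'   effect r, category.
#' @export
compare_populations <- function(dist_a, dist_b, scheme = "cohen") {
  stopifnot(inherits(dist_a, "itemrisk_score_dist"),
            inherits(dist_b, "itemrisk_score_dist"))
  if (dist_a$protein_id != dist_b$protein_id) {
    stop("distributions are for different proteins")
  }
  s <- paired_samples(dist_a$scores, dist_b$scores, label = dist_a$protein_id)
  tr <- wilcoxon_signed_rank(s)
  data.frame(
    protein = dist_a$protein_id,
    population_a = dist_a$population, population_b = dist_b$population,
    median_a = dist_a$median, median_b = dist_b$median,
    w_plus = tr$w_plus, w_minus = tr$w_minus, p_value = tr$p_value,
    effect_r = tr$effect_r,
    effect_category = interpret_effect(tr$effect_r, scheme),
    stringsAsFactors = FALSE
  )
}
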
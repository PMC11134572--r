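#' Construct a protein record
#'
#' @param id Sequence identifier.
#' @param sequence Amino-acid string over the canonical alphabet.
#' @return List of class `itemrisk_protein`.
#' @export
protein_record <- function(id, sequence) {
  seq <- toupper(gsub("\\s", "", sequence))
  res <- strsplit(seq, "")[[1]]
  bad <- which(!(res %in% amino_alphabet()))
  if (length(bad)) {
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1],
         " of protein ", id)
  }
  structure(list(id = as.character(id), sequence = seq),
            class = "itemrisk_protein")
}

#' Read proteins from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of [protein_record()] objects, named by id.
#' @export
read_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) protein_record(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' Write proteins to FASTA
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(vapply(proteins, function(p) p$sequence, ""))
  names(ss) <- vapply(proteins, function(p) p$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a Tregitope registry
#'
#' Accepts FASTA (ids from headers) or CSV with columns `id,peptide`.
#' Registry peptides are the regulatory T-cell epitope sequences whose
#' predicted binding content is excluded from the adjusted scores.
#'
#' @param path FASTA or CSV file.
#' @return A data.frame with columns `id` and `peptide`, class
#'   `itemrisk_registry`.
#' @export
read_tregitopes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("id", "peptide") %in% names(df))) {
      stop("registry CSV must have columns id,peptide: ", path)
    }
    reg <- df[, c("id", "peptide")]
  } else {
    ss <- Biostrings::readAAStringSet(path)
    reg <- data.frame(id = sub("\\s.*$", "", names(ss)),
                      peptide = as.character(ss), stringsAsFactors = FALSE)
  }
  tregitope_registry(reg$id, reg$peptide)
}

#' Construct a Tregitope registry
#'
#' @param id Character vector of unique registry ids.
#' @param peptide Character vector of peptide sequences (length >= 9).
#' @return A data.frame of class `itemrisk_registry`.
#' @export
tregitope_registry <- function(id, peptide) {
  peptide <- toupper(peptide)
  if (anyDuplicated(id)) stop("registry ids must be unique")
  if (any(nchar(peptide) < 9)) stop("registry peptides must be >= 9 residues")
  structure(data.frame(id = as.character(id), peptide = peptide,
                       stringsAsFactors = FALSE),
            class = c("itemrisk_registry", "data.frame"))
}

#' Locate Tregitope spans in a protein
#'
#' Finds all maximal exact substring matches of registry peptides in the
#' protein, in 1-based inclusive coordinates, and merges overlapping or
#' abutting matches into maximal covered runs. Matching is exact; no fuzzy
#' matching is attempted.
#'
#' @param protein A [protein_record()].
#' @param registry A [tregitope_registry()].
#' @return Data.frame with columns `start`, `end` (merged spans, sorted).
#' @export
find_tregitope_spans <- function(protein, registry) {
  stopifnot(inherits(protein, "itemrisk_protein"))
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(registry))) {
    pep <- registry$peptide[i]
    m <- gregexpr(pep, protein$sequence, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- c(starts, as.integer(m))
      ends <- c(ends, as.integer(m) + nchar(pep) - 1L)
    }
  }
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Scan a protein into a per-frame, per-allele Z-score grid
#'
#' Scores every overlapping 9-mer frame (1-based start positions 1..L-8,
#' step 1) against each allele's scoring matrix, converts raw scores to
#' Z-scores with the analytic null moments under `bg`, classifies each cell
#' at the thresholds, and marks frames whose nine residues all lie inside a
#' Tregitope span.
#'
#' @param protein A [protein_record()] of length >= 9.
#' @param matrices List of `itemrisk_pssm` objects (>= 1).
#' @param bg Background distribution (default uniform).
#' @param t Thresholds from [hit_thresholds()].
#' @param registry Optional [tregitope_registry()]; when supplied the grid's
#'   Tregitope mask is populated, otherwise no frame is masked.
#' @return An `itemrisk_grid`: list with `protein_id`, `frames`, `alleles`,
#'   `z` (frames x alleles), `hit_class`, `masked`, `thresholds`, `spans`.
#' @export
scan_protein <- function(protein, matrices, bg = background_frequencies(),
                         t = hit_thresholds(), registry = NULL) {
  stopifnot(inherits(protein, "itemrisk_protein"))
  if (inherits(matrices, "itemrisk_pssm")) matrices <- list(matrices)
  if (!length(matrices)) stop("at least one scoring matrix is required")
  L <- nchar(protein$sequence)
  if (L < 9) stop("protein ", protein$id, " is too short to scan (", L, " < 9)")
  res <- strsplit(protein$sequence, "")[[1]]
  ridx <- match(res, amino_alphabet())
  nF <- L - 8L
  frames <- seq_len(nF)
  # frame x position residue-index matrix
  idx <- outer(frames, 0:8, `+`)
  idx[] <- ridx[idx]
  alleles <- vapply(matrices, function(p) p$allele, "")
  if (anyDuplicated(alleles)) stop("duplicate allele matrices: ",
                                   paste(alleles[duplicated(alleles)], collapse = ", "))
  z <- matrix(NA_real_, nF, length(alleles), dimnames = list(NULL, alleles))
  for (j in seq_along(matrices)) {
    p <- matrices[[j]]
    nm <- null_moments(p, bg)
    raw <- numeric(nF)
    for (k in 1:9) raw <- raw + p$matrix[k, ][idx[, k]]
    z[, j] <- zscore(raw, nm)
  }
  hit_class <- matrix(classify_hit(z, t), nF, length(alleles),
                      dimnames = list(NULL, alleles))
  masked <- rep(FALSE, nF)
  spans <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(registry)) {
    spans <- find_tregitope_spans(protein, registry)
    for (i in seq_len(nrow(spans))) {
      inside <- frames >= spans$start[i] & (frames + 8L) <= spans$end[i]
      masked <- masked | inside
    }
  }
  structure(
    list(protein_id = protein$id, frames = frames, alleles = alleles,
         z = z, hit_class = hit_class, masked = masked,
         thresholds = t, spans = spans),
    class = "itemrisk_grid"
  )
}

#' @export
print.itemrisk_grid <- function(x, ...) {
  cat("Assessment grid for", x$protein_id, "\n")
  cat("  ", length(x$frames), "frames x", length(x$alleles), "alleles =",
      length(x$frames) * length(x$alleles), "assessments\n")
  cat("  ", sum(x$hit_class == "hit"), "hits,",
      sum(x$hit_class == "likely"), "likely,",
      sum(x$masked), "Tregitope-masked frames\n")
  invisible(x)
}

#' Per-allele observed epitope content
#'
#' The sum of Z-scores over cells classified as hits for each allele. With
#' `adjusted = TRUE`, cells in Tregitope-masked frames contribute zero.
#'
#' @param grid An `itemrisk_grid`.
#' @param adjusted Apply the Tregitope mask?
#' @return Named numeric vector over the grid's alleles.
#' @export
allele_content <- function(grid, adjusted = FALSE) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  keep <- grid$z * (grid$hit_class == "hit")
  if (adjusted) keep[grid$masked, ] <- 0
  colSums(keep)
}

#' Length-normalized protein immunogenicity score
#'
#' Aggregates predicted epitope content per unit length, relative to the
#' content expected of a random protein of the same length: with A = frames
#' x alleles assessments, O = sum of Z over hit cells, and e0 the null
#' per-cell expectation ([null_cell_expectation()]), the score is
#' `(O - A * e0) / A * 1000`. Positive scores indicate more epitope content
#' than random expectation. The Tregitope-adjusted variant zeroes the
#' contribution of masked frames but leaves A unchanged, so the adjusted
#' score never exceeds the raw score.
#'
#' @param grid An `itemrisk_grid`.
#' @return A list of class `itemrisk_score_report` with `protein_id`,
#'   `alleles`, `assessments`, `raw_score`, `adjusted_score`, and
#'   `per_allele_content` (a list with `raw` and `adjusted` named vectors).
#' @export
protein_score <- function(grid) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  nF <- length(grid$frames); nA <- length(grid$alleles)
  A <- nF * nA
  if (A == 0) stop("empty assessment grid")
  e0 <- null_cell_expectation(grid$thresholds$hit)
  o_raw <- allele_content(grid, adjusted = FALSE)
  o_adj <- allele_content(grid, adjusted = TRUE)
  structure(
    list(protein_id = grid$protein_id, alleles = grid$alleles,
         assessments = A,
         raw_score = (sum(o_raw) - A * e0) / A * 1000,
         adjusted_score = (sum(o_adj) - A * e0) / A * 1000,
         per_allele_content = list(raw = o_raw, adjusted = o_adj)),
    class = "itemrisk_score_report"
  )
}

#' @export
print.itemrisk_score_report <- function(x, ...) {
  cat(sprintf("%s: raw %.2f, Tregitope-adjusted %.2f (%d assessments)\n",
              x$protein_id, x$raw_score, x$adjusted_score, x$assessments))
  invisible(x)
}

#' Export a grid as long-format data
#'
#' @param grid An `itemrisk_grid`.
#' @return Data.frame with columns `protein`, `frame_start`, `allele`, `z`,
#'   `class`, `masked` (one row per assessment cell).
#' @export
grid_to_long <- function(grid) {
  stopifnot(inherits(grid, "itemrisk_grid"))
  data.frame(
    protein = grid$protein_id,
    frame_start = rep(grid$frames, times = length(grid$alleles)),
    allele = rep(grid$alleles, each = length(grid$frames)),
    z = as.vector(grid$z),
    class = as.vector(grid$hit_class),
    masked = rep(grid$masked, times = length(grid$alleles)),
    stringsAsFactors = FALSE
  )
}

#' Reference score annotations
#'
#' Published reference points on the protein immunogenicity score scale,
#' shipped as report metadata for plot annotation: the median
#' Tregitope-adjusted score of human proteins and of secreted human
#' proteins. These constants summarize external proteome-wide analyses with
#' proprietary scoring matrices; they cannot be recomputed from user-supplied
#' matrices and are marked accordingly.
#'
#' @return List with `human_proteome_median`, `secreted_median`, and
#'   `recomputable` (always FALSE).
#' @export
reference_annotations <- function() {
  list(human_proteome_median = -9.05, secreted_median = -23.08,
       recomputable = FALSE)
}
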
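#' Canonical amino-acid alphabet
#'
#' The fixed, ordered 20-letter amino-acid alphabet used by every scoring
#' matrix and sequence in the package. Column order in matrix files must
#' follow this order.
#'
#' @return Character vector of the 20 one-letter codes, alphabetical.
#' @export
amino_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' A background distribution over the 20 amino acids, used to calibrate the
#' null moments of 9-mer scores. The default is uniform; a named numeric
#' vector (e.g. proteome frequencies) may be supplied instead.
#'
#' @param probs Named numeric vector over [amino_alphabet()], or `NULL` for
#'   the uniform distribution. Values must be positive and sum to 1.
#' @return A named numeric vector of class `itemrisk_background`, ordered by
#'   the canonical alphabet.
#' @export
background_frequencies <- function(probs = NULL) {
  aa <- amino_alphabet()
  if (is.null(probs)) {
    probs <- stats::setNames(rep(1 / 20, 20), aa)
  }
  if (is.null(names(probs)) || !setequal(names(probs), aa)) {
    stop("background must be named over the full 20-letter alphabet")
  }
  probs <- probs[aa]
  if (any(probs <= 0)) stop("background probabilities must all be > 0")
  if (abs(sum(probs) - 1) > 1e-9) stop("background probabilities must sum to 1")
  structure(probs, class = "itemrisk_background")
}

#' Normalize an HLA-DRB1 allele name
#'
#' Accepts four-digit (`"DRB1*0901"`) and two-field colon (`"DRB1*09:01"`)
#' spellings, with or without the `"HLA-"` prefix; the canonical form is the
#' colon form, e.g. `"DRB1*09:01"`.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of canonical names.
#' @export
normalize_allele <- function(allele) {
  x <- toupper(trimws(as.character(allele)))
  x <- sub("^HLA-", "", x)
  bad <- !grepl("^DRB1\\*[0-9]{2}:?[0-9]{2}$", x)
  if (any(bad)) {
    stop("unrecognized allele name(s): ", paste(unique(allele[bad]), collapse = ", "))
  }
  sub("^(DRB1\\*[0-9]{2}):?([0-9]{2})$", "\\1:\\2", x)
}

#' Construct a position-specific scoring matrix (PSSM)
#'
#' A 9-position x 20-residue matrix of binding scores for one HLA-DRB1
#' allele. Raw 9-mer scores are additive over positions.
#'
#' @param allele Allele name (normalized with [normalize_allele()]).
#' @param matrix Numeric 9 x 20 matrix; columns named by [amino_alphabet()]
#'   (reordered to canonical order if needed).
#' @param source_tag Free-text provenance tag.
#' @return An object of class `itemrisk_pssm`.
#' @export
pssm <- function(allele, matrix, source_tag = "") {
  aa <- amino_alphabet()
  m <- as.matrix(matrix)
  if (nrow(m) != 9L) stop("expected 9 positions, got ", nrow(m))
  if (ncol(m) != 20L) stop("expected 20 residue columns, got ", ncol(m))
  if (is.null(colnames(m))) colnames(m) <- aa
  if (!setequal(colnames(m), aa)) {
    stop("matrix columns must cover the 20-letter alphabet; unknown: ",
         paste(setdiff(colnames(m), aa), collapse = ", "))
  }
  m <- m[, aa, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("matrix entries must all be finite")
  rownames(m) <- as.character(1:9)
  structure(
    list(allele = normalize_allele(allele), matrix = m,
         source_tag = as.character(source_tag)),
    class = "itemrisk_pssm"
  )
}

#' @export
print.itemrisk_pssm <- function(x, ...) {
  cat("PSSM for", x$allele,
      if (nzchar(x$source_tag)) paste0("[", x$source_tag, "]") else "", "\n")
  cat("  9 positions x 20 residues; score range ",
      sprintf("%.3f .. %.3f", min(x$matrix), max(x$matrix)), "\n", sep = "")
  invisible(x)
}

#' Read a scoring matrix from CSV or JSON
#'
#' CSV dialect: an optional `# allele=DRB1*XX:YY` comment line, then a header
#' row with the 20 residue columns in canonical alphabet order, then 9 data
#' rows for binding-register positions 1-9. If no comment line is present the
#' allele name is taken from the file name (e.g. `DRB1_0901.csv`).
#' JSON dialect: an object with fields `allele` and `matrix` (9 arrays of 20
#' numbers, canonical column order).
#'
#' @param path Path to a `.csv` or `.json` matrix file.
#' @return An `itemrisk_pssm`.
#' @export
load_pssm <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$allele) || is.null(obj$matrix)) {
      stop("JSON matrix file must have fields 'allele' and 'matrix': ", path)
    }
    m <- obj$matrix
    if (is.list(m)) m <- do.call(rbind, m)
    if (nrow(m) != 9L) stop("expected 9 positions in ", path, ", got ", nrow(m))
    colnames(m) <- amino_alphabet()
    return(pssm(obj$allele, m, source_tag = basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  allele <- NA_character_
  cmt <- grep("^#", lines)
  for (i in cmt) {
    hit <- regmatches(lines[i], regexec("allele\\s*=\\s*(\\S+)", lines[i]))[[1]]
    if (length(hit) == 2) allele <- hit[2]
  }
  body <- if (length(cmt)) lines[-cmt] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("matrix file has no data rows: ", path)
  header <- trimws(strsplit(body[1], ",")[[1]])
  header <- header[nzchar(header)]
  unknown <- setdiff(header, amino_alphabet())
  if (length(unknown)) {
    stop("unknown residue column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  if (length(header) != 20L) stop("expected 20 residue columns in ", path)
  rows <- lapply(seq_along(body[-1]), function(i) {
    fields <- trimws(strsplit(body[i + 1], ",")[[1]])
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop("non-numeric entry at data line ", i, " of ", path)
    }
    if (length(vals) != 20L) {
      stop("expected 20 values at data line ", i, " of ", path,
           ", got ", length(vals))
    }
    vals
  })
  if (length(rows) != 9L) stop("expected 9 positions in ", path, ", got ", length(rows))
  m <- do.call(rbind, rows)
  colnames(m) <- header
  if (is.na(allele)) {
    stem <- tools::file_path_sans_ext(basename(path))
    allele <- gsub("_", "*", stem, fixed = TRUE)
  }
  pssm(allele, m, source_tag = basename(path))
}

#' Write a scoring matrix to CSV
#'
#' Writes the dialect read by [load_pssm()]: a `# allele=` comment line, a
#' residue header, and 9 position rows.
#'
#' @param p An `itemrisk_pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "itemrisk_pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# allele=", p$allele), con)
  writeLines(paste(colnames(p$matrix), collapse = ","), con)
  for (k in 1:9) {
    writeLines(paste(format(p$matrix[k, ], digits = 12, trim = TRUE,
                            scientific = FALSE), collapse = ","), con)
  }
  invisible(path)
}

#' Analytic null moments of the raw 9-mer score
#'
#' Mean and standard deviation of the raw (additive) 9-mer score when the
#' nine residues are drawn independently from the background distribution.
#' Positions are independent under this null, so the mean is the sum of the
#' per-position background-weighted row means and the variance is the sum of
#' the per-position background-weighted row variances.
#'
#' @param p An `itemrisk_pssm`.
#' @param bg A [background_frequencies()] object (default uniform).
#' @return List with `allele`, `mu`, `sigma`, and `degenerate` (TRUE when
#'   `sigma` is numerically zero).
#' @export
null_moments <- function(p, bg = background_frequencies()) {
  stopifnot(inherits(p, "itemrisk_pssm"))
  bg <- background_frequencies(unclass(bg))
  row_mean <- as.numeric(p$matrix %*% bg)
  # centered form: exactly zero variance for constant rows
  dev <- sweep(p$matrix, 1, row_mean)
  row_var <- as.numeric(dev^2 %*% bg)
  sigma <- sqrt(sum(row_var))
  structure(
    list(allele = p$allele, mu = sum(row_mean), sigma = sigma,
         degenerate = sigma < 1e-12),
    class = "itemrisk_null_moments"
  )
}

#' Raw score of a single 9-mer
#'
#' Sum over the nine binding-register positions of the matrix entry for the
#' residue at that position.
#'
#' @param p An `itemrisk_pssm`.
#' @param peptide A 9-residue string over the canonical alphabet.
#' @return Numeric raw score.
#' @export
score_ninemer <- function(p, peptide) {
  stopifnot(inherits(p, "itemrisk_pssm"))
  res <- strsplit(toupper(peptide), "")[[1]]
  if (length(res) != 9L) stop("peptide must be exactly 9 residues, got ", length(res))
  idx <- match(res, amino_alphabet())
  if (anyNA(idx)) {
    stop("unknown residue '", res[which(is.na(idx))[1]], "' at position ",
         which(is.na(idx))[1])
  }
  sum(p$matrix[cbind(1:9, idx)])
}

#' Convert a raw 9-mer score to a Z-score
#'
#' @param raw Numeric raw score(s).
#' @param nm Null moments from [null_moments()].
#' @return Z-score(s) `(raw - mu) / sigma`.
#' @export
zscore <- function(raw, nm) {
  if (nm$degenerate || nm$sigma <= 0) {
    stop("degenerate matrix for ", nm$allele, ": null sigma is zero")
  }
  (raw - nm$mu) / nm$sigma
}

#' Hit classification thresholds
#'
#' The binding-hit cutoff (default Z >= 1.64) and the lower "likely" cutoff
#' (default Z >= 1.28). Comparisons are inclusive.
#'
#' @param hit Z cutoff for a binding hit.
#' @param likely Z cutoff for a likely hit; must be below `hit`.
#' @return List of class `itemrisk_thresholds`.
#' @export
hit_thresholds <- function(hit = 1.64, likely = 1.28) {
  stopifnot(is.numeric(hit), is.numeric(likely), length(hit) == 1, length(likely) == 1)
  if (!(likely < hit)) stop("'likely' threshold must be below 'hit' threshold")
  structure(list(hit = hit, likely = likely), class = "itemrisk_thresholds")
}

#' Classify a Z-score against the hit thresholds
#'
#' @param z Numeric Z-score(s).
#' @param t Thresholds from [hit_thresholds()].
#' @return Character vector in `c("none", "likely", "hit")`; ties at a
#'   cutoff classify upward (inclusive).
#' @export
classify_hit <- function(z, t = hit_thresholds()) {
  stopifnot(inherits(t, "itemrisk_thresholds"))
  out <- rep("none", length(z))
  out[z >= t$likely] <- "likely"
  out[z >= t$hit] <- "hit"
  out
}

#' Null expectation of hit-weighted Z-content per cell
#'
#' Under a standard-normal Z null, the expected contribution of one
#' (frame x allele) assessment to the hit-Z sum is
#' `E[Z 1(Z >= theta)] = dnorm(theta)`. This constant centers the
#' length-normalized protein scores at zero for background-random proteins.
#'
#' @param theta Hit threshold (default 1.64).
#' @return The expectation (0.10396 at the default threshold).
#' @export
null_cell_expectation <- function(theta = 1.64) {
  stats::dnorm(theta)
}
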
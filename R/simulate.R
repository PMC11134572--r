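#' Simulation specification
#'
#' Bundles the knobs of the synthetic-data generators: seed, matrix panel
#' size, protein length, planted epitopes (allele, frame position, target
#' Z), planted Tregitope spans (id, start, length), population frequency
#' specs, and the location shift for paired-sample generation.
#'
#' @param seed Integer seed.
#' @param n_alleles Number of synthetic allele matrices.
#' @param protein_length Protein length (>= 9).
#' @param planted_epitopes Data.frame with columns `allele`, `position`
#'   (1-based frame start), `target_z` (default 2); may have zero rows.
#' @param planted_tregitopes Data.frame with columns `id`, `start`,
#'   `length` (>= 9); may have zero rows.
#' @param populations List of lists with fields `label`, `total_n`,
#'   `carrier` (named vector).
#' @param delta Location shift for [generate_paired_scores()].
#' @return List of class `itemrisk_sim_spec`.
#' @export
sim_spec <- function(seed = 1, n_alleles = 5, protein_length = 300,
                     planted_epitopes = data.frame(allele = character(0),
                                                   position = integer(0),
                                                   target_z = numeric(0)),
                     planted_tregitopes = data.frame(id = character(0),
                                                     start = integer(0),
                                                     length = integer(0)),
                     populations = list(), delta = 0) {
  if (protein_length < 9) stop("protein_length must be >= 9")
  if (nrow(planted_epitopes) && is.null(planted_epitopes$target_z)) {
    planted_epitopes$target_z <- 2
  }
  if (nrow(planted_epitopes)) {
    if (any(planted_epitopes$position < 1 |
            planted_epitopes$position > protein_length - 8)) {
      stop("planted epitope position outside scannable frames")
    }
    pos <- sort(planted_epitopes$position)
    if (any(diff(pos) < 9)) stop("planted epitope frames must not overlap")
  }
  if (nrow(planted_tregitopes)) {
    if (any(planted_tregitopes$length < 9)) stop("Tregitope spans must be >= 9")
    if (any(planted_tregitopes$start < 1 |
            planted_tregitopes$start + planted_tregitopes$length - 1 >
              protein_length)) {
      stop("planted Tregitope span outside sequence bounds")
    }
  }
  structure(list(seed = seed, n_alleles = n_alleles,
                 protein_length = protein_length,
                 planted_epitopes = planted_epitopes,
                 planted_tregitopes = planted_tregitopes,
                 populations = populations, delta = delta),
            class = "itemrisk_sim_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a panel of synthetic scoring matrices
#'
#' Matrices with independent Gaussian entries. Averaged over the entry
#' distribution, the raw 9-mer score of a background-random peptide is then
#' exactly normal, so the analytic null moments and the per-cell hit
#' expectation are exact for this generator and the ~5% hit rate at
#' Z >= 1.64 is provable rather than approximate.
#'
#' @param n_alleles Number of matrices (1..99).
#' @param seed Integer seed.
#' @param entry_sd Standard deviation of matrix entries.
#' @return Named list of `itemrisk_pssm` objects with synthetic allele
#'   names `DRB1*99:01` ...
#' @export
generate_pssm_set <- function(n_alleles, seed = 1, entry_sd = 1) {
  stopifnot(n_alleles >= 1, n_alleles <= 99)
  with_seed(seed, {
    out <- lapply(seq_len(n_alleles), function(i) {
      m <- matrix(stats::rnorm(180, sd = entry_sd), nrow = 9,
                  dimnames = list(NULL, amino_alphabet()))
      pssm(sprintf("DRB1*99:%02d", i), m, source_tag = "synthetic")
    })
    names(out) <- vapply(out, function(p) p$allele, "")
    out
  })
}

#' Generate a background-random protein
#'
#' @param length Protein length.
#' @param seed Integer seed.
#' @param bg Background distribution.
#' @param id Sequence id.
#' @return A [protein_record()].
#' @export
generate_random_protein <- function(length, seed = 1,
                                    bg = background_frequencies(),
                                    id = "random") {
  with_seed(seed, {
    res <- sample(amino_alphabet(), length, replace = TRUE, prob = unclass(bg))
    protein_record(id, paste(res, collapse = ""))
  })
}

# Raw score matrix (frames x alleles) for a residue-index vector.
scan_raw_idx <- function(ridx, matrices) {
  nF <- length(ridx) - 8L
  idx <- outer(seq_len(nF), 0:8, `+`)
  idx[] <- ridx[idx]
  raw <- matrix(0, nF, length(matrices))
  for (j in seq_along(matrices)) {
    m <- matrices[[j]]$matrix
    for (k in 1:9) raw[, j] <- raw[, j] + m[k, ][idx[, k]]
  }
  raw
}

# Choose the 9 plant residues for one epitope: high enough for the target
# allele to reach target_z, while keeping every off-target allele's Z at
# the planted frame below z_cap. Returns residue indices or NULL when the
# constraints cannot be met.
choose_plant_residues <- function(target, others, nms, target_z,
                                  z_cap = 1.26, top_m = 8, jitter = FALSE) {
  tm <- target$matrix
  nm_t <- nms[[target$allele]]
  need_raw <- nm_t$mu + target_z * nm_t$sigma
  off <- lapply(others, function(o) o$matrix)
  off_nm <- lapply(others, function(o) nms[[o$allele]])
  cands <- lapply(1:9, function(k) order(tm[k, ], decreasing = TRUE)[seq_len(top_m)])
  pick <- integer(9)
  for (k in 1:9) {
    cand <- cands[[k]]
    if (length(off)) {
      off_max <- vapply(cand, function(r)
        max(vapply(off, function(m) m[k, r], 0)), 0)
      # prefer low off-target load, break ties toward high target value
      ord <- cand[order(off_max, -tm[k, cand])]
    } else {
      ord <- cand
    }
    # jitter spreads the choice over the best few candidates, so repeated
    # attempts explore different plant sequences
    pick[k] <- if (jitter) ord[sample.int(min(4L, length(ord)), 1)] else ord[1]
  }
  raw_t <- function(p) sum(tm[cbind(1:9, p)])
  # greedily upgrade positions to the target argmax until the target is met
  for (rounds in 1:9) {
    if (raw_t(pick) >= need_raw) break
    gain <- vapply(1:9, function(k) max(tm[k, ]) - tm[k, pick[k]], 0)
    k <- which.max(gain)
    if (gain[k] <= 0) break
    pick[k] <- which.max(tm[k, ])
  }
  if (raw_t(pick) < need_raw) return(NULL)
  # local swaps until every off-target allele stays below z_cap
  off_z <- function(p) vapply(seq_along(off), function(j)
    (sum(off[[j]][cbind(1:9, p)]) - off_nm[[j]]$mu) / off_nm[[j]]$sigma, 0)
  for (iter in seq_len(60)) {
    zo <- off_z(pick)
    if (!length(zo) || max(zo) < z_cap) break
    j <- which.max(zo)
    m_o <- off[[j]]
    # positions ranked by how much allele j gains from the current residue
    ord <- order(m_o[cbind(1:9, pick)], decreasing = TRUE)
    moved <- FALSE
    for (k in ord) {
      cand <- setdiff(cands[[k]], pick[k])
      cand <- cand[m_o[k, cand] < m_o[k, pick[k]]]
      if (!length(cand)) next
      # keep the target above threshold after the swap
      cand <- cand[raw_t(pick) - tm[k, pick[k]] + tm[k, cand] >= need_raw]
      if (!length(cand)) next
      # take the candidate giving allele j the least content
      pick[k] <- cand[which.min(m_o[k, cand])]
      moved <- TRUE
      break
    }
    if (!moved) return(NULL)
  }
  zo <- off_z(pick)
  if (length(zo) && max(zo) >= z_cap) return(NULL)
  pick
}

#' Plant epitopes and Tregitope spans into a synthetic protein
#'
#' Builds a protein whose planted frames score at or above the requested
#' Z for their target allele while every other (frame, allele) cell stays
#' below the "likely" tier: background residues are drawn at random, plant
#' residues are chosen greedily to be strong for the target allele and weak
#' for the others, and offending non-planted cells are repaired by locally
#' re-choosing free residues (with bounded restarts; an unsatisfiable
#' specification raises a generation error). Requested Tregitope spans are
#' registered from the finished sequence, so they match exactly at the
#' planned location.
#'
#' @param spec A [sim_spec()].
#' @param matrices Panel from [generate_pssm_set()] covering the planted
#'   alleles.
#' @param bg Background distribution.
#' @param t Thresholds; non-planted cells are forced below `t$likely`.
#' @param max_restarts Whole-sequence restarts before giving up.
#' @return List with `protein` ([protein_record()]), `registry`
#'   ([tregitope_registry()] or NULL), and `truth` (data.frame of planted
#'   `allele`, `frame`, plus achieved `z`).
#' @export
plant_protein <- function(spec, matrices, bg = background_frequencies(),
                          t = hit_thresholds(), max_restarts = 50) {
  stopifnot(inherits(spec, "itemrisk_sim_spec"))
  alleles <- vapply(matrices, function(p) p$allele, "")
  names(matrices) <- alleles
  plants <- spec$planted_epitopes
  if (nrow(plants)) {
    plants$allele <- normalize_allele(plants$allele)
    missing <- setdiff(plants$allele, alleles)
    if (length(missing)) stop("planted allele(s) not in matrix panel: ",
                              paste(missing, collapse = ", "))
  }
  nms <- lapply(matrices, null_moments, bg = bg)
  L <- spec$protein_length
  nF <- L - 8L
  mu <- vapply(nms, function(x) x$mu, 0)
  sg <- vapply(nms, function(x) x$sigma, 0)
  plant_pos <- logical(L)           # residues fixed by a plant
  planted_frame <- logical(nF)      # frames that ARE a planted epitope
  if (nrow(plants)) {
    for (i in seq_len(nrow(plants))) {
      plant_pos[plants$position[i] + 0:8] <- TRUE
      planted_frame[plants$position[i]] <- TRUE
    }
  }
  free <- which(!plant_pos)

  # row minima per allele, for feasibility bounds on plant-overlap frames
  row_min <- lapply(matrices, function(p) apply(p$matrix, 1, min))
  # can every frame overlapping a plant still be pushed below the likely
  # tier by optimizing its free residues? (necessary condition on the picks)
  overlap_feasible <- function(ridx, cap) {
    check <- setdiff(unique(unlist(lapply(plants$position, function(p)
      max(1L, p - 8L):min(nF, p + 8L)))), plants$position)
    for (f in check) {
      pos <- f + 0:8
      fixedp <- pos[plant_pos[pos]]
      if (!length(fixedp)) next
      k_fix <- fixedp - f + 1L
      k_free <- setdiff(1:9, k_fix)
      for (j in seq_along(alleles)) {
        m <- matrices[[j]]$matrix
        zmin <- (sum(m[cbind(k_fix, ridx[fixedp])]) +
                   sum(row_min[[j]][k_free]) - mu[j]) / sg[j]
        if (zmin >= cap) return(FALSE)
      }
    }
    TRUE
  }

  with_seed(spec$seed, {
    for (restart in seq_len(max_restarts)) {
      ridx <- sample(20L, L, replace = TRUE, prob = unclass(bg))
      ok_plants <- FALSE
      for (attempt in 1:30) {
        picked <- TRUE
        for (i in seq_len(nrow(plants))) {
          a <- plants$allele[i]
          pick <- choose_plant_residues(matrices[[a]],
                                        matrices[setdiff(alleles, a)], nms,
                                        plants$target_z[i],
                                        jitter = attempt > 1)
          if (is.null(pick)) { picked <- FALSE; break }
          ridx[plants$position[i] + 0:8] <- pick
        }
        if (picked && overlap_feasible(ridx, t$likely - 0.04)) {
          ok_plants <- TRUE
          break
        }
        if (!nrow(plants)) { ok_plants <- picked; break }
      }
      if (!ok_plants) next
      raw <- scan_raw_idx(ridx, matrices)
      z <- sweep(sweep(raw, 2, mu), 2, sg, "/")
      # planted cells must reach the target for their allele
      tgt_ok <- TRUE
      for (i in seq_len(nrow(plants))) {
        if (z[plants$position[i], match(plants$allele[i], alleles)] <
            plants$target_z[i]) tgt_ok <- FALSE
      }
      if (!tgt_ok) next
      # repair: every non-planted cell must stay below the likely tier.
      # Hill-climb on the summed excess above a cap slightly under the tier
      # (so accepted solutions carry a safety margin), changing one free
      # residue at a time; on a stall, randomly perturb a free residue in
      # the worst frame and continue.
      cap <- t$likely - 0.02
      cell_excess <- function(zv) pmax(0, zv - cap)
      offending <- function(z) {
        bad <- which(z >= t$likely, arr.ind = TRUE)
        bad[!planted_frame[bad[, 1]], , drop = FALSE]
      }
      apply_move <- function(p, r) {
        frames_p <- max(1L, p - 8L):min(nF, p)
        k_of <- p - frames_p + 1L
        for (j in seq_along(alleles)) {
          m <- matrices[[j]]$matrix
          z[frames_p, j] <<- z[frames_p, j] +
            (m[cbind(k_of, r)] - m[cbind(k_of, ridx[p])]) / sg[j]
        }
        ridx[p] <<- r
      }
      # best single-residue substitution at position p (global excess change)
      best_move_at <- function(p) {
        frames_p <- max(1L, p - 8L):min(nF, p)
        eligible <- frames_p[!planted_frame[frames_p]]
        if (!length(eligible)) return(NULL)
        k_el <- p - eligible + 1L
        base_ex <- sum(cell_excess(z[eligible, , drop = FALSE]))
        ex_r <- numeric(20)
        for (j in seq_along(alleles)) {
          m <- matrices[[j]]$matrix
          dz <- (m[k_el, , drop = FALSE] - m[cbind(k_el, ridx[p])]) / sg[j]
          ex <- cell_excess(z[eligible, j] + dz)
          dim(ex) <- dim(dz)
          ex_r <- ex_r + colSums(ex)
        }
        ex_r[ridx[p]] <- Inf
        r <- which.min(ex_r)
        list(p = p, r = r, dG = ex_r[r] - base_ex)
      }
      stuck <- FALSE
      perturbs <- 0
      for (pass in 1:400) {
        bad <- offending(z)
        if (!nrow(bad)) break
        # one descent sweep: per offending frame, apply its best
        # excess-decreasing substitution (each move strictly lowers the
        # global excess, so sweep order cannot cycle)
        moved <- FALSE
        for (f in unique(bad[, 1])) {
          cand_pos <- intersect(f + 0:8, free)
          best <- NULL
          for (p in cand_pos) {
            mv <- best_move_at(p)
            if (!is.null(mv) && (is.null(best) || mv$dG < best$dG)) best <- mv
          }
          if (!is.null(best) && best$dG < -1e-12) {
            apply_move(best$p, best$r)
            moved <- TRUE
          }
        }
        if (!moved) {
          # stall at a local minimum: re-draw the free residues of one
          # offending frame and resume the descent
          perturbs <- perturbs + 1
          if (perturbs > 60) { stuck <- TRUE; break }
          f <- bad[sample.int(nrow(bad), 1), 1]
          for (p in intersect(f + 0:8, free)) {
            apply_move(p, sample.int(20, 1))
          }
        }
      }
      if (stuck || nrow(offending(z))) next
      # success: assemble outputs
      seq_chr <- paste(amino_alphabet()[ridx], collapse = "")
      protein <- protein_record(sprintf("synthetic_%d", spec$seed), seq_chr)
      registry <- NULL
      if (nrow(spec$planted_tregitopes)) {
        tg <- spec$planted_tregitopes
        registry <- tregitope_registry(
          tg$id,
          vapply(seq_len(nrow(tg)), function(i)
            substr(seq_chr, tg$start[i], tg$start[i] + tg$length[i] - 1L), "")
        )
      }
      truth <- if (nrow(plants)) {
        data.frame(allele = plants$allele, frame = plants$position,
                   z = z[cbind(plants$position, match(plants$allele, alleles))],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(allele = character(0), frame = integer(0), z = numeric(0))
      }
      return(list(protein = protein, registry = registry, truth = truth))
    }
  })
  stop("plant_protein: specification unsatisfiable after ", max_restarts,
       " restarts")
}

#' Generate population frequency tables from a specification
#'
#' Emits one [frequency_table()] per population spec, with exactly the
#' requested carrier fractions, or (with `noise = TRUE`) with observed
#' fractions drawn binomially at the population's sample size.
#'
#' @param spec A [sim_spec()] with a non-empty `populations` field.
#' @param noise Draw observed fractions binomially?
#' @return Named list of [frequency_table()] objects.
#' @export
generate_population_tables <- function(spec, noise = FALSE) {
  stopifnot(inherits(spec, "itemrisk_sim_spec"))
  if (!length(spec$populations)) stop("sim_spec has no population specs")
  with_seed(spec$seed, {
    out <- lapply(spec$populations, function(ps) {
      carrier <- ps$carrier
      if (noise) {
        n <- round(ps$total_n)
        carrier <- stats::setNames(
          stats::rbinom(length(carrier), n, carrier) / n, names(carrier))
      }
      frequency_table(ps$label, carrier, ps$total_n)
    })
    names(out) <- vapply(out, function(t) t$population, "")
    out
  })
}

#' Generate paired score samples with a planted location shift
#'
#' Draws n paired observations sharing a common component (so the pairing
#' is informative), with the first member shifted upward by `delta`.
#'
#' @param n Number of pairs.
#' @param delta Location shift added to `x`.
#' @param seed Integer seed.
#' @param sd_common,sd_noise Standard deviations of the shared and
#'   pair-specific components.
#' @return A [paired_samples()] object.
#' @export
generate_paired_scores <- function(n, delta = 0, seed = 1,
                                   sd_common = 1, sd_noise = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    base <- stats::rnorm(n, sd = sd_common)
    paired_samples(base + stats::rnorm(n, sd = sd_noise) + delta,
                   base + stats::rnorm(n, sd = sd_noise),
                   label = sprintf("shift_%g", delta))
  })
}
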
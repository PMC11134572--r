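#' Pipeline configuration
#'
#' Collects the run-time constants of the end-to-end analysis. Defaults are
#' the package's standard settings: hit threshold 1.64, likely threshold
#' 1.28, 1% panel floor, 5% joint-probability and difference floors, 100
#' resamples.
#'
#' @param proteins Path to the protein FASTA.
#' @param matrix_dir Directory of per-allele matrix files (CSV/JSON).
#' @param frequencies Path to a two-population frequency CSV (percent
#'   scale); `NULL` uses the packaged reference table.
#' @param registry Optional Tregitope registry path (FASTA/CSV).
#' @param ata Optional ATA study CSV path.
#' @param background `"uniform"` (currently the only named option).
#' @param hit,likely Z thresholds.
#' @param min_freq Panel frequency floor (fraction).
#' @param jp_min,diff_min Differential-pair floors (fractions).
#' @param n_resamples Resamples per population.
#' @param seed Integer seed.
#' @param scheme Effect-size interpretation scheme name.
#' @param out_dir Output directory.
#' @return List of class `itemrisk_config`.
#' @export
pipeline_config <- function(proteins, matrix_dir, frequencies = NULL,
                            registry = NULL, ata = NULL,
                            background = "uniform",
                            hit = 1.64, likely = 1.28, min_freq = 0.01,
                            jp_min = 0.05, diff_min = 0.05,
                            n_resamples = 100, seed = 1, scheme = "cohen",
                            out_dir = "itemrisk_out") {
  structure(list(proteins = proteins, matrix_dir = matrix_dir,
                 frequencies = frequencies, registry = registry, ata = ata,
                 background = background, hit = hit, likely = likely,
                 min_freq = min_freq, jp_min = jp_min, diff_min = diff_min,
                 n_resamples = n_resamples, seed = seed, scheme = scheme,
                 out_dir = out_dir),
            class = "itemrisk_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths resolve against the YAML
#'   file's directory.
#' @return An `itemrisk_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p) || grepl("^/", p)) p else file.path(base, p)
  }
  cfg <- do.call(pipeline_config, y)
  for (f in c("proteins", "matrix_dir", "frequencies", "registry", "ata")) {
    cfg[[f]] <- resolve(cfg[[f]])
  }
  cfg
}

load_matrix_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  if (!length(files)) stop("no matrix files (*.csv, *.json) in ", dir)
  mats <- lapply(sort(files), load_pssm)
  names(mats) <- vapply(mats, function(p) p$allele, "")
  mats
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains the stages on one configuration: aggregate/load population
#' frequencies and select the panel; detect differential allele pairs;
#' scan each protein and compute raw and Tregitope-adjusted scores;
#' resample frequency-weighted score distributions per population; compute
#' all-pairs individual scores with quartiles and differential-pair
#' placement; compare populations per protein with the signed-rank test,
#' six multiplicity adjustments, and effect sizes; optionally aggregate ATA
#' rates. Writes one CSV per stage plus a JSON run manifest into
#' `config$out_dir`. Stage outputs are deterministic given the
#' configuration and seed (the manifest additionally records wall-clock
#' time).
#'
#' @param config An `itemrisk_config`.
#' @param quiet Suppress stage logging?
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "itemrisk_config"))
  say <- function(...) if (!quiet) message("[itemrisk] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  t <- hit_thresholds(config$hit, config$likely)
  bg <- background_frequencies()

  tables <- drb1_reference_frequencies(path = config$frequencies)
  if (length(tables) < 2) stop("need two population columns in the frequency table")
  tables <- tables[1:2]
  panel <- filter_panel(tables, config$min_freq)
  say(length(panel), " panel alleles above ", config$min_freq * 100,
      "% in ", paste(names(tables), collapse = " / "))
  freq_df <- data.frame(allele = panel, stringsAsFactors = FALSE)
  for (tab in tables) {
    freq_df[[tab$population]] <- sprintf("%.2f", vapply(
      panel, function(a) 100 * (if (a %in% names(tab$carrier)) tab$carrier[[a]] else 0), 0))
  }
  out$frequencies <- write_csv_plain(freq_df, file.path(config$out_dir, "frequencies.csv"))

  dp <- differential_pairs(tables[[1]], tables[[2]], panel,
                           config$jp_min, config$diff_min)
  dp_out <- dp
  for (col in c("jp_a", "jp_b", "diff")) dp_out[[col]] <- sprintf("%.4f", dp[[col]])
  names(dp_out)[3:4] <- paste0("jp_", c(tables[[1]]$population, tables[[2]]$population))
  say(nrow(dp), " differential pairs (",
      sum(dp$dominant == tables[[1]]$population), " ", tables[[1]]$population,
      "-dominant, ", sum(dp$dominant == tables[[2]]$population), " ",
      tables[[2]]$population, "-dominant)")
  out$pairs <- write_csv_plain(dp_out, file.path(config$out_dir, "differential_pairs.csv"))

  matrices <- load_matrix_dir(config$matrix_dir)
  proteins <- read_proteins(config$proteins)
  registry <- if (!is.null(config$registry)) read_tregitopes(config$registry)
  panel_alleles <- intersect(panel, names(matrices))
  if (!length(panel_alleles)) {
    stop("no overlap between the frequency panel and the matrix alleles")
  }
  grids <- lapply(proteins, scan_protein, matrices = matrices, bg = bg,
                  t = t, registry = registry)
  say(length(grids), " proteins scanned against ", length(matrices), " alleles")

  reports <- lapply(grids, protein_score)
  score_df <- data.frame(
    protein = vapply(reports, function(r) r$protein_id, ""),
    length = vapply(proteins, function(p) nchar(p$sequence), 0),
    assessments = vapply(reports, function(r) r$assessments, 0),
    raw_score = sprintf("%.4f", vapply(reports, function(r) r$raw_score, 0)),
    adjusted_score = sprintf("%.4f", vapply(reports, function(r) r$adjusted_score, 0)),
    stringsAsFactors = FALSE
  )
  out$scores <- write_csv_plain(score_df, file.path(config$out_dir, "protein_scores.csv"))

  grid_df <- do.call(rbind, lapply(grids, grid_to_long))
  grid_df$z <- sprintf("%.4f", grid_df$z)
  out$grid <- write_csv_plain(grid_df, file.path(config$out_dir, "assessment_grid.csv"))

  long <- list(); summ <- list(); comp <- list()
  for (pid in names(grids)) {
    for (adj in c(FALSE, TRUE)) {
      dists <- lapply(tables, function(tab)
        population_score_distribution(grids[[pid]], tab, panel_alleles,
                                      config$n_resamples, config$seed,
                                      adjusted = adj))
      for (d in dists) {
        long[[length(long) + 1]] <- data.frame(
          protein = pid, population = d$population,
          resample_index = seq_along(d$scores),
          variant = if (adj) "adjusted" else "raw",
          score = sprintf("%.4f", d$scores), stringsAsFactors = FALSE)
        summ[[length(summ) + 1]] <- data.frame(
          protein = pid, population = d$population,
          variant = if (adj) "adjusted" else "raw",
          q1 = sprintf("%.4f", d$q1), median = sprintf("%.4f", d$median),
          q3 = sprintf("%.4f", d$q3), stringsAsFactors = FALSE)
      }
      cc <- compare_populations(dists[[1]], dists[[2]], scheme = config$scheme)
      cc$variant <- if (adj) "adjusted" else "raw"
      comp[[length(comp) + 1]] <- cc
    }
  }
  out$population_scores <- write_csv_plain(
    do.call(rbind, long), file.path(config$out_dir, "population_scores.csv"))
  out$population_summary <- write_csv_plain(
    do.call(rbind, summ), file.path(config$out_dir, "population_summary.csv"))

  comp_df <- do.call(rbind, comp)
  adj_mat <- adjust_pvalues(comp_df$p_value, "all")
  for (m in colnames(adj_mat)) comp_df[[paste0("p_", m)]] <- sprintf("%.6g", adj_mat[, m])
  for (col in c("median_a", "median_b", "effect_r")) {
    comp_df[[col]] <- sprintf("%.4f", comp_df[[col]])
  }
  comp_df$p_value <- sprintf("%.6g", comp_df$p_value)
  out$comparisons <- write_csv_plain(comp_df, file.path(config$out_dir, "comparisons.csv"))
  say(nrow(comp_df), " population comparisons written")

  item <- list()
  for (pid in names(grids)) {
    idist <- item_distribution(grids[[pid]], panel_alleles)
    res <- idist$results
    res$quartile <- vapply(seq_len(nrow(res)), function(i)
      pair_quartile(idist, c(res$allele_a[i], res$allele_b[i])), 0L)
    res$protein <- pid
    res$raw_item <- sprintf("%.4f", as.numeric(res$raw_item))
    res$adjusted_item <- sprintf("%.4f", as.numeric(res$adjusted_item))
    item[[pid]] <- res[, c("protein", "allele_a", "allele_b", "raw_item",
                           "adjusted_item", "quartile")]
  }
  out$item <- write_csv_plain(do.call(rbind, item),
                              file.path(config$out_dir, "item_scores.csv"))

  if (!is.null(config$ata)) {
    studies <- read_ata_studies(config$ata)
    biologics <- unique(vapply(studies, function(s) s$biologic, ""))
    ata_df <- data.frame(
      biologic = biologics,
      ata_percent = sprintf("%.2f", vapply(biologics, function(b)
        100 * aggregate_ata_rate(Filter(function(s) s$biologic == b, studies)), 0)),
      stringsAsFactors = FALSE)
    out$ata <- write_csv_plain(ata_df, file.path(config$out_dir, "ata_rates.csv"))
  }

  manifest <- list(
    tool = "itemrisk",
    version = as.character(utils::packageVersion("itemrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      config$proteins, config$frequencies, config$registry, config$ata))))
  )
  out$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(out)
}

#' Generate a complete synthetic input dataset on disk
#'
#' Emits everything [run_pipeline()] consumes: a panel of synthetic
#' matrices, proteins with planted epitopes and one Tregitope span each, a
#' registry, a two-population frequency table over the synthetic alleles
#' (with a controllable differential structure), an ATA study table, and a
#' ready-to-run `config.yaml`.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param n_alleles Panel size.
#' @param n_proteins Number of proteins.
#' @param protein_length Protein length.
#' @param n_resamples Resamples for the config.
#' @return Path to the written `config.yaml`, invisibly.
#' @export
simulate_dataset <- function(dir, seed = 1, n_alleles = 6, n_proteins = 2,
                             protein_length = 160, n_resamples = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  mats <- generate_pssm_set(n_alleles, seed = seed)
  for (p in mats) {
    write_pssm(p, file.path(mdir, paste0(gsub("[*:]", "_", p$allele), ".csv")))
  }
  alleles <- names(mats)
  proteins <- list(); registries <- list()
  if (protein_length < 80) stop("protein_length must be >= 80 to place plants")
  pos2 <- as.integer(protein_length / 2)
  for (i in seq_len(n_proteins)) {
    target <- alleles[1 + (i - 1) %% n_alleles]
    sp <- sim_spec(seed = seed + 100 + i, n_alleles = n_alleles,
                   protein_length = protein_length,
                   planted_epitopes = data.frame(
                     allele = c(target, target),
                     position = c(20L, pos2), target_z = 2),
                   # span covering the second plant, so masking is exercised
                   planted_tregitopes = data.frame(
                     id = sprintf("TRG_%02d", i), start = pos2 - 3L,
                     length = 15L))
    pl <- plant_protein(sp, mats)
    pl$protein$id <- sprintf("biologic_%02d", i)
    proteins[[i]] <- pl$protein
    registries[[i]] <- pl$registry
  }
  write_proteins(proteins, file.path(dir, "proteins.fasta"))
  reg <- do.call(rbind, lapply(registries, as.data.frame))
  write_csv_plain(reg, file.path(dir, "tregitopes.csv"))
  # two populations differing mainly in the first allele's carriage
  base <- stats::setNames(rep(0.08, n_alleles), alleles)
  carA <- base; carA[1] <- 0.30
  carB <- base; carB[1] <- 0.02
  tables <- list(
    frequency_table("PopA", carA, 5000),
    frequency_table("PopB", carB, 5000)
  )
  names(tables) <- c("PopA", "PopB")
  write_frequency_tables(tables, file.path(dir, "frequencies.csv"))
  write_csv_plain(data.frame(
    biologic = rep(vapply(proteins, function(p) p$id, ""), each = 2),
    study_id = paste0("S", seq_len(2 * n_proteins)),
    n = rep(c(120, 260), n_proteins),
    ata_percent = rep(c(8, 14), n_proteins),
    monotherapy = TRUE, excluded = FALSE, reason = ""),
    file.path(dir, "ata_studies.csv"))
  cfg <- list(proteins = "proteins.fasta", matrix_dir = "matrices",
              frequencies = "frequencies.csv", registry = "tregitopes.csv",
              ata = "ata_studies.csv", min_freq = 0.01,
              n_resamples = n_resamples, seed = seed,
              out_dir = file.path(dir, "out"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
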
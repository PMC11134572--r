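# Shared in-code fixtures for the test suite. Everything is generated; no
# binary data on disk.

# Small deterministic matrix panel used across files.
test_matrices <- function(n = 3, seed = 424242, entry_sd = 1) {
  generate_pssm_set(n, seed = seed, entry_sd = entry_sd)
}

# A hand-crafted assessment grid with fully controlled Z-values, for
# closed-form score checks. z is a frames x alleles matrix.
make_grid <- function(z, masked = rep(FALSE, nrow(z)),
                      t = hit_thresholds(), protein_id = "crafted") {
  alleles <- colnames(z)
  if (is.null(alleles)) {
    alleles <- sprintf("DRB1*99:%02d", seq_len(ncol(z)))
    colnames(z) <- alleles
  }
  structure(
    list(protein_id = protein_id, frames = seq_len(nrow(z)), alleles = alleles,
         z = z,
         hit_class = matrix(classify_hit(z, t), nrow(z), ncol(z),
                            dimnames = dimnames(z)),
         masked = masked, thresholds = t,
         spans = data.frame(start = integer(0), end = integer(0))),
    class = "itemrisk_grid"
  )
}

# Write a matrix panel to a temporary directory in the CSV dialect.
write_matrix_dir <- function(mats, dir = tempfile("mats")) {
  dir.create(dir)
  for (p in mats) {
    write_pssm(p, file.path(dir, paste0(gsub("[*:]", "_", p$allele), ".csv")))
  }
  dir
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}
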
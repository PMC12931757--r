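# Small in-code fixtures shared across the suite.

# A compact schema: `n_cont` continuous features v1..vk, `n_bin` binary
# features b1..bk, and a binary target y.
toy_schema <- function(n_cont = 3L, n_bin = 1L) {
  cn <- if (n_cont) paste0("v", seq_len(n_cont)) else character(0)
  bn <- if (n_bin) paste0("b", seq_len(n_bin)) else character(0)
  variable_schema(
    name = c(cn, bn, "y"),
    kind = c(rep("continuous", n_cont), rep("binary", n_bin + 1L)),
    lower = c(rep(-1e6, n_cont), rep(NA, n_bin + 1L)),
    upper = c(rep(1e6, n_cont), rep(NA, n_bin + 1L)),
    positive_label = c(rep(NA, n_cont), rep("yes", n_bin), "case"),
    role = c(rep("feature", n_cont + n_bin), "target")
  )
}

# A complete toy cohort with independent N(0,1) features, Bernoulli(0.5)
# binary features, and a balanced target.
toy_cohort <- function(n = 40L, n_cont = 3L, n_bin = 1L, seed = 1L) {
  set.seed(seed)
  sch <- toy_schema(n_cont, n_bin)
  vals <- as.data.frame(matrix(rnorm(n * n_cont), n))
  names(vals) <- paste0("v", seq_len(n_cont))
  for (b in seq_len(n_bin)) {
    vals[[paste0("b", b)]] <- rbinom(n, 1, 0.5)
  }
  vals$y <- rep_len(c(0, 1), n)
  cohort_table(vals, sch)
}

# Mask specific cells of a cohort, returning the masked table.
mask_cells <- function(ct, cells) {
  vals <- ct$values
  mask <- ct$mask
  for (i in seq_len(nrow(cells))) {
    vals[cells$row[i], cells$var[i]] <- NA_real_
    mask[cells$row[i], cells$var[i]] <- TRUE
  }
  cohort_table(vals, ct$schema, record_ids = ct$record_ids, mask = mask)
}

# A small MAFLD-schema synthetic cohort with MAR missingness injected at
# the default clinic-like rates.
small_mafld_cohort <- function(n = 600L, seed = 1L,
                               mechanism = "MAR") {
  ct <- generate_cohort(cohort_sim_config(n_records = n, seed = seed))
  inject_missingness(ct, missingness_config(mechanism, seed = seed))
}
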
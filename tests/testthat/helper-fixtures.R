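# Fixture builders shared across the test files. Everything is built in
# code; no data files.

# A small, well-formed summary-statistics data frame (no palindromes).
toy_sumstats_df <- function(n = 3) {
  data.frame(
    SNP = sprintf("rs%d", seq_len(n)),
    CHR = "chr1",
    POS = seq_len(n) * 10000,
    EA = rep(c("A", "G", "T"), length.out = n),
    OA = rep(c("G", "T", "C"), length.out = n),
    EAF = seq(0.1, 0.45, length.out = n),
    BETA = seq(0.05, 0.2, length.out = n),
    SE = rep(0.02, n),
    P = 10^-seq(6, 8, length.out = n),
    N = 18473,
    stringsAsFactors = FALSE
  )
}

toy_sumstats <- function(n = 3, ...) {
  df <- toy_sumstats_df(n)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  suppressMessages(sumstats(df, trait_name = "toy"))
}

# Build a harmonized set directly from effect arrays (bypasses the
# allele-alignment machinery; for estimator-level tests).
make_hset <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.02,
                      eaf_exp = 0.3, eaf_out = 0.3,
                      n_exp = 18473, n_out = 46351) {
  k <- length(beta_exp)
  h <- data.frame(
    snp = sprintf("rs%d", seq_len(k)), chr = "chr1", pos = seq_len(k) * 1e4,
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    eaf_exp = rep_len(eaf_exp, k), n_exp = rep_len(n_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k),
    eaf_out = rep_len(eaf_out, k), n_out = rep_len(n_out, k),
    stringsAsFactors = FALSE
  )
  attr(h, "exposure") <- "exposure"
  attr(h, "outcome") <- "outcome"
  class(h) <- c("harmonized_set", "data.frame")
  h
}

# Simulate a scenario and harmonize every planted instrument (no
# selection step), returning the harmonized set.
sim_hset <- function(sc) {
  sim <- simulate_pair(sc)
  exp_instr <- suppressMessages(
    sumstats(as.data.frame(sim$exposure)[sim$exposure$SNP %in%
                                           sim$truth$instruments, ],
             trait_name = "exposure"))
  suppressMessages(harmonize(exp_instr, sim$outcome))
}

# Random harmonized set with true effect b (quick generator for
# property-style estimator tests; normal noise on both sides).
random_hset <- function(k, b = 0.2, se_exp = 0.01, se_out = 0.02) {
  gamma <- stats::runif(k, 0.03, 0.1) * sample(c(-1, 1), k, replace = TRUE)
  make_hset(beta_exp = stats::rnorm(k, gamma, se_exp),
            beta_out = stats::rnorm(k, b * gamma, se_out),
            se_exp = se_exp, se_out = se_out)
}

# Exhaustive checker for the clumping constraints: TRUE iff no retained
# pair violates (same chromosome, within window, r2 >= r2_max) and every
# discarded SNP conflicts with a retained SNP of smaller p.
clump_is_valid <- function(kept, full, ld, r2_max = 0.1, window_bp = 5e5) {
  kept_ids <- kept$SNP
  conflict <- function(i, j) {
    full$CHR[i] == full$CHR[j] &&
      abs(full$POS[i] - full$POS[j]) <= window_bp &&
      ld$r2[full$SNP[i], full$SNP[j]] >= r2_max
  }
  idx_kept <- match(kept_ids, full$SNP)
  for (a in idx_kept) {
    for (b in idx_kept) {
      if (a < b && conflict(a, b)) return(FALSE)
    }
  }
  for (d in setdiff(seq_len(nrow(full)), idx_kept)) {
    ok <- any(vapply(idx_kept, function(a) {
      full$P[a] < full$P[d] && conflict(a, d)
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

# Build a screening bench: features x outcomes with a matrix B of true
# causal effects (rows = features, cols = outcomes). A feature's exposure
# stats and LD are shared across outcomes (same scenario seed); each
# outcome's sumstats stack the per-feature outcome records.
make_bench <- function(B, levels, seed = 1, n_snps_total = 24,
                       n_instruments = 8, r2 = 0.03, ...) {
  n_feat <- nrow(B)
  n_out <- ncol(B)
  exposures <- vector("list", n_feat)
  out_parts <- vector("list", n_out)
  for (o in seq_len(n_out)) out_parts[[o]] <- vector("list", n_feat)
  for (f in seq_len(n_feat)) {
    for (o in seq_len(n_out)) {
      sc <- sim_scenario(n_snps_total = n_snps_total,
                         n_instruments = n_instruments, b_true = B[f, o],
                         instrument_r2_target = r2, seed = seed + f,
                         id_prefix = sprintf("f%02d_", f), ...)
      sim <- simulate_pair(sc)
      if (o == 1L) {
        exposures[[f]] <- list(
          meta = taxon_meta(sprintf("feature%02d", f), levels[f]),
          stats = sim$exposure, ld = sim$ld)
      }
      out_parts[[o]][[f]] <- as.data.frame(sim$outcome)
    }
  }
  outcomes <- lapply(seq_len(n_out), function(o) {
    df <- do.call(rbind, out_parts[[o]])
    suppressMessages(sumstats(df, trait_name = sprintf("disorder%02d", o),
                              trait_type = "binary"))
  })
  list(exposures = exposures, outcomes = outcomes)
}
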
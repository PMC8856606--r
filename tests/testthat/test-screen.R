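# Screen orchestration, multiple-testing control, plot data.

test_that("per-level thresholds are alpha over the taxa count and monotone", {
  thr <- level_thresholds(c(phylum = 9, genus = 102, x = 1))
  expect_equal(unname(thr["x"]), 0.05)
  counts <- c(a = 5, b = 10, c = 50)
  tt <- level_thresholds(counts)
  expect_true(all(diff(unname(tt)) < 0))
  expect_error(level_thresholds(c(a = 0)), "positive")
})

test_that("a single-pair screen reproduces the direct pipeline call", {
  sc <- sim_scenario(n_snps_total = 30, n_instruments = 8, b_true = 0.25,
                     instrument_r2_target = 0.03, seed = 55)
  sim <- simulate_pair(sc)
  cfg <- screen_config(n_sim = 200, n_boot = 100, seed = 10)
  tab <- suppressWarnings(run_screen(
    list(list(meta = taxon_meta("feat", "genus"), stats = sim$exposure,
              ld = sim$ld)),
    list(sim$outcome), cfg))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$status, "ok")

  # manual composition with the same derived per-pair seed
  sel <- select_by_pvalue(sim$exposure, cfg$p_threshold)
  cl <- drop_palindromic(clump(sel, sim$ld))
  h <- suppressMessages(harmonize(cl, sim$outcome))
  pr <- presso_prune(h, n_sim = cfg$n_sim, seed = cfg$seed + 97L)
  if (length(pr$removed_snps)) {
    h <- h[!h$snp %in% pr$removed_snps, ]
    class(h) <- c("harmonized_set", "data.frame")
  }
  expect_equal(tab$b_ivw, mr_ivw(h)$b)
  expect_equal(tab$p_ivw, mr_ivw(h)$pval)
  expect_equal(tab$k, nrow(h))
  expect_equal(tab$level_threshold, 0.05)
  expect_equal(tab$significant, tab$p_ivw < 0.05)
})

test_that("planted causal pairs are flagged and null pairs almost never are", {
  n_runs <- 5
  planted_hits <- 0
  false_flags <- 0
  for (run in seq_len(n_runs)) {
    B <- matrix(0, 12, 3)
    B[1, 1] <- 0.3
    B[5, 2] <- 0.35
    bench <- make_bench(B, levels = rep("genus", 12), seed = 1000 * run)
    cfg <- screen_config(n_sim = 200, n_boot = 100, seed = run)
    tab <- suppressWarnings(run_screen(bench$exposures, bench$outcomes, cfg))
    expect_equal(nrow(tab), 36L)
    planted <- tab$feature_id %in% c("feature01", "feature05") &
      ((tab$feature_id == "feature01" & tab$outcome == "disorder01") |
         (tab$feature_id == "feature05" & tab$outcome == "disorder02"))
    planted_hits <- planted_hits + sum(tab$significant[planted], na.rm = TRUE)
    false_flags <- false_flags + sum(tab$significant[!planted], na.rm = TRUE)
    expect_equal(unique(tab$level_threshold), 0.05 / 12)
  }
  expect_gte(planted_hits / (2 * n_runs), 0.9)
  expect_lte(false_flags, 3)
})

test_that("the family-wise false-flag rate per level stays near alpha on a null bench", {
  n_runs <- 20
  families <- 0
  flagged_families <- 0
  for (run in seq_len(n_runs)) {
    B <- matrix(0, 6, 2)
    bench <- make_bench(B, levels = rep("genus", 6), seed = 5000 + 13 * run,
                        n_snps_total = 12, n_instruments = 6)
    cfg <- screen_config(n_sim = 150, n_boot = 80, seed = run)
    tab <- suppressWarnings(run_screen(bench$exposures, bench$outcomes, cfg))
    for (o in unique(tab$outcome)) {
      families <- families + 1
      flagged_families <- flagged_families +
        any(tab$significant[tab$outcome == o], na.rm = TRUE)
    }
  }
  rate <- flagged_families / families
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / families))
})

test_that("pairs with no instruments are reported with a status, never dropped", {
  ss <- toy_sumstats(5, P = rep(0.5, 5)) # nothing passes selection
  tab <- run_screen(
    list(list(meta = taxon_meta("weak", "phylum"), stats = ss, ld = NULL)),
    list(toy_sumstats(5)), screen_config(n_sim = 100, n_boot = 50))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$status, "no_instruments")
  expect_true(is.na(tab$b_ivw))
  expect_true(is.na(tab$significant))
})

test_that("a screen is reproducible given the same config and seed", {
  B <- matrix(c(0.25, 0), 2, 1)
  bench <- make_bench(B, levels = c("family", "family"), seed = 99,
                      n_snps_total = 16, n_instruments = 8)
  cfg <- screen_config(n_sim = 150, n_boot = 80, seed = 4)
  a <- suppressWarnings(run_screen(bench$exposures, bench$outcomes, cfg))
  b <- suppressWarnings(run_screen(bench$exposures, bench$outcomes, cfg))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # every tested pair appears exactly once
  expect_equal(anyDuplicated(paste(a$feature_id, a$outcome)), 0L)
})

test_that("forward causation is flagged forward but not in reverse", {
  hits_fwd <- 0
  hits_rev <- 0
  for (run in 1:3) {
    B <- matrix(c(0.3, 0), 2, 1)
    bench <- make_bench(B, levels = c("genus", "genus"), seed = 300 + run,
                        n_snps_total = 16, n_instruments = 8)
    cfg <- screen_config(n_sim = 150, n_boot = 80, seed = run)
    fwd <- suppressWarnings(run_screen(bench$exposures, bench$outcomes, cfg))
    hits_fwd <- hits_fwd + sum(fwd$significant[fwd$feature_id == "feature01"],
                               na.rm = TRUE)
    rev_exposures <- lapply(bench$outcomes, function(o) {
      list(meta = taxon_meta(attr(o, "trait_name"), "genus"),
           stats = o, ld = NULL)
    })
    rev_outcomes <- lapply(bench$exposures, function(e) e$stats)
    rev <- suppressWarnings(reverse_screen(rev_exposures, rev_outcomes, cfg))
    expect_equal(unique(rev$level_threshold), 0.05 / nrow(rev))
    hits_rev <- hits_rev + sum(rev$significant, na.rm = TRUE)
  }
  expect_gte(hits_fwd, 3) # every run flags the planted forward effect
  expect_equal(hits_rev, 0)
})

test_that("plot-data export writes k points, one slope per method, and is byte-stable", {
  # 5 instruments spread over 5 LD blocks so clumping keeps all of them
  sc <- sim_scenario(n_snps_total = 50, n_instruments = 5, b_true = 0.3,
                     instrument_r2_target = 0.025, seed = 7)
  sim <- simulate_pair(sc)
  cfg <- screen_config(n_sim = 200, n_boot = 100, seed = 2)
  tab <- suppressWarnings(run_screen(
    list(list(meta = taxon_meta("feat", "species"), stats = sim$exposure,
              ld = sim$ld)),
    list(sim$outcome), cfg))
  dir1 <- withr::local_tempdir()
  paths <- export_plot_data(tab, "feat", "outcome", dir1)
  scatter <- read.table(paths["scatter"], sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  pts <- scatter[scatter$type == "point", ]
  slp <- scatter[scatter$type == "slope", ]
  expect_equal(nrow(pts), tab$k)
  expect_setequal(slp$method, c("ivw", "mle", "egger", "wme", "presso"))
  expect_equal(slp$slope[slp$method == "ivw"], tab$b_ivw)
  expect_equal(slp$slope[slp$method == "wme"], tab$b_wme)
  forest <- read.table(paths["forest"], sep = "\t", header = TRUE)
  expect_equal(nrow(forest), tab$k)
  loo <- read.table(paths["loo"], sep = "\t", header = TRUE)
  expect_equal(nrow(loo), tab$k)

  dir2 <- withr::local_tempdir()
  paths2 <- export_plot_data(tab, "feat", "outcome", dir2)
  for (i in seq_along(paths)) {
    expect_identical(readLines(paths[i]), readLines(paths2[i]))
  }
  expect_error(export_plot_data(tab, "nope", "outcome"), "not found")
})
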
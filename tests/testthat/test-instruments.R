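# Instrument selection, clumping, harmonization, diagnostics.

test_that("p-value selection is strict and order-preserving", {
  ss <- toy_sumstats(3, P = c(1e-6, 1e-5, 1e-4))
  kept <- select_by_pvalue(ss, 1e-5)
  expect_equal(kept$SNP, "rs1") # p == threshold is excluded
  ss2 <- toy_sumstats(5, P = runif(5, 0, 0.9))
  expect_equal(select_by_pvalue(ss2, 1)$SNP, ss2$SNP)
})

test_that("null-GWAS selection counts follow the binomial law", {
  # 200 seeded null GWAS of 10,000 SNPs each at threshold 1e-5: the total
  # kept count is Binomial(2e6, 1e-5); check it against the exact 99.9% CI.
  ss <- toy_sumstats(10000, P = runif(10000))
  total <- with(list(), {
    set.seed(20)
    sum(vapply(1:200, function(i) {
      z <- rnorm(10000)
      ss$P <- pmax(2 * pnorm(-abs(z)), 1e-300)
      nrow(select_by_pvalue(ss, 1e-5))
    }, numeric(1)))
  })
  bounds <- qbinom(c(0.0005, 0.9995), 2e6, 1e-5)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("clumping keeps the smaller-p SNP of a correlated nearby pair", {
  ss <- toy_sumstats(2, POS = c(10000, 20000), P = c(1e-8, 1e-6))
  ld <- ld_info(ss$SNP, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(clump(ss, ld)$SNP, "rs1")
  # same pair but 600 kb apart: outside the window, both kept
  ss2 <- toy_sumstats(2, POS = c(10000, 610001), P = c(1e-8, 1e-6))
  expect_equal(nrow(clump(ss2, ld_info(ss2$SNP, matrix(c(1, .5, .5, 1), 2)))), 2L)
})

test_that("greedy clumping satisfies all pairwise constraints on AR(1) blocks", {
  for (seed in 1:5) {
    sc <- sim_scenario(n_snps_total = 50, n_instruments = 5,
                       ld_block_size = 10, ld_rho = 0.7, seed = seed)
    sim <- simulate_pair(sc)
    kept <- clump(sim$exposure, sim$ld)
    expect_true(clump_is_valid(kept, sim$exposure, sim$ld))
  }
})

test_that("SNPs absent from the LD reference are kept with a warning, or dropped in strict mode", {
  ss <- toy_sumstats(3, POS = c(1e4, 2e4, 3e4), P = c(1e-8, 1e-7, 1e-6))
  ld <- ld_info(ss$SNP[1:2], matrix(c(1, 0.9, 0.9, 1), 2))
  expect_warning(kept <- clump(ss, ld), "retained as their own index")
  expect_setequal(kept$SNP, c("rs1", "rs3"))
  expect_message(strictly <- clump(ss, ld, strict = TRUE), "dropped")
  expect_setequal(strictly$SNP, "rs1")
})

test_that("palindromic SNPs are removed whatever the allele order", {
  ss <- toy_sumstats(5)
  ss$EA <- c("A", "G", "C", "A", "T")
  ss$OA <- c("T", "C", "G", "G", "C")
  kept <- drop_palindromic(ss)
  expect_equal(kept$SNP, c("rs4", "rs5")) # A/G and T/C survive
  expect_identical(drop_palindromic(kept), kept) # identity without palindromes
})

test_that("harmonization aligns swapped and strand-flipped alleles and drops ambiguous SNPs", {
  e <- toy_sumstats(4, EA = c("A", "A", "A", "A"), OA = c("G", "G", "G", "G"),
                    BETA = c(0.1, 0.1, 0.1, 0.1))
  o <- toy_sumstats(4, EA = c("A", "G", "T", "A"), OA = c("G", "A", "C", "C"),
                    BETA = c(0.2, 0.2, 0.2, 0.2), EAF = rep(0.3, 4))
  h <- suppressMessages(harmonize(e, o))
  expect_equal(h$snp, c("rs1", "rs2", "rs3")) # rs4 ambiguous
  expect_equal(h$beta_out, c(0.2, -0.2, 0.2)) # swap negates; flip keeps sign
  expect_equal(h$eaf_out[2], 0.7)
})

test_that("harmonizing an exposure with itself returns its own betas exactly", {
  ss <- toy_sumstats(6, BETA = rnorm(6))
  h <- suppressMessages(harmonize(ss, ss))
  expect_identical(h$beta_out, h$beta_exp)
  expect_identical(h$eaf_out, h$eaf_exp)
})

test_that("duplicated SNP ids are removed entirely from both sides", {
  e <- toy_sumstats(3)
  dup <- suppressMessages(keep <- rbind(as.data.frame(e), as.data.frame(e)[2, ]))
  e2 <- suppressMessages(sumstats(dup, trait_name = "exposure"))
  o <- toy_sumstats(3)
  expect_message(h <- harmonize(e2, o), "duplicated")
  expect_setequal(h$snp, c("rs1", "rs3"))
})

test_that("harmonize refuses palindromic input", {
  ss <- toy_sumstats(2, EA = c("A", "A"), OA = c("T", "G"))
  expect_error(harmonize(ss, ss), "palindromic")
})

test_that("variance explained follows 2f(1-f)beta^2 and peaks at f = 0.5", {
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.1, 0.2), 0.0032)
  f <- seq(0.05, 0.95, by = 0.05)
  v <- variance_explained(0.3, f)
  expect_equal(f[which.max(v)], 0.5)
  expect_true(all(diff(v[f <= 0.5]) > 0), info = "increasing below 0.5")
  expect_error(variance_explained(0.1, 1.2), "strictly in")
})

test_that("the F statistic matches its closed form and is monotone in R2 and n", {
  expect_equal(f_statistic(0.5, 103, 1), 101)
  expect_equal(f_statistic(0, 100, 5), 0)
  r2 <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(vapply(r2, f_statistic, numeric(1), n = 1e4, k = 5)) > 0))
  ns <- seq(1000, 20000, by = 1000)
  expect_true(all(diff(vapply(ns, function(n) f_statistic(0.02, n, 5),
                              numeric(1))) > 0))
  expect_error(f_statistic(0.02, 5, 5), "exceed")
  expect_error(f_statistic(1, 100, 5), "r2")
})

test_that("instrument diagnostics flag weak instruments below F = 10", {
  h <- make_hset(beta_exp = rep(0.02, 4), beta_out = rep(0.004, 4),
                 eaf_exp = 0.3, n_exp = 2000)
  d <- instrument_diagnostics(h)
  expect_lt(d$f_stat, 10)
  expect_true(d$weak_flag)
  expect_equal(d$r2_exp, sum(2 * 0.3 * 0.7 * 0.02^2 * rep(1, 4)))
})

test_that("the confounder filter removes exactly the planted associations", {
  h <- make_hset(beta_exp = runif(8, 0.03, 0.08), beta_out = rnorm(8, 0, 0.01))
  planted <- c("rs2", "rs5")
  tab <- simulate_confounder_table(h$snp, n_traits = 3, planted = planted,
                                   seed = 9)
  filtered <- suppressMessages(confounder_filter(h, tab))
  expect_setequal(setdiff(h$snp, filtered$snp), planted)
  # nothing planted, including SNPs absent from the table -> identity
  tab0 <- simulate_confounder_table(h$snp[1:4], n_traits = 3, seed = 9)
  expect_equal(confounder_filter(h, tab0)$snp, h$snp)
})
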
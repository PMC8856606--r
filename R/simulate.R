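# Synthetic GWAS summary-statistics generator with known ground truth.
#
# The generator emulates the statistical structure of a microbiome-GWAS
# exposure sample paired with a large case-control or population-scale
# outcome sample: standardized effect sizes, standard errors determined
# by allele frequency and sample size, AR(1) LD blocks, and optional
# pleiotropy, palindromic alleles, strand flips, and duplicate records.

#' Define a simulation scenario
#'
#' Defaults describe a realistic screening condition: a 18,473-sample
#' exposure GWAS (the scale of current microbiome meta-analyses)
#' providing 13 instruments that jointly explain 2.61% of exposure
#' variance, a 46,351-sample outcome GWAS, and a true causal effect of
#' 0.24 on the standardized scale.
#'
#' @param n_snps_total Total SNPs generated (instruments first, the rest
#'   drawn under the null).
#' @param n_instruments Number of true instruments.
#' @param b_true True causal effect of exposure on outcome.
#' @param n_exp,n_out Sample sizes of the exposure and outcome GWAS.
#' @param maf_range Range for uniform minor-allele frequencies, a subset
#'   of (0, 0.5].
#' @param instrument_r2_target Total exposure variance explained by the
#'   instruments; the true effects are rescaled so the sum of
#'   \code{2 f (1-f) gamma^2} hits this exactly.
#' @param pleiotropy_mode One of \code{"none"}, \code{"balanced"}
#'   (direct effects N(0, s^2)), \code{"directional"} (N(s, (s/2)^2)),
#'   or \code{"outliers"} (a fraction of instruments receive direct
#'   effects of +/- 10 outcome standard errors).
#' @param pleiotropy_scale The scale s above.
#' @param outlier_fraction Fraction of instruments contaminated in
#'   \code{"outliers"} mode.
#' @param ld_block_size SNPs per LD block; each block sits on its own
#'   pseudo-chromosome with 10 kb spacing between SNPs.
#' @param ld_rho AR(1) correlation parameter within a block (r between
#'   adjacent SNPs; r2 decays as \code{rho^(2 |i - j|)}).
#' @param palindromic_fraction,strand_flip_fraction,duplicate_fraction
#'   Fractions of SNPs given complementary allele pairs, outcome alleles
#'   reported on the opposite strand, or duplicated identifiers.
#' @param seed Scenario seed; [simulate_pair()] is a pure function of
#'   the scenario.
#' @param id_prefix Prefix for generated SNP identifiers, so stats from
#'   several simulated features can be combined without id collisions.
#' @return A list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(n_snps_total = 100, n_instruments = 13,
                         b_true = 0.24, n_exp = 18473, n_out = 46351,
                         maf_range = c(0.05, 0.5),
                         instrument_r2_target = 0.0261,
                         pleiotropy_mode = c("none", "balanced",
                                             "directional", "outliers"),
                         pleiotropy_scale = 0.05, outlier_fraction = 0.1,
                         ld_block_size = 10, ld_rho = 0.5,
                         palindromic_fraction = 0,
                         strand_flip_fraction = 0,
                         duplicate_fraction = 0, seed = 1,
                         id_prefix = "") {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_instruments >= 1, n_instruments <= n_snps_total,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1, ld_block_size >= 1)
  fr <- c(palindromic_fraction, strand_flip_fraction, duplicate_fraction,
          outlier_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (instrument_r2_target <= 0 || instrument_r2_target >= 1) {
    stop("instrument_r2_target must lie strictly in (0, 1)")
  }
  structure(list(n_snps_total = n_snps_total, n_instruments = n_instruments,
                 b_true = b_true, n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range,
                 instrument_r2_target = instrument_r2_target,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_scale = pleiotropy_scale,
                 outlier_fraction = outlier_fraction,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 palindromic_fraction = palindromic_fraction,
                 strand_flip_fraction = strand_flip_fraction,
                 duplicate_fraction = duplicate_fraction, seed = seed,
                 id_prefix = id_prefix),
            class = "sim_scenario")
}

# Non-palindromic allele pairs to sample from.
NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate an exposure/outcome summary-statistics pair with ground truth
#'
#' Minor-allele frequencies are uniform on the scenario's range; true
#' instrument effects are drawn and rescaled so the total variance
#' explained \code{sum 2 f (1-f) gamma^2} equals the target exactly.
#' Standard errors follow the standardized-trait closed form
#' \code{1 / sqrt(2 f (1-f) n)}; observed betas are normal around their
#' true values; non-instrument SNPs are null. Outcome betas are centered
#' on \code{b_true * gamma + alpha} with the direct (pleiotropic) effect
#' alpha set by the scenario's mode. P-values are two-sided normal.
#' Instruments are placed at the head of separate LD blocks wherever
#' possible so that clumping retains them; remaining SNPs fill the
#' blocks, which follow an AR(1) correlation structure on one
#' pseudo-chromosome per block with 10 kb spacing.
#'
#' @param sc A [sim_scenario()].
#' @return A list with elements \code{exposure} and \code{outcome}
#'   (\code{sumstats}), \code{ld} (an [ld_info()]), and \code{truth}
#'   (instrument ids, true effects gamma, direct effects alpha, planted
#'   outlier/palindromic/flipped/duplicated ids, and \code{b_true}).
#' @export
simulate_pair <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  with_seed(sc$seed, {
    m <- sc$n_snps_total
    k <- sc$n_instruments
    bs <- sc$ld_block_size
    n_blocks <- ceiling(m / bs)
    block <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
    pos_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)

    # Assign instruments to block heads first, then fill sequentially.
    heads <- which(pos_in_block == 1L)
    instr_idx <- if (k <= length(heads)) {
      heads[seq_len(k)]
    } else {
      c(heads, setdiff(seq_len(m), heads))[seq_len(k)]
    }
    is_instr <- seq_len(m) %in% instr_idx

    snp_id <- sprintf("%srs%05d", sc$id_prefix, seq_len(m))
    chrom <- paste0("chr", block)
    pos <- pos_in_block * 10000

    f <- stats::runif(m, sc$maf_range[1], sc$maf_range[2])
    # Roughly even per-instrument variance contributions (random sign,
    # squared magnitude uniform in [0.8, 1.2] before rescaling): planted
    # instruments then sit well above the usual selection threshold
    # instead of straddling it, which is how instruments that survived
    # p-value selection in a real GWAS behave.
    gamma <- numeric(m)
    share <- stats::runif(k, 0.8, 1.2)
    contrib <- share / sum(share) * sc$instrument_r2_target
    sign_g <- sample(c(-1, 1), k, replace = TRUE)
    fi <- f[instr_idx]
    gamma[instr_idx] <- sign_g * sqrt(contrib / (2 * fi * (1 - fi)))

    alpha <- numeric(m)
    outlier_ids <- character(0)
    se_out <- 1 / sqrt(2 * f * (1 - f) * sc$n_out)
    if (sc$pleiotropy_mode == "balanced") {
      alpha[instr_idx] <- stats::rnorm(k, 0, sc$pleiotropy_scale)
    } else if (sc$pleiotropy_mode == "directional") {
      alpha[instr_idx] <- stats::rnorm(k, sc$pleiotropy_scale,
                                       sc$pleiotropy_scale / 2)
    } else if (sc$pleiotropy_mode == "outliers") {
      n_out_snps <- max(1L, round(sc$outlier_fraction * k))
      chosen <- sample(instr_idx, n_out_snps)
      alpha[chosen] <- sample(c(-10, 10), n_out_snps, replace = TRUE) *
        se_out[chosen]
      outlier_ids <- snp_id[chosen]
    }

    se_exp <- 1 / sqrt(2 * f * (1 - f) * sc$n_exp)
    beta_exp <- stats::rnorm(m, gamma, se_exp)
    beta_out <- stats::rnorm(m, sc$b_true * gamma + alpha, se_out)

    pair_e <- NONPAL_PAIRS[sample(nrow(NONPAL_PAIRS), m, replace = TRUE), ,
                           drop = FALSE]
    pal_ids <- character(0)
    if (sc$palindromic_fraction > 0) {
      n_pal <- round(sc$palindromic_fraction * m)
      if (n_pal > 0) {
        pal_i <- sample(m, n_pal)
        pair_e[pal_i, ] <- PAL_PAIRS[sample(nrow(PAL_PAIRS), n_pal,
                                            replace = TRUE), , drop = FALSE]
        pal_ids <- snp_id[pal_i]
      }
    }
    ea_out <- pair_e[, 1]
    oa_out <- pair_e[, 2]
    flip_ids <- character(0)
    if (sc$strand_flip_fraction > 0) {
      n_flip <- round(sc$strand_flip_fraction * m)
      if (n_flip > 0) {
        fl <- sample(m, n_flip)
        ea_out[fl] <- complement_allele(ea_out[fl])
        oa_out[fl] <- complement_allele(oa_out[fl])
        flip_ids <- snp_id[fl]
      }
    }

    p_exp <- p_from_z(beta_exp / se_exp)
    p_out <- p_from_z(beta_out / se_out)

    exp_df <- data.frame(SNP = snp_id, CHR = chrom, POS = pos,
                         EA = pair_e[, 1], OA = pair_e[, 2], EAF = f,
                         BETA = beta_exp, SE = se_exp, P = p_exp,
                         N = sc$n_exp, stringsAsFactors = FALSE)
    out_df <- data.frame(SNP = snp_id, CHR = chrom, POS = pos,
                         EA = ea_out, OA = oa_out, EAF = f,
                         BETA = beta_out, SE = se_out, P = p_out,
                         N = sc$n_out, stringsAsFactors = FALSE)

    dup_ids <- character(0)
    if (sc$duplicate_fraction > 0) {
      n_dup <- round(sc$duplicate_fraction * m)
      if (n_dup > 0) {
        di <- sample(m, n_dup)
        exp_df <- rbind(exp_df, exp_df[di, , drop = FALSE])
        dup_ids <- snp_id[di]
      }
    }

    # Block-diagonal AR(1) LD: r2 between SNPs i, j in the same block is
    # rho^(2 |i - j|); different blocks sit on different chromosomes.
    r2 <- diag(1, m)
    for (bk in seq_len(n_blocks)) {
      idx <- which(block == bk)
      if (length(idx) > 1L) {
        d <- abs(outer(pos_in_block[idx], pos_in_block[idx], "-"))
        r2[idx, idx] <- sc$ld_rho^(2 * d)
      }
    }

    list(
      exposure = suppressMessages(
        sumstats(exp_df, trait_name = "exposure", trait_type = "continuous")),
      outcome = suppressMessages(
        sumstats(out_df, trait_name = "outcome", trait_type = "continuous")),
      ld = ld_info(snp_id, r2),
      truth = list(instruments = snp_id[instr_idx],
                   gamma = stats::setNames(gamma[instr_idx], snp_id[instr_idx]),
                   alpha = stats::setNames(alpha[instr_idx], snp_id[instr_idx]),
                   outliers = outlier_ids, palindromic = pal_ids,
                   flipped = flip_ids, duplicated = dup_ids,
                   b_true = sc$b_true)
    )
  })
}

#' Simulate a SNP x confounder-trait p-value table
#'
#' Planted SNPs receive a sub-threshold p-value (uniform on (0, 0.05))
#' for their first trait; every other entry is uniform on (0.05, 1), so
#' the confounder filter removes exactly the planted set.
#'
#' @param snp_ids SNP identifiers for the rows.
#' @param n_traits Number of confounder traits (columns).
#' @param planted Subset of \code{snp_ids} to plant as
#'   confounder-associated.
#' @param seed RNG seed.
#' @return A data frame: column \code{snp} plus \code{n_traits} p-value
#'   columns.
#' @export
simulate_confounder_table <- function(snp_ids, n_traits = 7,
                                      planted = character(0), seed = 1) {
  stopifnot(all(planted %in% snp_ids))
  with_seed(seed, {
    n <- length(snp_ids)
    p <- matrix(stats::runif(n * n_traits, 0.05, 1), n, n_traits)
    p[match(planted, snp_ids), 1] <- stats::runif(length(planted), 0, 0.05)
    out <- data.frame(snp = snp_ids, p, stringsAsFactors = FALSE)
    names(out) <- c("snp", paste0("trait", seq_len(n_traits)))
    out
  })
}
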
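# Instrument selection, pruning, harmonization, and strength diagnostics.

#' Select candidate instruments by association p-value
#'
#' Retains rows with \code{P < threshold} (strict inequality), in their
#' original order. The conventional suggestive threshold for
#' small-sample exposures such as microbiome GWAS is 1e-5.
#'
#' @param stats A \code{sumstats} object.
#' @param threshold P-value threshold in (0, 1].
#' @return A \code{sumstats} object with the retained rows.
#' @export
select_by_pvalue <- function(stats, threshold = 1e-5) {
  stopifnot(inherits(stats, "sumstats"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  keep_rows(stats, which(stats$P < threshold))
}

#' Greedy LD clumping of candidate instruments
#'
#' Reproduces the standard PLINK-style index-SNP selection: repeatedly
#' take the smallest-p unselected SNP as an index (ties broken by
#' chromosome, position, then identifier) and discard every unselected
#' SNP on the same chromosome within \code{window_bp} base pairs whose
#' squared correlation with the index is at least \code{r2_max}. Any two
#' retained SNPs therefore lie on different chromosomes, or more than
#' \code{window_bp} apart, or below the r2 threshold.
#'
#' SNPs absent from the LD reference are retained as their own index
#' with a warning; \code{strict = TRUE} drops them instead.
#'
#' @param stats A \code{sumstats} object.
#' @param ld An [ld_info()] reference, or \code{NULL} (all SNPs treated
#'   as missing from the reference).
#' @param r2_max Squared-correlation threshold (default 0.1).
#' @param window_bp Clumping window in base pairs (default 500 kb); a
#'   distance strictly greater than the window never triggers the r2 check.
#' @param strict Drop SNPs missing from the LD reference.
#' @return A \code{sumstats} object containing the index SNPs, in the
#'   original row order.
#' @export
clump <- function(stats, ld = NULL, r2_max = 0.1, window_bp = 500000,
                  strict = FALSE) {
  stopifnot(inherits(stats, "sumstats"))
  if (!is.null(ld)) stopifnot(inherits(ld, "ld_info"))
  n <- nrow(stats)
  if (n <= 1L) return(stats)

  in_ref <- if (is.null(ld)) rep(FALSE, n) else stats$SNP %in% ld$snp_ids
  if (any(!in_ref)) {
    if (strict) {
      stats <- keep_rows(stats, which(in_ref))
      message(sum(!in_ref), " SNP(s) absent from the LD reference dropped (strict mode)")
      n <- nrow(stats)
      if (n <= 1L) return(stats)
      in_ref <- rep(TRUE, n)
    } else {
      warning(sum(!in_ref),
              " SNP(s) absent from the LD reference retained as their own index")
    }
  }

  ord <- order(stats$P, stats$CHR, stats$POS, stats$SNP)
  state <- rep("pending", n) # indexed in original row order
  for (i in ord) {
    if (state[i] != "pending") next
    state[i] <- "kept"
    cand <- which(state == "pending" &
                    stats$CHR == stats$CHR[i] &
                    abs(stats$POS - stats$POS[i]) <= window_bp)
    if (length(cand) && in_ref[i]) {
      cand <- cand[in_ref[cand]]
      if (length(cand)) {
        r2 <- ld$r2[stats$SNP[i], stats$SNP[cand]]
        state[cand[r2 >= r2_max]] <- "dropped"
      }
    }
  }
  keep_rows(stats, which(state == "kept"))
}

#' Remove palindromic SNPs
#'
#' A palindromic SNP has complementary alleles (A/T or C/G in either
#' order), so its strand cannot be resolved between two studies; all
#' such SNPs are removed regardless of allele frequency.
#'
#' @param stats A \code{sumstats} object.
#' @return The object without palindromic SNPs.
#' @export
drop_palindromic <- function(stats) {
  stopifnot(inherits(stats, "sumstats"))
  pair <- paste(pmin(stats$EA, stats$OA), pmax(stats$EA, stats$OA))
  keep_rows(stats, which(!pair %in% c("A T", "C G")))
}

is_palindromic <- function(stats) {
  pair <- paste(pmin(stats$EA, stats$OA), pmax(stats$EA, stats$OA))
  pair %in% c("A T", "C G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on SNP identifier and aligns the outcome effect
#' to the exposure's effect allele: matching allele pairs are kept as
#' is; swapped pairs have the outcome beta negated and frequency
#' reflected (1 - eaf); pairs that match or swap only after
#' complementing both outcome alleles (strand flip) are treated the same
#' way after complementing. Irreconcilable allele sets are dropped as
#' ambiguous, and any identifier duplicated within either input has all
#' of its copies removed. Both inputs must already be palindrome-free
#' (see [drop_palindromic()]); with palindromes gone, no
#' allele-frequency inference is ever needed to resolve strand.
#'
#' @param exp,out \code{sumstats} objects for exposure and outcome.
#' @return A \code{harmonized_set}: a data frame with columns
#'   \code{snp, chr, pos, beta_exp, se_exp, eaf_exp, n_exp, beta_out,
#'   se_out, eaf_out, n_out} and attributes recording the trait names.
#' @export
harmonize <- function(exp, out) {
  stopifnot(inherits(exp, "sumstats"), inherits(out, "sumstats"))
  if (any(is_palindromic(exp)) || any(is_palindromic(out))) {
    stop("inputs contain palindromic SNPs; run drop_palindromic() first")
  }
  for (side in c("exposure", "outcome")) {
    s <- if (side == "exposure") exp else out
    dup <- unique(s$SNP[duplicated(s$SNP)])
    if (length(dup)) {
      message(length(dup), " duplicated SNP id(s) in the ", side,
              " input removed (all copies)")
      exp <- keep_rows(exp, which(!exp$SNP %in% dup))
      out <- keep_rows(out, which(!out$SNP %in% dup))
    }
  }
  common <- intersect(exp$SNP, out$SNP)
  if (length(common) == 0L) {
    warning("no SNPs shared between exposure and outcome after deduplication")
  }
  e <- as.data.frame(exp)[match(common, exp$SNP), ]
  o <- as.data.frame(out)[match(common, out$SNP), ]

  same <- o$EA == e$EA & o$OA == e$OA
  swap <- o$EA == e$OA & o$OA == e$EA
  csame <- complement_allele(o$EA) == e$EA & complement_allele(o$OA) == e$OA
  cswap <- complement_allele(o$EA) == e$OA & complement_allele(o$OA) == e$EA
  flip <- swap | cswap
  ambiguous <- !(same | swap | csame | cswap)
  if (any(ambiguous)) {
    message(sum(ambiguous), " SNP(s) dropped as ambiguous (alleles irreconcilable)")
  }

  beta_out <- ifelse(flip, -o$BETA, o$BETA)
  eaf_out <- ifelse(flip, 1 - o$EAF, o$EAF)
  keep <- !ambiguous
  h <- data.frame(
    snp = e$SNP[keep], chr = e$CHR[keep], pos = e$POS[keep],
    beta_exp = e$BETA[keep], se_exp = e$SE[keep], eaf_exp = e$EAF[keep],
    n_exp = e$N[keep],
    beta_out = beta_out[keep], se_out = o$SE[keep], eaf_out = eaf_out[keep],
    n_out = o$N[keep],
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  attr(h, "exposure") <- attr(exp, "trait_name")
  attr(h, "outcome") <- attr(out, "trait_name")
  class(h) <- c("harmonized_set", "data.frame")
  h
}

subset_hset <- function(h, i) {
  out <- as.data.frame(h)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exposure") <- attr(h, "exposure")
  attr(out, "outcome") <- attr(h, "outcome")
  class(out) <- class(h)
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", nrow(x), " SNPs ('",
      attr(x, "exposure"), "' -> '", attr(x, "outcome"), "')\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-SNP phenotypic variance explained
#'
#' For a standardized trait (mean 0, variance 1) the variance explained
#' by a SNP is \code{2 f (1 - f) beta^2}, with \code{f} the
#' effect-allele frequency. Summing over a harmonized set gives the
#' instruments' total R-squared.
#'
#' @param beta Effect size(s) on the standardized scale.
#' @param eaf Effect-allele frequency(ies) in (0, 1).
#' @return Numeric vector of variance proportions.
#' @export
#' @examples
#' variance_explained(0.1, 0.2) # 2 * 0.2 * 0.8 * 0.01
variance_explained <- function(beta, eaf) {
  if (any(!is.finite(eaf)) || any(eaf <= 0 | eaf >= 1)) {
    stop("effect-allele frequency must lie strictly in (0, 1)")
  }
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F statistic
#'
#' \code{F = R2 (n - 1 - k) / ((1 - R2) k)} for total variance explained
#' \code{R2}, sample size \code{n} and instrument count \code{k}. Values
#' below 10 conventionally indicate a weak instrument.
#'
#' @param r2 Total variance explained, in \code{[0, 1)}.
#' @param n Sample size, must exceed \code{k + 1}.
#' @param k Number of instruments, at least 1.
#' @return The F statistic (numeric scalar).
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(is.numeric(r2), is.numeric(n), is.numeric(k))
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (k < 1) stop("k must be at least 1")
  if (n <= k + 1) stop("sample size must exceed k + 1")
  r2 * (n - 1 - k) / ((1 - r2) * k)
}

#' Instrument diagnostics for a harmonized set
#'
#' Total variance explained on each side (sum of per-SNP
#' \code{2 f (1 - f) beta^2}), the instrument-strength F statistic on
#' the exposure side, and a weak-instrument flag (F < 10). The sample
#' size entering F is the minimum exposure-side n, a conservative choice
#' when per-SNP sample sizes differ.
#'
#' @param hset A \code{harmonized_set}.
#' @return A list of class \code{instrument_diagnostics} with elements
#'   \code{k, r2_exp, r2_out, f_stat, weak_flag}.
#' @export
instrument_diagnostics <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"), nrow(hset) >= 1L)
  r2_exp <- sum(variance_explained(hset$beta_exp, hset$eaf_exp))
  r2_out <- sum(variance_explained(hset$beta_out, hset$eaf_out))
  k <- nrow(hset)
  f <- f_statistic(r2_exp, min(hset$n_exp), k)
  structure(list(k = k, r2_exp = r2_exp, r2_out = r2_out, f_stat = f,
                 weak_flag = f < 10),
            class = "instrument_diagnostics")
}

#' Remove instruments associated with measured confounders
#'
#' Drops every instrument whose p-value for ANY trait in the confounder
#' table falls below \code{alpha} (nominal association). Instruments
#' absent from the table are retained.
#'
#' @param hset A \code{harmonized_set}.
#' @param conf_table Data frame whose first column (\code{snp}) holds SNP
#'   identifiers and whose remaining columns hold per-trait p-values.
#' @param alpha Nominal significance level (default 0.05).
#' @return The filtered \code{harmonized_set}.
#' @export
confounder_filter <- function(hset, conf_table, alpha = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"), is.data.frame(conf_table))
  idx <- match(hset$snp, conf_table[[1]])
  pmat <- as.matrix(conf_table[, -1, drop = FALSE])
  hit <- vapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) return(FALSE)
    any(pmat[idx[i], ] < alpha, na.rm = TRUE)
  }, logical(1))
  if (any(hit)) {
    message(sum(hit), " instrument(s) removed by the confounder filter")
  }
  subset_hset(hset, which(!hit))
}
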
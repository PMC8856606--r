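# Sensitivity analyses: heterogeneity, leave-one-out, directionality,
# and the MR-PRESSO pleiotropy tests with recursive outlier pruning.

#' Cochran / Ruecker heterogeneity Q test
#'
#' Q is the weighted residual sum of squares around the fitted model,
#' with weights \code{1/se_out^2}: the origin-constrained IVW fit
#' (df = k - 1) or the MR-Egger fit with intercept (df = k - 2). Under
#' homogeneity Q is chi-squared on df degrees of freedom. Because the
#' Egger fit nests the IVW fit, its Q can never exceed the IVW Q.
#'
#' @param hset A \code{harmonized_set}.
#' @param model \code{"ivw"} (k >= 2) or \code{"egger"} (k >= 3).
#' @return A list with \code{Q}, \code{df}, \code{pval}.
#' @export
q_test <- function(hset, model = c("ivw", "egger")) {
  model <- match.arg(model)
  k <- check_hset(hset, if (model == "ivw") 2L else 3L, paste0("q_test(", model, ")"))
  w <- 1 / hset$se_out^2
  if (model == "ivw") {
    b <- ivw_point(hset$beta_exp, hset$beta_out, hset$se_out)
    fitted <- b * hset$beta_exp
    df <- k - 1L
  } else {
    s <- ifelse(hset$beta_exp < 0, -1, 1)
    fit <- stats::lm(s * hset$beta_out ~ I(s * hset$beta_exp), weights = w)
    fitted <- s * stats::fitted(fit)
    df <- k - 2L
  }
  if (df < 1L) stop("not enough instruments for a heterogeneity test")
  Q <- sum(w * (hset$beta_out - fitted)^2)
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW series
#'
#' Recomputes the IVW estimate omitting each instrument in turn, to show
#' whether the causal signal is driven by any single SNP.
#'
#' @param hset A \code{harmonized_set} with k >= 3 instruments.
#' @param model IVW effects model, passed to [mr_ivw()].
#' @return A data frame with one row per omitted SNP:
#'   \code{snp_omitted, b, se, pval, k_used}.
#' @export
leave_one_out <- function(hset, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- check_hset(hset, 3L, "leave_one_out")
  rows <- lapply(seq_len(k), function(j) {
    fit <- mr_ivw(subset_hset(hset, -j), model = model)
    data.frame(snp_omitted = hset$snp[j], b = fit$b, se = fit$se,
               pval = fit$pval, k_used = fit$k_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steiger directionality test
#'
#' Compares the total variance the instruments explain in the exposure
#' against the variance they explain in the outcome (both via
#' \code{2 f (1 - f) beta^2}). A causal interpretation of
#' exposure -> outcome is directionally credible when the exposure-side
#' variance is strictly greater. The p-value compares the two implied
#' correlations (square roots of the R-squared values) on Fisher's z
#' scale, using each side's median sample size.
#'
#' @param hset A \code{harmonized_set} with frequencies and sample sizes
#'   on both sides.
#' @return A list with \code{direction} (TRUE = exposure -> outcome),
#'   \code{pval}, \code{r2_exp}, \code{r2_out}.
#' @export
steiger_test <- function(hset) {
  check_hset(hset, 1L, "steiger")
  if (any(is.na(hset$eaf_exp)) || any(is.na(hset$eaf_out))) {
    stop("steiger requires effect-allele frequencies on both sides; ",
         "frequency imputation is unsupported")
  }
  r2_exp <- sum(variance_explained(hset$beta_exp, hset$eaf_exp))
  r2_out <- sum(variance_explained(hset$beta_out, hset$eaf_out))
  n_exp <- stats::median(hset$n_exp)
  n_out <- stats::median(hset$n_out)
  z <- (atanh(sqrt(min(r2_exp, 1 - 1e-12))) - atanh(sqrt(min(r2_out, 1 - 1e-12)))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction = r2_exp > r2_out, pval = p_from_z(z),
       r2_exp = r2_exp, r2_out = r2_out)
}

presso_result <- function(global_pval, rss_obs, outlier_pvals, removed_snps,
                          corrected, n_sim, seed, initial_global_pval = NULL) {
  structure(list(global_pval = global_pval, rss_obs = rss_obs,
                 outlier_pvals = outlier_pvals, removed_snps = removed_snps,
                 corrected = corrected, n_sim = n_sim, seed = seed,
                 initial_global_pval = initial_global_pval %||% global_pval),
            class = "presso_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MR-PRESSO global and outlier tests (single pass)
#'
#' For each instrument j the IVW slope is refitted without it; the
#' observed residual sum of squares is
#' \code{sum_j w_j (beta_out_j - b_(-j) beta_exp_j)^2} with
#' \code{w_j = 1/se_out_j^2}. The null distribution comes from
#' \code{n_sim} parametric simulations (exposure betas redrawn about
#' their observed values, outcome betas redrawn about the leave-one-out
#' fitted values) with the RSS recomputed identically. The global
#' p-value and the per-SNP outlier p-values use the add-one estimator
#' \code{(1 + #exceedances) / (n_sim + 1)}, so the smallest attainable
#' p is \code{1/(n_sim + 1)}; outlier p-values are additionally
#' Bonferroni-adjusted by k.
#'
#' @param hset A \code{harmonized_set} with k >= 4 instruments.
#' @param n_sim Number of simulated null datasets (default 1000).
#' @param seed Seed making the test reproducible.
#' @return A \code{presso_result} with \code{global_pval},
#'   \code{rss_obs}, per-SNP \code{outlier_pvals} (columns \code{raw},
#'   \code{bonferroni} and the observed weighted \code{residual}), and
#'   the untouched IVW fit as \code{corrected}.
#' @export
presso_global <- function(hset, n_sim = 1000, seed = 1) {
  k <- check_hset(hset, 4L, "presso_global")
  be <- hset$beta_exp; bo <- hset$beta_out
  se_e <- hset$se_exp; se_o <- hset$se_out
  w <- 1 / se_o^2

  s1 <- sum(w * be * bo)
  s2 <- sum(w * be^2)
  b_loo <- (s1 - w * be * bo) / (s2 - w * be^2)
  res_obs <- w * (bo - b_loo * be)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    be_star <- matrix(stats::rnorm(k * n_sim, be, se_e), k)
    bo_star <- matrix(stats::rnorm(k * n_sim, b_loo * be, se_o), k)
    wbe_bo <- w * be_star * bo_star
    wbe2 <- w * be_star^2
    s1s <- matrix(colSums(wbe_bo), k, n_sim, byrow = TRUE)
    s2s <- matrix(colSums(wbe2), k, n_sim, byrow = TRUE)
    b_loo_star <- (s1s - wbe_bo) / (s2s - wbe2)
    res_star <- w * (bo_star - b_loo_star * be_star)^2
    list(rss = colSums(res_star), res = res_star)
  })

  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  raw <- (1 + rowSums(sims$res >= res_obs)) / (n_sim + 1)
  outlier <- data.frame(snp = hset$snp, raw = raw,
                        bonferroni = pmin(1, raw * k),
                        residual = res_obs,
                        stringsAsFactors = FALSE)
  presso_result(global_pval, rss_obs, outlier, character(0),
                mr_ivw(hset), n_sim, seed)
}

#' Recursive MR-PRESSO outlier pruning
#'
#' If the initial global test is not significant (p > 0.05) nothing is
#' removed. Otherwise instruments are sorted once, in ascending order of
#' their initial outlier p-values (ties broken by the observed weighted
#' residual, largest first), and removed one at a time in that order; after each removal the global test is rerun on the remainder,
#' and pruning stops as soon as its p-value exceeds 0.05. The corrected
#' estimate is the IVW fit on the survivors. Pruning that would leave
#' fewer than four instruments while the global test is still
#' significant is an error: the pair cannot be corrected.
#'
#' @param hset A \code{harmonized_set} with k >= 4 instruments.
#' @param n_sim,seed As in [presso_global()]; each rerun of the global
#'   test uses a distinct seed derived deterministically from
#'   \code{seed}.
#' @param alpha Global-test significance level (default 0.05, strict:
#'   p exactly equal to alpha continues pruning).
#' @param rerank Re-sort the remaining instruments by freshly computed
#'   outlier p-values after every removal instead of keeping the initial
#'   order (off by default).
#' @return A \code{presso_result}; \code{removed_snps} records the
#'   removal order and \code{global_pval} is the final (post-pruning)
#'   global p-value.
#' @export
presso_prune <- function(hset, n_sim = 1000, seed = 1, alpha = 0.05,
                         rerank = FALSE) {
  check_hset(hset, 4L, "presso_prune")
  initial <- presso_global(hset, n_sim = n_sim, seed = seed)
  if (initial$global_pval > alpha) {
    return(initial)
  }
  # Ascending outlier p; ties (several SNPs at the add-one floor) broken
  # by the observed weighted residual, largest first.
  order_ids <- initial$outlier_pvals$snp[
    order(initial$outlier_pvals$raw, -initial$outlier_pvals$residual)]
  cur <- hset
  removed <- character(0)
  last <- initial
  step <- 0L
  repeat {
    if (nrow(cur) - 1L < 4L) {
      stop("MR-PRESSO pruning exhausted the instruments for '",
           attr(hset, "exposure"), "' -> '", attr(hset, "outcome"),
           "' without reaching a non-significant global test; ",
           "the pair cannot be outlier-corrected")
    }
    step <- step + 1L
    drop_id <- order_ids[1]
    order_ids <- order_ids[-1]
    removed <- c(removed, drop_id)
    cur <- subset_hset(cur, which(cur$snp != drop_id))
    last <- presso_global(cur, n_sim = n_sim, seed = seed + step)
    if (last$global_pval > alpha) break
    if (rerank) {
      order_ids <- last$outlier_pvals$snp[order(last$outlier_pvals$raw)]
    }
  }
  presso_result(last$global_pval, last$rss_obs, initial$outlier_pvals,
                removed, mr_ivw(cur), n_sim, seed,
                initial_global_pval = initial$global_pval)
}

#' Assemble the full sensitivity report for one exposure-outcome pair
#'
#' Bundles the heterogeneity Q tests (IVW and Egger), the Egger
#' pleiotropy intercept, the recursive MR-PRESSO analysis, the Steiger
#' directionality test, the leave-one-out series, and the instrument
#' diagnostics.
#'
#' @param hset A \code{harmonized_set} with k >= 4 instruments (the
#'   minimum for MR-PRESSO).
#' @param n_sim,seed Passed to [presso_prune()].
#' @return A list of class \code{sensitivity_report}.
#' @export
sensitivity_report <- function(hset, n_sim = 1000, seed = 1) {
  check_hset(hset, 4L, "sensitivity_report")
  egger <- mr_egger(hset)
  structure(list(
    q_ivw = q_test(hset, "ivw"),
    q_egger = q_test(hset, "egger"),
    egger_intercept_pval = egger$intercept_pval,
    presso = presso_prune(hset, n_sim = n_sim, seed = seed),
    steiger = steiger_test(hset),
    loo = leave_one_out(hset),
    diagnostics = instrument_diagnostics(hset)
  ), class = "sensitivity_report")
}

#' Write a sensitivity report as JSON
#'
#' @param report A \code{sensitivity_report}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
export_report_json <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  x <- unclass(report)
  x$presso <- unclass(x$presso)
  x$presso$corrected <- as.data.frame(x$presso$corrected)
  x$diagnostics <- unclass(x$diagnostics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
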
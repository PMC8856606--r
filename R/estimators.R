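# Causal-effect estimators for two-sample MR on a harmonized set.
#
# All estimators regress outcome effects on exposure effects across
# instruments, weighting by inverse outcome variance; they differ in how
# they accommodate pleiotropy and measurement error. Two-sided p-values
# throughout, floored at the smallest positive double.

mr_result <- function(method, b, se, pval, k_used,
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_pval = NA_real_, extras = NULL) {
  out <- data.frame(method = method, b = b, se = se, pval = pval,
                    k_used = k_used, intercept = intercept,
                    intercept_se = intercept_se,
                    intercept_pval = intercept_pval,
                    stringsAsFactors = FALSE)
  attr(out, "extras") <- extras
  class(out) <- c("mr_result", "data.frame")
  out
}

check_hset <- function(hset, k_min, method) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (nrow(hset) < k_min) {
    stop(method, " requires at least ", k_min, " instruments (got ",
         nrow(hset), ")")
  }
  invisible(nrow(hset))
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect is the SNP-outcome effect divided by the
#' SNP-exposure effect; the standard error is the first-order delta
#' approximation \code{se_out / |beta_exp|}.
#'
#' @param hset A \code{harmonized_set} with exactly one instrument.
#' @return An \code{mr_result} row (\code{method = "wald_ratio"}).
#' @export
mr_wald_ratio <- function(hset) {
  check_hset(hset, 1L, "wald_ratio")
  if (nrow(hset) != 1L) stop("wald_ratio is defined for exactly one instrument")
  if (hset$beta_exp == 0) stop("degenerate instrument: beta_exp = 0")
  b <- hset$beta_out / hset$beta_exp
  se <- hset$se_out / abs(hset$beta_exp)
  mr_result("wald_ratio", b, se, p_from_z(b / se), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights \code{1/se_out^2}; equivalently the
#' inverse-variance weighted average of per-SNP Wald ratios. The default
#' multiplicative random-effects model scales the fixed-effect standard
#' error by the residual standard deviation, floored at 1 so that
#' under-dispersion never shrinks it. With a single instrument the
#' estimate reduces exactly to the Wald ratio.
#'
#' @param hset A \code{harmonized_set} with k >= 1 instruments.
#' @param model \code{"random"} (multiplicative random effects, default)
#'   or \code{"fixed"}.
#' @return An \code{mr_result} row (\code{method = "ivw"}).
#' @export
mr_ivw <- function(hset, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- check_hset(hset, 1L, "ivw")
  w <- 1 / hset$se_out^2
  s2 <- sum(w * hset$beta_exp^2)
  if (s2 == 0) stop("degenerate instruments: all beta_exp = 0")
  b <- sum(w * hset$beta_exp * hset$beta_out) / s2
  se <- sqrt(1 / s2)
  if (model == "random" && k >= 2L) {
    sigma2 <- sum(w * (hset$beta_out - b * hset$beta_exp)^2) / (k - 1)
    se <- se * max(1, sqrt(sigma2))
  }
  mr_result("ivw", b, se, p_from_z(b / se), k)
}

ivw_point <- function(beta_exp, beta_out, se_out) {
  w <- 1 / se_out^2
  sum(w * beta_exp * beta_out) / sum(w * beta_exp^2)
}

#' Maximum-likelihood estimate allowing error on both sides
#'
#' Models the observed exposure and outcome betas as jointly normal
#' around true instrument effects gamma_j and b * gamma_j, so that
#' uncertainty in the SNP-exposure associations is propagated (unlike
#' IVW, which conditions on them). For fixed b the gamma_j maximize in
#' closed form, leaving the one-dimensional profile log-likelihood
#' \code{-1/2 sum (beta_out - b beta_exp)^2 / (se_out^2 + b^2 se_exp^2)},
#' which is maximized numerically over \code{[-50, 50]} (standardized
#' effects make larger |b| implausible). The standard error comes from
#' the curvature of the profile log-likelihood at the optimum.
#'
#' @param hset A \code{harmonized_set} with k >= 2 instruments.
#' @param bracket Search interval for b.
#' @return An \code{mr_result} row (\code{method = "mle"}).
#' @export
mr_mle <- function(hset, bracket = c(-50, 50)) {
  k <- check_hset(hset, 2L, "mle")
  be <- hset$beta_exp; bo <- hset$beta_out
  ve <- hset$se_exp^2; vo <- hset$se_out^2
  nll <- function(b) 0.5 * sum((bo - b * be)^2 / (vo + b^2 * ve))
  opt <- stats::optimize(nll, bracket, tol = 1e-10)
  b <- opt$minimum
  if (min(abs(b - bracket)) < 1e-4) {
    stop("mle did not converge inside the search bracket [",
         bracket[1], ", ", bracket[2], "]")
  }
  h <- max(1e-4, abs(b) * 1e-4)
  d2 <- (nll(b + h) - 2 * nll(b) + nll(b - h)) / h^2
  if (!is.finite(d2) || d2 <= 0) {
    stop("mle curvature not positive definite at the optimum")
  }
  se <- 1 / sqrt(d2)
  mr_result("mle", b, se, p_from_z(b / se), k)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, after orienting every instrument so its exposure beta is
#' non-negative (the result is invariant to flipping any instrument's
#' sign pair). The intercept estimates the average directional
#' pleiotropy; a significant intercept signals its presence. Slope and
#' intercept standard errors use multiplicative random effects with the
#' residual standard deviation floored at 1, and p-values use the t
#' distribution with k - 2 degrees of freedom.
#'
#' @param hset A \code{harmonized_set} with k >= 3 instruments.
#' @return An \code{mr_result} row (\code{method = "egger"}) carrying
#'   the intercept, its standard error and its p-value.
#' @export
mr_egger <- function(hset) {
  k <- check_hset(hset, 3L, "egger")
  s <- ifelse(hset$beta_exp < 0, -1, 1)
  be <- s * hset$beta_exp
  bo <- s * hset$beta_out
  w <- 1 / hset$se_out^2
  fit <- stats::lm(bo ~ be, weights = w)
  cf <- stats::coef(summary(fit))
  sigma <- summary(fit)$sigma
  scale <- min(1, sigma) # dividing by min(1, sigma) floors the dispersion at 1
  b <- cf["be", "Estimate"]
  se <- cf["be", "Std. Error"] / scale
  a <- cf["(Intercept)", "Estimate"]
  a_se <- cf["(Intercept)", "Std. Error"] / scale
  mr_result("egger", b, se, p_from_t(b / se, k - 2), k,
            intercept = a, intercept_se = a_se,
            intercept_pval = p_from_t(a / a_se, k - 2))
}

# Weighted median of ratio estimates r with weights w: order the ratios,
# normalize the weights, and linearly interpolate the inverse of the
# centered cumulative weight function at probability 1/2.
weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  k <- length(r)
  if (s[k] <= 0.5) return(r[k])
  i <- findInterval(0.5, s)
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

#' Weighted median estimate
#'
#' The 50% point of the inverse-variance weighted empirical distribution
#' of per-SNP Wald ratios, consistent when less than half the weight
#' comes from pleiotropic instruments. Weights are the first-order terms
#' \code{beta_exp^2 / se_out^2}. The standard error is estimated by
#' parametric bootstrap: exposure and outcome betas are redrawn from
#' normal distributions centered on their observed values and the
#' weighted median recomputed.
#'
#' @param hset A \code{harmonized_set} with k >= 3 instruments.
#' @param n_boot Bootstrap replicates for the standard error (default
#'   1000). \code{n_boot = 0} returns the point estimate with NA se/p.
#' @param seed Seed for the bootstrap, making the se reproducible.
#' @return An \code{mr_result} row (\code{method = "wme"}).
#' @export
mr_wme <- function(hset, n_boot = 1000, seed = 1) {
  k <- check_hset(hset, 3L, "wme")
  r <- hset$beta_out / hset$beta_exp
  w <- hset$beta_exp^2 / hset$se_out^2
  b <- weighted_median(r, w)
  if (n_boot == 0) {
    return(mr_result("wme", b, NA_real_, NA_real_, k))
  }
  boots <- with_seed(seed, {
    be_star <- matrix(stats::rnorm(k * n_boot, hset$beta_exp, hset$se_exp), k)
    bo_star <- matrix(stats::rnorm(k * n_boot, hset$beta_out, hset$se_out), k)
    vapply(seq_len(n_boot), function(j) {
      weighted_median(bo_star[, j] / be_star[, j],
                      be_star[, j]^2 / hset$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result("wme", b, se, p_from_z(b / se), k,
            extras = list(n_boot = n_boot, seed = seed))
}

#' Run every applicable estimator on a harmonized set
#'
#' Wald ratio for a single instrument; IVW and maximum likelihood from
#' two instruments; MR-Egger and the weighted median from three.
#'
#' @param hset A \code{harmonized_set}.
#' @param n_boot,seed Passed to [mr_wme()].
#' @param ivw_model Passed to [mr_ivw()].
#' @return An \code{mr_result} data frame with one row per method run.
#' @export
mr_all <- function(hset, n_boot = 1000, seed = 1,
                   ivw_model = c("random", "fixed")) {
  ivw_model <- match.arg(ivw_model)
  k <- nrow(hset)
  res <- list()
  if (k == 1L) {
    res$wald <- mr_wald_ratio(hset)
  }
  if (k >= 1L) res$ivw <- mr_ivw(hset, model = ivw_model)
  if (k >= 2L) res$mle <- mr_mle(hset)
  if (k >= 3L) {
    res$egger <- mr_egger(hset)
    res$wme <- mr_wme(hset, n_boot = n_boot, seed = seed)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}
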
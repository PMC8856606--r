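# Orchestration of the exposure x outcome screen, multiple-testing
# control per taxonomic level, and plot-data export.

TAXON_LEVELS <- c("phylum", "class", "order", "family", "genus", "species")

#' Taxon metadata for an exposure feature
#'
#' @param feature_id Unique identifier for the feature.
#' @param level Taxonomic level, one of phylum, class, order, family,
#'   genus, species.
#' @param name Display name (defaults to \code{feature_id}).
#' @return A list of class \code{taxon_meta}.
#' @export
taxon_meta <- function(feature_id, level, name = feature_id) {
  level <- match.arg(level, TAXON_LEVELS)
  structure(list(feature_id = feature_id, level = level, name = name),
            class = "taxon_meta")
}

#' Per-level multiple-testing thresholds
#'
#' A Bonferroni threshold of \code{0.05 / n} per taxonomic level, where
#' n is the number of taxa tested at that level. With the study's level
#' counts (9 phyla, 15 classes, 19 orders, 30 families, 102 genera, 15
#' species) this yields 5.56e-3, 3.33e-3, 2.63e-3, 1.67e-3, 4.90e-4 and
#' 3.33e-3.
#'
#' @param counts Named numeric vector: taxa tested per level.
#' @param alpha Family-wise level (default 0.05).
#' @return Named numeric vector of thresholds.
#' @export
#' @examples
#' level_thresholds(c(phylum = 9, genus = 102))
level_thresholds <- function(counts, alpha = 0.05) {
  if (any(counts <= 0)) stop("taxa counts must be positive")
  alpha / counts
}

#' Configuration for a screening run
#'
#' @param p_threshold Instrument-selection p-value threshold.
#' @param clump_r2,clump_kb LD-clumping parameters (squared correlation
#'   threshold; window in kilobases).
#' @param n_sim MR-PRESSO simulation count.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Master seed; every stochastic step in the screen derives
#'   its own seed from it, so a run is reproducible end to end.
#' @param alpha Family-wise significance level for the thresholds.
#' @param confounder_alpha Nominal level for the confounder filter.
#' @param ivw_model IVW effects model.
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(p_threshold = 1e-5, clump_r2 = 0.1, clump_kb = 500,
                          n_sim = 1000, n_boot = 1000, seed = 1,
                          alpha = 0.05, confounder_alpha = 0.05,
                          ivw_model = c("random", "fixed")) {
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, n_sim = n_sim, n_boot = n_boot,
                 seed = seed, alpha = alpha,
                 confounder_alpha = confounder_alpha,
                 ivw_model = match.arg(ivw_model)),
            class = "screen_config")
}

empty_screen_row <- function(meta, outcome_name, status, threshold) {
  data.frame(
    feature_id = meta$feature_id, level = meta$level, name = meta$name,
    outcome = outcome_name, status = status, k = NA_integer_,
    k_removed = NA_integer_, r2_exp = NA_real_, f_stat = NA_real_,
    b_ivw = NA_real_, se_ivw = NA_real_, p_ivw = NA_real_,
    b_mle = NA_real_, p_mle = NA_real_,
    b_egger = NA_real_, p_egger = NA_real_, p_egger_intercept = NA_real_,
    b_wme = NA_real_, p_wme = NA_real_,
    b_presso = NA_real_, p_presso = NA_real_,
    q_ivw_p = NA_real_, q_egger_p = NA_real_, presso_global_p = NA_real_,
    steiger_direction = NA, steiger_p = NA_real_,
    n_concordant = NA_integer_, level_threshold = threshold,
    significant = NA, stringsAsFactors = FALSE
  )
}

# Run the per-pair pipeline: select -> clump -> drop palindromes ->
# harmonize -> confounder filter -> PRESSO prune -> estimate -> sensitivity.
screen_pair <- function(meta, exp_stats, ld, out_stats, config, conf_table,
                        threshold, pair_seed) {
  row <- empty_screen_row(meta, attr(out_stats, "trait_name"), "ok", threshold)
  detail <- list(meta = meta, outcome = attr(out_stats, "trait_name"))

  sel <- select_by_pvalue(exp_stats, config$p_threshold)
  if (nrow(sel) == 0L) {
    row$status <- "no_instruments"
    return(list(row = row, detail = detail))
  }
  cl <- suppressWarnings(clump(sel, ld, r2_max = config$clump_r2,
                               window_bp = config$clump_kb * 1000))
  cl <- drop_palindromic(cl)
  if (nrow(cl) == 0L) {
    row$status <- "no_instruments_after_pruning"
    return(list(row = row, detail = detail))
  }
  hset <- suppressMessages(harmonize(cl, drop_palindromic(out_stats)))
  if (!is.null(conf_table) && nrow(hset) > 0L) {
    hset <- suppressMessages(
      confounder_filter(hset, conf_table, alpha = config$confounder_alpha))
  }
  if (nrow(hset) == 0L) {
    row$status <- "no_instruments_after_harmonization"
    return(list(row = row, detail = detail))
  }

  presso <- NULL
  if (nrow(hset) >= 4L) {
    presso <- tryCatch(
      presso_prune(hset, n_sim = config$n_sim, seed = pair_seed),
      error = function(e) e
    )
    if (inherits(presso, "error")) {
      row$status <- "presso_uncorrectable"
      presso <- NULL
    } else if (length(presso$removed_snps)) {
      hset <- subset_hset(hset, which(!hset$snp %in% presso$removed_snps))
    }
  } else {
    row$status <- "presso_unavailable"
  }

  k <- nrow(hset)
  row$k <- k
  row$k_removed <- if (is.null(presso)) NA_integer_ else length(presso$removed_snps)

  est <- tryCatch(
    mr_all(hset, n_boot = config$n_boot, seed = pair_seed + 1L,
           ivw_model = config$ivw_model),
    error = function(e) NULL
  )
  if (is.null(est)) {
    row$status <- "estimation_failed"
    return(list(row = row, detail = detail))
  }
  get_row <- function(m) est[est$method == m, , drop = FALSE]
  ivw <- get_row("ivw")
  if (nrow(ivw) == 0L) ivw <- get_row("wald_ratio")
  row$b_ivw <- ivw$b; row$se_ivw <- ivw$se; row$p_ivw <- ivw$pval
  if (nrow(get_row("mle"))) {
    row$b_mle <- get_row("mle")$b; row$p_mle <- get_row("mle")$pval
  }
  if (nrow(get_row("egger"))) {
    eg <- get_row("egger")
    row$b_egger <- eg$b; row$p_egger <- eg$pval
    row$p_egger_intercept <- eg$intercept_pval
  }
  if (nrow(get_row("wme"))) {
    row$b_wme <- get_row("wme")$b; row$p_wme <- get_row("wme")$pval
  }
  if (!is.null(presso)) {
    corrected <- presso$corrected
    pres_row <- mr_result("presso", corrected$b, corrected$se,
                          corrected$pval, corrected$k_used)
    est <- rbind(est, pres_row)
    row$b_presso <- corrected$b
    row$p_presso <- corrected$pval
    row$presso_global_p <- presso$global_pval
  }

  diag <- instrument_diagnostics(hset)
  row$r2_exp <- diag$r2_exp
  row$f_stat <- diag$f_stat
  if (k >= 2L) row$q_ivw_p <- q_test(hset, "ivw")$pval
  if (k >= 3L) row$q_egger_p <- q_test(hset, "egger")$pval
  st <- steiger_test(hset)
  row$steiger_direction <- st$direction
  row$steiger_p <- st$pval

  # Concordance of the complementary methods with the IVW decision:
  # same sign and nominally significant (p < 0.05).
  others <- est[est$method %in% c("mle", "egger", "wme", "presso"), ]
  row$n_concordant <- sum(sign(others$b) == sign(ivw$b) &
                            others$pval < 0.05, na.rm = TRUE)

  row$significant <- row$p_ivw < threshold
  detail$hset <- hset
  detail$estimates <- est
  detail$presso <- presso
  if (k >= 3L) detail$loo <- leave_one_out(hset)
  list(row = row, detail = detail)
}

#' Run the forward exposure x outcome screen
#'
#' For every exposure-outcome pair the full pipeline is run: instrument
#' selection by p-value, LD clumping, palindrome removal, harmonization,
#' optional confounder filtering, recursive MR-PRESSO outlier pruning,
#' estimation by every applicable method, and the sensitivity suite.
#' Pairs that fail a precondition (for example, no instruments survive)
#' are reported with a status code, never silently skipped. The
#' significance flag compares the IVW p-value against the Bonferroni
#' threshold of the exposure's taxonomic level, computed from the
#' number of taxa tested at that level.
#'
#' @param exposures List of exposures, each a list with elements
#'   \code{meta} (a [taxon_meta()]), \code{stats} (a \code{sumstats})
#'   and optionally \code{ld} (an [ld_info()]).
#' @param outcomes List of outcome \code{sumstats} objects.
#' @param config A [screen_config()].
#' @param conf_table Optional confounder p-value table (see
#'   [confounder_filter()]).
#' @return A \code{screen_table} data frame with one row per pair, plus
#'   a \code{"details"} attribute holding per-pair harmonized sets,
#'   estimates and leave-one-out series for plotting.
#' @export
run_screen <- function(exposures, outcomes, config = screen_config(),
                       conf_table = NULL) {
  stopifnot(inherits(config, "screen_config"))
  levels_tested <- vapply(exposures, function(e) e$meta$level, character(1))
  counts <- table(levels_tested)
  thresholds <- level_thresholds(stats::setNames(as.numeric(counts),
                                                 names(counts)),
                                 alpha = config$alpha)
  rows <- list()
  details <- list()
  pair_i <- 0L
  for (e in exposures) {
    for (out_stats in outcomes) {
      pair_i <- pair_i + 1L
      pair_seed <- config$seed + 97L * pair_i
      res <- screen_pair(e$meta, e$stats, e$ld, out_stats, config,
                         conf_table,
                         threshold = thresholds[[e$meta$level]],
                         pair_seed = pair_seed)
      key <- paste(e$meta$feature_id, attr(out_stats, "trait_name"),
                   sep = "|")
      rows[[key]] <- res$row
      details[[key]] <- res$detail
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "thresholds") <- thresholds
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Run the reverse (outcome-to-microbiota) screen
#'
#' Runs the identical pipeline with the roles swapped: the former
#' outcomes act as exposures and the former exposure features as
#' outcomes. Because the reverse analysis tests one flat family of
#' pairs rather than per-level families, a single Bonferroni threshold
#' of \code{alpha / (number of tested pairs)} is applied to every row.
#'
#' @param exposures List of exposures, each a list with \code{meta},
#'   \code{stats}, and optionally \code{ld} (the psychiatric traits in
#'   the reverse direction).
#' @param outcomes List of outcome \code{sumstats} objects (the
#'   microbiota features in the reverse direction).
#' @param config A [screen_config()].
#' @param conf_table Optional confounder table.
#' @return A \code{screen_table} as in [run_screen()], with the flat
#'   threshold in \code{level_threshold}.
#' @export
reverse_screen <- function(exposures, outcomes, config = screen_config(),
                           conf_table = NULL) {
  out <- run_screen(exposures, outcomes, config = config,
                    conf_table = conf_table)
  n_pairs <- nrow(out)
  thr <- config$alpha / n_pairs
  out$level_threshold <- thr
  out$significant <- ifelse(is.na(out$p_ivw), NA, out$p_ivw < thr)
  attr(out, "thresholds") <- c(all = thr)
  out
}

#' Export scatter, forest and leave-one-out plot data for one pair
#'
#' Writes three tab-delimited files into \code{dir}:
#' \code{<feature>_<outcome>_scatter.tsv} with one row per instrument
#' (type "point") and one per fitted method (type "slope", slope and
#' intercept of the fitted line), \code{..._forest.tsv} with per-SNP
#' Wald ratios and 95% confidence limits, and \code{..._loo.tsv} with
#' the leave-one-out IVW series.
#'
#' @param table A \code{screen_table} from [run_screen()].
#' @param feature_id,outcome The pair to export.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_plot_data <- function(table, feature_id, outcome, dir = ".") {
  stopifnot(inherits(table, "screen_table"))
  key <- paste(feature_id, outcome, sep = "|")
  detail <- attr(table, "details")[[key]]
  if (is.null(detail) || is.null(detail$hset)) {
    stop("pair not found in screen table (or no harmonized data): ", key)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", feature_id), "_",
                                gsub("[^A-Za-z0-9_.-]", "_", outcome)))
  h <- detail$hset
  est <- detail$estimates

  points <- data.frame(type = "point", snp = h$snp, beta_exp = h$beta_exp,
                       se_exp = h$se_exp, beta_out = h$beta_out,
                       se_out = h$se_out, method = NA_character_,
                       slope = NA_real_, intercept = NA_real_,
                       stringsAsFactors = FALSE)
  slopes <- data.frame(type = "slope", snp = NA_character_,
                       beta_exp = NA_real_, se_exp = NA_real_,
                       beta_out = NA_real_, se_out = NA_real_,
                       method = est$method, slope = est$b,
                       intercept = ifelse(is.na(est$intercept), 0,
                                          est$intercept),
                       stringsAsFactors = FALSE)
  scatter_path <- paste0(stem, "_scatter.tsv")
  utils::write.table(rbind(points, slopes), scatter_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  wald_b <- h$beta_out / h$beta_exp
  wald_se <- h$se_out / abs(h$beta_exp)
  forest <- data.frame(snp = h$snp, b = wald_b, se = wald_se,
                       ci_low = wald_b - stats::qnorm(0.975) * wald_se,
                       ci_high = wald_b + stats::qnorm(0.975) * wald_se,
                       stringsAsFactors = FALSE)
  forest_path <- paste0(stem, "_forest.tsv")
  utils::write.table(forest, forest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  loo_path <- paste0(stem, "_loo.tsv")
  loo <- detail$loo
  if (is.null(loo)) {
    loo <- data.frame(snp_omitted = character(0), b = numeric(0),
                      se = numeric(0), pval = numeric(0),
                      k_used = integer(0))
  }
  utils::write.table(loo, loo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(scatter = scatter_path, forest = forest_path, loo = loo_path))
}
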
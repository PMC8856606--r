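# GWAS summary-statistics data model and delimited-text I/O.

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Describe how a foreign summary-statistics file maps onto the canonical columns
#'
#' The canonical on-disk layout is tab-delimited with header
#' \code{SNP CHR POS EA OA EAF BETA SE P N}: identifier, chromosome,
#' 1-based position (genome build 37), effect allele, other allele,
#' effect-allele frequency, effect size on a standardized scale, its
#' standard error, p-value, and sample size. A \code{column_map} adapts
#' files that use other column names, delimiters or missing-value tokens.
#'
#' @param snp,chr,pos,ea,oa,eaf,beta,se,p,n Source column names for each
#'   canonical field.
#' @param delim Field delimiter (default tab).
#' @param na Missing-value token.
#' @param n_value Optional constant sample size used when the source file
#'   carries no sample-size column (set \code{n = NA}).
#' @return An object of class \code{column_map}.
#' @export
#' @examples
#' column_map(snp = "rsid", beta = "effect", delim = ",")
column_map <- function(snp = "SNP", chr = "CHR", pos = "POS", ea = "EA",
                       oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                       p = "P", n = "N", delim = "\t", na = "NA",
                       n_value = NULL) {
  cols <- c(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
            BETA = beta, SE = se, P = p, N = n)
  if (is.null(n_value) && is.na(cols["N"])) {
    stop("either an N column or a constant `n_value` must be supplied")
  }
  structure(list(cols = cols, delim = delim, na = na, n_value = n_value),
            class = "column_map")
}

#' Construct a summary-statistics object from a data frame
#'
#' Rows violating the per-SNP record invariants are dropped with a
#' message: missing mandatory fields, multi-character or non-ACGT
#' alleles (the pipeline is SNP-only), identical alleles, non-positive
#' standard errors, allele frequencies outside (0, 1), p-values outside
#' (0, 1], or positions below 1. Alleles are uppercased.
#'
#' @param data Data frame with the canonical columns (see [column_map()]).
#' @param trait_name Label for the trait.
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @return A \code{sumstats} object: a data frame with canonical columns
#'   and \code{trait_name} / \code{trait_type} attributes.
#' @export
sumstats <- function(data, trait_name = "trait",
                     trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(CANONICAL_COLS, names(data))
  if (length(missing_cols)) {
    stop("missing canonical column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data)[, CANONICAL_COLS]
  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  df$EA <- toupper(as.character(df$EA))
  df$OA <- toupper(as.character(df$OA))
  for (col in c("POS", "EAF", "BETA", "SE", "P", "N")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  mandatory <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  bad <- rowSums(is.na(df[mandatory])) > 0 | df$SNP == ""
  ok_allele <- df$EA %in% c("A", "C", "G", "T") & df$OA %in% c("A", "C", "G", "T")
  bad <- bad | !ok_allele | df$EA == df$OA
  bad <- bad | !(df$SE > 0) | !(df$EAF > 0 & df$EAF < 1) |
    !(df$P > 0 & df$P <= 1) | df$POS < 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    message(sum(bad), " row(s) dropped while validating '", trait_name,
            "' summary statistics")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "trait_name") <- trait_name
  attr(df, "trait_type") <- trait_type
  class(df) <- c("sumstats", "data.frame")
  df
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for '", attr(x, "trait_name"), "' (",
      attr(x, "trait_type"), "): ", nrow(x), " SNPs\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a delimited GWAS summary-statistics file
#'
#' @param path Path to a delimited text file with a header.
#' @param colmap A [column_map()]; defaults to the canonical layout.
#' @param trait_name,trait_type Trait metadata attached to the result.
#' @return A \code{sumstats} object. Unparseable or invalid rows are
#'   dropped with a message (see [sumstats()]).
#' @export
read_sumstats <- function(path, colmap = column_map(), trait_name = "trait",
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = colmap$delim,
                           na.strings = colmap$na, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "",
                           quote = "\"")
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  cols <- colmap$cols
  wanted <- cols[!is.na(cols)]
  absent <- setdiff(unname(wanted), names(raw))
  if (length(absent)) {
    stop("mapped column(s) absent from header of ", path, ": ",
         paste(absent, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(wanted), drop = FALSE], names(wanted))
  if (is.na(cols["N"])) df$N <- colmap$n_value
  sumstats(df, trait_name = trait_name, trait_type = trait_type)
}

#' Write summary statistics in the canonical tab-delimited layout
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces every value to the last bit.
#'
#' @param stats A nonempty \code{sumstats} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats) == 0L) stop("refusing to write an empty sumstats object")
  out <- as.data.frame(stats)
  for (col in c("EAF", "BETA", "SE", "P", "N")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  out$POS <- sprintf("%d", as.integer(out$POS))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
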
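# Linkage-disequilibrium reference: pairwise squared correlations (r2).

#' Build an LD reference from a squared-correlation matrix
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param r2 Square symmetric matrix of squared correlations in
#'   \code{[0, 1]} with unit diagonal, in the order of \code{snp_ids}.
#' @return An \code{ld_info} object.
#' @export
ld_info <- function(snp_ids, r2) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  k <- length(snp_ids)
  if (!all(dim(r2) == c(k, k))) stop("r2 must be ", k, " x ", k)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in LD reference")
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  r2 <- pmin(pmax((r2 + t(r2)) / 2, 0), 1)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_info")
}

#' Read an LD reference from disk
#'
#' Two plain-text layouts are accepted: a square matrix (header row of
#' SNP ids, first column of SNP ids) or a three-column pairwise list
#' \code{snp_a snp_b r2} (unlisted pairs are taken as r2 = 0).
#'
#' @param path Path to a tab-delimited file.
#' @return An \code{ld_info} object.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) == 3L && all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(raw$snp_a, raw$snp_b)] <- raw$r2
    m[cbind(raw$snp_b, raw$snp_a)] <- raw$r2
    diag(m) <- 1
    return(ld_info(ids, m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  ld_info(ids, m)
}

#' Write an LD reference as a square matrix file
#'
#' @param ld An \code{ld_info} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_info"))
  out <- data.frame(SNP = ld$snp_ids, ld$r2, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
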
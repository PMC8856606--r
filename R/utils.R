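# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Two-sided normal p-value from a z statistic, floored at the smallest
# positive double so downstream -log10 transforms stay finite.
p_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# Two-sided t p-value with df degrees of freedom, same floor.
p_from_t <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), .Machine$double.xmin)
}

# DNA complement for allele strings (used in strand-flip detection).
complement_allele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

# Subset rows of a sumstats object while preserving its class and
# trait attributes ("[.data.frame" drops custom attributes).
keep_rows <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_name") <- attr(x, "trait_name")
  attr(out, "trait_type") <- attr(x, "trait_type")
  class(out) <- class(x)
  out
}
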
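#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package functions do not perturb the session RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")

#' Reverse complement of a character DNA string
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @keywords internal
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement of single bases (vectorized)
#' @keywords internal
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# variant identity key used by the concordance and sharing stages
variant_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}

position_key <- function(df) {
  paste(df$contig, df$pos, sep = ":")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
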
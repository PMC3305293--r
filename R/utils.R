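BASES <- c("A", "C", "G", "T")

#' Derive a per-stream random seed from a master seed
#'
#' Streams (one per sample, per stage, ...) are keyed by a string label so that
#' adding a stream never perturbs the draws of existing ones.  The label is
#' folded into the master seed with a polynomial rolling hash modulo
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Format a ratio as a percentage string
#'
#' Percentages in pipeline reports are printed at a fixed number of decimal
#' places; the unrounded value is always kept alongside in machine-readable
#' output.
#'
#' @param num,den numerator and denominator (den > 0).
#' @param digits decimal places to print.
#' @return character scalar like `"0.3%"` or `"70%"`.
#' @export
format_percent <- function(num, den, digits = 0) {
  stopifnot(is.numeric(num), is.numeric(den), den > 0, num >= 0)
  sprintf("%.*f%%", digits, 100 * num / den)
}

# md5 of an R object via canonical serialization to a temp file; used to
# fingerprint run configurations.
hash_config <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# truncated-normal positive integer draws (rejection on the lower bound)
rtrunc_norm_int <- function(n, mean, sd, min) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < min)
  while (length(bad) > 0) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < min]
  }
  as.integer(out)
}
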
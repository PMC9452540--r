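# Internal sequence helpers. The package alphabet is RNA (A, C, G, U);
# DNA input is converted on read and only converted back for Biostrings
# matching machinery, which operates on the DNA alphabet.

#' @importFrom methods new validObject is slot
#' @importFrom stats setNames rlnorm runif rbinom sd median quantile
#'   wilcox.test cor binom.test complete.cases qnorm
#' @importFrom utils read.delim write.table head
NULL

RNA_LETTERS <- c("A", "C", "G", "U")

as_rna <- function(x) {
  x <- toupper(x)
  chartr("T", "U", x)
}

as_dna <- function(x) chartr("U", "T", toupper(x))

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGU(T) characters: %s",
                 what, paste(head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Vectorised length of the common prefix of x and y (character vectors).
common_prefix_len <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  out <- integer(n)
  if (n == 0L) return(out)
  maxlen <- pmin(nchar(x), nchar(y))
  alive <- maxlen > 0L
  j <- 1L
  while (any(alive)) {
    idx <- which(alive)
    eq <- substr(x[idx], j, j) == substr(y[idx], j, j)
    out[idx[eq]] <- j
    alive[idx[!eq]] <- FALSE
    alive[maxlen <= j] <- FALSE
    j <- j + 1L
  }
  out
}

# Deterministic child seeds below 2^31 for independent simulation streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483399L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
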
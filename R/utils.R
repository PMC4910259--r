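# Small DNA and stream helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Complement DNA bases
#'
#' Vectorised complement of A/C/G/T characters (strings of any length).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse complement of trinucleotides
#'
#' Fast path for 3-base strings; used for strand collapse of contexts.
#'
#' @param x character vector of 3-base strings.
#' @return reverse-complemented strings.
#' @export
revcomp3 <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  paste0(substr(y, 3, 3), substr(y, 2, 2), substr(y, 1, 1))
}

#' Reverse complement of arbitrary DNA strings
#'
#' @param x character vector.
#' @return character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive a per-element random seed from a master seed
#'
#' Stable string hash (djb2 modulo 2^31 - 1) combined with the master seed, so
#' that per-element random streams do not depend on iteration order.
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. an element id).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, id) {
  stopifnot(length(id) == 1L, length(master) == 1L)
  m <- 2147483647
  h <- 5381
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 33 + b) %% m
  }
  as.integer((h + as.numeric(master)) %% m)
}

# internal: check single bases are in {A,C,G,T}
is_acgt <- function(x) x %in% BASES

# internal: TRUE when a string consists only of A/C/G/T
all_acgt_string <- function(x) {
  !grepl("[^ACGT]", x)
}
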
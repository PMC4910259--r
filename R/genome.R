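# Reference-sequence accessor.  Sequences are held in memory as uppercase
# character strings (toy/panel scale); FASTA IO goes through Biostrings.

#' Create a reference-genome accessor from named sequences
#'
#' @param seqs named character vector, one DNA string per chromosome.
#' @return an object of class `fml_genome`.
#' @export
fml_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  seqs <- toupper(seqs)
  structure(seqs, class = "fml_genome")
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (optionally gzipped). Sequence names are truncated at
#'   the first whitespace.
#' @return an `fml_genome`.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  fml_genome(stats::setNames(as.character(ss), names(ss)))
}

#' Write a reference genome to FASTA
#'
#' @param genome an `fml_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Chromosome lengths of a genome accessor
#'
#' @param genome an `fml_genome`.
#' @return named integer vector.
#' @export
chrom_lengths <- function(genome) {
  x <- unclass(genome)
  stats::setNames(nchar(x), names(x))
}

#' Extract a subsequence (1-based, inclusive)
#'
#' @param genome an `fml_genome`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return a character string.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  s <- unclass(genome)[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  if (start < 1 || end > nchar(s)) stop("coordinates outside chromosome ", chrom)
  substring(s, start, end)
}

#' Reference base at given positions
#'
#' Vectorised over `chrom`/`pos` (recycled).
#'
#' @param genome an `fml_genome`.
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return character vector of single bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  seqs <- unclass(genome)
  bad <- !(chrom %in% names(seqs))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  out <- character(n)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    s <- seqs[[cn]]
    p <- pos[i]
    if (any(p < 1 | p > nchar(s))) stop("position outside chromosome ", cn)
    out[i] <- substring(s, p, p)
  }
  out
}

#' Normalise chromosome names against a genome
#'
#' Adds or strips a `"chr"` prefix so mutation and score inputs match the
#' reference naming convention; names that cannot be reconciled raise an error.
#'
#' @param chrom character vector of chromosome names.
#' @param genome an `fml_genome`.
#' @return character vector of normalised names.
#' @export
normalize_chrom <- function(chrom, genome) {
  known <- names(unclass(genome))
  out <- chrom
  miss <- !(out %in% known)
  if (any(miss)) {
    pref <- paste0("chr", out[miss])
    ok <- pref %in% known
    out[miss][ok] <- pref[ok]
  }
  miss <- !(out %in% known)
  if (any(miss)) {
    strip <- sub("^chr", "", out[miss])
    ok <- strip %in% known
    out[miss][ok] <- strip[ok]
  }
  miss <- !(out %in% known)
  if (any(miss)) {
    stop("unknown chromosome: ", paste(unique(chrom[miss]), collapse = ", "))
  }
  out
}

#' @export
print.fml_genome <- function(x, ...) {
  cl <- chrom_lengths(x)
  cat("fml_genome with", length(cl), "sequence(s):\n")
  for (i in seq_along(cl)) cat("  ", names(cl)[i], ": ", cl[i], " bp\n", sep = "")
  invisible(x)
}
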
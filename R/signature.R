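# 96-channel trinucleotide mutational signature: channel definitions, strand
# collapse, and estimation from observed cohorts.

#' The 96 trinucleotide substitution channel names
#'
#' Channels are written `"5'[ref>alt]3'"` with the mutated base collapsed to
#' the pyrimidine strand (ref is C or T), the community convention that yields
#' exactly 96 classes from the 192 raw (context, alt) pairs.
#'
#' @return character vector of length 96 in a fixed order.
#' @export
channel_names <- function() {
  out <- character(0)
  for (ref in c("C", "T")) {
    for (alt in setdiff(BASES, ref)) {
      for (five in BASES) {
        for (three in BASES) {
          out <- c(out, paste0(five, "[", ref, ">", alt, "]", three))
        }
      }
    }
  }
  out
}

#' Trinucleotide context at a genomic position
#'
#' Returns the three + strand bases at `pos - 1 .. pos + 1`, uppercase.  With
#' `strict = TRUE` (default) a position at a chromosome edge is an error; with
#' `strict = FALSE` edge positions yield `NA` so callers can skip and count
#' them.
#'
#' @param genome an [fml_genome()].
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @param strict error on edge positions instead of returning `NA`.
#' @return character vector of 3-base strings (or `NA`).
#' @export
trinucleotide_context <- function(genome, chrom, pos, strict = TRUE) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  seqs <- unclass(genome)
  bad <- !(chrom %in% names(seqs))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  out <- rep(NA_character_, n)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    s <- seqs[[cn]]
    p <- pos[i]
    edge <- p < 2 | p > nchar(s) - 1
    if (any(edge) && strict) {
      stop("position at chromosome edge has no trinucleotide context (",
           cn, ":", p[edge][1], ")")
    }
    ok <- !edge
    if (any(ok)) out[i][ok] <- substring(s, p[ok] - 1, p[ok] + 1)
  }
  out
}

#' Collapse a (context, alt) pair to its pyrimidine-centered channel
#'
#' When the central base is a purine (A or G) the context is
#' reverse-complemented and the alternate allele complemented, so that every
#' substitution maps to one of the 96 channels and every channel receives
#' exactly two raw (context, alt) pairs.
#'
#' @param context character vector of 3-base + strand contexts.
#' @param alt alternate allele(s) on the + strand.
#' @return character vector of channel keys like `"A[C>T]G"`.
#' @export
canonical_channel <- function(context, alt) {
  context <- toupper(context)
  alt <- toupper(alt)
  if (any(!all_acgt_string(context)) || any(!is_acgt(alt))) {
    stop("unscorable context: ambiguous base in trinucleotide or alt")
  }
  center <- substr(context, 2, 2)
  if (any(center == alt)) stop("alt equals the central reference base")
  flip <- center %in% c("A", "G")
  ctx <- context
  a <- alt
  if (any(flip)) {
    ctx[flip] <- revcomp3(context[flip])
    a[flip] <- comp_base(alt[flip])
  }
  paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">", a, "]",
         substr(ctx, 3, 3))
}

#' Construct a SignatureMatrix
#'
#' @param probabilities numeric vector of 96 probabilities named by
#'   [channel_names()]; must be non-negative and sum to 1 (tolerance 1e-9).
#' @param counts raw channel counts before normalisation (0 when unknown).
#' @param mode one of `"cohort"`, `"per_sample"`, `"precomputed"`, `"uniform"`.
#' @return object of class `SignatureMatrix`.
#' @export
signature_matrix <- function(probabilities,
                             counts = stats::setNames(numeric(96), channel_names()),
                             mode = "precomputed") {
  ch <- channel_names()
  if (length(probabilities) != 96) stop("signature must have 96 channels")
  if (is.null(names(probabilities))) names(probabilities) <- ch
  if (!setequal(names(probabilities), ch)) stop("bad channel names")
  probabilities <- probabilities[ch]
  if (any(probabilities < 0)) stop("negative channel probability")
  if (abs(sum(probabilities) - 1) > 1e-9) stop("channel probabilities must sum to 1")
  structure(list(probabilities = probabilities, counts = counts, mode = mode),
            class = "SignatureMatrix")
}

#' @export
print.SignatureMatrix <- function(x, ...) {
  top <- sort(x$probabilities, decreasing = TRUE)[1:3]
  cat("SignatureMatrix (", x$mode, "), top channels: ",
      paste(names(top), signif(top, 3), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The uniform 96-channel signature
#' @return a `SignatureMatrix` with every channel at 1/96.
#' @export
uniform_signature <- function() {
  signature_matrix(stats::setNames(rep(1 / 96, 96), channel_names()),
                   mode = "uniform")
}

#' Estimate the mutational signature from observed mutations
#'
#' Counts every usable SNV of the set (genome-wide, not restricted to tested
#' elements) into its pyrimidine-collapsed trinucleotide channel and
#' normalises the counts to probabilities.  Mutations at chromosome edges or
#' in ambiguous (non-ACGT) contexts are skipped and counted.
#'
#' @param mutations a `MutationSet`.
#' @param genome an [fml_genome()].
#' @param mode `"cohort"` (one matrix for the whole set), `"per_sample"`
#'   (a named list of matrices), or `"uniform"`.
#' @return a `SignatureMatrix`, or a named list of them in per-sample mode.
#'   `attr(, "n_skipped")` reports unusable mutations.
#' @export
compute_signature <- function(mutations, genome,
                              mode = c("cohort", "per_sample", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform") return(uniform_signature())
  df <- mutations$mutations
  if (mode == "per_sample") {
    out <- lapply(split(df, df$sample_id), function(d) {
      compute_signature(mutation_set(d, mutations$provenance), genome, "cohort")
    })
    for (i in seq_along(out)) out[[i]]$mode <- "per_sample"
    return(out)
  }
  ctx <- trinucleotide_context(genome, df$chrom, df$pos, strict = FALSE)
  usable <- !is.na(ctx) & all_acgt_string(ifelse(is.na(ctx), "N", ctx)) &
    is_acgt(df$alt)
  n_skipped <- sum(!usable)
  if (!any(usable)) {
    stop("no countable mutations for signature estimation; ",
         "use uniform or a precomputed signature")
  }
  ch <- canonical_channel(ctx[usable], df$alt[usable])
  counts <- table(factor(ch, levels = channel_names()))
  counts <- stats::setNames(as.numeric(counts), channel_names())
  sig <- signature_matrix(counts / sum(counts), counts, "cohort")
  attr(sig, "n_skipped") <- n_skipped
  sig
}

#' Read a precomputed signature from TSV
#'
#' Expects 96 rows with columns CHANNEL (e.g. `"A[C>T]G"`) and PROBABILITY.
#'
#' @param path TSV file.
#' @return a `SignatureMatrix` with mode `"precomputed"`.
#' @export
read_signature <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  nm <- toupper(names(dt))
  p <- stats::setNames(as.numeric(dt[[which(nm == "PROBABILITY")]]),
                       dt[[which(nm == "CHANNEL")]])
  p <- p / sum(p)
  signature_matrix(p, mode = "precomputed")
}

#' Write a signature to TSV
#'
#' @param signature a `SignatureMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  data.table::fwrite(
    data.frame(CHANNEL = names(signature$probabilities),
               PROBABILITY = as.numeric(signature$probabilities)),
    path, sep = "\t")
  invisible(path)
}
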
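# Core domain types: mutations, mutation sets and their QC/validation, plus
# the tab-separated and minimal-VCF readers.  Internal coordinates are 0-based
# half-open; every file format read or written here uses 1-based positions.

#' Construct a MutationSet
#'
#' @param mutations data.frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based integer), `ref`, `alt` (single + strand bases).
#' @param provenance free-text label describing the origin of the calls.
#' @return an object of class `MutationSet`.
#' @export
mutation_set <- function(mutations, provenance = "unknown") {
  req <- c("sample_id", "chrom", "pos", "ref", "alt")
  stopifnot(all(req %in% names(mutations)))
  mutations <- as.data.frame(mutations)[req]
  mutations$sample_id <- as.character(mutations$sample_id)
  mutations$chrom <- as.character(mutations$chrom)
  mutations$pos <- as.integer(mutations$pos)
  mutations$ref <- toupper(as.character(mutations$ref))
  mutations$alt <- toupper(as.character(mutations$alt))
  rownames(mutations) <- NULL
  structure(
    list(
      mutations = mutations,
      samples = sort(unique(mutations$sample_id)),
      provenance = provenance
    ),
    class = "MutationSet"
  )
}

#' @export
print.MutationSet <- function(x, ...) {
  cat("MutationSet:", nrow(x$mutations), "SNVs across",
      length(x$samples), "samples (", x$provenance, ")\n")
  invisible(x)
}

#' Number of mutations in a MutationSet
#' @param ms a `MutationSet`.
#' @return integer count.
#' @export
n_mutations <- function(ms) nrow(ms$mutations)

#' Validate raw mutation records against a reference genome
#'
#' Keeps only single-nucleotide substitutions whose reported reference allele
#' matches the reference sequence; indels and mismatching records are dropped
#' and counted.  Chromosome names are normalised (chr-prefix) against the
#' genome; a chromosome absent from the reference is a hard error.
#'
#' @param raw data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id` (extra columns ignored).
#' @param genome an [fml_genome()] covering every referenced chromosome.
#' @param provenance label stored on the resulting set.
#' @return a `MutationSet`; QC counts are attached as `attr(, "qc")`, a list
#'   with `n_input`, `n_retained`, `n_malformed`, `n_non_snv`,
#'   `n_ref_mismatch`, `n_out_of_range`.
#' @export
validate_mutations <- function(raw, genome, provenance = "validated") {
  req <- c("chrom", "pos", "ref", "alt", "sample_id")
  stopifnot(all(req %in% names(raw)))
  raw <- as.data.frame(raw)[req]
  qc <- list(n_input = nrow(raw), n_retained = 0L, n_malformed = 0L,
             n_non_snv = 0L, n_ref_mismatch = 0L, n_out_of_range = 0L)
  if (nrow(raw) == 0L) {
    ms <- mutation_set(raw, provenance)
    attr(ms, "qc") <- qc
    return(ms)
  }
  raw$chrom <- as.character(raw$chrom)
  raw$ref <- toupper(as.character(raw$ref))
  raw$alt <- toupper(as.character(raw$alt))
  pos <- suppressWarnings(as.integer(raw$pos))

  # malformed: missing fields, non-numeric/positive positions, ref == alt,
  # or single-character alleles outside {A,C,G,T}
  malformed <- is.na(pos) | pos < 1L | is.na(raw$chrom) | !nzchar(raw$chrom) |
    is.na(raw$sample_id) | is.na(raw$ref) | is.na(raw$alt) |
    (nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
       (!is_acgt(raw$ref) | !is_acgt(raw$alt) | raw$ref == raw$alt))
  # non-SNV: multi-base (or empty) alleles, i.e. indels / MNVs
  non_snv <- !malformed & (nchar(raw$ref) != 1L | nchar(raw$alt) != 1L)
  qc$n_malformed <- sum(malformed)
  qc$n_non_snv <- sum(non_snv)
  keep <- !malformed & !non_snv
  df <- raw[keep, , drop = FALSE]
  df$pos <- pos[keep]

  if (nrow(df)) {
    # unknown chromosome (after normalisation) is a hard error
    df$chrom <- normalize_chrom(df$chrom, genome)
    lens <- chrom_lengths(genome)
    oor <- df$pos > lens[df$chrom]
    qc$n_out_of_range <- sum(oor)
    df <- df[!oor, , drop = FALSE]
  }
  if (nrow(df)) {
    refs <- genome_base(genome, df$chrom, df$pos)
    mismatch <- refs != df$ref
    qc$n_ref_mismatch <- sum(mismatch)
    df <- df[!mismatch, , drop = FALSE]
  }
  qc$n_retained <- nrow(df)
  ms <- mutation_set(df, provenance)
  attr(ms, "qc") <- qc
  ms
}

#' Read somatic mutations from the tab-separated dialect
#'
#' Expects a header with columns CHROMOSOME, POSITION (1-based), REF, ALT,
#' SAMPLE (aliases CHROM/POS/SAMPLE_ID accepted, case-insensitive).
#'
#' @param path TSV file.
#' @return data.frame of raw records suitable for [validate_mutations()].
#' @export
read_mutations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  nm <- toupper(names(dt))
  pick <- function(...) {
    cand <- c(...)
    i <- match(cand, nm)
    i <- i[!is.na(i)][1]
    if (is.na(i)) stop("missing column (one of ", paste(cand, collapse = "/"),
                       ") in ", path)
    dt[[i]]
  }
  data.frame(
    chrom = as.character(pick("CHROMOSOME", "CHROM", "CHR")),
    pos = as.integer(pick("POSITION", "POS")),
    ref = as.character(pick("REF")),
    alt = as.character(pick("ALT")),
    sample_id = as.character(pick("SAMPLE", "SAMPLE_ID")),
    stringsAsFactors = FALSE
  )
}

#' Write a MutationSet to the tab-separated dialect
#'
#' @param ms a `MutationSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(ms, path) {
  df <- ms$mutations
  out <- data.frame(CHROMOSOME = df$chrom, POSITION = df$pos, REF = df$ref,
                    ALT = df$alt, SAMPLE = df$sample_id)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read somatic SNVs from a minimal (single-sample) VCF
#'
#' Uses only CHROM/POS/REF/ALT; the first comma-separated ALT allele is taken.
#' One file corresponds to one sample (the usual per-sample VCF layout).
#'
#' @param path VCF file (plain text).
#' @param sample_id sample label; defaults to the file name without extension.
#' @return data.frame of raw records suitable for [validate_mutations()].
#' @export
read_mutations_vcf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), sample_id = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, function(x) strsplit(x[[5L]], ",", fixed = TRUE)[[1]][1], ""),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}
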
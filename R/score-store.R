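# Functional-impact score storage and per-element enumeration of all possible
# substitutions with their signature-derived sampling probabilities.

#' Construct a ScoreStore
#'
#' @param table data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `score` (finite numeric).
#' @param provider label of the scoring framework (e.g. `"cadd-like"`,
#'   `"rna-structure-like"`, `"synthetic"`).
#' @return object of class `ScoreStore`.
#' @export
score_store <- function(table, provider = "synthetic") {
  req <- c("chrom", "pos", "ref", "alt", "score")
  stopifnot(all(req %in% names(table)))
  tb <- as.data.frame(table)[req]
  tb$chrom <- as.character(tb$chrom)
  tb$pos <- as.integer(tb$pos)
  tb$ref <- toupper(as.character(tb$ref))
  tb$alt <- toupper(as.character(tb$alt))
  tb$score <- as.numeric(tb$score)
  if (any(!is.finite(tb$score))) stop("scores must be finite")
  key <- paste(tb$chrom, tb$pos, tb$alt, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) entries in score table")
  structure(list(table = tb, key = key,
                 poskey = paste(tb$chrom, tb$pos, sep = ":"),
                 provider = provider),
            class = "ScoreStore")
}

#' @export
print.ScoreStore <- function(x, ...) {
  cat("ScoreStore (", x$provider, "): ", nrow(x$table), " substitutions on ",
      length(unique(x$table$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a per-substitution score table
#'
#' Accepts the CADD-style whole-genome TSV shape (CHROM, POS, REF, ALT, then
#' one or more score columns; the last column is used unless `score_col`
#' names another one).  `#`-prefixed header lines are tolerated.
#'
#' @param path TSV file (plain or gzipped).
#' @param score_col optional name of the score column.
#' @param provider provider label.
#' @return a `ScoreStore`.
#' @export
read_scores <- function(path, score_col = NULL, provider = "cadd-like") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  names(dt) <- toupper(sub("^#+", "", names(dt)))
  nm <- names(dt)
  need <- function(cand) {
    i <- match(cand, nm); i <- i[!is.na(i)][1]
    if (is.na(i)) stop("missing column ", cand[1], " in ", path)
    i
  }
  ic <- need(c("CHROM", "CHROMOSOME", "CHR"))
  ip <- need(c("POS", "POSITION"))
  ir <- need(c("REF"))
  ia <- need(c("ALT"))
  is_ <- if (!is.null(score_col)) {
    match(toupper(score_col), nm)
  } else {
    setdiff(seq_along(nm), c(ic, ip, ir, ia))[length(setdiff(seq_along(nm), c(ic, ip, ir, ia)))]
  }
  if (is.na(is_) || !length(is_)) stop("no score column found in ", path)
  score_store(data.frame(chrom = as.character(dt[[ic]]), pos = dt[[ip]],
                         ref = dt[[ir]], alt = dt[[ia]],
                         score = as.numeric(dt[[is_]])),
              provider = provider)
}

#' Write a score store to TSV
#'
#' @param store a `ScoreStore`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(store, path) {
  tb <- store$table
  data.table::fwrite(
    data.frame(CHROM = tb$chrom, POS = tb$pos, REF = tb$ref, ALT = tb$alt,
               SCORE = tb$score),
    path, sep = "\t")
  invisible(path)
}

#' Look up functional-impact scores
#'
#' Vectorised over (chrom, pos, alt).  A missing entry yields `NA` (a
#' distinguished "unscored" result, never a silent zero).  Querying the
#' reference allele itself (alt equal to the stored ref at a scored position)
#' is a precondition violation and raises an error.
#'
#' @param store a `ScoreStore`.
#' @param chrom,pos,alt substitution coordinates (1-based) and alternate base.
#' @return numeric vector of scores with `NA` for unscored substitutions.
#' @export
get_score <- function(store, chrom, pos, alt) {
  n <- max(length(chrom), length(pos), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  alt <- rep_len(toupper(alt), n)
  i <- match(paste(chrom, pos, alt, sep = ":"), store$key)
  out <- store$table$score[i]
  miss <- is.na(i)
  if (any(miss)) {
    j <- match(paste(chrom[miss], pos[miss], sep = ":"), store$poskey)
    hit <- !is.na(j)
    if (any(hit) && any(store$table$ref[j[hit]] == alt[miss][hit])) {
      stop("query alt equals the reference allele at a scored position")
    }
  }
  out
}

#' Enumerate all possible substitutions of an element with sampling weights
#'
#' Lists every (position, alt) pair in the element's segments with its
#' functional-impact score, trinucleotide channel and sampling probability
#' proportional to the signature probability of the channel (normalised over
#' the element).  Positions with ambiguous reference bases, absent contexts
#' (chromosome edges) or missing scores are excluded and counted.
#'
#' @param store a `ScoreStore`.
#' @param element a `GenomicElement`.
#' @param signature a `SignatureMatrix` (or `NULL` to skip weights; the
#'   `channel` column still allows weights to be attached later).
#' @param genome an [fml_genome()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `channel`, `prob`; attributes `element_id`, `n_unscored`, `n_context_na`.
#' @export
element_scores <- function(store, element, signature, genome) {
  pos <- element_positions(element)
  chrom <- element$chrom
  ref <- genome_base(genome, chrom, pos)
  ctx <- trinucleotide_context(genome, chrom, pos, strict = FALSE)
  ok <- is_acgt(ref) & !is.na(ctx) & all_acgt_string(ifelse(is.na(ctx), "N", ctx))
  n_context_na <- sum(!ok)
  pos <- pos[ok]; ref <- ref[ok]; ctx <- ctx[ok]
  if (!length(pos)) {
    stop("element ", element$element_id, " has no usable positions")
  }
  # 3 alternate alleles per position
  alt_m <- matrix("", nrow = 3, ncol = length(ref))
  for (b in BASES) {
    sel <- ref == b
    if (any(sel)) alt_m[, sel] <- setdiff(BASES, b)
  }
  pos3 <- rep(pos, each = 3)
  ref3 <- rep(ref, each = 3)
  ctx3 <- rep(ctx, each = 3)
  alt3 <- as.vector(alt_m)
  channel <- canonical_channel(ctx3, alt3)
  score <- get_score(store, chrom, pos3, alt3)
  scored <- !is.na(score)
  n_unscored <- sum(!scored)
  if (!any(scored)) {
    stop("element ", element$element_id, " is entirely unscored; skipped")
  }
  df <- data.frame(chrom = chrom, pos = pos3[scored], ref = ref3[scored],
                   alt = alt3[scored], score = score[scored],
                   channel = channel[scored], stringsAsFactors = FALSE)
  if (!is.null(signature)) {
    w <- as.numeric(signature$probabilities[df$channel])
    tot <- sum(w)
    if (tot == 0) {
      stop("signature assigns zero probability to every substitution in ",
           element$element_id, "; signature/data mismatch")
    }
    df$prob <- w / tot
  } else {
    df$prob <- rep(1 / nrow(df), nrow(df))
  }
  attr(df, "element_id") <- element$element_id
  attr(df, "n_unscored") <- n_unscored
  attr(df, "n_context_na") <- n_context_na
  df
}
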
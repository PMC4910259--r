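# Genomic intervals and elements.  Intervals are plain data.frames with
# 0-based half-open coordinates; set operations are delegated to IRanges.

#' Construct an interval table
#'
#' @param chrom chromosome name(s).
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends (`end > start`).
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, sorted by
#'   (chrom, start, end).
#' @export
intervals <- function(chrom = character(), start = integer(),
                      end = integer(), strand = "*") {
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("interval end must exceed start")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

iv_to_iranges <- function(df) IRanges::IRanges(start = df$start + 1, end = df$end)

iranges_to_iv <- function(ir, chrom, strand = "*") {
  if (!length(ir)) return(empty_intervals())
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), strand = strand, stringsAsFactors = FALSE)
}

uniform_strand <- function(df) {
  s <- unique(df$strand)
  if (length(s) == 1L) s else "*"
}

#' Total length of an interval set
#' @param df interval data.frame.
#' @return numeric total of `end - start`.
#' @export
interval_length <- function(df) if (nrow(df)) sum(df$end - df$start) else 0

#' Merge intervals into a minimal disjoint sorted cover
#'
#' Overlapping and touching (`end == start`) intervals are merged.
#'
#' @param x interval data.frame (any number of chromosomes).
#' @return merged interval data.frame.
#' @export
merge_intervals <- function(x) {
  if (!nrow(x)) return(empty_intervals())
  strand <- uniform_strand(x)
  out <- lapply(split(x, x$chrom), function(d) {
    iranges_to_iv(IRanges::reduce(iv_to_iranges(d)), d$chrom[1], strand)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Subtract one interval set from another
#'
#' Computes the set difference `a \ b` as disjoint intervals; intervals fully
#' covered by `b` vanish.
#'
#' @param a,b interval data.frames.
#' @return interval data.frame covering `a` minus `b`.
#' @export
subtract_intervals <- function(a, b) {
  if (!nrow(a)) return(empty_intervals())
  if (!nrow(b)) return(merge_intervals(a))
  strand <- uniform_strand(a)
  out <- lapply(split(a, a$chrom), function(d) {
    cn <- d$chrom[1]
    bb <- b[b$chrom == cn, , drop = FALSE]
    ir <- IRanges::setdiff(iv_to_iranges(d), iv_to_iranges(bb))
    iranges_to_iv(ir, cn, strand)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Construct a genomic element
#'
#' An element is a named, typed set of disjoint segments on one chromosome and
#' strand, tested as a unit.
#'
#' @param element_id unique identifier.
#' @param symbol display name (gene symbol).
#' @param element_type one of `"cds"`, `"utr5"`, `"utr3"`, `"splice"`,
#'   `"promoter"`, `"lncrna"`.
#' @param chrom chromosome.
#' @param strand element strand.
#' @param segments interval data.frame (or matrix-like with `start`/`end`),
#'   0-based half-open; merged segments must be pairwise disjoint.
#' @return object of class `GenomicElement`.
#' @export
genomic_element <- function(element_id, symbol, element_type, chrom, strand,
                            segments) {
  types <- c("cds", "utr5", "utr3", "splice", "promoter", "lncrna")
  if (!element_type %in% types) {
    stop("element_type must be one of ", paste(types, collapse = ", "))
  }
  seg <- as.data.frame(segments)[, c("start", "end")]
  seg <- seg[order(seg$start, seg$end), , drop = FALSE]
  rownames(seg) <- NULL
  if (!nrow(seg)) stop("element must have at least one segment")
  if (any(seg$end <= seg$start)) stop("segment end must exceed start")
  if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
    stop("element segments must be disjoint")
  }
  structure(
    list(element_id = element_id, symbol = symbol, element_type = element_type,
         chrom = chrom, strand = strand, segments = seg),
    class = "GenomicElement"
  )
}

#' Total length of an element (bp)
#' @param element a `GenomicElement`.
#' @return numeric length.
#' @export
element_length <- function(element) {
  sum(element$segments$end - element$segments$start)
}

#' All 1-based positions covered by an element
#' @param element a `GenomicElement`.
#' @return integer vector of positions, ascending.
#' @export
element_positions <- function(element) {
  seg <- element$segments
  unlist(lapply(seq_len(nrow(seg)),
                function(i) seq.int(seg$start[i] + 1, seg$end[i])),
         use.names = FALSE)
}

#' @export
print.GenomicElement <- function(x, ...) {
  cat(sprintf("GenomicElement %s (%s, %s) %s%s: %d segment(s), %d bp\n",
              x$element_id, x$symbol, x$element_type, x$chrom,
              ifelse(x$strand == "*", "", x$strand),
              nrow(x$segments), element_length(x)))
  invisible(x)
}
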
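# Calibration and benchmarking utilities: QQ-plot data, truth-set fold
# enrichment, and needle-plot data export.  Rendering is out of scope; these
# produce tidy tables for any plotting layer.

#' Quantile-quantile data for a set of p-values
#'
#' Pairs the observed p-values (sorted ascending) with uniform expected
#' quantiles `i / (n + 1)`, both on the -log10 scale.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return data.frame with columns `expected` and `observed` (-log10 scale);
#'   `observed` is sorted descending as p ascends.
#' @export
qq_data <- function(p_values) {
  stopifnot(length(p_values) >= 1, all(p_values > 0 & p_values <= 1))
  n <- length(p_values)
  obs <- sort(p_values)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(obs))[order(seq_len(n)), , drop = FALSE]
}

#' Fold enrichment of a truth set among top-ranked elements
#'
#' For each `k`, the proportion of truth-set ids among the top `k` of the
#' ranking divided by their proportion in the full ranked list.
#'
#' @param ranked_ids character vector, best first.
#' @param truth_set character vector of known-positive ids.
#' @param top_k_grid integer vector of list sizes to evaluate.
#' @return data.frame with columns `k` and `fold` (0 when the truth set does
#'   not intersect the ranking).
#' @export
fold_enrichment <- function(ranked_ids, truth_set,
                            top_k_grid = unique(pmin(length(ranked_ids),
                                                     c(5, 10, 20, 50, 100)))) {
  stopifnot(length(ranked_ids) >= 1)
  truth_set <- unique(truth_set)
  background <- mean(ranked_ids %in% truth_set)
  fold <- vapply(top_k_grid, function(k) {
    if (background == 0) return(0)
    mean(ranked_ids[seq_len(min(k, length(ranked_ids)))] %in% truth_set) /
      background
  }, numeric(1))
  data.frame(k = top_k_grid, fold = fold)
}

#' Needle-plot data for one element
#'
#' Maps mutations and per-position maxima onto the concatenated coordinate of
#' the element's segments (segments joined in ascending genomic order, as in
#' lollipop plots of fragmented elements).
#'
#' @param element a `GenomicElement`.
#' @param mutations a `MutationSet`.
#' @param store a `ScoreStore`.
#' @return list of class `needle_data` with components:
#'   * `mutations`: one row per distinct observed (pos, alt) — `offset`
#'     (1-based concatenated coordinate), `pos`, `ref`, `alt`, `score`,
#'     `recurrence` (number of samples sharing the mutation), and
#'     `norm_score` (score normalised by the range of all possible scores in
#'     the element);
#'   * `positions`: per-base track — `offset`, `pos`, `max_score` (highest
#'     possible score at the position, NA when unscored);
#'   * `segments`: concatenated `start_offset`/`end_offset` per segment with
#'     the strand mark (`">"` for +, `"<"` for −).
#' @export
needle_data <- function(element, mutations, store) {
  seg <- element$segments
  seg_len <- seg$end - seg$start
  seg_off <- cumsum(c(0, seg_len[-length(seg_len)]))
  to_offset <- function(pos) {
    out <- rep(NA_real_, length(pos))
    for (i in seq_len(nrow(seg))) {
      sel <- pos > seg$start[i] & pos <= seg$end[i]
      out[sel] <- seg_off[i] + (pos[sel] - seg$start[i])
    }
    out
  }

  pos_all <- element_positions(element)
  tb <- store$table
  tb <- tb[tb$chrom == element$chrom & tb$pos %in% pos_all, , drop = FALSE]
  max_score <- rep(NA_real_, length(pos_all))
  if (nrow(tb)) {
    mx <- tapply(tb$score, tb$pos, max)
    m <- match(pos_all, as.integer(names(mx)))
    max_score <- as.numeric(mx)[m]
  }
  positions <- data.frame(offset = to_offset(pos_all), pos = pos_all,
                          max_score = max_score)

  obs <- observed_mean(element, mutations, store)$mutations
  if (nrow(obs)) {
    key <- paste(obs$pos, obs$alt)
    rec <- tapply(obs$sample_id, key, function(s) length(unique(s)))
    first <- obs[!duplicated(key), , drop = FALSE]
    first$recurrence <- as.integer(rec[paste(first$pos, first$alt)])
    rng <- range(tb$score)
    denom <- if (diff(rng) > 0) diff(rng) else 1
    muts <- data.frame(offset = to_offset(first$pos), pos = first$pos,
                       ref = first$ref, alt = first$alt, score = first$score,
                       recurrence = first$recurrence,
                       norm_score = (first$score - rng[1]) / denom)
    muts <- muts[order(muts$offset), , drop = FALSE]
    rownames(muts) <- NULL
  } else {
    muts <- data.frame(offset = numeric(), pos = integer(), ref = character(),
                       alt = character(), score = numeric(),
                       recurrence = integer(), norm_score = numeric())
  }
  segments <- data.frame(start_offset = seg_off + 1,
                         end_offset = seg_off + seg_len,
                         strand_mark = if (element$strand == "-") "<" else ">")
  structure(list(mutations = muts, positions = positions, segments = segments,
                 element_id = element$element_id),
            class = "needle_data")
}
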
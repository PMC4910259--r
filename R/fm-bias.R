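# The statistical core: observed mean functional impact, signature-weighted
# Monte-Carlo background, empirical p-values with adaptive resolution, and
# cohort-level Benjamini-Hochberg adjustment.

#' Configuration of the FM-bias test
#'
#' @param n_iterations number of background iterations N (default 10000,
#'   minimum 100).
#' @param max_iterations ceiling for adaptive p-resolution escalation: when no
#'   background mean reaches the observed mean, N is doubled up to this value
#'   (default 1e6).
#' @param seed master integer seed; per-element streams are derived from it
#'   with [derive_seed()] so results do not depend on element order.
#' @param sampling `"signature"` (cohort signature weighting), `"uniform"`, or
#'   `"per_sample"` (each observed mutation is resampled under the signature
#'   of the sample that contributed it).
#' @param min_samples minimum number of distinct mutated samples for an
#'   element to enter the BH adjustment (default 2; pan-cancer analyses use 5).
#' @param tie `"ge"` counts background means equal to the observed mean toward
#'   the exceedance (conservative default); `"gt"` uses a strict comparison.
#' @param pseudocount use `(count + 1) / (N + 1)` instead of `count / N`.
#' @param tail `"right"` tests for excess impact (positive selection);
#'   `"left"` computes the opposite tail (a negative-selection screen).
#' @return a list of class `fml_config`.
#' @export
fml_config <- function(n_iterations = 10000L, max_iterations = 1000000L,
                       seed = 1L, sampling = c("signature", "uniform",
                                               "per_sample"),
                       min_samples = 2L, tie = c("ge", "gt"),
                       pseudocount = FALSE, tail = c("right", "left")) {
  sampling <- match.arg(sampling)
  tie <- match.arg(tie)
  tail <- match.arg(tail)
  n_iterations <- as.integer(n_iterations)
  max_iterations <- as.integer(max_iterations)
  if (n_iterations < 100L) stop("n_iterations must be >= 100")
  if (max_iterations < n_iterations) stop("max_iterations must be >= n_iterations")
  structure(list(n_iterations = n_iterations, max_iterations = max_iterations,
                 seed = as.integer(seed), sampling = sampling,
                 min_samples = as.integer(min_samples), tie = tie,
                 pseudocount = pseudocount, tail = tail),
            class = "fml_config")
}

#' Observed mean functional impact of an element
#'
#' Arithmetic mean of the scores of all observed mutations falling in the
#' element's segments.  Recurrent mutations count once per occurrence;
#' mutations at unscored positions are dropped (and counted), symmetric with
#' their exclusion from the background pool.
#'
#' @param element a `GenomicElement`.
#' @param mutations a `MutationSet`.
#' @param store a `ScoreStore`.
#' @return list with `observed_mean`, `k` (scored mutation count),
#'   `n_samples` (distinct mutated samples among scored mutations),
#'   `n_unscored` (observed mutations dropped for lack of a score), and
#'   `mutations` (the scored observations with their scores).
#' @export
observed_mean <- function(element, mutations, store) {
  df <- mutations$mutations
  df <- df[df$chrom == element$chrom, , drop = FALSE]
  if (nrow(df)) {
    seg <- element$segments
    inside <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(seg))) {
      inside <- inside | (df$pos > seg$start[i] & df$pos <= seg$end[i])
    }
    df <- df[inside, , drop = FALSE]
  }
  if (!nrow(df)) {
    return(list(observed_mean = NA_real_, k = 0L, n_samples = 0L,
                n_unscored = 0L, mutations = df))
  }
  df$score <- get_score(store, df$chrom, df$pos, df$alt)
  scored <- !is.na(df$score)
  n_unscored <- sum(!scored)
  df <- df[scored, , drop = FALSE]
  if (!nrow(df)) {
    return(list(observed_mean = NA_real_, k = 0L, n_samples = 0L,
                n_unscored = n_unscored, mutations = df))
  }
  list(observed_mean = mean(df$score), k = nrow(df),
       n_samples = length(unique(df$sample_id)), n_unscored = n_unscored,
       mutations = df)
}

#' Sample a Monte-Carlo background of mean scores
#'
#' Draws `n_iterations` sets of `k` substitutions with replacement from a
#' score pool, each entry with its sampling probability, and records the mean
#' of each set.
#'
#' @param scores numeric vector of pool scores.
#' @param probs sampling probabilities (recycled uniform when `NULL`); must
#'   not be all zero.
#' @param k mutations drawn per iteration (>= 1).
#' @param n_iterations number of iterations.
#' @return numeric vector of `n_iterations` background means.
#' @export
sample_background <- function(scores, probs = NULL, k, n_iterations) {
  stopifnot(k >= 1, length(scores) >= 1)
  if (!is.null(probs)) {
    if (length(probs) != length(scores)) stop("probs/scores length mismatch")
    if (all(probs == 0)) {
      stop("all sampling probabilities are zero; signature/data mismatch")
    }
  }
  idx <- sample.int(length(scores), n_iterations * k, replace = TRUE,
                    prob = probs)
  if (k == 1L) return(scores[idx])
  .colMeans(scores[idx], k, n_iterations)
}

#' Empirical p-value of an observed mean against a background
#'
#' `p = #(background >= observed) / N` under the default tie convention
#' (background means equal to the observed mean count toward the exceedance).
#'
#' @param observed observed mean score.
#' @param background numeric vector of background means.
#' @param tie `"ge"` or `"gt"`.
#' @param pseudocount use `(count + 1) / (N + 1)`.
#' @param tail `"right"` or `"left"`.
#' @return the empirical p-value.
#' @export
empirical_p <- function(observed, background, tie = c("ge", "gt"),
                        pseudocount = FALSE, tail = c("right", "left")) {
  tie <- match.arg(tie)
  tail <- match.arg(tail)
  n <- length(background)
  stopifnot(n >= 1)
  count <- exceed_count(observed, background, tie, tail)
  if (pseudocount) (count + 1) / (n + 1) else count / n
}

# internal: number of background means at least as extreme as the observation
exceed_count <- function(observed, background, tie, tail) {
  if (tail == "right") {
    if (tie == "ge") sum(background >= observed) else sum(background > observed)
  } else {
    if (tie == "ge") sum(background <= observed) else sum(background < observed)
  }
}

#' Benjamini-Hochberg adjustment with a minimum-samples threshold
#'
#' Applies BH over the subset of elements mutated in at least `min_samples`
#' distinct samples; excluded elements keep their p-value but get `NA` q.
#'
#' @param results data.frame with columns `p_value` and `n_samples` (as
#'   produced by [run_fml()]).
#' @param min_samples eligibility threshold (2 for individual tumor types,
#'   5 for pan-cancer cohorts).
#' @return `results` with a `q_value` column.
#' @export
adjust_fdr <- function(results, min_samples = 2L) {
  results$q_value <- NA_real_
  eligible <- results$n_samples >= min_samples
  if (!any(eligible)) {
    if (nrow(results)) {
      warning("no element meets the minimum mutated-samples threshold; ",
              "all q-values missing")
    }
    return(results)
  }
  results$q_value[eligible] <- stats::p.adjust(results$p_value[eligible],
                                               method = "BH")
  results
}

#' Run the FM-bias test over a cohort
#'
#' Maps mutations to catalog elements (a mutation inside several elements is
#' tested in each), computes per-element observed means, simulates the
#' signature-weighted local background, derives empirical p-values (with
#' adaptive doubling of N while no background mean reaches the observation),
#' and adjusts eligible elements with Benjamini-Hochberg.  Deterministic given
#' `config$seed`, independently of element order.
#'
#' @param catalog an `ElementCatalog`.
#' @param mutations a validated `MutationSet`.
#' @param store a `ScoreStore`.
#' @param signature a `SignatureMatrix`, or a named list of per-sample
#'   matrices when `config$sampling == "per_sample"`.
#' @param genome an [fml_genome()].
#' @param config an [fml_config()].
#' @param score_cache optional environment used to memoise per-element score
#'   vectors across runs that share catalog, store, signature and genome.
#' @return data.frame of class `fml_result` with one row per tested element:
#'   `element_id`, `symbol`, `element_type`, `n_mutations`, `n_samples`,
#'   `observed_mean`, `p_value`, `q_value`, `n_iterations`, `p_censored`
#'   (TRUE when no background mean reached the observation at the escalation
#'   ceiling and the reported p is the upper bound `1/n_iterations`), sorted
#'   by p then element id.  Per-element skips are reported in
#'   `attr(, "skipped")`.
#' @export
run_fml <- function(catalog, mutations, store, signature, genome,
                    config = fml_config(), score_cache = NULL) {
  df <- mutations$mutations
  skipped <- character()
  cols <- c("element_id", "symbol", "element_type", "n_mutations", "n_samples",
            "observed_mean", "p_value", "q_value", "n_iterations", "p_censored")
  empty <- data.frame(element_id = character(), symbol = character(),
                      element_type = character(), n_mutations = integer(),
                      n_samples = integer(), observed_mean = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      n_iterations = integer(), p_censored = logical())
  if (!nrow(df) || !length(catalog$elements)) {
    class(empty) <- c("fml_result", "data.frame")
    return(empty)
  }
  mut_gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  ov <- GenomicRanges::findOverlaps(mut_gr, catalog$index)
  hit_ids <- unique(catalog$index$element_id[S4Vectors::subjectHits(ov)])
  hit_ids <- sort(hit_ids, method = "radix")   # locale-independent order
  if (!length(hit_ids)) {
    class(empty) <- c("fml_result", "data.frame")
    return(empty)
  }

  uniform_sig <- config$sampling == "uniform"
  per_sample <- config$sampling == "per_sample"
  if (per_sample && (!is.list(signature) || is.null(names(signature)))) {
    stop("per_sample sampling requires a named list of per-sample signatures")
  }

  rows <- vector("list", length(hit_ids))
  for (ii in seq_along(hit_ids)) {
    eid <- hit_ids[ii]
    el <- catalog$elements[[eid]]
    obs <- observed_mean(el, mutations, store)
    if (obs$k == 0L) {
      skipped <- c(skipped, paste0(eid, " [no scored observed mutations]"))
      next
    }
    # the cache holds the signature-independent enumeration (scores and
    # channels); sampling weights are attached per run below
    vec <- tryCatch({
      if (!is.null(score_cache) && !is.null(score_cache[[eid]])) {
        score_cache[[eid]]
      } else {
        v <- element_scores(store, el, NULL, genome)
        if (!is.null(score_cache)) score_cache[[eid]] <- v
        v
      }
    }, error = function(e) {
      skipped <<- c(skipped, paste0(eid, " [", conditionMessage(e), "]"))
      NULL
    })
    if (is.null(vec)) next
    if (!uniform_sig && !per_sample) {
      w <- as.numeric(signature$probabilities[vec$channel])
      if (sum(w) == 0) {
        skipped <- c(skipped, paste0(
          eid, " [signature assigns zero probability to every substitution]"))
        next
      }
      vec$prob <- w / sum(w)
    }

    set.seed(derive_seed(config$seed, eid))
    n_iter <- config$n_iterations
    repeat {
      means <- tryCatch(
        draw_background(vec, obs, config, signature, n_iter),
        error = function(e) {
          skipped <<- c(skipped, paste0(eid, " [", conditionMessage(e), "]"))
          NULL
        })
      if (is.null(means)) break
      count <- exceed_count(obs$observed_mean, means, config$tie, config$tail)
      if (count > 0L || n_iter >= config$max_iterations) break
      n_iter <- min(2L * n_iter, config$max_iterations)
    }
    if (is.null(means)) next
    censored <- count == 0L && !config$pseudocount
    p <- if (config$pseudocount) {
      (count + 1) / (n_iter + 1)
    } else if (censored) {
      1 / n_iter          # upper bound: true p < 1/n_iter at the ceiling
    } else {
      count / n_iter
    }
    rows[[ii]] <- data.frame(
      element_id = eid, symbol = el$symbol, element_type = el$element_type,
      n_mutations = obs$k, n_samples = obs$n_samples,
      observed_mean = obs$observed_mean, p_value = p, q_value = NA_real_,
      n_iterations = n_iter, p_censored = censored,
      stringsAsFactors = FALSE)
  }
  res <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  res <- as.data.frame(res)
  if (!nrow(res)) {
    class(empty) <- c("fml_result", "data.frame")
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  res <- res[order(res$p_value, res$element_id, method = "radix"), cols, drop = FALSE]
  rownames(res) <- NULL
  res <- adjust_fdr(res, config$min_samples)
  res <- res[order(res$p_value, res$element_id, method = "radix"), , drop = FALSE]
  class(res) <- c("fml_result", "data.frame")
  attr(res, "skipped") <- skipped
  res
}

# internal: one vector of background means for an element under the
# configured sampling mode
draw_background <- function(vec, obs, config, signature, n_iter) {
  if (config$sampling == "uniform") {
    return(sample_background(vec$score, NULL, obs$k, n_iter))
  }
  if (config$sampling == "signature") {
    return(sample_background(vec$score, vec$prob, obs$k, n_iter))
  }
  # per-sample: each observed mutation is resampled under the signature of
  # the sample that contributed it
  sam <- obs$mutations$sample_id
  total <- numeric(n_iter)
  for (s in unique(sam)) {
    ks <- sum(sam == s)
    sig_s <- signature[[s]]
    if (is.null(sig_s)) stop("no per-sample signature for sample ", s)
    w <- as.numeric(sig_s$probabilities[vec$channel])
    if (sum(w) == 0) {
      stop("signature of sample ", s, " assigns zero probability to every ",
           "substitution in the element")
    }
    idx <- sample.int(nrow(vec), n_iter * ks, replace = TRUE, prob = w)
    total <- total + if (ks == 1L) vec$score[idx] else
      .colSums(vec$score[idx], ks, n_iter)
  }
  total / length(sam)
}

#' Write FM-bias results as TSV
#'
#' Columns: ELEMENT_ID, SYMBOL, ELEMENT_TYPE, N_MUTATIONS, N_SAMPLES,
#' OBSERVED_MEAN, P_VALUE, Q_VALUE, N_ITERATIONS.
#'
#' @param results an `fml_result` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- data.frame(
    ELEMENT_ID = results$element_id, SYMBOL = results$symbol,
    ELEMENT_TYPE = results$element_type, N_MUTATIONS = results$n_mutations,
    N_SAMPLES = results$n_samples, OBSERVED_MEAN = results$observed_mean,
    P_VALUE = results$p_value, Q_VALUE = results$q_value,
    N_ITERATIONS = results$n_iterations)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
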
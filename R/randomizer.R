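# Negative-control generation: reposition each mutation within a 50-kb window
# while preserving per-sample counts and the 96-channel trinucleotide
# composition exactly.

#' Randomize a mutation dataset within local windows
#'
#' Each mutation is moved to a uniformly chosen position inside its window
#' whose reference trinucleotide matches the mutation's strand-collapsed
#' context (a site showing the reverse-complement context on the + strand is
#' eligible, with the alternate allele complemented), so the channel of every
#' mutation — and hence the cohort signature, count for count — is conserved.
#' Windows are fixed tiles of the chromosome (`floor((pos-1)/window)`) by
#' default, or ±`window/2` around the original position with
#' `centered = TRUE`.  Samples and per-sample mutation counts are unchanged;
#' the original position remains an eligible destination, and mutations
#' without a usable context (chromosome edges, ambiguous bases) keep their
#' position and are counted.
#'
#' @param mutations a validated `MutationSet` (reference alleles must match
#'   the genome).
#' @param genome an [fml_genome()].
#' @param window window length in bp (default 50000).
#' @param seed optional integer seed for reproducibility.
#' @param centered use windows centered on each mutation instead of fixed
#'   tiles.
#' @return a `MutationSet` with the same samples and per-sample counts;
#'   `attr(, "n_kept_in_place")` counts mutations left at their original
#'   position for lack of an eligible destination or context.
#' @export
randomize_dataset <- function(mutations, genome, window = 50000L,
                              seed = NULL, centered = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  df <- mutations$mutations
  n <- nrow(df)
  lens <- chrom_lengths(genome)
  new_pos <- df$pos
  new_ref <- df$ref
  new_alt <- df$alt
  n_kept <- 0L
  if (n) {
    ctx <- trinucleotide_context(genome, df$chrom, df$pos, strict = FALSE)
    ctx_ok <- !is.na(ctx) & all_acgt_string(ifelse(is.na(ctx), "N", ctx)) &
      is_acgt(df$alt)
    n_kept <- n_kept + sum(!ctx_ok)

    # canonical (pyrimidine-centered) representation of each mutation
    can_ctx <- ctx
    can_alt <- df$alt
    flip <- ctx_ok & substr(ctx, 2, 2) %in% c("A", "G")
    can_ctx[flip] <- revcomp3(ctx[flip])
    can_alt[flip] <- comp_base(df$alt[flip])

    idx_ok <- which(ctx_ok)
    if (length(idx_ok)) {
      tile <- (df$pos[idx_ok] - 1L) %/% window
      grp <- if (centered) seq_along(idx_ok) else
        paste(df$chrom[idx_ok], tile, can_ctx[idx_ok], sep = "|")
      # iterate groups in byte order so the random stream does not depend on
      # the collation locale
      grp <- factor(grp, levels = sort(unique(grp), method = "radix"))
      for (g in split(seq_along(idx_ok), grp)) {
        i0 <- idx_ok[g]
        cn <- df$chrom[i0[1]]
        if (centered) {
          wstart <- max(1L, df$pos[i0[1]] - as.integer(window / 2))
          wend <- min(lens[[cn]], df$pos[i0[1]] + as.integer(window / 2))
        } else {
          t0 <- tile[g[1]]
          wstart <- t0 * window + 1L
          wend <- min(lens[[cn]], (t0 + 1L) * window)
        }
        sites <- context_sites(genome, cn, wstart, wend, can_ctx[i0[1]])
        if (!nrow(sites)) {      # should not occur: the source site qualifies
          n_kept <- n_kept + length(i0)
          next
        }
        pick <- sites[sample.int(nrow(sites), length(i0), replace = TRUE), ,
                      drop = FALSE]
        new_pos[i0] <- pick$pos
        # forward-context sites keep the canonical alleles; reverse-complement
        # sites complement them back to the + strand
        pyr <- substr(can_ctx[i0[1]], 2, 2)
        new_ref[i0] <- ifelse(pick$fwd, pyr, comp_base(pyr))
        new_alt[i0] <- ifelse(pick$fwd, can_alt[i0], comp_base(can_alt[i0]))
      }
    }
  }
  out <- df
  out$pos <- as.integer(new_pos)
  out$ref <- new_ref
  out$alt <- new_alt
  ms <- mutation_set(out, paste0(mutations$provenance, " [randomized]"))
  attr(ms, "n_kept_in_place") <- n_kept
  ms
}

# internal: all positions in [wstart, wend] whose + strand trinucleotide is
# `ctx` (fwd = TRUE) or its reverse complement (fwd = FALSE)
context_sites <- function(genome, chrom, wstart, wend, ctx) {
  len <- chrom_lengths(genome)[[chrom]]
  lo <- max(1L, wstart - 1L)
  hi <- min(len, wend + 1L)
  sub <- Biostrings::DNAString(genome_seq(genome, chrom, lo, hi))
  hits <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), sub)
    # genomic position of the match center
    lo - 1L + IRanges::start(m) + 1L
  }
  p_fwd <- hits(ctx)
  p_rev <- hits(revcomp3(ctx))
  keep <- function(p) p[p >= wstart & p <= wend]
  p_fwd <- keep(p_fwd)
  p_rev <- keep(p_rev)
  data.frame(pos = c(p_fwd, p_rev),
             fwd = rep(c(TRUE, FALSE), c(length(p_fwd), length(p_rev))))
}
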
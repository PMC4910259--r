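# Synthetic data generator: toy genomes, Gencode-style annotations,
# per-substitution score tables and tumor cohorts (null and driver-injected)
# with the statistical structure the FM-bias test assumes, so every module is
# testable offline.

#' Default generating mutational signature (UV-like)
#'
#' A concentrated, biologically motivated spectrum emulating a UV-exposed
#' (melanoma-like) cohort: C>T channels carry ~88% of the mass, C>A ~9%, and
#' the remaining channels share the rest.  Concentrated spectra are the
#' realistic regime for signature-aware sampling (real cohorts are dominated
#' by a few mutational processes).
#'
#' @return a `SignatureMatrix` with mode `"precomputed"`.
#' @export
default_signature <- function() {
  ch <- channel_names()
  w <- rep(0.2, 96)
  w[grepl("C>T", ch, fixed = TRUE)] <- 20
  w[grepl("C>A", ch, fixed = TRUE)] <- 2
  signature_matrix(stats::setNames(w / sum(w), ch), mode = "precomputed")
}

#' Specification of a synthetic dataset
#'
#' Defaults describe the package's standard toy scale: one 2-Mb chromosome,
#' ~200 genomic elements (39 protein-coding genes contributing CDS, UTRs,
#' splice flanks and promoters, plus 5 lincRNA genes), 50 samples with ~40
#' mutations each, a UV-like generating signature, and CADD-like scores
#' (exponential-tailed, one decimal).
#'
#' @param seed master seed; the whole dataset is deterministic given it.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param gc GC content of the random genome (default 0.41, human-like).
#' @param n_genes number of protein-coding genes.
#' @param n_lncrna number of lincRNA genes.
#' @param exon_range,intron_range ranges (bp) for exon and intron lengths.
#' @param exons_range range of exon counts per gene.
#' @param utr5_range,utr3_range ranges (bp) for UTR lengths.
#' @param n_samples cohort size.
#' @param muts_per_sample mean somatic SNVs per sample (Poisson).
#' @param signature generating `SignatureMatrix` (the realized cohort
#'   spectrum).
#' @param score_scale scale of the exponential base-score distribution
#'   (score units; default 3).
#' @param score_jitter sd of the alt-specific Gaussian jitter.
#' @param score_digits scores are rounded to this many decimals (1 mirrors
#'   PHRED-like tables and creates realistic ties).
#' @param n_drivers number of driver elements to inject (0 for a pure null
#'   cohort).
#' @param driver_ids explicit driver element ids; when `NULL` the first
#'   `n_drivers` CDS elements (by id order) are used.
#' @param driver_samples number of samples receiving one driver mutation each.
#' @param driver_fraction fraction of driver mutations redirected to hotspot
#'   (pos, alt) entries (default 0.8).
#' @param n_hotspots hotspot entries per driver element.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           chrom_lengths = c(chr1 = 2000000L),
                           gc = 0.41,
                           n_genes = 39L, n_lncrna = 5L,
                           exons_range = c(2L, 4L),
                           exon_range = c(200L, 600L),
                           intron_range = c(300L, 2000L),
                           utr5_range = c(60L, 150L),
                           utr3_range = c(150L, 300L),
                           n_samples = 50L, muts_per_sample = 40,
                           signature = default_signature(),
                           score_scale = 3, score_jitter = 0.5,
                           score_digits = 1L,
                           n_drivers = 0L, driver_ids = NULL,
                           driver_samples = 12L, driver_fraction = 0.8,
                           n_hotspots = 5L) {
  stopifnot(all(chrom_lengths > 3), gc > 0, gc < 1,
            driver_fraction >= 0, driver_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a random reference genome
#'
#' @param spec a [synthetic_spec()].
#' @return an [fml_genome()]; deterministic given `spec$seed`.
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  g <- spec$gc
  p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  seqs <- vapply(spec$chrom_lengths, function(len) {
    paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  fml_genome(seqs)
}

#' Generate a Gencode-style annotation for the synthetic genome
#'
#' Places protein-coding genes (exons, CDS, UTRs) and lincRNA genes on evenly
#' spaced slots along each chromosome, leaving room for 2500-bp promoter
#' windows.  Returns a GTF-like data.frame consumable by [write_gtf()] and
#' [build_catalog()].
#'
#' @param spec a [synthetic_spec()].
#' @param genome the matching [generate_genome()] output.
#' @return data.frame with GTF columns (`seqnames`, `start`, `end`, `strand`,
#'   `type`) and Gencode attributes (`gene_id`, `transcript_id`, `gene_type`,
#'   `transcript_type`, `gene_name`).
#' @export
generate_annotation <- function(spec, genome) {
  set.seed(spec$seed + 1L)
  rows <- list()
  emit <- function(chrom, start, end, strand, type, gid, tid, btype, gname) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqnames = chrom, start = start, end = end, strand = strand, type = type,
      gene_id = gid, transcript_id = tid, gene_type = btype,
      transcript_type = btype, gene_name = gname, stringsAsFactors = FALSE)
  }
  rint <- function(range) if (range[1] >= range[2]) range[1] else
    sample(seq.int(range[1], range[2]), 1L)

  gi <- 0L
  for (cn in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cn]]
    n_tot <- spec$n_genes + spec$n_lncrna
    slot <- (len - 20000L) %/% max(1L, n_tot)
    kinds <- rep(c("protein_coding", "lincRNA"),
                 c(spec$n_genes, spec$n_lncrna))
    for (j in seq_len(n_tot)) {
      gi <- gi + 1L
      kind <- kinds[j]
      gid <- sprintf("GENE%03d", gi)
      tid <- sprintf("TX%03d", gi)
      gname <- sprintf("G%03d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- rint(spec$exons_range)
      ex_len <- vapply(seq_len(n_ex), function(i) rint(spec$exon_range), 1L)
      in_len <- if (n_ex > 1)
        vapply(seq_len(n_ex - 1), function(i) rint(spec$intron_range), 1L)
      else integer(0)
      slot_start <- 10000L + (j - 1L) * slot
      gstart <- slot_start + 3000L           # leaves promoter room upstream
      # genomic exon coordinates (1-based, ascending)
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      cur <- gstart
      for (i in seq_len(n_ex)) {
        ex_start[i] <- cur
        ex_end[i] <- cur + ex_len[i] - 1L
        cur <- ex_end[i] + (if (i < n_ex) in_len[i] else 0L) + 1L
      }
      gend <- ex_end[n_ex]
      emit(cn, gstart, gend, strand, "gene", gid, NA, kind, gname)
      emit(cn, gstart, gend, strand, "transcript", gid, tid, kind, gname)
      for (i in seq_len(n_ex)) {
        emit(cn, ex_start[i], ex_end[i], strand, "exon", gid, tid, kind, gname)
      }
      if (kind == "protein_coding") {
        # split the mature transcript into UTR5 / CDS / UTR3
        tlen <- sum(ex_len)
        u5 <- rint(spec$utr5_range)
        u3 <- rint(spec$utr3_range)
        if (tlen - u5 - u3 < 90L) { u5 <- 30L; u3 <- 60L }
        # transcript coordinate of each exon in 5'->3' order
        ord <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
        tx_hi <- cumsum(ex_len[ord])
        tx_lo <- tx_hi - ex_len[ord] + 1L
        feats <- rbind(c(1L, u5, 1L), c(u5 + 1L, tlen - u3, 2L),
                       c(tlen - u3 + 1L, tlen, 3L))
        fnames <- c("UTR", "CDS", "UTR")
        for (f in seq_len(3L)) {
          lo <- feats[f, 1]; hi <- feats[f, 2]
          for (e in seq_len(n_ex)) {
            a <- max(lo, tx_lo[e]); b <- min(hi, tx_hi[e])
            if (a > b) next
            i <- ord[e]
            if (strand == "-") {
              gs <- ex_end[i] - (b - tx_lo[e])
              ge <- ex_end[i] - (a - tx_lo[e])
            } else {
              gs <- ex_start[i] + (a - tx_lo[e])
              ge <- ex_start[i] + (b - tx_lo[e])
            }
            emit(cn, gs, ge, strand, fnames[f], gid, tid, kind, gname)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a GTF-like annotation data.frame to a GTF file
#'
#' @param anno data.frame as produced by [generate_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(anno, path) {
  attrs <- sprintf(
    'gene_id "%s"; %sgene_type "%s"; transcript_type "%s"; gene_name "%s";',
    anno$gene_id,
    ifelse(is.na(anno$transcript_id), "",
           sprintf('transcript_id "%s"; ', anno$transcript_id)),
    anno$gene_type, anno$transcript_type, anno$gene_name)
  lines <- paste(anno$seqnames, "synth", anno$type, anno$start, anno$end, ".",
                 anno$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# internal: resolve driver element ids for a spec/catalog pair
resolve_driver_ids <- function(spec, catalog) {
  if (!is.null(spec$driver_ids)) return(spec$driver_ids)
  if (spec$n_drivers == 0L) return(character(0))
  cds <- sort(names(catalog$elements)[
    vapply(catalog$elements, `[[`, "", "element_type") == "cds"],
    method = "radix")
  head(cds, spec$n_drivers)
}

#' Generate a per-substitution score table for a catalog
#'
#' Scores every (position, alt) pair of every element: a per-position
#' exponential base score (scale `spec$score_scale`) plus alt-specific
#' Gaussian jitter, clipped at zero and rounded to `spec$score_digits`
#' decimals (CADD-PHRED-like).  Hotspot entries of driver elements are set
#' above the element maximum, so they exceed the element's 99th percentile by
#' construction.
#'
#' @param spec a [synthetic_spec()].
#' @param genome the synthetic genome.
#' @param catalog the element catalog built from the synthetic annotation.
#' @return a `ScoreStore`; `attr(, "hotspots")` holds the hotspot entries
#'   (`element_id`, `chrom`, `pos`, `ref`, `alt`, `score`).
#' @export
generate_scores <- function(spec, genome, catalog) {
  set.seed(spec$seed + 2L)
  parts <- lapply(catalog$elements, function(e) {
    data.frame(chrom = e$chrom, pos = element_positions(e),
               stringsAsFactors = FALSE)
  })
  tab <- unique(do.call(rbind, parts))
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  tab$ref <- genome_base(genome, tab$chrom, tab$pos)
  keep <- is_acgt(tab$ref)
  tab <- tab[keep, , drop = FALSE]
  n <- nrow(tab)
  base <- stats::rexp(n, rate = 1 / spec$score_scale)
  alt_m <- matrix("", nrow = 3, ncol = n)
  for (b in BASES) {
    sel <- tab$ref == b
    if (any(sel)) alt_m[, sel] <- setdiff(BASES, b)
  }
  df <- data.frame(chrom = rep(tab$chrom, each = 3),
                   pos = rep(tab$pos, each = 3),
                   ref = rep(tab$ref, each = 3),
                   alt = as.vector(alt_m),
                   stringsAsFactors = FALSE)
  df$score <- round(pmax(0, rep(base, each = 3) +
                           stats::rnorm(3 * n, 0, spec$score_jitter)),
                    spec$score_digits)

  hotspots <- NULL
  drivers <- resolve_driver_ids(spec, catalog)
  if (length(drivers)) {
    key <- paste(df$chrom, df$pos, df$alt, sep = ":")
    hs <- list()
    for (d in drivers) {
      e <- catalog$elements[[d]]
      pos_e <- element_positions(e)
      in_e <- df$chrom == e$chrom & df$pos %in% pos_e
      hp <- sample(pos_e[is_acgt(genome_base(genome, e$chrom, pos_e))],
                   min(spec$n_hotspots, length(pos_e)))
      hi <- round(max(df$score[in_e]) + 5, spec$score_digits)
      for (p in hp) {
        ref <- genome_base(genome, e$chrom, p)
        alt <- sample(setdiff(BASES, ref), 1L)
        i <- match(paste(e$chrom, p, alt, sep = ":"), key)
        df$score[i] <- hi
        hs[[length(hs) + 1L]] <- data.frame(
          element_id = d, chrom = e$chrom, pos = p, ref = ref, alt = alt,
          score = hi, stringsAsFactors = FALSE)
      }
    }
    hotspots <- do.call(rbind, hs)
  }
  store <- score_store(df, provider = "synthetic")
  attr(store, "hotspots") <- hotspots
  store
}

#' Generate a synthetic tumor cohort
#'
#' Null mutations are generated per sample by first drawing the trinucleotide
#' channel from the generating signature and then a site uniformly among the
#' catalog's candidate substitutions of that channel, so the requested
#' signature is the realized mutation spectrum.  When drivers are configured,
#' the first `driver_samples` samples each receive one additional driver
#' mutation, redirected to a hotspot entry with probability
#' `driver_fraction` and otherwise drawn from the driver element's own
#' background.
#'
#' @param spec a [synthetic_spec()].
#' @param genome,catalog,store the matching synthetic genome, catalog and
#'   score store.
#' @param seed optional override of the cohort seed (defaults to
#'   `spec$seed + 3`), allowing repeated cohorts on one fixed
#'   genome/catalog/score backbone.
#' @return a validated `MutationSet` (zero QC drops by construction);
#'   `attr(, "truth")` lists the injected driver element ids.
#' @export
generate_cohort <- function(spec, genome, catalog, store, seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed + 3L else as.integer(seed))
  pool <- build_candidate_pool(store, catalog, genome)
  sigp <- spec$signature$probabilities
  avail <- intersect(names(sigp)[sigp > 0], unique(pool$channel))
  if (!length(avail)) stop("no candidate site matches the generating signature")
  pa <- sigp[avail] / sum(sigp[avail])

  m_i <- stats::rpois(spec$n_samples, spec$muts_per_sample)
  sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
  total <- sum(m_i)
  ch_draw <- sample(avail, total, replace = TRUE, prob = pa)
  row_idx <- integer(total)
  for (c0 in unique(ch_draw)) {
    sel <- which(ch_draw == c0)
    rows <- which(pool$channel == c0)
    row_idx[sel] <- rows[sample.int(length(rows), length(sel), replace = TRUE)]
  }
  df <- data.frame(sample_id = rep(sample_ids, m_i),
                   chrom = pool$chrom[row_idx], pos = pool$pos[row_idx],
                   ref = pool$ref[row_idx], alt = pool$alt[row_idx],
                   stringsAsFactors = FALSE)

  drivers <- resolve_driver_ids(spec, catalog)
  if (length(drivers)) {
    hs <- attr(store, "hotspots")
    ds <- head(sample_ids, spec$driver_samples)
    extra <- list()
    for (d in drivers) {
      el <- catalog$elements[[d]]
      vec <- element_scores(store, el, spec$signature, genome)
      hsd <- hs[hs$element_id == d, , drop = FALSE]
      for (s in ds) {
        if (nrow(hsd) && stats::runif(1) < spec$driver_fraction) {
          i <- sample.int(nrow(hsd), 1L)
          extra[[length(extra) + 1L]] <- data.frame(
            sample_id = s, chrom = hsd$chrom[i], pos = hsd$pos[i],
            ref = hsd$ref[i], alt = hsd$alt[i], stringsAsFactors = FALSE)
        } else {
          i <- sample.int(nrow(vec), 1L, prob = vec$prob)
          extra[[length(extra) + 1L]] <- data.frame(
            sample_id = s, chrom = vec$chrom[i], pos = vec$pos[i],
            ref = vec$ref[i], alt = vec$alt[i], stringsAsFactors = FALSE)
        }
      }
    }
    df <- rbind(df, do.call(rbind, extra))
  }
  ms <- validate_mutations(df, genome, provenance = "synthetic-cohort")
  attr(ms, "truth") <- drivers
  ms
}

# internal: pooled candidate substitutions over all catalog elements,
# deduplicated by (chrom, pos, alt)
build_candidate_pool <- function(store, catalog, genome) {
  parts <- lapply(catalog$elements, function(e) {
    element_scores(store, e, NULL, genome)[, c("chrom", "pos", "ref", "alt",
                                               "channel")]
  })
  pool <- as.data.frame(data.table::rbindlist(parts))
  pool[!duplicated(paste(pool$chrom, pool$pos, pool$alt, sep = ":")), ,
       drop = FALSE]
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates genome, annotation, catalog, score table and cohort; when
#' `dir` is given, also writes FASTA, GTF, element TSV, score TSV, mutation
#' TSV and a truth manifest.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory.
#' @return list with `spec`, `genome`, `annotation`, `catalog`, `store`,
#'   `cohort` and `truth` (driver element ids).
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  genome <- generate_genome(spec)
  anno <- generate_annotation(spec, genome)
  catalog <- build_catalog(anno, genome)
  store <- generate_scores(spec, genome, catalog)
  cohort <- generate_cohort(spec, genome, catalog, store)
  out <- list(spec = spec, genome = genome, annotation = anno,
              catalog = catalog, store = store, cohort = cohort,
              truth = attr(cohort, "truth"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(dir, "genome.fa"))
    write_gtf(anno, file.path(dir, "annotation.gtf"))
    write_catalog(catalog, file.path(dir, "elements.tsv"))
    write_scores(store, file.path(dir, "scores.tsv"))
    write_mutations(cohort, file.path(dir, "mutations.tsv"))
    writeLines(out$truth, file.path(dir, "truth.txt"))
  }
  out
}
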
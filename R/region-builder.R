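# Element catalog construction from GTF annotation, applying the subtraction
# and merging rules for CDS, UTRs, intronic splice flanks, promoters and
# lncRNA exons.

#' Build splice regions from intron coordinates
#'
#' Takes the first and last `flank` bp of each intron; introns not longer than
#' `2 * flank` contribute whole (the two flanks are merged, never counted
#' twice).
#'
#' @param introns interval data.frame of introns.
#' @param flank flank length in bp (> 0); 50 for elements under test, 10 for
#'   the short splice regions used in subtraction.
#' @return merged interval data.frame of splice regions.
#' @export
build_splice_regions <- function(introns, flank) {
  stopifnot(flank > 0)
  if (!nrow(introns)) return(empty_intervals())
  len <- introns$end - introns$start
  whole <- len <= 2 * flank
  parts <- list(introns[whole, , drop = FALSE])
  rest <- introns[!whole, , drop = FALSE]
  if (nrow(rest)) {
    left <- rest; left$end <- rest$start + flank
    right <- rest; right$start <- rest$end - flank
    parts <- c(parts, list(left, right))
  }
  merge_intervals(do.call(rbind, parts))
}

#' Build promoter windows upstream of transcription start sites
#'
#' For a + strand TSS at 1-based position `t` the window is the 0-based
#' interval `[t - 1 - upstream, t - 1)`; for a − strand TSS it is
#' `[t, t + upstream)`.  Windows are clipped at chromosome bounds.
#'
#' @param tss data.frame with columns `chrom`, `tss` (1-based), `strand`.
#' @param upstream window size in bp (default 2500).
#' @param chrom_lengths named vector of chromosome lengths (for clipping);
#'   a TSS beyond the chromosome end is an error.
#' @return interval data.frame, one row per TSS with a non-empty window.
#' @export
build_promoters <- function(tss, upstream = 2500, chrom_lengths = NULL) {
  stopifnot(upstream > 0)
  if (!nrow(tss)) return(empty_intervals())
  if (!is.null(chrom_lengths)) {
    if (any(tss$tss > chrom_lengths[tss$chrom] | tss$tss < 1)) {
      stop("TSS outside chromosome bounds")
    }
  }
  plus <- tss$strand != "-"
  start <- ifelse(plus, pmax(0, tss$tss - 1 - upstream), tss$tss)
  end <- ifelse(plus, tss$tss - 1, tss$tss + upstream)
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[tss$chrom])
  keep <- end > start
  if (!any(keep)) return(empty_intervals())
  intervals(tss$chrom[keep], start[keep], end[keep], tss$strand[keep])
}

# internal: read a Gencode-dialect GTF into a plain data.frame
read_gtf_df <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  norm <- function(x) if (is.null(x)) NULL else gsub("-", "_", as.character(x))
  # tolerate both Gencode (gene_type) and Ensembl (gene_biotype) attributes
  df$gene_type <- norm(df$gene_type) %||% norm(df$gene_biotype) %||%
    rep(NA_character_, nrow(df))
  df$transcript_type <- norm(df$transcript_type) %||%
    norm(df$transcript_biotype) %||% rep(NA_character_, nrow(df))
  if (is.null(df$gene_name)) df$gene_name <- df$gene_id
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: intervals (0-based) for a feature subset of a GTF data.frame
gtf_iv <- function(df) {
  if (!nrow(df)) return(empty_intervals())
  intervals(df$seqnames, df$start - 1, df$end, df$strand)
}

# internal: introns of one transcript given its exon rows
transcript_introns <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) < 2) return(empty_intervals())
  intervals(ex$seqnames[-1], ex$end[-nrow(ex)], ex$start[-1] - 1, ex$strand[1])
}

#' Build the element catalog from a GTF annotation
#'
#' Produces, per gene: merged CDS of protein-coding gene+transcript biotypes;
#' splice regions (intron edges, `splice_flank` bp); 5' and 3' UTRs minus all
#' CDS anywhere in the genome and minus short (`short_splice` bp) intronic
#' splice regions, with 5' UTRs additionally losing any 3' UTR overlap;
#' promoters (`promoter_upstream` bp upstream of the most 5' protein-coding
#' TSS of the gene) minus CDS, UTRs and short splice regions; and lncRNA
#' elements from merged exons of lincRNA biotype genes minus CDS, UTRs and
#' short splice regions.  Subtraction is global: any gene's CDS masks any
#' other gene's promoter or UTR.
#'
#' @param gtf path to a GTF file (Gencode dialect) or an object accepted by
#'   `rtracklayer::import`.
#' @param genome an [fml_genome()]; used for chromosome bounds.
#' @param types character vector of element types to build.
#' @param splice_flank flank of splice elements under test (default 50).
#' @param short_splice flank of the short splice regions used in subtraction
#'   (default 10).
#' @param promoter_upstream promoter window (default 2500).
#' @param blacklist optional character vector (or file of one id per line) of
#'   element ids or gene ids to discard, standing in for the manual removal of
#'   suspect annotations.
#' @return an `ElementCatalog`; elements that lose all their bases to
#'   subtraction are omitted and listed in `attr(, "dropped")`.
#' @export
build_catalog <- function(gtf, genome,
                          types = c("cds", "utr5", "utr3", "splice",
                                    "promoter", "lncrna"),
                          splice_flank = 50, short_splice = 10,
                          promoter_upstream = 2500, blacklist = NULL) {
  df <- if (is.data.frame(gtf)) gtf else read_gtf_df(gtf)
  lens <- chrom_lengths(genome)
  if (!is.null(blacklist) && length(blacklist) == 1 && file.exists(blacklist)) {
    blacklist <- readLines(blacklist)
  }

  pc <- !is.na(df$gene_type) & df$gene_type == "protein_coding" &
    !is.na(df$transcript_type) & df$transcript_type == "protein_coding"
  cds_rows <- df[df$type == "CDS" & pc, , drop = FALSE]
  exon_pc <- df[df$type == "exon" & pc, , drop = FALSE]

  # per-gene merged CDS and global CDS mask
  cds_by_gene <- lapply(split(cds_rows, cds_rows$gene_id),
                        function(d) merge_intervals(gtf_iv(d)))
  cds_global <- merge_intervals(gtf_iv(cds_rows))

  # introns of protein-coding transcripts
  introns <- do.call(rbind, c(list(empty_intervals()),
    lapply(split(exon_pc, exon_pc$transcript_id), transcript_introns)))
  intron_gene <- do.call(rbind, c(list(empty_intervals()[0, ]),
    lapply(split(exon_pc, exon_pc$gene_id), function(d) {
      iv <- do.call(rbind, c(list(empty_intervals()),
        lapply(split(d, d$transcript_id), transcript_introns)))
      if (nrow(iv)) iv$gene_id <- d$gene_id[1]
      iv
    })))
  splice_short_global <- build_splice_regions(introns, short_splice)

  # UTR rows, classified 5'/3' by position relative to the transcript CDS
  utr_rows <- df[df$type %in% c("UTR", "five_prime_utr", "three_prime_utr") & pc,
                 , drop = FALSE]
  side <- character(nrow(utr_rows))
  side[utr_rows$type == "five_prime_utr"] <- "utr5"
  side[utr_rows$type == "three_prime_utr"] <- "utr3"
  todo <- which(side == "")
  if (length(todo)) {
    cds_span <- do.call(rbind, lapply(split(cds_rows, cds_rows$transcript_id),
      function(d) data.frame(transcript_id = d$transcript_id[1],
                             lo = min(d$start), hi = max(d$end))))
    m <- match(utr_rows$transcript_id[todo], cds_span$transcript_id)
    lo <- cds_span$lo[m]; hi <- cds_span$hi[m]
    five <- ifelse(utr_rows$strand[todo] == "-",
                   utr_rows$start[todo] >= hi, utr_rows$end[todo] <= lo)
    side[todo] <- ifelse(is.na(five), NA, ifelse(five, "utr5", "utr3"))
  }
  utr5_rows <- utr_rows[!is.na(side) & side == "utr5", , drop = FALSE]
  utr3_rows <- utr_rows[!is.na(side) & side == "utr3", , drop = FALSE]
  utr5_global <- merge_intervals(gtf_iv(utr5_rows))
  utr3_global <- merge_intervals(gtf_iv(utr3_rows))
  utr_global <- merge_intervals(rbind(utr5_global, utr3_global))

  gene_meta <- df[df$type == "gene", c("gene_id", "gene_name", "seqnames",
                                       "strand"), drop = FALSE]
  gene_meta <- gene_meta[!duplicated(gene_meta$gene_id), , drop = FALSE]
  meta_of <- function(gid) gene_meta[match(gid, gene_meta$gene_id), ]

  elements <- list()
  dropped <- character()
  add_element <- function(gid, type, iv) {
    id <- paste0(gid, ":", type)
    if (!is.null(blacklist) && (id %in% blacklist || gid %in% blacklist)) {
      dropped <<- c(dropped, paste0(id, " [blacklisted]"))
      return(invisible())
    }
    if (!nrow(iv)) {
      dropped <<- c(dropped, paste0(id, " [no bases left after subtraction]"))
      return(invisible())
    }
    mm <- meta_of(gid)
    sym <- if (!is.na(mm$gene_name[1])) mm$gene_name[1] else gid
    strand <- if (!is.na(mm$strand[1])) mm$strand[1] else uniform_strand(iv)
    elements[[id]] <<- genomic_element(id, sym, type, iv$chrom[1], strand, iv)
  }

  if ("cds" %in% types) {
    for (gid in names(cds_by_gene)) add_element(gid, "cds", cds_by_gene[[gid]])
  }

  if ("splice" %in% types && nrow(intron_gene)) {
    for (gid in unique(intron_gene$gene_id)) {
      iv <- build_splice_regions(
        intron_gene[intron_gene$gene_id == gid, 1:4, drop = FALSE], splice_flank)
      add_element(gid, "splice", iv)
    }
  }

  if ("utr3" %in% types && nrow(utr3_rows)) {
    for (gid in unique(utr3_rows$gene_id)) {
      iv <- merge_intervals(gtf_iv(utr3_rows[utr3_rows$gene_id == gid, ]))
      iv <- subtract_intervals(iv, cds_global)
      iv <- subtract_intervals(iv, splice_short_global)
      add_element(gid, "utr3", iv)
    }
  }

  if ("utr5" %in% types && nrow(utr5_rows)) {
    for (gid in unique(utr5_rows$gene_id)) {
      iv <- merge_intervals(gtf_iv(utr5_rows[utr5_rows$gene_id == gid, ]))
      iv <- subtract_intervals(iv, cds_global)
      iv <- subtract_intervals(iv, splice_short_global)
      iv <- subtract_intervals(iv, utr3_global)
      add_element(gid, "utr5", iv)
    }
  }

  if ("promoter" %in% types) {
    # TSS per gene: most 5' start among its protein-coding transcripts
    tx <- df[df$type == "transcript" & pc, , drop = FALSE]
    if (!nrow(tx)) tx <- exon_pc
    if (nrow(tx)) {
      tss_list <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d) {
        minus <- d$strand[1] == "-"
        data.frame(gene_id = d$gene_id[1], chrom = d$seqnames[1],
                   tss = if (minus) max(d$end) else min(d$start),
                   strand = d$strand[1], stringsAsFactors = FALSE)
      }))
      for (i in seq_len(nrow(tss_list))) {
        iv <- build_promoters(tss_list[i, ], promoter_upstream, lens)
        iv <- subtract_intervals(iv, cds_global)
        iv <- subtract_intervals(iv, utr_global)
        iv <- subtract_intervals(iv, splice_short_global)
        add_element(tss_list$gene_id[i], "promoter", iv)
      }
    }
  }

  if ("lncrna" %in% types) {
    linc <- !is.na(df$gene_type) & df$gene_type == "lincRNA" &
      !is.na(df$transcript_type) & df$transcript_type == "lincRNA"
    linc_ex <- df[df$type == "exon" & linc, , drop = FALSE]
    for (gid in unique(linc_ex$gene_id)) {
      iv <- merge_intervals(gtf_iv(linc_ex[linc_ex$gene_id == gid, ]))
      iv <- subtract_intervals(iv, cds_global)
      iv <- subtract_intervals(iv, utr_global)
      iv <- subtract_intervals(iv, splice_short_global)
      add_element(gid, "lncrna", iv)
    }
  }

  cat <- element_catalog(elements)
  attr(cat, "dropped") <- dropped
  cat
}

#' Assemble an element catalog with a positional index
#'
#' @param elements named list of [genomic_element()] objects.
#' @return object of class `ElementCatalog` with fields `elements` and
#'   `index` (a `GRanges` mapping segments to element ids).
#' @export
element_catalog <- function(elements) {
  stopifnot(is.list(elements))
  ids <- vapply(elements, `[[`, "", "element_id")
  if (anyDuplicated(ids)) stop("duplicate element ids")
  names(elements) <- ids
  if (length(elements)) {
    seg <- do.call(rbind, lapply(elements, function(e) {
      data.frame(chrom = e$chrom, start = e$segments$start, end = e$segments$end,
                 element_id = e$element_id, stringsAsFactors = FALSE)
    }))
    idx <- GenomicRanges::GRanges(
      seqnames = seg$chrom,
      ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end),
      element_id = seg$element_id)
  } else {
    idx <- GenomicRanges::GRanges()
  }
  structure(list(elements = elements, index = idx), class = "ElementCatalog")
}

#' @export
print.ElementCatalog <- function(x, ...) {
  tt <- table(vapply(x$elements, `[[`, "", "element_type"))
  cat("ElementCatalog:", length(x$elements), "elements (",
      paste(names(tt), tt, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' Element ids covering a genomic position
#'
#' @param catalog an `ElementCatalog`.
#' @param chrom chromosome.
#' @param pos 1-based position(s).
#' @return for a single position, a character vector of element ids; for
#'   several, a list of such vectors.
#' @export
elements_at <- function(catalog, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(q, catalog$index)
  ids <- split(catalog$index$element_id[S4Vectors::subjectHits(ov)],
               factor(S4Vectors::queryHits(ov), levels = seq_along(pos)))
  ids <- lapply(ids, unique)
  if (length(pos) == 1L) ids[[1]] else unname(ids)
}

#' Write an element catalog as BED-like TSV
#'
#' Columns: CHROM, START (0-based), END, STRAND, ELEMENT_ID, ELEMENT_TYPE,
#' SYMBOL — one row per segment.
#'
#' @param catalog an `ElementCatalog`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  rows <- lapply(catalog$elements, function(e) {
    data.frame(CHROM = e$chrom, START = e$segments$start, END = e$segments$end,
               STRAND = e$strand, ELEMENT_ID = e$element_id,
               ELEMENT_TYPE = e$element_type, SYMBOL = e$symbol)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' Read an element catalog from BED-like TSV
#'
#' @param path file written by [write_catalog()] (or equivalent).
#' @return an `ElementCatalog`.
#' @export
read_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  els <- lapply(split(as.data.frame(dt), dt$ELEMENT_ID), function(d) {
    genomic_element(d$ELEMENT_ID[1], d$SYMBOL[1], d$ELEMENT_TYPE[1],
                    as.character(d$CHROM[1]), d$STRAND[1],
                    data.frame(start = d$START, end = d$END))
  })
  element_catalog(els)
}
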
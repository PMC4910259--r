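# Shared fixtures: all built in code at test time.

# deterministic random genome
toy_genome <- function(len = 10000, seed = 42, gc = 0.5,
                       chrom = "chr1") {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- rep_len(chrom, length(len))
  fml_genome(seqs)
}

# a fully scored store for every substitution in [from, to] of a genome
toy_store <- function(genome, chrom = "chr1", from, to, seed = 7) {
  set.seed(seed)
  pos <- seq.int(from, to)
  ref <- genome_base(genome, chrom, pos)
  alt <- unlist(lapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)))
  score_store(data.frame(chrom = chrom, pos = rep(pos, each = 3),
                         ref = rep(ref, each = 3), alt = alt,
                         score = round(rexp(3 * length(pos), 1 / 3), 1)))
}

toy_element <- function(id = "E1", chrom = "chr1", start, end,
                        type = "cds", strand = "+") {
  genomic_element(id, id, type, chrom, strand,
                  data.frame(start = start, end = end))
}

# small GTF writer used by region-builder tests; `rows` is a list of
# c(feature, start, end, strand, gene_id, transcript_id, biotype)
write_toy_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s"; transcript_type "%s"; gene_name "%s";',
                     r[[5]], r[[6]], r[[7]], r[[7]], r[[5]])
    paste("chr1", "test", r[[1]], r[[2]], r[[3]], ".", r[[4]], ".", attrs,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# mutation data.frame shorthand
raw_muts <- function(chrom, pos, ref, alt, sample_id) {
  data.frame(chrom = unname(chrom), pos = unname(pos), ref = unname(ref),
             alt = unname(alt), sample_id = unname(sample_id),
             stringsAsFactors = FALSE)
}
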
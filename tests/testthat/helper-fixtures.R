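# fixtures are built in code; nothing is read from disk

# small complete simulation used by several suites
small_sim <- function(seed = 7, ...) {
  simulate_dataset(sim_config(n_mrna = 120, n_lncrna = 24, n_spikein = 8,
                              seed = seed, ...))
}

# hand-built gene models: one row per gene, exons as 0-based [start, end) pairs
mk_gene_models <- function(chrom, start, end, strand, name, exons) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$exons <- methods::as(lapply(exons, function(e) {
    IRanges::IRanges(start = e[, 1] + 1L, end = e[, 2])
  }), "IRangesList")
  gr
}

# annotation-style interval table for lncRNAs (0-based half-open)
mk_lnc <- function(id, chrom, start, end, strand) {
  data.frame(transcript_id = id, chrom = chrom, start = start, end = end,
             strand = strand)
}

# minimal differential_records object for integrate-level tests
mk_records <- function(ids, calls, measure, comparison = "A vs B",
                       rna_class = "mRNA") {
  rec <- data.frame(transcript_id = ids, gene_symbol = ids,
                    rna_class = rna_class,
                    mean_condition = 1, mean_reference = 1,
                    fc = 1, p = 1, fdr_info = 1, call = calls)
  attr(rec, "comparison") <- comparison
  attr(rec, "measure") <- measure
  class(rec) <- c("differential_records", "data.frame")
  rec
}

# brute-force reference for the two-sided minimum-likelihood Fisher P,
# written against choose() rather than dhyper()
fisher_bruteforce <- function(k, n, K, N, tol = 1e-7) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  d <- choose(K, lo:hi) * choose(N - K, n - (lo:hi)) / choose(N, n)
  min(1, sum(d[d <= d[k - lo + 1] * (1 + tol)]))
}

# closed-form pooled two-sample t (textbook arithmetic, no shared code path)
pooled_t_reference <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}
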
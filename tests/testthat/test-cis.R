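# two genes on one chromosome; exons flank the gene boundaries
toy_models <- function() {
  mk_gene_models(
    chrom = c("chr1", "chr1"),
    start = c(301000, 900000), end = c(321000, 920000),
    strand = c("+", "-"), name = c("GeneA", "GeneB"),
    exons = list(rbind(c(301000, 302000), c(310000, 311000), c(320000, 321000)),
                 rbind(c(900000, 901000), c(919000, 920000))))
}

test_that("cis window boundary is inclusive at exactly 300 kb", {
  gm <- toy_models()
  lnc <- mk_lnc("L1", "chr1", 0, 1000, "+")       # gap to GeneA = 300000
  links <- find_cis_genes(lnc, gm, window = 300000)
  expect_equal(links$gene_symbol, "GeneA")
  expect_equal(links$distance, 300000L)
  lnc2 <- mk_lnc("L2", "chr1", 0, 999, "+")       # gap = 300001
  expect_equal(nrow(find_cis_genes(lnc2, gm, window = 300000)), 0)
  # overlapping gene: distance 0
  lnc3 <- mk_lnc("L3", "chr1", 305000, 306000, "+")
  l3 <- find_cis_genes(lnc3, gm, window = 300000)
  expect_equal(l3$distance[l3$gene_symbol == "GeneA"], 0L)
})

test_that("enlarging the window never removes a link", {
  gm <- toy_models()
  lnc <- rbind(mk_lnc("L1", "chr1", 0, 1000, "+"),
               mk_lnc("L2", "chr1", 500000, 501000, "-"))
  small <- find_cis_genes(lnc, gm, window = 150000)
  big <- find_cis_genes(lnc, gm, window = 600000)
  key <- function(x) paste(x$lncrna_id, x$gene_symbol)
  expect_true(all(key(small) %in% key(big)))
  expect_gt(nrow(big), nrow(small))
})

test_that("context classification follows the precedence definitions", {
  gm <- toy_models()
  cases <- rbind(
    mk_lnc("in_intron_same", "chr1", 304000, 305000, "+"),
    mk_lnc("on_exon_same", "chr1", 301500, 302500, "+"),
    mk_lnc("on_exon_anti", "chr1", 301500, 302500, "-"),
    mk_lnc("in_intron_anti", "chr1", 304000, 305000, "-"),
    mk_lnc("divergent", "chr1", 300000, 300500, "-"),
    mk_lnc("lonely", "chr1", 600000, 601000, "+"))
  ctx <- classify_context(cases, gm)
  expect_equal(ctx$context,
               c("intron_overlap", "exon_overlap", "natural_antisense",
                 "intronic_antisense", "bidirectional", "intergenic"))
  # minus-strand gene: divergent partner sits downstream on the plus strand
  div2 <- mk_lnc("divergent2", "chr1", 920300, 921000, "+")
  expect_equal(classify_context(div2, gm)$context, "bidirectional")
  # beyond the bidirectional gap it falls through to intergenic
  far <- mk_lnc("far", "chr1", 295000, 296000, "-")
  expect_equal(classify_context(far, gm)$context, "intergenic")
  # unknown chromosome: intergenic with warning
  expect_warning(ctx9 <- classify_context(mk_lnc("x", "chr9", 0, 100, "+"), gm),
                 "absent")
  expect_equal(ctx9$context, "intergenic")
})

test_that("generated layouts round-trip through the classifier", {
  for (seed in c(7, 11)) {
    ann <- simulate_annotation(sim_config(n_mrna = 60, n_lncrna = 12,
                                          n_spikein = 4, seed = seed))
    lnc <- ann$annotation[ann$annotation$rna_class == "lncRNA", ]
    got <- classify_context(lnc, ann$gene_models)
    expect_equal(got$context[match(ann$lnc_context$transcript_id,
                                   got$transcript_id)],
                 ann$lnc_context$context)
  }
})

test_that("find_cis_genes equals a brute-force all-pairs scan", {
  ann <- simulate_annotation(sim_config(n_mrna = 80, n_lncrna = 18,
                                        n_spikein = 4, seed = 13))
  anno <- ann$annotation
  lnc <- anno[anno$rna_class == "lncRNA", ]
  genes <- anno[anno$rna_class == "mRNA", ]
  window <- 300000
  links <- find_cis_genes(lnc, ann$gene_models, window = window)
  # brute force on the 0-based half-open annotation intervals
  brute <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(genes))) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    gap <- max(genes$start[j] - lnc$end[i], lnc$start[i] - genes$end[j], 0)
    if (gap <= window)
      brute[[length(brute) + 1L]] <- data.frame(
        lncrna_id = lnc$transcript_id[i],
        gene_symbol = genes$gene_symbol[j], distance = gap)
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$lncrna_id, brute$distance, brute$gene_symbol), ]
  expect_equal(nrow(links), nrow(brute))
  expect_equal(links$lncrna_id, brute$lncrna_id)
  expect_equal(links$gene_symbol, brute$gene_symbol)
  expect_equal(links$distance, brute$distance)
})

test_that("link_to_de joins links with expression calls and deduplicates", {
  links <- data.frame(
    lncrna_id = c("L1", "L1", "L2", "L3", "L3"),
    gene_symbol = c("GA", "GB", "GB", "GC", "GD"),
    distance = c(0L, 100L, 50L, 10L, 20L), relation = "intergenic")
  expr <- mk_records(c("GA", "GB", "GC", "GD", "GE"),
                     c("up", "down", "none", "none", "up"), "expression")
  out <- link_to_de(links, expr)
  # exhaustive join: GA (up) via L1; GB (down) via L1 and L2
  expect_equal(nrow(out$table), 3)
  expect_setequal(out$de_genes, c("GA", "GB"))  # GB linked twice, kept once
  expect_equal(out$n_lncrnas, 2)
  expect_equal(out$n_up_genes, 1)
  expect_equal(out$n_down_genes, 1)
  none <- link_to_de(links, mk_records("GA", "none", "expression"))
  expect_equal(nrow(none$table), 0)
  expect_error(link_to_de(links, mk_records("GA", "none", "methylation")),
               "expression")
})

test_that("sign-flip lncRNA selection", {
  a <- mk_records(c("l1", "l2", "l3", "m1"),
                  c("hyper", "hyper", "hypo", "hyper"), "methylation",
                  rna_class = c("lncRNA", "lncRNA", "lncRNA", "mRNA"))
  b <- mk_records(c("l1", "l2", "l3", "m1"),
                  c("hypo", "hyper", "hyper", "hypo"), "methylation",
                  rna_class = c("lncRNA", "lncRNA", "lncRNA", "mRNA"))
  flips <- select_signflip_lncrnas(a, b)
  expect_equal(flips$hyper_then_hypo, "l1")   # l2 hyper in both: excluded
  expect_equal(flips$hypo_then_hyper, "l3")   # m1 flips but is mRNA
})

test_that("planted group-specific methylation shifts flip sign across comparisons", {
  # a shift planted in M1-L is hyper in M1-L vs M0-L and hypo in M2-L vs M1-L
  eff <- planted_effect("lnc_00003", "M1-L", "methylation_shift", 2.5)
  cfg <- sim_config(n_mrna = 60, n_lncrna = 12, n_spikein = 8,
                    planted_effects = eff, seed = 21)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann)
  q <- quantify(si$arrays)
  a <- run_comparison(q, "M1-L", "M0-L", "methylation")
  b <- run_comparison(q, "M2-L", "M1-L", "methylation")
  flips <- select_signflip_lncrnas(a, b)
  expect_equal(flips$hyper_then_hypo, "lnc_00003")
  expect_equal(flips$hypo_then_hyper, character(0))
})
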
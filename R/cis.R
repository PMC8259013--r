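# lncRNA genomic-context classification and cis-gene linkage.
# Annotation coordinates are 0-based half-open (BED); internally converted
# to 1-based GRanges. The gap between [a,b) and [c,d) with c >= b is c - b,
# which matches GenomicRanges::distance() on the 1-based ranges.

context_precedence <- c("exon_overlap", "intron_overlap", "natural_antisense",
                        "intronic_antisense", "bidirectional", "intergenic")

anno_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

# exon GRanges of the gene models, with a gene index
gene_exons_gr <- function(gene_models) {
  exons <- S4Vectors::mcols(gene_models)$exons
  n <- lengths(exons)
  GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(gene_models), n),
    ranges = unlist(exons, use.names = FALSE),
    strand = rep(GenomicRanges::strand(gene_models), n),
    gene = rep(seq_along(gene_models), n))
}

# relation of (lnc, gene) index pairs; NA when none of the overlap-based
# classes applies
pair_relation <- function(lnc_gr, gene_models, qh, sh, exon_hit) {
  ls <- GenomicRanges::start(lnc_gr)[qh]; le <- GenomicRanges::end(lnc_gr)[qh]
  gs <- GenomicRanges::start(gene_models)[sh]
  ge <- GenomicRanges::end(gene_models)[sh]
  same <- as.character(GenomicRanges::strand(lnc_gr))[qh] ==
    as.character(GenomicRanges::strand(gene_models))[sh]
  within <- ls >= gs & le <= ge
  ifelse(same & exon_hit, "exon_overlap",
    ifelse(same & within, "intron_overlap",
      ifelse(!same & exon_hit, "natural_antisense",
        ifelse(!same & within, "intronic_antisense", NA_character_))))
}

# divergent-promoter test for non-overlapping (lnc, gene) pairs
is_bidirectional <- function(lnc_gr, gene_models, qh, sh, gap) {
  lstr <- as.character(GenomicRanges::strand(lnc_gr))[qh]
  gstr <- as.character(GenomicRanges::strand(gene_models))[sh]
  ls <- GenomicRanges::start(lnc_gr)[qh]; le <- GenomicRanges::end(lnc_gr)[qh]
  gs <- GenomicRanges::start(gene_models)[sh]
  ge <- GenomicRanges::end(gene_models)[sh]
  (gstr == "+" & lstr == "-" & le < gs & gs - le <= gap) |
    (gstr == "-" & lstr == "+" & ls > ge & ls - ge <= gap)
}

#' Classify lncRNAs by genomic context
#'
#' Assigns exactly one context class per lncRNA by precedence:
#' exon overlap (same strand, intersects an exon) > intron overlap (same
#' strand, within the gene body, no exon hit) > natural antisense (opposite
#' strand, intersects an exon) > intronic antisense (opposite strand, within
#' the gene body) > bidirectional (no overlap, divergent transcription start
#' sites within `bidirectional_gap`) > intergenic (fall-through). lncRNAs on
#' chromosomes absent from the gene models are intergenic with a warning.
#'
#' @param lncrnas data frame with columns `transcript_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (e.g. the lncRNA rows of the probe
#'   annotation).
#' @param gene_models `GRanges` of coding genes with metadata `name` and
#'   absolute-coordinate `exons` (an `IRangesList`), as produced by
#'   [simulate_annotation()] or [read_bed12()].
#' @param bidirectional_gap maximum TSS-to-TSS distance (bp) for the
#'   bidirectional class.
#' @return data frame: transcript_id, context.
#' @export
classify_context <- function(lncrnas, gene_models, bidirectional_gap = 1000) {
  lnc_gr <- anno_granges(lncrnas)
  unknown <- !as.character(GenomicRanges::seqnames(lnc_gr)) %in%
    as.character(GenomicRanges::seqnames(gene_models))
  if (any(unknown))
    warning(sum(unknown), " lncRNA(s) on chromosomes absent from the gene",
            " models classified intergenic", call. = FALSE)
  # seqlevel-merge chatter is silenced: unknown chromosomes are handled above
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(lnc_gr, gene_models, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ex_gr <- gene_exons_gr(gene_models)
  ovx <- suppressWarnings(
    GenomicRanges::findOverlaps(lnc_gr, ex_gr, ignore.strand = TRUE))
  exon_pairs <- unique(paste(S4Vectors::queryHits(ovx),
                             S4Vectors::mcols(ex_gr)$gene[S4Vectors::subjectHits(ovx)]))
  exon_hit <- paste(qh, sh) %in% exon_pairs
  rel <- pair_relation(lnc_gr, gene_models, qh, sh, exon_hit)
  rank <- match(rel, context_precedence)
  best <- rep(NA_integer_, length(lnc_gr))
  ok <- !is.na(rank)
  if (any(ok)) {
    agg <- tapply(rank[ok], qh[ok], min)
    best[as.integer(names(agg))] <- agg
  }
  # bidirectional for lncRNAs with no overlap-based class
  near <- suppressWarnings(
    GenomicRanges::findOverlaps(lnc_gr, gene_models,
                                maxgap = bidirectional_gap,
                                ignore.strand = TRUE))
  nq <- S4Vectors::queryHits(near); ns <- S4Vectors::subjectHits(near)
  bid <- is_bidirectional(lnc_gr, gene_models, nq, ns, bidirectional_gap)
  bid_lnc <- unique(nq[bid])
  idx_bid <- is.na(best) & seq_along(lnc_gr) %in% bid_lnc
  best[idx_bid] <- match("bidirectional", context_precedence)
  best[is.na(best)] <- match("intergenic", context_precedence)
  data.frame(transcript_id = lncrnas$transcript_id,
             context = context_precedence[best], row.names = NULL)
}

#' Find coding genes within a genomic window of each lncRNA
#'
#' Emits every same-chromosome gene whose boundary gap to the lncRNA is at
#' most `window` bp (inclusive; overlapping or touching intervals have gap
#' 0). Links are sorted by lncRNA, then distance, then gene symbol, and
#' carry the context class of the pair.
#'
#' @inheritParams classify_context
#' @param window maximum boundary gap in bp.
#' @return data frame of class `cis_links`: lncrna_id, gene_symbol,
#'   distance, relation.
#' @export
find_cis_genes <- function(lncrnas, gene_models, window = 300000,
                           bidirectional_gap = 1000) {
  stopifnot(window > 0)
  lnc_gr <- anno_granges(lncrnas)
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_models, maxgap = window,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lnc_gr[qh], gene_models[sh],
                               ignore.strand = TRUE)
  ex_gr <- gene_exons_gr(gene_models)
  ovx <- GenomicRanges::findOverlaps(lnc_gr, ex_gr, ignore.strand = TRUE)
  exon_pairs <- unique(paste(S4Vectors::queryHits(ovx),
                             S4Vectors::mcols(ex_gr)$gene[S4Vectors::subjectHits(ovx)]))
  rel <- pair_relation(lnc_gr, gene_models, qh, sh,
                       paste(qh, sh) %in% exon_pairs)
  bid <- is_bidirectional(lnc_gr, gene_models, qh, sh, bidirectional_gap)
  rel[is.na(rel) & bid] <- "bidirectional"
  rel[is.na(rel)] <- "intergenic"
  out <- data.frame(
    lncrna_id = lncrnas$transcript_id[qh],
    gene_symbol = S4Vectors::mcols(gene_models)$name[sh],
    distance = as.integer(d), relation = rel, row.names = NULL)
  out <- out[order(out$lncrna_id, out$distance, out$gene_symbol), ]
  rownames(out) <- NULL
  class(out) <- c("cis_links", "data.frame")
  out
}

#' Intersect cis links with differential-expression calls
#'
#' Keeps links whose coding gene is called up or down, and collects the
#' deduplicated differentially expressed neighbor gene set (input for
#' enrichment).
#'
#' @param links a [find_cis_genes()] result.
#' @param expr_records an expression [run_comparison()] result.
#' @return list: `table` (links of DE genes, with the expression call),
#'   `de_genes` (unique symbols), `n_lncrnas` (lncRNAs with >= 1 DE
#'   neighbor), `n_up_genes`, `n_down_genes`.
#' @export
link_to_de <- function(links, expr_records) {
  if (!identical(attr(expr_records, "measure"), "expression"))
    stopf("link_to_de needs expression differential records")
  de <- expr_records[expr_records$call %in% c("up", "down"),
                     c("gene_symbol", "call")]
  tab <- links[links$gene_symbol %in% de$gene_symbol, , drop = FALSE]
  tab$call <- de$call[match(tab$gene_symbol, de$gene_symbol)]
  rownames(tab) <- NULL
  genes <- unique(tab$gene_symbol)
  list(table = tab, de_genes = genes,
       n_lncrnas = length(unique(tab$lncrna_id)),
       n_up_genes = length(unique(tab$gene_symbol[tab$call == "up"])),
       n_down_genes = length(unique(tab$gene_symbol[tab$call == "down"])))
}

#' Select lncRNAs whose methylation direction flips between comparisons
#'
#' @param meth_a,meth_b methylation [run_comparison()] results for two
#'   comparisons (e.g. M1-L vs M0-L and M2-L vs M1-L).
#' @return list: `hyper_then_hypo` (lncRNA ids hyper in A and hypo in B),
#'   `hypo_then_hyper` (the reverse).
#' @export
select_signflip_lncrnas <- function(meth_a, meth_b) {
  pick <- function(rec, call) {
    rec$transcript_id[rec$rna_class == "lncRNA" & rec$call == call]
  }
  list(hyper_then_hypo = intersect(pick(meth_a, "hyper"), pick(meth_b, "hypo")),
       hypo_then_hyper = intersect(pick(meth_a, "hypo"), pick(meth_b, "hyper")))
}
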
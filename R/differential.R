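#' Differential-call thresholds
#'
#' Fold-change and significance cutoffs used to call differential
#' methylation/expression: FC >= `fc_up` or <= `fc_down` (boundaries
#' inclusive, asymmetric as conventionally printed) and raw P < `alpha`.
#'
#' @param fc_up upper fold-change cutoff (> 1).
#' @param fc_down lower fold-change cutoff (in (0, 1)).
#' @param alpha significance level (strict `<`).
#' @return validated list of class `diff_thresholds`.
#' @export
diff_thresholds <- function(fc_up = 1.5, fc_down = 0.7, alpha = 0.05) {
  if (fc_up <= 1) stopf("fc_up must be > 1")
  if (fc_down <= 0 || fc_down >= 1) stopf("fc_down must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha),
            class = "diff_thresholds")
}

#' Linear fold change between group means
#'
#' `mean(condition) / max(mean(reference), mean_floor)`; the floor keeps the
#' ratio finite when the reference mean is zero (flagged via the `floored`
#' attribute).
#'
#' @param condition,reference numeric replicate values (>= 1 each).
#' @param mean_floor floor applied to the reference mean.
#' @return fold change (linear scale).
#' @export
fold_change <- function(condition, reference, mean_floor = 1e-6) {
  if (length(condition) < 1 || length(reference) < 1)
    stopf("fold_change: empty group")
  mr <- mean(reference)
  fc <- mean(condition) / max(mr, mean_floor)
  attr(fc, "floored") <- mr < mean_floor
  fc
}

# shared pooled-variance t machinery, vectorized over matrix rows
.row_t <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  a <- x[, ia, drop = FALSE]; b <- x[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  # zero pooled variance: equal means -> p = 1; unequal means -> p -> 0+
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- .Machine$double.xmin
  t[degenerate] <- NA_real_
  list(t = t, df = df, p = p, degenerate = degenerate,
       mean_a = ma, mean_b = mb)
}

#' Two-sample pooled-variance Student's t-test (two-tailed P)
#'
#' Equal-variance t with `df = n_a + n_b - 2`. With zero pooled variance the
#' P value is 1 for equal means and the smallest positive double (flagged)
#' for unequal means.
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @return two-tailed P value with attributes `t`, `df`, `degenerate`.
#' @export
student_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("student_t: each group needs >= 2 values")
  r <- .row_t(rbind(c(a, b)), seq_along(a), length(a) + seq_along(b))
  structure(r$p, t = unname(r$t), df = r$df, degenerate = unname(r$degenerate))
}

#' Differential call from fold change and P value
#'
#' hyper/up iff `fc >= fc_up & p < alpha`; hypo/down iff
#' `fc <= fc_down & p < alpha`; otherwise none. Vectorized.
#'
#' @param fc,p numeric vectors.
#' @param thresholds a [diff_thresholds()].
#' @param measure `"methylation"` (labels hyper/hypo) or `"expression"`
#'   (labels up/down).
#' @return character vector of calls.
#' @export
call_differential <- function(fc, p, thresholds = diff_thresholds(),
                              measure = c("methylation", "expression")) {
  measure <- match.arg(measure)
  up <- if (measure == "methylation") "hyper" else "up"
  down <- if (measure == "methylation") "hypo" else "down"
  ifelse(fc >= thresholds$fc_up & p < thresholds$alpha, up,
         ifelse(fc <= thresholds$fc_down & p < thresholds$alpha, down, "none"))
}

#' Differential analysis of one comparison
#'
#' Computes per-transcript fold change (condition mean over reference mean),
#' pooled two-tailed Student's t P value, and the differential call at the
#' given thresholds, on the percent-modification or expression matrix of a
#' quantified set. Spike-in probes are excluded. Tests run on the linear
#' values; a BH-adjusted column (`fdr_info`) is emitted for information only
#' and never used for calls.
#'
#' @param quant a [quantify()] result carrying an annotation.
#' @param condition,reference phenotype group labels (>= 2 replicates each).
#' @param measure `"methylation"` or `"expression"`.
#' @param thresholds a [diff_thresholds()].
#' @param mean_floor floor for the reference mean in the fold change.
#' @return data frame of class `differential_records` (one row per
#'   transcript: transcript_id, gene_symbol, rna_class, mean_condition,
#'   mean_reference, fc, p, fdr_info, call) with attributes `comparison`,
#'   `condition`, `reference`, `measure`.
#' @export
run_comparison <- function(quant, condition, reference,
                           measure = c("methylation", "expression"),
                           thresholds = diff_thresholds(),
                           mean_floor = 1e-6) {
  stopifnot(inherits(quant, "quantified_set"))
  measure <- match.arg(measure)
  if (condition == reference) stopf("condition and reference must differ")
  anno <- quant$annotation
  if (is.null(anno)) stopf("quantified set carries no annotation")
  smp <- quant$samples
  ia <- which(smp$group == condition)
  ib <- which(smp$group == reference)
  if (length(ia) < 2 || length(ib) < 2)
    stopf("each group needs >= 2 replicates (%s: %d, %s: %d)",
          condition, length(ia), reference, length(ib))
  mat <- quant[[measure]]
  keep <- anno$probe_id[anno$rna_class != "spikein"]
  mat <- mat[keep, , drop = FALSE]
  tt <- .row_t(mat, ia, ib)
  fc <- tt$mean_a / pmax(tt$mean_b, mean_floor)
  call <- call_differential(fc, tt$p, thresholds, measure)
  idx <- match(keep, anno$probe_id)
  rec <- data.frame(
    transcript_id = anno$transcript_id[idx],
    gene_symbol = anno$gene_symbol[idx],
    rna_class = anno$rna_class[idx],
    mean_condition = tt$mean_a, mean_reference = tt$mean_b,
    fc = fc, p = tt$p, fdr_info = p.adjust(tt$p, "BH"), call = call,
    row.names = NULL)
  attr(rec, "comparison") <- paste(condition, "vs", reference)
  attr(rec, "condition") <- condition
  attr(rec, "reference") <- reference
  attr(rec, "measure") <- measure
  attr(rec, "thresholds") <- thresholds
  class(rec) <- c("differential_records", "data.frame")
  rec
}

#' Per-class directional summary of differential records
#'
#' @param records a [run_comparison()] result.
#' @return data frame: comparison, measure, rna_class, n_up (hyper or up),
#'   n_down (hypo or down), total.
#' @export
differential_summary <- function(records) {
  measure <- attr(records, "measure")
  up <- if (measure == "methylation") "hyper" else "up"
  down <- if (measure == "methylation") "hypo" else "down"
  cls <- sort(unique(records$rna_class))
  out <- do.call(rbind, lapply(cls, function(k) {
    r <- records[records$rna_class == k, ]
    data.frame(comparison = attr(records, "comparison"), measure = measure,
               rna_class = k,
               n_up = sum(r$call == up), n_down = sum(r$call == down))
  }))
  out$total <- out$n_up + out$n_down
  out
}

#' Agglomerative clustering of a differential matrix
#'
#' Average-linkage clustering on Euclidean distances of both transcripts
#' (rows) and samples (columns), as used to display differential methylation
#' patterns. Deterministic given the input ordering. With fewer than 2 rows
#' or columns the corresponding tree degenerates to the identity leaf order.
#'
#' @param mat numeric matrix (e.g. percent modification restricted to
#'   differential transcripts).
#' @return list of class `hier_clustering`: `row_tree`, `col_tree`
#'   (`hclust` objects or NULL when degenerate), `row_order`, `col_order`
#'   (leaf label orders).
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  cl <- function(m) {
    if (nrow(m) < 2) return(list(tree = NULL, order = rownames(m)))
    h <- hclust(dist(m), method = "average")
    list(tree = h, order = rownames(m)[h$order])
  }
  r <- cl(mat); c <- cl(t(mat))
  structure(list(row_tree = r$tree, col_tree = c$tree,
                 row_order = r$order, col_order = c$order),
            class = "hier_clustering")
}

# serializable nested-list view of an hclust tree (merge heights + leaves)
cluster_tree_list <- function(h) {
  if (is.null(h)) return(NULL)
  build <- function(i) {
    if (i < 0) return(h$labels[-i])
    list(height = h$height[i],
         left = build(h$merge[i, 1]), right = build(h$merge[i, 2]))
  }
  build(nrow(h$merge))
}
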
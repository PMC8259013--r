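#' MeRIP-qPCR percent input
#'
#' Enrichment of the immunoprecipitated fraction relative to the
#' dilution-adjusted input: the input Ct is shifted by
#' `-log2(1 / input_fraction)` to account for the reserved input fraction,
#' then `percent = 100 * 2^(adjusted input Ct - IP Ct)`. Invariant to adding
#' a constant to both Ct values. Vectorized.
#'
#' @param ct_ip,ct_input cycle-threshold values.
#' @param input_fraction fraction of material reserved as input, in (0, 1].
#' @return percent input values.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.1) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stopf("input_fraction must be in (0, 1]")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = mean dCt(treated) - mean dCt(control)`; fold change is
#' `2^-ddCt`. Statistics (SEM, two-group Student's t) are computed on the
#' Ct-scale dCt values, which are closer to normal than the folds; folds are
#' reported as transformed means. Per-replicate folds use the control-group
#' mean dCt as baseline.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   replicate Ct vectors; target and reference vectors of one condition
#'   must be replicate-aligned and of equal length.
#' @return list of class `ddct_result`: `fold`, `ddct`, `sem_ddct`,
#'   `fold_per_replicate`, `p` (pooled two-tailed Student's t on the dCt
#'   values; NA with fewer than 2 replicates per condition).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  if (length(ct_target_treated) != length(ct_ref_treated) ||
      length(ct_target_control) != length(ct_ref_control))
    stopf("ddct: target and reference Ct vectors must be replicate-aligned")
  if (any(!is.finite(c(ct_target_treated, ct_ref_treated,
                       ct_target_control, ct_ref_control))))
    stopf("ddct: all Ct values must be finite")
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  dd <- mean(dct_t) - mean(dct_c)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  p <- if (length(dct_t) >= 2 && length(dct_c) >= 2)
    as.numeric(student_t(dct_t, dct_c)) else NA_real_
  structure(list(fold = 2^-dd, ddct = dd,
                 sem_ddct = sqrt(sum(c(sem(dct_t), sem(dct_c))^2)),
                 fold_per_replicate = 2^-(dct_t - mean(dct_c)),
                 p = p),
            class = "ddct_result")
}

#' Two-group summary: mean, SEM and Student's t
#'
#' SEM uses the sample standard deviation (n - 1 denominator); the P value
#' is the pooled two-tailed Student's t of [student_t()].
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param alpha significance level for the flag.
#' @return list: mean_a, sem_a, mean_b, sem_b, p, significant.
#' @export
group_compare <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stopf("group_compare: each group needs >= 2 values")
  sem <- function(x) sd(x) / sqrt(length(x))
  p <- as.numeric(student_t(a, b))
  list(mean_a = mean(a), sem_a = sem(a), mean_b = mean(b), sem_b = sem(b),
       p = p, significant = p < alpha)
}

#' qPCR expression analysis from a Ct table
#'
#' Convenience wrapper extracting the cDNA-tube Cts of a target and the
#' reference gene from a long-format Ct table (as written by
#' [simulate_qpcr()]) and running [ddct()] for treated vs control groups.
#'
#' @param ct Ct table (sample_id, group, tube, target, is_reference, ct).
#' @param target target gene name.
#' @param treated,control group labels.
#' @param reference_gene reference gene name (error if absent).
#' @return a [ddct()] result.
#' @export
qpcr_expression <- function(ct, target, treated, control,
                            reference_gene = "Gapdh") {
  cd <- ct[ct$tube == "cdna", ]
  grab <- function(gene, grp) {
    r <- cd[cd$target == gene & cd$group == grp, ]
    r$ct[order(r$sample_id)]
  }
  ref_t <- grab(reference_gene, treated)
  ref_c <- grab(reference_gene, control)
  if (length(ref_t) == 0 || length(ref_c) == 0)
    stopf("reference gene %s missing from Ct table", reference_gene)
  ddct(grab(target, treated), ref_t, grab(target, control), ref_c)
}

#' MeRIP percent-input per sample from a Ct table
#'
#' @param ct Ct table with `input` and `ip` tube rows carrying
#'   `input_fraction`.
#' @param target target gene name.
#' @return data frame: sample_id, group, percent_input.
#' @export
qpcr_percent_input <- function(ct, target) {
  ip <- ct[ct$tube == "ip" & ct$target == target, ]
  inp <- ct[ct$tube == "input" & ct$target == target, ]
  idx <- match(ip$sample_id, inp$sample_id)
  if (any(is.na(idx))) stopf("unpaired ip/input rows for %s", target)
  data.frame(sample_id = ip$sample_id, group = ip$group,
             percent_input = percent_input(ip$ct, inp$ct[idx],
                                           ip$input_fraction),
             row.names = NULL)
}
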
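quadrant_levels <- c("Hyper-Up", "Hyper-Down", "Hypo-Up", "Hypo-Down")

#' Cross methylation and expression calls into quadrants
#'
#' A transcript is assigned `Hyper-Up`, `Hyper-Down`, `Hypo-Up` or
#' `Hypo-Down` when its methylation call is hyper/hypo AND its expression
#' call is up/down for the same comparison; otherwise it is `unassociated`.
#'
#' @param meth,expr [run_comparison()] results for the same comparison, with
#'   measures `"methylation"` and `"expression"` and the same transcript
#'   universe.
#' @return data frame of class `quadrant_assignments` (transcript_id,
#'   gene_symbol, rna_class, meth_call, expr_call, quadrant) with attributes
#'   `comparison` and `counts` (quadrant x rna_class table).
#' @export
assign_quadrants <- function(meth, expr) {
  if (!identical(attr(meth, "comparison"), attr(expr, "comparison")))
    stopf("comparison mismatch: %s vs %s",
          attr(meth, "comparison"), attr(expr, "comparison"))
  if (!identical(attr(meth, "measure"), "methylation") ||
      !identical(attr(expr, "measure"), "expression"))
    stopf("assign_quadrants needs one methylation and one expression record set")
  if (!setequal(meth$transcript_id, expr$transcript_id))
    stopf("record sets cover different transcript universes")
  expr <- expr[match(meth$transcript_id, expr$transcript_id), ]
  quadrant <- ifelse(
    meth$call != "none" & expr$call != "none",
    paste0(ifelse(meth$call == "hyper", "Hyper", "Hypo"), "-",
           ifelse(expr$call == "up", "Up", "Down")),
    "unassociated")
  out <- data.frame(transcript_id = meth$transcript_id,
                    gene_symbol = meth$gene_symbol,
                    rna_class = meth$rna_class,
                    meth_call = meth$call, expr_call = expr$call,
                    quadrant = quadrant, row.names = NULL)
  attr(out, "comparison") <- attr(meth, "comparison")
  attr(out, "counts") <- table(
    factor(out$quadrant, c(quadrant_levels, "unassociated")), out$rna_class)
  class(out) <- c("quadrant_assignments", "data.frame")
  out
}

#' Fully opposite quadrant
#'
#' Both the methylation and the expression direction flip:
#' Hyper-Up <-> Hypo-Down, Hyper-Down <-> Hypo-Up. An involution.
#'
#' @param q character vector of quadrant labels (not `unassociated`).
#' @return opposite quadrant labels.
#' @export
opposite_quadrant <- function(q) {
  map <- c("Hyper-Up" = "Hypo-Down", "Hypo-Down" = "Hyper-Up",
           "Hyper-Down" = "Hypo-Up", "Hypo-Up" = "Hyper-Down")
  if (any(!q %in% names(map)))
    stopf("opposite_quadrant undefined for: %s",
          paste(unique(q[!q %in% names(map)]), collapse = ", "))
  unname(map[q])
}

#' Cross-comparison quadrant concordance (sign-flip analysis)
#'
#' Builds the 4x4 contingency of quadrant assignments over transcripts that
#' are quadrant-assigned in both comparisons. `n_opposite` sums the four
#' fully-opposite cells (methylation AND expression direction flipped);
#' `fraction_opposite = n_opposite / n_both`. Per-quadrant conditional
#' flip fractions are also reported.
#'
#' @param a,b [assign_quadrants()] results for two comparisons.
#' @return list of class `concordance_report`: `comparison_a`,
#'   `comparison_b`, `table` (4x4), `n_both`, `n_opposite`,
#'   `fraction_opposite` (NA, flagged, when `n_both` is 0), `per_quadrant`.
#' @export
concordance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stopf("empty assignment set")
  aa <- a[a$quadrant != "unassociated", c("transcript_id", "quadrant")]
  bb <- b[b$quadrant != "unassociated", c("transcript_id", "quadrant")]
  shared <- intersect(aa$transcript_id, bb$transcript_id)
  qa <- factor(aa$quadrant[match(shared, aa$transcript_id)], quadrant_levels)
  qb <- factor(bb$quadrant[match(shared, bb$transcript_id)], quadrant_levels)
  tab <- table(a = qa, b = qb)
  n_both <- length(shared)
  n_opp <- sum(vapply(quadrant_levels,
                      function(q) tab[q, opposite_quadrant(q)], numeric(1)))
  per_q <- data.frame(
    quadrant = quadrant_levels,
    n_in_a = as.integer(rowSums(tab)),
    n_opposite = vapply(quadrant_levels,
                        function(q) as.integer(tab[q, opposite_quadrant(q)]),
                        integer(1)),
    row.names = NULL)
  per_q$fraction_opposite <- ifelse(per_q$n_in_a > 0,
                                    per_q$n_opposite / per_q$n_in_a, NA_real_)
  structure(list(comparison_a = attr(a, "comparison"),
                 comparison_b = attr(b, "comparison"),
                 table = tab, n_both = n_both, n_opposite = n_opp,
                 fraction_opposite = if (n_both > 0) n_opp / n_both else NA_real_,
                 undefined = n_both == 0, per_quadrant = per_q),
            class = "concordance_report")
}

#' Headline count-and-percentage report
#'
#' Reproduces the printed-style reporting: per comparison and RNA class, the
#' total number of differential transcripts (hyper + hypo, or up + down) and
#' the one-decimal directional percentages (ties rounded half away from
#' zero). Percentages are NA (flagged in `undefined`) when the total is 0.
#'
#' @param meth_summary data frame with columns `comparison`, `rna_class`,
#'   `n_hyper`, `n_hypo` (e.g. reshaped from [differential_summary()]).
#' @param expr_summary optional data frame with `comparison`, `n_up`,
#'   `n_down`.
#' @param quadrant_counts optional data frame with `comparison`, `quadrant`,
#'   `n`; per-direction m6A-associated totals (Hyper-Up + Hypo-Up etc.) are
#'   derived from it.
#' @return list of class `run_report` with elements `methylation`,
#'   `expression`, `m6a_associated`.
#' @export
report_counts <- function(meth_summary, expr_summary = NULL,
                          quadrant_counts = NULL) {
  m <- meth_summary
  m$total <- m$n_hyper + m$n_hypo
  m$pct_hyper <- ifelse(m$total > 0,
                        round_half_up(100 * m$n_hyper / m$total, 1), NA_real_)
  m$pct_hypo <- ifelse(m$total > 0,
                       round_half_up(100 * m$n_hypo / m$total, 1), NA_real_)
  m$undefined <- m$total == 0
  out <- list(methylation = m)
  if (!is.null(expr_summary)) {
    e <- expr_summary
    e$total <- e$n_up + e$n_down
    out$expression <- e
  }
  if (!is.null(quadrant_counts)) {
    q <- quadrant_counts
    agg <- function(cmp, quads) sum(q$n[q$comparison == cmp & q$quadrant %in% quads])
    cmps <- unique(q$comparison)
    out$m6a_associated <- data.frame(
      comparison = cmps,
      n_up = vapply(cmps, agg, numeric(1), quads = c("Hyper-Up", "Hypo-Up")),
      n_down = vapply(cmps, agg, numeric(1), quads = c("Hyper-Down", "Hypo-Down")),
      n_total = vapply(cmps, agg, numeric(1), quads = quadrant_levels),
      row.names = NULL)
  }
  class(out) <- "run_report"
  out
}
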
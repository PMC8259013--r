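#' Run the full analysis pipeline
#'
#' Orchestrates quantification, per-comparison differential methylation and
#' expression, quadrant integration, cross-comparison concordance,
#' quadrant-group pathway enrichment, lncRNA context classification,
#' sign-flip selection and cis-gene linkage, and writes every output table
#' plus `report.json` to `out_dir`. Outputs are a pure function of
#' (inputs, config).
#'
#' @param input a [simulate_dataset()] result or a directory readable by
#'   [read_dataset()].
#' @param out_dir output directory.
#' @param config named list of options: `fc_up`, `fc_down`, `alpha`,
#'   `expression_mode` ("total"/"supernatant"), `universe_mode`,
#'   `cis_window`, `bidirectional_gap`, `comparisons` (list of
#'   c(condition, reference); default all later-vs-earlier group pairs),
#'   `intensity_floor`.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = list()) {
  if (is.character(input)) input <- read_dataset(input,
                                                 floor = config$intensity_floor %||% 1)
  thresholds <- diff_thresholds(config$fc_up %||% 1.5,
                                config$fc_down %||% 0.7,
                                config$alpha %||% 0.05)
  arrays <- input$arrays
  groups <- unique(arrays$samples$group)
  comparisons <- config$comparisons %||% {
    idx <- which(upper.tri(diag(length(groups))), arr.ind = TRUE)
    lapply(seq_len(nrow(idx)),
           function(i) c(groups[idx[i, 2]], groups[idx[i, 1]]))
  }
  for (cmp in comparisons) {
    if (!all(cmp %in% groups))
      stopf("comparison references unknown group: %s",
            paste(setdiff(cmp, groups), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  stage <- "quantify"
  report <- list(thresholds = unclass(thresholds),
                 expression_mode = config$expression_mode %||% "total")
  tryCatch({
    quant <- quantify(arrays, expression_mode = config$expression_mode %||% "total")
    write_matrix_tsv(quant$methylation, p("methylation.tsv"))
    write_matrix_tsv(quant$expression, p("expression.tsv"))
    write_tsv(quant$factors, p("normalization_factors.tsv"))

    stage <- "differential"
    records <- list()
    summaries <- list()
    for (cmp in comparisons) {
      nm <- paste(cmp[1], "vs", cmp[2])
      for (measure in c("methylation", "expression")) {
        rec <- run_comparison(quant, cmp[1], cmp[2], measure, thresholds)
        records[[nm]][[measure]] <- rec
        summaries[[length(summaries) + 1L]] <- differential_summary(rec)
        write_tsv(as.data.frame(rec),
                  p(sprintf("differential_%s_%s.tsv", safe(nm), measure)))
      }
    }
    summaries <- do.call(rbind, summaries)
    report$differential <- summaries

    diff_tx <- unique(unlist(lapply(records, function(r)
      r$methylation$transcript_id[r$methylation$call != "none"])))
    if (length(diff_tx) >= 2) {
      anno <- quant$annotation
      probes <- anno$probe_id[match(diff_tx, anno$transcript_id)]
      cl <- hierarchical_cluster(quant$methylation[probes, , drop = FALSE])
      jsonlite::write_json(
        list(row_order = cl$row_order, col_order = cl$col_order,
             col_tree = cluster_tree_list(cl$col_tree)),
        p("clustering.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    stage <- "integrate"
    quadrants <- list()
    qc_rows <- list()
    for (nm in names(records)) {
      qa <- assign_quadrants(records[[nm]]$methylation,
                             records[[nm]]$expression)
      quadrants[[nm]] <- qa
      write_tsv(as.data.frame(qa), p(sprintf("quadrants_%s.tsv", safe(nm))))
      cnt <- attr(qa, "counts")
      qc_rows[[nm]] <- data.frame(comparison = nm,
                                  quadrant = rownames(cnt),
                                  n = as.integer(rowSums(cnt)))
    }
    quadrant_counts <- do.call(rbind, qc_rows)
    rownames(quadrant_counts) <- NULL

    conc <- NULL
    if (length(comparisons) >= 2) {
      a <- quadrants[[1]]
      b <- quadrants[[length(quadrants)]]
      conc <- concordance(a, b)
      ct <- as.data.frame.matrix(conc$table)
      ct <- cbind(quadrant_a = rownames(ct), ct)
      write_tsv(ct, p(sprintf("concordance_%s__%s.tsv",
                              safe(conc$comparison_a), safe(conc$comparison_b))))
      report$concordance <- list(comparison_a = conc$comparison_a,
                                 comparison_b = conc$comparison_b,
                                 n_both = conc$n_both,
                                 n_opposite = conc$n_opposite,
                                 fraction_opposite = conc$fraction_opposite)
    }

    meth_sum <- summaries[summaries$measure == "methylation", ]
    expr_sum <- summaries[summaries$measure == "expression", ]
    meth_in <- data.frame(comparison = meth_sum$comparison,
                          rna_class = meth_sum$rna_class,
                          n_hyper = meth_sum$n_up, n_hypo = meth_sum$n_down)
    expr_in <- stats::aggregate(cbind(n_up, n_down) ~ comparison, expr_sum, sum)
    counts_report <- report_counts(meth_in, expr_in,
                                   quadrant_counts[quadrant_counts$quadrant !=
                                                     "unassociated", ])
    report$counts <- counts_report

    stage <- "enrich"
    sets <- input$gene_sets
    if (!is.null(sets)) {
      universe <- build_universe(input$annotation, sets,
                                 config$universe_mode %||% "array_genesets")
      report$enrichment <- list()
      for (nm in names(quadrants)) {
        enr <- enrich_quadrant_groups(quadrants[[nm]], sets, universe)
        for (g in names(enr)) {
          write_tsv(enr[[g]],
                    p(sprintf("enrichment_%s_%s.tsv", g, safe(nm))))
          report$enrichment[[nm]][[g]] <- list(
            n_significant = sum(enr[[g]]$significant),
            top_set = if (nrow(enr[[g]])) enr[[g]]$set[1] else NA)
        }
      }
    }

    stage <- "cis"
    lnc <- input$annotation[input$annotation$rna_class == "lncRNA", ]
    if (nrow(lnc) > 0 && !is.null(input$gene_models)) {
      ctx <- classify_context(lnc, input$gene_models,
                              config$bidirectional_gap %||% 1000)
      write_tsv(ctx, p("lnc_context.tsv"))
      report$lnc_context <- as.list(table(ctx$context))
      if (length(comparisons) >= 2) {
        flips <- select_signflip_lncrnas(
          records[[1]]$methylation,
          records[[length(records)]]$methylation)
        write_tsv(data.frame(
          transcript_id = c(flips$hyper_then_hypo, flips$hypo_then_hyper),
          pattern = rep(c("hyper_then_hypo", "hypo_then_hyper"),
                        c(length(flips$hyper_then_hypo),
                          length(flips$hypo_then_hyper)))),
          p("signflip_lncrnas.tsv"))
        report$signflip <- list(
          hyper_then_hypo = length(flips$hyper_then_hypo),
          hypo_then_hyper = length(flips$hypo_then_hyper))
        sel <- lnc[lnc$transcript_id %in% flips$hyper_then_hypo, ]
        if (nrow(sel) > 0) {
          links <- find_cis_genes(sel, input$gene_models,
                                  config$cis_window %||% 300000,
                                  config$bidirectional_gap %||% 1000)
          write_tsv(as.data.frame(links), p("cis_links.tsv"))
          lde <- link_to_de(links, records[[1]]$expression)
          report$cis <- list(n_links = nrow(links),
                             n_lncrnas_with_de_neighbor = lde$n_lncrnas,
                             n_de_genes = length(lde$de_genes),
                             n_up_genes = lde$n_up_genes,
                             n_down_genes = lde$n_down_genes)
          if (!is.null(sets) && length(lde$de_genes) > 0) {
            cis_enr <- enrich(lde$de_genes, sets,
                              build_universe(input$annotation, sets,
                                             config$universe_mode %||% "array_genesets"))
            write_tsv(cis_enr, p("enrichment_cis_de_genes.tsv"))
            report$cis$n_enriched_pathways <- sum(cis_enr$significant)
          }
        }
      }
    }
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
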
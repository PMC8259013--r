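#' Simulation configuration
#'
#' Parameters of the in-silico epitranscriptomic array. Defaults emulate the
#' design of a rat mRNA + lncRNA m6A array (three microglial phenotype groups,
#' three replicates each, spike-in controls shared by both channels) at
#' reduced scale: ~3000 transcripts instead of ~38,000.
#'
#' @param n_mrna number of mRNA probes (one probe per transcript).
#' @param n_lncrna number of lncRNA probes.
#' @param n_spikein number of spike-in control probes (present in both
#'   channels; at least 2, since normalization averages over them).
#' @param groups ordered phenotype group labels.
#' @param n_replicates samples per group.
#' @param baseline_log2_mean,baseline_log2_sd log2 abundance distribution.
#' @param base_methylation_alpha,base_methylation_beta shape parameters of the
#'   Beta distribution of baseline methylation fractions.
#' @param planted_effects `NULL` for the default planted-effect panel (see
#'   [default_planted_effects()]), a zero-row data frame for no effects, or a
#'   data frame as returned by [planted_effect()].
#' @param array_effect_sd per-sample-per-channel log2 scaling spread (what the
#'   spike-ins are there to remove).
#' @param noise_log2_sd multiplicative measurement noise (log2 sd), applied
#'   independently to each measured intensity.
#' @param n_pathways,pathway_size,n_enriched_pathways gene-set layout for
#'   [simulate_gene_sets()].
#' @param seed integer master seed; all stages derive their streams from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 2200, n_lncrna = 800, n_spikein = 24,
                       groups = c("M0-L", "M1-L", "M2-L"), n_replicates = 3,
                       baseline_log2_mean = 10, baseline_log2_sd = 1.5,
                       base_methylation_alpha = 2, base_methylation_beta = 2,
                       planted_effects = NULL,
                       array_effect_sd = 0.3, noise_log2_sd = 0.1,
                       n_pathways = 40, pathway_size = 25,
                       n_enriched_pathways = 3, seed = 1L) {
  if (n_mrna < 1) stopf("n_mrna must be >= 1 (at least one mRNA probe)")
  if (n_lncrna < 1) stopf("n_lncrna must be >= 1")
  if (n_spikein < 2) stopf("n_spikein must be >= 2 (normalization averages spike-ins)")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (anyDuplicated(groups) || length(groups) < 2)
    stopf("groups must be >= 2 unique labels")
  if (baseline_log2_sd < 0 || array_effect_sd < 0 || noise_log2_sd < 0)
    stopf("standard deviations must be >= 0")
  if (base_methylation_alpha <= 0 || base_methylation_beta <= 0)
    stopf("methylation Beta shape parameters must be > 0")
  if (n_pathways < 1 || pathway_size < 2 || n_enriched_pathways < 0)
    stopf("invalid gene-set layout")
  cfg <- list(
    n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
    n_spikein = as.integer(n_spikein), groups = as.character(groups),
    n_replicates = as.integer(n_replicates),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    base_methylation_alpha = base_methylation_alpha,
    base_methylation_beta = base_methylation_beta,
    planted_effects = planted_effects,
    array_effect_sd = array_effect_sd, noise_log2_sd = noise_log2_sd,
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    n_enriched_pathways = as.integer(n_enriched_pathways),
    seed = as.integer(seed))
  if (!is.null(cfg$planted_effects)) validate_effects(cfg$planted_effects, cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Declare one planted effect
#'
#' @param transcript_id target transcript.
#' @param target_group group label receiving the shift.
#' @param effect_kind `"methylation_shift"` (logit-scale shift of the
#'   methylation fraction) or `"expression_shift"` (log2 abundance shift).
#' @param magnitude finite nonzero shift.
#' @return one-row data frame; rbind rows to build a panel.
#' @export
planted_effect <- function(transcript_id, target_group, effect_kind, magnitude) {
  data.frame(transcript_id = transcript_id, target_group = target_group,
             effect_kind = effect_kind, magnitude = magnitude)
}

validate_effects <- function(effects, config, annotation = NULL) {
  if (nrow(effects) == 0) return(invisible(effects))
  need <- c("transcript_id", "target_group", "effect_kind", "magnitude")
  if (!all(need %in% names(effects))) stopf("planted_effects missing columns")
  if (!all(effects$target_group %in% config$groups))
    stopf("planted effect targets unknown group: %s",
          paste(setdiff(effects$target_group, config$groups), collapse = ", "))
  if (!all(effects$effect_kind %in% c("methylation_shift", "expression_shift")))
    stopf("unknown effect_kind")
  if (any(!is.finite(effects$magnitude)) || any(effects$magnitude == 0))
    stopf("effect magnitudes must be finite and nonzero")
  if (!is.null(annotation)) {
    known <- annotation$transcript_id[annotation$rna_class != "spikein"]
    if (!all(effects$transcript_id %in% known))
      stopf("planted effect on unknown transcript")
  }
  invisible(effects)
}

## ---- genome / annotation -------------------------------------------------

lnc_classes <- c("exon_overlap", "intron_overlap", "natural_antisense",
                 "intronic_antisense", "bidirectional", "intergenic")

#' Generate the synthetic probe annotation and gene models
#'
#' Lays out one coding gene (>= 3 exons) per mRNA probe on synthetic
#' chromosomes and places lncRNA probes so that, cycling through placements,
#' every genomic context class (exon overlap, intron overlap, natural
#' antisense, intronic antisense, bidirectional, intergenic) is realized at
#' least once whenever `n_lncrna >= 6`. Coordinates in the annotation table
#' are 0-based half-open (BED convention). Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_annotation` with elements `annotation` (data
#'   frame: probe_id, transcript_id, gene_symbol, rna_class, chrom, start,
#'   end, strand), `gene_models` (a `GRanges` with `name` and absolute-exon
#'   `exons` metadata), and `lnc_context` (the intended context class and
#'   host gene of every lncRNA).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  n_g <- config$n_mrna
  genes_per_chrom <- 110L
  chrom_idx <- (seq_len(n_g) - 1L) %/% genes_per_chrom + 1L
  within_idx <- (seq_len(n_g) - 1L) %% genes_per_chrom + 1L
  chrom <- paste0("chr", chrom_idx)
  len <- sample(seq(12000L, 28000L, by = 400L), n_g, replace = TRUE)
  start <- 100000L + (within_idx - 1L) * 140000L
  end <- start + len
  strand <- rep(c("+", "-"), length.out = n_g)
  symbol <- sprintf("Gene%04d", seq_len(n_g))
  n_ex <- sample(3:5, n_g, replace = TRUE)

  exon_list <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    eL <- round(0.06 * len[i])
    rel <- round(seq(0, len[i] - eL, length.out = n_ex[i]))
    exon_list[[i]] <- IRanges::IRanges(start = start[i] + rel + 1L,
                                       width = eL)  # 1-based
  }
  gene_models <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  S4Vectors::mcols(gene_models)$name <- symbol
  S4Vectors::mcols(gene_models)$exons <- methods::as(exon_list, "IRangesList")

  mrna <- data.frame(
    transcript_id = sprintf("mrna_%05d", seq_len(n_g)),
    gene_symbol = symbol, rna_class = "mRNA",
    chrom = chrom, start = start, end = end, strand = strand)

  n_l <- config$n_lncrna
  if (n_l < 6)
    warning("n_lncrna < 6: not every lncRNA context class is realized",
            call. = FALSE)
  cls <- lnc_classes[(seq_len(n_l) - 1L) %% 6L + 1L]
  host <- (seq_len(n_l) - 1L) %% n_g + 1L
  ls <- le <- integer(n_l)
  lstr <- character(n_l)
  opp <- function(s) if (s == "+") "-" else "+"
  for (j in seq_len(n_l)) {
    h <- host[j]
    ex <- exon_list[[h]]                       # 1-based absolute
    ex2s0 <- IRanges::start(ex)[2] - 1L        # 0-based start of exon 2
    ex1e0 <- IRanges::end(ex)[1]               # 0-based exclusive end exon 1
    g0s <- start[h]; g0e <- end[h]; sg <- strand[h]
    switch(cls[j],
      exon_overlap = { ls[j] <- ex2s0 - 300L; le[j] <- ex2s0 + 500L; lstr[j] <- sg },
      intron_overlap = { ls[j] <- ex1e0 + 200L; le[j] <- ex1e0 + 900L; lstr[j] <- sg },
      natural_antisense = { ls[j] <- ex2s0 - 300L; le[j] <- ex2s0 + 500L; lstr[j] <- opp(sg) },
      intronic_antisense = { ls[j] <- ex1e0 + 200L; le[j] <- ex1e0 + 900L; lstr[j] <- opp(sg) },
      bidirectional = if (sg == "+") {
        ls[j] <- g0s - 1200L; le[j] <- g0s - 300L; lstr[j] <- "-"
      } else {
        ls[j] <- g0e + 300L; le[j] <- g0e + 1200L; lstr[j] <- "+"
      },
      intergenic = { ls[j] <- g0e + 50000L; le[j] <- g0e + 52000L; lstr[j] <- "+" })
  }
  lnc <- data.frame(
    transcript_id = sprintf("lnc_%05d", seq_len(n_l)),
    gene_symbol = sprintf("lnc_%05d", seq_len(n_l)), rna_class = "lncRNA",
    chrom = chrom[host], start = ls, end = le, strand = lstr)

  n_s <- config$n_spikein
  spike <- data.frame(
    transcript_id = sprintf("spike_%02d", seq_len(n_s)),
    gene_symbol = sprintf("SPIKE%02d", seq_len(n_s)), rna_class = "spikein",
    chrom = "chrC", start = (seq_len(n_s) - 1L) * 1000L,
    end = (seq_len(n_s) - 1L) * 1000L + 200L, strand = "+")

  annotation <- rbind(mrna, lnc, spike)
  annotation <- cbind(probe_id = sprintf("P%06d", seq_len(nrow(annotation))),
                      annotation)
  rownames(annotation) <- NULL
  out <- list(annotation = annotation, gene_models = gene_models,
              lnc_context = data.frame(transcript_id = lnc$transcript_id,
                                       context = cls,
                                       host_gene = symbol[host]))
  class(out) <- "sim_annotation"
  out
}

## ---- planted effects ------------------------------------------------------

#' Default planted-effect panel
#'
#' Plants methylation shifts (logit scale, |magnitude| in \[2, 3\]) on 4% / 2%
#' of transcripts targeting the second / third group, and expression shifts
#' (log2 scale, |magnitude| in \[1, 2\]) on 6% / 4% of the remaining
#' transcripts. Half of the methylation targets additionally receive an
#' expression shift on the same group, cycling through the four sign
#' combinations so that all methylation-by-expression quadrants are
#' populated.
#'
#' @param ann a [simulate_annotation()] result.
#' @param config the [sim_config()].
#' @return effects data frame (transcript_id, target_group, effect_kind,
#'   magnitude).
#' @export
default_planted_effects <- function(ann, config) {
  set.seed(derive_seed(config$seed, "effects"))
  tx <- ann$annotation$transcript_id[ann$annotation$rna_class != "spikein"]
  n_tx <- length(tx)
  cond <- config$groups[-1]
  n_meth <- pmax(1L, round(c(0.04, 0.02) * n_tx))[seq_along(cond)]
  n_expr <- pmax(1L, round(c(0.06, 0.04) * n_tx))[seq_along(cond)]
  pick <- sample(tx, sum(n_meth))
  meth_tx <- split(pick, rep(seq_along(cond), n_meth))
  rest <- setdiff(tx, pick)
  pick2 <- sample(rest, sum(n_expr))
  expr_tx <- split(pick2, rep(seq_along(cond), n_expr))

  rows <- list()
  combo_sign <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (g in seq_along(cond)) {
    mt <- meth_tx[[g]]
    m_sign <- sample(c(-1, 1), length(mt), replace = TRUE)
    # joint expression shifts on half the methylation targets, cycling
    # through the four sign combinations so every quadrant is populated
    joint <- mt[seq_len(length(mt) %/% 2)]
    cmb <- combo_sign[(seq_along(joint) - 1L) %% 4L + 1L, , drop = FALSE]
    m_sign[match(joint, mt)] <- cmb[, 1]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = mt, target_group = cond[g],
      effect_kind = "methylation_shift",
      magnitude = m_sign * runif(length(mt), 2, 3))
    if (length(joint)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = joint, target_group = cond[g],
        effect_kind = "expression_shift",
        magnitude = cmb[, 2] * runif(length(joint), 1, 2))
    }
    et <- expr_tx[[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = et, target_group = cond[g],
      effect_kind = "expression_shift",
      magnitude = sample(c(-1, 1), length(et), TRUE) * runif(length(et), 1, 2))
  }
  eff <- do.call(rbind, rows)
  rownames(eff) <- NULL
  validate_effects(eff, config, ann$annotation)
  eff
}

## ---- intensities ----------------------------------------------------------

#' Generate two-channel intensities with known ground truth
#'
#' For transcript t in sample s of group g, the linear abundance is
#' `A = 2^(baseline + expression shifts)`; the IP channel measures
#' `A * m * 2^(array effect + noise)` and the supernatant channel
#' `A * (1 - m) * 2^(array effect + noise)`, with `m` the true methylation
#' fraction after logit-scale shifts. Array effects are shared by every probe
#' (spike-ins included) of one sample/channel, which is what makes spike-in
#' normalization identifiable; measurement noise is independent per measured
#' intensity. Spike-ins have fixed known abundance.
#'
#' @param config a [sim_config()].
#' @param ann result of [simulate_annotation()].
#' @param baseline_methylation,baseline_log2_abundance optional numeric
#'   vectors (one value per non-spike-in transcript) overriding the random
#'   baselines, for controlled experiments.
#' @return list of class `sim_intensities`: `arrays` (a
#'   [two_channel_set()]) and `truth` (list: `m_true` and `log2_abund`
#'   transcript-by-group matrices, `effects`, `spike_log2`).
#' @export
simulate_intensities <- function(config, ann, baseline_methylation = NULL,
                                 baseline_log2_abundance = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"))
  effects <- config$planted_effects %||% default_planted_effects(ann, config)
  validate_effects(effects, config, ann$annotation)
  set.seed(derive_seed(config$seed, "intensities"))

  anno <- ann$annotation
  tx <- anno$transcript_id[anno$rna_class != "spikein"]
  n_t <- length(tx)
  groups <- config$groups

  samples <- data.frame(
    sample_id = paste0(rep(groups, each = config$n_replicates), "_R",
                       rep(seq_len(config$n_replicates), length(groups))),
    group = rep(groups, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(groups)))

  # baseline methylation: Beta(a, b); transcripts targeted by a methylation
  # shift draw from the same Beta truncated to [0.2, 0.6], so a >= 2-logit
  # shift translates into a detectable percent-modification fold change
  meth_targets <- unique(effects$transcript_id[
    effects$effect_kind == "methylation_shift"])
  if (is.null(baseline_methylation)) {
    m0 <- rbeta(n_t, config$base_methylation_alpha, config$base_methylation_beta)
    idx <- which(tx %in% meth_targets)
    while (length(bad <- idx[m0[idx] < 0.2 | m0[idx] > 0.6]) > 0) {
      m0[bad] <- rbeta(length(bad), config$base_methylation_alpha,
                       config$base_methylation_beta)
    }
  } else {
    stopifnot(length(baseline_methylation) == n_t)
    m0 <- baseline_methylation
  }
  if (is.null(baseline_log2_abundance)) {
    a0 <- rnorm(n_t, config$baseline_log2_mean, config$baseline_log2_sd)
  } else {
    stopifnot(length(baseline_log2_abundance) == n_t)
    a0 <- baseline_log2_abundance
  }

  m_logit <- matrix(logit(m0), n_t, length(groups),
                    dimnames = list(tx, groups))
  a_true <- matrix(a0, n_t, length(groups), dimnames = list(tx, groups))
  for (i in seq_len(nrow(effects))) {
    r <- effects[i, ]
    if (r$effect_kind == "methylation_shift") {
      m_logit[r$transcript_id, r$target_group] <-
        m_logit[r$transcript_id, r$target_group] + r$magnitude
    } else {
      a_true[r$transcript_id, r$target_group] <-
        a_true[r$transcript_id, r$target_group] + r$magnitude
    }
  }
  m_true <- inv_logit(m_logit)

  n_s <- nrow(samples)
  ae <- matrix(rnorm(2 * n_s, 0, config$array_effect_sd), n_s, 2,
               dimnames = list(samples$sample_id, c("IP", "SUP")))
  spike_log2 <- seq(8, 12, length.out = config$n_spikein)
  spike_ids <- anno$probe_id[anno$rna_class == "spikein"]

  probe_of <- setNames(anno$probe_id, anno$transcript_id)
  ip <- sup <- matrix(NA_real_, nrow(anno), n_s,
                      dimnames = list(anno$probe_id, samples$sample_id))
  for (s in seq_len(n_s)) {
    g <- samples$group[s]
    A <- 2^a_true[, g]
    m <- m_true[, g]
    eps_ip <- rnorm(n_t, 0, config$noise_log2_sd)
    eps_sup <- rnorm(n_t, 0, config$noise_log2_sd)
    ip[probe_of[tx], s] <- A * m * 2^(ae[s, "IP"] + eps_ip)
    sup[probe_of[tx], s] <- A * (1 - m) * 2^(ae[s, "SUP"] + eps_sup)
    ip[spike_ids, s] <- 2^(spike_log2 + ae[s, "IP"] +
                             rnorm(length(spike_ids), 0, config$noise_log2_sd))
    sup[spike_ids, s] <- 2^(spike_log2 + ae[s, "SUP"] +
                              rnorm(length(spike_ids), 0, config$noise_log2_sd))
  }

  arrays <- two_channel_set(ip, sup, samples, spike_ids,
                            annotation = anno)
  truth <- list(m_true = m_true, log2_abund = a_true, effects = effects,
                spike_log2 = spike_log2, array_effects = ae)
  out <- list(arrays = arrays, truth = truth)
  class(out) <- "sim_intensities"
  out
}

#' Ground-truth differential labels for one comparison
#'
#' Derives per-transcript truth labels from the planted effects: the net
#' logit (methylation) or log2 (expression) shift of condition minus
#' reference determines hyper/hypo (up/down); zero net shift is `none`.
#'
#' @param truth the `truth` element of [simulate_intensities()].
#' @param condition,reference group labels.
#' @param min_magnitude only count planted shifts with absolute magnitude at
#'   least this large (smaller shifts become `none`).
#' @return data frame: transcript_id, meth_truth, expr_truth.
#' @export
truth_labels <- function(truth, condition, reference, min_magnitude = 0) {
  tx <- rownames(truth$m_true)
  eff <- truth$effects
  lab <- function(kind, up, down) {
    net <- setNames(numeric(length(tx)), tx)
    e <- eff[eff$effect_kind == kind & abs(eff$magnitude) >= min_magnitude, ,
             drop = FALSE]
    for (i in seq_len(nrow(e))) {
      sgn <- if (e$target_group[i] == condition) 1 else
        if (e$target_group[i] == reference) -1 else 0
      net[e$transcript_id[i]] <- net[e$transcript_id[i]] + sgn * e$magnitude[i]
    }
    ifelse(net > 0, up, ifelse(net < 0, down, "none"))
  }
  data.frame(transcript_id = tx,
             meth_truth = lab("methylation_shift", "hyper", "hypo"),
             expr_truth = lab("expression_shift", "up", "down"),
             row.names = NULL)
}

## ---- gene sets ------------------------------------------------------------

#' Generate synthetic gene sets (GMT-style pathways)
#'
#' Builds `n_pathways` pathways over the coding-gene symbols of the array.
#' The first `n_enriched_pathways` are seeded with genes that carry joint
#' planted methylation + expression effects (cycling through quadrant sign
#' combinations), so that quadrant-group enrichment has recoverable planted
#' pathways; the rest are random draws.
#'
#' @param ann a [simulate_annotation()] result.
#' @param config the [sim_config()].
#' @param effects planted-effect data frame (defaults to the config's panel).
#' @return named list of symbol vectors, with attributes `enriched`
#'   (names of the planted pathways) and `universe`.
#' @export
simulate_gene_sets <- function(ann, config, effects = NULL) {
  set.seed(derive_seed(config$seed, "genesets"))
  anno <- ann$annotation
  effects <- effects %||% config$planted_effects %||%
    default_planted_effects(ann, config)
  universe <- anno$gene_symbol[anno$rna_class == "mRNA"]
  symbol_of <- setNames(anno$gene_symbol, anno$transcript_id)

  meth <- effects[effects$effect_kind == "methylation_shift", ]
  expr <- effects[effects$effect_kind == "expression_shift", ]
  joint <- merge(meth, expr, by = c("transcript_id", "target_group"),
                 suffixes = c("_m", "_e"))
  joint <- joint[symbol_of[joint$transcript_id] %in% universe, ]
  combos <- list(c(-1, 1), c(1, 1), c(-1, -1), c(1, -1))  # hypo-up first

  sets <- list()
  n_seed <- min(15L, config$pathway_size - 5L)
  for (k in seq_len(config$n_enriched_pathways)) {
    cmb <- combos[[(k - 1L) %% 4L + 1L]]
    pool <- unique(symbol_of[joint$transcript_id[
      sign(joint$magnitude_m) == cmb[1] & sign(joint$magnitude_e) == cmb[2]]])
    core <- sample(pool, min(n_seed, length(pool)))
    filler <- sample(setdiff(universe, core), config$pathway_size - length(core))
    sets[[sprintf("PATH_%04d", k)]] <- sample(c(core, filler))
  }
  for (k in seq_len(config$n_pathways - config$n_enriched_pathways) +
       config$n_enriched_pathways) {
    sets[[sprintf("PATH_%04d", k)]] <- sample(universe, config$pathway_size)
  }
  attr(sets, "enriched") <- sprintf("PATH_%04d",
                                    seq_len(config$n_enriched_pathways))
  attr(sets, "universe") <- unique(universe)
  sets
}

## ---- qPCR -----------------------------------------------------------------

#' Generate a synthetic qPCR Ct table with known truth
#'
#' Ct values are constructed as `Ct = c0 - log2(abundance) + noise`. The
#' table holds, per group and replicate: cDNA Cts for each target and for a
#' GAPDH-like reference gene (for 2^-ddCt expression), and input/IP tube Cts
#' for MeRIP percent-input quantification. With `sd_ct = 0` and a true fold
#' of 2, ddCt is exactly -1.
#'
#' @param fold true expression fold change of the target in each non-reference
#'   group versus the first group (recycled over groups).
#' @param percent_ip true percent-input m6A enrichment per group.
#' @param groups group labels (first is the control/reference condition).
#' @param n_replicates replicates per group.
#' @param sd_ct Ct measurement noise sd (cycles).
#' @param c0 calibration constant relating log2 abundance to Ct.
#' @param input_fraction fraction of material reserved as MeRIP input.
#' @param target,reference_gene gene names used in the table.
#' @param seed RNG seed.
#' @return list of class `sim_qpcr`: `ct` (data frame: sample_id, group,
#'   tube, target, is_reference, ct, input_fraction) and `truth`.
#' @export
simulate_qpcr <- function(fold = 2, percent_ip = c(10, 25),
                          groups = c("M0-L", "M1-L"), n_replicates = 3,
                          sd_ct = 0.2, c0 = 20, input_fraction = 0.1,
                          target = "TargetA", reference_gene = "Gapdh",
                          seed = 1L) {
  stopifnot(input_fraction > 0, input_fraction <= 1, n_replicates >= 1)
  set.seed(derive_seed(seed, "qpcr"))
  fold_g <- c(1, rep(fold, length.out = length(groups) - 1L))
  pct_g <- rep(percent_ip, length.out = length(groups))
  ref_abund <- 2^10
  base_abund <- 2^8
  rows <- list()
  for (g in seq_along(groups)) {
    for (r in seq_len(n_replicates)) {
      sid <- paste0(groups[g], "_R", r)
      tgt_ab <- base_abund * fold_g[g]
      ct <- function(ab) c0 - log2(ab) + rnorm(1, 0, sd_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = groups[g],
        tube = c("cdna", "cdna", "input", "ip"),
        target = c(target, reference_gene, target, target),
        is_reference = c(FALSE, TRUE, FALSE, FALSE),
        ct = c(ct(tgt_ab), ct(ref_abund),
               ct(tgt_ab * input_fraction),
               ct(tgt_ab * pct_g[g] / 100)),
        input_fraction = c(NA, NA, input_fraction, input_fraction))
    }
  }
  out <- list(ct = do.call(rbind, rows),
              truth = list(fold = fold_g, percent_ip = pct_g,
                           groups = groups))
  class(out) <- "sim_qpcr"
  out
}

## ---- convenience ----------------------------------------------------------

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_annotation()], the planted-effect panel,
#' [simulate_intensities()] and [simulate_gene_sets()] from one config.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `config`, `annotation`,
#'   `gene_models`, `lnc_context`, `arrays`, `truth`, `gene_sets`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  effects <- config$planted_effects %||% default_planted_effects(ann, config)
  config$planted_effects <- effects
  sim <- simulate_intensities(config, ann)
  gene_sets <- simulate_gene_sets(ann, config, effects)
  out <- list(config = config, annotation = ann$annotation,
              gene_models = ann$gene_models, lnc_context = ann$lnc_context,
              arrays = sim$arrays, truth = sim$truth, gene_sets = gene_sets)
  class(out) <- "sim_dataset"
  out
}
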
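test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_mrna = 0), "n_mrna")
  expect_error(sim_config(n_spikein = 1), "n_spikein")
  expect_error(sim_config(groups = c("A", "A")), "unique")
  expect_error(sim_config(noise_log2_sd = -1), "deviations")
  expect_error(sim_config(base_methylation_alpha = 0), "shape")
  eff <- planted_effect("mrna_00001", "M9-L", "methylation_shift", 2)
  expect_error(sim_config(planted_effects = eff), "unknown group")
  eff2 <- planted_effect("mrna_00001", "M1-L", "methylation_shift", 0)
  expect_error(sim_config(planted_effects = eff2), "nonzero")
})

test_that("identical config and seed produce byte-identical dataset files", {
  cfg <- function() sim_config(n_mrna = 40, n_lncrna = 6, n_spikein = 4,
                               n_pathways = 6, seed = 3)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg()), d1)
  write_dataset(simulate_dataset(cfg()), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("channels conserve abundance when array effects and noise are off", {
  cfg <- sim_config(n_mrna = 60, n_lncrna = 8, n_spikein = 4,
                    array_effect_sd = 0, noise_log2_sd = 0,
                    planted_effects = data.frame(), seed = 4)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann)
  tx <- rownames(si$truth$m_true)
  probe <- setNames(ann$annotation$probe_id, ann$annotation$transcript_id)
  total <- si$arrays$ip[probe[tx], ] + si$arrays$sup[probe[tx], ]
  want <- 2^si$truth$log2_abund[, si$arrays$samples$group]
  expect_equal(unname(total), unname(want), tolerance = 1e-9)
})

test_that("a half-methylated transcript yields equal channels", {
  cfg <- sim_config(n_mrna = 10, n_lncrna = 6, n_spikein = 4,
                    array_effect_sd = 0, noise_log2_sd = 0,
                    planted_effects = data.frame(), seed = 4)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann,
                             baseline_methylation = rep(0.5, 16))
  tx <- rownames(si$truth$m_true)
  probe <- setNames(ann$annotation$probe_id, ann$annotation$transcript_id)
  expect_equal(si$arrays$ip[probe[tx], ], si$arrays$sup[probe[tx], ])
})

test_that("a planted +2 logit shift raises mean % modification in the target group", {
  eff <- planted_effect("mrna_00005", "M1-L", "methylation_shift", 2)
  cfg <- sim_config(n_mrna = 30, n_lncrna = 6, n_spikein = 4,
                    noise_log2_sd = 0, planted_effects = eff, seed = 6)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann)
  q <- quantify(si$arrays)
  probe <- ann$annotation$probe_id[ann$annotation$transcript_id == "mrna_00005"]
  m <- q$methylation[probe, ]
  grp <- q$samples$group
  expect_gt(mean(m[grp == "M1-L"]), mean(m[grp == "M0-L"]))
})

test_that("ground-truth labels are consistent with the planted effects", {
  eff <- rbind(planted_effect("mrna_00001", "M1-L", "methylation_shift", 2.5),
               planted_effect("mrna_00002", "M1-L", "methylation_shift", -2.5),
               planted_effect("mrna_00003", "M2-L", "expression_shift", 1.5))
  cfg <- sim_config(n_mrna = 10, n_lncrna = 6, n_spikein = 4,
                    planted_effects = eff, seed = 1)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann)
  tl <- truth_labels(si$truth, "M1-L", "M0-L")
  expect_equal(tl$meth_truth[tl$transcript_id == "mrna_00001"], "hyper")
  expect_equal(tl$meth_truth[tl$transcript_id == "mrna_00002"], "hypo")
  expect_equal(tl$expr_truth[tl$transcript_id == "mrna_00003"], "none")
  # condition in the reference slot flips the direction
  tl2 <- truth_labels(si$truth, "M2-L", "M1-L")
  expect_equal(tl2$meth_truth[tl2$transcript_id == "mrna_00001"], "hypo")
  expect_equal(tl2$expr_truth[tl2$transcript_id == "mrna_00003"], "up")
  # filtering by magnitude blanks small shifts
  tl3 <- truth_labels(si$truth, "M2-L", "M0-L", min_magnitude = 2)
  expect_equal(tl3$expr_truth[tl3$transcript_id == "mrna_00003"], "none")
})

test_that("fewer than six lncRNAs triggers a context-coverage warning", {
  expect_warning(simulate_annotation(sim_config(n_mrna = 10, n_lncrna = 3,
                                                n_spikein = 4, seed = 1)),
                 "context class")
})

test_that("the null generator is calibrated at alpha = 0.05", {
  # no planted effects: fraction of raw P < 0.05 (no FC filter) in band
  fr <- vapply(1:3, function(s) {
    cfg <- sim_config(n_mrna = 800, n_lncrna = 200, n_spikein = 24,
                      planted_effects = data.frame(), seed = s)
    si <- simulate_intensities(cfg, simulate_annotation(cfg))
    q <- quantify(si$arrays)
    rec <- run_comparison(q, "M1-L", "M0-L", "methylation")
    mean(rec$p < 0.05)
  }, numeric(1))
  expect_gte(mean(fr), 0.03)
  expect_lte(mean(fr), 0.07)
})

test_that("noise-free qPCR tables realize their constructed truth", {
  sq <- simulate_qpcr(fold = 2, sd_ct = 0, seed = 1)
  r <- qpcr_expression(sq$ct, "TargetA", treated = "M1-L", control = "M0-L")
  expect_equal(r$ddct, -1)
  expect_equal(r$fold, 2)
  sq0 <- simulate_qpcr(fold = 1, sd_ct = 0, seed = 1)
  r0 <- qpcr_expression(sq0$ct, "TargetA", treated = "M1-L", control = "M0-L")
  expect_equal(r0$ddct, 0)
  expect_equal(r0$fold, 1)
  # percent-input truth round-trips through the Ct construction
  pi <- qpcr_percent_input(sq$ct, "TargetA")
  expect_equal(pi$percent_input, rep(c(10, 25), each = 3), tolerance = 1e-12)
})
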
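test_that("spike-in normalization matches the element-wise formula", {
  set.seed(11)
  n_p <- 30; n_s <- 5
  spikes <- paste0("S", 1:4)
  probes <- c(paste0("P", 1:n_p), spikes)
  samples <- data.frame(sample_id = paste0("smp", 1:n_s),
                        group = rep(c("A", "B", "C"), length.out = n_s),
                        replicate = 1:n_s)
  ip <- matrix(2^runif(length(probes) * n_s, 4, 14), length(probes), n_s,
               dimnames = list(probes, samples$sample_id))
  sup <- matrix(2^runif(length(probes) * n_s, 4, 14), length(probes), n_s,
                dimnames = list(probes, samples$sample_id))
  x <- two_channel_set(ip, sup, samples, spikes)
  nm <- spikein_normalize(x)

  # brute-force recomputation in log2 arithmetic
  f <- matrix(NA_real_, n_s, 2)
  for (s in 1:n_s) {
    f[s, 1] <- mean(log2(ip[spikes, s]))
    f[s, 2] <- mean(log2(sup[spikes, s]))
  }
  fbar <- mean(f)
  for (s in 1:n_s) {
    for (p in probes) {
      expect_equal(log2(nm$norm_ip[p, s]), log2(ip[p, s]) - f[s, 1] + fbar)
      expect_equal(log2(nm$norm_sup[p, s]), log2(sup[p, s]) - f[s, 2] + fbar)
    }
  }
  # after normalization every array's spike-in mean log2 equals the grand mean
  expect_equal(unname(colMeans(log2(nm$norm_ip[spikes, ]))), rep(fbar, n_s))
  expect_equal(unname(colMeans(log2(nm$norm_sup[spikes, ]))), rep(fbar, n_s))
})

test_that("normalization equalizes arrays and is the identity at the grand mean", {
  samples <- data.frame(sample_id = c("a1", "a2"), group = c("A", "B"),
                        replicate = c(1, 1))
  probes <- c("P1", "S1", "S2")
  ip <- cbind(a1 = c(500, 1024, 1024), a2 = c(500, 256, 256))
  sup <- ip
  rownames(ip) <- rownames(sup) <- probes
  nm <- spikein_normalize(two_channel_set(ip, sup, samples, c("S1", "S2")))
  expect_equal(nm$grand_mean, 9)  # mean of log2(1024)=10 and log2(256)=8
  expect_equal(unname(colMeans(log2(nm$norm_ip[c("S1", "S2"), ]))), c(9, 9))

  # single array with spike-ins already at the grand mean: identity
  ip1 <- cbind(a1 = c(123.4, 512, 512))
  rownames(ip1) <- probes
  s1 <- data.frame(sample_id = "a1", group = "A", replicate = 1)
  nm1 <- spikein_normalize(two_channel_set(ip1, ip1, s1, c("S1", "S2")))
  expect_equal(nm1$norm_ip, ip1)
  expect_equal(nm1$norm_sup, ip1)
})

test_that("percent modification arithmetic, bounds and degenerate input", {
  expect_equal(percent_modification(matrix(3), matrix(3))[1], 50)
  expect_equal(percent_modification(matrix(0), matrix(7))[1], 0)
  expect_equal(percent_modification(matrix(3), matrix(1))[1], 75)
  z <- percent_modification(matrix(0), matrix(0))
  expect_equal(z[1], 0)
  expect_equal(attr(z, "n_zero"), 1)
  expect_error(percent_modification(matrix(1, 2, 2), matrix(1, 3, 2)),
               "shape mismatch")
  set.seed(2)
  a <- matrix(rexp(200), 20); b <- matrix(rexp(200), 20)
  m <- percent_modification(a, b)
  expect_true(all(m >= 0 & m <= 100))
})

test_that("expression level modes", {
  e <- expression_level(matrix(3), matrix(1), "total")
  expect_equal(e[1], 4)
  expect_equal(expression_level(matrix(3), matrix(1), "supernatant")[1], 1)
  expect_error(expression_level(matrix(3), matrix(1), "median"))
})

test_that("rescaling one sample leaves % modification and expression ratios unchanged", {
  sim <- small_sim(seed = 3)
  q1 <- quantify(sim$arrays)
  ip2 <- sim$arrays$ip; sup2 <- sim$arrays$sup
  ip2[, 4] <- ip2[, 4] * 7.3
  sup2[, 4] <- sup2[, 4] * 7.3
  q2 <- quantify(two_channel_set(ip2, sup2, sim$arrays$samples,
                                 sim$arrays$spikein_ids,
                                 annotation = sim$annotation))
  expect_equal(q2$methylation, q1$methylation, tolerance = 1e-12)
  # expression changes only by one global factor (all ratios preserved)
  ratio <- q2$expression / q1$expression
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("noise-free quantification recovers truth exactly", {
  cfg <- sim_config(n_mrna = 80, n_lncrna = 12, n_spikein = 8,
                    noise_log2_sd = 0, planted_effects = data.frame(),
                    seed = 5)
  ann <- simulate_annotation(cfg)
  si <- simulate_intensities(cfg, ann)
  q <- quantify(si$arrays)
  tx <- rownames(si$truth$m_true)
  probe <- setNames(ann$annotation$probe_id, ann$annotation$transcript_id)
  want <- 100 * si$truth$m_true[, q$samples$group]
  expect_equal(unname(q$methylation[probe[tx], ]), unname(want),
               tolerance = 1e-10)

  # with array effects also disabled, expression equals true linear abundance
  cfg0 <- sim_config(n_mrna = 80, n_lncrna = 12, n_spikein = 8,
                     noise_log2_sd = 0, array_effect_sd = 0,
                     planted_effects = data.frame(), seed = 5)
  si0 <- simulate_intensities(cfg0, simulate_annotation(cfg0))
  q0 <- quantify(si0$arrays)
  expect_equal(unname(q0$expression[probe[tx], ]),
               unname(2^si0$truth$log2_abund[, q0$samples$group]),
               tolerance = 1e-10)
})

test_that("two_channel_set validates its inputs", {
  samples <- data.frame(sample_id = "a1", group = "A", replicate = 1)
  m <- matrix(1, 2, 1, dimnames = list(c("P1", "P1"), "a1"))
  expect_error(two_channel_set(m, m, samples, "P1"), "duplicated probe id: P1")
  m2 <- matrix(1, 2, 1, dimnames = list(c("P1", "S1"), "a2"))
  expect_error(two_channel_set(m2, m2, samples, "S1"), "absent from sheet: a2")
  m3 <- matrix(1, 2, 1, dimnames = list(c("P1", "S1"), "a1"))
  expect_error(two_channel_set(m3, m3, samples, character(0)), "non-empty")
})
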
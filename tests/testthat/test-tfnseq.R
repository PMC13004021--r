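test_that("relative abundance is exact arithmetic on hand matrices", {
  counts <- rbind(g1 = c(100, 50), g2 = c(900, 1950))
  colnames(counts) <- c("t=0", "t=2")
  aset <- relative_abundance(counts, min_count0 = 1)
  expect_equal(unname(aset$rel["g1", ]), c(1, 0.25))
  expect_equal(unname(aset$totals), c(1000, 2000))
  # counts proportional to totals -> trajectories identically 1
  counts2 <- rbind(a = c(10, 20, 40), b = c(30, 60, 120))
  colnames(counts2) <- c("t=0", "t=2", "t=4")
  aset2 <- relative_abundance(counts2, min_count0 = 1)
  expect_true(all(abs(aset2$rel - 1) < 1e-12))
})

test_that("low-count genes are dropped with a reason, never silently", {
  counts <- rbind(ok = c(100, 90, 80), low = c(5, 4, 3),
                  zero = c(0, 2, 1))
  colnames(counts) <- c("t=0", "t=2", "t=4")
  aset <- relative_abundance(counts, min_count0 = 20)
  expect_equal(aset$gene_id, "ok")
  expect_setequal(aset$dropped$gene_id, c("low", "zero"))
  expect_match(aset$dropped$reason[aset$dropped$gene_id == "zero"],
               "zero count")
  expect_error(relative_abundance(counts[, c(2, 1, 3)],
                                  times = c(2, 0, 4)), "t = 0")
})

test_that("noise-free piecewise trajectory is fit exactly", {
  times <- c(0, 2, 4, 6)
  r <- c(1, 1, 0.25, 0.0625)
  counts <- exact_library(r, times)
  aset <- relative_abundance(counts, min_count0 = 1)
  calls <- call_mutants(aset, k0 = 1.2, normalization = "reference",
                        reference_genes = sprintf("ref%d", 1:9))
  focal <- calls[calls$gene_id == "focal", ]
  expect_equal(focal$model, "overabundance")
  expect_equal(focal$T_hat, 2, tolerance = 0.02)
  # decline rate: r falls 4x per 2 h after T
  fit <- fit_models(aset$counts["focal", ], aset$totals, aset$times,
                    norm = attr(calls, "norm"))
  expect_equal(fit$delta_o, log(2), tolerance = 1e-3)
  # halving time of the piecewise trajectory: log-linear crossing at 3 h
  expect_equal(focal$halving_time, 3, tolerance = 0.02)
})

test_that("flat and purely declining trajectories select their models", {
  times <- c(0, 2, 4, 6)
  # sufficiency: r = exp(-0.5 t) from t = 0
  counts <- exact_library(exp(-0.5 * times), times, focal0 = 4000)
  aset <- relative_abundance(counts, min_count0 = 1)
  calls <- call_mutants(aset, k0 = 1.2, normalization = "reference",
                        reference_genes = sprintf("ref%d", 1:9))
  focal <- calls[calls$gene_id == "focal", ]
  expect_equal(focal$model, "sufficiency")
  expect_equal(focal$log10_o, 0)
  expect_equal(focal$o, 1)
  # a flat gene (nonessential control) selects no effect
  counts2 <- exact_library(rep(1, 4), times)
  aset2 <- relative_abundance(counts2, min_count0 = 1)
  calls2 <- call_mutants(aset2, k0 = 1.2, normalization = "reference",
                         reference_genes = sprintf("ref%d", 1:9))
  focal2 <- calls2[calls2$gene_id == "focal", ]
  expect_equal(focal2$model, "no_effect")
  expect_true(is.na(focal2$log10_o))
})

test_that("model log-likelihoods are nested for every trajectory", {
  set.seed(42)
  truth <- demo_truth(n_genes = 40, seed = 7)
  cfg <- sim_config(depth = 1e5, n_genes = 40, seed = 7)
  counts <- simulate_tfnseq(truth, cfg)
  aset <- relative_abundance(counts, min_count0 = 1)
  for (i in seq_along(aset$gene_id)) {
    fit <- fit_models(aset$counts[i, ], aset$totals, aset$times)
    ll <- fit$loglik
    expect_lte(ll["no_effect"], ll["sufficiency"] + 1e-9)
    expect_lte(ll["sufficiency"], ll["overabundance"] + 1e-9)
  }
})

test_that("small-instance MLEs agree with the brute-force grid oracle", {
  times <- c(0, 2, 4, 6)
  totals <- rep(50, 4)
  cases <- list(c(20, 18, 8, 3), c(30, 12, 5, 2), c(15, 15, 14, 16),
                c(25, 20, 20, 6))
  for (counts in cases) {
    fit <- fit_models(counts, totals, times, delta_max = 5)
    oracle <- brute_force_fit(counts, totals, times)
    expect_equal(unname(fit$loglik["overabundance"]), oracle$loglik,
                 tolerance = 0.01)
    # same optimum location up to grid resolution (likelihood can be
    # flat in T between timepoints at these depths)
    r_fit <- exp(-fit$delta_o * pmax(0, times - fit$T_hat))
    r_orc <- exp(-oracle$delta * pmax(0, times - oracle$T))
    expect_equal(r_fit, r_orc, tolerance = 0.05)
  }
})

test_that("overabundance follows the arrest-time exponential exactly", {
  calls <- data.frame(gene_id = c("a", "b", "c"),
                      model = c("overabundance", "overabundance",
                                "sufficiency"),
                      T_hat = c(2, 1.5, 0))
  out <- overabundance(calls, k0 = 1)
  expect_equal(out$o[1], exp(2))
  expect_equal(out$o[3], 1)
  out2 <- overabundance(calls, k0 = log(10))
  expect_equal(log10(out2$o[2]), 1.5)
  expect_error(overabundance(calls), "k0")
})

test_that("deep-library recovery is within one timepoint spacing", {
  truth <- rbind(
    data.frame(gene_id = "target", essential = TRUE,
               class_true = "overabundance", log10_o_true = 1.5,
               mu_m = 10),
    data.frame(gene_id = sprintf("bg%02d", 1:19), essential = FALSE,
               class_true = "no_effect", log10_o_true = 0, mu_m = 10))
  cfg <- sim_config(k0 = 1.2, depth = 1e6, seed = 6)
  counts <- simulate_tfnseq(truth, cfg, seed = 6)
  aset <- relative_abundance(counts)
  calls <- call_mutants(aset, k0 = 1.2)
  target <- calls[calls$gene_id == "target", ]
  T_true <- 1.5 * log(10) / 1.2
  expect_equal(target$model, "overabundance")
  expect_lt(abs(target$T_hat - T_true), 2)
  expect_equal(target$log10_o, 1.5, tolerance = 0.15)
})

test_that("arrest times at or beyond the window edge are censored", {
  mk <- function(l10) rbind(
    data.frame(gene_id = "late", essential = TRUE,
               class_true = "overabundance", log10_o_true = l10,
               mu_m = 10),
    data.frame(gene_id = sprintf("bg%02d", 1:19), essential = FALSE,
               class_true = "no_effect", log10_o_true = 0, mu_m = 10))
  cfg <- sim_config(k0 = 1.2, depth = 1e6, seed = 13)
  # arrest at 11.5 h: inside the window but within the censoring margin
  aset <- relative_abundance(simulate_tfnseq(mk(11.5 * 1.2 / log(10)),
                                             cfg, seed = 13))
  late <- call_mutants(aset, k0 = 1.2)
  late <- late[late$gene_id == "late", ]
  expect_true(late$model != "overabundance" || late$censored)
  # arrest beyond the last timepoint: indistinguishable from no effect,
  # never reported as an overabundance point estimate
  aset2 <- relative_abundance(simulate_tfnseq(mk(14 * 1.2 / log(10)),
                                              cfg, seed = 14))
  far <- call_mutants(aset2, k0 = 1.2)
  far <- far[far$gene_id == "late", ]
  expect_true(far$model %in% c("no_effect", "sufficiency") ||
                far$censored)
})

test_that("replicate combination reports mean, spread, and discord", {
  a <- data.frame(gene_id = c("x", "y"), model = "overabundance",
                  log10_o = c(1.4, 2.0), stringsAsFactors = FALSE)
  b <- data.frame(gene_id = c("x", "y"), model = c("overabundance",
                                                   "sufficiency"),
                  log10_o = c(1.6, 0), stringsAsFactors = FALSE)
  out <- replicate_error(list(a, b))
  x <- out[out$gene_id == "x", ]
  expect_equal(x$log10_o_mean, 1.5)
  expect_equal(x$log10_o_sd, sd(c(1.4, 1.6)))
  expect_false(x$discordant)
  expect_true(out$discordant[out$gene_id == "y"])
  # identical replicates have zero spread
  out2 <- replicate_error(list(a, a))
  expect_equal(out2$log10_o_sd, c(0, 0))
  # missing genes are flagged, not imputed
  out3 <- replicate_error(list(a, b[1, ]))
  expect_true(out3$missing_in_some[out3$gene_id == "y"])
  expect_error(replicate_error(list(a)), "2 replicates")
})

test_that("replicate spread at high depth is on the reported error scale", {
  truth <- rbind(
    data.frame(gene_id = "target", essential = TRUE,
               class_true = "overabundance", log10_o_true = 1.5,
               mu_m = 10),
    data.frame(gene_id = sprintf("bg%02d", 1:19), essential = FALSE,
               class_true = "no_effect", log10_o_true = 0, mu_m = 10))
  cfg <- sim_config(k0 = 1.2, depth = 1e6, seed = 1)
  calls <- lapply(1:2, function(k) {
    aset <- relative_abundance(simulate_tfnseq(truth, cfg, seed = k))
    call_mutants(aset, k0 = 1.2)
  })
  out <- replicate_error(calls)
  tg <- out[out$gene_id == "target", ]
  expect_equal(tg$log10_o_mean, 1.5, tolerance = 0.2)
  # order-of-magnitude check: spread ~ 0.1, not ~ 1
  expect_lt(tg$log10_o_sd, 0.3)
})

test_that("parametric bootstrap statistics bracket the observed null", {
  times <- c(0, 2, 4, 6)
  totals <- rep(5000, 4)
  counts <- c(250, 248, 252, 249)
  stats <- bootstrap_null(counts, totals, times, null = "no_effect",
                          n_boot = 30, seed = 3)
  expect_length(stats, 30)
  expect_true(all(stats >= 0))
  # the bootstrap null is on the same scale as the chi-squared reference
  expect_lt(stats::median(stats), stats::qchisq(0.9, df = 2))
})
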
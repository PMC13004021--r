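test_that("sim_config enforces its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(k0 = -1), "k0")
  expect_error(sim_config(timepoints = c(2, 4)), "include 0")
  expect_error(sim_config(timepoints = c(0, 4, 2)), "increasing")
  expect_error(sim_config(partition_cv = 0.6), "partition_cv")
  expect_error(sim_config(residual_rate = 1), "residual_rate")
})

test_that("expected cell numbers follow the piecewise-exponential model", {
  # one overabundant gene with log10 o = 1 at k0 = ln 10 arrests at 1 h
  truth <- data.frame(
    gene_id = c("flat", "oa"), essential = c(FALSE, TRUE),
    class_true = c("no_effect", "overabundance"),
    log10_o_true = c(0, 1), mu_m = c(1, 1))
  cfg <- sim_config(k0 = log(10), timepoints = c(0, 0.5, 1, 1.5, 2),
                    residual_rate = 0)
  n <- expected_cells(truth, cfg)
  expect_equal(attr(n, "arrest_time")[["oa"]], 1)
  expect_equal(n["oa", "t=1"], n["oa", "t=2"])  # stops growing at 1 h
  expect_equal(n["oa", "t=1"], 10)
  expect_equal(unname(n["flat", ]), exp(log(10) * cfg$timepoints))
})

test_that("a single no-effect gene has relative abundance identically 1", {
  truth <- data.frame(gene_id = "only", essential = FALSE,
                      class_true = "no_effect", log10_o_true = 0, mu_m = 1)
  cfg <- sim_config(depth = 1000)
  counts <- simulate_tfnseq(truth, cfg)
  aset <- relative_abundance(counts, min_count0 = 1)
  expect_equal(unname(aset$rel[1, ]), rep(1, length(cfg$timepoints)))
})

test_that("library counts close multinomially and are seed-reproducible", {
  truth <- demo_truth(n_genes = 40, seed = 3)
  cfg <- sim_config(depth = 5e4, n_genes = 40, seed = 3)
  c1 <- simulate_tfnseq(truth, cfg, seed = 11)
  c2 <- simulate_tfnseq(truth, cfg, seed = 11)
  c3 <- simulate_tfnseq(truth, cfg, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_equal(unname(colSums(c1)), rep(5e4, length(cfg$timepoints)))
})

test_that("demo truth carries the anchor genes and class split", {
  truth <- demo_truth(n_genes = 200, seed = 1)
  anchors <- truth[match(c("dnaA", "dnaN", "ftsN", "murA"),
                         truth$gene_id), ]
  expect_equal(anchors$mu_m, c(30, 49, 20, 26))
  expect_equal(anchors$log10_o_true, c(0, 1.5, 2.6, 0.7))
  ess <- truth[truth$essential, ]
  expect_equal(nrow(ess), 100)
  expect_equal(sum(ess$class_true == "overabundance"), 69)
  expect_equal(sum(ess$class_true == "sufficiency"), 31)
  expect_true(all(truth$class_true[!truth$essential] == "no_effect"))
})

test_that("RNA-seq counts follow message-number proportions", {
  truth <- data.frame(gene_id = c("a", "b"), essential = TRUE,
                      class_true = "sufficiency", log10_o_true = 0,
                      mu_m = c(1, 3))
  counts <- simulate_rnaseq(truth, total_reads = 1e6, seed = 4)
  expect_equal(sum(counts), 1e6)
  expect_equal(unname(counts["b"] / 1e6), 0.75, tolerance = 0.005)
  # anchors recoverable from deep sampling
  anchors <- demo_truth(seed = 1)[1:4, ]
  deep <- simulate_rnaseq(anchors, total_reads = 2e6, seed = 5)
  mu_hat <- message_number(deep, M_total = sum(anchors$mu_m))
  expect_equal(unname(mu_hat), anchors$mu_m, tolerance = 0.02)
})

test_that("microcolony with o = 1 arrests at t = 0", {
  cfg <- sim_config(k0 = 1, partition_cv = 0, residual_rate = 0.05)
  tree <- simulate_microcolony(1, 1, cfg, t_max = 1)
  first <- tree$tracks[tree$tracks$frame == 0, ]
  expect_true(all(first$arrested))
  expect_equal(nrow(tree$edges), 0)  # no division before arrest
})

test_that("o = 8 noise-free colony arrests after exactly 3 synchronous divisions", {
  cfg <- sim_config(k0 = 1, partition_cv = 0, residual_rate = 0.05)
  tree <- simulate_microcolony(8, 1, cfg, t_max = 4)
  ids <- unique(tree$tracks$cell_id)
  leaves <- setdiff(ids, tree$edges$parent)
  expect_length(leaves, 8)
  expect_length(ids, 15)  # 1 + 2 + 4 + 8
  # every leaf is three divisions from the progenitor
  depth_of <- function(id) {
    d <- 0
    while (id %in% tree$edges$child) {
      id <- tree$edges$parent[tree$edges$child == id]
      d <- d + 1
    }
    d
  }
  expect_true(all(vapply(leaves, depth_of, numeric(1)) == 3))
  # leaves arrest in the same generation, at the dilution time ln(8)/k0
  last <- tree$tracks[tree$tracks$frame == max(tree$tracks$frame), ]
  expect_true(all(last$arrested))
  arr_t <- vapply(leaves, function(id) {
    tk <- tree$tracks[tree$tracks$cell_id == id, ]
    min(tk$time_h[tk$arrested])
  }, numeric(1))
  expect_lt(max(arr_t) - min(arr_t), 1e-9)
})

test_that("protein amount is conserved and the dilution law is exact", {
  cfg <- sim_config(k0 = 1, partition_cv = 0, residual_rate = 0.05,
                    seed = 2)
  tree <- simulate_microcolony(10, 1, cfg, t_max = 3)
  amount <- tapply(tree$tracks$fluor_total, tree$tracks$frame, sum)
  expect_equal(max(abs(amount / amount[1] - 1)), 0, tolerance = 1e-12)
  # Eq-style dilution law: common concentration C(t)/C0 = V0/V(t)
  rc <- relative_concentration(tree)
  conc <- as.numeric(tapply(tree$tracks$conc_true, tree$tracks$frame,
                            function(v) v[1]))
  expect_equal(conc / conc[1], rc$rel_conc, tolerance = 1e-12)
})

test_that("amount conservation survives partitioning noise", {
  cfg <- sim_config(k0 = 1, partition_cv = 0.05, seed = 8)
  tree <- simulate_microcolony(10, 1, cfg, t_max = 3.5, seed = 21)
  amount <- tapply(tree$tracks$fluor_total, tree$tracks$frame, sum)
  expect_equal(max(abs(amount / amount[1] - 1)), 0, tolerance = 1e-12)
  # when every cell has arrested, total area ~ o x progenitor area:
  # each cell arrests at area P/C_A and residual growth is slow
  last <- tree$tracks[tree$tracks$frame == max(tree$tracks$frame), ]
  expect_true(all(last$arrested))
  expect_equal(sum(last$area), 10, tolerance = 0.1)
})

test_that("microcolony simulation is deterministic given a seed", {
  cfg <- sim_config(k0 = 1, partition_cv = 0.1, seed = 5)
  t1 <- simulate_microcolony(6, 1, cfg, t_max = 2.5, seed = 5)
  t2 <- simulate_microcolony(6, 1, cfg, t_max = 2.5, seed = 5)
  expect_identical(t1$tracks, t2$tracks)
})

test_that("generator input validation rejects bad calls", {
  cfg <- sim_config()
  expect_error(simulate_microcolony(0.5, 1, cfg, t_max = 1), "o_true")
  expect_error(simulate_microcolony(2, 1, cfg, t_max = 0.01), "frame")
  truth <- demo_truth(n_genes = 10)
  expect_error(simulate_rnaseq(truth, total_reads = 0), "total_reads")
})

test_that("the overdispersion knob widens count noise but keeps closure", {
  truth <- demo_truth(n_genes = 50, seed = 6)
  base <- sim_config(depth = 1e5, seed = 6)
  od <- sim_config(depth = 1e5, seed = 6, overdispersion = 0.5)
  reps_var <- function(cfg) {
    fr <- vapply(1:8, function(k) {
      counts <- simulate_tfnseq(truth, cfg, seed = 100 + k)
      counts[1, 2] / sum(counts[, 2])
    }, numeric(1))
    stats::var(fr)
  }
  expect_gt(reps_var(od), reps_var(base))
  counts <- simulate_tfnseq(truth, od, seed = 1)
  expect_equal(unname(colSums(counts)), rep(1e5, ncol(counts)))
  expect_error(sim_config(overdispersion = -1), "overdispersion")
})

test_that("count and track TSV round-trips preserve the data", {
  truth <- demo_truth(n_genes = 20, seed = 2)
  cfg <- sim_config(depth = 1e4, seed = 2)
  counts <- simulate_tfnseq(truth, cfg)
  tf <- tempfile(fileext = ".tsv")
  write_counts_tsv(counts, tf)
  back <- read_counts_tsv(tf)
  expect_equal(unname(back), unname(counts))
  expect_equal(attr(back, "times"), cfg$timepoints)

  tree <- simulate_microcolony(4, 1, sim_config(k0 = 1, seed = 3),
                               t_max = 2)
  tf2 <- tempfile(fileext = ".tsv")
  write_tracks_tsv(tree, tf2)
  tree2 <- read_tracks_tsv(tf2)
  expect_s3_class(tree2, "lineage_tree")
  expect_equal(tree2$tracks$area, tree$tracks$area, tolerance = 1e-9)
  expect_equal(sort(unique(tree2$tracks$cell_id)),
               sort(unique(tree$tracks$cell_id)))
})
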
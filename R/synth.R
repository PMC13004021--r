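# Synthetic-data generators: library-scale depletion counts, single-cell
# microcolonies, and RNA-seq counts, with the statistical structure the
# downstream estimators assume.

#' Simulation configuration
#'
#' Bundles the parameters shared by the simulators: the wild-type growth
#' rate, the library sampling schedule and depth, and the single-cell
#' partitioning/arrest parameters.
#'
#' @param k0 Wild-type exponential growth rate (1/h).  The default 1.2/h
#'   corresponds to a doubling time of about 35 min.
#' @param timepoints Sampling times in hours; must be strictly increasing
#'   and include 0.  Default: fractions collected every 2 h from 0 to 12 h.
#' @param depth Sequencing reads per timepoint.
#' @param n_genes Library size used by the default truth generators.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param partition_cv Coefficient of variation of the division asymmetry
#'   (dimensionless, on the area split fraction); must lie in [0, 0.5).
#' @param residual_rate Post-arrest growth rate as a fraction of `k0`;
#'   must lie in [0, 1).  Arrest is modeled as a sharp change from `k0` to
#'   `residual_rate * k0` at the threshold concentration.
#' @param frame_dt Imaging frame interval in hours (default 2 min).
#' @param overdispersion Extra-multinomial read-count dispersion
#'   (variance of a unit-mean gamma perturbation of the sampling
#'   weights); reserved knob, default 0 (plain multinomial).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(k0 = 1.2,
                       timepoints = seq(0, 12, by = 2),
                       depth = 1e6,
                       n_genes = 200,
                       seed = 1L,
                       partition_cv = 0.05,
                       residual_rate = 0.05,
                       frame_dt = 1 / 30,
                       overdispersion = 0) {
  if (!is.numeric(k0) || length(k0) != 1L || !is.finite(k0) || k0 <= 0)
    stop("k0 must be a single finite positive number", call. = FALSE)
  if (length(timepoints) < 2L || any(!is.finite(timepoints)) ||
      any(diff(timepoints) <= 0) || timepoints[1] != 0)
    stop("timepoints must be strictly increasing and include 0", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (partition_cv < 0 || partition_cv >= 0.5)
    stop("partition_cv must lie in [0, 0.5)", call. = FALSE)
  if (residual_rate < 0 || residual_rate >= 1)
    stop("residual_rate must lie in [0, 1)", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be positive", call. = FALSE)
  if (overdispersion < 0)
    stop("overdispersion must be >= 0", call. = FALSE)
  structure(list(k0 = k0, timepoints = timepoints, depth = depth,
                 n_genes = as.integer(n_genes), seed = as.integer(seed),
                 partition_cv = partition_cv, residual_rate = residual_rate,
                 frame_dt = frame_dt, overdispersion = overdispersion),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: k0 =", x$k0, "/h;",
      length(x$timepoints), "timepoints to", max(x$timepoints), "h;",
      "depth", format(x$depth, big.mark = ","), "reads;",
      "partition_cv", x$partition_cv, "; residual_rate", x$residual_rate, "\n")
  invisible(x)
}

#' Demonstration gene truth table
#'
#' Builds a gene truth table for end-to-end demonstrations: half the genes
#' are nonessential with no depletion phenotype; among the essential half,
#' 69% are overabundant and 31% sufficient.  Four anchor genes carry the
#' measured transcription levels (messages per cell cycle) of dnaA (30),
#' dnaN (49), ftsN (20), and murA (26), with dnaA sufficient and the other
#' three overabundant.
#'
#' @param n_genes Total library size (>= 8).
#' @param frac_essential Fraction of genes that are essential.
#' @param frac_overabundant Fraction of essential genes in the
#'   overabundance class (remainder are sufficiency).
#' @param log10_o_range Range from which overabundant genes' true
#'   log10 overabundance is drawn uniformly.
#' @param seed Integer seed.
#'
#' @return A data frame with columns `gene_id`, `essential`, `class_true`
#'   (`no_effect`, `sufficiency`, or `overabundance`), `log10_o_true`, and
#'   `mu_m` (messages per cell cycle).
#' @export
demo_truth <- function(n_genes = 200, frac_essential = 0.5,
                       frac_overabundant = 0.69,
                       log10_o_range = c(0.5, 2.5), seed = 1L) {
  stopifnot(n_genes >= 8)
  set.seed(seed)
  n_ess <- round(n_genes * frac_essential)
  n_oa  <- round(n_ess * frac_overabundant)
  anchors <- data.frame(
    gene_id = c("dnaA", "dnaN", "ftsN", "murA"),
    essential = TRUE,
    class_true = c("sufficiency", "overabundance", "overabundance",
                   "overabundance"),
    log10_o_true = c(0, 1.5, 2.6, 0.7),
    mu_m = c(30, 49, 20, 26),
    stringsAsFactors = FALSE)
  n_rest_ess <- n_ess - nrow(anchors)
  n_rest_oa <- n_oa - sum(anchors$class_true == "overabundance")
  rest_class <- rep(c("overabundance", "sufficiency"),
                    c(n_rest_oa, n_rest_ess - n_rest_oa))
  ess <- data.frame(
    gene_id = sprintf("ess%03d", seq_len(n_rest_ess)),
    essential = TRUE,
    class_true = rest_class,
    log10_o_true = ifelse(rest_class == "overabundance",
                          stats::runif(n_rest_ess, log10_o_range[1],
                                       log10_o_range[2]), 0),
    mu_m = 10^stats::runif(n_rest_ess, -0.5, 2.5),
    stringsAsFactors = FALSE)
  non <- data.frame(
    gene_id = sprintf("non%03d", seq_len(n_genes - n_ess)),
    essential = FALSE,
    class_true = "no_effect",
    log10_o_true = 0,
    mu_m = 10^stats::runif(n_genes - n_ess, -0.5, 2.5),
    stringsAsFactors = FALSE)
  truth <- rbind(anchors, ess, non)
  rownames(truth) <- NULL
  validate_truth(truth)
  truth
}

#' RLTO-optimal gene truth table
#'
#' Draws message numbers log-uniformly and sets each essential gene's true
#' overabundance to the RLTO optimum for its message number, perturbed by
#' lognormal noise.  Used to emulate a genome whose expression program
#' follows the robustness-load trade-off.
#'
#' @param n_genes Number of (essential) genes.
#' @param epsilon Relative metabolic cost per unit of threshold-level
#'   expression used for the optimum.
#' @param mu_range Range of message numbers (log-uniform draw).
#' @param sd_log10 Lognormal spread (in log10 units) around the optimum.
#' @param seed Integer seed.
#' @return A truth data frame as in [demo_truth()].
#' @export
rlto_truth <- function(n_genes = 200, epsilon = 1e-4,
                       mu_range = c(0.5, 1000), sd_log10 = 0.3, seed = 1L) {
  set.seed(seed)
  mu <- 10^stats::runif(n_genes, log10(mu_range[1]), log10(mu_range[2]))
  o_star <- vapply(mu, function(m) optimize_o(m, epsilon)$o_star,
                   numeric(1))
  l10 <- pmax(0, log10(o_star) + stats::rnorm(n_genes, 0, sd_log10))
  truth <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    essential = TRUE,
    class_true = ifelse(l10 > 0.05, "overabundance", "sufficiency"),
    log10_o_true = ifelse(l10 > 0.05, l10, 0),
    mu_m = mu,
    stringsAsFactors = FALSE)
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  req <- c("gene_id", "essential", "class_true", "log10_o_true", "mu_m")
  if (!all(req %in% names(truth)))
    stop("truth table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(truth) == 0) stop("truth table is empty", call. = FALSE)
  if (anyDuplicated(truth$gene_id))
    stop("duplicated gene_id in truth table", call. = FALSE)
  ok_class <- truth$class_true %in% c("no_effect", "sufficiency",
                                      "overabundance")
  if (!all(ok_class)) stop("unknown class_true value", call. = FALSE)
  if (any(truth$log10_o_true < 0) || any(!is.finite(truth$log10_o_true)))
    stop("log10_o_true must be finite and >= 0", call. = FALSE)
  if (any(truth$class_true == "no_effect" & truth$essential))
    stop("no_effect genes must be nonessential", call. = FALSE)
  if (any(truth$mu_m <= 0)) stop("mu_m must be positive", call. = FALSE)
  invisible(truth)
}

#' Expected cell numbers under the piecewise-exponential depletion model
#'
#' Each mutant grows at the wild-type rate `k0` until its arrest time and at
#' `residual_rate * k0` afterwards.  Arrest times are `T = log10_o *
#' ln(10) / k0` for overabundant genes (the inverse of `o = exp(k0 T)`),
#' `T = 0` for sufficiency genes, and infinite for no-effect genes.
#'
#' @param truth Truth table (see [demo_truth()]).
#' @param cfg A [sim_config()].
#' @param times Times (h) at which to evaluate; defaults to
#'   `cfg$timepoints`.
#' @return A genes x times matrix of expected cell numbers, normalized to
#'   1 at t = 0, with an `"arrest_time"` attribute.
#' @export
expected_cells <- function(truth, cfg, times = cfg$timepoints) {
  validate_truth(truth)
  T_arr <- ifelse(truth$class_true == "no_effect", Inf,
                  ifelse(truth$class_true == "sufficiency", 0,
                         truth$log10_o_true * log(10) / cfg$k0))
  n <- outer(T_arr, times, function(Ti, t)
    exp(cfg$k0 * pmin(t, Ti) +
          cfg$residual_rate * cfg$k0 * pmax(0, t - Ti)))
  if (any(!is.finite(n)))
    stop("non-finite expected cell number; check rates and arrest times",
         call. = FALSE)
  dimnames(n) <- list(truth$gene_id, sprintf("t=%g", times))
  attr(n, "arrest_time") <- stats::setNames(T_arr, truth$gene_id)
  n
}

#' Simulate a library-scale depletion count matrix
#'
#' Reads at each timepoint are drawn multinomially over genes with
#' probabilities proportional to the expected cell numbers of
#' [expected_cells()], at fixed depth per timepoint.
#'
#' @param truth Truth table.
#' @param cfg A [sim_config()].
#' @param seed Seed for this draw (defaults to `cfg$seed`); pass distinct
#'   seeds for replicate libraries.
#' @return Integer count matrix (genes x timepoints) with `gene_id`
#'   rownames and `t=<hours>` column names; column sums equal `cfg$depth`.
#' @export
simulate_tfnseq <- function(truth, cfg, seed = cfg$seed) {
  n <- expected_cells(truth, cfg)
  set.seed(seed)
  od <- if (is.null(cfg$overdispersion)) 0 else cfg$overdispersion
  counts <- vapply(seq_len(ncol(n)), function(j) {
    w <- n[, j]
    if (od > 0)
      w <- w * stats::rgamma(length(w), shape = 1 / od, rate = 1 / od)
    stats::rmultinom(1, cfg$depth, w)[, 1]
  }, integer(nrow(n)))
  counts <- matrix(counts, nrow = nrow(n), dimnames = dimnames(n))
  attr(counts, "times") <- cfg$timepoints
  counts
}

#' Simulate an RNA-seq count vector
#'
#' Reads are multinomial over genes with probabilities proportional to the
#' true message numbers `mu_m`.
#'
#' @param truth Truth table.
#' @param total_reads Total reads to draw (>= 1).
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `total_reads`.
#' @export
simulate_rnaseq <- function(truth, total_reads, seed = 1L) {
  validate_truth(truth)
  if (total_reads < 1) stop("total_reads must be >= 1", call. = FALSE)
  if (all(truth$mu_m == 0)) stop("all mu_m are zero", call. = FALSE)
  set.seed(seed)
  stats::setNames(stats::rmultinom(1, total_reads, truth$mu_m)[, 1],
                  truth$gene_id)
}

# Truncated-Gaussian division asymmetry: `center` is the mean split
# fraction, the standard deviation is `0.5 * partition_cv`.
split_fraction <- function(partition_cv, center = 0.5,
                           lower = 0.2, upper = 0.8) {
  if (partition_cv == 0) return(center)
  sdev <- 0.5 * partition_cv
  repeat {
    f <- stats::rnorm(1, center, sdev)
    if (f > lower && f < upper) return(f)
  }
}

#' Simulate a knockout-depletion microcolony
#'
#' Event-driven simulation of a lineage growing from a single progenitor
#' whose target protein synthesis stops at t = 0.  The progenitor starts
#' with concentration `o_true` times the arrest threshold.  Each cell grows
#' exponentially in area at rate `k0` while its concentration exceeds the
#' threshold and at `residual_rate * k0` below it, divides when its area
#' doubles, and partitions protein between daughters in proportion to
#' daughter area perturbed by partitioning noise: the area split fraction
#' is Gaussian around 0.5 (truncated to (0.2, 0.8)) and the protein split
#' fraction is Gaussian around the area split fraction, both with
#' coefficient of variation `partition_cv`.  Protein amount is conserved
#' exactly across every division.
#'
#' @param o_true True overabundance (>= 1) of the progenitor.
#' @param k0 Wild-type areal growth rate (1/h).
#' @param cfg A [sim_config()] (supplies `partition_cv`, `residual_rate`,
#'   `frame_dt`).
#' @param t_max Duration of the simulated movie (h); must cover at least
#'   one frame.
#' @param c_arrest Threshold concentration (arbitrary units; default 1).
#' @param a0 Progenitor area at t = 0 (area units).
#' @param max_cells Safety cap on the number of cells.
#' @param seed Seed for partitioning noise (defaults to `cfg$seed`).
#'
#' @return A `lineage_tree`: a list with `tracks` (data frame: `cell_id`,
#'   `parent_id`, `frame`, `time_h`, `area`, `fluor_total`, `conc_true`,
#'   `arrested`), `edges` (parent/child), `progenitor_id`, and the
#'   generator's ground truth (`o_true`, `k0`, `c_arrest`, `frame_dt`).
#' @export
simulate_microcolony <- function(o_true, k0, cfg, t_max,
                                 c_arrest = 1, a0 = 1,
                                 max_cells = 4096, seed = cfg$seed) {
  if (!is.finite(o_true) || o_true < 1)
    stop("o_true must be finite and >= 1", call. = FALSE)
  if (t_max < cfg$frame_dt)
    stop("t_max is shorter than one frame interval", call. = FALSE)
  set.seed(seed)
  res <- cfg$residual_rate * k0
  queue <- list(list(id = "c0001", parent = NA_character_, tb = 0,
                     ab = a0, P = o_true * c_arrest * a0))
  done <- list()
  edges <- list()
  next_id <- 2L
  while (length(queue) > 0) {
    cell <- queue[[1]]
    queue <- queue[-1]
    a_arr <- cell$P / c_arrest  # area at which concentration hits threshold
    t_arr <- if (a_arr <= cell$ab * (1 + 1e-12)) cell$tb else
      cell$tb + log(a_arr / cell$ab) / k0
    a_div <- 2 * cell$ab
    if (a_arr >= a_div) {
      t_div <- cell$tb + log(2) / k0
    } else {
      a_at_arr <- cell$ab * exp(k0 * (t_arr - cell$tb))
      t_div <- if (res > 0) t_arr + log(a_div / a_at_arr) / res else Inf
    }
    cell$t_arr <- t_arr
    cell$t_div <- t_div
    done[[cell$id]] <- cell
    if (t_div <= t_max) {
      if (length(done) + length(queue) + 2L > max_cells)
        stop("max_cells exceeded; reduce t_max or raise max_cells",
             call. = FALSE)
      f_area <- split_fraction(cfg$partition_cv)
      f_prot <- split_fraction(cfg$partition_cv, center = f_area,
                               lower = 0.05, upper = 0.95)
      f_a <- c(f_area, 1 - f_area)
      f_p <- c(f_prot, 1 - f_prot)
      for (d in 1:2) {
        id <- sprintf("c%04d", next_id)
        next_id <- next_id + 1L
        queue[[length(queue) + 1L]] <-
          list(id = id, parent = cell$id, tb = t_div,
               ab = f_a[d] * a_div, P = f_p[d] * cell$P)
        edges[[length(edges) + 1L]] <- c(cell$id, id)
      }
    }
  }
  frames <- seq(0, t_max, by = cfg$frame_dt)
  tracks <- do.call(rbind, lapply(done, function(cell) {
    t_end <- min(cell$t_div, t_max)
    sel <- frames >= cell$tb - 1e-12 &
      (if (cell$t_div <= t_max) frames < cell$t_div - 1e-12
       else frames <= t_max + 1e-12)
    t <- frames[sel]
    if (length(t) == 0) return(NULL)
    area <- ifelse(t <= cell$t_arr,
                   cell$ab * exp(k0 * (t - cell$tb)),
                   cell$ab * exp(k0 * (cell$t_arr - cell$tb)) *
                     exp(res * (t - cell$t_arr)))
    data.frame(cell_id = cell$id, parent_id = cell$parent,
               frame = which(sel) - 1L, time_h = t, area = area,
               fluor_total = cell$P, conc_true = cell$P / area,
               arrested = t >= cell$t_arr - 1e-12,
               stringsAsFactors = FALSE)
  }))
  rownames(tracks) <- NULL
  tracks <- tracks[order(tracks$cell_id, tracks$frame), ]
  edges <- if (length(edges) > 0)
    data.frame(parent = vapply(edges, `[`, "", 1),
               child = vapply(edges, `[`, "", 2),
               stringsAsFactors = FALSE)
  else data.frame(parent = character(), child = character(),
                  stringsAsFactors = FALSE)
  structure(list(progenitor_id = "c0001", tracks = tracks, edges = edges,
                 o_true = o_true, k0 = k0, c_arrest = c_arrest,
                 frame_dt = cfg$frame_dt, t_max = t_max),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", length(unique(x$tracks$cell_id)), "cells,",
      nrow(x$edges), "division edges,",
      max(x$tracks$frame) + 1, "frames (dt =", x$frame_dt, "h)\n")
  invisible(x)
}

#' Assemble a lineage tree from a track table
#'
#' Builds a `lineage_tree` from a track table with columns `cell_id`,
#' `parent_id`, `frame`, `time_h`, `area` (and optionally `fluor_total`,
#' `arrested`).  Validates single-rootedness, strictly increasing times
#' within each cell, positive areas, and parent/child time ordering.
#'
#' @param tracks Track data frame.
#' @param frame_dt Frame interval (h); inferred from the data if `NULL`.
#' @return A `lineage_tree` object.
#' @export
lineage_tree <- function(tracks, frame_dt = NULL) {
  req <- c("cell_id", "parent_id", "frame", "time_h", "area")
  if (!all(req %in% names(tracks)))
    stop("tracks must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tracks$area) | tracks$area <= 0)
  if (length(bad) > 0)
    stop("non-positive area at track row ", bad[1], " (cell ",
         tracks$cell_id[bad[1]], ", frame ", tracks$frame[bad[1]], ")",
         call. = FALSE)
  cells <- split(tracks, tracks$cell_id)
  for (cc in cells) {
    if (any(diff(cc$time_h) <= 0))
      stop("times not strictly increasing for cell ", cc$cell_id[1],
           call. = FALSE)
  }
  first_t <- vapply(cells, function(cc) min(cc$time_h), numeric(1))
  last_t <- vapply(cells, function(cc) max(cc$time_h), numeric(1))
  parent_of <- vapply(cells, function(cc) cc$parent_id[1], character(1))
  roots <- names(cells)[is.na(parent_of)]
  if (length(roots) != 1)
    stop("lineage must have exactly one root, found ", length(roots),
         call. = FALSE)
  for (id in names(cells)) {
    p <- parent_of[[id]]
    if (!is.na(p)) {
      if (!p %in% names(cells))
        stop("unknown parent ", p, " for cell ", id, call. = FALSE)
      if (first_t[[id]] < last_t[[p]] - 1e-9)
        stop("cell ", id, " starts before its parent ends", call. = FALSE)
    }
  }
  edges <- data.frame(parent = parent_of[!is.na(parent_of)],
                      child = names(cells)[!is.na(parent_of)],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  if (is.null(frame_dt)) {
    dts <- diff(sort(unique(tracks$time_h)))
    frame_dt <- if (length(dts) > 0) min(dts) else 1
  }
  structure(list(progenitor_id = roots, tracks = tracks, edges = edges,
                 frame_dt = frame_dt, t_max = max(tracks$time_h)),
            class = "lineage_tree")
}
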
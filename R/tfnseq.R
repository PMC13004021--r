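# Library-scale depletion trajectory analysis: relative abundance,
# nested trajectory models (no effect / sufficiency / overabundance),
# model selection by successive likelihood-ratio tests, and overabundance.

#' Relative abundance trajectories from a count matrix
#'
#' Converts a genes x timepoints count matrix into per-gene relative
#' abundance trajectories: the library fraction at each timepoint
#' normalized to its t = 0 value,
#' `rel(t) = [count(t)/total(t)] / [count(0)/total(0)]`.
#' Totals are the column sums of the full matrix.  Genes whose t = 0 count
#' falls below `min_count0` are dropped and reported, never silently.
#'
#' @param counts Count matrix with `gene_id` rownames and `t=<hours>`
#'   column names (as written by [simulate_tfnseq()] or
#'   [read_counts_tsv()]).
#' @param times Timepoints in hours; parsed from column names if `NULL`.
#' @param min_count0 Minimum t = 0 count for a gene to be retained
#'   (default 20 reads, standard insertion-library practice).
#' @return An `abundance_set`: list with `gene_id`, `times`, `counts`
#'   (retained genes), `totals`, `f0` (t = 0 fractions), `rel` (raw
#'   relative abundance matrix), and `dropped` (data frame of excluded
#'   genes with reasons).
#' @export
relative_abundance <- function(counts, times = NULL, min_count0 = 20) {
  counts <- as.matrix(counts)
  if (is.null(times)) {
    times <- attr(counts, "times")
    if (is.null(times)) times <- parse_time_header(colnames(counts))
  }
  if (length(times) != ncol(counts))
    stop("times length does not match count columns", call. = FALSE)
  if (times[1] != 0) stop("t = 0 column must be present first",
                          call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("totals must be positive at every timepoint",
                             call. = FALSE)
  c0 <- counts[, 1]
  keep <- c0 >= max(min_count0, 1)
  dropped <- data.frame(
    gene_id = rownames(counts)[!keep],
    reason = ifelse(c0[!keep] == 0, "zero count at t = 0",
                    sprintf("t = 0 count below minimum (%d < %d)",
                            c0[!keep], as.integer(max(min_count0, 1)))),
    stringsAsFactors = FALSE)
  counts <- counts[keep, , drop = FALSE]
  frac <- sweep(counts, 2, totals, "/")
  rel <- frac / frac[, 1]
  structure(list(gene_id = rownames(counts), times = times,
                 counts = counts, totals = totals, f0 = frac[, 1],
                 rel = rel, dropped = dropped),
            class = "abundance_set")
}

#' @export
print.abundance_set <- function(x, ...) {
  cat("abundance_set:", length(x$gene_id), "genes,",
      length(x$times), "timepoints (", min(x$times), "-", max(x$times),
      "h );", nrow(x$dropped), "genes dropped\n")
  invisible(x)
}

parse_time_header <- function(hdr) {
  if (is.null(hdr) || !all(grepl("^t=", hdr)))
    stop("count matrix columns must be named t=<hours>", call. = FALSE)
  as.numeric(sub("^t=", "", hdr))
}

# Binomial log-likelihood of a trajectory given an expected relative
# decline r(t).  The expected library fraction is s * r(t) * g(t), where
# g(t) is the library renormalization (the inverse of the library-average
# decline, shared across genes) and s is the gene's initial abundance
# scale.  s is a nuisance parameter common to all three trajectory
# models; it is profiled out in closed form (the small-fraction/Poisson
# profile MLE), rather than anchored to the observed t = 0 count, so that
# t = 0 sampling noise does not masquerade as a depletion trend.  `const`
# carries the parameter-free binomial coefficient term so the inner
# optimization loop stays cheap.
traj_loglik <- function(counts, totals, g, r,
                        const = sum(lchoose(totals, counts))) {
  lam <- totals * r * g
  s <- sum(counts) / sum(lam)
  p <- pmin(pmax(s * r * g, 1e-12), 1 - 1e-9)
  const + sum(counts * log(p) + (totals - counts) * log1p(-p))
}

#' Fit the three nested trajectory models to one gene
#'
#' Fits, by maximum binomial likelihood, the three competing growth
#' models for the expected relative abundance `r(t)`:
#' * no effect: `r(t) = 1` (0 free parameters);
#' * sufficiency: `r(t) = exp(-delta t)`, `delta >= 0` (1 parameter);
#' * overabundance: `r(t) = 1` for `t < T`, `exp(-delta (t - T))` after,
#'   `T >= 0` (2 parameters).
#'
#' The arrest time `T` is profiled on a coarse grid and refined to 0.01 h
#' resolution; `delta` is profiled by one-dimensional optimization at each
#' candidate `T`.  A gene-level initial-abundance scale, common to all
#' three models, is profiled out in closed form.  The models are nested
#' (`delta = 0`; `T = 0`), and the returned log-likelihoods respect the
#' nesting ordering exactly.
#'
#' @param counts,totals Read counts and per-timepoint library totals.
#' @param times Timepoints (h); at least 3.
#' @param norm Library renormalization `g(t)` (defaults to 1).
#' @param delta_max Upper bound for the decline rate (1/h).
#' @param coarse_step Coarse grid step for `T` (h).
#' @param t_resolution Final grid resolution for `T` (h).
#' @return A `trajectory_fits` list: per-model log-likelihoods and MLEs
#'   (`delta_s`; `T_hat`, `delta_o`), plus a `converged` flag.
#' @export
fit_models <- function(counts, totals, times, norm = NULL,
                       delta_max = 12, coarse_step = 0.5,
                       t_resolution = 0.01) {
  if (length(times) < 3) stop("need at least 3 timepoints", call. = FALSE)
  g <- if (is.null(norm)) rep(1, length(times)) else norm
  const <- sum(lchoose(totals, counts))
  ll <- function(r) traj_loglik(counts, totals, g, r, const)
  ll_ne <- ll(rep(1, length(times)))

  prof_delta <- function(Tc) {
    obj <- function(d) ll(exp(-d * pmax(0, times - Tc)))
    opt <- stats::optimize(obj, c(0, delta_max), maximum = TRUE,
                           tol = 1e-4)
    at0 <- ll(rep(1, length(times)))  # delta = 0 boundary
    if (at0 >= opt$objective) list(delta = 0, loglik = at0)
    else list(delta = opt$maximum, loglik = opt$objective)
  }

  s_fit <- prof_delta(0)
  ll_s <- max(s_fit$loglik, ll_ne)

  t_max <- max(times)
  best <- list(T = 0, delta = s_fit$delta, loglik = s_fit$loglik)
  scan <- function(grid, best) {
    for (Tc in grid) {
      f <- prof_delta(Tc)
      if (f$loglik > best$loglik)
        best <- list(T = Tc, delta = f$delta, loglik = f$loglik)
    }
    best
  }
  coarse_T <- seq(0, t_max, by = coarse_step)
  coarse_ll <- vapply(coarse_T, function(Tc) prof_delta(Tc)$loglik,
                      numeric(1))
  # The profile over T can be locally flat (any arrest time inside the
  # final sampled interval fits identically), so refine around every
  # coarse candidate close to the best, not just the argmax.
  near <- which(coarse_ll >= max(coarse_ll) - 3)
  near <- near[order(coarse_ll[near], decreasing = TRUE)]
  near <- near[!duplicated(round(coarse_ll[near], 6))]  # collapse plateaus
  near <- utils::head(near, 8)
  for (j in near) {
    b <- list(T = coarse_T[j], delta = NA, loglik = coarse_ll[j])
    for (step in c(coarse_step / 5, t_resolution)) {
      lo <- max(0, b$T - 5 * step)
      hi <- min(t_max, b$T + 5 * step)
      b <- scan(seq(lo, hi, by = step), b)
    }
    if (is.na(b$delta)) b$delta <- prof_delta(b$T)$delta
    if (b$loglik > best$loglik) best <- b
  }
  ll_o <- max(best$loglik, ll_s)
  converged <- is.finite(ll_ne) && is.finite(ll_s) && is.finite(ll_o)
  structure(list(loglik = c(no_effect = ll_ne, sufficiency = ll_s,
                            overabundance = ll_o),
                 delta_s = s_fit$delta,
                 T_hat = best$T, delta_o = best$delta,
                 times = times, converged = converged),
            class = "trajectory_fits")
}

#' Select a trajectory model by two successive null-hypothesis tests
#'
#' Test 1 takes the no-effect model as the null against the best
#' alternative (the overabundance fit, which nests sufficiency); if it is
#' not rejected at `alpha1`, the gene is called `no_effect`.  Test 2 takes
#' sufficiency as the null against overabundance; if rejected at `alpha2`
#' the gene is called `overabundance`, otherwise `sufficiency`.
#'
#' P-values use chi-squared reference distributions: plain df = 2 for test
#' 1 (conservative, since both extra parameters are boundary-constrained
#' under the null) and the boundary mixture `0.5 chi2_0 + 0.5 chi2_1` for
#' test 2.  [bootstrap_null()] provides parametric-bootstrap calibration.
#'
#' @param fits A `trajectory_fits` from [fit_models()].
#' @param alpha1,alpha2 Significance levels of the two tests (default
#'   1e-4 each).
#' @param k0 Wild-type growth rate (1/h); needed to convert the arrest
#'   time into an overabundance (`log10_o = k0 T / ln 10`).  Relative
#'   abundances alone cannot identify `k0`; it must come from an external
#'   measurement (for example the library's doubling time).
#' @param censor_margin Arrest times within this margin of the last
#'   timepoint are flagged censored (default: half the median timepoint
#'   spacing); their `log10_o` is a lower bound.
#' @return One-row data frame (a mutant call): `model`, `p_no_effect`,
#'   `p_sufficiency`, `T_hat`, `log10_o`, `censored`, `converged`.
#' @export
select_model <- function(fits, alpha1 = 1e-4, alpha2 = 1e-4, k0 = NULL,
                         censor_margin = NULL) {
  stopifnot(inherits(fits, "trajectory_fits"))
  ll <- fits$loglik
  stat1 <- max(0, 2 * (ll["overabundance"] - ll["no_effect"]))
  p1 <- stats::pchisq(stat1, df = 2, lower.tail = FALSE)
  stat2 <- max(0, 2 * (ll["overabundance"] - ll["sufficiency"]))
  p2 <- if (stat2 <= 1e-12) 1 else
    0.5 * stats::pchisq(stat2, df = 1, lower.tail = FALSE)
  if (!fits$converged) {
    model <- "unclassifiable"; T_hat <- NA_real_
  } else if (p1 >= alpha1) {
    model <- "no_effect"; T_hat <- NA_real_
  } else if (p2 < alpha2 && fits$T_hat > 0) {
    model <- "overabundance"; T_hat <- fits$T_hat
  } else {
    model <- "sufficiency"; T_hat <- 0
  }
  if (is.null(censor_margin))
    censor_margin <- stats::median(diff(fits$times)) / 2
  censored <- model == "overabundance" &&
    T_hat >= max(fits$times) - censor_margin
  log10_o <- if (model == "overabundance" && !is.null(k0))
    k0 * T_hat / log(10)
  else if (model == "sufficiency") 0
  else NA_real_
  data.frame(model = model, p_no_effect = unname(p1),
             p_sufficiency = unname(p2), T_hat = T_hat,
             log10_o = log10_o, censored = censored,
             converged = fits$converged, stringsAsFactors = FALSE)
}

#' Overabundance from an arrest time
#'
#' `o = exp(k0 T)` for overabundance calls and `o = 1` for sufficiency
#' calls (`T = 0` by definition).  `k0` cannot be inferred from relative
#' abundances and must be supplied.
#'
#' @param calls A mutant-call data frame (from [select_model()] or
#'   [call_mutants()]).
#' @param k0 Wild-type growth rate (1/h).
#' @return The calls with an `o` column (fold overabundance; `NA` for
#'   no-effect genes).
#' @export
overabundance <- function(calls, k0) {
  if (missing(k0) || is.null(k0) || !is.finite(k0))
    stop("k0 is required: it cannot be identified from relative ",
         "abundances and must come from configuration", call. = FALSE)
  o <- rep(NA_real_, nrow(calls))
  oa <- calls$model == "overabundance"
  o[oa] <- exp(k0 * calls$T_hat[oa])
  o[calls$model == "sufficiency"] <- 1
  calls$o <- o
  calls
}

# Halving time: first time the renormalized relative abundance crosses
# 0.5, by linear interpolation of log relative abundance.
halving_time_of <- function(times, rel_corrected) {
  r <- pmax(rel_corrected, 1e-12)
  below <- which(r < 0.5)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(times[1])
  l0 <- log(r[i - 1]); l1 <- log(r[i]); lt <- log(0.5)
  times[i - 1] + (l0 - lt) / (l0 - l1) * (times[i] - times[i - 1])
}

# Library renormalization g(t) shared by all genes: either from a
# reference set of genes assumed unaffected (their median relative
# abundance estimates g directly), or self-consistently, iterating
# between per-gene fits and the implied library-average decline
# w(t) = sum_j f0_j r_j(t), g = 1/w.
estimate_norm <- function(aset, normalization, reference_genes, n_iter,
                          delta_max, coarse_step) {
  nt <- length(aset$times)
  if (normalization == "none") return(rep(1, nt))
  if (normalization == "reference") {
    if (is.null(reference_genes))
      stop("reference normalization requires reference_genes",
           call. = FALSE)
    ref <- intersect(reference_genes, aset$gene_id)
    if (length(ref) < 3)
      stop("fewer than 3 reference genes retained", call. = FALSE)
    g <- apply(aset$rel[ref, , drop = FALSE], 2, stats::median)
    return(g / g[1])
  }
  # Self-consistent: initialize the shared decline from the upper
  # envelope of the raw trajectories (genes that have not yet arrested
  # trace the inverse library-average decline exactly), then iterate
  # between per-gene fits and the renormalization they imply.  Genes
  # showing no significant decline under the current normalization act
  # as an internal reference: their median trajectory estimates g
  # without the downward bias of averaging fitted declines (the decline
  # models can only absorb downward noise excursions).  When too few
  # flat genes exist, fall back to the model-implied library average.
  g <- apply(aset$rel, 2, stats::quantile, probs = 0.9)
  g <- g / g[1]
  f0n <- aset$f0 / sum(aset$f0)
  for (iter in seq_len(n_iter)) {
    w <- rep(0, nt)
    flat <- logical(length(aset$gene_id))
    for (i in seq_along(aset$gene_id)) {
      fit <- fit_models(aset$counts[i, ], aset$totals, aset$times,
                        norm = g, delta_max = delta_max,
                        coarse_step = coarse_step, t_resolution = 0.05)
      r <- exp(-fit$delta_o * pmax(0, aset$times - fit$T_hat))
      w <- w + f0n[i] * r
      flat[i] <- 2 * (fit$loglik["overabundance"] -
                        fit$loglik["no_effect"]) <
        stats::qchisq(0.999, df = 2)
    }
    if (sum(flat) >= max(20, 0.1 * length(flat))) {
      g <- apply(aset$rel[flat, , drop = FALSE], 2, stats::median)
    } else {
      g <- 1 / w
    }
    g <- g / g[1]
  }
  g
}

#' Classify all trajectories of a library
#'
#' Runs [fit_models()] and [select_model()] on every retained gene of an
#' [relative_abundance()] set, after estimating the shared library
#' renormalization.  With `normalization = "self_consistent"` (default)
#' the renormalization is iterated from the fits themselves; with
#' `"reference"` it is the median trajectory of a user-supplied reference
#' set (for example genes annotated nonessential).
#'
#' @param aset An `abundance_set`.
#' @param k0 Wild-type growth rate (1/h); required.
#' @param alpha1,alpha2 Significance levels of the two successive tests.
#' @param normalization `"self_consistent"`, `"reference"`, or `"none"`.
#' @param reference_genes Gene ids for `"reference"` normalization.
#' @param n_iter Iterations of the self-consistent renormalization.
#' @param multiple_testing `"none"` (per-gene thresholds, default) or
#'   `"BH"` (Benjamini-Hochberg adjustment of each test's p-values across
#'   genes before thresholding).
#' @param delta_max,coarse_step,t_resolution Passed to [fit_models()].
#' @return A calls data frame with one row per retained gene: `gene_id`,
#'   `model`, `p_no_effect`, `p_sufficiency`, `T_hat`, `halving_time`,
#'   `log10_o`, `o`, `censored`.  The library renormalization and class
#'   fractions are attached as attributes `"norm"` and
#'   `"class_fractions"`.
#' @export
call_mutants <- function(aset, k0, alpha1 = 1e-4, alpha2 = 1e-4,
                         normalization = c("self_consistent", "reference",
                                           "none"),
                         reference_genes = NULL, n_iter = 2,
                         multiple_testing = c("none", "BH"),
                         delta_max = 12, coarse_step = 0.5,
                         t_resolution = 0.01) {
  stopifnot(inherits(aset, "abundance_set"))
  normalization <- match.arg(normalization)
  multiple_testing <- match.arg(multiple_testing)
  if (missing(k0) || is.null(k0))
    stop("k0 is required configuration for call_mutants", call. = FALSE)
  g <- estimate_norm(aset, normalization, reference_genes, n_iter,
                     delta_max, coarse_step)
  rows <- vector("list", length(aset$gene_id))
  for (i in seq_along(aset$gene_id)) {
    fit <- fit_models(aset$counts[i, ], aset$totals, aset$times,
                      norm = g, delta_max = delta_max,
                      coarse_step = coarse_step,
                      t_resolution = t_resolution)
    row <- select_model(fit, alpha1 = alpha1, alpha2 = alpha2, k0 = k0)
    row$gene_id <- aset$gene_id[i]
    row$halving_time <- halving_time_of(aset$times, aset$rel[i, ] / g)
    rows[[i]] <- row
  }
  calls <- do.call(rbind, rows)
  if (multiple_testing == "BH") {
    p1 <- stats::p.adjust(calls$p_no_effect, method = "BH")
    p2 <- stats::p.adjust(calls$p_sufficiency, method = "BH")
    demote1 <- p1 >= alpha1 & calls$model != "no_effect"
    calls$model[demote1] <- "no_effect"
    calls$log10_o[demote1] <- NA_real_
    calls$T_hat[demote1] <- NA_real_
    demote2 <- !demote1 & p2 >= alpha2 & calls$model == "overabundance"
    calls$model[demote2] <- "sufficiency"
    calls$log10_o[demote2] <- 0
    calls$T_hat[demote2] <- 0
  }
  calls <- overabundance(calls, k0)
  calls <- calls[, c("gene_id", "model", "p_no_effect", "p_sufficiency",
                     "T_hat", "halving_time", "log10_o", "o", "censored",
                     "converged")]
  attr(calls, "norm") <- g
  attr(calls, "class_fractions") <-
    table(factor(calls$model,
                 levels = c("no_effect", "sufficiency", "overabundance",
                            "unclassifiable"))) / nrow(calls)
  calls
}

#' Parametric-bootstrap calibration of the trajectory tests
#'
#' Simulates trajectories under a fitted null model (no effect or
#' sufficiency) by binomial resampling and returns the bootstrap
#' distribution of the likelihood-ratio statistic, for calibrating the
#' chi-squared reference p-values of [select_model()].
#'
#' @param counts,totals,times,norm As in [fit_models()].
#' @param null `"no_effect"` or `"sufficiency"`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Numeric vector of bootstrap likelihood-ratio statistics.
#' @export
bootstrap_null <- function(counts, totals, times, norm = NULL,
                           null = c("no_effect", "sufficiency"),
                           n_boot = 200, seed = 1L) {
  null <- match.arg(null)
  g <- if (is.null(norm)) rep(1, length(times)) else norm
  fit0 <- fit_models(counts, totals, times, norm = g)
  r0 <- if (null == "no_effect") rep(1, length(times))
        else exp(-fit0$delta_s * times)
  s0 <- sum(counts) / sum(totals * r0 * g)
  p0 <- pmin(pmax(s0 * r0 * g, 1e-12), 1 - 1e-9)
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    cb <- stats::rbinom(length(times), totals, p0)
    fb <- fit_models(cb, totals, times, norm = g,
                     t_resolution = 0.05)
    if (null == "no_effect")
      max(0, 2 * (fb$loglik["overabundance"] - fb$loglik["no_effect"]))
    else
      max(0, 2 * (fb$loglik["overabundance"] - fb$loglik["sufficiency"]))
  }, numeric(1))
}

#' Replicate agreement of mutant calls
#'
#' Combines calls from replicate libraries: per-gene mean and standard
#' deviation of `log10_o` across replicates, with flags for genes whose
#' class is discordant between replicates or missing from some replicate.
#'
#' @param calls_list List of >= 2 calls data frames (one per replicate).
#' @return Data frame: `gene_id`, `n_replicates`, `model` (consensus or
#'   `"discordant"`), `log10_o_mean`, `log10_o_sd`, `discordant`,
#'   `missing_in_some`.
#' @export
replicate_error <- function(calls_list) {
  if (length(calls_list) < 2)
    stop("need at least 2 replicates", call. = FALSE)
  genes <- unique(unlist(lapply(calls_list, function(d) d$gene_id)))
  rows <- lapply(genes, function(gid) {
    sub <- lapply(calls_list, function(d) d[d$gene_id == gid, ])
    present <- vapply(sub, nrow, integer(1)) > 0
    sub <- do.call(rbind, sub[present])
    models <- unique(sub$model)
    lo <- sub$log10_o[!is.na(sub$log10_o)]
    data.frame(gene_id = gid, n_replicates = sum(present),
               model = if (length(models) == 1) models else "discordant",
               log10_o_mean = if (length(lo)) mean(lo) else NA_real_,
               log10_o_sd = if (length(lo) >= 2) stats::sd(lo) else NA_real_,
               discordant = length(models) > 1,
               missing_in_some = !all(present),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
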
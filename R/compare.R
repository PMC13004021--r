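# Genome-wide synthesis: message-number estimation, transcription vs
# overabundance trend extraction, subgroup statistics, summary statistics,
# and a KDE surface for figures.

#' Message number per gene from RNA-seq counts
#'
#' Converts RNA-seq counts into messages per gene per cell cycle by
#' scaling read fractions to a total message budget:
#' `mu_m_hat = (count_g / sum(counts)) * M_total`.
#' The total budget `M_total` is explicit configuration (default 4000
#' messages per cell cycle) and is propagated to outputs as metadata.
#'
#' @param counts Named non-negative count vector.
#' @param M_total Total messages per cell cycle (> 0).
#' @return Named numeric vector summing exactly to `M_total`.
#' @export
message_number <- function(counts, M_total = 4000) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (M_total <= 0) stop("M_total must be positive", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("zero total counts", call. = FALSE)
  counts / tot * M_total
}

#' Binned transcription-overabundance trend
#'
#' Bins `(mu_m, o)` points by one of two complementary approaches and
#' reports per-bin medians with bootstrap intervals:
#' * `quantile`: equal-count bins in the rank of `mu_m` (default 10
#'   bins);
#' * `log_width`: equal-width bins in `log10 mu_m` (default 0.25 decades,
#'   8 bins per two decades); empty bins are dropped with a warning.
#'
#' @param mu_m Message numbers (> 0).
#' @param o Overabundances (>= 1).
#' @param method `"quantile"` or `"log_width"`.
#' @param n_bins Number of quantile bins.
#' @param bin_width Width of log-width bins in log10 units.
#' @param n_boot Bootstrap resamples for the median interval.
#' @param conf Confidence level of the bootstrap interval.
#' @param seed Seed for the bootstrap.
#' @return Data frame: `bin`, `n`, `mu_m_median`, `o_median`, `o_lo`,
#'   `o_hi`.
#' @export
trend_bins <- function(mu_m, o, method = c("quantile", "log_width"),
                       n_bins = 10, bin_width = 0.25, n_boot = 200,
                       conf = 0.9, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(mu_m) == length(o))
  if (length(mu_m) < 2 * 2)
    stop("too few points to bin", call. = FALSE)
  if (method == "quantile") {
    idx <- ceiling(rank(mu_m, ties.method = "first") /
                     (length(mu_m) / n_bins))
    idx <- pmin(pmax(idx, 1), n_bins)
  } else {
    lg <- log10(mu_m)
    edges <- seq(floor(min(lg) / bin_width) * bin_width,
                 ceiling(max(lg) / bin_width) * bin_width + 1e-9,
                 by = bin_width)
    idx <- findInterval(lg, edges, rightmost.closed = TRUE)
    present <- sort(unique(idx))
    if (length(present) < length(edges) - 1)
      warning("empty log-width bins dropped", call. = FALSE)
  }
  set.seed(seed)
  groups <- split(data.frame(mu_m = mu_m, o = o), idx)
  rows <- lapply(seq_along(groups), function(j) {
    gdf <- groups[[j]]
    boots <- vapply(seq_len(n_boot), function(b)
      stats::median(sample(gdf$o, replace = TRUE)), numeric(1))
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))
    data.frame(bin = j, n = nrow(gdf),
               mu_m_median = stats::median(gdf$mu_m),
               o_median = stats::median(gdf$o),
               o_lo = unname(qs[1]), o_hi = unname(qs[2]))
  })
  out <- do.call(rbind, rows)
  out[order(out$mu_m_median), ]
}

#' Two-sample Kolmogorov-Smirnov comparison of overabundance groups
#'
#' Compares the `log10 o` distribution of a gene subgroup against a
#' reference set (typically all essential genes) with the two-sample
#' Kolmogorov-Smirnov test.  The statistic is the maximum absolute
#' difference of the two empirical CDFs (the standard convention under
#' ties); the p-value is exact for small tie-free samples and asymptotic
#' otherwise.
#'
#' @param o_group,o_reference Overabundances (fold units), >= 3 each.
#' @return List: `D`, `p_value`, `median_fold` (group median in fold
#'   units), `n_group`, `n_reference`.
#' @export
group_test <- function(o_group, o_reference) {
  if (length(o_group) < 3 || length(o_reference) < 3)
    stop("each sample needs at least 3 values", call. = FALSE)
  x <- log10(o_group)
  y <- log10(o_reference)
  v <- sort(unique(c(x, y)))
  D <- max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
  p <- suppressWarnings(stats::ks.test(x, y)$p.value)
  list(D = D, p_value = p, median_fold = stats::median(o_group),
       n_group = length(x), n_reference = length(y))
}

#' Genome-wide overabundance summary statistics
#'
#' Median overabundance over essential genes, the expression-weighted mean
#' overabundance (weights `mu_m_hat`), and the class fractions among
#' essential and nonessential genes.  Sufficiency genes enter the
#' distribution at `o = 1` exactly.
#'
#' @param records Gene records: data frame with `essential`, `model`,
#'   `o`, and `mu_m_hat` columns (see [merge_gene_records()]).
#' @return List: `median_o`, `weighted_mean_o`, `n_essential`,
#'   `class_fractions_essential`, `class_fractions_nonessential`.
#' @export
summary_stats <- function(records) {
  ess <- records[records$essential & !is.na(records$o), ]
  if (nrow(ess) < 1)
    stop("need at least one essential gene with an overabundance",
         call. = FALSE)
  w <- ess$mu_m_hat
  cls <- function(sub) if (nrow(sub) == 0) NULL else
    table(factor(sub$model, levels = c("no_effect", "sufficiency",
                                       "overabundance",
                                       "unclassifiable"))) / nrow(sub)
  list(median_o = stats::median(ess$o),
       weighted_mean_o = sum(w * ess$o) / sum(w),
       n_essential = nrow(ess),
       class_fractions_essential = cls(records[records$essential, ]),
       class_fractions_nonessential = cls(records[!records$essential, ]))
}

#' Kernel density surface of the transcription-overabundance cloud
#'
#' Two-dimensional kernel density estimate in `(log10 mu_m, log10 o)`,
#' with bandwidths from the normal-reference rule, for figure overlays.
#'
#' @param mu_m Message numbers.
#' @param o Overabundances.
#' @param n_grid Grid size per axis.
#' @param expand Margin (in bandwidths) added around the data range.
#' @return List `x`, `y`, `z` (density grid, integrating to ~1 over the
#'   evaluation window).
#' @export
kde_overlay <- function(mu_m, o, n_grid = 64, expand = 3) {
  if (length(mu_m) < 10) stop("need at least 10 points", call. = FALSE)
  lx <- log10(mu_m)
  ly <- log10(o)
  bx <- MASS::bandwidth.nrd(lx)
  by <- MASS::bandwidth.nrd(ly)
  if (by == 0) by <- max(0.1, stats::sd(ly))  # degenerate, e.g. all o = 1
  if (bx == 0) bx <- max(0.1, stats::sd(lx))
  lims <- c(min(lx) - expand * bx, max(lx) + expand * bx,
            min(ly) - expand * by, max(ly) + expand * by)
  MASS::kde2d(lx, ly, h = c(bx, by), n = n_grid, lims = lims)
}

#' Merge mutant calls, transcription, and annotation into gene records
#'
#' @param calls Calls data frame (from [call_mutants()] or
#'   [replicate_error()] merged back; must have `gene_id`, `model`, and
#'   either `o` or `log10_o_mean`).
#' @param mu_m_hat Named message-number vector (from [message_number()]).
#' @param annotation Data frame with `gene_id`, `essential`, and
#'   optionally `groups` (comma-separated category labels).
#' @return Gene-record data frame: `gene_id`, `essential`, `mu_m_hat`,
#'   `model`, `log10_o`, `o`, `groups`.
#' @export
merge_gene_records <- function(calls, mu_m_hat, annotation) {
  if (!"o" %in% names(calls)) {
    calls$o <- ifelse(calls$model == "overabundance",
                      10^calls$log10_o_mean,
                      ifelse(calls$model == "sufficiency", 1, NA_real_))
    calls$log10_o <- ifelse(calls$model == "sufficiency", 0,
                            calls$log10_o_mean)
  }
  rec <- merge(annotation, calls, by = "gene_id", all.x = FALSE)
  rec$mu_m_hat <- unname(mu_m_hat[rec$gene_id])
  if (!"groups" %in% names(rec)) rec$groups <- ""
  rec[, c("gene_id", "essential", "mu_m_hat", "model", "log10_o", "o",
          "groups")]
}

#' Overabundance statistics for annotated gene subgroups
#'
#' Applies [group_test()] to every category label found in the records'
#' `groups` column, against the full essential set as reference.
#'
#' @param records Gene records from [merge_gene_records()].
#' @return Data frame: `group`, `n`, `median_fold`, `KS_D`, `KS_p`.
#' @export
group_stats <- function(records) {
  ess <- records[records$essential & !is.na(records$o), ]
  ess$groups <- as.character(ess$groups)
  ess$groups[is.na(ess$groups)] <- ""
  labels <- unique(unlist(strsplit(ess$groups[ess$groups != ""], ",")))
  labels <- trimws(labels)
  labels <- labels[labels != ""]
  rows <- lapply(labels, function(lab) {
    in_grp <- vapply(strsplit(ess$groups, ","), function(g)
      lab %in% trimws(g), logical(1))
    if (sum(in_grp) < 3) return(NULL)
    gt <- group_test(ess$o[in_grp], ess$o)
    data.frame(group = lab, n = gt$n_group, median_fold = gt$median_fold,
               KS_D = gt$D, KS_p = gt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), n = integer(),
                      median_fold = numeric(), KS_D = numeric(),
                      KS_p = numeric(), stringsAsFactors = FALSE)
  out
}
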
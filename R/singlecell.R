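# Single-cell estimators: areal growth rate, dilution-law relative
# concentration, the threshold fitness landscape, and arrest times.

# Least-squares log-slope over a sliding window.  Interior points use a
# centered window of `window` frames; the first and last half-windows use
# one-sided windows of the same width, so the series has no NA padding.
ls_slope_series <- function(t, y, window = 5) {
  n <- length(y)
  if (n < window) stop("series shorter than the smoothing window",
                       call. = FALSE)
  h <- window %/% 2
  vapply(seq_len(n), function(i) {
    idx <- if (i <= h) 1:window
           else if (i > n - h) (n - window + 1):n
           else (i - h):(i + h)
    tt <- t[idx] - mean(t[idx])
    yy <- y[idx]
    sum(tt * (yy - mean(yy))) / sum(tt^2)
  }, numeric(1))
}

#' Areal growth rate of a single-cell track
#'
#' The instantaneous areal growth rate is the time derivative of log cell
#' area, estimated as the slope of a centered least-squares line through
#' log(area) over a sliding window (one-sided windows at the endpoints).
#'
#' @param times Frame times (h), strictly increasing.
#' @param areas Cell areas (positive).
#' @param window Smoothing window in frames (odd, >= 3; default 5).
#' @return Numeric vector of growth rates (1/h), one per frame.
#' @export
areal_growth_rate <- function(times, areas, window = 5) {
  if (is.data.frame(times)) {
    areas <- times$area
    times <- times$time_h
  }
  if (window < 3) stop("window must be >= 3", call. = FALSE)
  if (window %% 2 == 0) window <- window + 1
  if (length(times) < window)
    stop("track has fewer points than the window", call. = FALSE)
  bad <- which(!is.finite(areas) | areas <= 0)
  if (length(bad) > 0)
    stop("non-positive area at frame ", bad[1], call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  ls_slope_series(times, log(areas), window)
}

# Total progeny area per frame; the lineage-level volume proxy.
colony_area_series <- function(tree) {
  tr <- tree$tracks
  agg <- stats::aggregate(tr$area, by = list(frame = tr$frame), FUN = sum)
  tm <- stats::aggregate(tr$time_h, by = list(frame = tr$frame),
                         FUN = function(v) v[1])
  out <- data.frame(frame = agg$frame, time_h = tm$x, total_area = agg$x)
  full <- seq(min(out$frame), max(out$frame))
  if (!all(full %in% out$frame))
    stop("frames with no progeny present: ",
         paste(utils::head(setdiff(full, out$frame), 3), collapse = ", "),
         call. = FALSE)
  out[order(out$frame), ]
}

#' Relative concentration from the dilution law
#'
#' Under dilution (no synthesis, conserved protein amount, equal
#' concentration across progeny), the relative concentration is the
#' inverse of the fold growth in total progeny area:
#' `C(t)/C0 = V0/V(t)`.
#'
#' @param tree A `lineage_tree`.
#' @param ref_frame Frame index used for `V0` (default 0, the first frame;
#'   the knockout reference time).
#' @return Data frame with `frame`, `time_h`, `total_area`, `rel_conc`.
#' @export
relative_concentration <- function(tree, ref_frame = 0) {
  stopifnot(inherits(tree, "lineage_tree"))
  ca <- colony_area_series(tree)
  if (!ref_frame %in% ca$frame)
    stop("reference frame ", ref_frame, " not present", call. = FALSE)
  V0 <- ca$total_area[ca$frame == ref_frame]
  ca$rel_conc <- V0 / ca$total_area
  ca
}

#' Fitness landscape from a depletion microcolony
#'
#' Pairs every cell-frame areal growth rate with the lineage-level relative
#' concentration at that frame and fits a threshold (two-level changepoint)
#' model by least squares over the grid of candidate arrest concentrations:
#' a plateau rate above the threshold and a floor rate below it.  The
#' overabundance estimate is the inverse of the fitted arrest concentration,
#' `o_hat = C0 / C_A`.
#'
#' If no rate change is detectable (fitted floor not below `drop_frac`
#' times the plateau), the landscape is flagged censored and `o_hat` is the
#' dilution lower bound `V(t_max)/V0`.
#'
#' @param tree A `lineage_tree`.
#' @param window Growth-rate smoothing window in frames.
#' @param min_side Minimum number of points on each side of the
#'   changepoint.
#' @param drop_frac Maximum floor/plateau ratio for a detectable arrest.
#' @param ref_frame Reference frame for `C0`/`V0`.
#' @return A `fitness_landscape`: list with `pairs` (rel_conc, k, cell_id,
#'   frame), `o_hat`, `arrest_conc`, `k_plateau`, `k_floor`, `censored`,
#'   and `plateau_slope` with its standard error.
#' @export
fitness_landscape <- function(tree, window = 5, min_side = 3,
                              drop_frac = 0.5, ref_frame = 0) {
  stopifnot(inherits(tree, "lineage_tree"))
  rc <- relative_concentration(tree, ref_frame = ref_frame)
  rel_of_frame <- stats::setNames(rc$rel_conc, rc$frame)
  cells <- split(tree$tracks, tree$tracks$cell_id)
  pairs <- do.call(rbind, lapply(cells, function(cc) {
    if (nrow(cc) < max(window, 3)) return(NULL)
    k <- areal_growth_rate(cc$time_h, cc$area, window = window)
    data.frame(cell_id = cc$cell_id, frame = cc$frame,
               rel_conc = rel_of_frame[as.character(cc$frame)], k = k,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  if (is.null(pairs) || nrow(pairs) < 2 * min_side)
    stop("too few cell-frame observations for a landscape", call. = FALSE)
  ord <- order(pairs$rel_conc)
  x <- pairs$rel_conc[ord]
  y <- pairs$k[ord]
  n <- length(y)
  # Two-level least squares: for split i, low side 1..i, high side (i+1)..n.
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  i <- seq_len(n - 1)
  ss_lo <- cs2[i] - cs[i]^2 / i
  ss_hi <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  valid <- i >= min_side & (n - i) >= min_side & x[i] < x[i + 1] - 1e-12
  if (!any(valid)) {
    split_at <- NA_integer_
  } else {
    tot <- ss_lo + ss_hi
    tot[!valid] <- Inf
    split_at <- which.min(tot)
  }
  censored <- FALSE
  if (is.na(split_at)) {
    censored <- TRUE
    k_plateau <- mean(y); k_floor <- NA_real_; c_hat <- NA_real_
  } else {
    k_floor <- mean(y[seq_len(split_at)])
    k_plateau <- mean(y[(split_at + 1):n])
    c_hat <- sqrt(x[split_at] * x[split_at + 1])  # geometric midpoint
    if (!(k_floor < drop_frac * k_plateau)) {
      censored <- TRUE
      k_plateau <- mean(y); k_floor <- NA_real_; c_hat <- NA_real_
    }
  }
  if (censored) {
    o_hat <- 1 / min(x)  # dilution bound V(t_max)/V0
    plateau_idx <- seq_len(n)
  } else {
    o_hat <- 1 / c_hat
    plateau_idx <- (split_at + 1):n
  }
  # Flatness diagnostic of the plateau
  slope <- se <- NA_real_
  if (length(plateau_idx) >= 3 && stats::sd(x[plateau_idx]) > 0) {
    fit <- stats::lm(y[plateau_idx] ~ x[plateau_idx])
    slope <- unname(stats::coef(fit)[2])
    se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  }
  structure(list(pairs = pairs, o_hat = o_hat, arrest_conc = c_hat,
                 k_plateau = k_plateau, k_floor = k_floor,
                 censored = censored, plateau_slope = slope,
                 plateau_slope_se = se),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("fitness_landscape:", nrow(x$pairs), "cell-frame pairs; o_hat =",
      signif(x$o_hat, 4),
      if (x$censored) "(censored lower bound)" else "",
      "; plateau k =", signif(x$k_plateau, 3), "/h\n")
  invisible(x)
}

# Time at which a smoothed rate series falls below the threshold and
# stays below for the rest of the series (transient dips are ignored;
# the final below-threshold run must span at least `persist` frames).
# Returns the linearly interpolated crossing time, or NA.
first_sustained_crossing <- function(times, rate, threshold, persist) {
  below <- rate < threshold
  n <- length(below)
  if (!below[n]) return(NA_real_)
  i <- n
  while (i > 1 && below[i - 1]) i <- i - 1
  if (n - i + 1 < persist) return(NA_real_)
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  r0 <- rate[i - 1]; r1 <- rate[i]
  if (r0 == r1) return(t1)
  tc <- t0 + (r0 - threshold) / (r0 - r1) * (t1 - t0)
  min(max(tc, t0), t1)
}

#' Write a fitness landscape as TSV with a JSON sidecar
#'
#' The main table holds the (relative concentration, growth rate) pairs;
#' the sidecar (`<path>.json`) records `o_hat`, `arrest_conc`, the
#' censoring flag, plateau diagnostics, and, when several landscapes from
#' distinct progenitor cells are supplied, the between-progenitor spread
#' of `log10 o_hat` as the error estimate.
#'
#' @param landscape A `fitness_landscape`, or a list of them from
#'   distinct progenitor cells (the first is written as the main table).
#' @param path Output TSV path.
#' @return Invisibly, the sidecar list.
#' @export
write_landscape_tsv <- function(landscape, path) {
  landscapes <- if (inherits(landscape, "fitness_landscape"))
    list(landscape) else landscape
  main <- landscapes[[1]]
  utils::write.table(main$pairs[, c("rel_conc", "k")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(o_hat = main$o_hat, arrest_conc = main$arrest_conc,
               censored = main$censored, k_plateau = main$k_plateau,
               k_floor = main$k_floor,
               n_progenitors = length(landscapes))
  if (length(landscapes) >= 2) {
    sp <- progenitor_spread(landscapes)
    side$log10_o_mean <- sp$log10_o_mean
    side$log10_o_sd <- sp$log10_o_sd
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(side)
}

#' Between-progenitor spread of overabundance estimates
#'
#' Error estimate for imaging-based overabundance: the mean and standard
#' deviation of `log10 o_hat` across landscapes (or arrest-time results)
#' obtained from distinct progenitor cells.
#'
#' @param estimates List of `fitness_landscape` objects, or of
#'   [arrest_time()] results, or a numeric vector of `o` estimates.
#' @return List: `log10_o_mean`, `log10_o_sd`, `n`.
#' @export
progenitor_spread <- function(estimates) {
  o <- if (is.numeric(estimates)) estimates
  else vapply(estimates, function(e)
    if (inherits(e, "fitness_landscape")) e$o_hat else e$o, numeric(1))
  o <- o[is.finite(o)]
  if (length(o) < 2)
    stop("need estimates from at least 2 progenitor cells", call. = FALSE)
  list(log10_o_mean = mean(log10(o)), log10_o_sd = stats::sd(log10(o)),
       n = length(o))
}

#' Arrest time of a depletion microcolony
#'
#' Detects growth arrest from the colony time series by one of two
#' metrics.  `elongation`: the first time the smoothed total-area log-slope
#' falls below `frac * k0` and stays below for `persist` frames.
#' `septation`: the same criterion applied to the log-slope of the cell
#' count (divisions per unit time), smoothed over about one doubling time.
#' Both report the dilution-based overabundance `o = V(t_A)/V0`.
#'
#' @param tree A `lineage_tree`.
#' @param metric `"elongation"` or `"septation"`.
#' @param frac Fraction of the wild-type rate defining arrest (default
#'   0.5).
#' @param window Smoothing window in frames for the area log-slope.
#' @param persist Number of consecutive frames required below threshold.
#' @param k0 Wild-type rate; estimated from the pre-arrest plateau (90th
#'   percentile of the smoothed area log-slope) when `NULL`.
#' @return List with `t_arrest` (h), `o` (fold dilution at arrest),
#'   `k0_hat`, and `metric`.
#' @export
arrest_time <- function(tree, metric = c("elongation", "septation"),
                        frac = 0.5, window = 5, persist = 3, k0 = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  metric <- match.arg(metric)
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)", call. = FALSE)
  ca <- colony_area_series(tree)
  slope_area <- ls_slope_series(ca$time_h, log(ca$total_area), window)
  k0_hat <- if (is.null(k0))
    as.numeric(stats::quantile(slope_area, 0.9)) else k0
  if (!is.finite(k0_hat) || k0_hat <= 0)
    stop("could not estimate a positive wild-type rate", call. = FALSE)
  if (metric == "elongation") {
    rate <- slope_area
  } else {
    if (nrow(tree$edges) == 0)
      stop("septation metric requires division events, none found",
           call. = FALSE)
    cnt <- stats::aggregate(tree$tracks$cell_id,
                            by = list(frame = tree$tracks$frame),
                            FUN = function(v) length(unique(v)))
    cnt <- cnt[order(cnt$frame), ]
    lcount <- log(cnt$x)
    # The raw count series is a staircase; interpolate log count through
    # the division-event midpoints to recover the underlying septation
    # rate before smoothing.
    jumps <- which(diff(lcount) > 0) + 1L
    nfr <- length(lcount)
    pts_t <- c(ca$time_h[1], ca$time_h[jumps], ca$time_h[nfr])
    pts_y <- c(lcount[1], (lcount[jumps - 1L] + lcount[jumps]) / 2,
               lcount[nfr])
    sm <- stats::approx(pts_t, pts_y, xout = ca$time_h, rule = 2,
                        ties = mean)$y
    rate <- ls_slope_series(ca$time_h, sm, window)
  }
  t_A <- first_sustained_crossing(ca$time_h, rate, frac * k0_hat, persist)
  if (is.na(t_A)) {
    return(list(t_arrest = NA_real_, o = NA_real_, k0_hat = k0_hat,
                metric = metric, censored = TRUE,
                o_lower = max(ca$total_area) / ca$total_area[1]))
  }
  lV <- stats::approx(ca$time_h, log(ca$total_area), xout = t_A)$y
  list(t_arrest = t_A, o = exp(lV) / ca$total_area[1], k0_hat = k0_hat,
       metric = metric, censored = FALSE)
}
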
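# Independent oracles and fixture builders used across tests.

# Brute-force grid maximization of the trajectory binomial likelihood
# over (T, delta), profiling the initial-abundance scale the same way as
# the implementation but computing the likelihood independently via
# dbinom.  Used to check the MLE path on small instances.
brute_force_fit <- function(counts, totals, times, g = rep(1, length(times)),
                            T_grid = seq(0, max(times), by = 0.01),
                            d_grid = seq(0, 5, by = 0.005)) {
  best <- list(loglik = -Inf, T = NA, delta = NA)
  for (Tc in T_grid) {
    tt <- pmax(0, times - Tc)
    r <- exp(-outer(tt, d_grid))          # times x deltas
    lam <- totals * r * g
    s <- colSums(counts * r^0) * 0 + sum(counts)  # constant
    s <- s / colSums(lam)
    p <- sweep(r * g, 2, s, "*")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-9)
    ll <- colSums(dbinom(counts, totals, p, log = TRUE))
    j <- which.max(ll)
    if (ll[j] > best$loglik)
      best <- list(loglik = ll[j], T = Tc, delta = d_grid[j])
  }
  best
}

# Exact two-sample Kolmogorov-Smirnov p-value by enumeration of all
# assignments of the pooled sample (valid for small tie-free samples).
ks_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ks_D <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(v) - ecdf(b)(v)))
  }
  D_obs <- ks_D(x, y)
  combs <- utils::combn(length(pooled), n)
  Ds <- apply(combs, 2, function(idx)
    ks_D(pooled[idx], pooled[-idx]))
  mean(Ds >= D_obs - 1e-12)
}

# Small multi-gene library in which one focal gene follows an exact
# relative-abundance trajectory r(t) and a panel of reference genes has
# constant counts; the reference set traces the library renormalization
# exactly, so noise-free fits should recover the focal parameters.
exact_library <- function(r, times, focal0 = 1600, ref_count = 1000,
                          n_ref = 9) {
  counts <- rbind(focal = round(focal0 * r),
                  matrix(ref_count, nrow = n_ref, ncol = length(times),
                         dimnames = list(sprintf("ref%d", seq_len(n_ref)),
                                         NULL)))
  colnames(counts) <- sprintf("t=%g", times)
  attr(counts, "times") <- times
  counts
}

# Hand-built lineage with exponential elongation throughout but divisions
# that stop at a given time: a septation-only arrest.
septation_only_tree <- function(k0 = 1, t_stop = 1.4, t_max = 3,
                                dt = 1 / 30) {
  frames <- seq(0, t_max, by = dt)
  mk <- function(id, parent, tb, te, ab) {
    sel <- frames >= tb - 1e-9 & frames <= te + 1e-9
    t <- frames[sel]
    data.frame(cell_id = id, parent_id = parent,
               frame = which(sel) - 1L, time_h = t,
               area = ab * exp(k0 * (t - tb)),
               stringsAsFactors = FALSE)
  }
  td <- log(2) / k0  # doubling time; one division before t_stop
  tracks <- rbind(
    mk("m", NA_character_, 0, td - dt / 2, 1),
    mk("d1", "m", td, t_max, 1),
    mk("d2", "m", td, t_max, 1))
  lineage_tree(tracks, frame_dt = dt)
}
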
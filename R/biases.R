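# Quantification of the protocol's experimental biases as binned
# reads-per-possible-interaction profiles, with model fits:
#   fragment length  -> crosslink saturation fit f(x) = A (1 - (1 - p_c)^x)
#   end GC content   -> reads per possible interaction vs mean end GC
#   circle length    -> d_A + d_B profile, envelope mode, twist periodicity
#   genomic distance -> polynomial log-log fit used for distance detrending

.new_profile <- function(bin_lo, bin_hi, N, R, covariate) {
  r <- ifelse(N > 0, R / N, NA_real_)
  out <- data.frame(bin_lo = bin_lo, bin_hi = bin_hi, N = N, R = R, r = r)
  attr(out, "covariate") <- covariate
  attr(out, "flagged_empty") <- which(N == 0)
  class(out) <- c("BiasProfile", "data.frame")
  out
}

#' Reads-per-fragment profile against fragment length
#'
#' Bins fragment lengths into `bin`-bp windows; per bin, `N` is the number
#' of fragments, `R` the number of read-ends landing on those fragments
#' (each event contributes both of its ends), and `r = R / N`. Bins with
#' `N = 0` carry `NA` and are listed in `attr(, "flagged_empty")`.
#'
#' @param frags A `FragmentTable` (the fragment-length universe).
#' @param events Events `data.frame` carrying `frag_a`, `frag_b`.
#' @param bin Bin width in bp (default 100).
#' @return A `BiasProfile` data frame (`bin_lo`, `bin_hi`, `N`, `R`, `r`).
#' @export
length_profile <- function(frags, events, bin = 100) {
  breaks <- seq(0, max(frags$length) + bin, by = bin)
  N <- as.integer(table(cut(frags$length, breaks, right = FALSE)))
  ends_len <- frags$length[c(events$frag_a, events$frag_b)]
  R <- as.integer(table(cut(ends_len, breaks, right = FALSE)))
  .new_profile(head(breaks, -1L), tail(breaks, -1L), N, R, "fragment_length")
}

#' Fit the crosslink saturation model to a length profile
#'
#' Least-squares fit of `f(x) = A * (1 - (1 - p_c)^x)` to the bin-midpoint
#' profile, where `p_c` is the per-bp crosslink probability and `A` the
#' saturation plateau: the chance of a fragment escaping crosslinking decays
#' geometrically with its length, producing the rise-then-plateau shape of
#' the length bias.
#'
#' @param profile A `BiasProfile` from [length_profile()] with >= 3 occupied
#'   bins.
#' @return `list(A, p_c, residual_norm, converged, degenerate)`;
#'   `degenerate` flags a saturated fit (`p_c` at the upper bound, where
#'   `f(x) = A` for all `x >= 1` and the two parameters are not separable).
#' @export
fit_crosslink <- function(profile) {
  ok <- profile$N > 0 & !is.na(profile$r)
  if (sum(ok) < 3L) stop("fit_crosslink needs >= 3 occupied bins")
  x <- (profile$bin_lo[ok] + profile$bin_hi[ok]) / 2
  y <- profile$r[ok]
  # a flat profile is the saturation limit (p_c -> 1: f(x) = A for x >= 1):
  # A and p_c are not jointly identifiable there
  if (stats::sd(y) <= 1e-9 * abs(mean(y)))
    return(list(A = mean(y), p_c = 1, residual_norm = 0,
                converged = TRUE, degenerate = TRUE))
  A0 <- max(y)
  # initial p_c from the small-x slope: f(x) ~ A * p_c * x
  p0 <- min(max(y[1L] / (A0 * x[1L]), 1e-6), 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - (1 - pc)^x),
                      start = list(A = A0, pc = p0),
                      lower = c(1e-12, 1e-12), upper = c(Inf, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(A = NA_real_, p_c = NA_real_, residual_norm = NA_real_,
                converged = FALSE, degenerate = FALSE,
                message = conditionMessage(fit)))
  cf <- coef(fit)
  # saturation over the whole observed range (e.g. p_c = 1, where f(x) = A
  # for every x >= 1) leaves p_c unidentifiable: flag it
  sat <- (1 - unname(cf["pc"]))^min(x) < 1e-6
  list(A = unname(cf["A"]), p_c = unname(cf["pc"]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       converged = TRUE,
       degenerate = sat)
}

# exact count of unordered distinct pairs with a given sum, from an integer
# histogram h over values 0..(length(h)-1); returns counts for sums
# 0..2*(length(h)-1)
.pair_sum_counts <- function(h) {
  n <- length(h)
  conv <- rep(0, 2L * n - 1L)
  for (k in seq_len(n)) {                     # direct convolution; n is small
    if (h[k] == 0) next
    conv[(k - 1L) + seq_len(n)] <- conv[(k - 1L) + seq_len(n)] + h[k] * h
  }
  sums <- 0:(2L * n - 2L)
  same <- numeric(length(sums))
  even <- sums %% 2L == 0L
  same[even] <- h[sums[even] / 2L + 1L]
  (conv - same) / 2
}

#' Reads-per-possible-interaction profile against mean end GC
#'
#' The covariate of an event is the mean GC fraction of its two engaged
#' 20-bp end flanks. `N` per bin is the number of possible end pairs at that
#' mean GC, enumerated over all RE2-valid fragment extremities; `R` is the
#' number of detected events; `r = R / N`.
#'
#' @param events Events `data.frame` with `gc_a`, `gc_b`.
#' @param frags Annotated `FragmentTable` (defines the valid-end universe).
#' @param bin Bin width on the GC fraction (default 0.025, i.e. 2.5%).
#' @export
gc_profile <- function(events, frags, bin = 0.025) {
  gc_ends <- c(frags$end_gc_minus[frags$valid_minus],
               frags$end_gc_plus[frags$valid_plus])
  gc_ends <- gc_ends[!is.na(gc_ends)]
  if (length(gc_ends) < 2L) stop("no valid fragment extremities")
  breaks <- seq(0, 1 + bin, by = bin)
  n_ends <- length(gc_ends)
  if (n_ends <= 4000L) {
    pm <- outer(gc_ends, gc_ends, "+") / 2
    means <- pm[upper.tri(pm)]
  } else {
    sel <- sample.int(n_ends, 4000L)       # subsample the universe
    pm <- outer(gc_ends[sel], gc_ends[sel], "+") / 2
    means <- pm[upper.tri(pm)]
  }
  N <- as.numeric(table(cut(means, breaks, right = FALSE)))
  ev_gc <- (events$gc_a + events$gc_b) / 2
  ev_gc <- ev_gc[!is.na(ev_gc)]
  R <- as.numeric(table(cut(ev_gc, breaks, right = FALSE)))
  .new_profile(head(breaks, -1L), tail(breaks, -1L), N, R, "mean_end_gc")
}

#' Reads-per-possible-interaction profile against circle length
#'
#' Bins the circularization-segment length `d_A + d_B` of each event (sum of
#' the two circle arms, RE1 cut to nearest RE2 site). `N` per bin is the
#' exact number of unordered valid-end pairs whose arm lengths sum into the
#' bin, computed by self-convolution of the arm-length histogram.
#'
#' @param events Events `data.frame` with `circle_length`.
#' @param frags Annotated `FragmentTable`.
#' @param bin Bin width in bp (default 1).
#' @export
circularization_profile <- function(events, frags, bin = 1) {
  d_ends <- c(frags$d_minus[frags$valid_minus], frags$d_plus[frags$valid_plus])
  d_ends <- round(d_ends[!is.na(d_ends)])
  if (length(d_ends) < 2L) stop("no valid fragment extremities")
  h <- tabulate(d_ends + 1L, nbins = max(d_ends) + 1L)
  Ns <- .pair_sum_counts(h)                     # sums 0 .. 2*max(d)
  max_sum <- length(Ns) - 1L
  breaks <- seq(0, max_sum + bin, by = bin)
  nb <- length(breaks) - 1L
  sum_bin <- pmin(findInterval(0:max_sum, breaks), nb)
  N <- tapply(Ns, sum_bin, sum)
  Nfull <- numeric(nb); Nfull[as.integer(names(N))] <- as.numeric(N)
  cl <- events$circle_length[!is.na(events$circle_length)]
  cl <- cl[cl <= max_sum]
  R <- as.numeric(table(cut(cl, breaks, right = FALSE)))
  .new_profile(head(breaks, -1L), tail(breaks, -1L), Nfull, R, "circle_length")
}

# moving-average smoother, partial windows at the edges
.moving_average <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Dominant oscillation period of a circularization profile
#'
#' Detrends the 1-bp `r` profile below `max_length` by subtracting a
#' moving-average envelope, then locates the dominant magnitude-spectrum
#' peak (discrete Fourier transform with zero padding) with period inside
#' `period_range`. This recovers the helical-twist modulation of
#' circularization efficiency.
#'
#' @param profile A 1-bp `BiasProfile` from [circularization_profile()] with
#'   at least 64 occupied bins below `max_length`.
#' @param max_length Only circle lengths below this are analysed (bp).
#' @param period_range Admissible period band in bp (default 5-50).
#' @param ma_window Moving-average envelope window (bp, default 21).
#' @param pad Zero-padding factor for the DFT (default 8).
#' @param min_ratio Peak-to-median spectral power ratio below which the
#'   result is reported as "no significant periodicity".
#' @return `list(period, power_fraction, ratio, significant)`; `period` is
#'   `NA` when no peak rises above the noise floor.
#' @export
estimate_period <- function(profile, max_length = 500, period_range = c(5, 50),
                            ma_window = 21L, pad = 8L, min_ratio = 15) {
  sel <- profile$bin_hi <= max_length
  r <- profile$r[sel]
  if (sum(!is.na(r)) < 64L)
    stop("estimate_period needs >= 64 occupied 1-bp bins below max_length")
  # fill gaps so the series is regular, then detrend
  idx <- seq_along(r)
  if (anyNA(r)) r <- approx(idx[!is.na(r)], r[!is.na(r)], xout = idx, rule = 2)$y
  env <- .moving_average(r, ma_window)
  d <- r - env
  if (stats::sd(d) == 0)
    return(list(period = NA_real_, power_fraction = 0, ratio = 0,
                significant = FALSE))
  d <- d - mean(d)
  n <- length(d)
  nfft <- pad * n
  p <- Mod(fft(c(d, numeric(nfft - n))))^2
  freq <- (seq_len(nfft) - 1L) / nfft           # cycles per bp
  band <- freq > 0 & freq <= 0.5 &
    freq >= 1 / period_range[2L] & freq <= 1 / period_range[1L]
  if (!any(band))
    return(list(period = NA_real_, power_fraction = 0, ratio = 0,
                significant = FALSE))
  pk <- which.max(p * band)
  ratio <- p[pk] / median(p[band])
  significant <- is.finite(ratio) && ratio >= min_ratio
  list(period = if (significant) 1 / freq[pk] else NA_real_,
       power_fraction = p[pk] / sum(p[band]),
       ratio = ratio, significant = significant)
}

#' Mode of a bias profile
#'
#' Smooths `r` with a moving average, finds the peak bin and refines the
#' location with a weighted quadratic (vertex) fit of `log(r)` against the
#' log covariate over a multiplicative window around the peak. Efficiency
#' curves over positive covariates (circle length, fragment length) are
#' single-peaked and approximately parabolic in log space, so the vertex
#' fit pools hundreds of bins instead of trusting a single noisy argmax;
#' weights are the per-bin pair counts `N` (inverse-variance weighting for
#' a ratio estimator).
#'
#' @param profile A `BiasProfile`.
#' @param smooth_window Moving-average window in bins (default 21).
#' @param min_N Bins with fewer than this many possible pairs are ignored.
#' @param refine_factor Multiplicative half-window of the refinement: bins
#'   with covariate in `[peak / refine_factor, peak * refine_factor]` enter
#'   the vertex fit.
#' @return The covariate value (bin midpoint scale) at the profile mode.
#' @export
profile_mode <- function(profile, smooth_window = 21L, min_N = 20,
                         refine_factor = 1.6) {
  mid <- (profile$bin_lo + profile$bin_hi) / 2
  r <- profile$r
  r[profile$N < min_N] <- NA
  sm <- .moving_average(r, smooth_window)
  pk <- which.max(sm)
  w <- which(mid >= mid[pk] / refine_factor & mid <= mid[pk] * refine_factor)
  ok <- !is.na(sm[w]) & sm[w] > 0 & mid[w] > 0
  if (sum(ok) >= 5L) {
    xs <- log(mid[w][ok]); ys <- log(sm[w][ok])
    wt <- profile$N[w][ok]
    fit <- lm(ys ~ xs + I(xs^2), weights = wt)
    a2 <- coef(fit)[3L]; a1 <- coef(fit)[2L]
    if (is.finite(a2) && a2 < 0) {
      vertex <- exp(-a1 / (2 * a2))
      if (vertex >= min(mid[w]) && vertex <= max(mid[w])) return(unname(vertex))
    }
  }
  mid[pk]
}

#' Genomic-distance decay expectation
#'
#' Averages reads per possible interaction over genomic distance: per
#' distance bin (log-spaced by default), `N` is the number of
#' intra-chromosomal fragment pairs at that midpoint distance, `R` the
#' total observed counts, `r = R / N`. A polynomial of degree `degree` is
#' fitted to `log10(r)` vs `log10(D_g)` (heavy-tailed monotone decay is
#' poorly captured by low-degree polynomials in linear space); the
#' evaluation domain is clamped to the observed distance range so the
#' expectation stays strictly positive.
#'
#' @param cm An intra-scope `ContactMatrix` (raw counts) with `chrom`/`mid`
#'   index.
#' @param degree Polynomial degree (default 8, reduced if few occupied bins).
#' @param bins_per_decade Number of log-spaced distance bins per decade.
#' @return A `DistanceExpectation`: `list(profile, fit, domain, degree)`.
#' @export
distance_expectation <- function(cm, degree = 8L, bins_per_decade = 20L) {
  stopifnot(is(cm, "ContactMatrix"))
  v <- cm$values
  mid <- cm$index$mid
  same <- outer(cm$index$chrom, cm$index$chrom, "==")
  up <- same & upper.tri(v)
  if (!any(up)) stop("no intra-chromosomal pairs")
  dg <- abs(outer(mid, mid, "-"))[up]
  counts <- v[up]
  keep <- dg > 0
  dg <- dg[keep]; counts <- counts[keep]
  lo <- floor(log10(min(dg)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(dg)) * bins_per_decade) / bins_per_decade
  breaks <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  binid <- cut(dg, breaks, right = FALSE, include.lowest = TRUE)
  N <- as.numeric(table(binid))
  R <- as.numeric(tapply(counts, binid, sum))
  R[is.na(R)] <- 0
  prof <- .new_profile(head(breaks, -1L), tail(breaks, -1L), N, R,
                       "genomic_distance")
  ok <- prof$N > 0 & prof$R > 0
  if (sum(ok) < 3L) stop("too few occupied distance bins to fit")
  x <- log10(sqrt(prof$bin_lo[ok] * prof$bin_hi[ok]))   # geometric bin mid
  y <- log10(prof$r[ok])
  deg <- max(1L, min(degree, sum(ok) - 1L))
  fit <- lm(y ~ poly(x, deg))
  out <- list(profile = prof, fit = fit, domain = range(x), degree = deg)
  class(out) <- "DistanceExpectation"
  out
}

#' Evaluate a fitted distance expectation
#'
#' Returns the expected reads per interaction at genomic distance `dg`,
#' clamped to the fitted domain (so extrapolation never goes negative: the
#' model lives in log space).
#'
#' @param expectation A `DistanceExpectation`.
#' @param dg Genomic distances (bp).
#' @export
expected_contacts <- function(expectation, dg) {
  x <- log10(pmax(dg, 1))
  x <- pmin(pmax(x, expectation$domain[1L]), expectation$domain[2L])
  10^unname(predict(expectation$fit, newdata = data.frame(x = x)))
}

#' Write a bias profile as TSV
#' @param profile A `BiasProfile`.
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
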
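# Bias profiles, the crosslink fit, periodicity and distance expectation.

make_profile <- function(lo, hi, N, R) {
  out <- data.frame(bin_lo = lo, bin_hi = hi, N = N, R = R,
                    r = ifelse(N > 0, R / N, NA))
  class(out) <- c("BiasProfile", "data.frame")
  out
}

test_that("length profile equals a hand tally and conserves read-ends", {
  frags <- toy_frags()
  # three events over the chr1 fragments (lengths 1001, 1500, 1700, 1799)
  ev <- data.frame(frag_a = c(1L, 1L, 2L), frag_b = c(2L, 3L, 3L))
  lp <- length_profile(frags, ev, bin = 100)
  # fragment 1 has length 1001 -> bin [1000,1100); two ends land there
  b1 <- which(lp$bin_lo == 1000)
  expect_equal(lp$R[b1], 2)
  expect_equal(sum(lp$R), 2 * nrow(ev))              # each event = two ends
  expect_equal(sum(lp$N), nrow(frags))
  # empty bins are flagged, not silently zero
  expect_true(all(is.na(lp$r[lp$N == 0])))
  expect_true(all(attr(lp, "flagged_empty") %in% which(lp$N == 0)))
})

test_that("profiles are invariant under duplicating fragments and events", {
  frags <- toy_frags()
  ev <- data.frame(frag_a = c(1L, 2L), frag_b = c(3L, 4L))
  lp1 <- length_profile(frags, ev)
  frags2 <- rbind(as.data.frame(frags), as.data.frame(frags))
  class(frags2) <- class(frags)
  lp2 <- length_profile(frags2, rbind(ev, ev))
  expect_equal(lp2$r, 2 * lp1$R / (2 * lp1$N))       # ratio estimator
  expect_equal(lp2$r[lp1$N > 0], lp1$r[lp1$N > 0])
})

test_that("the crosslink fit recovers (A, p_c) from noiseless samples", {
  mids <- seq(50, 2950, by = 100)
  for (par in list(c(1000, 0.01), c(4000, 0.004), c(250, 0.1))) {
    A <- par[1L]; pc <- par[2L]
    r <- A * (1 - (1 - pc)^mids)
    prof <- make_profile(mids - 50, mids + 50, rep(10, length(mids)),
                         r * 10)
    fit <- fit_crosslink(prof)
    expect_true(fit$converged)
    expect_equal(fit$A, A, tolerance = 1e-6)
    expect_equal(fit$p_c, pc, tolerance = 1e-6)
  }
  # saturated profile: p_c at the boundary is flagged degenerate
  prof_sat <- make_profile(seq(0, 900, 100), seq(100, 1000, 100),
                           rep(5, 10), rep(5 * 1000, 10))
  fit_sat <- fit_crosslink(prof_sat)
  expect_true(fit_sat$degenerate)
  expect_error(fit_crosslink(make_profile(0, 100, 5, 10)), "3 occupied")
})

test_that("the length bias saturates near 800 bp on generator output", {
  # crosslink bias on: reads per fragment rise with length then plateau
  sim <- default_sim()
  fe <- filter_events(sim$pairs, sim$frags, condition = "A")
  lp <- length_profile(sim$frags, fe$events)
  mid <- (lp$bin_lo + lp$bin_hi) / 2
  ok <- lp$N >= 3 & !is.na(lp$r)
  short <- ok & mid < 500
  long <- ok & mid >= 1000 & mid <= 4000
  # monotone rise at short lengths, flat at long lengths
  expect_gt(mean(lp$r[long]), 2 * mean(lp$r[short & mid < 300]))
  r_long <- lp$r[long]
  expect_lt(stats::sd(r_long) / mean(r_long), 0.5)   # plateau, not a trend
  fit <- fit_crosslink(lp)
  expect_true(fit$converged)
  # recovered per-bp crosslink probability near the generator's 0.004
  expect_gt(fit$p_c, 0.002); expect_lt(fit$p_c, 0.008)
})

test_that("gc profile bins the mean of the two engaged ends", {
  frags <- toy_frags()
  ev <- data.frame(gc_a = 0.40, gc_b = 0.50)
  gp <- gc_profile(ev, frags)
  hit <- which(gp$R > 0)
  expect_length(hit, 1L)
  expect_true(gp$bin_lo[hit] <= 0.45 && gp$bin_hi[hit] > 0.45)
  expect_equal(sum(gp$R), 1)
})

test_that("circularization profile counts and normalizes per 1 bp bin", {
  frags <- toy_frags()
  ev <- data.frame(circle_length = c(100, 100, 200))
  cp <- circularization_profile(ev, frags)
  expect_equal(cp$R[cp$bin_lo == 100], 2)
  expect_equal(cp$R[cp$bin_lo == 200], 1)
  expect_equal(sum(cp$R), 3)
  # the possible-pair universe is the exact unordered-pair convolution
  d <- c(frags$d_minus[frags$valid_minus], frags$d_plus[frags$valid_plus])
  d <- d[!is.na(d)]
  pairs <- utils::combn(d, 2)
  expected_N <- table(colSums(pairs))
  for (s in as.integer(names(expected_N))[1:5])
    expect_equal(cp$N[cp$bin_lo == s], as.numeric(expected_N[as.character(s)]))
})

test_that("spectral period estimation finds a planted 10.5 bp cosine", {
  L <- 1:499
  r <- 10 + 3 * cos(2 * pi * L / 10.5)
  prof <- make_profile(L, L + 1, rep(100, length(L)), r * 100)
  est <- estimate_period(prof)
  expect_true(est$significant)
  expect_equal(est$period, 10.5, tolerance = 0.05)

  # constant profile: no significant periodicity
  flat <- make_profile(L, L + 1, rep(100, length(L)), rep(1000, length(L)))
  est0 <- estimate_period(flat)
  expect_false(est0$significant)
  expect_true(is.na(est0$period))

  expect_error(estimate_period(make_profile(1:20, 2:21, rep(1, 20), rep(1, 20))),
               "64")
})

test_that("profile_mode locates a smooth peak", {
  L <- 1:1500
  r <- exp(-(log(L) - log(500))^2 / (2 * 0.35^2))
  prof <- make_profile(L, L + 1, rep(1000, length(L)), r * 1000)
  expect_equal(profile_mode(prof), 500, tolerance = 0.02)
})

test_that("distance expectation reproduces a planted power law", {
  # counts exactly D^-1 (scaled): the log-log polynomial fit recovers the
  # exponent and residuals vanish
  n <- 80
  cmv <- matrix(0, n, n)
  mid <- (seq_len(n) - 0.5) * 1000
  dg <- abs(outer(mid, mid, "-"))
  cmv[upper.tri(cmv)] <- 1e6 / dg[upper.tri(dg)]
  cmv <- cmv + t(cmv)
  cm <- cm_from_matrix(cmv)
  de <- distance_expectation(cm, degree = 8)
  # residuals limited by log-binning discreteness only, not by the fit
  expect_lt(max(abs(stats::resid(de$fit))), 0.05)
  # implied exponent between two probe distances
  e1 <- expected_contacts(de, 5000); e2 <- expected_contacts(de, 50000)
  slope <- (log10(e2) - log10(e1)) / 1
  expect_equal(slope, -1, tolerance = 0.05)

  # uniform matrix: flat expectation
  cu <- cm_from_matrix(matrix(1, 30, 30) - diag(30) + diag(30))
  de_u <- distance_expectation(cu, degree = 3)
  probe <- expected_contacts(de_u, c(2000, 10000, 25000))
  expect_lt(max(abs(probe / probe[1L] - 1)), 0.05)
})

test_that("distance exponent is recovered from sampled generator counts", {
  sim <- default_sim()
  set.seed(99)
  cmi <- sample_contacts(sim$propensities, sim$frags, 3e5, scope = "intra")
  de <- distance_expectation(cmi)
  e1 <- expected_contacts(de, 4000); e2 <- expected_contacts(de, 40000)
  beta_hat <- -(log10(e2) - log10(e1))
  expect_equal(beta_hat, sim$config$decay_exponent, tolerance = 0.15)
})

test_that("distance normalization flattens matched counts and is linear", {
  n <- 60
  mid <- (seq_len(n) - 0.5) * 1000
  dg <- abs(outer(mid, mid, "-"))
  v <- 1e5 / pmax(dg, 1)^1.4
  diag(v) <- 0
  cm <- cm_from_matrix(v)
  de <- distance_expectation(cm, degree = 8)
  # replace counts by the fitted expectation itself: normalization -> 1
  ve <- matrix(0, n, n)
  ve[upper.tri(ve)] <- expected_contacts(de, dg[upper.tri(dg)])
  ve <- ve + t(ve)
  cme <- cm_from_matrix(ve)
  dn <- distance_normalize(cme, de)
  off <- upper.tri(dn$values)
  expect_equal(unname(dn$values[off]), rep(1, sum(off)), tolerance = 1e-9)
  # linearity: doubling counts doubles the normalized values
  cm2 <- cm_from_matrix(2 * ve)
  dn2 <- distance_normalize(cm2, de)
  expect_equal(dn2$values, 2 * dn$values)
})
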
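# Mate assignment, event classification, filtering, matrix accumulation.

test_that("mapping quality follows the phred transform", {
  expect_identical(mapq_from_error(0.001), 30L)
  expect_identical(mapq_from_error(1), 0L)
  expect_identical(mapq_from_error(0.01), 20L)
  expect_error(mapq_from_error(0), "0, 1")
  expect_error(mapq_from_error(-1), "0, 1")
})

test_that("mates engage the 3'-direction boundary with the right distance", {
  frags <- toy_frags()
  # chr1 cuts at 1001, 2501, 4201; second fragment is [1001, 2501)
  f2 <- frags[frags$chrom == "chr1", ][2L, ]
  mates <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr9", "chr1"),
    pos = c(f2$end - 21,    # forward mate 21 bp left of the '+' boundary
            f2$start + 21,  # reverse mate 21 bp right of the '-' boundary
            f2$end,         # exactly on the next cut site (next fragment)
            50,             # unknown chromosome
            -5),            # out of range
    strand = c("+", "-", "+", "+", "+"))
  ea <- assign_end(mates, frags)
  expect_equal(ea$extremity[1:2], c("+", "-"))
  expect_equal(ea$dist_re1[1:2], c(21, 21))
  expect_equal(ea$fragment_id[1:2], rep(f2$fragment_id, 2))
  # a mate exactly on a cut site belongs to the next fragment, distance 0
  # from its '-' boundary but engages '+' on the forward strand
  expect_equal(ea$fragment_id[3L], f2$fragment_id + 1L)
  expect_true(all(is.na(ea$fragment_id[4:5])))
})

test_that("orientation patterns diagnose the event classes", {
  frags <- toy_frags()
  ids <- frags$fragment_id[frags$chrom == "chr1"]
  mk <- function(fid, ext, off = 21) {
    # place a mate engaging the requested extremity of fragment fid
    f <- frags[fid, ]
    if (ext == "+") data.frame(chrom = f$chrom, pos = f$end - off, strand = "+",
                               mapq = 37)
    else data.frame(chrom = f$chrom, pos = f$start + off, strand = "-", mapq = 37)
  }
  pair_of <- function(m1, m2) data.frame(
    chrom1 = m1$chrom, pos1 = m1$pos, strand1 = m1$strand, mapq1 = m1$mapq,
    chrom2 = m2$chrom, pos2 = m2$pos, strand2 = m2$strand, mapq2 = m2$mapq)

  cases <- rbind(
    pair_of(mk(ids[2], "-"), mk(ids[2], "+")),   # one fragment, -/+: self loop
    pair_of(mk(ids[1], "+"), mk(ids[2], "-")),   # adjacent +/-: religation
    pair_of(mk(ids[1], "-"), mk(ids[2], "+")),   # adjacent -/+: adjacent loop
    pair_of(mk(ids[1], "+"), mk(ids[3], "-")),   # same chrom, 1 apart
    pair_of(mk(ids[1], "-"),                      # different chromosomes
            mk(frags$fragment_id[frags$chrom == "chr2"][1L], "+")))
  ev <- classify_pairs(cases, frags)
  expect_equal(ev$event_class,
               c("self_loop", "religation", "adjacent_loop",
                 "long_range_intra", "long_range_inter"))
  expect_equal(ev$orientation[1:3], c("-/+", "+/-", "-/+"))

  # classification is invariant under swapping mate order
  swapped <- cases[, c(5:8, 1:4)]
  names(swapped) <- names(cases)
  ev2 <- classify_pairs(swapped, frags)
  expect_equal(ev2$event_class, ev$event_class)
  expect_equal(ev2$orientation, ev$orientation)
  expect_equal(ev2$frag_a, ev$frag_a)

  # intra genomic distance is the midpoint separation
  mid <- fragment_mid(frags)
  expect_equal(ev$D_g[4L], abs(mid[ids[3]] - mid[ids[1]]))
  expect_true(is.na(ev$D_g[5L]))
  # circle length sums the two engaged arms
  expect_equal(ev$circle_length, ev$d_a + ev$d_b)
})

test_that("the RE1-distance window separates conditions A and B", {
  frags <- toy_frags()
  f <- frags[2L, ]
  mate1 <- data.frame(chrom1 = f$chrom, pos1 = f$end - 23, strand1 = "+",
                      mapq1 = 37)
  mate2 <- data.frame(chrom2 = f$chrom, pos2 = frags$start[4L] + 21,
                      strand2 = "-", mapq2 = 37)
  pr <- cbind(mate1, mate2)
  # distance 23 fails condition A but passes condition B
  a <- filter_events(pr, frags, condition = "A")
  b <- filter_events(pr, frags, condition = "B")
  expect_equal(a$summary$removed$dist_re1, 1L)
  expect_equal(a$summary$n_kept, 0L)
  expect_equal(b$summary$removed$dist_re1, 0L)
  expect_equal(b$summary$n_kept, 1L)
})

test_that("filter accounting closes and malformed rows never kill the run", {
  sim <- default_sim()
  pairs <- sim$pairs
  # corrupt a few rows
  pairs$strand1[1:3] <- "?"
  pairs$pos2[4:5] <- NA
  fe <- filter_events(pairs, sim$frags, condition = "A")
  s <- fe$summary
  expect_equal(s$removed$malformed, 5L)
  expect_equal(s$n_input, s$n_kept + sum(unlist(s$removed)))
  # class fractions sum to one over classified events
  expect_equal(sum(unlist(s$class_fractions)), 1, tolerance = 1e-12)
  expect_equal(sum(unlist(s$class_counts)),
               s$n_input - s$removed$malformed - s$removed$unassigned -
                 s$removed$mapq - s$removed$dist_re1)
  # kept events are exclusively long-range
  expect_true(all(fe$events$event_class %in%
                    c("long_range_intra", "long_range_inter")))
})

test_that("the classifier agrees exactly with generator truth labels", {
  sim <- default_sim()
  ev <- classify_pairs(sim$pairs, sim$frags)
  expect_equal(attr(ev, "n_unassigned"), 0L)
  expect_identical(ev$event_class, sim$truth$event_class)
  expect_identical(ev$frag_a, pmin(sim$truth$frag_a, sim$truth$frag_b))
  expect_identical(ev$frag_b, pmax(sim$truth$frag_a, sim$truth$frag_b))
})

test_that("contact matrices match a brute-force tally and stay symmetric", {
  frags <- toy_frags()
  # empty event list: zero matrix
  ev0 <- data.frame(frag_a = integer(0), frag_b = integer(0))
  cm0 <- build_contact_matrix(ev0, frags)
  expect_true(all(cm0$values == 0))

  # single event between two retained fragments
  valid <- frags$fragment_id[frags$has_valid_re2]
  ev1 <- data.frame(frag_a = valid[1L], frag_b = valid[2L])
  cm1 <- build_contact_matrix(ev1, frags)
  i <- match(valid[1L], cm1$index$fragment_id)
  j <- match(valid[2L], cm1$index$fragment_id)
  expect_equal(cm1$values[i, j], 1)
  expect_equal(cm1$values[j, i], 1)
  expect_equal(sum(cm1$values), 2)

  # random stream over 3 fragments equals an independent counting oracle
  set.seed(1)
  fr3 <- valid[1:3]
  ev <- data.frame(frag_a = sample(fr3, 200, TRUE),
                   frag_b = sample(fr3, 200, TRUE))
  cm <- build_contact_matrix(ev, frags)
  rows <- match(fr3, cm$index$fragment_id)
  for (a in 1:3) for (b in 1:3) {
    expected <- if (a == b) sum(ev$frag_a == fr3[a] & ev$frag_b == fr3[a]) else
      sum((ev$frag_a == fr3[a] & ev$frag_b == fr3[b]) |
            (ev$frag_a == fr3[b] & ev$frag_b == fr3[a]))
    expect_equal(cm$values[rows[a], rows[b]], expected)
  }
  expect_equal(cm$values, t(cm$values))
  # off-diagonal mass is twice the number of off-diagonal events
  off <- sum(ev$frag_a != ev$frag_b)
  expect_equal(sum(cm$values) - sum(diag(cm$values)), 2 * off)

  # events touching filtered fragments are skipped with a tally
  bad <- frags$fragment_id[!frags$has_valid_re2][1L]
  ev_bad <- data.frame(frag_a = c(valid[1L], bad), frag_b = c(valid[2L], valid[1L]))
  cm_b <- build_contact_matrix(ev_bad, frags)
  expect_equal(cm_b$skipped, 1L)

  # scope separation
  sim <- default_sim()
  fe <- filter_events(sim$pairs, sim$frags, condition = "A")
  cm_i <- build_contact_matrix(fe$events, sim$frags, scope = "intra")
  cm_x <- build_contact_matrix(fe$events, sim$frags, scope = "inter")
  same <- outer(cm_i$index$chrom, cm_i$index$chrom, "==")
  expect_true(all(cm_i$values[!same] == 0))
  expect_true(all(cm_x$values[same] == 0))
})

test_that("pairs round-trip through the TSV format", {
  sim <- default_sim()
  p <- utils::head(sim$pairs, 100)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(p, tf)
  p2 <- read_pairs(tf)
  expect_equal(p2, p, ignore_attr = TRUE)
})
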
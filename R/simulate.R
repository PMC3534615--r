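# Synthetic-data generator: toy genomes with planted restriction sites,
# ground-truth contact propensities, and paired-end 3C tags carrying every
# modeled bias, with truth labels. This is the forward model of the protocol
# used by the parameter-recovery test suite.

#' Generator configuration
#'
#' Defaults encode the study conditions the package is validated against:
#' an event mixture with 80% loops+religations, a polymer-like intra
#' distance decay, a Gaussian GC acceptance peaked at 45%, a log-normal
#' circularization envelope with a 500-bp optimum modulated by the 10.5-bp
#' helical twist, and mate offsets of 20-22 bp from the RE1 cut (condition
#' A geometry).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param re1_motif,re1_offset,re1_spacing Primary enzyme: motif, cut offset
#'   within it, and mean spacing (bp) of planted sites (6-cutter-like).
#' @param re2_motif,re2_offset,re2_spacing Secondary enzyme, 4-cutter-like.
#' @param mixture Event-class probabilities over `self_loop`, `religation`,
#'   `adjacent_loop`, `long_range_intra`, `long_range_inter`; must sum to 1.
#' @param decay_exponent Intra-chromosomal contact decay exponent beta in
#'   `propensity ~ D_g^(-beta)`.
#' @param inter_base Relative propensity of inter-chromosomal pairs.
#' @param length_bias,p_c Crosslink length bias switch and per-bp crosslink
#'   probability: fragment factor `f(L) = 1 - (1 - p_c)^L`.
#' @param gc_bias,gc_mu,gc_sigma GC acceptance switch and Gaussian optimum /
#'   width on the mean end-GC fraction.
#' @param circ_bias,circ_opt,circ_log_sd Circularization acceptance switch
#'   and log-normal envelope: optimum (bp) and log-sd.
#' @param twist_amp,twist_period Helical-twist modulation amplitude (0
#'   disables) and period (bp) of the circularization acceptance.
#' @param offsets,offset_probs Mate 5'-to-cut offsets and their
#'   probabilities.
#' @param mapq_good,low_mapq_frac Mapping quality of clean reads and the
#'   fraction drawn with a low (0-29) quality.
#' @param coloc_fragments,coloc_gamma Fragment ids of a planted
#'   colocalization block and its pairwise enrichment factor.
#' @param boost_fragments,boost_factor Fragment ids with inflated global
#'   coverage (every pair touching them is multiplied by the factor): the
#'   "interacts more with everything" artifact, not true colocalization.
#' @param seed Mandatory random seed.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(chrom_lengths = c(chrI = 200000L, chrII = 200000L,
                                         chrIII = 200000L),
                       re1_motif = "AAGCTT", re1_offset = 1L, re1_spacing = 2000,
                       re2_motif = "CCGG", re2_offset = 1L, re2_spacing = 300,
                       mixture = c(self_loop = 0.40, religation = 0.35,
                                   adjacent_loop = 0.05,
                                   long_range_intra = 0.12,
                                   long_range_inter = 0.08),
                       decay_exponent = 1.5, inter_base = 1e-3,
                       length_bias = TRUE, p_c = 0.004,
                       gc_bias = TRUE, gc_mu = 0.45, gc_sigma = 0.10,
                       circ_bias = TRUE, circ_opt = 500, circ_log_sd = 0.35,
                       twist_amp = 0.3, twist_period = 10.5,
                       offsets = c(20L, 21L, 22L),
                       offset_probs = c(1, 1, 1) / 3,
                       mapq_good = 37L, low_mapq_frac = 0.02,
                       coloc_fragments = integer(0), coloc_gamma = 1,
                       boost_fragments = integer(0), boost_factor = 1,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: a seed is mandatory for reproducibility")
  classes <- c("self_loop", "religation", "adjacent_loop",
               "long_range_intra", "long_range_inter")
  if (!all(classes %in% names(mixture)) || abs(sum(mixture) - 1) > 1e-9)
    stop("mixture must be named over the five event classes and sum to 1")
  stopifnot(decay_exponent > 0, inter_base > 0,
            p_c > 0, p_c < 1, gc_mu > 0, gc_mu < 1, gc_sigma > 0,
            circ_opt > 0, circ_log_sd > 0,
            twist_amp >= 0, twist_amp < 1, twist_period > 0,
            length(offsets) == length(offset_probs),
            abs(sum(offset_probs) - 1) < 1e-9,
            low_mapq_frac >= 0, low_mapq_frac < 1,
            coloc_gamma >= 1, boost_factor >= 1)
  cfg <- list(chrom_lengths = chrom_lengths,
              re1_motif = re1_motif, re1_offset = re1_offset,
              re1_spacing = re1_spacing,
              re2_motif = re2_motif, re2_offset = re2_offset,
              re2_spacing = re2_spacing,
              mixture = mixture[classes], decay_exponent = decay_exponent,
              inter_base = inter_base,
              length_bias = length_bias, p_c = p_c,
              gc_bias = gc_bias, gc_mu = gc_mu, gc_sigma = gc_sigma,
              circ_bias = circ_bias, circ_opt = circ_opt,
              circ_log_sd = circ_log_sd,
              twist_amp = twist_amp, twist_period = twist_period,
              offsets = offsets, offset_probs = offset_probs,
              mapq_good = mapq_good, low_mapq_frac = low_mapq_frac,
              coloc_fragments = coloc_fragments, coloc_gamma = coloc_gamma,
              boost_fragments = boost_fragments, boost_factor = boost_factor,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# remove every occurrence of the given motifs from a random sequence by
# point mutation, iterating until clean
.scrub_motifs <- function(chars, motifs, max_rounds = 25L) {
  seq_str <- paste(chars, collapse = "")
  for (round in seq_len(max_rounds)) {
    dirty <- FALSE
    for (mo in motifs) {
      x <- Biostrings::DNAString(seq_str)
      st <- Biostrings::start(Biostrings::matchPattern(mo, x))
      if (length(st)) {
        dirty <- TRUE
        at <- st + (nchar(mo) %/% 2L)         # mutate a middle base
        cur <- substring(seq_str, at, at)
        repl <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        for (k in seq_along(at))
          substr(seq_str, at[k], at[k]) <- repl[k]
      }
    }
    if (!dirty) return(seq_str)
  }
  stop("could not scrub accidental motif occurrences")
}

#' Generate a toy genome with planted restriction sites
#'
#' Random A/C/G/T background, scrubbed of accidental RE1/RE2 occurrences,
#' with RE1 and RE2 motifs planted at exponentially distributed spacings
#' (Poisson-process site placement, like a real digest). After planting the
#' sequence is re-verified: the motif occurrence sets equal the planted
#' sets exactly, so [digest_genome()] recovers the planted boundaries.
#'
#' Sets the RNG seed from `config$seed`; two calls with the same config are
#' byte-identical.
#'
#' @param config A `SimConfig`.
#' @return A [Biostrings::DNAStringSet].
#' @export
make_toy_genome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config$seed)
  motifs <- unique(c(config$re1_motif, config$re2_motif))
  out <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    seq_str <- .scrub_motifs(chars, motifs)

    plant <- function(seq_str, motif, spacing, avoid) {
      w <- nchar(motif)
      if (!is.finite(spacing) || spacing <= 0) return(list(seq = seq_str, pos = integer(0)))
      gaps <- stats::rexp(ceiling(2.5 * len / spacing) + 10L, rate = 1 / spacing)
      pos <- as.integer(cumsum(pmax(round(gaps), w + 1L)))
      pos <- pos[pos + w - 1L <= len - 1L & pos >= 1L]   # 0-based motif starts
      # drop plants that would overlap an existing (avoid) motif
      if (length(avoid)) {
        wa <- max(nchar(motifs))
        bad <- vapply(pos, function(p0) any(avoid < p0 + w & avoid + wa > p0),
                      logical(1L))
        pos <- pos[!bad]
      }
      for (p0 in pos) substr(seq_str, p0 + 1L, p0 + w) <- motif
      list(seq = seq_str, pos = pos)
    }
    p1 <- plant(seq_str, config$re1_motif, config$re1_spacing, integer(0))
    p2 <- plant(p1$seq, config$re2_motif, config$re2_spacing, p1$pos)
    seq_str <- p2$seq
    # planted intervals (0-based) that the repair step below must not touch
    w1 <- nchar(config$re1_motif); w2 <- nchar(config$re2_motif)
    protected <- c(unlist(lapply(p1$pos, function(p0) p0:(p0 + w1 - 1L))),
                   unlist(lapply(p2$pos, function(p0) p0:(p0 + w2 - 1L))))
    # verify: planting may create new occurrences at junctions; mutate a
    # base of each accidental occurrence outside the planted intervals
    for (round in 1:25) {
      x <- Biostrings::DNAString(seq_str)
      extra1 <- setdiff(Biostrings::start(Biostrings::matchPattern(config$re1_motif, x)) - 1L, p1$pos)
      extra2 <- if (config$re2_motif == config$re1_motif) integer(0) else
        setdiff(Biostrings::start(Biostrings::matchPattern(config$re2_motif, x)) - 1L, p2$pos)
      if (!length(extra1) && !length(extra2)) break
      if (round == 25L) stop("could not stabilize planted motif set")
      occ <- c(extra1, extra2)
      wd <- c(rep(w1, length(extra1)), rep(w2, length(extra2)))
      for (k in seq_along(occ)) {
        cand <- setdiff(occ[k]:(occ[k] + wd[k] - 1L), protected)
        if (!length(cand)) next
        at <- cand[1L] + 1L
        cur <- substring(seq_str, at, at)
        substr(seq_str, at, at) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    list(seq = seq_str, re1 = p1$pos, re2 = p2$pos)
  })
  gen <- Biostrings::DNAStringSet(setNames(vapply(out, `[[`, "", "seq"),
                                           names(config$chrom_lengths)))
  attr(gen, "re1_sites") <- setNames(lapply(out, `[[`, "re1"),
                                     names(config$chrom_lengths))
  attr(gen, "re2_sites") <- setNames(lapply(out, `[[`, "re2"),
                                     names(config$chrom_lengths))
  gen
}

#' Ground-truth contact propensities
#'
#' `propensity(i, j)` is `D_g^(-beta)` for intra pairs and `inter_base` for
#' inter pairs, times `gamma` when both fragments belong to the planted
#' colocalization block, times the separable coverage factors `b_i b_j`
#' (`b = boost_factor` inside the boost set, 1 outside — fragments that
#' interact more with everything), times the crosslink length factors
#' `f(L_i) f(L_j)` with `f(L) = 1 - (1 - p_c)^L` when the length bias is
#' on. The diagonal is 0.
#'
#' @param frags An annotated `FragmentTable`.
#' @param config A `SimConfig`.
#' @return Dense symmetric propensity matrix.
#' @export
simulate_propensities <- function(frags, config) {
  stopifnot(is(config, "SimConfig"))
  n <- nrow(frags)
  mid <- fragment_mid(frags)
  dg <- abs(outer(mid, mid, "-"))
  same <- outer(frags$chrom, frags$chrom, "==")
  p <- matrix(config$inter_base, n, n)
  p[same] <- pmax(dg[same], 1)^(-config$decay_exponent)
  if (length(config$coloc_fragments) && config$coloc_gamma != 1) {
    inb <- frags$fragment_id %in% config$coloc_fragments
    p[outer(inb, inb, "&")] <- p[outer(inb, inb, "&")] * config$coloc_gamma
  }
  if (length(config$boost_fragments) && config$boost_factor != 1) {
    # separable per-fragment coverage factor: a boosted fragment interacts
    # more with *everything*, so a pair scales as b_i * b_j
    b <- ifelse(frags$fragment_id %in% config$boost_fragments,
                config$boost_factor, 1)
    p <- p * outer(b, b)
  }
  if (config$length_bias) {
    f <- 1 - (1 - config$p_c)^frags$length
    p <- p * outer(f, f)
  }
  diag(p) <- 0
  p
}

#' Sample a contact matrix directly from propensities
#'
#' Draws `n_events` independent contacts from the (upper-triangle)
#' propensity weights and accumulates them into a symmetric count matrix —
#' the idealized experiment without read-level noise, used for
#' normalization and colocalization recovery tests.
#'
#' @param propensities Matrix from [simulate_propensities()].
#' @param frags The matching `FragmentTable`.
#' @param n_events Number of contacts to draw.
#' @param scope `"all"`, `"intra"` or `"inter"`.
#' @return A `ContactMatrix`.
#' @export
sample_contacts <- function(propensities, frags, n_events,
                            scope = c("all", "intra", "inter")) {
  scope <- match.arg(scope)
  n <- nrow(propensities)
  same <- outer(frags$chrom, frags$chrom, "==")
  sel <- upper.tri(propensities)
  if (scope == "intra") sel <- sel & same
  if (scope == "inter") sel <- sel & !same
  w <- propensities; w[!sel] <- 0
  idx <- which(sel & w > 0)
  draws <- sample(idx, n_events, replace = TRUE, prob = w[idx])
  tab <- tabulate(factor(draws, levels = idx), nbins = length(idx))
  v <- matrix(0, n, n)
  v[idx] <- tab
  v <- v + t(v)
  index <- data.frame(fragment_id = frags$fragment_id, chrom = frags$chrom,
                      start = frags$start, end = frags$end,
                      mid = fragment_mid(frags), stringsAsFactors = FALSE)
  contact_matrix(v, index, scope = scope)
}

#' Emit paired-end 3C tags with truth labels
#'
#' The forward model of the protocol: draw an event class from the mixture,
#' draw partner fragments (propensity-weighted for long-range classes,
#' adjacency for religations and loops, crosslink-weighted fragment choice
#' for single/adjacent-fragment classes), draw engaged extremities, then
#' accept/reject by the GC factor `exp(-(gc - mu)^2 / (2 sigma^2))` and the
#' circularization factor `env(d_A + d_B) * (1 + amp *
#' cos(2 pi L / T)) / (1 + amp)` with a log-normal envelope peaked at the
#' configured optimum. Accepted events are written as mate pairs: 5' ends at
#' the configured offsets from the engaged cut sites with the matching
#' strands (forward mates engage `+` extremities), in random mate order.
#'
#' Candidates whose mate offset reaches past the engaged fragment, or (when
#' the circularization bias is on) whose circle length is undefined because
#' a fragment lacks RE2 sites, are rejected — such molecules are not
#' observable under the protocol geometry.
#'
#' Sets the RNG seed to `config$seed + 9973` so genome generation and tag
#' emission are independently reproducible.
#'
#' @param frags Annotated `FragmentTable`.
#' @param propensities Matrix from [simulate_propensities()].
#' @param config A `SimConfig`.
#' @param n_pairs Number of accepted pairs to emit.
#' @return `list(pairs, truth, acceptance_rate)`: `pairs` is the 8-column
#'   pairs table; `truth` carries the generative class, fragments,
#'   extremities, circle length and mean GC per emitted pair.
#' @export
emit_read_pairs <- function(frags, propensities, config, n_pairs) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config$seed + 9973L)
  n <- nrow(frags)
  classes <- names(config$mixture)
  chrom <- frags$chrom
  Ls <- frags$length
  d_of <- cbind(`-` = frags$d_minus, `+` = frags$d_plus)
  gc_of <- cbind(`-` = frags$end_gc_minus, `+` = frags$end_gc_plus)
  max_off <- max(config$offsets)

  f_len <- if (config$length_bias) 1 - (1 - config$p_c)^Ls else rep(1, n)
  self_ok <- which(Ls > max_off)
  w_self <- f_len[self_ok]^2
  adj_up <- which(chrom[-n] == chrom[-1L])        # upstream index of adjacent pairs
  w_adj <- f_len[adj_up] * f_len[adj_up + 1L]
  same <- outer(chrom, chrom, "==")
  ut <- upper.tri(propensities)
  intra_idx <- which(ut & same & abs(row(propensities) - col(propensities)) > 1L &
                       propensities > 0)
  inter_idx <- which(ut & !same & propensities > 0)
  if (!length(intra_idx) && config$mixture[["long_range_intra"]] > 0)
    stop("no eligible long-range intra pairs")
  if (!length(inter_idx) && config$mixture[["long_range_inter"]] > 0)
    stop("no eligible inter pairs")
  w_intra <- propensities[intra_idx]
  w_inter <- propensities[inter_idx]
  ij_from_lin <- function(lin) cbind((lin - 1L) %% n + 1L, (lin - 1L) %/% n + 1L)

  acc_fa <- acc_fb <- acc_ea <- acc_eb <- acc_cls <- list()
  n_acc <- 0L; n_drawn <- 0L; chunk_no <- 0L
  rate_est <- 0.3
  while (n_acc < n_pairs) {
    chunk_no <- chunk_no + 1L
    m <- min(max(ceiling((n_pairs - n_acc) / rate_est * 1.25), 2e4), 2e6)
    cls <- sample(classes, m, replace = TRUE, prob = config$mixture)
    fa <- fb <- integer(m)
    ea <- eb <- character(m)

    k <- cls == "self_loop"
    if (any(k)) {
      f0 <- self_ok[sample.int(length(self_ok), sum(k), replace = TRUE, prob = w_self)]
      fa[k] <- f0; fb[k] <- f0; ea[k] <- "-"; eb[k] <- "+"
    }
    k <- cls == "religation"
    if (any(k)) {
      up <- adj_up[sample.int(length(adj_up), sum(k), replace = TRUE, prob = w_adj)]
      fa[k] <- up; fb[k] <- up + 1L; ea[k] <- "+"; eb[k] <- "-"
    }
    k <- cls == "adjacent_loop"
    if (any(k)) {
      up <- adj_up[sample.int(length(adj_up), sum(k), replace = TRUE, prob = w_adj)]
      fa[k] <- up; fb[k] <- up + 1L; ea[k] <- "-"; eb[k] <- "+"
    }
    k <- cls == "long_range_intra"
    if (any(k)) {
      lin <- intra_idx[sample.int(length(intra_idx), sum(k), replace = TRUE, prob = w_intra)]
      ij <- ij_from_lin(lin)
      fa[k] <- ij[, 1L]; fb[k] <- ij[, 2L]
      ea[k] <- sample(c("-", "+"), sum(k), replace = TRUE)
      eb[k] <- sample(c("-", "+"), sum(k), replace = TRUE)
    }
    k <- cls == "long_range_inter"
    if (any(k)) {
      lin <- inter_idx[sample.int(length(inter_idx), sum(k), replace = TRUE, prob = w_inter)]
      ij <- ij_from_lin(lin)
      fa[k] <- ij[, 1L]; fb[k] <- ij[, 2L]
      ea[k] <- sample(c("-", "+"), sum(k), replace = TRUE)
      eb[k] <- sample(c("-", "+"), sum(k), replace = TRUE)
    }

    d_a <- d_of[cbind(fa, match(ea, c("-", "+")))]
    d_b <- d_of[cbind(fb, match(eb, c("-", "+")))]
    gc_a <- gc_of[cbind(fa, match(ea, c("-", "+")))]
    gc_b <- gc_of[cbind(fb, match(eb, c("-", "+")))]
    Lc <- d_a + d_b

    p_acc <- rep(1, m)
    if (config$gc_bias) {
      gm <- (gc_a + gc_b) / 2
      p_acc <- p_acc * exp(-(gm - config$gc_mu)^2 / (2 * config$gc_sigma^2))
    }
    if (config$circ_bias) {
      env <- exp(-(log(pmax(Lc, 1e-9)) - log(config$circ_opt))^2 /
                   (2 * config$circ_log_sd^2))
      tw <- (1 + config$twist_amp * cos(2 * pi * Lc / config$twist_period)) /
        (1 + config$twist_amp)
      p_acc <- p_acc * ifelse(is.na(Lc), 0, env * tw)
    }
    geom_ok <- Ls[fa] > max_off & Ls[fb] > max_off
    keep <- geom_ok & runif(m) < p_acc
    n_drawn <- n_drawn + m
    if (any(keep)) {
      acc_fa[[chunk_no]] <- fa[keep]; acc_fb[[chunk_no]] <- fb[keep]
      acc_ea[[chunk_no]] <- ea[keep]; acc_eb[[chunk_no]] <- eb[keep]
      acc_cls[[chunk_no]] <- cls[keep]
      n_acc <- n_acc + sum(keep)
    }
    rate_est <- max(n_acc / n_drawn, 1e-4)
    if (n_drawn >= 5e4 && n_acc / n_drawn < 0.001)
      stop("emit_read_pairs: acceptance rate below 0.1% - mis-configured biases")
  }
  fa <- unlist(acc_fa)[seq_len(n_pairs)]
  fb <- unlist(acc_fb)[seq_len(n_pairs)]
  ea <- unlist(acc_ea)[seq_len(n_pairs)]
  eb <- unlist(acc_eb)[seq_len(n_pairs)]
  cls <- unlist(acc_cls)[seq_len(n_pairs)]

  off_a <- config$offsets[sample.int(length(config$offsets), n_pairs,
                                     replace = TRUE, prob = config$offset_probs)]
  off_b <- config$offsets[sample.int(length(config$offsets), n_pairs,
                                     replace = TRUE, prob = config$offset_probs)]
  pos_a <- ifelse(ea == "-", frags$start[fa] + off_a, frags$end[fa] - off_a)
  pos_b <- ifelse(eb == "-", frags$start[fb] + off_b, frags$end[fb] - off_b)
  strand_a <- ea   # engaged '+' extremity <=> forward-strand mate
  strand_b <- eb
  draw_mapq <- function(k) ifelse(runif(k) < config$low_mapq_frac,
                                  sample(0:29, k, replace = TRUE),
                                  config$mapq_good)
  mq_a <- draw_mapq(n_pairs); mq_b <- draw_mapq(n_pairs)

  sw <- runif(n_pairs) < 0.5
  pairs <- data.frame(
    chrom1 = ifelse(sw, frags$chrom[fb], frags$chrom[fa]),
    pos1 = ifelse(sw, pos_b, pos_a),
    strand1 = ifelse(sw, strand_b, strand_a),
    mapq1 = ifelse(sw, mq_b, mq_a),
    chrom2 = ifelse(sw, frags$chrom[fa], frags$chrom[fb]),
    pos2 = ifelse(sw, pos_a, pos_b),
    strand2 = ifelse(sw, strand_a, strand_b),
    mapq2 = ifelse(sw, mq_a, mq_b),
    stringsAsFactors = FALSE)
  d_a <- d_of[cbind(fa, match(ea, c("-", "+")))]
  d_b <- d_of[cbind(fb, match(eb, c("-", "+")))]
  gc_a <- gc_of[cbind(fa, match(ea, c("-", "+")))]
  gc_b <- gc_of[cbind(fb, match(eb, c("-", "+")))]
  truth <- data.frame(event_class = cls, frag_a = fa, ext_a = ea,
                      frag_b = fb, ext_b = eb,
                      circle_length = d_a + d_b,
                      gc_mean = (gc_a + gc_b) / 2,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth, acceptance_rate = n_acc / n_drawn)
}

#' One-call synthetic dataset
#'
#' Generates the toy genome, builds and annotates the fragment table,
#' computes ground-truth propensities and emits `n_pairs` tagged read pairs.
#'
#' @param config A `SimConfig`.
#' @param n_pairs Number of read pairs to emit.
#' @param mappability Run the mappability scan on the toy genome (off by
#'   default: planted-motif toy genomes have essentially no repeats).
#' @return `list(genome, frags, propensities, pairs, truth,
#'   acceptance_rate)`.
#' @export
simulate_dataset <- function(config, n_pairs, mappability = FALSE) {
  genome <- make_toy_genome(config)
  frags <- build_fragment_table(genome, config$re1_motif, config$re2_motif,
                                re1_offset = config$re1_offset,
                                re2_offset = config$re2_offset,
                                mappability = mappability)
  prop <- simulate_propensities(frags, config)
  em <- emit_read_pairs(frags, prop, config, n_pairs)
  c(list(genome = genome, frags = frags, propensities = prop), em)
}
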
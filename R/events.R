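# Ligation-event assignment, classification, filtering and matrix accumulation.

#' Mapping quality from an error probability
#'
#' Phred-scaled mapping quality `Q = round(-10 * log10(p))` where `p` is the
#' probability that the reported alignment position is wrong. A one-in-a-
#' thousand error rate gives the standard filter value Q = 30.
#'
#' @param p_error Error probability in (0, 1].
#' @return Integer quality score.
#' @export
mapq_from_error <- function(p_error) {
  if (any(!is.finite(p_error)) || any(p_error <= 0) || any(p_error > 1))
    stop("'p_error' must be in (0, 1]")
  as.integer(round(-10 * log10(p_error)))
}

#' Number of distinct pairs among n restriction sites
#'
#' `n * (n - 1) / 2`, the count of potential pairwise interactions a digest
#' with `n` sites can produce (computed in double precision: for genome-scale
#' `n` the result exceeds integer range).
#'
#' @param n Number of sites/fragments.
#' @export
possible_pairs <- function(n) as.numeric(n) * (as.numeric(n) - 1) / 2

# chromosome order as it appears in the fragment table
.chrom_levels <- function(frags) unique(frags$chrom)

#' Assign read mates to fragment extremities
#'
#' Each mate engages the fragment boundary lying in its 3' direction: a
#' forward-strand mate engages the `+` (high-coordinate) extremity of the
#' fragment containing its 5' position, a reverse-strand mate the `-`
#' extremity. `dist_re1` is the distance from the 5' position to that
#' boundary's cut site; the protocol places it ~20 bp from the cut.
#'
#' @param mates `data.frame` with columns `chrom`, `pos` (0-based 5'
#'   coordinate), `strand` (`"+"`/`"-"`), and optionally `mapq`.
#' @param frags An annotated `FragmentTable`.
#' @return `data.frame` with columns `fragment_id`, `extremity`, `dist_re1`,
#'   `gc`, `d_circle`; rows that fall outside every fragment (unknown
#'   chromosome or out-of-range position) are `NA` ("unassigned").
#' @export
assign_end <- function(mates, frags) {
  n <- nrow(mates)
  fid <- rep(NA_integer_, n)
  for (chrom in .chrom_levels(frags)) {
    rows <- which(frags$chrom == chrom)
    sel <- which(mates$chrom == chrom)
    if (!length(sel)) next
    len <- frags$end[rows[length(rows)]]
    pos <- mates$pos[sel]
    ok <- !is.na(pos) & pos >= 0 & pos < len
    loc <- findInterval(pos[ok], frags$start[rows])
    fid[sel[ok]] <- rows[loc]
  }
  ext <- ifelse(mates$strand == "+", "+", "-")
  ext[!(mates$strand %in% c("+", "-"))] <- NA
  bad <- is.na(ext)
  fid[bad] <- NA_integer_
  dist <- ifelse(ext == "+", frags$end[fid] - mates$pos, mates$pos - frags$start[fid])
  gc <- ifelse(ext == "+", frags$end_gc_plus[fid], frags$end_gc_minus[fid])
  dc <- ifelse(ext == "+", frags$d_plus[fid], frags$d_minus[fid])
  valid <- ifelse(ext == "+", frags$valid_plus[fid], frags$valid_minus[fid])
  data.frame(fragment_id = fid, extremity = ext, dist_re1 = dist,
             gc = gc, d_circle = dc, re2_valid = valid,
             stringsAsFactors = FALSE)
}

#' Assign and classify paired-end ligation products
#'
#' Runs [assign_end()] on both mates and classifies each assigned pair:
#' same fragment is a `self_loop`; genomically adjacent fragments joined
#' upstream-`+` to downstream-`-` are a `religation` (the original sequence
#' restored), joined upstream-`-` to downstream-`+` an `adjacent_loop`
#' (two-fragment circle); every other same-chromosome pair is
#' `long_range_intra`, and pairs on different chromosomes `long_range_inter`.
#' Ends are reported with the lower-coordinate fragment first, so
#' classification is invariant under swapping mate order.
#'
#' @param pairs `data.frame` with columns `chrom1`, `pos1`, `strand1`,
#'   `mapq1`, `chrom2`, `pos2`, `strand2`, `mapq2` (the pairs-TSV layout).
#' @param frags An annotated `FragmentTable`.
#' @return `data.frame` of classified events (one row per assigned pair) with
#'   per-end columns (`frag_a` <= `frag_b` in genome order), `event_class`,
#'   `orientation`, genomic distance `D_g` (fragment-midpoint distance, `NA`
#'   for inter), and `circle_length` = d_A + d_B. The number of pairs dropped
#'   as unassigned is in `attr(, "n_unassigned")`.
#' @export
classify_pairs <- function(pairs, frags) {
  e1 <- assign_end(data.frame(chrom = pairs$chrom1, pos = pairs$pos1,
                              strand = pairs$strand1), frags)
  e2 <- assign_end(data.frame(chrom = pairs$chrom2, pos = pairs$pos2,
                              strand = pairs$strand2), frags)
  e1$mapq <- pairs$mapq1
  e2$mapq <- pairs$mapq2
  ok <- !is.na(e1$fragment_id) & !is.na(e2$fragment_id)
  n_unassigned <- sum(!ok)
  e1 <- e1[ok, , drop = FALSE]; e2 <- e2[ok, , drop = FALSE]

  # order ends by genome coordinate: fragment id is global and follows
  # (chromosome order, start), so id order is genome order; within one
  # fragment put the '-' extremity first
  swap <- e1$fragment_id > e2$fragment_id |
    (e1$fragment_id == e2$fragment_id & e1$extremity == "+" & e2$extremity == "-")
  a <- e1; b <- e2
  a[swap, ] <- e2[swap, , drop = FALSE]
  b[swap, ] <- e1[swap, , drop = FALSE]

  chrom_a <- frags$chrom[a$fragment_id]
  chrom_b <- frags$chrom[b$fragment_id]
  same_chrom <- chrom_a == chrom_b
  same_frag <- a$fragment_id == b$fragment_id
  adjacent <- same_chrom & (b$fragment_id - a$fragment_id == 1L)

  cls <- rep("long_range_inter", nrow(a))
  cls[same_chrom] <- "long_range_intra"
  cls[adjacent & a$extremity == "+" & b$extremity == "-"] <- "religation"
  cls[adjacent & a$extremity == "-" & b$extremity == "+"] <- "adjacent_loop"
  cls[same_frag] <- "self_loop"

  mid <- fragment_mid(frags)
  dg <- ifelse(same_chrom, abs(mid[b$fragment_id] - mid[a$fragment_id]), NA_real_)

  out <- data.frame(
    frag_a = a$fragment_id, ext_a = a$extremity, dist_a = a$dist_re1,
    gc_a = a$gc, d_a = a$d_circle, valid_a = a$re2_valid, mapq_a = a$mapq,
    frag_b = b$fragment_id, ext_b = b$extremity, dist_b = b$dist_re1,
    gc_b = b$gc, d_b = b$d_circle, valid_b = b$re2_valid, mapq_b = b$mapq,
    event_class = cls,
    orientation = paste0(a$extremity, "/", b$extremity),
    D_g = dg,
    circle_length = a$d_circle + b$d_circle,
    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Filter a stream of read pairs into analysable long-range events
#'
#' Applies, in order: (1) a mapping-quality threshold on both mates;
#' (2) the RE1-distance window on both mates (`{20, 21, 22}` bp for
#' condition A, `{21, 22, 23}` bp for condition B — the two DNA
#' concentrations of the protocol); (3) RE2 validity of both engaged
#' extremities; (4) removal of the protocol byproducts (`self_loop`,
#' `religation`, `adjacent_loop`). Event-class tallies (the pie-chart
#' accounting) are taken after the read-level filters (1)-(2) and before the
#' fragment-level filter (3).
#'
#' @param pairs Pairs `data.frame` (see [classify_pairs()]); malformed rows
#'   (missing fields, invalid strand) are counted and skipped, never fatal.
#' @param frags Annotated `FragmentTable`.
#' @param condition `"A"` or `"B"`.
#' @param mapq_min Minimum mapping quality per mate (default 30).
#' @return `list(events, summary)`: `events` are the surviving long-range
#'   events; `summary` holds class counts/fractions and per-filter removal
#'   tallies satisfying `n_input = n_kept + sum(removed)`.
#' @export
filter_events <- function(pairs, frags, condition = c("A", "B"), mapq_min = 30) {
  condition <- match.arg(condition)
  window <- if (condition == "A") c(20, 21, 22) else c(21, 22, 23)
  n_input <- nrow(pairs)

  need <- c("chrom1", "pos1", "strand1", "mapq1", "chrom2", "pos2", "strand2", "mapq2")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) stop("pairs table lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  well_formed <- !is.na(pairs$pos1) & !is.na(pairs$pos2) &
    pairs$strand1 %in% c("+", "-") & pairs$strand2 %in% c("+", "-") &
    !is.na(pairs$mapq1) & !is.na(pairs$mapq2)
  n_malformed <- sum(!well_formed)
  pairs <- pairs[well_formed, , drop = FALSE]

  ev <- classify_pairs(pairs, frags)
  n_unassigned <- attr(ev, "n_unassigned")

  pass_mapq <- ev$mapq_a >= mapq_min & ev$mapq_b >= mapq_min
  n_mapq <- sum(!pass_mapq)
  ev <- ev[pass_mapq, , drop = FALSE]

  pass_dist <- ev$dist_a %in% window & ev$dist_b %in% window
  n_dist <- sum(!pass_dist)
  ev <- ev[pass_dist, , drop = FALSE]

  classes <- c("self_loop", "religation", "adjacent_loop",
               "long_range_intra", "long_range_inter")
  class_counts <- setNames(integer(5), classes)
  tab <- table(factor(ev$event_class, levels = classes))
  class_counts[names(tab)] <- as.integer(tab)
  class_fractions <- if (nrow(ev)) class_counts / nrow(ev) else class_counts * NA_real_

  pass_re2 <- ev$valid_a & ev$valid_b
  n_re2 <- sum(!pass_re2)
  ev <- ev[pass_re2, , drop = FALSE]

  byproduct <- ev$event_class %in% c("self_loop", "religation", "adjacent_loop")
  n_byproduct <- sum(byproduct)
  ev <- ev[!byproduct, , drop = FALSE]
  rownames(ev) <- NULL

  summary <- list(
    n_input = n_input,
    n_kept = nrow(ev),
    class_counts = as.list(class_counts),
    class_fractions = as.list(class_fractions),
    removed = list(malformed = n_malformed, unassigned = n_unassigned,
                   mapq = n_mapq, dist_re1 = n_dist, re2_invalid = n_re2,
                   byproduct_class = n_byproduct),
    condition = condition, mapq_min = mapq_min, dist_window = window)
  list(events = ev, summary = summary)
}

#' Accumulate filtered events into a symmetric contact matrix
#'
#' Counts each event once at `(i, j)` and `(j, i)` over the retained
#' fragments (mappable and RE2-valid). Events touching a non-retained
#' fragment are skipped and tallied. `scope` keeps only intra- or
#' inter-chromosomal pairs.
#'
#' @param events Events `data.frame` from [filter_events()] (or
#'   [classify_pairs()]).
#' @param frags Annotated `FragmentTable`.
#' @param scope `"all"`, `"intra"` or `"inter"`.
#' @return A `ContactMatrix` (see [contact_matrix()]).
#' @export
build_contact_matrix <- function(events, frags, scope = c("all", "intra", "inter")) {
  scope <- match.arg(scope)
  mp <- if (is.null(frags$mappable)) rep(TRUE, nrow(frags)) else
    !is.na(frags$mappable) & frags$mappable
  rv <- if (is.null(frags$has_valid_re2)) rep(TRUE, nrow(frags)) else
    frags$has_valid_re2
  retained <- mp & rv
  idx <- data.frame(fragment_id = frags$fragment_id[retained],
                    chrom = frags$chrom[retained],
                    start = frags$start[retained],
                    end = frags$end[retained],
                    mid = fragment_mid(frags)[retained],
                    stringsAsFactors = FALSE)
  m <- nrow(idx)
  if (m == 0L) stop("no retained fragments")
  row_of <- rep(NA_integer_, nrow(frags))
  row_of[idx$fragment_id] <- seq_len(m)

  ii <- row_of[events$frag_a]
  jj <- row_of[events$frag_b]
  keep <- !is.na(ii) & !is.na(jj)
  n_skipped <- sum(!keep)
  ii <- ii[keep]; jj <- jj[keep]
  if (scope == "intra") {
    s <- idx$chrom[ii] == idx$chrom[jj]
    ii <- ii[s]; jj <- jj[s]
  } else if (scope == "inter") {
    s <- idx$chrom[ii] != idx$chrom[jj]
    ii <- ii[s]; jj <- jj[s]
  }
  v <- matrix(0, m, m)
  if (length(ii)) {
    lin <- c((jj - 1L) * m + ii, (ii - 1L) * m + jj)
    tab <- tabulate(lin, nbins = m * m)
    v <- matrix(tab, m, m)
    diag(v) <- diag(v) / 2   # self events land on the diagonal once
  }
  contact_matrix(v, idx, scope = scope, skipped = n_skipped)
}

#' Read / write a pairs table
#'
#' Tab-separated, eight columns (`chrom1 pos1 strand1 mapq1 chrom2 pos2
#' strand2 mapq2`); lines starting with `#` are comments.
#'
#' @param path File path.
#' @export
read_pairs <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop("pairs file must have 8 columns")
  names(df)[1:8] <- c("chrom1", "pos1", "strand1", "mapq1",
                      "chrom2", "pos2", "strand2", "mapq2")
  df
}

#' @rdname read_pairs
#' @param pairs Pairs `data.frame`.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom1\tpos1\tstrand1\tmapq1\tchrom2\tpos2\tstrand2\tmapq2", con)
  write.table(pairs, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
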
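# Modified ROC test for 3D colocalization of genomic features: among the
# interactions touching a feature of interest, are feature-feature pairs
# enriched at the top of the normalized-score ranking?

#' Map a feature set to fragment ids
#'
#' A fragment carries a feature iff a feature interval overlaps it by at
#' least 1 bp. Features can be a BED file path, a `data.frame` with
#' `chrom`/`start`/`end` (0-based half-open), or a
#' [GenomicRanges::GRanges].
#'
#' @param frags A `FragmentTable`.
#' @param features BED path, `data.frame`, or `GRanges`.
#' @param name Feature-set name.
#' @return `list(name, fragment_id)` of class `FeatureSet`.
#' @export
features_to_fragments <- function(frags, features, name = "features") {
  gr <- if (is.character(features)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      rtracklayer::import(features, format = "BED")
    } else {
      df <- read.table(features, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE)
      GenomicRanges::GRanges(df[[1L]],
                             IRanges::IRanges(df[[2L]] + 1L, df[[3L]]))
    }
  } else if (is.data.frame(features)) {
    GenomicRanges::GRanges(features$chrom,
                           IRanges::IRanges(features$start + 1L, features$end))
  } else if (is(features, "GRanges")) {
    features
  } else stop("unsupported feature input")
  frag_gr <- GenomicRanges::GRanges(frags$chrom,
                                    IRanges::IRanges(frags$start + 1L, frags$end))
  # disjoint seqlevels are not an error here: they simply yield no overlap
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(frag_gr, gr, minoverlap = 1L))
  ids <- sort(unique(frags$fragment_id[S4Vectors::queryHits(hits)]))
  if (!length(ids)) stop("feature set '", name, "' overlaps no fragment")
  structure(list(name = name, fragment_id = ids), class = "FeatureSet")
}

#' Telomeric fragments: the last n restriction fragments of each arm
#'
#' Without centromere annotation the distal ends of each chromosome stand
#' in for its two arms, so this takes the first and last `n_arm` fragments
#' per chromosome.
#'
#' @param frags A `FragmentTable`.
#' @param n_arm Fragments per arm end (default 10).
#' @export
telomere_features <- function(frags, n_arm = 10L) {
  ids <- unlist(lapply(unique(frags$chrom), function(c0) {
    f <- frags$fragment_id[frags$chrom == c0]
    unique(c(head(f, n_arm), tail(f, n_arm)))
  }))
  structure(list(name = "telomeres", fragment_id = sort(unique(ids))),
            class = "FeatureSet")
}

#' Rank and label the feature-touching interactions of a contact map
#'
#' Keeps every off-diagonal pair `(i, j)`, `i < j`, in which at least one
#' fragment carries the feature, ranks them by interaction score
#' (descending; ties broken by `(i, j)` index so the order is stable), and
#' labels a pair positive iff both fragments carry the feature.
#'
#' @param cm A (normalized) `ContactMatrix`.
#' @param features A `FeatureSet` (or integer vector of fragment ids).
#' @return `data.frame(i, j, fragment_i, fragment_j, score, positive)`
#'   sorted by rank.
#' @export
label_interactions <- function(cm, features) {
  stopifnot(is(cm, "ContactMatrix"))
  ids <- if (is(features, "FeatureSet")) features$fragment_id else as.integer(features)
  m <- nrow(cm$values)
  frag_ids <- if (!is.null(cm$index$fragment_id)) cm$index$fragment_id else seq_len(m)
  S <- which(frag_ids %in% ids)
  if (!length(S))
    stop("no feature-bearing fragment retained in the contact map")
  inS <- logical(m); inS[S] <- TRUE
  notS <- which(!inS)
  pp <- if (length(S) >= 2L) t(utils::combn(S, 2L)) else
    matrix(integer(0), 0L, 2L)
  pn <- if (length(notS)) cbind(rep(S, each = length(notS)),
                                rep(notS, times = length(S))) else
    matrix(integer(0), 0L, 2L)
  ij <- rbind(pp, cbind(pmin(pn[, 1L], pn[, 2L]), pmax(pn[, 1L], pn[, 2L])))
  out <- data.frame(i = ij[, 1L], j = ij[, 2L],
                    fragment_i = frag_ids[ij[, 1L]],
                    fragment_j = frag_ids[ij[, 2L]],
                    score = cm$values[ij],
                    positive = inS[ij[, 1L]] & inS[ij[, 2L]])
  out <- out[order(-out$score, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC over a ranked labeled interaction list
#'
#' Traverses the ranking and accumulates the percentage of positives
#' (feature-feature pairs) against the percentage of negatives above each
#' threshold; the curve runs from (0, 0) to (100, 100) and is monotone in
#' both coordinates. AUC (in `[0, 1]`) is computed by the trapezoid rule;
#' a curve above the diagonal means the feature's pairs concentrate among
#' the strongest interactions.
#'
#' @param ranked Output of [label_interactions()] (or any `data.frame` with
#'   a logical `positive` column in rank order).
#' @return `list(curve, auc, n_pos, n_neg, degenerate)` of class
#'   `RocResult`; with a single-class input `auc` is `NA` and
#'   `degenerate` is `TRUE`.
#' @export
roc_curve <- function(ranked) {
  pos <- as.logical(ranked$positive)
  P <- sum(pos); Ng <- sum(!pos)
  if (P == 0L || Ng == 0L) {
    warning("single-class ranking: AUC undefined")
    return(structure(list(curve = NULL, auc = NA_real_, n_pos = P, n_neg = Ng,
                          degenerate = TRUE), class = "RocResult"))
  }
  x <- c(0, 100 * cumsum(!pos) / Ng)
  y <- c(0, 100 * cumsum(pos) / P)
  auc <- sum(diff(x / 100) * (head(y / 100, -1L) + tail(y / 100, -1L)) / 2)
  structure(list(curve = data.frame(pct_negatives = x, pct_positives = y),
                 auc = auc, n_pos = P, n_neg = Ng, degenerate = FALSE),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %s (%d positives, %d negatives)\n",
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Batch ROC colocalization test over several feature sets
#'
#' @param cm A (normalized) `ContactMatrix`.
#' @param feature_sets Named list of `FeatureSet`s (or id vectors).
#' @return Named list of `RocResult`s.
#' @export
roc_batch <- function(cm, feature_sets) {
  lapply(feature_sets, function(fs) roc_curve(label_interactions(cm, fs)))
}
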
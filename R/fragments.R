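#' @importFrom methods is
#' @importFrom stats approx coef fft lm median poly predict quantile runif rnorm rpois setNames var
#' @importFrom utils head read.table tail write.table
NULL

# ---- internal helpers -------------------------------------------------------

.as_dna <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("character sequences must be named by chromosome")
    return(Biostrings::DNAStringSet(sequences))
  }
  stop("'sequences' must be a DNAStringSet or a named character vector")
}

.check_motif <- function(motif, arg = "motif") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop(sprintf("'%s' must be a single non-empty string", arg))
  if (grepl("[^ACGT]", motif))
    stop(sprintf("'%s' must be plain uppercase ACGT (no IUPAC ambiguity codes)", arg))
  motif
}

# 0-based cut coordinates of a motif on one chromosome, restricted to the
# interior (a cut at 0 or at the chromosome end produces no new boundary)
.cut_sites <- function(seq, motif, cut_offset) {
  if (length(seq) < nchar(motif)) return(integer(0))
  st <- Biostrings::start(Biostrings::matchPattern(motif, seq))  # 1-based
  cuts <- st - 1L + as.integer(cut_offset)                       # 0-based
  sort(unique(cuts[cuts > 0L & cuts < length(seq)]))
}

# ---- FragmentTable ----------------------------------------------------------

#' In silico digestion of a genome with the primary restriction enzyme
#'
#' Cuts every chromosome at each occurrence of the RE1 recognition motif and
#' returns the resulting restriction fragments as a `FragmentTable`
#' (a `data.frame` with 0-based half-open coordinates). Fragments tile each
#' chromosome without gaps: the first fragment starts at 0 and the last one
#' ends at the chromosome length.
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector of
#'   chromosome sequences.
#' @param re1_motif Recognition motif of the primary enzyme, plain ACGT
#'   (e.g. `"AAGCTT"` for HindIII).
#' @param cut_offset Position of the cut within the motif, in bp from the
#'   motif start (default 1, matching HindIII `A^AGCTT`).
#' @return A `FragmentTable`: columns `chrom`, `start`, `end`, `fragment_id`,
#'   `length`; annotation columns are filled by [annotate_re2()], [end_gc()]
#'   and [annotate_mappability()].
#' @examples
#' seqs <- c(chr1 = paste(rep("ACGT", 30), collapse = ""))
#' digest_genome(seqs, "AAGCTT")   # no site: one whole-chromosome fragment
#' @export
digest_genome <- function(sequences, re1_motif, cut_offset = 1L) {
  seqs <- .as_dna(sequences)
  .check_motif(re1_motif, "re1_motif")
  if (length(seqs) == 0L) stop("'sequences' is empty")
  if (cut_offset < 0L || cut_offset > nchar(re1_motif))
    stop("'cut_offset' must lie within the motif")
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L))
    stop("empty sequence for chromosome(s): ",
         paste(names(seqs)[widths == 0L], collapse = ", "))

  rows <- lapply(seq_along(seqs), function(k) {
    len <- widths[k]
    cuts <- .cut_sites(seqs[[k]], re1_motif, cut_offset)
    bounds <- c(0L, cuts, len)
    data.frame(chrom = names(seqs)[k],
               start = bounds[-length(bounds)],
               end   = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, rows)
  frags$fragment_id <- seq_len(nrow(frags))
  frags$length <- frags$end - frags$start
  attr(frags, "re1_motif") <- re1_motif
  attr(frags, "re1_offset") <- as.integer(cut_offset)
  attr(frags, "chrom_lengths") <- setNames(as.integer(widths), names(seqs))
  class(frags) <- c("FragmentTable", "data.frame")
  frags
}

#' Annotate fragments with secondary-enzyme (RE2) sites
#'
#' Locates all RE2 cut sites inside each fragment and derives, per fragment
#' extremity, the circle-arm length (distance from the RE1 cut to the nearest
#' interior RE2 cut) and the validity flag. An extremity is usable for the
#' protocol iff its nearest RE2 site lies at least `min_gap` bp away from the
#' RE1 cut; a fragment with no RE2 site is invalid at both extremities and is
#' discarded from contact matrices downstream.
#'
#' @param frags A `FragmentTable` from [digest_genome()] built on the same
#'   `sequences`.
#' @param sequences The genome sequences.
#' @param re2_motif Recognition motif of the secondary enzyme (must differ
#'   from the RE1 motif).
#' @param min_gap Minimum RE1-to-RE2 distance for a usable extremity (bp).
#' @param cut_offset Cut position within the RE2 motif (bp from motif start).
#' @return `frags` with columns `n_re2`, `d_minus`, `d_plus` (circle-arm
#'   lengths, `NA` when no RE2 site), `valid_minus`, `valid_plus`,
#'   `has_valid_re2`, and a list column `re2` of 0-based RE2 cut coordinates.
#' @export
annotate_re2 <- function(frags, sequences, re2_motif, min_gap = 20L,
                         cut_offset = 1L) {
  stopifnot(is(frags, "FragmentTable"))
  .check_motif(re2_motif, "re2_motif")
  re1 <- attr(frags, "re1_motif")
  if (!is.null(re1) && identical(re2_motif, re1))
    stop("RE2 motif equals the RE1 motif: degenerate protocol")
  seqs <- .as_dna(sequences)

  n <- nrow(frags)
  re2_list <- vector("list", n)
  d_minus <- d_plus <- rep(NA_real_, n)
  n_re2 <- integer(n)

  for (chrom in unique(frags$chrom)) {
    rows <- which(frags$chrom == chrom)
    sites <- .cut_sites(seqs[[chrom]], re2_motif, cut_offset)
    # also admit a cut exactly at coordinate 0 or len: it sits on a fragment
    # boundary and yields a zero-length arm for the terminal fragment
    st0 <- Biostrings::start(Biostrings::matchPattern(re2_motif, seqs[[chrom]])) -
      1L + as.integer(cut_offset)
    sites <- sort(unique(c(sites, st0[st0 == 0L])))
    if (length(sites) == 0L) { re2_list[rows] <- list(integer(0)); next }
    # fragment row index per site (fragments tile [0, len))
    idx <- findInterval(sites, frags$start[rows])
    for (j in seq_along(rows)) {
      s <- sites[idx == j]
      r <- rows[j]
      re2_list[[r]] <- s
      n_re2[r] <- length(s)
      if (length(s)) {
        d_minus[r] <- min(s) - frags$start[r]
        d_plus[r]  <- frags$end[r] - max(s)
      }
    }
  }
  frags$n_re2 <- n_re2
  frags$d_minus <- d_minus
  frags$d_plus <- d_plus
  frags$valid_minus <- !is.na(d_minus) & d_minus >= min_gap
  frags$valid_plus  <- !is.na(d_plus)  & d_plus  >= min_gap
  frags$has_valid_re2 <- frags$valid_minus | frags$valid_plus
  frags$re2 <- re2_list
  attr(frags, "re2_motif") <- re2_motif
  attr(frags, "re2_offset") <- as.integer(cut_offset)
  attr(frags, "min_gap") <- as.integer(min_gap)
  frags
}

#' GC content of the fragment end flanks
#'
#' Computes the G+C fraction of the `flank` bp of reference sequence
#' immediately interior to each fragment extremity (truncated to the fragment
#' for short fragments). Non-ACGT letters count toward the flank length but
#' not toward GC, so an all-N flank yields 0 (with a warning).
#'
#' @param frags A `FragmentTable`.
#' @param sequences The genome sequences.
#' @param flank Flank width in bp (default 20, the protocol's tag length).
#' @return `frags` with columns `end_gc_minus` and `end_gc_plus` in `[0, 1]`.
#' @export
end_gc <- function(frags, sequences, flank = 20L) {
  stopifnot(is(frags, "FragmentTable"))
  seqs <- .as_dna(sequences)
  n <- nrow(frags)
  gcm <- gcp <- rep(NA_real_, n)
  n_all_nonacgt <- 0L
  for (chrom in unique(frags$chrom)) {
    rows <- which(frags$chrom == chrom)
    x <- seqs[[chrom]]
    w <- pmin(flank, frags$length[rows])
    vm <- Biostrings::Views(x, start = frags$start[rows] + 1L, width = w)
    vp <- Biostrings::Views(x, start = frags$end[rows] - w + 1L, width = w)
    fm <- Biostrings::letterFrequency(Biostrings::DNAStringSet(vm), "GC")[, 1L]
    fp <- Biostrings::letterFrequency(Biostrings::DNAStringSet(vp), "GC")[, 1L]
    acgt_m <- Biostrings::letterFrequency(Biostrings::DNAStringSet(vm), "ACGT")[, 1L]
    acgt_p <- Biostrings::letterFrequency(Biostrings::DNAStringSet(vp), "ACGT")[, 1L]
    n_all_nonacgt <- n_all_nonacgt + sum(acgt_m == 0L) + sum(acgt_p == 0L)
    gcm[rows] <- fm / w
    gcp[rows] <- fp / w
  }
  if (n_all_nonacgt > 0L)
    warning(n_all_nonacgt, " end flank(s) contain no ACGT letters; GC set to 0")
  frags$end_gc_minus <- gcm
  frags$end_gc_plus <- gcp
  attr(frags, "gc_flank") <- as.integer(flank)
  frags
}

#' Flag fragments with ambiguously mapping end flanks
#'
#' A fragment extremity is ambiguous when its `flank` bp of end sequence
#' occurs more than once in the genome (exact match on either strand), or
#' contains non-ACGT letters. A fragment is flagged unmappable when *both*
#' extremities are ambiguous, mirroring the removal of fragments whose two
#' ends cannot be placed uniquely.
#'
#' @inheritParams end_gc
#' @return `frags` with a logical `mappable` column.
#' @export
annotate_mappability <- function(frags, sequences, flank = 20L) {
  stopifnot(is(frags, "FragmentTable"))
  seqs <- .as_dna(sequences)
  n <- nrow(frags)
  get_flank <- function(rows, side) {
    chrom <- frags$chrom[rows[1L]]
    x <- seqs[[chrom]]
    w <- pmin(flank, frags$length[rows])
    if (side == "-")
      Biostrings::DNAStringSet(Biostrings::Views(x, start = frags$start[rows] + 1L, width = w))
    else
      Biostrings::DNAStringSet(Biostrings::Views(x, start = frags$end[rows] - w + 1L, width = w))
  }
  fl_minus <- fl_plus <- vector("list", 0L)
  ord <- integer(0)
  for (chrom in unique(frags$chrom)) {
    rows <- which(frags$chrom == chrom)
    fl_minus <- c(fl_minus, list(get_flank(rows, "-")))
    fl_plus <- c(fl_plus, list(get_flank(rows, "+")))
    ord <- c(ord, rows)
  }
  fm <- do.call(c, fl_minus); fp <- do.call(c, fl_plus)
  flanks <- c(fm, fp)

  counts <- integer(length(flanks))
  chr_flanks <- as.character(flanks)
  has_bad <- grepl("[^ACGT]", chr_flanks) | nchar(chr_flanks) < flank
  uniq <- unique(chr_flanks[!has_bad])
  occ <- setNames(integer(length(uniq)), uniq)
  if (length(uniq)) {
    pats <- Biostrings::DNAStringSet(uniq)
    pd <- Biostrings::PDict(pats)
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(pats))
    fwd <- rowSums(Biostrings::vcountPDict(pd, seqs))
    rev <- rowSums(Biostrings::vcountPDict(pd_rc, seqs))
    palin <- as.character(Biostrings::reverseComplement(pats)) == uniq
    occ[uniq] <- fwd + ifelse(palin, 0L, rev)
  }
  # short (truncated) flanks counted individually; non-ACGT flanks stay ambiguous
  short <- which(nchar(chr_flanks) < flank & !grepl("[^ACGT]", chr_flanks))
  for (i in short) {
    u <- chr_flanks[i]
    cnt <- sum(Biostrings::vcountPattern(u, seqs))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
    if (!identical(rc, u)) cnt <- cnt + sum(Biostrings::vcountPattern(rc, seqs))
    counts[i] <- cnt
  }
  counts[!has_bad] <- occ[chr_flanks[!has_bad]]
  has_bad <- grepl("[^ACGT]", chr_flanks)
  amb <- has_bad | counts > 1L
  half <- length(flanks) / 2L
  amb_minus <- amb[seq_len(half)]
  amb_plus <- amb[half + seq_len(half)]
  mappable <- rep(NA, n)
  mappable[ord] <- !(amb_minus & amb_plus)
  frags$mappable <- mappable
  frags
}

#' Circle-arm length at a fragment extremity
#'
#' Distance (bp) from the RE1 cut at the given extremity to the nearest RE2
#' cut inside the fragment; this is one arm of the circularization segment
#' whose total length d_A + d_B governs ligation-circle efficiency.
#' Fragments without any RE2 site return `NA` (the "no-RE2" signal); such
#' fragments are filtered out upstream of any circle-length analysis.
#'
#' @param frags A `FragmentTable` annotated by [annotate_re2()].
#' @param extremity `"-"` or `"+"`, recycled along fragments.
#' @return Numeric vector of arm lengths in bp.
#' @export
circle_arm_length <- function(frags, extremity) {
  stopifnot(is(frags, "FragmentTable"), all(extremity %in% c("-", "+")))
  if (is.null(frags$d_minus)) stop("fragments not annotated; run annotate_re2() first")
  extremity <- rep_len(extremity, nrow(frags))
  ifelse(extremity == "-", frags$d_minus, frags$d_plus)
}

#' Build a fully annotated fragment table in one call
#'
#' Convenience wrapper: [digest_genome()] + [annotate_re2()] + [end_gc()] +
#' optionally [annotate_mappability()].
#'
#' @inheritParams digest_genome
#' @inheritParams annotate_re2
#' @param re1_offset,re2_offset Cut offsets within each motif.
#' @param flank End-flank width (bp) for GC and mappability.
#' @param mappability Whether to run the (exact-match) mappability scan.
#' @export
build_fragment_table <- function(sequences, re1_motif, re2_motif,
                                 re1_offset = 1L, re2_offset = 1L,
                                 min_gap = 20L, flank = 20L,
                                 mappability = TRUE) {
  seqs <- .as_dna(sequences)
  fr <- digest_genome(seqs, re1_motif, re1_offset)
  fr <- annotate_re2(fr, seqs, re2_motif, min_gap = min_gap, cut_offset = re2_offset)
  fr <- end_gc(fr, seqs, flank = flank)
  if (mappability) fr <- annotate_mappability(fr, seqs, flank = flank)
  else fr$mappable <- TRUE
  fr
}

#' Fragment midpoints
#' @param frags A `FragmentTable`.
#' @return Numeric vector of (start+end)/2 per fragment.
#' @export
fragment_mid <- function(frags) (frags$start + frags$end) / 2

#' Write / read a fragment table as BED-like TSV
#'
#' Columns: chrom, start, end, fragment_id, length, n_re2, end_gc_minus,
#' end_gc_plus, mappable, valid_minus, valid_plus, d_minus, d_plus.
#' Ordering is chromosome order of the source FASTA, then start.
#'
#' @param frags A `FragmentTable`.
#' @param path Output file.
#' @export
write_fragment_table <- function(frags, path) {
  cols <- c("chrom", "start", "end", "fragment_id", "length", "n_re2",
            "end_gc_minus", "end_gc_plus", "mappable",
            "valid_minus", "valid_plus", "d_minus", "d_plus")
  missing <- setdiff(cols, names(frags))
  for (m in missing) frags[[m]] <- NA
  write.table(as.data.frame(frags)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$has_valid_re2 <- df$valid_minus | df$valid_plus
  class(df) <- c("FragmentTable", "data.frame")
  df
}
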
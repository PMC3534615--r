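# Pipeline orchestration: digest -> annotate -> classify/filter -> matrices
# -> (intra: low-norm filter -> distance normalization) -> SCN -> optional
# correlation map and ROC colocalization, with per-stage logging and JSON
# metadata sidecars.

#' Validated pipeline configuration
#'
#' @param fasta Path to the genome FASTA.
#' @param pairs Path to the aligned pairs TSV (8 columns).
#' @param out_dir Output directory for all artifacts.
#' @param re1_motif,re1_offset,re2_motif,re2_offset Enzyme motifs and cut
#'   offsets.
#' @param condition Protocol condition `"A"` (RE1-distance window 20-22 bp)
#'   or `"B"` (21-23 bp).
#' @param mapq_min Mapping-quality threshold per mate.
#' @param min_gap Minimum RE1-RE2 gap for a usable extremity (bp).
#' @param low_norm_threshold Euclidean-norm cutoff for weak fragments.
#' @param scn_tol,scn_max_iter SCN convergence settings.
#' @param distance_degree Polynomial degree of the log-log distance fit.
#' @param bin_size Fragments per bin (1 = fragment resolution).
#' @param mappability Run the exact-match mappability scan.
#' @param features Named list of BED paths (or feature data frames) to test
#'   for 3D colocalization on the normalized maps.
#' @param correlation Also write Pearson correlation maps.
#' @export
pipeline_config <- function(fasta, pairs, out_dir,
                            re1_motif = "AAGCTT", re1_offset = 1L,
                            re2_motif = "CCGG", re2_offset = 1L,
                            condition = "A", mapq_min = 30,
                            min_gap = 20L, low_norm_threshold = 30,
                            scn_tol = 1e-3, scn_max_iter = 50L,
                            distance_degree = 8L, bin_size = 1L,
                            mappability = TRUE,
                            features = list(), correlation = FALSE) {
  if (!condition %in% c("A", "B")) stop("condition must be 'A' or 'B'")
  stopifnot(mapq_min >= 0, low_norm_threshold >= 0, scn_tol > 0,
            scn_max_iter >= 1, distance_degree >= 1, bin_size >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.log_stage <- function(...) message("[scn3c] ", sprintf(...))

#' Run the full contact-map pipeline
#'
#' Executes digestion, annotation, event classification/filtering, matrix
#' accumulation, then per scope: intra maps are low-norm filtered,
#' distance-normalized and SCN-normalized; inter maps are low-norm filtered
#' and SCN-normalized. Every stage logs its counts; outputs (TSV matrices
#' with index and JSON metadata sidecars, event summary, bias profiles) are
#' written under `config$out_dir`.
#'
#' @param config A `PipelineConfig` from [pipeline_config()].
#' @return (Invisibly) a list with the in-memory objects: `frags`,
#'   `events`, `summary`, `intra`, `inter` (each raw + normalized), and ROC
#'   results if features were given.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  if (!file.exists(config$fasta)) stop("FASTA not found: ", config$fasta)
  if (!file.exists(config$pairs)) stop("pairs file not found: ", config$pairs)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- Biostrings::readDNAStringSet(config$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  .log_stage("read %d chromosome(s), %g bp total", length(seqs),
             sum(Biostrings::width(seqs)))

  frags <- build_fragment_table(seqs, config$re1_motif, config$re2_motif,
                                re1_offset = config$re1_offset,
                                re2_offset = config$re2_offset,
                                min_gap = config$min_gap,
                                mappability = config$mappability)
  .log_stage("digest: %d fragments, %d RE2-valid, %d mappable",
             nrow(frags), sum(frags$has_valid_re2), sum(frags$mappable))
  write_fragment_table(frags, file.path(config$out_dir, "fragments.tsv"))

  pairs <- read_pairs(config$pairs)
  fe <- filter_events(pairs, frags, condition = config$condition,
                      mapq_min = config$mapq_min)
  s <- fe$summary
  .log_stage("events: %d pairs in, %d kept (removed: %s)", s$n_input, s$n_kept,
             paste(names(s$removed), unlist(s$removed), sep = "=", collapse = ", "))
  if (s$n_kept == 0L)
    stop(structure(class = c("scn3c_data_error", "error", "condition"),
                   list(message = "no events survive filtering", call = NULL)))
  jsonlite::write_json(s, file.path(config$out_dir, "event_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  ev <- fe$events
  write.table(ev, file.path(config$out_dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  out <- list(frags = frags, events = ev, summary = s)

  for (scope in c("intra", "inter")) {
    cm <- build_contact_matrix(ev, frags, scope = scope)
    if (config$bin_size > 1L) cm <- bin_matrix(cm, config$bin_size)
    write_contact_matrix(cm, file.path(config$out_dir,
                                       sprintf("matrix_raw_%s.tsv", scope)))
    if (sum(cm$values) == 0) {
      .log_stage("%s: no events in scope, skipping normalization", scope)
      out[[scope]] <- list(raw = cm)
      next
    }
    cmf <- filter_low_norm(cm, config$low_norm_threshold)
    .log_stage("%s: low-norm filter removed %d of %d fragments", scope,
               attr(cmf, "n_removed"), nrow(cm$values))
    if (scope == "intra") {
      de <- distance_expectation(cmf, degree = config$distance_degree)
      write_profile(de$profile, file.path(config$out_dir, "distance_profile.tsv"))
      cmf <- distance_normalize(cmf, de)
      out$distance_expectation <- de
    }
    sres <- scn(cmf, tol = config$scn_tol, max_iter = config$scn_max_iter)
    .log_stage("%s: SCN converged in %d sweep(s), deviation %.2e", scope,
               sres$n_iterations, sres$deviation)
    cmn <- sres$matrix
    write_contact_matrix(cmn, file.path(config$out_dir,
                                        sprintf("matrix_scn_%s.tsv", scope)))
    if (isTRUE(config$correlation)) {
      cc <- correlation_map(cmn)   # Pearson values in [-1, 1]: plain dense TSV
      write.table(cc$values,
                  file.path(config$out_dir, sprintf("matrix_cor_%s.tsv", scope)),
                  sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    out[[scope]] <- list(raw = cm, normalized = cmn,
                         n_scn_iterations = sres$n_iterations)
  }

  if (length(config$features)) {
    roc <- list()
    for (nm in names(config$features)) {
      fs <- features_to_fragments(frags, config$features[[nm]], name = nm)
      roc[[nm]] <- lapply(c("intra", "inter"), function(scope) {
        cmn <- out[[scope]]$normalized
        if (is.null(cmn)) return(NULL)
        rr <- tryCatch(roc_curve(label_interactions(cmn, fs)),
                       error = function(e) NULL)
        rr
      })
      names(roc[[nm]]) <- c("intra", "inter")
    }
    jsonlite::write_json(
      lapply(roc, function(r) lapply(r, function(x) if (is.null(x)) NULL else
        list(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg))),
      file.path(config$out_dir, "roc_auc.json"), auto_unbox = TRUE, digits = NA)
    out$roc <- roc
  }

  meta <- config
  meta$features <- names(config$features)
  class(meta) <- NULL
  jsonlite::write_json(list(config = meta,
                            package_version = as.character(utils::packageVersion("scn3c")),
                            counts = s),
                       file.path(config$out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage("pipeline complete: %s", config$out_dir)
  invisible(out)
}
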
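# ContactMatrix: dense symmetric nonnegative matrix over retained fragments
# (or bins), with an index of identities and a normalization history.

#' Construct a ContactMatrix
#'
#' @param values Dense symmetric nonnegative numeric matrix.
#' @param index `data.frame` with one row per matrix row; must contain
#'   `chrom` and `mid` (fragment/bin midpoint, bp); typically also
#'   `fragment_id`, `start`, `end`.
#' @param scope `"all"`, `"intra"` or `"inter"`.
#' @param history Character vector of normalization steps applied so far.
#' @param skipped Number of events skipped while accumulating (if any).
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, index, scope = "all",
                           history = character(), skipped = 0L) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (nrow(index) != nrow(values)) stop("index length must match matrix size")
  if (any(values < 0, na.rm = TRUE)) stop("contact matrix must be nonnegative")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9)
    stop("contact matrix must be symmetric (tolerance 1e-9)")
  structure(list(values = values, index = index, scope = scope,
                 history = history, skipped = as.integer(skipped)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d x %d (%s scope), total mass %.4g\n",
              nrow(x$values), ncol(x$values), x$scope, sum(x$values)))
  if (length(x$history)) cat("history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
as.matrix.ContactMatrix <- function(x, ...) x$values

#' @export
dim.ContactMatrix <- function(x) dim(x$values)

# dispatch helpers: all matrix operations accept either a ContactMatrix or a
# bare matrix and return the same kind
.cm_values <- function(x) if (is(x, "ContactMatrix")) x$values else as.matrix(x)

.cm_rewrap <- function(x, values, note = NULL, index = NULL) {
  if (!is(x, "ContactMatrix")) return(values)
  x$values <- values
  if (!is.null(index)) x$index <- index
  if (!is.null(note)) x$history <- c(x$history, note)
  x
}

#' Write / read a ContactMatrix
#'
#' `format = "coo"` writes sparse triplets (`frag_i`, `frag_j`, `count`,
#' upper triangle including diagonal, fragment ids from the index) plus an
#' index sidecar `<path>.index.tsv`; `format = "dense"` writes the full
#' matrix as TSV. A JSON metadata sidecar `<path>.meta.json` records scope
#' and history.
#'
#' @param cm A `ContactMatrix`.
#' @param path Output file for the matrix values.
#' @param format `"coo"` or `"dense"`.
#' @export
write_contact_matrix <- function(cm, path, format = c("coo", "dense")) {
  format <- match.arg(format)
  stopifnot(is(cm, "ContactMatrix"))
  ids <- if (!is.null(cm$index$fragment_id)) cm$index$fragment_id else seq_len(nrow(cm$values))
  if (format == "coo") {
    up <- which(upper.tri(cm$values, diag = TRUE) & cm$values != 0, arr.ind = TRUE)
    coo <- data.frame(frag_i = ids[up[, 1L]], frag_j = ids[up[, 2L]],
                      count = cm$values[up])
    coo <- coo[order(coo$frag_i, coo$frag_j), , drop = FALSE]
    write.table(coo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(cm$values, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  write.table(cm$index, paste0(path, ".index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(scope = cm$scope, history = cm$history,
                            format = format, n = nrow(cm$values)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path, format = c("coo", "dense")) {
  format <- match.arg(format)
  index <- read.table(paste0(path, ".index.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(scope = "all", history = list())
  m <- nrow(index)
  if (format == "coo") {
    coo <- read.table(path, header = TRUE, sep = "\t")
    row_of <- setNames(seq_len(m), index$fragment_id)
    v <- matrix(0, m, m)
    i <- row_of[as.character(coo$frag_i)]
    j <- row_of[as.character(coo$frag_j)]
    v[cbind(i, j)] <- coo$count
    v[cbind(j, i)] <- coo$count
  } else {
    v <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
    dimnames(v) <- NULL
  }
  contact_matrix(v, index, scope = meta$scope,
                 history = unlist(meta$history))
}
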
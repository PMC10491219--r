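#' Minimal FCS 3.1 input/output
#'
#' The package reads and writes list-mode FCS 3.1 files with float32 data
#' ($DATATYPE F, $MODE L), which is what mass cytometers and all common
#' cytometry software emit post-acquisition. The writer always produces
#' little-endian files; the reader accepts both byte orders. This is not a
#' general FCS implementation: integer data types, multiple datasets per
#' file and analysis segments are not supported.
#'
#' @name fcs-io
NULL

fcs_text_escape <- function(x, delim = "/") gsub(delim, paste0(delim, delim), x, fixed = TRUE)

#' Write an EventMatrix to per-sample FCS files
#'
#' Writes one FCS 3.1 file per sample (`<sample_id>.fcs`), a sidecar
#' `metadata.tsv` (sample_id, batch_id, tissue, is_anchor, file), and — when
#' ground-truth columns are present — a `truth.tsv` aligned with the
#' concatenated per-sample event order.
#'
#' @param events an `EventMatrix` (any scale; values are stored as float32).
#' @param directory output directory, created if needed.
#' @param sample_ids samples to write; defaults to all samples present.
#'   A requested sample with zero events is an error.
#' @return invisibly, the metadata data.frame including the `file` column.
#' @export
write_fcs <- function(events, directory, sample_ids = NULL) {
  stopifnot(inherits(events, "EventMatrix"))
  if (is.null(sample_ids)) sample_ids <- unique(events$pheno$sample_id)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)

  meta_cols <- intersect(c("sample_id", "batch_id", "tissue", "is_anchor"),
                         names(events$pheno))
  rows <- list()
  for (sid in sample_ids) {
    sel <- which(events$pheno$sample_id == sid)
    if (!length(sel)) stop("sample '", sid, "' has 0 events")
    path <- file.path(directory, paste0(sid, ".fcs"))
    write_fcs_file(events$exprs[sel, , drop = FALSE], path)
    meta <- events$pheno[sel[1], meta_cols, drop = FALSE]
    meta$file <- basename(path)
    rows[[sid]] <- meta
  }
  metadata <- do.call(rbind, rows)
  rownames(metadata) <- NULL
  utils::write.table(metadata, file.path(directory, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_cols <- intersect(c("population", "branch", "latent_time"), names(events$pheno))
  if (length(truth_cols)) {
    ord <- unlist(lapply(sample_ids, function(s) which(events$pheno$sample_id == s)))
    utils::write.table(events$pheno[ord, c("sample_id", truth_cols)],
                       file.path(directory, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(metadata)
}

# single-file FCS 3.1 writer (float32, little-endian)
write_fcs_file <- function(mat, path) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L) stop("cannot write an FCS file with 0 events")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)) ||
      any(!nzchar(colnames(mat)))) {
    stop("channel names must be non-empty and unique")
  }
  n <- nrow(mat); p <- ncol(mat)
  d <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$NEXTDATA", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$PAR", as.character(p), "$TOT", as.character(n))
  for (j in seq_len(p)) {
    rng <- max(1024, 2^ceiling(log2(max(mat[, j], 1))))
    kw <- c(kw,
            sprintf("$P%dN", j), fcs_text_escape(colnames(mat)[j]),
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(rng, scientific = FALSE))
  }
  data_bytes <- 4L * n * p
  # data offsets written fixed-width so the TEXT length is offset-independent
  build_text <- function(db, de) {
    paste0(d, paste0(c(kw, "$BEGINDATA", sprintf("%012d", db),
                       "$ENDDATA", sprintf("%012d", de)),
                     collapse = d), d)
  }
  text <- build_text(0, 0)
  data_begin <- 58L + nchar(text, type = "bytes")
  data_end <- data_begin + data_bytes - 1L
  text <- build_text(data_begin, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    58L, 58L + nchar(text, type = "bytes") - 1L,
                    data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

# single-file FCS reader: returns a float matrix with channel names
read_fcs_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!startsWith(header, "FCS3")) stop("not an FCS 3.x file: ", path)
  off <- suppressWarnings(as.integer(substring(header,
    c(11, 19, 27, 35, 43, 51), c(18, 26, 34, 42, 50, 58))))
  text_begin <- off[1]; text_end <- off[2]
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  body <- substr(text, 2, nchar(text))
  if (endsWith(body, delim)) body <- substr(body, 1, nchar(body) - 1L)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L != 0L) stop("malformed TEXT segment in ", path)
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(vals, toupper(keys))

  if (toupper(kw[["$DATATYPE"]]) != "F") stop("only $DATATYPE F supported")
  if (toupper(kw[["$MODE"]]) != "L") stop("only list mode ($MODE L) supported")
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  data_begin <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_begin) || data_begin == 0L) data_begin <- off[3]
  ch <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]], character(1))
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n = n * p, size = 4, endian = endian)
  matrix(vals, nrow = n, ncol = p, byrow = TRUE, dimnames = list(NULL, ch))
}

#' Read a set of FCS files into one EventMatrix
#'
#' Reads each file, harmonizes channel order to the first file, attaches
#' per-event sample metadata, and concatenates. All files must share exactly
#' the same channel set.
#'
#' @param paths character vector of FCS file paths.
#' @param metadata_table data.frame with one row per file, in `paths` order
#'   (or with a `file` column matching basenames), carrying at least
#'   `sample_id`; `batch_id`, `tissue`, `is_anchor` are propagated when
#'   present.
#' @return an `EventMatrix` with scale tag `"raw"`.
#' @export
read_fcs_set <- function(paths, metadata_table) {
  metadata_table <- as.data.frame(metadata_table, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata_table)) stop("metadata needs a 'sample_id' column")
  if ("file" %in% names(metadata_table)) {
    idx <- match(basename(paths), metadata_table$file)
    if (anyNA(idx)) stop("missing metadata for file(s): ",
                         paste(basename(paths)[is.na(idx)], collapse = ", "))
    metadata_table <- metadata_table[idx, , drop = FALSE]
  } else if (nrow(metadata_table) != length(paths)) {
    stop("metadata must have one row per file")
  }
  mats <- lapply(paths, read_fcs_file)
  ref <- colnames(mats[[1]])
  for (i in seq_along(mats)) {
    have <- colnames(mats[[i]])
    miss <- setdiff(ref, have); extra <- setdiff(have, ref)
    if (length(miss) || length(extra)) {
      stop("channel-set mismatch in ", basename(paths[i]),
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
    }
    mats[[i]] <- mats[[i]][, ref, drop = FALSE]
  }
  counts <- vapply(mats, nrow, integer(1))
  meta_cols <- intersect(c("sample_id", "batch_id", "tissue", "is_anchor"),
                         names(metadata_table))
  pheno <- metadata_table[rep(seq_along(paths), counts), meta_cols, drop = FALSE]
  rownames(pheno) <- NULL
  if ("is_anchor" %in% names(pheno)) pheno$is_anchor <- as.logical(pheno$is_anchor)
  event_matrix(do.call(rbind, mats), pheno, scale = "raw")
}
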
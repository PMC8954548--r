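# File formats: fast5 (HDF5) raw signal, FASTA references/basecalls, and the
# ground-truth alignment TSV.
#
# All coordinates on disk are 0-based, half-open, and validated at parse
# time.  fast5 I/O is delegated to a small bundled Python helper running on
# the h5py stack (both single-read `Raw/Reads/Read_*/Signal` and multi-read
# `read_*/Raw/Signal` dialects are supported); data crosses the process
# boundary as JSON.

fast5_helper <- function() {
  path <- system.file("python", "fast5_io.py", package = "squigglecall")
  if (!nzchar(path)) stop("bundled fast5 helper not found")
  path
}

run_fast5_helper <- function(args, input = NULL) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("`python` (with h5py) is required for fast5 I/O")
  out <- suppressWarnings(system2(py, c(fast5_helper(), args),
                                  stdout = TRUE, stderr = TRUE,
                                  input = input))
  status <- attr(out, "status")
  txt <- paste(out, collapse = "\n")
  res <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (!is.null(res) && !is.null(res$error)) stop("fast5: ", res$error)
  if (!is.null(status) && status != 0L) stop("fast5 helper failed: ", txt)
  res
}

#' Write reads to a fast5 (HDF5) file
#'
#' @param reads list of `raw_read` (or lists with `read_id` and `signal`)
#' @param path output file
#' @param layout "single" writes the classic one-read
#'   `Raw/Reads/Read_<i>/Signal` layout (one file per read is the historical
#'   convention, but multiple reads are accepted); "multi" writes
#'   `read_<id>/Raw/Signal`
#' @return `path`, invisibly
#' @export
write_fast5 <- function(reads, path, layout = c("single", "multi")) {
  layout <- match.arg(layout)
  # signals cross the process boundary as little-endian float64 (bit-exact);
  # metadata as JSON
  bin <- tempfile(fileext = ".f64")
  con <- file(bin, "wb")
  for (r in reads) writeBin(as.numeric(r$signal), con, size = 8L,
                            endian = "little")
  close(con)
  payload <- jsonlite::toJSON(list(
    path = path, layout = layout, signal_file = bin,
    reads = lapply(reads, function(r)
      list(read_id = r$read_id, n = length(r$signal)))),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp, bin)))
  writeLines(payload, tmp)
  run_fast5_helper(c("write", tmp))
  invisible(path)
}

#' Read all reads from a fast5 (HDF5) file
#'
#' Detects single- and multi-read layouts.  When calibration attributes
#' (digitisation, offset, range) are present the signal is converted to pA as
#' `(raw + offset) * range / digitisation`; otherwise values pass through.
#'
#' @param path fast5 file
#' @return list of records: `read_id`, `signal`
#' @export
read_fast5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bin <- tempfile(fileext = ".f64")
  on.exit(unlink(bin))
  res <- run_fast5_helper(c("read", path, bin))
  ids <- res$reads$read_id
  ns <- res$reads$n
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  lapply(seq_along(ids), function(i)
    list(read_id = ids[i],
         signal = readBin(con, "double", n = ns[i], size = 8L,
                          endian = "little")))
}

#' Write sequences to FASTA
#'
#' @param records named character vector or list (names are ids, values
#'   A/C/G/T sequences); duplicate ids or empty sequences are errors
#' @param path output file (80-column wrapped)
#' @export
write_fasta <- function(records, path) {
  seqs <- unlist(records)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all records must be named")
  if (anyDuplicated(ids)) stop("duplicate ids in FASTA records")
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA records")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file
#' @return named character vector (ids to sequences)
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate ids in FASTA file")
  stats::setNames(as.character(x), ids)
}

#' Write ground-truth base/raw alignment to TSV
#'
#' Columns: read_id, base_index, base, raw_start, raw_end (0-based,
#' half-open).
#'
#' @param reads list of `raw_read`
#' @param path output file
#' @export
write_truth_tsv <- function(reads, path) {
  tabs <- lapply(reads, function(r)
    cbind(read_id = r$read_id, r$truth_ranges))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a ground-truth alignment TSV
#'
#' Per read, ranges must be sorted, disjoint and contiguous from 0 (i.e. they
#' partition `[0, n)`); violations (including 1-based files, which leave a
#' gap at 0) are errors.
#'
#' @param path TSV written by [write_truth_tsv()]
#' @return named list of per-read data.frames (base_index, base, raw_start,
#'   raw_end)
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer"))
  need <- c("read_id", "base_index", "base", "raw_start", "raw_end")
  if (!all(need %in% names(df))) stop("truth TSV missing columns")
  out <- split(df[need[-1L]], df$read_id)
  for (id in names(out)) {
    t <- out[[id]][order(out[[id]]$base_index), ]
    if (any(t$raw_end <= t$raw_start))
      stop("empty or inverted range in read ", id)
    if (t$raw_start[1L] != 0L)
      stop("ranges of read ", id, " do not start at 0 (1-based file?)")
    if (nrow(t) > 1L &&
        any(t$raw_start[-1L] != t$raw_end[-nrow(t)]))
      stop("ranges of read ", id, " are overlapping or leave gaps")
    out[[id]] <- t
  }
  out
}
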
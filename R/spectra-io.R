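# Reading and writing delimited spectral matrices and label tables.
#
# Matrix file layout: header row, first column the wavenumber axis (cm^-1),
# one further column per spectrum. Label file layout: header with columns
# spectrum_id, subject_id, replicate, label. Both comma- and tab-delimited
# files are accepted; the delimiter is sniffed from the first line.

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a spectral matrix (and optional label table) from delimited text
#'
#' The wavenumber axis is canonicalized to ascending order on read (rows are
#' reordered consistently if the file stores the axis descending). Duplicate
#' axis values, ragged rows, and label keys that do not match the matrix
#' column headers are rejected with informative errors.
#'
#' @param path Path to the matrix file (first column: wavenumbers; remaining
#'   columns: one spectrum each, named in the header).
#' @param label_path Optional path to the label table (columns `spectrum_id`,
#'   `subject_id`, `replicate`, `label`). When absent, each spectrum becomes
#'   its own subject with replicate 1 and NA label.
#' @return A [SpectrumSet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("wavenumber,a,b", "500,1,2", "1000,3,4", "2000,5,6"), f)
#' readSpectra(f)
#' @export
readSpectra <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged matrix file: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 1) stop("matrix file has no columns")
  wn <- as.numeric(df[[1]])
  if (anyNA(wn)) stop("non-numeric wavenumber values in first column")
  if (anyDuplicated(wn)) {
    stop(sprintf("duplicate wavenumber value %g in axis", wn[duplicated(wn)][1]))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("missing/non-numeric intensity values in matrix file")
  ord <- order(wn)
  wn <- wn[ord]
  mat <- mat[ord, , drop = FALSE]

  subject_id <- NULL; replicate <- NULL; label <- NULL
  if (!is.null(label_path)) {
    lsep <- .sniff_sep(label_path)
    lab <- utils::read.table(label_path, header = TRUE, sep = lsep,
                             check.names = FALSE, comment.char = "",
                             quote = "\"", colClasses = "character")
    need <- c("spectrum_id", "subject_id", "replicate")
    miss <- setdiff(need, colnames(lab))
    if (length(miss)) stop("label table missing column(s): ",
                           paste(miss, collapse = ", "))
    unmatched <- setdiff(lab$spectrum_id, colnames(mat))
    if (length(unmatched)) {
      stop("label keys absent from matrix columns: ",
           paste(unmatched, collapse = ", "))
    }
    unlabelled <- setdiff(colnames(mat), lab$spectrum_id)
    if (length(unlabelled)) {
      stop("matrix columns missing from label table: ",
           paste(unlabelled, collapse = ", "))
    }
    m <- match(colnames(mat), lab$spectrum_id)
    subject_id <- lab$subject_id[m]
    replicate <- as.integer(lab$replicate[m])
    if ("label" %in% colnames(lab)) {
      label <- lab$label[m]
      label[label %in% c("", "NA")] <- NA_character_
    }
  }
  SpectrumSet(wn, mat, subject_id = subject_id, replicate = replicate,
              label = label, spectrum_id = colnames(mat))
}

#' Write a SpectrumSet as delimited text
#'
#' Values are serialized with 15 significant digits so that a write/read
#' round trip reproduces axis and intensities to well under 1e-9. When the
#' set carries annotations beyond the defaults (or `label_path` is given), a
#' companion label table is written too.
#'
#' @param x A [SpectrumSet-class].
#' @param path Output matrix file; `.tsv` extension selects tab, otherwise
#'   comma.
#' @param label_path Output label table path, or `NULL` to derive
#'   `<path>_labels.<ext>` automatically whenever labels/replicates are
#'   non-trivial.
#' @return Invisibly, the paths written.
#' @export
writeSpectra <- function(x, path, label_path = NULL) {
  stopifnot(methods::is(x, "SpectrumSet"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  mat <- intensities(x)
  out <- cbind(wavenumber = wavenumbers(x), mat)
  df <- as.data.frame(out, check.names = FALSE)
  df[] <- lapply(df, function(col) format(col, digits = 15, trim = TRUE,
                                          scientific = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)

  info <- spectrumInfo(x)
  nontrivial <- ncol(x) > 0 &&
    (!all(is.na(info$label)) || any(info$replicate != 1L) ||
       !identical(info$subject_id, colnames(x)))
  if (is.null(label_path) && nontrivial) {
    ext <- tools::file_ext(path)
    label_path <- sub(paste0("\\.", ext, "$"), paste0("_labels.", ext), path)
  }
  if (!is.null(label_path)) {
    lab <- data.frame(spectrum_id = colnames(x),
                      subject_id = info$subject_id,
                      replicate = info$replicate,
                      label = as.character(info$label),
                      check.names = FALSE)
    utils::write.table(lab, label_path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(c(matrix = path, labels = label_path))
}
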
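#' SpectrumSet: a set of Raman spectra on a shared wavenumber axis
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' conventions used throughout this package: rows are wavenumber points (the
#' axis, in cm^-1, stored in `rowData()$wavenumber` and required to be strictly
#' increasing), columns are individual recorded spectra, and `colData()` carries
#' one row per spectrum with at least `subject_id` (character), `replicate`
#' (integer >= 1) and `label` (factor, may be all-NA when the set is
#' unlabeled). Each `(subject_id, replicate)` pair must be unique: a subject's
#' serum sample is measured several times, and grouped train/test splitting
#' relies on this bookkeeping.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment]; the single assay
#'   is named `"intensity"` and holds the P x S intensity matrix (arbitrary
#'   units; values may be negative after baseline correction, only NA is
#'   rejected).
#'
#' @seealso [SpectrumSet()], [readSpectra()], [wavenumbers()], [intensities()]
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

.validate_spectrum_set <- function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else {
    if (anyNA(wn)) msg <- c(msg, "wavenumber axis contains NA")
    if (length(wn) > 1 && any(diff(wn) <= 0)) {
      bad <- wn[which(diff(wn) <= 0)[1] + 1]
      msg <- c(msg, sprintf(
        "wavenumber axis must be strictly increasing (violated at %g cm^-1)", bad))
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "replicate", "label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("colData missing column(s):", paste(miss, collapse = ", ")))
  } else if (ncol(object) > 0) {
    if (anyNA(cd$subject_id)) msg <- c(msg, "subject_id contains NA")
    if (anyNA(cd$replicate) || any(cd$replicate < 1)) {
      msg <- c(msg, "replicate must be an integer >= 1")
    }
    key <- paste(cd$subject_id, cd$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- cd$subject_id[duplicated(key)][1]
      msg <- c(msg, sprintf("duplicated (subject_id, replicate) pair for subject '%s'", dup))
    }
  }
  if (ncol(object) > 0 && anyNA(SummarizedExperiment::assay(object))) {
    msg <- c(msg, "intensity matrix contains missing values")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SpectrumSet", .validate_spectrum_set)

#' Construct a SpectrumSet
#'
#' @param wavenumbers Numeric vector of axis points in cm^-1, strictly
#'   increasing, length P.
#' @param intensities Numeric P x S matrix, one column per spectrum.
#' @param subject_id Character vector of length S (default: the column names,
#'   or `"spec<i>"`).
#' @param replicate Integer vector of length S (default all 1).
#' @param label Optional factor/character of class labels, length S.
#' @param spectrum_id Optional spectrum identifiers (column names).
#' @return A validated [SpectrumSet-class] object.
#' @examples
#' ss <- SpectrumSet(c(500, 1000, 2000), matrix(1:6, nrow = 3))
#' dim(ss)
#' @export
SpectrumSet <- function(wavenumbers, intensities,
                        subject_id = NULL, replicate = NULL, label = NULL,
                        spectrum_id = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavenumbers)) {
    stop("intensities must have one row per wavenumber point (P = ",
         length(wavenumbers), ", got ", nrow(intensities), " rows)")
  }
  S <- ncol(intensities)
  spectrum_id <- spectrum_id %||% colnames(intensities) %||%
    (if (S > 0) paste0("spec", seq_len(S)) else character())
  subject_id <- subject_id %||% spectrum_id
  replicate <- replicate %||% rep.int(1L, S)
  # factor labels keep their given level order; bare characters get a
  # locale-independent (byte-order) level ordering so that class indexing
  # never depends on the session's collation
  lab <- if (is.null(label)) {
    factor(rep(NA_character_, S))
  } else if (is.factor(label)) {
    label
  } else {
    label <- as.character(label)
    factor(label, levels = sort(unique(label[!is.na(label)]),
                                method = "radix"))
  }
  colnames(intensities) <- spectrum_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = S4Vectors::DataFrame(
      subject_id = as.character(subject_id),
      replicate = as.integer(replicate),
      label = lab,
      row.names = spectrum_id))
  methods::new("SpectrumSet", se)
}

#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Axis and intensity accessors
#'
#' `wavenumbers()` returns the shared axis (cm^-1); `intensities()` the
#' P x S intensity matrix; `spectrumInfo()` the per-spectrum annotation as a
#' data.frame; `classLabels()` the label factor.
#'
#' @param x A [SpectrumSet-class].
#' @return See description.
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber)
})

#' @rdname wavenumbers
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname wavenumbers
#' @export
setMethod("intensities", "SpectrumSet", function(x) {
  SummarizedExperiment::assay(x, "intensity")
})

#' @rdname wavenumbers
#' @export
spectrumInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @rdname wavenumbers
#' @export
classLabels <- function(x) {
  SummarizedExperiment::colData(x)$label
}

#' Replace the intensity matrix, keeping axis and annotations
#' @noRd
set_intensities <- function(x, m) {
  colnames(m) <- colnames(x)
  SummarizedExperiment::assay(x, "intensity") <- m
  x
}

setMethod("show", "SpectrumSet", function(object) {
  wn <- wavenumbers(object)
  cat("SpectrumSet with", ncol(object), "spectra x", nrow(object), "points\n")
  if (nrow(object)) {
    cat(sprintf("  axis: %.6g .. %.6g cm^-1\n", wn[1], wn[length(wn)]))
  }
  cd <- SummarizedExperiment::colData(object)
  if (ncol(object)) {
    cat("  subjects:", length(unique(cd$subject_id)), "\n")
    if (!all(is.na(cd$label))) {
      tb <- table(cd$label)
      cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    }
  }
  invisible(NULL)
})

#' Describe a classification task
#'
#' A label scheme pairs a task name with its ordered class labels. The
#' `"diagnosis"` task is binary (non-SLE vs SLE, SLE positive); the
#' `"activity"` task grades lupus disease activity and defaults to the
#' two-class mild/moderate formulation (the severe grade is rare enough in a
#' cohort of this size that it is excluded by default, but a three-class
#' scheme is selectable).
#'
#' @param task `"diagnosis"` or `"activity"`.
#' @param classes Optional character vector of class names overriding the task
#'   default (diagnosis must keep exactly 2 classes).
#' @param include_severe For `"activity"`, include the `"severe"` grade
#'   (default `FALSE`).
#' @return A list with elements `task`, `classes`, `positive` (class treated
#'   as positive in binary metrics), of class `"labelScheme"`.
#' @examples
#' labelScheme("diagnosis")
#' labelScheme("activity", include_severe = TRUE)
#' @export
labelScheme <- function(task = c("diagnosis", "activity"), classes = NULL,
                        include_severe = FALSE) {
  task <- match.arg(task)
  if (is.null(classes)) {
    classes <- switch(task,
      diagnosis = c("non-SLE", "SLE"),
      activity = if (include_severe) c("mild", "moderate", "severe")
                 else c("mild", "moderate"))
  }
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("class names must be unique")
  if (task == "diagnosis" && length(classes) != 2) {
    stop("the diagnosis task has exactly 2 classes")
  }
  structure(list(task = task, classes = classes,
                 positive = classes[length(classes)]),
            class = "labelScheme")
}
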
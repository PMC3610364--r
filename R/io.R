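# Plain-text I/O: one-column signal files, a CSV manifest (id, path, label),
# and the feature table CSV.

#' Read a cohort from a CSV manifest
#'
#' The manifest must have a header `id,path,label`; each `path` (relative
#' paths are resolved against the manifest's directory) points to a
#' one-column text file with one sample value per line.
#'
#' @param path Manifest CSV path.
#' @param fs Sampling rate to attach to the signals (Hz).
#' @return List of [vag_signal()] objects in manifest order.
#' @export
read_manifest <- function(path, fs = 2000) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns id, path, label: ", path)
  bad <- setdiff(unique(man$label), c("normal", "abnormal", "unknown"))
  if (length(bad) > 0)
    stop("manifest ", path, ": unknown label token(s): ",
         paste(bad, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$path[i]
    if (!file.exists(f)) f <- file.path(base, man$path[i])
    vag_signal(read_signal_file(f), fs = fs, label = man$label[i],
               id = man$id[i])
  })
}

#' Read a one-column signal file
#'
#' @param path Text file with one numeric value per line.
#' @return Numeric vector. Non-numeric lines are an error naming the file
#'   and line number.
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric value in ", path, " at line ", bad, ": '",
         lines[bad], "'")
  }
  vals
}

#' Write a cohort to signal files plus a manifest
#'
#' Writes each signal as a one-column text file (12 significant digits,
#' enough for an exact round trip at the printed precision) into `dir`, and
#' a `manifest.csv` alongside.
#'
#' @param signals List of [vag_signal()] objects.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(signals, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(signals, function(s) {
    fn <- paste0(s$id, ".txt")
    writeLines(sprintf("%.12g", s$samples), file.path(dir, fn))
    data.frame(id = s$id, path = fn, label = s$label,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Write / read the feature table
#'
#' The feature CSV has the header
#' `id,label,natom,tcft,ff1,ff2,vms,mu,fd`.
#'
#' @param path CSV path.
#' @param table Data frame as returned by [extract_cohort_features()].
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the data frame.
#' @export
write_features <- function(path, table) {
  need <- c("id", "label", "natom", "tcft", "ff1", "ff2", "vms", "mu", "fd")
  if (!all(need %in% names(table)))
    stop("feature table must have columns ", paste(need, collapse = ","))
  utils::write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
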
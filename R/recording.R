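# Recording container and plain-text IO.
#
# A recording is one continuous session from a single waist-worn triaxial
# accelerometer: a T x 3 acceleration matrix (units g, axis order x,y,z), a
# per-sample binary FOG annotation, a subject identifier and a sampling rate.

#' Construct a triaxial acceleration recording
#'
#' @param subject_id character scalar identifying the subject.
#' @param fs sampling rate in Hz (> 0).
#' @param accel numeric T x 3 matrix of accelerations in g (columns x, y, z).
#' @param labels integer vector of length T; 1 marks a FOG-annotated sample,
#'   0 normal movement.
#' @param meta free-form provenance list (generator profile, source file, ...).
#' @return an object of class `fog_recording`.
#' @export
fog_recording <- function(subject_id, fs, accel, labels, meta = list()) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("accel must have exactly 3 columns (x, y, z)")
  labels <- as.integer(labels)
  if (nrow(accel) != length(labels))
    stop("labels length (", length(labels), ") must equal accel rows (",
         nrow(accel), ")")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  colnames(accel) <- c("ax", "ay", "az")
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 accel = accel, labels = labels, meta = meta),
            class = "fog_recording")
}

#' @export
print.fog_recording <- function(x, ...) {
  cat(sprintf("<fog_recording> subject %s: %d samples @ %g Hz (%.1f s), %.2f%% FOG\n",
              x$subject_id, nrow(x$accel), x$fs, nrow(x$accel) / x$fs,
              if (length(x$labels)) 100 * mean(x$labels) else 0))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `fog_recording`.
#' @export
n_samples <- function(rec) nrow(rec$accel)

#' Read a recording from CSV
#'
#' Expected dialect: a header line `subject,t,ax,ay,az,label` (column order
#' free; extra columns ignored).  The sampling rate is taken from `fs`, or, if
#' `NULL`, inferred from the median spacing of the `t` column.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz, or `NULL` to infer from the time column.
#' @return a `fog_recording`.
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "ax", "ay", "az", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(df[, c("ax", "ay", "az", "label")])
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped from ", basename(path))
    df <- df[!bad, , drop = FALSE]
  }
  if (!all(df$label %in% c(0, 1)))
    stop("non-binary label values in ", basename(path))
  if (is.null(fs)) {
    if (!"t" %in% names(df) || nrow(df) < 2)
      stop("fs not given and no time column to infer it from")
    fs <- 1 / stats::median(diff(df$t))
  }
  fog_recording(df$subject[1], fs, as.matrix(df[, c("ax", "ay", "az")]),
                df$label, meta = list(source = path))
}

#' Write a recording to CSV
#'
#' Emits the `subject,t,ax,ay,az,label` dialect read back by
#' [read_recording()]; values are written in full double precision.
#'
#' @param rec a `fog_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  T <- n_samples(rec)
  df <- data.frame(subject = rec$subject_id,
                   t = if (T) (seq_len(T) - 1) / rec$fs else numeric(0),
                   ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                   label = rec$labels)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
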
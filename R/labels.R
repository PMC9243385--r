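# Sign-consistent averaging of within-parcel source time courses.

#' Sign-align and average dipole time courses within a cortical label
#'
#' Source orientations fixed perpendicular to the cortical surface make the
#' sign of each dipole's time course arbitrary with respect to its
#' neighbors, so a plain average across a parcel can cancel. This routine
#' computes the singular value decomposition of the dipoles x samples
#' matrix; the first left singular vector carries one loading per dipole,
#' and any row whose loading sign disagrees with the dominant orientation
#' (the sign of the largest-magnitude loading) is inverted before averaging.
#'
#' The global sign of an SVD is arbitrary, so the output is defined up to a
#' global sign; referencing the flips to the largest-magnitude loading makes
#' the result deterministic for a given input.
#'
#' @param x numeric matrix, dipoles x samples (>= 1 row, not all zero), or a
#'   [label_timecourses()] object.
#' @return numeric vector: the mean of the sign-aligned rows.
#' @examples
#' s <- sin(2 * pi * 13 * (0:199) / 200)
#' x <- rbind(s, -s, s, -s)
#' out <- sign_align_average(x)   # +-s, coherent
#' @export
sign_align_average <- function(x) {
  if (inherits(x, "label_timecourses")) x <- x$X
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (!all(is.finite(x))) stop("all values must be finite")
  if (all(x == 0)) stop("degenerate input: all-zero label matrix")
  if (nrow(x) == 1L) return(as.numeric(x[1L, ]))
  u1 <- svd(x, nu = 1L, nv = 0L)$u[, 1L]
  ref <- sign(u1[which.max(abs(u1))])
  flip <- ifelse(sign(u1) * ref < 0, -1, 1)
  as.numeric(colMeans(x * flip))
}

#' Dipole time courses of one cortical label
#'
#' @param label_id label (parcel) identifier.
#' @param X numeric matrix, dipoles x samples, all finite.
#' @param fs sampling rate in Hz.
#' @return an object of class `"label_timecourses"`.
#' @export
label_timecourses <- function(label_id, X, fs) {
  if (!is.matrix(X) || nrow(X) < 1L || !all(is.finite(X))) {
    stop("`X` must be a finite matrix with >= 1 dipole row")
  }
  structure(list(label_id = as.character(label_id), X = X, fs = fs),
            class = "label_timecourses")
}

#' Collapse dipole-level source estimates into a label-level recording
#'
#' Applies [sign_align_average()] to each label of a dipole-level recording,
#' producing one sign-consistent time course per cortical region. The label
#' manifest maps recording channels (dipoles) to labels.
#'
#' @param rec a [recording()] whose channels are dipole time courses.
#' @param manifest data.frame with columns `label_id` and `rows`
#'   (semicolon-joined 1-based dipole row indices), or the path of such a
#'   TSV.
#' @param modality modality tag of the output recording (default
#'   `"source-eeg"`).
#' @return a [recording()] with one channel per label.
#' @export
aggregate_labels <- function(rec, manifest, modality = "source-eeg") {
  stopifnot(inherits(rec, "recording"))
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                                  colClasses = "character")
  }
  if (is.null(manifest$label_id) || is.null(manifest$rows)) {
    stop("manifest needs columns label_id and rows")
  }
  out <- t(vapply(seq_len(nrow(manifest)), function(i) {
    rows <- as.integer(strsplit(manifest$rows[i], ";", fixed = TRUE)[[1L]])
    if (any(rows < 1L | rows > nrow(rec$data))) {
      stop("manifest row indices out of range for label ",
           manifest$label_id[i])
    }
    sign_align_average(rec$data[rows, , drop = FALSE])
  }, numeric(n_samples(rec))))
  recording(out, fs = rec$fs, channel_ids = manifest$label_id,
            modality = modality, t0 = rec$t0)
}
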
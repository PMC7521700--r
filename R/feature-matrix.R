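#' Align per-sample peak lists into a feature x sample matrix
#'
#' Pools every (m/z, intensity) peak from all samples, sorts by m/z, and
#' cuts the sorted list into features wherever the gap between
#' consecutive m/z values exceeds the tolerance (single-linkage gap
#' clustering). This is deterministic and independent of sample order.
#' A sample may contribute at most one peak per feature: when several
#' peaks of one sample land in a cluster, the peak closest to the
#' cluster median m/z is kept and the remaining peaks are re-clustered
#' into new features. Missing values are zeros (absence of signal), not
#' NA. The representative feature m/z is the intensity-weighted mean of
#' the member peaks.
#'
#' @param peaks data.frame with columns `sample_id`, `mz`, `intensity`.
#' @param samples optional sample sheet (`sample_id`, `isolate_id`,
#'   `condition`, `replicate`); defaults to the distinct sample ids seen.
#' @param tolerance alignment tolerance, > 0; in Da by default, 0.01 Da
#'   is TOF-scale.
#' @param unit `"da"` or `"ppm"`; for ppm the gap threshold is evaluated
#'   at the lower of the two adjacent m/z values.
#' @return object of class `feature_matrix`: list with `mz` (strictly
#'   increasing representative m/z), `intensities` (features x samples
#'   numeric matrix), `samples` (sample metadata in column order).
#' @export
align_peaks <- function(peaks, samples = NULL, tolerance = 0.01,
                        unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(peaks),
            all(c("sample_id", "mz", "intensity") %in% names(peaks)))
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  if (any(peaks$intensity < 0)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sort(unique(peaks$sample_id)),
                          stringsAsFactors = FALSE)
  }
  stopifnot("sample_id" %in% names(samples))
  if (!all(peaks$sample_id %in% samples$sample_id)) {
    stop("peaks reference sample ids absent from the sample sheet",
         call. = FALSE)
  }
  sample_ids <- samples$sample_id

  gap_ok <- function(mz_sorted) {
    # TRUE where a new cluster starts
    if (length(mz_sorted) <= 1) return(logical(length(mz_sorted)))
    tol <- if (unit == "da") tolerance else
      tolerance * 1e-6 * mz_sorted[-length(mz_sorted)]
    c(FALSE, diff(mz_sorted) > tol)
  }
  cluster_ids <- function(df) cumsum(gap_ok(df$mz)) + 1L

  ord <- order(peaks$mz, peaks$sample_id)
  work <- list(peaks[ord, c("sample_id", "mz", "intensity")])
  features <- list()
  while (length(work)) {
    df <- work[[1]]
    work <- work[-1]
    cl <- cluster_ids(df)
    for (id in unique(cl)) {
      member <- df[cl == id, , drop = FALSE]
      dup <- duplicated(member$sample_id) |
        duplicated(member$sample_id, fromLast = TRUE)
      if (any(dup)) {
        med <- median(member$mz)
        keep <- rep(TRUE, nrow(member))
        for (sid in unique(member$sample_id[dup])) {
          idx <- which(member$sample_id == sid)
          best <- idx[which.min(abs(member$mz[idx] - med))]
          keep[setdiff(idx, best)] <- FALSE
        }
        leftover <- member[!keep, , drop = FALSE]
        member <- member[keep, , drop = FALSE]
        work <- c(work, list(leftover))   # re-cluster spilled peaks
      }
      features[[length(features) + 1L]] <- member
    }
  }

  rep_mz <- vapply(features, function(f) {
    if (sum(f$intensity) > 0) {
      sum(f$mz * f$intensity) / sum(f$intensity)
    } else {
      mean(f$mz)
    }
  }, numeric(1))
  o <- order(rep_mz)
  features <- features[o]
  rep_mz <- rep_mz[o]

  mat <- matrix(0, nrow = length(features), ncol = length(sample_ids),
                dimnames = list(sprintf("F%04d", seq_along(features)),
                                sample_ids))
  for (i in seq_along(features)) {
    f <- features[[i]]
    mat[i, f$sample_id] <- f$intensity
  }
  structure(list(mz = rep_mz, intensities = mat,
                 samples = samples[match(sample_ids, samples$sample_id), ,
                                   drop = FALSE]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples, m/z %.3f-%.3f\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Per-sample relative intensities
#'
#' Converts a feature matrix to relative intensities: each entry becomes
#' the percentage of that peak's raw intensity over the sample's total
#' raw signal. Non-empty sample columns sum to 100; all-zero (empty)
#' samples stay zero and are flagged.
#'
#' @param fm a `feature_matrix`.
#' @return object of class `rel_intensity_matrix` (same shape as `fm`)
#'   with an extra element `empty_samples` naming all-zero columns.
#' @export
relative_intensities <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  totals <- colSums(fm$intensities)
  empty <- totals == 0
  rel <- sweep(fm$intensities, 2, ifelse(empty, 1, totals), "/") * 100
  rel[, empty] <- 0
  structure(list(mz = fm$mz, intensities = rel, samples = fm$samples,
                 empty_samples = colnames(rel)[empty]),
            class = c("rel_intensity_matrix", "feature_matrix"))
}
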
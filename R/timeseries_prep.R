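#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes from a subject's time series and
#' realignment trace, the conventional guard against scanner
#' equilibration and subject habituation. Default 10.
#'
#' @param series T x g numeric matrix of ROI time series.
#' @param realignment T x 6 numeric matrix of realignment parameters.
#' @param n_discard number of leading volumes to drop.
#' @return list with trimmed `series` and `realignment`.
#' @export
discard_initial <- function(series, realignment, n_discard = 10L) {
  if (nrow(series) != nrow(realignment))
    stop("series and realignment must have the same number of rows")
  if (n_discard >= nrow(series))
    stop(sprintf("discarding %d volumes leaves no data (T = %d)",
                 n_discard, nrow(series)))
  if (n_discard == 0L) return(list(series = series, realignment = realignment))
  keep <- (n_discard + 1L):nrow(series)
  list(series = series[keep, , drop = FALSE],
       realignment = realignment[keep, , drop = FALSE])
}

#' Framewise displacement
#'
#' FD at volume t is the sum of the absolute backward differences of the
#' six rigid-body realignment parameters, with the three rotational
#' differences converted from radians to millimetres as arc length on a
#' sphere of radius `radius_mm` (Power's convention, 50 mm). The first
#' volume has FD 0 by convention.
#'
#' @param realignment T x 6 matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations (radians).
#' @param radius_mm sphere radius for the rotation-to-displacement
#'   conversion.
#' @return numeric vector of length T, non-negative, first element 0.
#' @export
compute_fd <- function(realignment, radius_mm = 50) {
  if (ncol(realignment) != 6L)
    stop("realignment must have exactly 6 columns (3 translations mm, 3 rotations rad)")
  if (any(!is.finite(realignment)))
    stop("realignment contains non-finite values")
  d <- diff(realignment)
  d[, 4:6] <- d[, 4:6] * radius_mm
  c(0, rowSums(abs(d)))
}

#' Motion-based subject exclusion check
#'
#' A subject is excluded when (in this order of reporting) the scan time
#' surviving FD scrubbing falls below `min_minutes`, any translation
#' exceeds `trans_limit_mm`, or any rotation exceeds `rot_limit_deg`.
#' Scrubbing removes volumes with FD above `fd_threshold`.
#'
#' @param fd framewise-displacement vector (mm), aligned with
#'   `realignment`.
#' @param realignment T x 6 realignment matrix (translations mm,
#'   rotations radians).
#' @param tr_seconds repetition time in seconds.
#' @param fd_threshold scrubbing threshold in mm (default 0.2).
#' @param min_minutes minimum surviving scan time in minutes (default 3).
#' @param trans_limit_mm maximum absolute translation (default 2).
#' @param rot_limit_deg maximum absolute rotation in degrees (default 2).
#' @return an object of class `motion_summary`: fd, mean_fd, retained
#'   volume count, max translation (mm) and rotation (degrees), the
#'   exclusion flag and reason.
#' @export
exclusion_check <- function(fd, realignment, tr_seconds,
                            fd_threshold = 0.2, min_minutes = 3,
                            trans_limit_mm = 2, rot_limit_deg = 2) {
  if (length(fd) != nrow(realignment))
    stop("fd and realignment are not aligned")
  retained <- sum(fd <= fd_threshold)
  max_trans <- max(abs(realignment[, 1:3]))
  max_rot_deg <- max(abs(realignment[, 4:6])) * 180 / pi
  reason <- "none"
  if (retained * tr_seconds < min_minutes * 60) {
    reason <- "scan_time_lt_3min"
  } else if (max_trans > trans_limit_mm) {
    reason <- "translation_gt_2mm"
  } else if (max_rot_deg > rot_limit_deg) {
    reason <- "rotation_gt_2deg"
  }
  structure(list(fd = fd, mean_fd = mean(fd),
                 max_translation = max_trans, max_rotation = max_rot_deg,
                 retained_volumes = retained,
                 excluded = reason != "none", exclusion_reason = reason),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(
    "Motion summary: mean FD %.3f mm, %d volumes retained, max trans %.2f mm, max rot %.2f deg -> %s\n",
    x$mean_fd, x$retained_volumes, x$max_translation, x$max_rotation,
    if (x$excluded) paste0("EXCLUDED (", x$exclusion_reason, ")") else "retained"))
  invisible(x)
}

#' Scrub high-motion volumes
#'
#' Removes rows whose FD exceeds the threshold; the returned mask maps
#' retained rows back to the input volume indices.
#'
#' @param series T x g matrix.
#' @param fd FD vector aligned with `series`.
#' @param fd_threshold scrub threshold in mm.
#' @return list with censored `series` and logical `volume_mask` (TRUE =
#'   retained).
#' @export
censor_volumes <- function(series, fd, fd_threshold = 0.2) {
  if (length(fd) != nrow(series)) stop("fd and series are not aligned")
  mask <- fd <= fd_threshold
  if (!any(mask))
    stop("all volumes exceed the FD threshold; subject should have been excluded")
  list(series = series[mask, , drop = FALSE], volume_mask = mask)
}

# Friston-24 motion confounds from the retained realignment rows: the six
# parameters, their one-volume-back values (zero for the first retained
# row), and the squares of both.
friston24 <- function(realignment) {
  rp <- as.matrix(realignment)
  lag <- rbind(rep(0, 6), rp[-nrow(rp), , drop = FALSE])
  cbind(rp, lag, rp^2, lag^2)
}

#' Nuisance regression (Friston-24 + global signal)
#'
#' Regresses out, per ROI, the 24-parameter motion model (six realignment
#' parameters, their one-volume-back values, and both sets squared), a
#' global signal regressor (the mean across ROIs, standing in for the
#' gray-matter signal when no voxel data exist), and an intercept.
#' Collinear confound columns are dropped with a warning.
#'
#' @param series T' x g matrix (after censoring).
#' @param realignment T' x 6 realignment matrix, row-aligned with
#'   `series`.
#' @return residual T' x g matrix, orthogonal to every retained confound.
#' @export
regress_nuisance <- function(series, realignment) {
  if (nrow(series) != nrow(realignment))
    stop("series and realignment must be row-aligned after censoring")
  confounds <- cbind(1, friston24(realignment), rowMeans(series))
  colnames(confounds) <- c("intercept",
                           paste0("rp", 1:6), paste0("rp_lag", 1:6),
                           paste0("rp_sq", 1:6), paste0("rp_lag_sq", 1:6),
                           "global")
  qrX <- qr(confounds)
  if (qrX$rank < ncol(confounds)) {
    dropped <- colnames(confounds)[qrX$pivot[(qrX$rank + 1):ncol(confounds)]]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, series)
}

#' Temporal bandpass filter
#'
#' Zero-phase bandpass via the discrete Fourier transform: frequency bins
#' outside \[`low_hz`, `high_hz`\] (including the DC component) are zeroed
#' and the series inverse-transformed. This ideal-rectangular realization
#' matches the convention of the standard rs-fMRI preprocessing toolchains
#' and is exactly zero-phase.
#'
#' @param series T x g matrix, assumed uniformly sampled.
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz lower passband edge (default 0.01 Hz).
#' @param high_hz upper passband edge (default 0.08 Hz).
#' @return filtered T x g matrix (mean-free).
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  nyquist <- 1 / (2 * tr_seconds)
  if (high_hz >= nyquist)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyquist))
  n <- nrow(series)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz
  f <- stats::mvfft(series)
  f[!keep, ] <- 0
  Re(stats::mvfft(f, inverse = TRUE)) / n
}

#' Preprocess one subject
#'
#' Runs the fixed time-series preprocessing chain: initial-volume discard,
#' FD computation and exclusion check, FD scrubbing, Friston-24 + global
#' signal nuisance regression, and bandpass filtering. The head-motion
#' covariate (`mean_fd`) is the mean FD over post-discard, pre-censor
#' volumes. Excluded subjects return the motion summary and no series.
#'
#' @param subject a `subject_record` (fields `series`, `realignment`) or a
#'   list with those fields.
#' @param tr_seconds repetition time in seconds.
#' @param n_discard initial volumes to drop (default 10).
#' @param fd_threshold scrub threshold in mm (default 0.2).
#' @param min_minutes minimum surviving scan time (default 3).
#' @param trans_limit_mm,rot_limit_deg gross-motion exclusion limits
#'   (defaults 2 mm, 2 degrees).
#' @param low_hz,high_hz bandpass edges (defaults 0.01 and 0.08 Hz).
#' @return list of class `clean_series`: `series` (NULL if excluded),
#'   `volume_mask`, `motion` (a `motion_summary`), `excluded`.
#' @export
prep_subject <- function(subject, tr_seconds, n_discard = 10L,
                         fd_threshold = 0.2, min_minutes = 3,
                         trans_limit_mm = 2, rot_limit_deg = 2,
                         low_hz = 0.01, high_hz = 0.08) {
  trimmed <- discard_initial(subject$series, subject$realignment, n_discard)
  fd <- compute_fd(trimmed$realignment)
  motion <- exclusion_check(fd, trimmed$realignment, tr_seconds,
                            fd_threshold, min_minutes,
                            trans_limit_mm, rot_limit_deg)
  if (motion$excluded) {
    return(structure(list(series = NULL, volume_mask = NULL,
                          motion = motion, excluded = TRUE),
                     class = "clean_series"))
  }
  cens <- censor_volumes(trimmed$series, fd, fd_threshold)
  rp_retained <- trimmed$realignment[cens$volume_mask, , drop = FALSE]
  resid <- regress_nuisance(cens$series, rp_retained)
  clean <- bandpass(resid, tr_seconds, low_hz, high_hz)
  structure(list(series = clean, volume_mask = cens$volume_mask,
                 motion = motion, excluded = FALSE),
            class = "clean_series")
}

#' Preprocess a cohort and tabulate motion QC
#'
#' Applies [prep_subject()] to every subject and assembles the motion-QC
#' bookkeeping used both for exclusion reporting and for the head-motion
#' covariate in group statistics.
#'
#' @param cohort a `cohort` from [generate_cohort()] or an equivalent list
#'   with `subjects` and `spec$tr_seconds`.
#' @param tr_seconds repetition time; defaults to the cohort spec's value.
#' @param ... further arguments passed to [prep_subject()].
#' @return list with `clean` (named list of `clean_series` for retained
#'   subjects) and `qc` (data.frame: subject_id, group, mean_fd,
#'   retained_volumes, excluded, reason).
#' @export
prep_cohort <- function(cohort, tr_seconds = cohort$spec$tr_seconds, ...) {
  clean <- list()
  qc <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    res <- prep_subject(s, tr_seconds, ...)
    qc[[i]] <- data.frame(subject_id = s$subject_id, group = s$group,
                          mean_fd = res$motion$mean_fd,
                          retained_volumes = res$motion$retained_volumes,
                          excluded = res$excluded,
                          reason = res$motion$exclusion_reason,
                          stringsAsFactors = FALSE)
    if (!res$excluded) clean[[s$subject_id]] <- res
  }
  list(clean = clean, qc = do.call(rbind, qc))
}
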
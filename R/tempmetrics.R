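#' Back-project iCAP maps into activity-inducing signals
#'
#' Per time point, ordinary least-squares regression of the activity map on
#' the K iCAP z-maps (columns mean-centred over the mask) yields the iCAP
#' activation amplitudes, i.e. the iCAP time courses for that session.
#'
#' @param zmaps K x voxel matrix of iCAP maps (from an `icap_set`).
#' @param activity voxel x time activity-inducing signals (from an
#'   `innovation_set`).
#' @param scrub_mask optional logical vector of usable volumes.
#' @return object of class `icap_timecourses`: `raw` and `z` (per-iCAP
#'   z-normalised over non-scrubbed volumes) K x T matrices, `scrub_mask`.
#' @export
transient_informed_regression <- function(zmaps, activity, scrub_mask = NULL) {
  if (inherits(zmaps, "icap_set")) zmaps <- zmaps$zmaps
  if (ncol(zmaps) != nrow(activity)) {
    stop("zmaps and activity do not share a voxel dimension", call. = FALSE)
  }
  Z <- scale(t(zmaps), center = TRUE, scale = FALSE)  # voxel x K, centred
  cc <- abs(cor(Z))
  diag(cc) <- 0
  if (any(cc > 0.999)) {
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("collinear iCAP maps (", pair[1], ", ", pair[2],
         "): regression is rank-deficient", call. = FALSE)
  }
  G <- crossprod(Z)
  B <- solve(G, crossprod(Z, activity))  # K x T
  T <- ncol(B)
  if (is.null(scrub_mask)) scrub_mask <- rep(TRUE, T)
  use <- which(scrub_mask)
  mu <- rowMeans(B[, use, drop = FALSE])
  sdv <- apply(B[, use, drop = FALSE], 1, sd)
  sdv[sdv == 0] <- 1
  Zc <- (B - mu) / sdv
  structure(list(raw = B, z = Zc, scrub_mask = scrub_mask),
            class = "icap_timecourses")
}

#' @export
print.icap_timecourses <- function(x, ...) {
  cat("<icap_timecourses>", nrow(x$raw), "iCAPs x", ncol(x$raw), "volumes\n")
  invisible(x)
}

#' Threshold iCAP time courses into signed activation block trains
#'
#' A volume is active-positive (+1) when the z-normalised course exceeds
#' `z_thresh`, active-negative (-1) below `-z_thresh`, otherwise 0.
#' Scrubbed volumes are forced to 0 and are excluded from all downstream
#' denominators.
#'
#' @param timecourses an `icap_timecourses` object or a K x T (or vector)
#'   z-valued course.
#' @param z_thresh activation threshold (> 0), default 1.
#' @param scrub_mask logical vector of usable volumes; defaults to the one
#'   stored in `timecourses` when available.
#' @return integer matrix (or vector) of -1/0/+1 trains with attribute
#'   `scrub_mask`.
#' @export
binarize_blocks <- function(timecourses, z_thresh = 1, scrub_mask = NULL) {
  if (z_thresh <= 0) stop("`z_thresh` must be > 0", call. = FALSE)
  if (inherits(timecourses, "icap_timecourses")) {
    if (is.null(scrub_mask)) scrub_mask <- timecourses$scrub_mask
    z <- timecourses$z
  } else {
    z <- timecourses
  }
  vec <- is.null(dim(z))
  z <- rbind(z)
  if (is.null(scrub_mask)) scrub_mask <- rep(TRUE, ncol(z))
  train <- sign(z) * (abs(z) > z_thresh)
  train[, !scrub_mask] <- 0L
  storage.mode(train) <- "integer"
  if (vec) train <- drop(train)
  attr(train, "scrub_mask") <- scrub_mask
  train
}

#' Total duration of activation
#'
#' Percent of non-scrubbed volumes in which the train is nonzero.
#'
#' @param blocks signed train (vector) or K x T matrix from
#'   [binarize_blocks()].
#' @param scrub_mask logical vector of usable volumes; defaults to the
#'   attribute on `blocks`, else all volumes.
#' @return percent in \[0, 100\] (vector of length K for a matrix input).
#' @export
total_duration <- function(blocks, scrub_mask = NULL) {
  if (is.null(scrub_mask)) scrub_mask <- attr(blocks, "scrub_mask")
  m <- rbind(blocks)
  if (is.null(scrub_mask)) scrub_mask <- rep(TRUE, ncol(m))
  denom <- sum(scrub_mask)
  if (denom == 0) stop("all volumes scrubbed: duration undefined", call. = FALSE)
  out <- 100 * rowSums(m[, scrub_mask, drop = FALSE] != 0) / denom
  if (is.null(dim(blocks))) out <- unname(out[1]) else out <- unname(out)
  out
}

#' Number of activation blocks
#'
#' Counts maximal runs of same-signed nonzero values; a sign change without
#' an intervening zero starts a new block.
#'
#' @param blocks signed train (vector) or K x T matrix.
#' @return integer count (vector of length K for a matrix input).
#' @export
occurrences <- function(blocks) {
  count1 <- function(tr) {
    r <- rle(as.integer(tr))
    sum(r$values != 0L)
  }
  if (is.null(dim(blocks))) count1(blocks) else
    unname(apply(blocks, 1, count1))
}

#' Jaccard coupling and anticoupling of two trains
#'
#' Coupling is the fraction of time both trains are active with the same
#' sign, anticoupling with opposite signs, each relative to the time at
#' least one is active (Jaccard score). Both are 0 when neither train is
#' ever active.
#'
#' @param blocks_i,blocks_j signed trains of equal length (same scrub mask
#'   already applied).
#' @return named numeric vector `c(coupling, anticoupling)`.
#' @export
coupling_jaccard <- function(blocks_i, blocks_j) {
  if (length(blocks_i) != length(blocks_j)) {
    stop("trains must have equal length", call. = FALSE)
  }
  union_t <- sum(blocks_i != 0 | blocks_j != 0)
  if (union_t == 0) return(c(coupling = 0, anticoupling = 0))
  both <- blocks_i != 0 & blocks_j != 0
  c(coupling = sum(both & (blocks_i == blocks_j)) / union_t,
    anticoupling = sum(both & (blocks_i == -blocks_j)) / union_t)
}

#' Static inter-iCAP Pearson correlations
#'
#' Correlation of raw iCAP time courses over non-scrubbed volumes.
#' Zero-variance courses yield NA entries with a warning.
#'
#' @param timecourses an `icap_timecourses` object or K x T matrix.
#' @param scrub_mask logical vector of usable volumes.
#' @return symmetric K x K correlation matrix with unit diagonal.
#' @export
static_correlation <- function(timecourses, scrub_mask = NULL) {
  if (inherits(timecourses, "icap_timecourses")) {
    if (is.null(scrub_mask)) scrub_mask <- timecourses$scrub_mask
    B <- timecourses$raw
  } else {
    B <- timecourses
  }
  if (is.null(scrub_mask)) scrub_mask <- rep(TRUE, ncol(B))
  if (sum(scrub_mask) < 3) stop("need at least 3 usable volumes", call. = FALSE)
  Bu <- t(B[, scrub_mask, drop = FALSE])
  v <- apply(Bu, 2, var)
  if (any(v == 0)) {
    warning("zero-variance time course: correlation entries set to NA",
            call. = FALSE)
  }
  suppressWarnings(R <- cor(Bu))
  diag(R) <- 1
  R
}

#' Tidy per-session temporal metrics table
#'
#' Computes total duration and occurrences per iCAP and Jaccard
#' coupling/anticoupling per unordered iCAP pair (upper triangle, i < j,
#' row-major), in the long format
#' `subject,session,icap_i,icap_j,metric,value` (icap_j is NA for unary
#' metrics).
#'
#' @param blocks signed K x T train matrix from [binarize_blocks()].
#' @param subject,session provenance labels.
#' @param scrub_mask logical vector of usable volumes.
#' @return data frame in the tidy format above.
#' @export
temporal_metrics <- function(blocks, subject = "sub01", session = "ses1",
                             scrub_mask = NULL) {
  if (is.null(scrub_mask)) scrub_mask <- attr(blocks, "scrub_mask")
  K <- nrow(blocks)
  dur <- total_duration(blocks, scrub_mask)
  occ <- occurrences(blocks)
  rows <- list(
    data.frame(subject = subject, session = session,
               icap_i = seq_len(K), icap_j = NA_integer_,
               metric = "duration", value = dur),
    data.frame(subject = subject, session = session,
               icap_i = seq_len(K), icap_j = NA_integer_,
               metric = "occurrences", value = as.numeric(occ))
  )
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      cj <- coupling_jaccard(blocks[i, ], blocks[j, ])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, session = session,
        icap_i = i, icap_j = j,
        metric = c("coupling", "anticoupling"),
        value = as.numeric(cj))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
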
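#' Select significant transient frames from innovation signals
#'
#' For each subject, a threshold is set at the given percentile of the
#' pooled absolute innovations over all of that subject's sessions (or over
#' all subjects when `pooling = "global"`). A volume is kept as a transient
#' frame if at least `min_active_voxels` voxels exceed the threshold; kept
#' frames are stored as signed innovation snapshots, concatenated across
#' subjects in input order with a subject's sessions adjacent.
#'
#' @param innovation_sets one `innovation_set` or a list of them.
#' @param percentile threshold percentile in (50, 100), default 95.
#' @param min_active_voxels minimum suprathreshold voxels per kept frame;
#'   default 1% of the mask size (at least 1).
#' @param pooling `"subject"` (default) or `"global"` threshold pooling.
#' @return object of class `transient_frames`: `frames` (frame x voxel),
#'   `provenance` (subject, session, volume), `threshold_used` per subject.
#'   With a warning, an empty set when no frame survives.
#' @export
select_transients <- function(innovation_sets, percentile = 95,
                              min_active_voxels = NULL,
                              pooling = c("subject", "global")) {
  pooling <- match.arg(pooling)
  if (inherits(innovation_sets, "innovation_set")) {
    innovation_sets <- list(innovation_sets)
  }
  if (percentile <= 50 || percentile >= 100) {
    stop("`percentile` must be in (50, 100)", call. = FALSE)
  }
  nvox <- nrow(innovation_sets[[1]]$innovations)
  if (is.null(min_active_voxels)) min_active_voxels <- max(1L, floor(0.01 * nvox))

  subjects <- vapply(innovation_sets, `[[`, character(1), "subject")
  thr_by_subject <- c()
  if (pooling == "global") {
    g <- quantile(abs(unlist(lapply(innovation_sets, `[[`, "innovations"))),
                  percentile / 100, names = FALSE)
    thr_by_subject <- setNames(rep(g, length(unique(subjects))), unique(subjects))
  } else {
    for (s in unique(subjects)) {
      pool <- unlist(lapply(innovation_sets[subjects == s], `[[`, "innovations"))
      thr_by_subject[s] <- quantile(abs(pool), percentile / 100, names = FALSE)
    }
  }

  frames <- list()
  prov <- list()
  for (i in seq_along(innovation_sets)) {
    iset <- innovation_sets[[i]]
    thr <- thr_by_subject[[iset$subject]]
    keep_t <- which(colSums(abs(iset$innovations) > thr) >= min_active_voxels)
    if (!is.null(iset$scrub_mask)) keep_t <- keep_t[iset$scrub_mask[keep_t]]
    if (length(keep_t) == 0L) next
    frames[[length(frames) + 1L]] <- t(iset$innovations[, keep_t, drop = FALSE])
    prov[[length(prov) + 1L]] <- data.frame(
      subject = iset$subject, session = iset$session_id, volume = keep_t)
  }

  if (length(frames) == 0L) {
    warning("no transient frame survived the threshold; returning empty set",
            call. = FALSE)
    return(structure(list(frames = matrix(0, 0, nvox),
                          provenance = data.frame(subject = character(),
                                                  session = character(),
                                                  volume = integer()),
                          threshold_used = thr_by_subject),
                     class = "transient_frames"))
  }
  structure(list(frames = do.call(rbind, frames),
                 provenance = do.call(rbind, prov),
                 threshold_used = thr_by_subject),
            class = "transient_frames")
}

#' @export
print.transient_frames <- function(x, ...) {
  cat("<transient_frames>", nrow(x$frames), "frames x", ncol(x$frames),
      "voxels from", length(unique(x$provenance$subject)), "subject(s)\n")
  invisible(x)
}

#' Sign-invariant cosine k-means of transient frames
#'
#' Clusters frames with distance `1 - |cos(frame, centroid)|`: a frame may
#' be flipped to best match its centroid, so onset (+map) and offset (-map)
#' transients of one network land in one cluster. Centroids are means of
#' sign-aligned member frames. k-means++ initialisation; on exact distance
#' ties the lowest cluster index wins; best of `n_replicates` restarts by
#' total dispersion. Deterministic for a given `seed`.
#'
#' @param frames a `transient_frames` object or a frame x voxel matrix.
#' @param K number of clusters (<= number of frames).
#' @param n_replicates random restarts (default 20).
#' @param seed RNG seed.
#' @param max_iter assignment/update iterations per restart.
#' @return list with `labels` (signed integers: cluster id, sign = flip
#'   applied to the frame), `centroids` (K x voxel, unit norm),
#'   `objective` (total dispersion `sum(1 - |cos|)`).
#' @export
kmeans_transients <- function(frames, K, n_replicates = 20, seed = 1,
                              max_iter = 100) {
  F <- if (inherits(frames, "transient_frames")) frames$frames else frames
  n <- nrow(F)
  if (n < K) stop("need at least K frames (", n, " < ", K, ")", call. = FALSE)
  norms <- sqrt(rowSums(F^2))
  if (any(norms == 0)) stop("zero-norm frame cannot be clustered", call. = FALSE)
  Fn <- F / norms

  best <- NULL
  withr::with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      fit <- cosine_kmeans_once(Fn, K, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  best
}

cosine_kmeans_once <- function(Fn, K, max_iter) {
  n <- nrow(Fn)
  # k-means++ on d = 1 - |cos|
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d <- 1 - abs(Fn %*% Fn[centers[1], ])
  if (K > 1) {
    for (k in 2:K) {
      w <- pmax(as.numeric(d), 0)
      centers[k] <- if (sum(w) == 0) sample.int(n, 1L) else
        sample.int(n, 1L, prob = w)
      d <- pmin(d, 1 - abs(Fn %*% Fn[centers[k], ]))
    }
  }
  C <- Fn[centers, , drop = FALSE]

  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    S <- Fn %*% t(C)                       # cosine similarities
    A <- abs(S)
    new_labels <- max.col(A, ties.method = "first")
    signs <- sign(S[cbind(seq_len(n), new_labels)])
    signs[signs == 0] <- 1L
    # refill emptied clusters with the worst-fitted frame
    for (k in seq_len(K)) {
      if (!any(new_labels == k)) {
        far <- which.min(A[cbind(seq_len(n), new_labels)])
        new_labels[far] <- k
        signs[far] <- 1L
      }
    }
    changed <- !identical(new_labels, labels)
    labels <- new_labels
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      ck <- colSums(Fn[idx, , drop = FALSE] * signs[idx])
      nk <- sqrt(sum(ck^2))
      if (nk > 0) C[k, ] <- ck / nk
    }
    if (!changed) break
  }
  S <- Fn %*% t(C)
  objective <- sum(1 - abs(S)[cbind(seq_len(n), labels)])
  list(labels = labels * signs, centroids = C, objective = objective)
}

#' Choose the number of clusters by consensus clustering
#'
#' For each K in `K_range`, frames are repeatedly subsampled (fraction
#' `subsample_frac`, `n_resamples` times) and clustered; the consensus
#' matrix entry (i, j) is the fraction of co-samplings in which i and j were
#' co-clustered (NA if never co-sampled). Clustering quality at each K is
#' the mean over the full-data clusters of the within-cluster mean
#' consensus; the selected K maximises it.
#'
#' @param frames a `transient_frames` object or frame x voxel matrix.
#' @param K_range candidate cluster counts, within `[2, n_frames / 2]`.
#' @param n_resamples number of subsamples per K (default 30).
#' @param subsample_frac fraction of frames per subsample (default 0.8).
#' @param seed RNG seed.
#' @param n_replicates k-means restarts inside each resample (default 5).
#' @return object of class `consensus_result`: `K_range`, `consensus`
#'   (list of frame x frame matrices), `mean_consensus` (per K),
#'   `per_cluster` (list of per-cluster means), `selected_K`, `labels`
#'   (full-data labels per K).
#' @export
consensus_select_K <- function(frames, K_range = 5:15, n_resamples = 30,
                               subsample_frac = 0.8, seed = 1,
                               n_replicates = 5) {
  F <- if (inherits(frames, "transient_frames")) frames$frames else frames
  n <- nrow(F)
  if (min(K_range) < 2 || max(K_range) > n / 2) {
    stop("`K_range` must lie within [2, n_frames/2]", call. = FALSE)
  }
  m <- max(2L, round(subsample_frac * n))

  consensus <- list()
  per_cluster <- list()
  mean_consensus <- setNames(numeric(length(K_range)), K_range)
  labels_by_K <- list()
  withr::with_seed(seed, {
    sub_seeds <- matrix(sample.int(2^30, length(K_range) * n_resamples),
                        nrow = length(K_range))
    full_seeds <- sample.int(2^30, length(K_range))
  })
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    together <- matrix(0, n, n)
    sampled <- matrix(0, n, n)
    for (r in seq_len(n_resamples)) {
      withr::with_seed(sub_seeds[ki, r], idx <- sort(sample.int(n, m)))
      fit <- kmeans_transients(F[idx, , drop = FALSE], K,
                               n_replicates = n_replicates,
                               seed = sub_seeds[ki, r])
      lab <- abs(fit$labels)
      sampled[idx, idx] <- sampled[idx, idx] + 1
      same <- outer(lab, lab, "==") * 1
      together[idx, idx] <- together[idx, idx] + same
    }
    cons <- together / sampled
    cons[sampled == 0] <- NA_real_
    consensus[[as.character(K)]] <- cons

    full <- kmeans_transients(F, K, n_replicates = n_replicates,
                              seed = full_seeds[ki])
    lab <- abs(full$labels)
    labels_by_K[[as.character(K)]] <- full$labels
    pc <- vapply(seq_len(K), function(k) {
      idx <- which(lab == k)
      if (length(idx) < 2) return(1)
      block <- cons[idx, idx]
      vals <- block[upper.tri(block)]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1))
    per_cluster[[as.character(K)]] <- pc
    mean_consensus[ki] <- mean(pc, na.rm = TRUE)
  }
  selected_K <- K_range[which.max(mean_consensus)]
  structure(list(K_range = K_range, consensus = consensus,
                 per_cluster = per_cluster,
                 mean_consensus = mean_consensus,
                 selected_K = selected_K, labels = labels_by_K),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> K range", min(x$K_range), "-", max(x$K_range),
      "; selected K =", x$selected_K, "\n")
  invisible(x)
}

#' Build z-scored iCAP spatial maps from clustered frames
#'
#' Each cluster map is the mean of its sign-aligned member frames,
#' z-scored over the mask (mean 0, SD 1). When an integer atlas labelling
#' is supplied, a region report lists every region for which more than
#' `report_frac` of its voxels have `|z| > z_cut` in a map.
#'
#' @param frames a `transient_frames` object or frame x voxel matrix.
#' @param labels signed labels from [kmeans_transients()].
#' @param atlas_labels optional integer vector (one per masked voxel,
#'   0 = unlabelled) naming regions.
#' @param z_cut z threshold for the region report (default 2).
#' @param report_frac coverage fraction above which a region is listed
#'   (default 0.2).
#' @return object of class `icap_set`: `K`, `zmaps` (K x voxel), `labels`,
#'   `centroid_norms`, `sizes`, and `region_report` (data frame: icap,
#'   region, coverage) or NULL.
#' @export
build_zmaps <- function(frames, labels, atlas_labels = NULL, z_cut = 2,
                        report_frac = 0.2) {
  F <- if (inherits(frames, "transient_frames")) frames$frames else frames
  K <- max(abs(labels))
  if (any(abs(labels) < 1) || length(labels) != nrow(F)) {
    stop("invalid labels", call. = FALSE)
  }
  zmaps <- matrix(0, K, ncol(F))
  sizes <- integer(K)
  norms <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(abs(labels) == k)
    if (length(idx) == 0L) stop("cluster ", k, " is empty", call. = FALSE)
    sizes[k] <- length(idx)
    m <- colSums(F[idx, , drop = FALSE] * sign(labels[idx])) / length(idx)
    norms[k] <- sqrt(sum(m^2))
    zmaps[k, ] <- (m - mean(m)) / sd(m)
  }
  report <- NULL
  if (!is.null(atlas_labels)) {
    stopifnot(length(atlas_labels) == ncol(F))
    rows <- list()
    for (k in seq_len(K)) {
      for (reg in setdiff(sort(unique(atlas_labels)), 0L)) {
        inreg <- atlas_labels == reg
        cov <- mean(abs(zmaps[k, inreg]) > z_cut)
        if (cov > report_frac) {
          rows[[length(rows) + 1L]] <-
            data.frame(icap = k, region = reg, coverage = cov)
        }
      }
    }
    report <- if (length(rows)) do.call(rbind, rows) else
      data.frame(icap = integer(), region = integer(), coverage = numeric())
  }
  structure(list(K = K, zmaps = zmaps, labels = labels,
                 centroid_norms = norms, sizes = sizes,
                 region_report = report),
            class = "icap_set")
}

#' @export
print.icap_set <- function(x, ...) {
  cat("<icap_set> K =", x$K, "; cluster sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Match iCAP maps to reference network maps
#'
#' Greedy assignment of clusters to reference maps by decreasing absolute
#' spatial correlation; used to compare recovered networks with planted
#' ones.
#'
#' @param icap_set an `icap_set`.
#' @param atlas a `network_atlas` (or voxel x network weight matrix).
#' @param mask optional logical mask restricting the atlas rows to the
#'   voxels the zmaps were computed on.
#' @return data frame with `icap`, `network`, `spatial_cor`.
#' @export
match_icaps_to_atlas <- function(icap_set, atlas, mask = NULL) {
  W <- if (inherits(atlas, "network_atlas")) atlas$maps else atlas
  if (!is.null(mask)) W <- W[as.logical(mask), , drop = FALSE]
  R <- abs(cor(t(icap_set$zmaps), W))
  ic <- nrow(R); nw <- ncol(R)
  out <- data.frame(icap = integer(), network = integer(),
                    spatial_cor = numeric())
  Rw <- R
  for (step in seq_len(min(ic, nw))) {
    pos <- which(Rw == max(Rw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(icap = pos[1], network = pos[2],
                                 spatial_cor = R[pos[1], pos[2]]))
    Rw[pos[1], ] <- NA
    Rw[, pos[2]] <- NA
  }
  out[order(out$network), ]
}
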
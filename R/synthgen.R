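#' Build a synthetic atlas of contiguous network blobs
#'
#' Places `n_networks` contiguous blobs on a 3-D lattice by region growing
#' from well-separated seed voxels. Cores are grown disjoint; when
#' `overlap_frac > 0` each network is then dilated into its neighbours'
#' territory, with the fraction of shared voxels between any two networks
#' (relative to the smaller of the pair) capped at `overlap_frac`.
#' Core voxels carry weight 1, dilated voxels weight 0.5.
#'
#' @param n_networks number of networks (>= 2).
#' @param grid_shape integer vector of 3 lattice dimensions.
#' @param overlap_frac maximum pairwise shared-voxel fraction in \[0, 1\].
#' @param seed RNG seed.
#' @param coverage total fraction of the lattice covered by network cores
#'   (default 0.5); each blob targets `coverage * volume / n_networks`
#'   voxels.
#' @return object of class `network_atlas`: list with `n_networks`,
#'   `grid_shape`, `maps` (voxel-count x n_networks weight matrix, one row
#'   per lattice voxel in array order), and `voxel_sets`.
#' @export
make_network_atlas <- function(n_networks, grid_shape, overlap_frac = 0.1,
                               seed = 1, coverage = 0.5) {
  if (n_networks < 2) stop("`n_networks` must be >= 2", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be three positive integers", call. = FALSE)
  }
  V <- prod(grid_shape)
  if (V < 10L * n_networks) {
    stop("grid too small: need at least 10 voxels per network to place disjoint cores",
         call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop("`overlap_frac` must be in [0, 1]", call. = FALSE)
  }
  target_size <- max(8L, floor(coverage * V / n_networks))

  withr::with_seed(seed, {
    coords <- arrayInd(seq_len(V), grid_shape)
    # maximin seed placement: greedy farthest-point from a random start
    seeds <- integer(n_networks)
    seeds[1] <- sample.int(V, 1L)
    d2 <- rowSums((coords - rep(coords[seeds[1], ], each = V))^2)
    for (k in seq_len(n_networks)[-1]) {
      seeds[k] <- which.max(d2)
      d2 <- pmin(d2, rowSums((coords - rep(coords[seeds[k], ], each = V))^2))
    }

    owner <- integer(V)  # 0 = unclaimed
    owner[seeds] <- seq_len(n_networks)
    frontiers <- lapply(seq_len(n_networks), function(k) neighbours6(seeds[k], grid_shape))
    sizes <- rep(1L, n_networks)
    active <- rep(TRUE, n_networks)
    while (any(active & sizes < target_size)) {
      progressed <- FALSE
      for (k in seq_len(n_networks)) {
        if (!active[k] || sizes[k] >= target_size) next
        fr <- frontiers[[k]]
        fr <- fr[owner[fr] == 0L]
        if (length(fr) == 0L) { active[k] <- FALSE; next }
        v <- if (length(fr) == 1L) fr else sample(fr, 1L)
        owner[v] <- k
        sizes[k] <- sizes[k] + 1L
        frontiers[[k]] <- unique(c(frontiers[[k]], neighbours6(v, grid_shape)))
        progressed <- TRUE
      }
      if (!progressed) break
    }

    voxel_sets <- lapply(seq_len(n_networks), function(k) which(owner == k))
    maps <- matrix(0, nrow = V, ncol = n_networks)
    for (k in seq_len(n_networks)) maps[voxel_sets[[k]], k] <- 1

    if (overlap_frac > 0) {
      for (k in seq_len(n_networks)) {
        boundary <- setdiff(
          unique(unlist(lapply(voxel_sets[[k]], neighbours6, grid_shape))),
          voxel_sets[[k]]
        )
        boundary <- boundary[owner[boundary] > 0L]
        if (length(boundary) > 1L) boundary <- sample(boundary)
        size_k <- sum(maps[, k] > 0)
        for (v in boundary) {
          holders <- setdiff(which(maps[v, ] > 0), k)
          # sizes only grow during dilation, so capping against the current
          # minimum size keeps every final pairwise fraction under the limit
          ok <- all(vapply(holders, function(j) {
            shared_after <- sum(maps[, k] > 0 & maps[, j] > 0) + 1L
            shared_after <= overlap_frac * min(size_k, sum(maps[, j] > 0))
          }, logical(1)))
          if (ok) {
            maps[v, k] <- 0.5
            size_k <- size_k + 1L
          }
        }
      }
      voxel_sets <- lapply(seq_len(n_networks), function(k) which(maps[, k] > 0))
    }
  })

  structure(
    list(n_networks = n_networks, grid_shape = grid_shape,
         maps = maps, voxel_sets = voxel_sets),
    class = "network_atlas"
  )
}

# 6-connected lattice neighbours of linear index v
neighbours6 <- function(v, grid_shape) {
  ijk <- arrayInd(v, grid_shape)[1, ]
  out <- integer(0)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      p <- ijk
      p[d] <- p[d] + s
      if (p[d] >= 1L && p[d] <= grid_shape[d]) {
        out <- c(out, p[1] + grid_shape[1] * (p[2] - 1L) +
                   grid_shape[1] * grid_shape[2] * (p[3] - 1L))
      }
    }
  }
  out
}

#' Simulate a block activity train for one network
#'
#' Places non-overlapping activation blocks (separated by at least one
#' inactive volume so occurrences stay well defined) on a time axis of
#' `n_volumes`. The number of blocks is `round(rate * n_volumes / 100)`;
#' block lengths are drawn uniformly from `block_len_range`.
#'
#' @param n_volumes number of volumes; must exceed the maximum block length.
#' @param rate expected blocks per 100 volumes.
#' @param block_len_range integer vector `c(min, max)` block length.
#' @param seed RNG seed.
#' @return list with `train` (0/1 integer vector), `onsets`, `offsets`
#'   (first/last active volume of each block) and `duration_pct`
#'   (exact percent of active volumes).
#' @export
simulate_block_activity <- function(n_volumes, rate, block_len_range = c(5, 15),
                                    seed = 1) {
  if (n_volumes <= max(block_len_range)) {
    stop("`n_volumes` must exceed the maximum block length", call. = FALSE)
  }
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  n_blocks <- round(rate * n_volumes / 100)
  withr::with_seed(seed, {
    res <- place_blocks(n_volumes, n_blocks, block_len_range)
  })
  if (is.null(res)) {
    stop("cannot place ", n_blocks, " non-overlapping blocks of length ",
         block_len_range[1], "-", block_len_range[2], " in ", n_volumes,
         " volumes", call. = FALSE)
  }
  res
}

# rejection placement of n_blocks blocks with >= 1 volume gap; NULL on failure
place_blocks <- function(n_volumes, n_blocks, block_len_range, max_tries = 2000L) {
  train <- integer(n_volumes)
  onsets <- integer(0)
  offsets <- integer(0)
  if (n_blocks > 0) {
    lens <- sample(seq(block_len_range[1], block_len_range[2]), n_blocks,
                   replace = TRUE)
    # forbid adjacency by padding each block with one volume on each side
    blocked <- rep(FALSE, n_volumes)
    for (len in lens) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        start <- sample.int(n_volumes - len + 1L, 1L)
        span <- start:(start + len - 1L)
        pad <- max(1L, start - 1L):min(n_volumes, start + len)
        if (!any(blocked[pad])) {
          train[span] <- 1L
          blocked[pad] <- TRUE
          onsets <- c(onsets, start)
          offsets <- c(offsets, start + len - 1L)
          placed <- TRUE
          break
        }
      }
      if (!placed) return(NULL)
    }
  }
  ord <- order(onsets)
  list(train = train, onsets = onsets[ord], offsets = offsets[ord],
       duration_pct = 100 * sum(train) / n_volumes)
}

# reach a target active fraction by lengthening the blocks of a baseline
# train (new blocks only as a last resort), so a planted duration shift
# leaves the number of activation blocks essentially unchanged
simulate_activity_target <- function(n_volumes, target_pct,
                                     block_len_range = c(5, 15), seed = 1,
                                     rate = NULL) {
  target_pct <- min(max(target_pct, 0), 95)
  if (is.null(rate)) {
    rate <- 100 * mean(block_len_range) / n_volumes  # ~1 block if unspecified
  }
  base <- simulate_block_activity(n_volumes, rate, block_len_range, seed)
  train <- base$train
  onsets <- base$onsets
  offsets <- base$offsets
  withr::with_seed(seed + 1L, {
    guard <- 0L
    while (100 * sum(train) / n_volumes < target_pct && guard < 5000L) {
      guard <- guard + 1L
      nb <- length(onsets)
      grown <- FALSE
      if (nb > 0) {
        i <- sample.int(nb, 1L)
        if (runif(1) < 0.5) {  # extend left, keeping a >= 1 volume gap
          o <- onsets[i]
          if (o > 1L && (o - 2L < 1L || train[o - 2L] == 0L)) {
            train[o - 1L] <- 1L; onsets[i] <- o - 1L; grown <- TRUE
          }
        } else {               # extend right
          f <- offsets[i]
          if (f < n_volumes && (f + 2L > n_volumes || train[f + 2L] == 0L)) {
            train[f + 1L] <- 1L; offsets[i] <- f + 1L; grown <- TRUE
          }
        }
      }
      if (!grown && guard %% 50L == 0L) {  # no room left: add a block
        len <- sample(seq(block_len_range[1], block_len_range[2]), 1L)
        start <- sample.int(n_volumes - len + 1L, 1L)
        span <- start:(start + len - 1L)
        pad <- max(1L, start - 1L):min(n_volumes, start + len)
        if (all(train[pad] == 0L)) {
          train[span] <- 1L
          onsets <- c(onsets, start)
          offsets <- c(offsets, start + len - 1L)
        }
      }
    }
  })
  ord <- order(onsets)
  list(train = train, onsets = onsets[ord], offsets = offsets[ord],
       duration_pct = 100 * sum(train) / n_volumes)
}

#' Simulate a BOLD session from an atlas and per-network activity trains
#'
#' Forward model: each voxel's time series is the weighted sum over networks
#' of the HRF-convolved activity train, plus iid Gaussian noise. A plausible
#' motion record (random-walk drift with occasional spikes) is attached.
#'
#' @param atlas a `network_atlas`.
#' @param trains n_networks x n_volumes 0/1 matrix of activity trains.
#' @param tr repetition time in seconds.
#' @param hrf HRF kernel vector; default `hrf_kernel(tr)`.
#' @param noise_sd Gaussian noise SD (BOLD units; network amplitude is 1).
#' @param seed RNG seed.
#' @param motion_spike_prob per-volume probability of a 1 mm motion spike.
#' @return object of class `bold_session`: list with 4-D array `bold`
#'   (x, y, z, t), logical `mask` array, `motion` data frame (tx, ty, tz,
#'   rx, ry, rz), `tr`, and `scrub_mask` (NULL until scrubbing).
#' @export
simulate_bold <- function(atlas, trains, tr = 2, hrf = hrf_kernel(tr),
                          noise_sd = 0.1, seed = 1,
                          motion_spike_prob = 0.02) {
  stopifnot(inherits(atlas, "network_atlas"))
  if (!is.matrix(trains) || nrow(trains) != atlas$n_networks) {
    stop("`trains` must be an n_networks x n_volumes matrix", call. = FALSE)
  }
  T <- ncol(trains)
  V <- prod(atlas$grid_shape)
  conv <- t(apply(trains, 1, convolve_causal, kernel = hrf))  # N x T
  signal <- atlas$maps %*% conv                               # V x T
  withr::with_seed(seed, {
    noise <- if (noise_sd > 0) {
      matrix(rnorm(V * T, sd = noise_sd), V, T)
    } else {
      matrix(0, V, T)
    }
    data <- signal + noise
    motion <- simulate_motion(T, spike_prob = motion_spike_prob)
  })
  bold <- array(data, dim = c(atlas$grid_shape, T))
  # the whole lattice is "brain": background voxels carry noise only, which
  # keeps the network maps linearly independent after mean-centring
  mask <- array(TRUE, dim = atlas$grid_shape)
  new_bold_session(bold, mask, motion, tr)
}

simulate_motion <- function(n_volumes, drift_sd = 0.02, spike_prob = 0.02,
                            spike_mm = 1) {
  steps <- matrix(rnorm(n_volumes * 6, sd = drift_sd), n_volumes, 6)
  steps[, 4:6] <- steps[, 4:6] / 50  # rotations in radians, ~same FD scale
  spikes <- runif(n_volumes) < spike_prob
  spikes[1] <- FALSE
  steps[spikes, 1] <- steps[spikes, 1] + spike_mm
  motion <- apply(steps, 2, cumsum)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  as.data.frame(motion)
}

#' Construct a BOLD session object
#'
#' @param bold 4-D numeric array (x, y, z, t).
#' @param mask logical 3-D array matching the spatial dimensions.
#' @param motion data frame with columns tx, ty, tz, rx, ry, rz.
#' @param tr repetition time in seconds.
#' @export
new_bold_session <- function(bold, mask, motion, tr) {
  stopifnot(length(dim(bold)) == 4L)
  if (!all(dim(bold)[1:3] == dim(mask))) {
    stop("mask dimensions do not match the session grid", call. = FALSE)
  }
  if (nrow(motion) != dim(bold)[4]) {
    stop("motion record length does not match the number of volumes", call. = FALSE)
  }
  structure(
    list(bold = bold, mask = mask, motion = motion, tr = tr,
         scrub_mask = NULL),
    class = "bold_session"
  )
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$bold)
  cat("<bold_session> grid", paste(d[1:3], collapse = "x"),
      "volumes", d[4], "tr", x$tr, "s\n")
  invisible(x)
}

# flatten masked voxels to a V x T matrix
session_matrix <- function(session, mask = session$mask) {
  d <- dim(session$bold)
  mat <- matrix(session$bold, nrow = prod(d[1:3]), ncol = d[4])
  mat[as.logical(mask), , drop = FALSE]
}

#' Simulate a paired-session cohort with planted brain-behaviour coupling
#'
#' For each subject two sessions are generated. Session 1 uses baseline
#' block activity at `rate`; in session 2 the networks in `effect_networks`
#' receive a per-subject duration increase `delta_s ~ N(delta_mean,
#' delta_sd)` percentage points (other networks are re-drawn at baseline).
#' Clinical change for the planted scores equals
#' `clinical_effect * mean(delta_s)` plus Gaussian noise, so recovered
#' duration change and clinical change are correlated by construction.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param atlas a `network_atlas`.
#' @param truth list of generator settings; see `default_truth()` for the
#'   fields and defaults.
#' @param seed RNG seed; all per-subject seeds derive from it.
#' @return list with `sessions` (list of subjects, each a list of two
#'   `bold_session`s), `clinical` (data frame: subject, score, before,
#'   after, gestational_age, age_months), and `truth` (per subject-session
#'   trains, planted durations, `delta_s`, seeds).
#' @export
simulate_cohort <- function(n_subjects, atlas, truth = default_truth(),
                            seed = 1) {
  if (n_subjects < 4) stop("`n_subjects` must be >= 4", call. = FALSE)
  stopifnot(inherits(atlas, "network_atlas"))
  truth <- utils::modifyList(default_truth(), truth)
  N <- atlas$n_networks
  T <- truth$n_volumes
  if (any(!truth$effect_networks %in% seq_len(N))) {
    stop("`effect_networks` must be a subset of 1..n_networks", call. = FALSE)
  }

  withr::with_seed(seed, {
    subj_seeds <- sample.int(2^30, n_subjects)
    delta_s <- rnorm(n_subjects, truth$delta_mean, truth$delta_sd)
    ga <- rnorm(n_subjects, 29, 2)
    age <- rnorm(n_subjects, 146, 14)
    clin_noise <- matrix(rnorm(n_subjects * truth$n_scores,
                               sd = truth$clinical_noise_sd),
                         n_subjects, truth$n_scores)
    baselines <- matrix(rnorm(n_subjects * truth$n_scores, mean = 50, sd = 10),
                        n_subjects, truth$n_scores)
  })

  sessions <- vector("list", n_subjects)
  truth_rec <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ss <- subj_seeds[s]
    trains1 <- matrix(0L, N, T)
    trains2 <- matrix(0L, N, T)
    dur1 <- dur2 <- numeric(N)
    for (k in seq_len(N)) {
      a1 <- simulate_block_activity(T, truth$rate, truth$block_len_range,
                                    seed = (ss + 7L * k) %% 2^30)
      trains1[k, ] <- a1$train
      dur1[k] <- a1$duration_pct
      if (k %in% truth$effect_networks) {
        a2 <- simulate_activity_target(T, a1$duration_pct + delta_s[s],
                                       truth$block_len_range,
                                       seed = (ss + 7L * k + 3L) %% 2^30,
                                       rate = truth$rate)
      } else {
        a2 <- simulate_block_activity(T, truth$rate, truth$block_len_range,
                                      seed = (ss + 7L * k + 3L) %% 2^30)
      }
      trains2[k, ] <- a2$train
      dur2[k] <- a2$duration_pct
    }
    sessions[[s]] <- list(
      before = simulate_bold(atlas, trains1, tr = truth$tr,
                             noise_sd = truth$noise_sd,
                             seed = (ss + 11L) %% 2^30,
                             motion_spike_prob = truth$motion_spike_prob),
      after = simulate_bold(atlas, trains2, tr = truth$tr,
                            noise_sd = truth$noise_sd,
                            seed = (ss + 13L) %% 2^30,
                            motion_spike_prob = truth$motion_spike_prob)
    )
    truth_rec[[s]] <- list(trains = list(before = trains1, after = trains2),
                           duration_pct = cbind(before = dur1, after = dur2),
                           delta = delta_s[s], seed = ss)
  }

  mean_delta <- vapply(truth_rec, function(tt) {
    mean(tt$duration_pct[truth$effect_networks, "after"] -
           tt$duration_pct[truth$effect_networks, "before"])
  }, numeric(1))

  score_names <- paste0("score", seq_len(truth$n_scores))
  clinical <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    change <- clin_noise[s, ]
    eff <- seq_len(truth$n_scores) %in% truth$effect_scores
    change[eff] <- change[eff] + truth$clinical_effect * mean_delta[s]
    data.frame(subject = sprintf("sub%02d", s),
               score = score_names,
               before = baselines[s, ],
               after = baselines[s, ] + change,
               gestational_age = ga[s],
               age_months = age[s],
               row.names = NULL)
  }))

  list(sessions = sessions, clinical = clinical,
       truth = list(per_subject = truth_rec, delta_s = delta_s,
                    planted_mean_delta = mean_delta, settings = truth,
                    seed = seed))
}

#' Default planted-truth settings for `simulate_cohort()`
#'
#' Baseline activity runs at 2 blocks per 100 volumes with block lengths of
#' 5-10 volumes (about 15% duty cycle, in the range reported for transient
#' network activations at rest); the first four networks gain 10 +/- 3
#' percentage points of duration after the intervention, and the first
#' three of five clinical scores change with that gain at unit coefficient
#' plus SD-1 noise.
#'
#' @return named list of generator settings.
#' @export
default_truth <- function() {
  list(
    n_volumes = 105L,
    tr = 2,
    rate = 2,
    block_len_range = c(5, 10),
    noise_sd = 0.1,
    motion_spike_prob = 0.02,
    effect_networks = 1:4,
    delta_mean = 10,
    delta_sd = 3,
    n_scores = 5L,
    effect_scores = 1:3,
    clinical_effect = 1,
    clinical_noise_sd = 1
  )
}
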
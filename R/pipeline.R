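#' Reliable change matrix for paired wide metric matrices
#'
#' Column-wise RCI across subjects. The SEM of the difference uses
#' [estimate_sem_d()] with `sd_baseline = sd(before column)` and, unless a
#' reliability is supplied, the pre/post Pearson correlation of that column
#' clamped to \[0, 0.95\] (a loud message reports the estimated values).
#' Columns with zero baseline variance cannot carry reliable change and are
#' dropped with a warning.
#'
#' @param before,after subjects x p matrices of the metric at each session.
#' @param reliability optional scalar or per-column reliability in \[0, 1).
#' @param quiet suppress the reliability message.
#' @return list with `rci` (subjects x kept columns), `sem_d`,
#'   `reliability`, `dropped` (names/indices of dropped columns).
#' @export
rci_matrix <- function(before, after, reliability = NULL, quiet = FALSE) {
  before <- as.matrix(before); after <- as.matrix(after)
  stopifnot(all(dim(before) == dim(after)))
  sdb <- apply(before, 2, sd)
  keep <- sdb > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped from RCI",
            call. = FALSE)
  }
  b <- before[, keep, drop = FALSE]; a <- after[, keep, drop = FALSE]
  sdb <- sdb[keep]
  if (is.null(reliability)) {
    r <- vapply(seq_len(ncol(b)), function(j) cor(b[, j], a[, j]), numeric(1))
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, 0), 0.95)
    if (!quiet) {
      message("rci_matrix: reliability estimated from pre/post correlation ",
              "(clamped to [0, 0.95]): ",
              paste(sprintf("%.2f", r), collapse = " "))
    }
  } else {
    r <- rep_len(reliability, ncol(b))
  }
  sem <- estimate_sem_d(sdb, r)
  rci <- sweep(a - b, 2, sem, "/")
  colnames(rci) <- colnames(b)
  list(rci = rci, sem_d = sem, reliability = r,
       dropped = which(!keep))
}

# wide subjects x metric matrix from tidy per-session metric tables
metrics_wide <- function(tidy, metric, session) {
  sub <- tidy[tidy$metric == metric & tidy$session == session, ]
  subjects <- sort(unique(sub$subject))
  key <- if (all(is.na(sub$icap_j))) {
    sprintf("icap%d", sub$icap_i)
  } else {
    sprintf("icap%d_%d", sub$icap_i, sub$icap_j)
  }
  cols <- unique(key)
  out <- matrix(NA_real_, length(subjects), length(cols),
                dimnames = list(subjects, cols))
  out[cbind(match(sub$subject, subjects), match(key, cols))] <- sub$value
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains the stages: simulate a paired-session cohort, scrub, deconvolve
#' every session, select transient frames, cluster them into iCAPs (fixed
#' `K` or consensus selection over `K_range`), recover per-session time
#' courses and temporal metrics, form reliable-change matrices, and run the
#' four PLSC analyses (clinical X against duration, occurrence, coupling,
#' and anticoupling Y). All randomness derives from `config$seed`.
#'
#' @param config an `icapr_config` from [default_config()] /
#'   [load_config()].
#' @param out_dir optional artifact directory; when given, metrics,
#'   loadings, PLSC summaries, the config and a hash manifest are written.
#' @param bootstrap which PLSC analyses to bootstrap (default "duration").
#' @return list with `atlas`, `cohort` (truth and clinical), `icaps`,
#'   `consensus` (NULL for fixed K), `metrics` (tidy table), `X`, `Y`
#'   (list of four matrices), `plsc` (per analysis: fit, `p`, boot),
#'   `match` (iCAP-to-planted-network assignment), `recovery` (per-network
#'   correlation of recovered and planted durations), and `paths`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         bootstrap = "duration") {
  validate_config(config)
  seed <- as.integer(config$seed) %% 2^30

  atlas <- make_network_atlas(config$n_networks, config$grid_shape,
                              config$overlap_frac, seed = seed + 1L)
  cohort <- simulate_cohort(config$n_subjects, atlas, config$truth,
                            seed = seed + 2L)

  innovation_sets <- list()
  scrubbed <- list()
  for (s in seq_len(config$n_subjects)) {
    for (ses in c("before", "after")) {
      sess <- scrub(cohort$sessions[[s]][[ses]],
                    fd_thresh = config$fd_thresh,
                    drop_initial = config$drop_initial,
                    head_radius = config$head_radius)
      iset <- deconvolve_session(sess,
                                 lambda_factor = config$lambda_factor,
                                 max_iter = config$deconv_max_iter,
                                 tol = config$deconv_tol,
                                 subject = sprintf("sub%02d", s),
                                 session_id = ses)
      key <- sprintf("sub%02d_%s", s, ses)
      innovation_sets[[key]] <- iset
      scrubbed[[key]] <- sess
    }
  }

  frames <- select_transients(innovation_sets,
                              percentile = config$transient_percentile)
  if (nrow(frames$frames) < 2 * max(config$K, config$K_range)) {
    stop("too few transient frames for clustering", call. = FALSE)
  }

  consensus <- NULL
  if (!is.null(config$K_range)) {
    consensus <- consensus_select_K(frames, K_range = config$K_range,
                                    n_resamples = config$consensus_resamples,
                                    subsample_frac = config$subsample_frac,
                                    seed = seed + 3L)
    K <- consensus$selected_K
  } else {
    K <- config$K
  }
  km <- kmeans_transients(frames, K, n_replicates = config$kmeans_replicates,
                          seed = seed + 4L)
  icaps <- build_zmaps(frames, km$labels)

  metrics <- list()
  for (key in names(innovation_sets)) {
    iset <- innovation_sets[[key]]
    tc <- transient_informed_regression(icaps$zmaps, iset$activity,
                                        scrub_mask = iset$scrub_mask)
    blocks <- binarize_blocks(tc, z_thresh = config$z_thresh)
    metrics[[key]] <- temporal_metrics(blocks, subject = iset$subject,
                                       session = iset$session_id)
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  # clinical X: per-score RCI + gestational age + age at assessment
  clin <- cohort$clinical
  scores <- unique(clin$score)
  bmat <- sapply(scores, function(sc) clin$before[clin$score == sc])
  amat <- sapply(scores, function(sc) clin$after[clin$score == sc])
  clin_rci <- rci_matrix(bmat, amat, reliability = config$rci_reliability,
                         quiet = TRUE)
  subj_rows <- !duplicated(clin$subject)
  X <- cbind(clin_rci$rci,
             gestational_age = clin$gestational_age[subj_rows],
             age_months = clin$age_months[subj_rows])

  # brain Y blocks: RCI of each temporal property
  Y <- list()
  rci_info <- list()
  for (metric in c("duration", "occurrences", "coupling", "anticoupling")) {
    b <- metrics_wide(metrics, metric, "before")
    a <- metrics_wide(metrics, metric, "after")
    ri <- rci_matrix(b, a, reliability = config$rci_reliability, quiet = TRUE)
    Y[[metric]] <- ri$rci
    rci_info[[metric]] <- ri
  }

  plsc <- list()
  for (metric in names(Y)) {
    fit <- plsc_fit(X, Y[[metric]])
    p <- plsc_permute(X, Y[[metric]], n_perm = config$n_perm,
                      seed = seed + 5L)
    boot <- NULL
    if (metric %in% bootstrap) {
      boot <- plsc_bootstrap(X, Y[[metric]], n_boot = config$n_boot,
                             seed = seed + 6L, robust_z = config$robust_z,
                             n_lc = 1)
    }
    plsc[[metric]] <- list(fit = fit, p = p, boot = boot)
  }

  match <- match_icaps_to_atlas(icaps, atlas, mask = innovation_sets[[1]]$mask)
  recovery <- duration_recovery(metrics, cohort, scrubbed, match, config)

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_artifacts(out_dir, config, metrics, plsc, consensus)
  }

  list(atlas = atlas, cohort = cohort[c("clinical", "truth")],
       icaps = icaps, consensus = consensus, metrics = metrics,
       X = X, Y = Y, plsc = plsc, match = match, recovery = recovery,
       frames = frames, paths = paths)
}

# correlation between recovered and planted durations, per planted network,
# on the post-scrub analysis window
duration_recovery <- function(metrics, cohort, scrubbed, match, config) {
  n_networks <- nrow(cohort$truth$per_subject[[1]]$duration_pct)
  drop <- config$drop_initial
  rec <- list()
  for (ses in c("before", "after")) {
    wide <- metrics_wide(metrics, "duration", ses)
    planted <- matrix(NA_real_, nrow(wide), n_networks)
    for (s in seq_len(nrow(wide))) {
      key <- sprintf("sub%02d_%s", s, ses)
      sm <- scrubbed[[key]]$scrub_mask
      trains <- cohort$truth$per_subject[[s]]$trains[[ses]]
      T <- ncol(trains)
      win <- trains[, (drop + 1):T, drop = FALSE]
      planted[s, ] <- 100 * rowSums(win[, sm, drop = FALSE] != 0) / sum(sm)
    }
    rec[[ses]] <- list(recovered = wide, planted = planted)
  }
  recovered <- rbind(rec$before$recovered, rec$after$recovered)
  planted <- rbind(rec$before$planted, rec$after$planted)
  r <- rep(NA_real_, n_networks)
  for (row in seq_len(nrow(match))) {
    k <- match$network[row]
    icap_col <- paste0("icap", match$icap[row])
    if (icap_col %in% colnames(recovered)) {
      r[k] <- cor(recovered[, icap_col], planted[, k])
    }
  }
  list(per_network_cor = r, recovered = recovered, planted = planted)
}

write_artifacts <- function(out_dir, config, metrics, plsc, consensus) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "metrics.csv")
  write.csv(metrics, p, row.names = FALSE)
  paths <- c(paths, metrics = p)

  summ <- lapply(plsc, function(a) {
    list(singular = a$fit$singular, p = a$p)
  })
  p <- file.path(out_dir, "plsc_summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, plsc = p)

  for (metric in names(plsc)) {
    if (!is.null(plsc[[metric]]$boot)) {
      p <- file.path(out_dir, paste0("loadings_", metric, ".csv"))
      write.csv(plsc_loading_table(plsc[[metric]]$boot), p, row.names = FALSE)
      paths <- c(paths, setNames(p, paste0("loadings_", metric)))
    }
  }
  if (!is.null(consensus)) {
    p <- file.path(out_dir, "consensus.csv")
    write.csv(data.frame(K = consensus$K_range,
                         mean_consensus = consensus$mean_consensus),
              p, row.names = FALSE)
    paths <- c(paths, consensus = p)
  }
  p <- file.path(out_dir, "config.yaml")
  save_config(config, p)
  paths <- c(paths, config = p)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    files = as.list(tools::md5sum(unname(paths)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  c(paths, manifest = mp)
}
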
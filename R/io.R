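#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum(|delta translations|) + head_radius * sum(|delta rotations|)`
#' with `FD_1 = 0`; rotations (radians) are converted to millimetres of arc
#' on a sphere of `head_radius`.
#'
#' @param motion matrix or data frame with 6 columns
#'   (tx, ty, tz in mm; rx, ry, rz in radians) and >= 2 rows.
#' @param head_radius sphere radius in mm (default 50).
#' @return list with `fd` (per-volume series, first entry 0) and `mean_fd`
#'   (mean over volumes 2..T).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop("motion must have 6 columns (tx,ty,tz,rx,ry,rz)",
                         call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Drop initial volumes and mask high-motion volumes
#'
#' Removes the first `drop_initial` volumes (dummy scans), recomputes FD on
#' the remaining motion record, and marks volumes with `FD > fd_thresh` as
#' scrubbed. Scrubbed volumes are masked, not deleted, so trains keep their
#' time axis; zero gaps introduced by scrubbing do split activation blocks.
#'
#' @param session a `bold_session`.
#' @param fd_thresh FD scrub threshold in mm (default 0.5).
#' @param drop_initial number of initial volumes to drop (default 5).
#' @param head_radius passed to [framewise_displacement()].
#' @return the session with volumes dropped, `scrub_mask` (TRUE = usable)
#'   and `fd` attached.
#' @export
scrub <- function(session, fd_thresh = 0.5, drop_initial = 5,
                  head_radius = 50) {
  stopifnot(inherits(session, "bold_session"))
  if (fd_thresh <= 0) stop("`fd_thresh` must be > 0", call. = FALSE)
  T <- dim(session$bold)[4]
  if (T <= drop_initial + 1) {
    stop("fewer volumes than `drop_initial`", call. = FALSE)
  }
  keep <- (drop_initial + 1):T
  session$bold <- session$bold[, , , keep, drop = FALSE]
  session$motion <- session$motion[keep, , drop = FALSE]
  fd <- framewise_displacement(session$motion, head_radius)
  session$fd <- fd$fd
  session$mean_fd <- fd$mean_fd
  session$scrub_mask <- fd$fd <= fd_thresh
  session
}

#' Write a BOLD session to disk
#'
#' BOLD and mask as NIfTI-1 (identity-scaled affine), motion as TSV with
#' columns `tx,ty,tz,rx,ry,rz`.
#'
#' @param session a `bold_session`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_bold_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bold_path <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  motion_path <- file.path(dir, paste0(prefix, "_motion.tsv"))
  img <- RNifti::asNifti(session$bold)
  RNifti::pixdim(img) <- c(1, 1, 1, session$tr)
  RNifti::writeNifti(img, bold_path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(session$mask),
                                           dim = dim(session$mask))),
                     mask_path)
  write.table(session$motion, motion_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(bold = bold_path, mask = mask_path, motion = motion_path))
}

#' Read a BOLD session written by [write_bold_session()]
#'
#' @param dir directory holding the files.
#' @param prefix file name prefix used at write time.
#' @param tr repetition time in seconds (default: from the NIfTI header).
#' @return a `bold_session`.
#' @export
read_bold_session <- function(dir, prefix = "session", tr = NULL) {
  bold <- RNifti::readNifti(file.path(dir, paste0(prefix, "_bold.nii.gz")))
  mask <- RNifti::readNifti(file.path(dir, paste0(prefix, "_mask.nii.gz")))
  motion <- read.delim(file.path(dir, paste0(prefix, "_motion.tsv")))
  if (is.null(tr)) {
    pd <- RNifti::pixdim(bold)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  new_bold_session(array(as.numeric(bold), dim = dim(bold)),
                   array(as.numeric(mask) > 0, dim = dim(mask)),
                   motion, tr)
}

#' Default pipeline configuration
#'
#' Every stochastic stage carries an explicit seed derived from
#' `seed`. Values mirror the package defaults documented on each stage.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return named list (class `icapr_config`).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    n_subjects = 16L,
    grid_shape = c(8L, 8L, 8L),
    n_networks = 8L,
    overlap_frac = 0,
    truth = default_truth(),
    drop_initial = 5L,
    fd_thresh = 0.5,
    head_radius = 50,
    lambda_factor = 1,
    deconv_max_iter = 300L,
    deconv_tol = 1e-5,
    transient_percentile = 95,
    K = 8L,
    K_range = NULL,            # set to e.g. 5:15 to select K by consensus
    consensus_resamples = 30L,
    subsample_frac = 0.8,
    kmeans_replicates = 50L,
    z_thresh = 1,
    rci_reliability = NULL,    # NULL: estimate from the pre/post correlation
    n_perm = 1000L,
    n_boot = 500L,
    robust_z = 2
  ), class = "icapr_config")
}

#' Validate a pipeline configuration
#'
#' @param config list as from [default_config()].
#' @return the config, invisibly; errors on missing seed or invalid fields.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    stop("config must carry an explicit `seed`", call. = FALSE)
  }
  if (is.null(config$K) && is.null(config$K_range)) {
    stop("config must set `K` or `K_range`", call. = FALSE)
  }
  stopifnot(config$n_subjects >= 4, config$fd_thresh > 0,
            config$drop_initial >= 0, config$n_perm >= 100,
            config$n_boot >= 100)
  invisible(config)
}

#' Load / save a configuration as YAML
#'
#' @param path YAML file path.
#' @return `load_config`: the validated config; `save_config`: the path.
#' @export
load_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  # modifyList drops NULL-valued fields; restore the optional ones
  for (field in c("K_range", "rci_reliability")) {
    if (!field %in% names(cfg)) cfg[field] <- list(NULL)
  }
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  validate_config(structure(cfg, class = "icapr_config"))
  structure(cfg, class = "icapr_config")
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
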
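#' Partial least-squares correlation of two data blocks
#'
#' Columns of X (clinical) and Y (brain) are z-scored; the cross-correlation
#' matrix `R = t(Xz) %*% Yz / (n - 1)` is decomposed by SVD, `R = U S V'`.
#' Columns of U/V are the clinical/brain saliences of the latent components
#' (LCs); subject scores are `Xz U` and `Yz V`.
#'
#' @param X subjects x p numeric matrix (no missing values).
#' @param Y subjects x q numeric matrix (same rows).
#' @return object of class `plsc_fit`: `singular` (descending), `u`, `v`,
#'   `x_scores`, `y_scores`, `Xz`, `Yz`, column names, `n`.
#' @export
plsc_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts", call. = FALSE)
  if (nrow(X) < 4) stop("need at least 4 subjects", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("missing entries are not allowed", call. = FALSE)
  check_variance <- function(M, side) {
    v <- apply(M, 2, var)
    if (any(v == 0)) {
      bad <- colnames(M)[v == 0]
      if (is.null(bad)) bad <- which(v == 0)
      stop("zero-variance ", side, " column: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_variance(X, "X"); check_variance(Y, "Y")
  Xz <- scale(X); Yz <- scale(Y)
  n <- nrow(X)
  R <- crossprod(Xz, Yz) / (n - 1)
  sv <- svd(R)
  structure(
    list(singular = sv$d, u = sv$u, v = sv$v,
         x_scores = Xz %*% sv$u, y_scores = Yz %*% sv$v,
         Xz = Xz, Yz = Yz, n = n,
         x_names = colnames(X), y_names = colnames(Y)),
    class = "plsc_fit"
  )
}

#' @export
print.plsc_fit <- function(x, ...) {
  cat("<plsc_fit>", x$n, "subjects;", length(x$singular),
      "latent components; singular values:",
      paste(signif(head(x$singular, 5), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation p-values for PLSC latent components
#'
#' Rows of X are permuted relative to Y; for each LC rank k,
#' `p_k = (1 + #{permuted singular_k >= observed singular_k}) / (n_perm + 1)`.
#'
#' @param X,Y data blocks as in [plsc_fit()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return numeric vector of p-values, one per LC.
#' @export
plsc_permute <- function(X, Y, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  fit <- plsc_fit(X, Y)
  n <- fit$n
  r <- length(fit$singular)
  exceed <- integer(r)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Rp <- crossprod(fit$Xz[idx, , drop = FALSE], fit$Yz) / (n - 1)
      sp <- svd(Rp, nu = 0, nv = 0)$d
      exceed <- exceed + (sp >= fit$singular)
    }
  })
  (1 + exceed) / (n_perm + 1)
}

#' Bootstrap stability of PLSC loadings
#'
#' Subjects are resampled with replacement; each bootstrap refits the PLSC,
#' sign-aligns every LC to the original via the salience dot products, and
#' records the loading of each variable (Pearson correlation of the
#' variable with the LC subject score on the opposite block's side of the
#' decomposition: X variables with `Xz u`, Y variables with `Yz v`).
#' A loading is flagged robust when `|mean| / SD >= robust_z`. Resamples in
#' which some column becomes constant are redrawn (counted).
#'
#' @param X,Y data blocks as in [plsc_fit()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param robust_z bootstrap-ratio threshold for robustness (default 2).
#' @param n_lc number of LCs to summarise (default all).
#' @return object of class `plsc_bootstrap`: lists `x` and `y`, each with
#'   `mean`, `sd`, `ratio`, `robust` (variables x LCs), plus `n_redrawn`.
#' @export
plsc_bootstrap <- function(X, Y, n_boot = 500, seed = 1, robust_z = 2,
                           n_lc = NULL) {
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  fit <- plsc_fit(X, Y)
  n <- fit$n
  r <- length(fit$singular)
  if (is.null(n_lc)) n_lc <- r
  n_lc <- min(n_lc, r)
  p <- ncol(X); q <- ncol(Y)
  lx <- array(NA_real_, c(p, n_lc, n_boot))
  ly <- array(NA_real_, c(q, n_lc, n_boot))
  n_redrawn <- 0L
  withr::with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      if (any(apply(Xb, 2, var) == 0) || any(apply(Yb, 2, var) == 0)) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      fb <- plsc_fit(Xb, Yb)
      for (k in seq_len(n_lc)) {
        s <- sign(sum(fb$u[, k] * fit$u[, k]) + sum(fb$v[, k] * fit$v[, k]))
        if (s == 0) s <- 1
        lx[, k, b] <- suppressWarnings(cor(Xb, s * fb$x_scores[, k]))
        ly[, k, b] <- suppressWarnings(cor(Yb, s * fb$y_scores[, k]))
      }
      b <- b + 1L
    }
  })
  summarise <- function(arr, names) {
    m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    s <- apply(arr, c(1, 2), sd, na.rm = TRUE)
    ratio <- ifelse(s > 0, abs(m) / s, Inf)
    rownames(m) <- rownames(s) <- rownames(ratio) <- names
    list(mean = m, sd = s, ratio = ratio, robust = ratio >= robust_z)
  }
  structure(
    list(x = summarise(lx, fit$x_names), y = summarise(ly, fit$y_names),
         n_redrawn = n_redrawn, robust_z = robust_z),
    class = "plsc_bootstrap"
  )
}

#' Tidy loading table from a PLSC bootstrap
#'
#' @param boot a `plsc_bootstrap`.
#' @param n_lc number of LCs to include (default all summarised).
#' @return data frame `lc,side,variable,boot_mean,boot_sd,robust`.
#' @export
plsc_loading_table <- function(boot, n_lc = NULL) {
  stopifnot(inherits(boot, "plsc_bootstrap"))
  if (is.null(n_lc)) n_lc <- ncol(boot$x$mean)
  rows <- list()
  for (side in c("x", "y")) {
    s <- boot[[side]]
    vars <- rownames(s$mean)
    if (is.null(vars)) vars <- paste0(side, seq_len(nrow(s$mean)))
    for (k in seq_len(n_lc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lc = k, side = side, variable = vars,
        boot_mean = s$mean[, k], boot_sd = s$sd[, k],
        robust = s$robust[, k], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
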
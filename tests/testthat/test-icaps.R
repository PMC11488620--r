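make_iset <- function(innovations, subject = "s1", session = "ses1",
                      scrub_mask = NULL) {
  structure(list(innovations = innovations,
                 activity = innovations,  # unused by selection
                 subject = subject, session_id = session,
                 scrub_mask = scrub_mask),
            class = "innovation_set")
}

test_that("transient selection keeps planted edge volumes and handles extremes", {
  z <- make_iset(matrix(0, 20, 30))
  expect_warning(empty <- select_transients(z, percentile = 95), "no transient")
  expect_identical(nrow(empty$frames), 0L)

  ph <- make_phantom(seed = 9, noise_sd = 0.02)
  iset <- deconvolve_session(ph$session)
  sel <- select_transients(iset, percentile = 95)
  edges <- sort(unique(unlist(ph$edges)))
  edges <- edges[edges > 1 & edges <= ncol(iset$innovations)]
  for (e in edges) {
    expect_true(min(abs(sel$provenance$volume - e)) <= 1)
  }

  weak <- make_iset(matrix(rnorm(600, sd = 1e-4), 20, 30))
  expect_warning(
    sel2 <- select_transients(weak, percentile = 99.9,
                              min_active_voxels = 10),
    "no transient")
  expect_identical(nrow(sel2$frames), 0L)

  expect_error(select_transients(iset, percentile = 40), "percentile")
})

test_that("sign-invariant k-means recovers planted patterns", {
  pf <- make_planted_frames(n_per = 12, n_patterns = 3, seed = 2)
  km <- kmeans_transients(pf$frames, 3, seed = 4)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(abs(km$labels), pf$labels)
  expect_gte(ari, 0.9)

  one <- kmeans_transients(pf$frames, 1, seed = 1)
  expect_true(all(abs(one$labels) == 1))
  aligned <- pf$frames / sqrt(rowSums(pf$frames^2)) * sign(one$labels)
  m <- colSums(aligned)
  expect_gt(abs(cor(as.numeric(one$centroids), m)), 0.999)

  expect_error(kmeans_transients(pf$frames[1:2, ], 3), "at least K")
})

test_that("k-means equals the exhaustive best 2-partition on 6 frames", {
  withr::with_seed(11, {
    F <- rbind(matrix(rnorm(3 * 10, mean = 2), 3, 10),
               matrix(rnorm(3 * 10, mean = -1, sd = 2), 3, 10))
  })
  km <- kmeans_transients(F, 2, n_replicates = 50, seed = 3)

  Fn <- F / sqrt(rowSums(F^2))
  part_obj <- function(lab, signs) {
    tot <- 0
    for (k in 1:2) {
      idx <- which(lab == k)
      if (length(idx) == 0) return(Inf)
      ck <- colSums(Fn[idx, , drop = FALSE] * signs[idx])
      nk <- sqrt(sum(ck^2))
      if (nk == 0) return(Inf)
      tot <- tot + sum(1 - abs((Fn[idx, , drop = FALSE] %*% ck) / nk))
    }
    tot
  }
  best <- Inf
  for (code in 0:(2^6 - 1)) {
    lab <- as.integer(intToBits(code))[1:6] + 1L
    if (length(unique(lab)) < 2) next
    for (scode in 0:(2^6 - 1)) {
      signs <- ifelse(as.integer(intToBits(scode))[1:6] == 1, 1, -1)
      best <- min(best, part_obj(lab, signs))
    }
  }
  expect_equal(km$objective, best, tolerance = 1e-8)
})

test_that("clustering is invariant to flipping input frames", {
  pf <- make_planted_frames(n_per = 8, n_patterns = 2, seed = 6)
  km1 <- kmeans_transients(pf$frames, 2, seed = 9)
  flipped <- pf$frames
  flipped[3, ] <- -flipped[3, ]
  km2 <- kmeans_transients(flipped, 2, seed = 9)
  expect_identical(abs(km1$labels), abs(km2$labels))
  expect_identical(km1$labels[3], -km2$labels[3])
  expect_equal(km1$objective, km2$objective, tolerance = 1e-12)
})

test_that("consensus clustering finds the planted K and is well-formed", {
  pf <- make_planted_frames(n_per = 10, n_patterns = 2, nvox = 40, seed = 3)
  cons <- consensus_select_K(pf$frames, K_range = 2:5, n_resamples = 20,
                             seed = 8)
  expect_identical(cons$selected_K, 2L)
  for (K in names(cons$consensus)) {
    M <- cons$consensus[[K]]
    expect_true(isSymmetric(unname(M)))
    expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))
    expect_true(all(diag(M)[!is.na(diag(M))] == 1))
  }

  single <- consensus_select_K(pf$frames, K_range = 2:3, n_resamples = 1,
                               subsample_frac = 1.0, seed = 1)
  vals <- unique(as.numeric(single$consensus[["2"]]))
  expect_true(all(vals %in% c(0, 1)))

  expect_error(consensus_select_K(pf$frames, K_range = 2:40), "K_range")
})

test_that("z-maps recover planted networks and report covered regions", {
  f <- matrix(rep(c(1, 1, 0, 0, 0, 0), 4), 4, 6, byrow = TRUE)
  f[3:4, ] <- -f[3:4, ]  # offset transients: sign-flipped copies
  z <- build_zmaps(f, labels = c(1L, 1L, -1L, -1L))
  expect_equal(nrow(z$zmaps), 1)
  expect_equal(as.numeric(z$zmaps[1, ]),
               as.numeric(scale(abs(f[1, ]))), tolerance = 1e-10)

  ph <- make_phantom(seed = 12, noise_sd = 0.02)
  iset <- deconvolve_session(ph$session)
  sel <- select_transients(iset, percentile = 95)
  km <- kmeans_transients(sel, 2, seed = 2)
  icaps <- build_zmaps(sel, km$labels)
  W <- ph$atlas$maps[as.logical(ph$session$mask), ]
  dice_best <- numeric(2)
  for (k in 1:2) {
    hit <- abs(icaps$zmaps[k, ]) > 2
    dice <- vapply(1:2, function(j) {
      truth <- W[, j] > 0
      2 * sum(hit & truth) / (sum(hit) + sum(truth))
    }, numeric(1))
    dice_best[k] <- max(dice)
  }
  expect_true(all(dice_best > 0.7))

  # a region fully inside planted network 1 must be listed
  region <- integer(nrow(W))
  region[which(W[, 1] > 0)[1:5]] <- 1L
  rep1 <- build_zmaps(sel, km$labels, atlas_labels = region)
  expect_true(any(rep1$region_report$region == 1 &
                    rep1$region_report$coverage > 0.2))
})
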
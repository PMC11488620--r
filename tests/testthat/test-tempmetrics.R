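test_that("transient-informed regression is exact on its own maps", {
  withr::with_seed(21, {
    V <- 120; K <- 4; T <- 30
    W <- matrix(0, V, K)
    for (k in 1:K) W[((k - 1) * 25 + 1):(k * 25), k] <- 1
    zm <- t(scale(W))
    S <- matrix(rbinom(K * T, 1, 0.3), K, T)
  })
  A <- W %*% S
  tc <- transient_informed_regression(zm, A)
  sds <- apply(W, 2, sd)
  expect_equal(tc$raw, diag(sds) %*% S, tolerance = 1e-10)

  # pure multiple of one map
  A1 <- matrix(3 * zm[1, ], ncol = 1)
  tc1 <- transient_informed_regression(zm, A1)
  expect_equal(as.numeric(tc1$raw), c(3, 0, 0, 0), tolerance = 1e-8)

  # orthogonal mean-centred maps: coefficients are projections
  withr::with_seed(3, Q <- qr.Q(qr(matrix(rnorm(60 * 3), 60))))
  Qc <- scale(Q, center = TRUE, scale = FALSE)
  act <- Qc %*% matrix(c(2, -1, 0.5), 3, 5) # constant-in-time mixture
  tcq <- transient_informed_regression(t(Qc), act)
  proj <- solve(crossprod(Qc), crossprod(Qc, act))
  expect_equal(tcq$raw, proj, tolerance = 1e-10)

  expect_error(transient_informed_regression(rbind(zm, zm[1, ]), A),
               "collinear")
})

test_that("binarisation follows the threshold, sign and scrub rules", {
  expect_identical(binarize_blocks(rep(0, 6), z_thresh = 1),
                   structure(rep(0L, 6), scrub_mask = rep(TRUE, 6)),
                   ignore_attr = TRUE)
  course <- c(0, 2, 2, 0, -2, 0)
  tr <- binarize_blocks(course, z_thresh = 1)
  expect_identical(as.integer(tr), c(0L, 1L, 1L, 0L, -1L, 0L))
  expect_identical(occurrences(tr), 2L)

  sm <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  tr2 <- binarize_blocks(course, z_thresh = 1, scrub_mask = sm)
  expect_identical(as.integer(tr2), c(0L, 1L, 0L, 0L, -1L, 0L))
  expect_equal(total_duration(tr2, sm), 100 * 2 / 5)

  expect_error(binarize_blocks(course, z_thresh = 0), "> 0")
})

test_that("duration and occurrences match brute-force recounts", {
  tr <- c(0, 1, 1, 0, -1, 0)
  expect_equal(total_duration(tr), 50)
  expect_equal(total_duration(rep(0, 10)), 0)
  expect_identical(occurrences(tr), 2L)
  expect_identical(occurrences(c(1, -1, 1)), 3L)

  withr::with_seed(5, {
    for (i in 1:200) {
      train <- sample(c(-1L, 0L, 1L), 30, replace = TRUE,
                      prob = c(0.2, 0.6, 0.2))
      scrubm <- runif(30) > 0.1
      masked <- train
      masked[!scrubm] <- 0L
      expect_identical(occurrences(masked), count_blocks_oracle(masked))
      expect_equal(total_duration(masked, scrubm),
                   100 * sum(masked[scrubm] != 0) / sum(scrubm))
      # joint permutation of time and scrub mask leaves duration unchanged
      perm <- sample(30)
      expect_equal(total_duration(masked[perm], scrubm[perm]),
                   total_duration(masked, scrubm))
    }
  })
  expect_error(total_duration(tr, rep(FALSE, 6)), "scrubbed")
})

test_that("Jaccard coupling/anticoupling match hand counts and bounds", {
  expect_equal(coupling_jaccard(c(1, 1, 0, -1), c(1, 1, 0, -1)),
               c(coupling = 1, anticoupling = 0))
  expect_equal(coupling_jaccard(c(1, 1, 0, 0), c(-1, -1, 0, 0)),
               c(coupling = 0, anticoupling = 1))
  expect_equal(coupling_jaccard(c(1, 0, 1, -1), c(1, 1, 0, -1)),
               c(coupling = 0.5, anticoupling = 0))
  expect_equal(coupling_jaccard(rep(0, 4), rep(0, 4)),
               c(coupling = 0, anticoupling = 0))

  withr::with_seed(6, {
    for (i in 1:100) {
      a <- sample(c(-1L, 0L, 1L), 25, replace = TRUE)
      b <- sample(c(-1L, 0L, 1L), 25, replace = TRUE)
      cj <- coupling_jaccard(a, b)
      expect_lte(cj["coupling"] + cj["anticoupling"], 1)
      expect_identical(cj, coupling_jaccard(b, a))
      un <- sum(a != 0 | b != 0)
      same <- sum(a != 0 & a == b)
      expect_equal(unname(cj["coupling"]), if (un == 0) 0 else same / un)
    }
  })
  expect_error(coupling_jaccard(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("static correlations are Pearson over usable volumes", {
  withr::with_seed(9, B <- matrix(rnorm(4 * 30), 4, 30))
  B[2, ] <- B[1, ]
  expect_warning(R <- static_correlation(rbind(B, 0)), "zero-variance")
  expect_equal(R[1, 2], 1)
  expect_true(is.na(R[1, 5]))

  sm <- rep(c(TRUE, FALSE), 15)
  R2 <- static_correlation(B, scrub_mask = sm)
  manual <- cor(t(B[, sm]))
  expect_equal(R2, manual, tolerance = 1e-12)
  expect_true(isSymmetric(R2))
  expect_equal(diag(R2), rep(1, 4))
  expect_error(static_correlation(B[, 1:2]), "3 usable")
})

test_that("the pairwise feature space has choose(K, 2) columns for K = 8", {
  withr::with_seed(10, blocks <- matrix(sample(c(-1L, 0L, 1L), 8 * 40,
                                               replace = TRUE), 8, 40))
  tm <- temporal_metrics(blocks, subject = "s", session = "ses1")
  expect_identical(sum(tm$metric == "coupling"), 28L)
  expect_identical(sum(tm$metric == "anticoupling"), 28L)
  expect_identical(sum(tm$metric == "duration"), 8L)
  expect_identical(sum(tm$metric == "occurrences"), 8L)
  # upper-triangle ordering, i < j
  pairs <- tm[tm$metric == "coupling", c("icap_i", "icap_j")]
  expect_true(all(pairs$icap_i < pairs$icap_j))
})

test_that("recovered durations track planted durations across the duty range", {
  # sessions spanning the realistic duty-cycle range (roughly 8-40%);
  # deconvolve, back-project on the true maps, threshold, and compare the
  # measured duration with the planted one
  atlas <- make_network_atlas(4, c(6, 6, 5), 0, seed = 71, coverage = 0.4)
  rates <- rep(c(1, 2, 3, 4), each = 4)
  planted <- matrix(NA_real_, length(rates), 4)
  recovered <- matrix(NA_real_, length(rates), 4)
  W <- atlas$maps
  zm <- t(scale(W))
  for (i in seq_along(rates)) {
    trains <- do.call(rbind, lapply(1:4, function(k) {
      simulate_block_activity(100, rates[i], c(5, 10),
                              seed = 700 + 10 * i + k)$train
    }))
    sess <- simulate_bold(atlas, trains, noise_sd = 0.1, seed = 800 + i,
                          motion_spike_prob = 0)
    iset <- deconvolve_session(sess)
    tc <- transient_informed_regression(zm, iset$activity)
    blocks <- binarize_blocks(tc, z_thresh = 1)
    recovered[i, ] <- total_duration(blocks)
    planted[i, ] <- 100 * rowMeans(trains != 0)
  }
  for (k in 1:4) {
    expect_gt(cor(recovered[, k], planted[, k]), 0.9)
  }
})
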
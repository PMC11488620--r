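test_that("atlas blobs are contiguous, non-empty and respect the overlap cap", {
  a0 <- make_network_atlas(2, c(6, 6, 6), overlap_frac = 0, seed = 1)
  expect_equal(a0$n_networks, 2)
  expect_true(all(colSums(a0$maps > 0) >= 1))
  expect_identical(sum(a0$maps[, 1] > 0 & a0$maps[, 2] > 0), 0L)

  a <- make_network_atlas(8, c(12, 12, 12), overlap_frac = 0.1, seed = 7)
  sets <- lapply(seq_len(8), function(k) which(a$maps[, k] > 0))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      frac <- shared / min(length(sets[[i]]), length(sets[[j]]))
      expect_lte(frac, 0.1)
    }
  }
  # contiguity: each blob is one 6-connected component
  for (k in 1:8) {
    vox <- sets[[k]]
    seen <- vox[1]
    frontier <- vox[1]
    while (length(frontier) > 0) {
      nb <- unique(unlist(lapply(frontier, icapr:::neighbours6, a$grid_shape)))
      frontier <- setdiff(intersect(nb, vox), seen)
      seen <- c(seen, frontier)
    }
    expect_setequal(seen, vox)
  }
})

test_that("atlas placement fails on an impossible grid", {
  expect_error(make_network_atlas(3, c(1, 1, 1), 0, seed = 1), "too small")
})

test_that("block trains book-keep their duration exactly", {
  z <- simulate_block_activity(100, rate = 0, c(5, 10), seed = 1)
  expect_identical(z$train, integer(100))
  expect_equal(z$duration_pct, 0)

  a <- simulate_block_activity(200, rate = 5, c(5, 10), seed = 3)
  expect_equal(a$duration_pct, 100 * sum(a$train) / 200)
  recount <- sum(unlist(Map(function(o, f) f - o + 1L, a$onsets, a$offsets)))
  expect_identical(sum(a$train), recount)
  # blocks are separated by at least one inactive volume
  expect_equal(occurrences(a$train), length(a$onsets))
})

test_that("infeasible block placement errors", {
  expect_error(simulate_block_activity(10, rate = 90, c(8, 9), seed = 1),
               "cannot place")
  expect_error(simulate_block_activity(8, rate = 10, c(8, 9), seed = 1),
               "exceed")
})

test_that("duration-targeted trains reach the target by lengthening blocks", {
  base <- simulate_block_activity(105, rate = 2, c(5, 10), seed = 11)
  grown <- icapr:::simulate_activity_target(105, base$duration_pct + 10,
                                            c(5, 10), seed = 11, rate = 2)
  expect_gte(grown$duration_pct, base$duration_pct + 10 - 1)
  expect_equal(grown$duration_pct, 100 * sum(grown$train) / 105)
  expect_equal(occurrences(grown$train), length(grown$onsets))
})

test_that("the BOLD forward model is exact, linear and deterministic", {
  atlas <- make_network_atlas(2, c(5, 5, 4), 0, seed = 2)
  T <- 60
  trains <- matrix(0L, 2, T)
  trains[1, 20:29] <- 1L
  h <- hrf_kernel(2)
  s <- simulate_bold(atlas, trains, tr = 2, noise_sd = 0, seed = 1,
                     motion_spike_prob = 0)
  vox <- which(atlas$maps[, 1] == 1 & atlas$maps[, 2] == 0)[1]
  flat <- matrix(s$bold, nrow = prod(atlas$grid_shape))
  expect_equal(flat[vox, ], icapr:::convolve_causal(trains[1, ], h),
               tolerance = 1e-12)

  z <- simulate_bold(atlas, matrix(0L, 2, T), tr = 2, noise_sd = 0, seed = 1,
                     motion_spike_prob = 0)
  expect_true(all(z$bold == 0))

  # superposition: bold(t1 + t2) = bold(t1) + bold(t2) (noiseless)
  t1 <- matrix(0L, 2, T); t1[1, 10:15] <- 1L
  t2 <- matrix(0L, 2, T); t2[2, 30:40] <- 1L
  b12 <- simulate_bold(atlas, t1 + t2, tr = 2, noise_sd = 0, seed = 1,
                       motion_spike_prob = 0)$bold
  b1 <- simulate_bold(atlas, t1, tr = 2, noise_sd = 0, seed = 1,
                      motion_spike_prob = 0)$bold
  b2 <- simulate_bold(atlas, t2, tr = 2, noise_sd = 0, seed = 1,
                      motion_spike_prob = 0)$bold
  expect_equal(b12, b1 + b2, tolerance = 1e-10)

  r1 <- simulate_bold(atlas, trains, tr = 2, noise_sd = 1, seed = 9)
  r2 <- simulate_bold(atlas, trains, tr = 2, noise_sd = 1, seed = 9)
  expect_identical(r1$bold, r2$bold)
  expect_identical(r1$motion, r2$motion)

  expect_error(simulate_bold(atlas, matrix(0L, 3, T)), "n_networks")
})

test_that("cohorts plant the brain-behaviour coupling they record", {
  atlas <- make_network_atlas(3, c(6, 6, 4), 0, seed = 3)
  truth <- list(n_volumes = 80L, effect_networks = 1:2, n_scores = 3L,
                effect_scores = 1L, clinical_noise_sd = 0.2,
                clinical_effect = 1, noise_sd = 0.05)

  co <- simulate_cohort(30, atlas, truth, seed = 5)
  chg <- with(co$clinical, after[score == "score1"] - before[score == "score1"])
  expect_gt(cor(chg, co$cohort_delta <- co$truth$planted_mean_delta), 0.8)

  truth0 <- truth; truth0$clinical_effect <- 0
  co0 <- simulate_cohort(30, atlas, truth0, seed = 5)
  chg0 <- with(co0$clinical, after[score == "score1"] - before[score == "score1"])
  expect_lt(abs(cor(chg0, co0$truth$planted_mean_delta)), 0.3)

  # bookkeeping conservation: recorded durations equal an independent recount
  for (s in seq_len(4)) {
    tt <- co$truth$per_subject[[s]]
    for (ses in c("before", "after")) {
      recount <- 100 * rowSums(tt$trains[[ses]] != 0) / ncol(tt$trains[[ses]])
      expect_equal(unname(tt$duration_pct[, ses]), recount)
    }
  }

  co_b <- simulate_cohort(6, atlas, truth, seed = 42)
  co_c <- simulate_cohort(6, atlas, truth, seed = 42)
  expect_identical(co_b$sessions[[2]]$after$bold, co_c$sessions[[2]]$after$bold)
  expect_identical(co_b$clinical, co_c$clinical)
})

test_that("a 32-subject cohort yields the 32 x 7 clinical design", {
  atlas <- make_network_atlas(2, c(5, 5, 4), 0, seed = 2)
  truth <- list(n_volumes = 40L, n_scores = 5L, noise_sd = 0.05,
                block_len_range = c(3, 6), effect_networks = 1:2)
  co <- simulate_cohort(32, atlas, truth, seed = 1)
  scores <- unique(co$clinical$score)
  expect_length(scores, 5)
  b <- sapply(scores, function(sc) co$clinical$before[co$clinical$score == sc])
  a <- sapply(scores, function(sc) co$clinical$after[co$clinical$score == sc])
  ri <- rci_matrix(b, a, quiet = TRUE)
  X <- cbind(ri$rci,
             co$clinical$gestational_age[!duplicated(co$clinical$subject)],
             co$clinical$age_months[!duplicated(co$clinical$subject)])
  expect_identical(dim(X), c(32L, 7L))
})
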
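# shared fixtures and independent oracles used across the suite

# exact TV-denoising oracle: solve the box-constrained dual QP
#   min_u 0.5 * ||y - t(D) u||^2,  |u| <= lam,  x = y - t(D) u
tv_prox_oracle <- function(y, lam) {
  n <- length(y)
  D <- diff(diag(n))
  obj <- function(u) {
    r <- y - as.vector(crossprod(D, u))
    0.5 * sum(r^2)
  }
  grad <- function(u) as.vector(-D %*% (y - as.vector(crossprod(D, u))))
  o <- optim(rep(0, n - 1), obj, grad, method = "L-BFGS-B",
             lower = -lam, upper = lam,
             control = list(maxit = 5000, factr = 10))
  y - as.vector(crossprod(D, o$par))
}

# deconvolution objective evaluated directly
deconv_objective <- function(y, kernel, s, lam) {
  fit <- icapr:::convolve_causal(s, kernel)
  0.5 * sum((y - fit)^2) + lam * sum(abs(diff(s)))
}

# brute-force run count: a block starts at any nonzero entry whose
# predecessor differs
count_blocks_oracle <- function(train) {
  n <- 0L
  for (t in seq_along(train)) {
    if (train[t] != 0 && (t == 1 || train[t - 1] != train[t])) n <- n + 1L
  }
  n
}

# brute-force BH step-up q-values
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# small orthogonal frame set with planted cluster labels
make_planted_frames <- function(n_per = 12, n_patterns = 3, nvox = 60,
                                noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    patterns <- matrix(0, n_patterns, nvox)
    block <- floor(nvox / n_patterns)
    for (k in seq_len(n_patterns)) {
      patterns[k, ((k - 1) * block + 1):(k * block)] <- 1
    }
    frames <- NULL
    labels <- integer(0)
    for (k in seq_len(n_patterns)) {
      signs <- sample(c(-1, 1), n_per, replace = TRUE)
      f <- outer(signs, patterns[k, ]) +
        matrix(rnorm(n_per * nvox, sd = noise_sd), n_per)
      frames <- rbind(frames, f)
      labels <- c(labels, rep(k, n_per))
    }
  })
  list(frames = frames, labels = labels, patterns = patterns)
}

# tiny noiseless two-network phantom used by deconv/icaps tests
make_phantom <- function(seed = 5, noise_sd = 0, n_volumes = 80) {
  atlas <- make_network_atlas(2, c(5, 5, 4), overlap_frac = 0, seed = seed,
                              coverage = 0.25)
  t1 <- simulate_block_activity(n_volumes, rate = 3, c(6, 10), seed = seed + 1)
  t2 <- simulate_block_activity(n_volumes, rate = 3, c(6, 10), seed = seed + 2)
  trains <- rbind(t1$train, t2$train)
  session <- simulate_bold(atlas, trains, tr = 2, noise_sd = noise_sd,
                           seed = seed + 3, motion_spike_prob = 0)
  list(atlas = atlas, trains = trains, session = session,
       edges = list(c(t1$onsets, t1$offsets + 1L),
                    c(t2$onsets, t2$offsets + 1L)))
}

expect_no_na <- function(x) expect_false(anyNA(x))
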
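test_that("focal CLIP matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    N <- sample(2:8, 1)
    d <- sample(2:16, 1)
    I <- matrix(rnorm(N * d), N)
    T <- matrix(rnorm(N * d), N)
    gamma <- sample(c(0, 0.5, 2), 1)
    tau <- runif(1, 0.05, 1)
    expect_equal(focal_clip_loss(I, T, gamma, tau),
                 oracle_focal_clip(I, T, gamma, tau), tolerance = 1e-10)
  }
})

test_that("gamma = 0 recovers the plain symmetric CLIP cross-entropy", {
  set.seed(12)
  I <- matrix(rnorm(6 * 8), 6)
  T <- matrix(rnorm(6 * 8), 6)
  expect_equal(focal_clip_loss(I, T, gamma = 0, tau = 0.1),
               oracle_plain_clip(I, T, 0.1), tolerance = 1e-10)
})

test_that("a single pair gives exactly zero loss", {
  I <- matrix(rnorm(5), 1)
  T <- matrix(rnorm(5), 1)
  expect_identical(focal_clip_loss(I, T, gamma = 2, tau = 0.07), 0)
  expect_identical(focal_clip_loss(I, T, gamma = 0, tau = 0.07), 0)
})

test_that("focal CLIP is symmetric under joint row permutation and never
           exceeds the unfocused loss", {
  set.seed(13)
  for (rep in 1:5) {
    N <- 6
    I <- matrix(rnorm(N * 10), N)
    T <- matrix(rnorm(N * 10), N)
    p <- sample(N)
    expect_equal(focal_clip_loss(I[p, ], T[p, ], 2, 0.2),
                 focal_clip_loss(I, T, 2, 0.2), tolerance = 1e-12)
    expect_lte(focal_clip_loss(I, T, 2, 0.2),
               focal_clip_loss(I, T, 0, 0.2) + 1e-12)
  }
})

test_that("zero-norm rows are guarded with a warning", {
  I <- rbind(rep(0, 4), rnorm(4))
  T <- matrix(rnorm(8), 2)
  expect_warning(v <- focal_clip_loss(I, T, 2, 0.1), "zero-norm")
  expect_true(is.finite(v))
})

test_that("positivity BCE matches an independent per-element oracle", {
  set.seed(14)
  s <- matrix(runif(12), 3, 4)
  t <- matrix(rbinom(12, 1, 0.5), 3, 4)
  m <- matrix(rbinom(12, 1, 0.7), 3, 4)
  m[1, 1] <- 1
  expect_equal(positivity_loss(s, t, m, smoothing = 0.2),
               oracle_bce(s, t, m, 0.2), tolerance = 1e-12)
  expect_equal(positivity_loss(s, t, m, smoothing = 0),
               oracle_bce(s, t, m, 0), tolerance = 1e-12)
})

test_that("BCE is minimized at the smoothed target, equalling its entropy", {
  smoothing <- 0.2
  t <- matrix(c(1, 0, 1, 0), 2)
  tp <- t * (1 - smoothing) + smoothing / 2
  m <- matrix(1, 2, 2)
  closed <- mean(-(tp * log(tp) + (1 - tp) * log(1 - tp)))
  expect_equal(positivity_loss(tp, t, m, smoothing), closed,
               tolerance = 1e-12)
  # and perfect unsmoothed predictions give (numerically) zero
  expect_lt(positivity_loss(t, t, m, smoothing = 0), 1e-4)
})

test_that("an unlabeled batch yields zero positivity loss with a warning", {
  s <- matrix(0.5, 2, 3)
  expect_warning(v <- positivity_loss(s, s * 0, s * 0), "no labeled")
  expect_identical(v, 0)
})

test_that("the adversarial ramp follows the quartic root exactly", {
  w <- 0.37
  expect_identical(adversarial_weight(0, w), 0)
  expect_identical(adversarial_weight(1, w), w)
  expect_equal(adversarial_weight(16, w), 2 * w, tolerance = 1e-15)
  expect_error(adversarial_weight(-1, w), "non-negative")
})

test_that("the total loss is the documented weighted sum", {
  w <- list(w_cls = 0.7, w_pos = 1.3, w_adv_base = 0.2)
  tl <- total_loss(2, 3, 5, w, epoch = 16)
  expect_equal(tl$total, 0.7 * 2 + 1.3 * 3 + 0.4 * 5)
  expect_equal(unname(tl$breakdown), c(1.4, 3.9, 2.0))
  z <- total_loss(2, 3, 5, list(w_cls = 0, w_pos = 0, w_adv_base = 0), 4)
  expect_identical(z$total, 0)
  expect_error(total_loss(NaN, 1, 1, w, 1), "cls")
})

test_that("modality CE with smoothing matches a direct computation", {
  set.seed(15)
  lg <- matrix(rnorm(6), 2, 3)
  y <- c(2L, 3L)
  s <- 0.01
  manual <- 0
  for (b in 1:2) {
    p <- exp(lg[b, ] - max(lg[b, ]))
    p <- p / sum(p)
    q <- rep(s / 3, 3)
    q[y[b]] <- q[y[b]] + 1 - s
    manual <- manual - sum(q * log(p))
  }
  expect_equal(modality_loss(lg, y, s), manual / 2, tolerance = 1e-12)
})
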
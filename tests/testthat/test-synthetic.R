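test_that("the noiseless limit renders constant cells at the profile level", {
  spec <- mini_spec(noise = FALSE)
  set.seed(2)
  rf <- render_fov(spec, "dsA")        # modality m1: no blur or offset
  gain <- spec$modalities$m1$gain
  for (k in c(1, 10)) {
    type <- rf$truth$cell_type[k]
    pix <- rf$mask$labels == k
    for (m in seq_along(spec$panels$dsA)) {
      vals <- rf$image$pixels[, , m][pix]
      expected <- gain * exp(spec$profile[type, spec$panels$dsA[m]])
      expect_equal(unique(round(vals, 12)), round(expected, 12),
                   info = paste("cell", k, "marker", m))
    }
  }
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- mini_spec()
  a <- render_fov(spec, "dsA", seed = 33)
  b <- render_fov(spec, "dsA", seed = 33)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$truth, b$truth)
})

test_that("cells do not overlap and some sit near the boundary", {
  spec <- mini_spec()
  fovs <- render_corpus_fovs(spec)
  labs <- fovs[[1]]$mask$labels
  expect_equal(sort(unique(labs[labs > 0])), seq_len(spec$cells_per_fov))
  # each labelled pixel belongs to exactly one cell by construction;
  # boundary-adjacent cells exist somewhere in the corpus
  near_edge <- vapply(fovs, function(f) {
    e <- f$mask$labels
    any(e[1:3, ] > 0) || any(e[, 1:3] > 0) ||
      any(e[nrow(e) - 0:2, ] > 0) || any(e[, ncol(e) - 0:2] > 0)
  }, TRUE)
  expect_true(any(near_edge))
})

test_that("midpoint gating on rendered data recovers the positivity bits", {
  spec <- mini_spec()                   # SNR well above 10
  set.seed(9)
  rf <- render_fov(spec, "dsA")
  modal <- spec$modalities$m1
  on <- modal$gain * exp(log(0.7)) + modal$offset
  offv <- modal$gain * exp(log(0.02)) + modal$offset
  cut <- (on + offv) / 2
  bits_true <- as.matrix(rf$truth[, paste0("pos_", spec$panels$dsA)])
  n_ok <- 0L
  for (k in rf$truth$cell_id) {
    pix <- rf$mask$labels == k
    for (m in seq_along(spec$panels$dsA)) {
      called <- mean(rf$image$pixels[, , m][pix]) > cut
      if (called == (bits_true[k, m] == 1)) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / length(bits_true), 0.99)
})

test_that("noiseless profiles are perfectly identifiable by nearest profile", {
  spec <- mini_spec(noise = FALSE)
  set.seed(4)
  rf <- render_fov(spec, "dsA")
  prof_lin <- exp(spec$profile)         # dsA: gain 1, offset 0, blur 0
  hits <- 0L
  for (k in rf$truth$cell_id) {
    pix <- rf$mask$labels == k
    means <- vapply(seq_along(spec$panels$dsA), function(m)
      mean(rf$image$pixels[, , m][pix]), 0)
    d <- apply(prof_lin, 1, function(p) sum((means - p)^2))
    if (names(which.min(d)) == rf$truth$cell_type[k]) hits <- hits + 1L
  }
  expect_equal(hits, nrow(rf$truth))
})

test_that("within-cell means converge to the transformed profile value", {
  # law of large numbers over cells, blur disabled so means are exact
  spec <- mini_spec()
  spec$modalities$m1$blur <- 0
  spec$noise_sigma <- 0
  spec$fovs_per_dataset <- 4L
  set.seed(10)
  obs <- c()
  for (f in 1:4) {
    rf <- render_fov(spec, "dsA")
    tc <- rf$truth$cell_id[rf$truth$cell_type == "T cell"]
    m <- match("CD3", spec$panels$dsA)
    for (k in tc)
      obs <- c(obs, mean(rf$image$pixels[, , m][rf$mask$labels == k]))
  }
  modal <- spec$modalities$m1
  expected <- modal$gain * exp(log(0.7) + spec$jitter_sd^2 / 2) +
              modal$offset
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se + 1e-12)
})

test_that("corpora conserve cell counts and panel structure", {
  corpus <- mini_corpus()
  spec <- mini_spec()
  expect_equal(nrow(corpus$cells),
               2 * spec$fovs_per_dataset * spec$cells_per_fov)
  expect_identical(corpus$panels, spec$panels)
  expect_equal(unique(corpus$cells$n_channels[
    corpus$cells$dataset_id == "dsB"]), 3)
  # patch store size matches the cell table exactly
  last <- nrow(corpus$cells)
  expect_equal(corpus$cells$offset[last] +
               corpus$cells$n_channels[last] * 12288,
               length(corpus$patch_data))
  # same spec seed regenerates the corpus bit-exactly
  again <- make_corpus(spec)
  expect_identical(again$patch_data, corpus$patch_data)
  expect_identical(again$cells, corpus$cells)
})

test_that("simulate_to_dir writes a loadable dataset layout", {
  spec <- mini_spec()
  spec$fovs_per_dataset <- 1L
  out <- file.path(tempdir(), "simout")
  simulate_to_dir(spec, out)
  expect_true(file.exists(file.path(out, "spec.yaml")))
  img <- read_fov_tiff(file.path(out, "dsA", "fov01.tiff"),
                       file.path(out, "dsA", "fov01_channels.csv"),
                       mpp = 0.5)
  expect_equal(img$panel$canonical_names, spec$panels$dsA)
  truth <- read.csv(file.path(out, "dsA", "fov01_truth.csv"))
  expect_equal(nrow(truth), spec$cells_per_fov)
  unlink(out, recursive = TRUE)
})
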
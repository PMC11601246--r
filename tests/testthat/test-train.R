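test_that("augmentation identities hold", {
  batch <- random_batch(c(4L, 6L), C_max = 6L, seed = 71L)
  same <- augment_batch(batch, codes = c(0L, 0L), dropout_k = 0L)
  expect_identical(same$tensor, batch$tensor)
  expect_identical(same$padding_mask, batch$padding_mask)
  # flipping twice along the same axis is the identity
  once <- augment_batch(batch, codes = c(4L, 4L))
  twice <- augment_batch(once, codes = c(4L, 4L))
  expect_identical(twice$tensor, batch$tensor)
  # four quarter rotations are the identity
  r <- batch
  for (i in 1:4) r <- augment_batch(r, codes = c(1L, 1L))
  expect_identical(r$tensor, batch$tensor)
})

test_that("spatial transforms act identically on all three planes", {
  batch <- random_batch(3L, seed = 72L)
  out <- augment_batch(batch, codes = 3L)
  idx <- phenoclip:::aug_index(3L)
  for (p in 1:3) {
    src <- batch$tensor[, , p, 2, 1]
    expect_identical(as.vector(out$tensor[, , p, 2, 1]),
                     as.vector(src)[idx])
  }
})

test_that("channel dropout conserves the padding-mask bit count", {
  set.seed(73)
  batch <- random_batch(rep(24L, 3L), C_max = 24L, seed = 73L)
  out <- augment_batch(batch, codes = rep(0L, 3L), dropout_k = 8L)
  expect_equal(rowSums(out$padding_mask), rep(16, 3))
  # dropped channels lose tensor content and their names
  for (b in 1:3) {
    gone <- which(out$padding_mask[b, ] == 0)
    expect_true(all(out$tensor[, , , gone, b] == 0))
    expect_length(out$channel_names[[b]], 16L)
  }
  # never drops the last channel
  b1 <- random_batch(1L, seed = 74L)
  out1 <- augment_batch(b1, codes = 0L, dropout_k = 8L)
  expect_equal(sum(out1$padding_mask), 1)
})

test_that("training loss decreases on separable data in most seeds", {
  # optimization smoke test: 200 cells of 3 well-separated types, the
  # phenotype objective alone, augmentation off so the epoch loss is a
  # near-deterministic function of the parameters
  corpus <- smoke_corpus()
  prov <- offline_provider(32L)
  drops <- 0L
  for (s in 1:10) {
    model <- init_phenotype_model(tiny_config(seed = s, d_model = 32L))
    tc <- train_config(lr = 1e-2, epochs = 5L, batch_size = 50L,
                       channel_dropout_k = 0L, embed_noise_sigma = 0,
                       augment = FALSE, w_pos = 0, w_adv_base = 0,
                       seed = 100L + s)
    fit <- fit_phenotype_model(model, corpus, tc, prov)
    if (all(diff(fit$history$loss_total) < 0)) drops <- drops + 1L
  }
  expect_gte(drops, 9L)
})

test_that("a fixed seed reproduces the training history bit-exactly", {
  corpus <- mini_corpus()
  sub <- subset_corpus(corpus, "dsA")
  prov <- offline_provider(32L)
  run <- function() {
    model <- init_phenotype_model(tiny_config(seed = 4L))
    fit_phenotype_model(model, sub,
                        train_config(lr = 3e-3, epochs = 2L,
                                     batch_size = 32L,
                                     channel_dropout_k = 1L, seed = 9L),
                        prov)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training can log a resolved config and per-epoch metrics", {
  corpus <- mini_corpus()
  sub <- subset_corpus(corpus, "dsA")
  ld <- file.path(tempdir(), "trainlog")
  unlink(ld, recursive = TRUE)
  model <- init_phenotype_model(tiny_config(seed = 14L))
  fit <- fit_phenotype_model(
    model, sub,
    train_config(lr = 3e-3, epochs = 2L, batch_size = 32L,
                 channel_dropout_k = 1L, seed = 3L, log_dir = ld),
    offline_provider(32L))
  cfg <- yaml::read_yaml(file.path(ld, "config.yaml"))
  expect_equal(cfg$train$epochs, 2L)
  expect_equal(cfg$provider, "offline-hash-v1")
  lines <- readLines(file.path(ld, "metrics.jsonl"))
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$epoch, 2L)
  expect_equal(rec$loss_total, fit$history$loss_total[2])
  unlink(ld, recursive = TRUE)
})

test_that("fitting requires labels and a matching provider dimension", {
  corpus <- mini_corpus()
  sub <- subset_corpus(corpus, "dsA")
  sub$cells$type <- NA_character_
  model <- init_phenotype_model(tiny_config())
  expect_error(fit_phenotype_model(model, sub, train_config(),
                                   offline_provider(32L)), "labels")
  expect_error(fit_phenotype_model(model, subset_corpus(corpus, "dsA"),
                                   train_config(), offline_provider(64L)),
               "d_raw")
})
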
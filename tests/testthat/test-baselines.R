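test_that("mean-intensity features match a per-pixel brute-force oracle", {
  set.seed(31)
  H <- 40
  labs <- matrix(0L, H, H)
  labs[5:12, 5:12] <- 1L
  labs[20:29, 18:23] <- 2L
  px <- array(runif(H * H * 3), c(H, H, 3))
  img <- fov_image(px, 0.5, marker_panel(c("A", "B", "C")),
                   dataset_id = "dX")
  ft <- extract_feature_table(list(list(image = img,
                                        mask = segmentation_mask(labs))))
  for (k in 1:2) for (m in 1:3) {
    acc <- 0; n <- 0
    for (i in 1:H) for (j in 1:H) if (labs[i, j] == k) {
      acc <- acc + px[i, j, m]; n <- n + 1
    }
    expect_equal(ft[ft$cell_id == k, c("A", "B", "C")[m]], acc / n,
                 tolerance = 1e-12)
    expect_equal(ft$cell_size[ft$cell_id == k], n)
  }
})

test_that("uniform cells yield their intensity exactly; absent markers get
           the placeholder", {
  labs <- matrix(0L, 20, 20)
  labs[3:8, 3:8] <- 1L
  px <- array(0, c(20, 20, 1))
  px[, , 1][labs == 1] <- 0.42
  f1 <- list(image = fov_image(px, 0.5, marker_panel("A"),
                               dataset_id = "d1"),
             mask = segmentation_mask(labs))
  f2 <- list(image = fov_image(px, 0.5, marker_panel("B"),
                               dataset_id = "d2"),
             mask = segmentation_mask(labs))
  ft <- extract_feature_table(list(f1, f2))
  expect_equal(ft$A[ft$dataset_id == "d1"], 0.42)
  expect_true(is.na(ft$B[ft$dataset_id == "d1"]))
  expect_true(is.na(ft$A[ft$dataset_id == "d2"]))
  ft0 <- extract_feature_table(list(f1, f2), placeholder = 0)
  expect_equal(ft0$B[ft0$dataset_id == "d1"], 0)
})

test_that("feature extraction is invariant to channel order and
           translation", {
  set.seed(32)
  labs <- matrix(0L, 30, 30)
  labs[10:15, 10:15] <- 1L
  px <- array(runif(30 * 30 * 2), c(30, 30, 2))
  f <- list(image = fov_image(px, 0.5, marker_panel(c("A", "B"))),
            mask = segmentation_mask(labs))
  fr <- list(image = fov_image(px[, , 2:1], 0.5,
                               marker_panel(c("B", "A"))),
             mask = segmentation_mask(labs))
  t1 <- extract_feature_table(list(f), all_markers = c("A", "B"))
  t2 <- extract_feature_table(list(fr), all_markers = c("A", "B"))
  expect_equal(t1[, c("A", "B", "cell_size")],
               t2[, c("A", "B", "cell_size")])
  # translation with the mask
  px2 <- array(0, c(30, 30, 2)); labs2 <- matrix(0L, 30, 30)
  px2[6:30, 4:30, ] <- px[1:25, 1:27, ]
  labs2[6:30, 4:30] <- labs[1:25, 1:27]
  t3 <- extract_feature_table(list(list(
    image = fov_image(px2, 0.5, marker_panel(c("A", "B"))),
    mask = segmentation_mask(labs2))), all_markers = c("A", "B"))
  expect_equal(t3[, c("A", "B", "cell_size")],
               t1[, c("A", "B", "cell_size")])
})

test_that("classification metrics match hand-computed values", {
  pred <- c("a", "a", "b", "b", "c", "c", "c", "a")
  truth <- c("a", "b", "b", "b", "c", "c", "a", "a")
  ev <- evaluate_classification(pred, truth)
  # class a: tp 2, fp 1, fn 1 -> p = 2/3, r = 2/3, f1 = 2/3
  # class b: tp 2, fp 0, fn 1 -> p = 1, r = 2/3, f1 = 4/5
  # class c: tp 2, fp 1, fn 0 -> p = 2/3, r = 1, f1 = 4/5
  f <- setNames(ev$per_class$f1, ev$per_class$class)
  expect_equal(unname(f[c("a", "b", "c")]), c(2 / 3, 4 / 5, 4 / 5),
               tolerance = 1e-12)
  expect_equal(ev$macro_f1, mean(c(2 / 3, 4 / 5, 4 / 5)))
  perfect <- evaluate_classification(truth, truth)
  expect_true(all(perfect$per_class$f1 == 1))
})

test_that("macro F1 is invariant to class relabeling and respects
           min_support", {
  set.seed(33)
  truth <- sample(c("x", "y", "z"), 60, TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("x", "y", "z"), 60, TRUE))
  e1 <- evaluate_classification(pred, truth)
  map <- c(x = "q", y = "r", z = "s")
  e2 <- evaluate_classification(unname(map[pred]), unname(map[truth]))
  expect_equal(e1$macro_f1, e2$macro_f1)
  expect_error(evaluate_classification("x", "x", min_support = 100),
               "min_support")
  # support filter drops rare classes from the macro average; the rare
  # cell mispredicted as "big" still costs one false positive
  truth2 <- c(rep("big", 50), "rare")
  pred2 <- c(rep("big", 50), "big")
  e3 <- evaluate_classification(pred2, truth2, min_support = 10)
  expect_equal(e3$per_class$class, "big")
  expect_equal(e3$macro_f1, 2 * (50 / 51) / (1 + 50 / 51))
})

test_that("the modality probe hits its trivial endpoints", {
  set.seed(34)
  n <- 80
  mods <- rep(c("codex", "mibi"), each = n / 2)
  flat <- matrix(rnorm(n * 6, sd = 1e-6), n) + 0.5   # no information
  pf <- modality_probe(flat, mods, seed = 1)
  expect_lt(abs(pf$accuracy - pf$chance), 0.2)
  hot <- cbind((mods == "codex") * 1, (mods == "mibi") * 1,
               matrix(rnorm(n * 4, sd = 0.01), n))
  ph <- modality_probe(hot, mods, seed = 1)
  expect_gte(ph$accuracy, 0.95)
  expect_error(modality_probe(flat, rep("codex", n)), "two modalities")
})

test_that("the tree baseline learns separable features and handles
           missing markers", {
  set.seed(35)
  n <- 240
  lab <- sample(c("t1", "t2", "t3"), n, TRUE)
  A <- ifelse(lab == "t1", 0.8, 0.1) + rnorm(n, 0, 0.02)
  B <- ifelse(lab == "t2", 0.8, 0.1) + rnorm(n, 0, 0.02)
  C <- ifelse(lab == "t3", 0.8, 0.1) + rnorm(n, 0, 0.02)
  ft <- data.frame(dataset_id = "d", modality_id = "m", fov = 1,
                   cell_id = seq_len(n), label = lab, A = A, B = B, C = C,
                   cell_size = 50)
  fit <- fit_intensity_baseline(ft[1:160, ], nrounds = 40L)
  pred <- predict(fit, ft[161:n, ])
  expect_gte(mean(pred == lab[161:n]), 0.95)
  # missing markers route through the native NA handling without error
  ft_na <- ft[161:n, ]
  ft_na$C <- NA_real_
  pred_na <- predict(fit, ft_na)
  expect_equal(length(pred_na), n - 160)
})
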
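test_that("PoS is the union pixel count over the image area", {
  h <- 100; w <- 100
  nuc <- as_object(bar_mask(h, w, 10, 10, 15, 20), class = "NUCLEUS")  # 300 px
  expect_equal(compute_pos(list(nuc), c(h, w)), 0.03)
  expect_equal(compute_pos(list(), c(h, w)), 0)
  # overlapping masks counted once: two 600 px bars overlapping by 200
  a <- as_object(bar_mask(h, w, 40, 11, 20, 30), class = "NUCLEUS")
  b <- as_object(bar_mask(h, w, 40, 31, 20, 30), class = "NUCLEUS")
  expect_equal(sum(bar_mask(h, w, 40, 11, 20, 30) &
                   bar_mask(h, w, 40, 31, 20, 30)), 200)
  expect_equal(compute_pos(list(a, b), c(h, w)), 0.10)
  expect_error(compute_pos(list(), c(0, 0)), "positive")
})

test_that("PoS never decreases when objects are added and stays in [0,1]", {
  set.seed(61)
  h <- 80; w <- 80
  objs <- list()
  prev <- 0
  for (i in 1:15) {
    objs <- c(objs, list(as_object(random_blob_mask(h, w), id = i)))
    cur <- compute_pos(objs, c(h, w))
    expect_gte(cur, prev)
    expect_lte(cur, 1)
    prev <- cur
  }
})

test_that("neuropil density is the summed perimeter over 100", {
  expect_equal(compute_neuropil_density(list()), 0)
  h <- 60; w <- 300
  f1 <- as_object(bar_mask(h, w, 10, 10, 2, 280), class = "NEUROPIL")
  expect_equal(compute_neuropil_density(list(f1)), f1$perimeter / 100)
  f2 <- as_object(bar_mask(h, w, 30, 10, 3, 150), class = "NEUROPIL")
  expect_equal(compute_neuropil_density(list(f1, f2)),
               (f1$perimeter + f2$perimeter) / 100)
})

test_that("the two-threshold rule is a strict OR", {
  f <- function(cp, np) data.frame(cell_pos = cp, nucleus_pos = np)
  r <- classify_image(f(0.18, 0))
  expect_equal(r$label, "TUMOR"); expect_equal(r$triggered_rule, "CELL_POS")
  r <- classify_image(f(0.17, 0.03))  # boundary: "higher than" is strict
  expect_equal(r$label, "NORMAL"); expect_equal(r$triggered_rule, "NONE")
  r <- classify_image(f(0.10, 0.05))
  expect_equal(r$label, "TUMOR"); expect_equal(r$triggered_rule, "NUCLEUS_POS")
  r <- classify_image(f(0.2, 0.2))
  expect_equal(r$triggered_rule, "BOTH")
  # label TUMOR iff a rule fired
  for (cp in c(0.1, 0.17, 0.18)) for (np in c(0, 0.03, 0.05)) {
    r <- classify_image(f(cp, np))
    expect_identical(r$label == "TUMOR", r$triggered_rule != "NONE")
  }
})

test_that("raising either density never flips a tumor call back to normal", {
  set.seed(62)
  for (i in 1:50) {
    cp <- runif(1, 0, 0.4); np <- runif(1, 0, 0.1)
    base <- classify_image(data.frame(cell_pos = cp, nucleus_pos = np))
    up <- classify_image(data.frame(cell_pos = cp + runif(1, 0, 0.3),
                                    nucleus_pos = np + runif(1, 0, 0.1)))
    if (base$label == "TUMOR") expect_equal(up$label, "TUMOR")
  }
})

test_that("confusion metrics match hand counts and a brute-force oracle", {
  pred <- c(rep("TUMOR", 3), "NORMAL", rep("NORMAL", 4), rep("TUMOR", 2))
  truth <- c(rep("TUMOR", 4), rep("NORMAL", 6))
  m <- compare_with_reference(pred, truth)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$percent_agreement, 0.7)
  # perfect and maximally wrong predictions
  expect_equal(compare_with_reference(truth, truth)$percent_agreement, 1)
  allno <- compare_with_reference(rep("NORMAL", 4), rep("TUMOR", 4))
  expect_equal(allno$sensitivity, 0)
  expect_equal(allno$percent_agreement, 0)
  expect_error(compare_with_reference(character(0), character(0)), "empty")
  # random lists against the oracle
  set.seed(63)
  for (i in 1:30) {
    p <- sample(c("NORMAL", "TUMOR"), 40, replace = TRUE)
    t <- sample(c("NORMAL", "TUMOR"), 40, replace = TRUE)
    m <- compare_with_reference(p, t)
    o <- oracle_confusion(p, t)
    expect_equal(m$sensitivity, o$sens)
    expect_equal(m$specificity, o$spec)
    expect_equal(m$percent_agreement, o$agree)
  }
})

test_that("quartered tiles average their quarter features", {
  # 200x200 px at 2.5 um/px = 500 um field: quartering engages; plant
  # dark discs so the four 100x100 quarters carry different cell density
  set.seed(64)
  img <- matrix(0.55, 200, 200) +
    matrix(rnorm(200 * 200, 0, 0.015), 200, 200)
  plant <- function(img, ctr, r) { img[disc_mask(200, 200, ctr, r)] <- 0.1; img }
  img <- plant(img, c(50, 50), 22)     # q1: one cell
  img <- plant(img, c(50, 150), 22)    # q2: one cell
  img <- plant(img, c(130, 40), 22)    # q3: two cells
  img <- plant(img, c(170, 75), 22)
  img <- plant(img, c(150, 160), 22)   # q4: one cell
  cfg <- default_config()
  res <- classify_mosaic(list(img), c(1, 1), cfg, pixel_size_um = 2.5)
  expect_equal(nrow(res$quarters), 4)
  f <- res$features
  expect_equal(f$cell_pos, mean(res$quarters$cell_pos))
  expect_equal(f$n_cells, mean(res$quarters$n_cells))
  # tile label comes from the averaged features
  expect_equal(res$results[[1]]$label,
               classify_image(f)$label)
  # without quartering the same tile is quantified whole
  cfg$classifier$quarter_large_tiles <- FALSE
  res2 <- classify_mosaic(list(img), c(1, 1), cfg, pixel_size_um = 2.5)
  expect_null(res2$quarters)
  expect_lt(abs(res2$features$cell_pos - f$cell_pos), 0.02)
})

test_that("averaging quarters reproduces the stated tumor-call example", {
  qf <- data.frame(cell_pos = c(0.10, 0.10, 0.30, 0.30),
                   nucleus_pos = rep(0, 4))
  tile <- data.frame(cell_pos = mean(qf$cell_pos),
                     nucleus_pos = mean(qf$nucleus_pos))
  expect_equal(tile$cell_pos, 0.20)
  expect_equal(classify_image(tile)$label, "TUMOR")
})

test_that("threshold tuning maximizes Youden's J on labeled features", {
  set.seed(65)
  feats <- data.frame(cell_pos = c(runif(30, 0, 0.12), runif(30, 0.22, 0.4)),
                      nucleus_pos = 0)
  truth <- rep(c("NORMAL", "TUMOR"), each = 30)
  fit <- tune_thresholds(feats, truth, cell_grid = seq(0.05, 0.45, 0.01),
                         nucleus_grid = 0.5)
  expect_equal(fit$youden_j, 1)
  expect_gt(fit$cell_pos_threshold, 0.11)
  expect_lt(fit$cell_pos_threshold, 0.23)
})
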
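# A small feature table whose target is exactly linear in one feature.
linear_toy <- function(n = 400, seed = 1) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(n * 10), n, 10)
    colnames(f) <- paste0("ch", rep(1:5, each = 2), "_",
                          rep(c("mav", "zc"), 5))
    tibble::as_tibble(f) |>
      dplyr::mutate(alpha1 = 20 * .data$ch1_mav + 5,
                    alpha2 = 0, alpha3 = 90,
                    window = dplyr::row_number(), run = 1L,
                    position = "POS1")
  })
}

test_that("the MLP fits a noiseless linear map almost perfectly", {
  d <- linear_toy()
  m <- train_mlp(d, dof = 1, seed = 3)
  expect_gt(m$train_r2, 0.99)
  expect_lt(sqrt(mean((predict(m, d) - d$alpha1)^2)), 1)
})

test_that("training is deterministic given the seed", {
  d <- linear_toy()
  m1 <- train_mlp(d, dof = 1, seed = 7)
  m2 <- train_mlp(d, dof = 1, seed = 7)
  expect_identical(m1$fit$wts, m2$fit$wts)
  m3 <- train_mlp(d, dof = 1, seed = 8)
  expect_false(identical(m1$fit$wts, m3$fit$wts))
})

test_that("prediction is a row-wise map and guards degenerate inputs", {
  d <- linear_toy()
  m <- train_mlp(d, dof = 1, seed = 3)
  perm <- withr::with_seed(2, sample(nrow(d)))
  expect_equal(predict(m, d[perm, ]), predict(m, d)[perm])
  # constant feature column: scale falls back to 1, no NaN anywhere
  d2 <- d
  d2$ch1_zc <- 0
  m2 <- train_mlp(d2, dof = 1, seed = 3)
  expect_true(all(is.finite(predict(m2, d2))))
  # constant targets are flagged; the model predicts the constant
  d3 <- d
  d3$alpha1 <- 42
  expect_warning(m3 <- train_mlp(d3, dof = 1, seed = 3),
                 class = "wristemg_degenerate_target")
  expect_equal(predict(m3, d3), rep(42, nrow(d3)))
  expect_true(is.na(m3$train_r2))
  # contract errors
  expect_error(train_mlp(d, dof = 5), class = "wristemg_contract_error")
  expect_error(predict(m, d["alpha1"]), class = "wristemg_contract_error")
  d4 <- d
  d4$ch1_mav[3] <- NA
  expect_error(train_mlp(d4, dof = 1), class = "wristemg_data_error")
})

test_that("tidy and glance expose the fitted model", {
  m <- train_mlp(linear_toy(), dof = 1, seed = 3)
  td <- tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(td), length(m$fit$wts))
  gl <- glance(m)
  expect_equal(gl$n_train, 400)
  expect_gt(gl$train_r2, 0.99)
})

test_that("folds partition each run into balanced contiguous blocks", {
  d <- tibble::tibble(position = "POS1", run = 1L, window = 1:1621)
  f <- make_folds(d, k = 5, seed = 1)
  sizes <- sort(f$to - f$from + 1, decreasing = TRUE)
  expect_equal(sizes, c(325, 324, 324, 324, 324))
  expect_equal(sort(f$fold), 1:5)
  # union of test blocks covers every window exactly once
  covered <- unlist(purrr::map2(f$from, f$to, seq))
  expect_equal(sort(covered), 1:1621)
  # determinism
  expect_identical(f, make_folds(d, k = 5, seed = 1))
  expect_false(identical(f$fold, make_folds(d, k = 5, seed = 2)$fold))
  expect_error(make_folds(d[1:3, ], k = 5),
               class = "wristemg_contract_error")
})

# A multi-position, multi-run session-like feature table with a known
# linear feature-angle relation.
toy_session <- function(n_per_run = 150, seed = 1) {
  grid <- expand.grid(run = 1:7, position = c("POS1", "POS2", "POS3"),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, purrr::pmap_dfr(grid, function(run, position) {
    f <- matrix(rnorm(n_per_run * 6), n_per_run, 6)
    colnames(f) <- paste0("ch", 1:6, "_mav")
    tibble::as_tibble(f) |>
      dplyr::mutate(window = dplyr::row_number(), run = run,
                    position = position,
                    alpha1 = 30 * .data$ch1_mav,
                    alpha2 = 30 * .data$ch2_mav,
                    alpha3 = 90 + 20 * .data$ch3_mav)
  }))
}

test_that("splits honour scenarios, pooling and the leakage guard", {
  d <- toy_session()
  folds <- make_folds(d, k = 5, seed = 4)
  sp <- assemble_split(d, folds, "DoF12", "POS1", fold = 2)
  expect_setequal(unique(sp$train$run), 1:2)
  expect_true(all(sp$train$position == "POS1"))
  sp123 <- assemble_split(d, folds, "DoF123", "POS2", fold = 1)
  expect_setequal(unique(sp123$train$run), 1:7)
  # intra test: held-out block rows at the training position
  expect_equal(attr(sp$test$POS1, "type"), "intra")
  # inter test: all scenario rows at the other positions
  expect_equal(attr(sp$test$POS2, "type"), "inter")
  expect_equal(nrow(sp$test$POS2), 2 * 150)
  expect_equal(nrow(sp$test$POS3), 2 * 150)
  # no test window within the overlap radius of any training window
  for (r in 1:2) {
    trainw <- sp$train$window[sp$train$run == r]
    testw <- sp$test$POS1$window[sp$test$POS1$run == r]
    if (length(testw)) {
      expect_gt(min(outer(testw, trainw,
                          function(a, b) abs(a - b))), 2)
    }
  }
  # train and intra-test rows are disjoint
  key <- function(x) paste(x$position, x$run, x$window)
  expect_length(intersect(key(sp$train), key(sp$test$POS1)), 0)
  # pooling concatenates the three single-position training sets
  pooled <- assemble_split(d, folds, "DoF12", c("POS1", "POS2", "POS3"),
                           fold = 2)
  singles <- sum(vapply(c("POS1", "POS2", "POS3"), function(p) {
    nrow(assemble_split(d, folds, "DoF12", p, fold = 2)$train)
  }, numeric(1)))
  expect_equal(nrow(pooled$train), singles)
  expect_error(assemble_split(d, folds, "DoF12", character(0), 1),
               class = "wristemg_contract_error")
})

test_that("scenario definitions map to the protocol's runs and DoFs", {
  expect_equal(scenario_spec("DoF12")$runs, 1:2)
  expect_equal(scenario_spec("DoF13")$runs, 3:4)
  expect_equal(scenario_spec("DoF23")$runs, 5:6)
  expect_equal(scenario_spec("DoF123")$runs, 1:7)
  expect_equal(scenario_spec("DoF123")$dofs, 1:3)
  expect_equal(scenario_spec("DoF23")$dofs, c(2L, 3L))
  expect_error(scenario_spec("DoF1"), class = "wristemg_contract_error")
})

test_that("an invertible noiseless feature-angle map evaluates near 1", {
  d <- toy_session()
  g <- evaluate_session(d, scenarios = "DoF12", k = 5, seed = 2,
                        pooled = FALSE)
  intra <- g[g$type == "intra", ]
  expect_gt(min(intra$r2), 0.95)
})
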
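test_that("multivariate R^2 matches hand-computed cases", {
  tgt <- cbind(c(10, 20, 30), c(-5, 0, 5))
  expect_equal(multivariate_r2(tgt, tgt), 1)
  # estimating each DoF's temporal mean scores exactly 0
  means <- matrix(colMeans(tgt), 3, 2, byrow = TRUE)
  expect_equal(multivariate_r2(means, tgt), 0)
  # hand evaluation: est-tgt squared errors pool over DoFs before the
  # ratio. tgt DoF1 var-sum 200, DoF2 var-sum 50; est errors 100 and 50
  # -> R^2 = 1 - 150/250 = 0.4
  est <- cbind(c(10, 10, 30), c(-5, 5, 0))
  num <- sum((est - tgt)^2)
  den <- sum(sweep(tgt, 2, colMeans(tgt))^2)
  expect_equal(num, 150)
  expect_equal(den, 250)
  expect_equal(multivariate_r2(est, tgt), 0.4)
  # pooling is a single fraction, not a mean of per-DoF R^2 values
  per_dof_mean <- mean(c(1 - 100 / 200, 1 - 50 / 50))
  expect_false(isTRUE(all.equal(multivariate_r2(est, tgt),
                                per_dof_mean)))
})

test_that("multivariate R^2 equals the brute-force double sum", {
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      D <- sample(1:3, 1)
      tgt <- matrix(rnorm(n * D, sd = sample(c(0.1, 1, 50), 1)), n, D)
      est <- tgt + matrix(rnorm(n * D, sd = runif(1, 0, 2)), n, D)
      r <- multivariate_r2(est, tgt)
      expect_equal(r, oracle_r2(est, tgt), tolerance = 1e-12)
      expect_lte(r, 1)
    }
  })
})

test_that("R^2 is shift invariant and degrades monotonically with noise", {
  withr::with_seed(21, {
    tgt <- matrix(rnorm(200), 100, 2)
    est <- tgt + matrix(rnorm(200, sd = 0.3), 100, 2)
    expect_equal(multivariate_r2(est + 17, tgt + 17),
                 multivariate_r2(est, tgt), tolerance = 1e-12)
    sds <- c(0, 0.2, 0.5, 1, 2)
    r2s <- vapply(sds, function(s) {
      mean(vapply(1:30, function(i) {
        multivariate_r2(tgt + matrix(rnorm(200, sd = s), 100, 2), tgt)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(r2s) < 0))
  })
})

test_that("zero target variance is an undefined-metric error", {
  expect_error(multivariate_r2(cbind(1:3), cbind(rep(5, 3))),
               class = "wristemg_undefined_metric")
  expect_error(multivariate_r2(cbind(1:3), cbind(1:4)),
               class = "wristemg_contract_error")
})

# A hand-built grid: 2 scenarios x 2 positions x 2 folds.
hand_grid <- function() {
  g <- expand.grid(scenario = c("DoF12", "DoF123"),
                   train_pos = c("POS1", "POS2"),
                   test_pos = c("POS1", "POS2"), fold = 1:2,
                   stringsAsFactors = FALSE)
  g$type <- ifelse(g$train_pos == g$test_pos, "intra", "inter")
  g$r2 <- ifelse(g$type == "intra", 0.6, 0.3)
  g$n <- 100L
  tibble::as_tibble(g)
}

test_that("normalization divides by the fold-matched intra baseline", {
  g <- normalize_to_intra(hand_grid())
  expect_equal(g$r2_norm[g$type == "intra"],
               rep(1, sum(g$type == "intra")))
  expect_equal(g$r2_norm[g$type == "inter"],
               rep(0.5, sum(g$type == "inter")))
  # missing baseline is a contract error naming the key
  broken <- hand_grid()
  broken <- broken[!(broken$type == "intra" &
                       broken$train_pos == "POS2"), ]
  expect_error(normalize_to_intra(broken), "POS2",
               class = "wristemg_contract_error")
})

test_that("summaries aggregate the grid as documented", {
  g <- hand_grid()
  tb <- summarize_grid(g)
  s <- tb$summary
  expect_equal(s$mean_r2_pct[s$scenario == "DoF12" & s$type == "intra"],
               60)
  expect_equal(s$sd_r2_pct[s$scenario == "DoF12" & s$type == "intra"], 0)
  pm <- tb$position_matrix
  diag_rows <- pm$train_pos == pm$test_pos
  expect_equal(pm$mean_r2_norm[diag_rows], rep(1, sum(diag_rows)))
  expect_true(all(pm$mean_r2_norm[!diag_rows] < 1))
})

test_that("uniformly better pooled training is detected by the paired t test", {
  g <- hand_grid()
  pooled <- g[g$type == "intra", ]
  pooled$train_pos <- "POOLED"
  pooled$type <- "pooled"
  pooled$r2 <- 0.7
  gp <- dplyr::bind_rows(g, pooled)
  withr::with_seed(3, {
    # jitter so the paired differences have positive, nonzero variance
    gp$r2 <- gp$r2 + rnorm(nrow(gp), sd = 0.01)
  })
  tb <- summarize_grid(gp, pooling_tests = "inter")
  expect_true(all(tb$pooling$mean_diff_pct > 0))
  expect_true(all(tb$pooling$p_value < 0.05))
})
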
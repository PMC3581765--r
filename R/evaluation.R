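# Evaluation: multivariate R^2 over the scenario x position x fold grid,
# normalization of inter-position scores to their intra-position
# baselines, and the positional-pooling comparison.

#' Multivariate R-squared of a multi-DoF estimate
#'
#' `R^2 = 1 - sum_i sum_t (est_i(t) - tgt_i(t))^2 /
#'        sum_i sum_t (tgt_i(t) - mean_t tgt_i)^2`,
#' with squared errors and target variances pooled over all DoFs before
#' the ratio is formed (a single fraction, not a mean of per-DoF R^2
#' values). Equals 1 for a perfect estimate and 0 for an estimator that
#' returns each target's temporal mean; can be arbitrarily negative.
#'
#' @param estimates numeric matrix/data frame (rows = time or windows,
#'   one column per DoF), or a vector for a single DoF.
#' @param targets measured angles, same shape as `estimates`.
#' @return the multivariate R-squared (fraction, not percent).
#' @export
multivariate_r2 <- function(estimates, targets) {
  E <- as.matrix(estimates)
  A <- as.matrix(targets)
  if (!all(dim(E) == dim(A))) {
    stop_contract("estimates and targets must have matching dimensions")
  }
  if (!all(is.finite(E)) || !all(is.finite(A))) {
    stop_data("non-finite values in estimates or targets")
  }
  denom <- sum(sweep(A, 2, colMeans(A))^2)
  if (denom <= 0) {
    abort("total target variance is zero: R^2 undefined",
          class = "wristemg_undefined_metric")
  }
  1 - sum((E - A)^2) / denom
}

#' Evaluate a processed session over the full analysis grid
#'
#' For every analysis scenario, training configuration (each single
#' position, plus the positionally pooled training set), and
#' cross-validation fold, trains one MLP per scenario DoF on the training
#' rows and scores the multivariate R^2 on each test position. Intra-
#' position cells test on the fold's held-out blocks; inter-position
#' cells test on all rows of the other positions; pooled cells test on
#' the fold's held-out blocks of each position (the pooled training set
#' never sees them).
#'
#' @param data session feature table from [process_session()].
#' @param scenarios scenarios to evaluate (default all four).
#' @param k number of folds.
#' @param seed master seed (fold permutations and MLP initializations).
#' @param control an [mlp_control()].
#' @param pooled include the pooled-training configuration.
#' @param progress print one line per scenario.
#' @return a `wrist_eval_grid` tibble: `scenario`, `train_pos` (position
#'   label or `"POOLED"`), `test_pos`, `type` (`intra`/`inter`/`pooled`),
#'   `fold`, `r2`, `n` (test rows).
#' @export
evaluate_session <- function(data, scenarios = SCENARIOS, k = 5, seed = 1,
                             control = mlp_control(), pooled = TRUE,
                             progress = FALSE) {
  data <- as_tibble(data)
  positions <- intersect(POSITIONS, unique(data$position))
  folds <- make_folds(data, k = k, seed = seed)
  rows <- list()
  model_i <- 0L
  for (scenario in scenarios) {
    if (progress) message("evaluating ", scenario)
    sp <- scenario_spec(scenario)
    configs <- c(as.list(positions),
                 if (pooled && length(positions) > 1) list(positions))
    for (cfg in configs) {
      is_pooled <- length(cfg) > 1
      label <- if (is_pooled) "POOLED" else cfg
      for (fold in seq_len(k)) {
        split <- assemble_split(data, folds, scenario, cfg, fold)
        model_i <- model_i + 1L
        models <- lapply(sp$dofs, function(d) {
          train_mlp(split$train, d,
                    seed = derive_seed(seed, model_i * 10 + d),
                    control = control)
        })
        for (p in names(split$test)) {
          tt <- split$test[[p]]
          if (!nrow(tt)) next
          est <- vapply(models, function(m) predict(m, tt),
                        numeric(nrow(tt)))
          tgt <- as.matrix(tt[paste0("alpha", sp$dofs)])
          type <- if (is_pooled) "pooled" else attr(tt, "type")
          rows[[length(rows) + 1L]] <- tibble(
            scenario = scenario, train_pos = label, test_pos = p,
            type = type, fold = fold,
            r2 = multivariate_r2(est, tgt), n = nrow(tt))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("wrist_eval_grid", class(out)))
}

#' Normalize inter-position scores to their intra-position baselines
#'
#' Each single-position grid entry is divided by the intra-position R^2 of
#' the same scenario, training position and fold, yielding 1 on the
#' diagonal by construction. Pooled-training entries have no single-
#' position baseline and get `NA`. Non-positive baselines are flagged and
#' their cells dropped to `NA`.
#'
#' @param grid a grid from [evaluate_session()].
#' @return the grid with an `r2_norm` column.
#' @export
normalize_to_intra <- function(grid) {
  g <- as_tibble(grid)
  base <- g[g$type == "intra", c("scenario", "train_pos", "fold", "r2")]
  names(base)[names(base) == "r2"] <- "r2_intra"
  single <- g$train_pos != "POOLED"
  merged <- dplyr::left_join(g, base,
                             by = c("scenario", "train_pos", "fold"))
  missing <- single & is.na(merged$r2_intra)
  if (any(missing)) {
    key <- merged[which(missing)[1], c("scenario", "train_pos", "fold")]
    stop_contract(sprintf(
      "missing intra-position baseline for (%s, %s, fold %d)",
      key$scenario, key$train_pos, key$fold))
  }
  bad <- single & merged$r2_intra <= 0
  if (any(bad)) {
    warn(sprintf("%d cells dropped: non-positive intra baseline",
                 sum(bad)))
  }
  merged$r2_norm <- ifelse(single & !bad, merged$r2 / merged$r2_intra,
                           NA_real_)
  merged$r2_intra <- NULL
  structure(merged, class = c("wrist_eval_grid", class(merged)))
}

#' Summary tables of an evaluation grid
#'
#' Produces the three report tables: per-scenario mean +/- sd of the
#' intra- and inter-position R^2 (percent); the per-scenario
#' training x testing position matrix of mean normalized R^2 (diagonal 1
#' by construction); and the positional-pooling comparison with a
#' one-tailed paired t test (pooled vs matched single-position training,
#' paired by scenario, test position and fold).
#'
#' @param grid a grid from [evaluate_session()].
#' @param pooling_tests which single-position cells enter the pooling
#'   comparison: `"inter"` (default, the hard cases) or `"all"`.
#' @return list with tibbles `summary`, `position_matrix`, `pooling`.
#' @export
summarize_grid <- function(grid, pooling_tests = c("inter", "all")) {
  pooling_tests <- match.arg(pooling_tests)
  g <- as_tibble(grid)
  if (!"r2_norm" %in% names(g)) g <- normalize_to_intra(g)
  pct <- function(x) 100 * x
  summary <- dplyr::summarise(
    dplyr::group_by(g[g$type %in% c("intra", "inter"), ],
                    .data$scenario, .data$type),
    mean_r2_pct = pct(mean(.data$r2)),
    sd_r2_pct = pct(sd(.data$r2)), n_cells = dplyr::n(),
    .groups = "drop")
  position_matrix <- dplyr::summarise(
    dplyr::group_by(g[g$train_pos != "POOLED", ],
                    .data$scenario, .data$train_pos, .data$test_pos),
    mean_r2 = mean(.data$r2), mean_r2_norm = mean(.data$r2_norm),
    .groups = "drop")
  pooled <- g[g$type == "pooled",
              c("scenario", "test_pos", "fold", "r2")]
  names(pooled)[names(pooled) == "r2"] <- "r2_pooled"
  single <- g[g$train_pos != "POOLED" &
                (if (pooling_tests == "inter") g$type == "inter"
                 else g$type %in% c("intra", "inter")), ]
  pairs <- dplyr::inner_join(
    single[c("scenario", "train_pos", "test_pos", "fold", "r2")],
    pooled, by = c("scenario", "test_pos", "fold"))
  pooling <- dplyr::summarise(
    dplyr::group_by(pairs, .data$scenario),
    n_pairs = dplyr::n(),
    mean_single_pct = pct(mean(.data$r2)),
    mean_pooled_pct = pct(mean(.data$r2_pooled)),
    mean_diff_pct = pct(mean(.data$r2_pooled - .data$r2)),
    p_value = tryCatch(
      t.test(.data$r2_pooled, .data$r2, paired = TRUE,
             alternative = "greater")$p.value,
      error = function(e) NA_real_),
    .groups = "drop")
  list(summary = summary, position_matrix = position_matrix,
       pooling = pooling)
}

#' @export
glance.wrist_eval_grid <- function(x, ...) {
  g <- as_tibble(x)
  tibble(
    n_cells = nrow(g),
    intra_r2_mean = mean(g$r2[g$type == "intra"]),
    inter_r2_mean = mean(g$r2[g$type == "inter"]),
    pooled_r2_mean = if (any(g$type == "pooled"))
      mean(g$r2[g$type == "pooled"]) else NA_real_)
}
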
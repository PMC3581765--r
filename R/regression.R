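# Contralateral MLP regression.
#
# One small multilayer perceptron per DoF maps the 70-dimensional TDAR
# feature vector of the control side to the contralateral measured joint
# angle. Three hidden units (as in the study), linear output, fitted by
# nnet with weight-decay regularization; inputs are z-scored with
# statistics computed on the training set only, targets stay in degrees.

#' MLP training hyperparameters
#'
#' With only three hidden units, randomly initialized training stalls in
#' poor local minima on a substantial fraction of starts. The default
#' therefore warm-starts the network at the ridge-regression solution of
#' the same problem: the hidden layer is initialized in its near-linear
#' operating range so the initial network output equals the regularized
#' linear predictor (plus a small seeded jitter to break symmetry), and
#' the optimizer refines from there.
#'
#' @param hidden hidden-layer size (3, the study's choice).
#' @param decay weight-decay regularization passed to [nnet::nnet()].
#' @param maxit maximum optimizer iterations.
#' @param warm_start initialize at the ridge solution (recommended);
#'   `FALSE` uses nnet's random initialization.
#' @param ridge_lambda ridge penalty (times `n`) for the warm start.
#' @return an `mlp_control` list.
#' @export
mlp_control <- function(hidden = 3, decay = 1e-4, maxit = 300,
                        warm_start = TRUE, ridge_lambda = 1e-3) {
  structure(list(hidden = as.integer(hidden), decay = decay,
                 maxit = as.integer(maxit),
                 warm_start = isTRUE(warm_start),
                 ridge_lambda = ridge_lambda), class = "mlp_control")
}

# Initial nnet weight vector placing the network at the ridge predictor.
# nnet weight order: per hidden unit (bias, inputs), then output
# (bias, hidden). With small input weights the logistic hidden units are
# near-linear: sigma(z) ~ 0.5 + z/4, so output weights 4/(H*delta) make
# the net compute mean(y) + X beta at initialization.
warm_start_wts <- function(Xs, y, hidden, lambda) {
  p <- ncol(Xs)
  beta <- tryCatch(
    solve(crossprod(Xs) + lambda * nrow(Xs) * diag(p),
          crossprod(Xs, y - mean(y))),
    error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  delta <- 0.1
  w_out <- 4 / (hidden * delta)
  c(unlist(lapply(seq_len(hidden), function(j) {
    c(0, delta * beta) * (1 + 0.02 * rnorm(p + 1))
  })),
  mean(y) - hidden * w_out * 0.5, rep(w_out, hidden))
}

#' Train one DoF-angle MLP on windowed features
#'
#' @param data a data frame holding feature columns (`ch<k>_<feature>`,
#'   see [extract_features()]) and target columns `alpha1..alpha3`.
#' @param dof which DoF angle to regress (1, 2 or 3).
#' @param seed seed for the (random) initial weights; training is
#'   deterministic given `seed` and `data`.
#' @param control an [mlp_control()].
#' @return a `wrist_mlp` model object (supports [predict()], [tidy()] and
#'   [glance()]).
#' @export
train_mlp <- function(data, dof, seed = 1, control = mlp_control()) {
  if (!dof %in% 1:3) stop_contract("dof must be 1, 2 or 3")
  fc <- feature_cols(data)
  if (!length(fc)) stop_contract("no feature columns in `data`")
  tcol <- paste0("alpha", dof)
  if (!tcol %in% names(data)) {
    stop_contract(sprintf("target column %s not found", tcol))
  }
  X <- as.matrix(data[fc])
  y <- data[[tcol]]
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_data("non-finite values in features or targets")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1  # constant-feature guard
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  degenerate <- sd(y) == 0
  fit <- NULL
  if (!degenerate) {
    fit <- withr::with_seed(seed, {
      wts <- if (control$warm_start) {
        warm_start_wts(Xs, y, control$hidden, control$ridge_lambda)
      }
      args <- list(Xs, matrix(y, ncol = 1), size = control$hidden,
                   linout = TRUE, decay = control$decay,
                   maxit = control$maxit, trace = FALSE, MaxNWts = 5000)
      if (!is.null(wts)) args$Wts <- wts
      do.call(nnet::nnet, args)
    })
    if (any(!is.finite(fit$wts))) {
      stop_data("MLP training diverged (non-finite weights)")
    }
  } else {
    warn("constant training targets: R^2 is undefined for this model",
         class = "wristemg_degenerate_target")
  }
  pred <- if (degenerate) rep(mean(y), length(y))
          else as.numeric(predict(fit, Xs))
  structure(list(fit = fit, center = center, scale = scale_,
                 features = fc, dof = dof, seed = seed, control = control,
                 degenerate = degenerate, constant = mean(y),
                 n_train = length(y),
                 train_rmse = sqrt(mean((pred - y)^2)),
                 train_r2 = if (degenerate) NA_real_ else
                   1 - sum((pred - y)^2) / sum((y - mean(y))^2)),
            class = "wrist_mlp")
}

#' Predict DoF angles from features
#'
#' @param object a `wrist_mlp` from [train_mlp()].
#' @param newdata data frame holding the model's feature columns.
#' @param ... unused.
#' @return numeric vector of angle estimates (degrees), one per row.
#' @export
predict.wrist_mlp <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop_contract(paste("missing feature columns:",
                        paste(head(miss, 3), collapse = ", ")))
  }
  X <- as.matrix(newdata[object$features])
  if (object$degenerate) return(rep(object$constant, nrow(X)))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  as.numeric(predict(object$fit, Xs))
}

#' @export
print.wrist_mlp <- function(x, ...) {
  cat(sprintf(
    "<wrist_mlp> DoF%d: %d features -> %d hidden -> 1, n=%d, train RMSE %.2f deg\n",
    x$dof, length(x$features), x$control$hidden, x$n_train, x$train_rmse))
  invisible(x)
}

#' @rdname train_mlp
#' @param x a `wrist_mlp`.
#' @param ... unused.
#' @export
tidy.wrist_mlp <- function(x, ...) {
  if (x$degenerate) return(tibble(term = character(), estimate = double()))
  wts <- stats::coef(x$fit)
  tibble(term = names(wts), estimate = as.numeric(wts))
}

#' @rdname train_mlp
#' @export
glance.wrist_mlp <- function(x, ...) {
  tibble(dof = x$dof, n_train = x$n_train,
         n_weights = if (x$degenerate) 0L else length(x$fit$wts),
         converged = if (x$degenerate) NA else x$fit$convergence == 0,
         train_rmse = x$train_rmse, train_r2 = x$train_r2)
}

#' Contiguous-block 5-fold splits per run
#'
#' Each (position, run) window sequence is partitioned into `k` contiguous
#' blocks whose sizes differ by at most one; the block-to-fold assignment
#' is a seeded random permutation per run. Fold `i` tests block `i` of
#' every run and trains on the rest, so 4/5 of each run's data trains and
#' 1/5 tests, while the contiguous blocks prevent leakage between
#' overlapping neighbour windows.
#'
#' @param data a data frame with columns `position`, `run`, `window`
#'   (e.g. from [process_session()]).
#' @param k number of folds (5 in the study).
#' @param seed seed for the block-to-fold permutations.
#' @return a tibble `position`, `run`, `block`, `fold`, `from`, `to`
#'   (inclusive window-index ranges).
#' @export
make_folds <- function(data, k = 5, seed = 1) {
  need <- c("position", "run", "window")
  if (!all(need %in% names(data))) {
    stop_contract("data must have position, run and window columns")
  }
  groups <- dplyr::summarise(
    dplyr::group_by(as_tibble(data), .data$position, .data$run),
    n = dplyr::n(), lo = min(.data$window), .groups = "drop")
  if (any(groups$n < k)) {
    stop_contract(sprintf("each run needs at least %d windows", k))
  }
  out <- purrr::pmap(groups, function(position, run, n, lo) {
    sizes <- rep(n %/% k, k)
    rem <- n %% k
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    to <- cumsum(sizes) + lo - 1L
    from <- to - sizes + 1L
    perm <- withr::with_seed(
      derive_seed(seed, match(position, POSITIONS) * 1000 +
                    as.integer(run)),
      sample.int(k))
    tibble(position = position, run = run, block = seq_len(k),
           fold = perm, from = from, to = to)
  })
  dplyr::bind_rows(out)
}

#' Runs and DoFs of an analysis scenario
#'
#' Scenario `DoF12` uses runs 1-2 and estimates DoF1 and DoF2; `DoF13`
#' runs 3-4, `DoF23` runs 5-6, and `DoF123` all seven runs and all three
#' DoFs.
#'
#' @param scenario one of `"DoF12"`, `"DoF13"`, `"DoF23"`, `"DoF123"`.
#' @return list with integer vectors `runs` and `dofs`.
#' @export
scenario_spec <- function(scenario) {
  switch(scenario,
         DoF12 = list(runs = 1:2, dofs = c(1L, 2L)),
         DoF13 = list(runs = 3:4, dofs = c(1L, 3L)),
         DoF23 = list(runs = 5:6, dofs = c(2L, 3L)),
         DoF123 = list(runs = 1:7, dofs = 1:3),
         stop_contract("unknown scenario"))
}

# Tag each row of a session feature table with its fold (NA outside the
# fold table).
row_folds <- function(data, folds) {
  f <- rep(NA_integer_, nrow(data))
  for (i in seq_len(nrow(folds))) {
    sel <- data$position == folds$position[i] &
      data$run == folds$run[i] &
      data$window >= folds$from[i] & data$window <= folds$to[i]
    f[sel] <- folds$fold[i]
  }
  f
}

#' Assemble the train/test split of one evaluation cell
#'
#' Training rows are the fold's training blocks of the scenario's runs at
#' the training position(s) (concatenated when pooled over positions).
#' Intra-position test rows are the fold's held-out blocks at each
#' training position; inter-position test rows are all rows of the
#' scenario's runs at each non-training position.
#'
#' Because neighbouring analysis windows overlap by 60 ms, the test
#' windows at a block boundary share samples with training windows; the
#' `guard` parameter drops held-out test windows within that many window
#' indices of any training window of the same run, so no test window's
#' sample span intersects the training data (2 = the overlap radius of
#' the default 100 ms / 40 ms-step windows).
#'
#' @param data session feature table ([process_session()]).
#' @param folds fold table from [make_folds()].
#' @param scenario analysis scenario (see [scenario_spec()]).
#' @param train_positions character vector of training positions (length
#'   1, or all three for positional pooling).
#' @param fold fold index in `1..k`.
#' @param guard leakage guard radius in window indices (see above; 0
#'   disables it).
#' @return list with `train` (tibble) and `test` (named list of tibbles,
#'   one per test position, each with a `type` attribute `"intra"` or
#'   `"inter"`).
#' @export
assemble_split <- function(data, folds, scenario, train_positions, fold,
                           guard = 2) {
  sp <- scenario_spec(scenario)
  data <- as_tibble(data)
  if (!length(train_positions)) stop_contract("empty training selection")
  keep <- data$run %in% sp$runs
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop_contract("no rows for this scenario")
  ff <- row_folds(data, folds[folds$run %in% sp$runs, ])
  in_train_pos <- data$position %in% train_positions
  train <- data[in_train_pos & ff != fold, , drop = FALSE]
  test <- list()
  for (p in intersect(POSITIONS, unique(data$position))) {
    if (p %in% train_positions) {
      sel <- data$position == p & ff == fold
      if (guard > 0 && any(sel)) {
        # drop held-out windows whose sample span overlaps training
        for (r in unique(data$run[sel])) {
          in_run <- data$position == p & data$run == r
          trainw <- data$window[in_run & ff != fold]
          testw <- which(sel & data$run == r)
          if (length(trainw) && length(testw)) {
            near <- vapply(data$window[testw], function(w) {
              min(abs(w - trainw)) <= guard
            }, logical(1))
            sel[testw[near]] <- FALSE
          }
        }
      }
      tt <- data[sel, , drop = FALSE]
      attr(tt, "type") <- "intra"
    } else {
      tt <- data[data$position == p, , drop = FALSE]
      attr(tt, "type") <- "inter"
    }
    test[[p]] <- tt
  }
  if (!nrow(train)) stop_contract("empty training set")
  list(train = train, test = test)
}
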
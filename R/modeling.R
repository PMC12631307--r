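#' Root mean squared error
#' @param pred,obs numeric vectors of equal positive length.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (!length(pred)) stop("rmse: empty input")
  sqrt(mean((pred - obs)^2))
}

#' Spearman rank correlation with average-rank tie handling
#'
#' @param pred,obs numeric vectors, length >= 3.
#' @return Correlation in [-1, 1], or `NA` with a warning when either
#'   vector is constant (the coefficient is undefined).
#' @export
spearman_rho <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 3) stop("spearman_rho: need at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("spearman_rho undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(pred, obs, method = "spearman")
}

# ---- single-task random-forest baseline -------------------------------------

#' Single-task random-forest baseline for one endpoint
#'
#' Trains a 500-tree random forest on molecular descriptors for a single
#' endpoint. Being single-task, it can exhibit no cross-endpoint learning or
#' leakage, which makes it the reference point for quantifying the benefit
#' of multitask training.
#'
#' @param table a `multitask_table` (training values are taken from its
#'   observed cells, optionally restricted by `train_smiles`).
#' @param endpoint one of [endpoint_names()].
#' @param descriptors numeric descriptor matrix, rownames = compound SMILES
#'   (typically `compute_descriptors(..., set = "baseline_full")`).
#' @param seed integer seed.
#' @param train_smiles optional compound subset to train on.
#' @param num_trees forest size (default 500).
#' @param importance variable-importance mode passed to ranger (default
#'   `"permutation"`, required by [rank_descriptors()]).
#' @return Object of class `stl_model`.
#' @export
fit_stl_baseline <- function(table, endpoint, descriptors, seed = 1,
                             train_smiles = NULL, num_trees = 500,
                             importance = "permutation") {
  stopifnot(inherits(table, "multitask_table"), endpoint %in% endpoint_names())
  smi <- rownames(table$mask)
  obs <- smi[table$mask[, endpoint]]
  if (!is.null(train_smiles)) obs <- intersect(obs, train_smiles)
  if (length(obs) < 20) {
    stop(sprintf("fit_stl_baseline: %s has %d training records, need >= 20",
                 endpoint, length(obs)))
  }
  x <- descriptors[obs, , drop = FALSE]
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- impute_with(x, med)
  y <- table$values[obs, endpoint]
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        importance = importance, seed = seed,
                        num.threads = 1)
  structure(list(forest = fit, endpoint = endpoint,
                 features = colnames(descriptors), medians = med, seed = seed),
            class = "stl_model")
}

impute_with <- function(x, med) {
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[[j]]
  }
  x
}

#' Predict from a single-task baseline
#' @param object an `stl_model`.
#' @param descriptors descriptor matrix for the compounds to predict
#'   (rownames = SMILES), same columns as used in fitting.
#' @param ... ignored.
#' @return Named numeric vector of predictions.
#' @export
predict.stl_model <- function(object, descriptors, ...) {
  x <- impute_with(descriptors[, object$features, drop = FALSE], object$medians)
  p <- stats::predict(object$forest, data = as.data.frame(x), num.threads = 1)
  stats::setNames(p$predictions, rownames(descriptors))
}

#' Rank descriptors by attribution for each endpoint
#'
#' Ranks descriptors by mean absolute permutation importance from the
#' single-task random-forest baseline of each endpoint, the package's
#' tree-ensemble attribution method. This is how the structural descriptors
#' offered to the augmented multitask models are selected.
#'
#' @param models a single `stl_model` or a named list of them (per endpoint).
#' @param top_k how many descriptor names to return per endpoint (the full
#'   ranking when `top_k` exceeds the descriptor count).
#' @return Named list (per endpoint) of character vectors of descriptor
#'   names, most important first.
#' @export
rank_descriptors <- function(models, top_k = 5) {
  if (inherits(models, "stl_model")) models <- list(models)
  lapply(stats::setNames(models, vapply(models, function(m) m$endpoint, "")),
         function(m) {
    if (!inherits(m, "stl_model")) stop("rank_descriptors: not a fitted stl_model")
    imp <- m$forest$variable.importance
    if (is.null(imp)) {
      stop("rank_descriptors: baseline was fitted without importance; refit with importance = 'permutation'")
    }
    names(sort(abs(imp), decreasing = TRUE))[seq_len(min(top_k, length(imp)))]
  })
}

# ---- multitask regressor ----------------------------------------------------

#' Fit the masked-loss multitask regressor
#'
#' Trains a feed-forward network that maps molecular features to a 4-vector
#' of endpoint predictions, minimising mean squared error over observed
#' cells only ([masked_loss()]). Targets are standardized per task over the
#' observed training cells and de-standardized at prediction; a task with no
#' observed training cells inherits pooled statistics from the other tasks.
#' Early stopping monitors a held-out slice of the training compounds.
#'
#' The molecular encoder is pluggable: by default compounds are encoded with
#' [fingerprint_matrix()], optionally concatenated with a descriptor block
#' (the "+"/"++" augmentation). Passing `features` directly bypasses the
#' encoder, e.g. to use an external graph embedding.
#'
#' @param table a `multitask_table`; training uses its observed cells,
#'   optionally restricted to `train_records`.
#' @param descriptors optional descriptor matrix (rownames = SMILES)
#'   concatenated to the encoding; columns are z-scored using training
#'   statistics and median-imputed per training set.
#' @param features optional precomputed feature matrix (rownames = SMILES)
#'   replacing the fingerprint encoder.
#' @param config an [mtl_config()].
#' @param seed integer seed controlling initialisation, minibatching and the
#'   early-stopping holdout.
#' @param train_records optional data.frame (`smiles_std`, `endpoint`)
#'   restricting which observed cells are trained on (split-plan rounds).
#' @return Object of class `mtl_model`.
#' @export
fit_mtl <- function(table, descriptors = NULL, features = NULL,
                    config = mtl_config(), seed = 1, train_records = NULL) {
  stopifnot(inherits(table, "multitask_table"))
  smi <- rownames(table$mask)
  mask <- table$mask
  if (!is.null(train_records)) {
    keep <- matrix(FALSE, nrow(mask), ncol(mask), dimnames = dimnames(mask))
    keep[cbind(match(train_records$smiles_std, smi),
               match(train_records$endpoint, colnames(mask)))] <- TRUE
    mask <- mask & keep
  }
  used <- rowSums(mask) > 0
  if (!any(used)) stop("fit_mtl: no training records")
  n_tasks_obs <- sum(colSums(mask) > 0)
  if (n_tasks_obs < 2) {
    warning("fit_mtl: training data cover a single endpoint; model degenerates to single-task")
  }
  smi_tr <- smi[used]

  if (is.null(features)) {
    fp <- fingerprint_matrix(smi_tr)
    encoder <- "fingerprint"
  } else {
    fp <- features[smi_tr, , drop = FALSE]
    encoder <- "external"
  }
  desc_stats <- NULL
  if (!is.null(descriptors)) {
    d <- descriptors[smi_tr, , drop = FALSE]
    med <- apply(d, 2, stats::median, na.rm = TRUE)
    d <- impute_with(d, med)
    mu <- colMeans(d); sd <- apply(d, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    desc_stats <- list(median = med, mu = mu, sd = sd,
                       cols = colnames(descriptors))
    d <- sweep(sweep(d, 2, mu), 2, sd, "/")
    fp <- cbind(fp, d)
  }

  Yraw <- table$values[smi_tr, , drop = FALSE]
  M <- (mask[smi_tr, , drop = FALSE]) * 1
  mu_t <- sd_t <- rep(NA_real_, ncol(Yraw))
  for (t in seq_len(ncol(Yraw))) {
    obs <- M[, t] > 0
    if (sum(obs) >= 2) {
      mu_t[t] <- mean(Yraw[obs, t]); sd_t[t] <- stats::sd(Yraw[obs, t])
    } else if (sum(obs) == 1) {
      mu_t[t] <- Yraw[obs, t][1]; sd_t[t] <- NA_real_
    }
  }
  pool_mu <- mean(mu_t, na.rm = TRUE); pool_sd <- mean(sd_t, na.rm = TRUE)
  zero_shot <- is.na(mu_t)
  mu_t[is.na(mu_t)] <- pool_mu
  sd_t[is.na(sd_t) | sd_t == 0] <- if (is.finite(pool_sd) && pool_sd > 0) pool_sd else 1
  Y <- sweep(sweep(Yraw, 2, mu_t), 2, sd_t, "/")
  Y[M == 0] <- 0

  fit <- nn_train(fp, Y, M, config, seed)
  structure(list(par = fit$par, val_loss = fit$loss, epochs = fit$epoch,
                 mu = mu_t, sigma = sd_t, zero_shot = zero_shot,
                 encoder = encoder, n_features = ncol(fp),
                 desc_stats = desc_stats, config = config, seed = seed),
            class = "mtl_model")
}

#' @export
print.mtl_model <- function(x, ...) {
  cat(sprintf("mtl_model: %s encoder, %d features, stopped at epoch %d (val loss %.4f)\n",
              x$encoder, x$n_features, x$epochs,
              if (is.na(x$val_loss)) NaN else x$val_loss))
  if (any(x$zero_shot)) {
    cat("  zero-shot endpoints:",
        paste(endpoint_names()[x$zero_shot], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict all four endpoints for new compounds
#'
#' @param object an `mtl_model`.
#' @param smiles character vector of standardized SMILES (used with the
#'   fingerprint encoder), or `NULL` when `features` is given.
#' @param descriptors descriptor matrix for the same compounds, required if
#'   the model was fitted with one.
#' @param features precomputed feature matrix (external encoder).
#' @param ... ignored.
#' @return Numeric matrix, one row per compound, columns in the fixed
#'   endpoint order.
#' @export
predict.mtl_model <- function(object, smiles = NULL, descriptors = NULL,
                              features = NULL, ...) {
  if (is.null(features)) {
    if (object$encoder != "fingerprint" || is.null(smiles)) {
      stop("model uses an external encoder; supply `features`")
    }
    x <- fingerprint_matrix(smiles)
  } else {
    x <- features
    if (!is.null(smiles)) x <- x[smiles, , drop = FALSE]
  }
  if (!is.null(object$desc_stats)) {
    if (is.null(descriptors)) stop("model was fitted with descriptors; supply them")
    d <- descriptors[rownames(x), object$desc_stats$cols, drop = FALSE]
    d <- impute_with(d, object$desc_stats$median)
    d <- sweep(sweep(d, 2, object$desc_stats$mu), 2, object$desc_stats$sd, "/")
    x <- cbind(x, d)
  }
  P <- nn_forward(object$par, x)$P
  P <- sweep(sweep(P, 2, object$sigma, "*"), 2, object$mu, "+")
  dimnames(P) <- list(rownames(x), endpoint_names())
  P
}

# ---- benchmarking -----------------------------------------------------------

#' Benchmark models across split strategies
#'
#' Runs each requested model on each round of each split plan, computing the
#' per-endpoint test RMSE. Features (fingerprints, descriptors) are computed
#' once per table and reused. For temporal plans the per-round leakage
#' percentages are joined onto the results; for modality plans the metrics
#' are additionally grouped by modality. A model failure on one round is
#' recorded as `NA` and the run continues.
#'
#' Models: `"rf"` (single-task forest baseline on the full descriptor set),
#' `"mtl"` (fingerprint multitask net), `"mtl_plus"` (+ physchem proxies),
#' `"mtl_plusplus"` (+ proxies and structural descriptors).
#'
#' @param table a `multitask_table`.
#' @param plans a `split_plan` or list of them.
#' @param models character subset of `c("rf", "mtl", "mtl_plus", "mtl_plusplus")`.
#' @param seed integer seed.
#' @param config an [mtl_config()] for the neural models.
#' @param feature_cache optional precomputed list with elements `fp`,
#'   `desc_full`, `desc_plus`, `desc_pp` (from [benchmark_features()]).
#' @return data.frame with columns `model`, `strategy`, `endpoint`,
#'   (`modality`,) `round`, `rmse`, `n_test`, `seed` and, for temporal
#'   strategies, `test_pct` and `train_overlap_pct`.
#' @export
benchmark <- function(table, plans, models = c("rf", "mtl", "mtl_plusplus"),
                      seed = 1, config = mtl_config(), feature_cache = NULL) {
  stopifnot(inherits(table, "multitask_table"))
  if (inherits(plans, "split_plan")) plans <- list(plans)
  models <- match.arg(models, c("rf", "mtl", "mtl_plus", "mtl_plusplus"),
                      several.ok = TRUE)
  fc <- feature_cache %||% benchmark_features(rownames(table$mask), models)
  out <- list()
  for (plan in plans) {
    leak <- if (startsWith(plan$strategy, "temporal")) leakage_report(plan, table)
    for (r in plan$rounds) {
      for (mod in models) {
        res <- tryCatch(
          eval_round(table, r, mod, fc, seed, config,
                     modality = if (plan$strategy == "modality_cv") plan$params$modality),
          error = function(e) {
            warning(sprintf("benchmark: %s failed on %s round %s: %s",
                            mod, plan$strategy, format(r$round), conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        res$model <- mod; res$strategy <- plan$strategy
        res$round <- r$round; res$seed <- seed
        if (!is.null(leak)) {
          j <- match(paste(res$endpoint, res$round),
                     paste(leak$endpoint, leak$round))
          res$test_pct <- leak$test_pct[j]
          res$train_overlap_pct <- leak$train_overlap_pct[j]
        }
        out[[length(out) + 1]] <- res
      }
    }
  }
  lead <- c("model", "strategy", "endpoint", "round", "rmse", "n_test", "seed")
  all_cols <- Reduce(union, c(list(lead), lapply(out, names)))
  out <- do.call(rbind, lapply(out, function(d) {
    for (cn in setdiff(all_cols, names(d))) d[[cn]] <- NA
    d[, all_cols, drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Precompute the feature blocks used by [benchmark()]
#' @param smiles compound SMILES (table rownames).
#' @param models which models will be run (controls what is computed).
#' @return List with elements `fp`, `desc_full`, `desc_plus`, `desc_pp`.
#' @export
benchmark_features <- function(smiles, models = c("rf", "mtl", "mtl_plusplus")) {
  list(
    fp = if (any(models != "rf")) fingerprint_matrix(smiles),
    desc_full = if ("rf" %in% models) compute_descriptors(smiles, "baseline_full"),
    desc_plus = if ("mtl_plus" %in% models) compute_descriptors(smiles, "plus"),
    desc_pp = if ("mtl_plusplus" %in% models) compute_descriptors(smiles, "plusplus")
  )
}

eval_round <- function(table, round, model, fc, seed, config, modality = NULL) {
  test <- round$test
  if (!nrow(test)) return(NULL)
  if (model == "rf") {
    preds <- rep(NA_real_, nrow(test))
    for (ep in unique(test$endpoint)) {
      train_smi <- unique(round$train$smiles_std[round$train$endpoint == ep])
      fit <- fit_stl_baseline(table, ep, fc$desc_full, seed = seed,
                              train_smiles = train_smi)
      sel <- test$endpoint == ep
      p <- predict(fit, fc$desc_full[unique(test$smiles_std[sel]), , drop = FALSE])
      preds[sel] <- p[test$smiles_std[sel]]
    }
  } else {
    desc <- switch(model, mtl = NULL, mtl_plus = fc$desc_plus,
                   mtl_plusplus = fc$desc_pp)
    fit <- fit_mtl(table, descriptors = desc, features = fc$fp,
                   config = config, seed = seed, train_records = round$train)
    P <- predict(fit, smiles = unique(test$smiles_std), descriptors = desc,
                 features = fc$fp)
    preds <- P[cbind(test$smiles_std, test$endpoint)]
  }
  obs <- table$values[cbind(test$smiles_std, test$endpoint)]
  grp <- if (is.null(modality)) {
    data.frame(endpoint = test$endpoint, stringsAsFactors = FALSE)
  } else {
    data.frame(endpoint = test$endpoint,
               modality = unname(modality[test$smiles_std]),
               stringsAsFactors = FALSE)
  }
  keys <- unique(grp)
  res <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(grp))
    for (cn in names(keys)) sel <- sel & grp[[cn]] == keys[[cn]][i]
    ok <- sel & !is.na(preds)
    cbind(keys[i, , drop = FALSE],
          data.frame(rmse = if (any(ok)) rmse(preds[ok], obs[ok]) else NA_real_,
                     n_test = sum(ok)))
  }))
  rownames(res) <- NULL
  res
}

#' Mean and standard deviation of RMSE across rounds
#'
#' Collapses a [benchmark()] result to one row per (model, strategy,
#' endpoint), the shape in which repeated-holdout results are reported.
#'
#' @param results data.frame from [benchmark()].
#' @return data.frame with `rmse_mean`, `rmse_sd`, `n_rounds`.
#' @export
summarize_benchmark <- function(results) {
  key <- interaction(results$model, results$strategy, results$endpoint, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(model = d$model[1], strategy = d$strategy[1],
               endpoint = d$endpoint[1],
               rmse_mean = mean(d$rmse, na.rm = TRUE),
               rmse_sd = stats::sd(d$rmse, na.rm = TRUE),
               n_rounds = sum(!is.na(d$rmse)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
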
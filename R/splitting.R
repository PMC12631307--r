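# Train/test assignment strategies for sparse multiendpoint tables.
#
# Compound-level strategies (stratified-random, scaffold-balanced, k-fold,
# modality CV) move a compound's observed cells together; the temporal
# strategies operate at (compound, endpoint) record granularity, which is
# what makes the "leaky" variant leaky.

new_split_plan <- function(strategy, rounds, seed, params = list()) {
  structure(list(strategy = strategy, rounds = rounds, seed = seed,
                 params = params),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan [%s], %d round(s), seed %s\n", x$strategy,
              length(x$rounds), format(x$seed)))
  for (r in x$rounds) {
    cat(sprintf("  round %s: %d train / %d test records\n",
                format(r$round), nrow(r$train), nrow(r$test)))
  }
  invisible(x)
}

#' Flatten a split plan to a long data.frame
#' @param x a `split_plan`.
#' @param ... ignored.
#' @return data.frame with columns `smiles_std`, `endpoint`, `round`, `role`.
#' @export
as.data.frame.split_plan <- function(x, ...) {
  do.call(rbind, lapply(x$rounds, function(r) {
    rbind(cbind(r$train, round = r$round, role = "train",
                stringsAsFactors = FALSE),
          cbind(r$test, round = r$round, role = "test",
                stringsAsFactors = FALSE))
  }))
}

table_records <- function(table) {
  stopifnot(inherits(table, "multitask_table"))
  idx <- which(table$mask, arr.ind = TRUE)
  data.frame(smiles_std = rownames(table$mask)[idx[, 1]],
             endpoint = colnames(table$mask)[idx[, 2]],
             date = table$date[idx],
             stringsAsFactors = FALSE)
}

records_of <- function(table, smiles) {
  rec <- table_records(table)
  rec[rec$smiles_std %in% smiles, c("smiles_std", "endpoint"), drop = FALSE]
}

#' Stratified-random repeated holdout split
#'
#' Assigns whole compounds to train or test at random, holding the
#' distribution of endpoint-availability patterns constant: the strata are
#' the observed endpoint subsets (up to 15 patterns over 4 endpoints), and
#' `round(n * test_frac)` compounds of each stratum go to test in each
#' repeat. Repeats are independent draws, giving an n-repeat holdout
#' validation.
#'
#' @param table a `multitask_table`.
#' @param test_frac fraction of compounds designated as test (default 0.2).
#' @param n_repeats number of independent holdout draws (default 5).
#' @param seed integer seed; identical seeds give identical plans.
#' @return A `split_plan` with one round per repeat.
#' @export
stratified_random_split <- function(table, test_frac = 0.2, n_repeats = 5, seed = 1) {
  stopifnot(inherits(table, "multitask_table"), nrow(table$mask) > 0)
  pattern <- apply(table$mask, 1, function(m) paste(as.integer(m), collapse = ""))
  smi <- rownames(table$mask)
  strata <- split(smi, pattern)
  small <- names(strata)[lengths(strata) < 1 / test_frac]
  if (length(small)) {
    warning(sprintf("%d stratum/strata smaller than 1/test_frac; best-effort assignment",
                    length(small)))
  }
  rounds <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    test_smi <- unlist(lapply(strata, function(s) {
      k <- floor(length(s) * test_frac + 0.5)
      if (k == 0) return(character(0))
      sample(s, k)
    }), use.names = FALSE)
    list(round = r,
         train = records_of(table, setdiff(smi, test_smi)),
         test = records_of(table, test_smi))
  }))
  new_split_plan("stratified_random", rounds, seed,
                 list(test_frac = test_frac, n_repeats = n_repeats))
}

#' Scaffold-balanced split with no scaffold overlap
#'
#' Groups compounds by Bemis-Murcko scaffold and assigns whole scaffold
#' groups greedily: groups are visited in order of decreasing size (ties
#' broken by scaffold string; repeats shuffle equal-size blocks under the
#' seed) and each group goes to the split - train or test - with the largest
#' remaining deficit relative to its target size. Train and test therefore
#' never share a scaffold. Acyclic compounds form one shared empty-scaffold
#' group.
#'
#' @param table a `multitask_table`.
#' @param test_frac target test fraction of compounds (default 0.2).
#' @param n_repeats number of repeats differing in tie-breaking (default 5).
#' @param seed integer seed.
#' @param scaffolds optional named character vector (names = compound
#'   SMILES) of precomputed scaffolds; computed with
#'   [bemis_murcko_scaffold()] when absent.
#' @return A `split_plan`; each round records its scaffold assignment in
#'   `params`.
#' @export
scaffold_balanced_split <- function(table, test_frac = 0.2, n_repeats = 5,
                                    seed = 1, scaffolds = NULL) {
  stopifnot(inherits(table, "multitask_table"), nrow(table$mask) > 0)
  smi <- rownames(table$mask)
  if (is.null(scaffolds)) {
    scaffolds <- stats::setNames(bemis_murcko_scaffold(smi), smi)
  }
  scaffolds <- scaffolds[smi]
  groups <- split(smi, scaffolds[smi])
  n <- length(smi)
  target_test <- test_frac * n
  target_train <- (1 - test_frac) * n
  if (max(lengths(groups)) > target_train) {
    warning("a scaffold group exceeds the training target size; assigned to train")
  }
  rounds <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    sz <- lengths(groups)
    ord <- order(-sz, names(groups))
    # shuffle blocks of equal size so repeats differ
    perm <- unlist(lapply(split(ord, sz[ord]),
                          function(ix) if (length(ix) == 1) ix else sample(ix)),
                   use.names = FALSE)
    ord <- perm[order(-sz[perm])]
    n_train <- 0; n_test <- 0
    test_groups <- character(0)
    for (g in ord) {
      k <- sz[g]
      deficit_train <- target_train - n_train
      deficit_test <- target_test - n_test
      if (deficit_test > deficit_train && k <= max(0, ceiling(deficit_test))) {
        test_groups <- c(test_groups, names(groups)[g])
        n_test <- n_test + k
      } else {
        n_train <- n_train + k
      }
    }
    test_smi <- unlist(groups[test_groups], use.names = FALSE)
    list(round = r,
         train = records_of(table, setdiff(smi, test_smi)),
         test = records_of(table, test_smi))
  }))
  new_split_plan("scaffold_balanced", rounds, seed,
                 list(test_frac = test_frac, n_repeats = n_repeats,
                      scaffolds = scaffolds))
}

#' Temporal rounds: leaky and all-for-one
#'
#' All (compound, endpoint) records are sorted globally by timestamp (ties
#' broken by SMILES then endpoint for a total order). Round r trains on the
#' oldest fraction of records given by `train_fracs[r]` and tests on the
#' remainder, so training sets are nested across rounds. In `"leaky"` mode a
#' compound may train on one endpoint while being tested on another; in
#' `"all_for_one"` mode any training record whose SMILES occurs anywhere in
#' that round's test set is removed from training.
#'
#' @param records data.frame with columns `smiles_std`, `endpoint`, `date`
#'   (or `earliest_date`), or a `multitask_table`.
#' @param n_rounds number of rounds (default 5).
#' @param mode `"leaky"` or `"all_for_one"`.
#' @param train_fracs training fraction schedule; default
#'   `0.8 * (1:n_rounds) / n_rounds`, i.e. 16/32/48/64/80 percent for five
#'   rounds, ending at an 80:20 split.
#' @return A `split_plan`.
#' @export
temporal_rounds <- function(records, n_rounds = 5,
                            mode = c("leaky", "all_for_one"),
                            train_fracs = NULL) {
  mode <- match.arg(mode)
  if (inherits(records, "multitask_table")) records <- table_records(records)
  if (is.null(records$date) && !is.null(records$earliest_date)) {
    records$date <- records$earliest_date
  }
  if (is.null(records$date) || anyNA(records$date)) {
    offenders <- if (is.null(records$date)) "all records" else {
      paste(utils::head(records$smiles_std[is.na(records$date)], 5), collapse = ", ")
    }
    stop("temporal_rounds: missing timestamps (", offenders, ")")
  }
  if (is.null(train_fracs)) train_fracs <- 0.8 * seq_len(n_rounds) / n_rounds
  stopifnot(length(train_fracs) == n_rounds, !is.unsorted(train_fracs))
  ord <- order(records$date, records$smiles_std, records$endpoint)
  rec <- records[ord, c("smiles_std", "endpoint"), drop = FALSE]
  n <- nrow(rec)
  rounds <- lapply(seq_len(n_rounds), function(r) {
    n_train <- floor(train_fracs[r] * n)
    train <- rec[seq_len(n_train), , drop = FALSE]
    test <- rec[setdiff(seq_len(n), seq_len(n_train)), , drop = FALSE]
    if (mode == "all_for_one") {
      train <- train[!train$smiles_std %in% unique(test$smiles_std), , drop = FALSE]
    }
    list(round = r, train = train, test = test)
  })
  new_split_plan(if (mode == "leaky") "temporal_leaky" else "temporal_all_for_one",
                 rounds, seed = NA_integer_,
                 list(n_rounds = n_rounds, mode = mode, train_fracs = train_fracs))
}

#' Quantify per-endpoint test share and train/test compound leakage
#'
#' For every endpoint and round, reports the percentage of that endpoint's
#' records that are in the test set and the percentage of its test compounds
#' whose SMILES also appears anywhere (any endpoint) in that round's
#' training set. All-for-one plans report exactly 0 overlap everywhere.
#'
#' @param plan a `split_plan`.
#' @param table the `multitask_table` the plan was built from.
#' @return data.frame with columns `endpoint`, `round`, `test_pct`,
#'   `train_overlap_pct`, `n_test`.
#' @export
leakage_report <- function(plan, table) {
  stopifnot(inherits(plan, "split_plan"), inherits(table, "multitask_table"))
  totals <- colSums(table$mask)
  out <- lapply(plan$rounds, function(r) {
    train_smi <- unique(r$train$smiles_std)
    do.call(rbind, lapply(endpoint_names(), function(ep) {
      test_ep <- r$test$smiles_std[r$test$endpoint == ep]
      n_test <- length(test_ep)
      data.frame(endpoint = ep, round = r$round,
                 test_pct = if (totals[[ep]] > 0) 100 * n_test / totals[[ep]] else NA_real_,
                 train_overlap_pct = if (n_test > 0) {
                   100 * mean(unique(test_ep) %in% train_smi)
                 } else NA_real_,
                 n_test = n_test,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compound-level k-fold cross-validation split
#'
#' @param table a `multitask_table`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `split_plan` whose rounds are the folds; each compound appears
#'   in exactly one test fold.
#' @export
kfold_cv <- function(table, k = 5, seed = 1) {
  stopifnot(inherits(table, "multitask_table"))
  smi <- rownames(table$mask)
  n <- length(smi)
  if (k > n) stop(sprintf("kfold_cv: k = %d exceeds number of compounds (%d)", k, n))
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  rounds <- lapply(seq_len(k), function(f) {
    test_smi <- smi[fold == f]
    list(round = f,
         train = records_of(table, smi[fold != f]),
         test = records_of(table, test_smi))
  })
  new_split_plan("kfold_cv", rounds, seed, list(k = k))
}

#' Modality-grouped k-fold cross-validation
#'
#' A plain compound-level k-fold split whose evaluation is keyed by
#' (endpoint, modality), so accuracy can be compared across small molecules,
#' macrocycles, peptides and PROTACs. Groups with very few test compounds
#' (down to n = 1) are still reported, flagged by their `n_test`.
#'
#' @param table a `multitask_table` with modality labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `split_plan` with strategy `"modality_cv"`; `params$modality`
#'   carries the per-compound labels used for grouped evaluation.
#' @export
modality_folds <- function(table, k = 5, seed = 1) {
  plan <- kfold_cv(table, k = k, seed = seed)
  plan$strategy <- "modality_cv"
  plan$params$modality <- table$modality
  plan
}

check_plan <- function(plan) {
  for (r in plan$rounds) {
    key_tr <- paste(r$train$smiles_std, r$train$endpoint)
    key_te <- paste(r$test$smiles_std, r$test$endpoint)
    if (length(intersect(key_tr, key_te))) {
      stop("split_plan invariant violated: record in both train and test")
    }
  }
  invisible(plan)
}
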
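test_that("masked loss ignores unobserved cells exactly", {
  pred <- matrix(c(1, 2), 1); targ <- matrix(c(1, 4), 1)
  expect_equal(masked_loss(pred, targ, matrix(c(1, 0), 1)), 0)
  expect_equal(masked_loss(pred, targ, matrix(c(1, 1), 1)), 2)   # (0 + 4) / 2
  # perturbing a masked prediction leaves the loss unchanged
  pred2 <- pred; pred2[1, 2] <- 1e6
  expect_equal(masked_loss(pred2, targ, matrix(c(1, 0), 1)),
               masked_loss(pred, targ, matrix(c(1, 0), 1)))
  # full mask is plain mean squared error
  set.seed(1)
  p <- matrix(rnorm(40), 10); y <- matrix(rnorm(40), 10)
  expect_equal(masked_loss(p, y, matrix(1, 10, 4)), mean((p - y)^2))
  expect_warning(z <- masked_loss(p, y, matrix(0, 10, 4)), "empty mask")
  expect_equal(z, 0)
})

test_that("rmse and spearman match their closed forms and tie oracle", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1, 3), 2)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1)
  expect_warning(v <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
  set.seed(2)
  for (i in 1:10) {                       # heavy ties vs rank-formula oracle
    a <- sample(1:4, 30, replace = TRUE)
    b <- a + sample(-1:1, 30, replace = TRUE)
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("single-task forest overfits its training data and is seeded", {
  fix <- small_dataset()
  tab <- fix$table
  d <- fix$ds$descriptors[rownames(tab$mask), , drop = FALSE]
  fit <- fit_stl_baseline(tab, "Caco2Papp", d, seed = 1)
  obs_smi <- rownames(tab$mask)[tab$mask[, "Caco2Papp"]]
  p <- predict(fit, d[obs_smi, , drop = FALSE])
  y <- tab$values[obs_smi, "Caco2Papp"]
  expect_lt(rmse(p, y), 0.6 * sd(y))      # in-sample fit well under the null
  fit2 <- fit_stl_baseline(tab, "Caco2Papp", d, seed = 1)
  expect_identical(p, predict(fit2, d[obs_smi, , drop = FALSE]))
  expect_error(fit_stl_baseline(tab, "Caco2Papp", d, train_smiles = obs_smi[1:5]),
               "need >= 20")
})

test_that("permuted labels drive test error to the label spread", {
  fix <- small_dataset()
  tab <- fix$table
  smi <- rownames(tab$mask)[tab$mask[, "Caco2ER"]]
  d <- fix$ds$descriptors[rownames(tab$mask), , drop = FALSE]
  set.seed(31)
  tr <- sample(smi, floor(0.8 * length(smi)))
  te <- setdiff(smi, tr)
  perm_tab <- tab
  perm_tab$values[tr, "Caco2ER"] <- sample(perm_tab$values[tr, "Caco2ER"])
  fit <- fit_stl_baseline(perm_tab, "Caco2ER", d, seed = 1, train_smiles = tr)
  p <- predict(fit, d[te, , drop = FALSE])
  e <- rmse(p, tab$values[te, "Caco2ER"])
  expect_equal(e, sd(tab$values[te, "Caco2ER"]), tolerance = 0.2)
})

test_that("constant predictor RMSE equals the population SD of test labels", {
  y <- c(0.2, 0.9, 1.4, 2.0, 0.7)
  const <- mean(y)
  pop_sd <- sqrt(mean((y - mean(y))^2))
  expect_equal(rmse(rep(const, length(y)), y), pop_sd)
})

test_that("descriptor ranking recovers a planted single-descriptor signal", {
  fix <- small_dataset()
  tab <- fix$table
  d <- fix$ds$descriptors[rownames(tab$mask), , drop = FALSE]
  planted <- tab
  set.seed(12)
  planted$values[, "Caco2ER"] <- 0.01 * d[, "MolWt"] +
    rnorm(nrow(d), 0, 0.05)
  planted$mask[, "Caco2ER"] <- TRUE
  fit <- fit_stl_baseline(planted, "Caco2ER", d, seed = 3)
  ranked <- rank_descriptors(fit, top_k = 5)
  expect_identical(ranked[["Caco2ER"]][1], "MolWt")
  # top_k beyond the descriptor count returns the full ranking
  all_ranked <- rank_descriptors(fit, top_k = 1000)
  expect_length(all_ranked[["Caco2ER"]], ncol(d))
  # same seed, same ranking
  expect_identical(ranked, rank_descriptors(fit_stl_baseline(planted, "Caco2ER",
                                                             d, seed = 3),
                                            top_k = 5))
})

test_that("multitask training round-trips per-task standardization", {
  fix <- small_dataset()
  tab <- fix$table
  fp <- memoise_fixture("small_fp", function() fingerprint_matrix(rownames(tab$mask)))
  m <- fit_mtl(tab, features = fp, seed = 1,
               config = mtl_config(epochs = 30, patience = 10))
  P <- predict(m, smiles = rownames(tab$mask), features = fp)
  expect_identical(colnames(P), endpoint_names())
  expect_true(all(is.finite(P)))
  # de-standardized predictions live on the data scale, not the z scale
  for (ep in endpoint_names()) {
    obs <- tab$values[tab$mask[, ep], ep]
    expect_lt(abs(mean(P[, ep]) - mean(obs)), 2 * sd(obs))
  }
  # determinism under the seed
  m2 <- fit_mtl(tab, features = fp, seed = 1,
                config = mtl_config(epochs = 30, patience = 10))
  expect_equal(m$par, m2$par, tolerance = 1e-12)
  # masked cells do not influence training: perturbing unobserved values is a no-op
  tab3 <- tab
  tab3$values[!tab3$mask] <- 99
  m3 <- fit_mtl(tab3, features = fp, seed = 1,
                config = mtl_config(epochs = 30, patience = 10))
  expect_equal(m$par, m3$par, tolerance = 1e-12)
})

test_that("single-endpoint training warns and degenerates to single-task", {
  fix <- small_dataset()
  tab <- fix$table
  fp <- memoise_fixture("small_fp", function() fingerprint_matrix(rownames(tab$mask)))
  rec <- as.data.frame(tab)
  one <- rec[rec$endpoint == "Caco2Papp", c("smiles_std", "endpoint")]
  expect_warning(fit_mtl(tab, features = fp, seed = 1, train_records = one,
                         config = mtl_config(epochs = 5, patience = 2)),
                 "single")
})

test_that("duplicated-endpoint table makes multitask equal single-task", {
  # one endpoint copied into all four columns: cross-learning has nothing to
  # add, so MTL test RMSE tracks STL within 10%
  fix <- small_dataset()
  tab <- fix$table
  fp <- memoise_fixture("small_fp", function() fingerprint_matrix(rownames(tab$mask)))
  smi <- rownames(tab$mask)
  dup <- tab
  dup$values <- matrix(tab$values[, "Caco2ER"], nrow(tab$values), 4,
                       dimnames = dimnames(tab$values))
  keep <- tab$mask[, "Caco2ER"]
  dup$mask <- matrix(keep, nrow(tab$mask), 4, dimnames = dimnames(tab$mask))
  dup$values[!dup$mask] <- NA
  obs <- smi[keep]
  set.seed(17)
  tr <- sample(obs, floor(0.8 * length(obs)))
  te <- setdiff(obs, tr)
  rec <- expand.grid(smiles_std = tr, endpoint = endpoint_names(),
                     stringsAsFactors = FALSE)
  cfg <- mtl_config(epochs = 60, patience = 15)
  mtl <- fit_mtl(dup, features = fp, seed = 5, train_records = rec)
  stl <- suppressWarnings(fit_mtl(dup, features = fp, seed = 5,
                                  train_records = rec[rec$endpoint == "Caco2ER", ]))
  y <- tab$values[te, "Caco2ER"]
  r_mtl <- rmse(predict(mtl, smiles = te, features = fp)[, "Caco2ER"], y)
  r_stl <- rmse(predict(stl, smiles = te, features = fp)[, "Caco2ER"], y)
  expect_lt(abs(r_mtl - r_stl) / r_stl, 0.10)
})

test_that("benchmark reports one RMSE per model, endpoint and round with provenance", {
  fix <- small_dataset()
  tab <- fix$table
  fc <- list(fp = memoise_fixture("small_fp",
                                  function() fingerprint_matrix(rownames(tab$mask))),
             desc_full = fix$ds$descriptors[rownames(tab$mask), , drop = FALSE])
  plan <- kfold_cv(tab, k = 2, seed = 9)
  res <- suppressWarnings(
    benchmark(tab, plan, models = c("rf", "mtl"), seed = 2,
              config = mtl_config(epochs = 20, patience = 5),
              feature_cache = fc))
  expect_setequal(unique(res$model), c("rf", "mtl"))
  expect_equal(nrow(res[res$model == "mtl", ]), 2 * 4)  # rounds x endpoints
  expect_true(all(res$rmse >= 0, na.rm = TRUE))
  expect_true(all(res$seed == 2))
  summ <- summarize_benchmark(res)
  expect_equal(nrow(summ), 2 * 4)
  expect_true(all(c("rmse_mean", "rmse_sd") %in% names(summ)))
  # temporal strategies carry their leakage columns
  recs <- as.data.frame(tab); recs$date <- recs$earliest_date
  tplan <- temporal_rounds(recs, n_rounds = 2, mode = "leaky")
  tres <- suppressWarnings(
    benchmark(tab, tplan, models = "mtl", seed = 2,
              config = mtl_config(epochs = 15, patience = 5), feature_cache = fc))
  expect_true(all(c("test_pct", "train_overlap_pct") %in% names(tres)))
  expect_false(anyNA(tres$test_pct))
})
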
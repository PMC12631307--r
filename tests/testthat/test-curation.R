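test_that("bounded values parse into payload and qualifier", {
  pv <- parse_bounded_value(c("<0.1", ">50", "3.2", " <2.5"))
  expect_equal(pv$value, c(0.1, 50, 3.2, 2.5))
  expect_equal(pv$qualifier, c("lower_bound", "upper_bound", "none", "lower_bound"))
  expect_error(parse_bounded_value(c("3.2", "<abc")), "non-numeric")
  # numeric passthrough
  expect_equal(parse_bounded_value(c(1, 2))$qualifier, c("none", "none"))
})

test_that("log transform and efflux ratio obey their identities", {
  expect_equal(to_log(c(100, 1, 10)), c(2, 0, 1))
  expect_error(to_log(-1e-3), "positive")
  expect_error(to_log(0), "positive")
  expect_equal(efflux_ratio(10, 5), 2)
  expect_equal(efflux_ratio(5, 5), 1)         # no-efflux identity
  expect_equal(efflux_ratio(0.3, 0.1), 3)
  expect_error(efflux_ratio(1, 0), "positive")
})

test_that("aggregation reproduces a brute-force group-by oracle", {
  set.seed(42)
  n <- 200
  m <- data.frame(
    smiles_std = sample(sprintf("M%02d", 1:25), n, replace = TRUE),
    endpoint = sample(endpoint_names(), n, replace = TRUE),
    log_value = rnorm(n),
    qualifier = "none",
    date = as.Date("2020-01-01") + sample(0:1000, n, replace = TRUE),
    modality = "small_molecule", stringsAsFactors = FALSE)
  agg <- aggregate_measurements(m)
  # count conservation, per endpoint and overall
  expect_equal(sum(agg$n), n)
  for (ep in endpoint_names()) {
    expect_equal(sum(agg$n[agg$endpoint == ep]), sum(m$endpoint == ep))
  }
  # each group against direct computation
  for (i in sample(nrow(agg), 20)) {
    sel <- m$smiles_std == agg$smiles_std[i] & m$endpoint == agg$endpoint[i]
    expect_equal(agg$mean_log[i], mean(m$log_value[sel]))
    expect_equal(agg$n[i], sum(sel))
    if (sum(sel) >= 2) expect_equal(agg$sd_log[i], sd(m$log_value[sel]))
    expect_equal(agg$earliest_date[i], min(m$date[sel]))
  }
  # singletons carry no sd
  expect_true(all(is.na(agg$sd_log[agg$n == 1])))
  expect_false(anyNA(agg$sd_log[agg$n >= 2]))
})

test_that("replicate triple and singleton aggregate to the documented values", {
  m <- data.frame(smiles_std = c("A", "A", "A", "B"),
                  endpoint = "Caco2ER",
                  log_value = c(1.0, 1.2, 1.4, 0.5))
  agg <- aggregate_measurements(m)
  expect_equal(agg$mean_log[agg$smiles_std == "A"], 1.2)
  expect_equal(agg$sd_log[agg$smiles_std == "A"], 0.2)
  expect_equal(agg$n[agg$smiles_std == "A"], 3L)
  expect_equal(agg$mean_log[agg$smiles_std == "B"], 0.5)
  expect_true(is.na(agg$sd_log[agg$smiles_std == "B"]))
  expect_equal(nrow(aggregate_measurements(m[0, ])), 0L)
})

test_that("mixed < and > qualifiers in one group warn but aggregate", {
  m <- data.frame(smiles_std = c("A", "A"), endpoint = "Caco2Papp",
                  log_value = c(0, 1),
                  qualifier = c("lower_bound", "upper_bound"))
  expect_warning(agg <- aggregate_measurements(m), "mix")
  expect_equal(nrow(agg), 1L)
  expect_true(agg$any_qualifier)
})

test_that("sigma regression equals the closed-form normal equations", {
  # collinear points: exact line
  r <- fake_records(c("A", "B", "C"), "Caco2ER", mean_log = c(0, 1, 2),
                    sd_log = c(0.3, 0.2, 0.1), n = 2)
  sm <- fit_sigma_model(r, "Caco2ER")
  expect_equal(sm$intercept, 0.3, tolerance = 1e-12)
  expect_equal(sm$slope, -0.1, tolerance = 1e-12)
  # random non-collinear sets against the oracle
  set.seed(9)
  for (rep in 1:5) {
    k <- sample(5:40, 1)
    r <- fake_records(sprintf("C%02d", 1:k), "MDCKER",
                      mean_log = rnorm(k), sd_log = abs(rnorm(k, 0.2, 0.05)),
                      n = 2)
    sm <- fit_sigma_model(r, "MDCKER")
    ols <- oracle_ols(r$mean_log, r$sd_log)
    expect_equal(sm$intercept, ols[1], tolerance = 1e-10)
    expect_equal(sm$slope, ols[2], tolerance = 1e-10)
  }
  # eligibility: replicated records only, at least three of them
  r <- fake_records(c("A", "B"), "Caco2ER", mean_log = c(0, 1),
                    sd_log = c(0.1, 0.2), n = 2)
  expect_error(fit_sigma_model(r, "Caco2ER"), "insufficient|need")
})

test_that("outlier flags equal an exhaustive evaluation of the rule", {
  model <- structure(list(intercept = 0.3, slope = -0.1, endpoint = "Caco2Papp",
                          n_fit = 10, sigma_floor = 0.01), class = "sigma_model")
  # documented examples: sigma_hat(1.0) = 0.2
  r <- fake_records(c("A", "B", "C"), "Caco2Papp", mean_log = 1.0,
                    sd_log = c(0.5, 0.3, NA), n = c(2, 3, 1))
  expect_identical(flag_outliers(r, model, k = 2), c(TRUE, FALSE, FALSE))
  # randomized records vs per-record hand evaluation, floor included
  set.seed(4)
  r <- fake_records(sprintf("R%02d", 1:50), "Caco2Papp",
                    mean_log = runif(50, -1, 4),
                    sd_log = abs(rnorm(50, 0.2, 0.15)),
                    n = sample(c(1L, 2L, 3L), 50, replace = TRUE))
  r$sd_log[r$n == 1] <- NA
  got <- flag_outliers(r, model, k = 2)
  want <- vapply(seq_len(nrow(r)), function(i) {
    if (r$n[i] < 2) return(FALSE)
    pred <- max(0.01, 0.3 - 0.1 * r$mean_log[i])
    r$sd_log[i] > 2 * pred
  }, logical(1))
  expect_identical(got, want)
})

test_that("multitask table pivot matches a brute-force oracle and is order-invariant", {
  recs <- rbind(
    fake_records("A", "Caco2ER", 1.1), fake_records("A", "MDCKER", 0.4),
    fake_records("B", "Caco2Papp", 0.9))
  tab <- build_multitask_table(recs)
  expect_equal(dim(tab), c(2L, 4L))
  expect_equal(sort(rowSums(tab$mask), decreasing = TRUE), c(A = 2, B = 1))
  expect_equal(tab$values["A", "Caco2ER"], 1.1)
  expect_true(all(is.na(tab$values[!tab$mask])))
  expect_identical(colnames(tab$values),
                   c("Caco2ER", "Caco2Papp", "MDCKER", "NIHMDCKER"))
  # permuting record order yields the identical table
  perm <- build_multitask_table(recs[c(3, 1, 2), ])
  expect_identical(tab, perm)
  # duplicates violate the aggregation contract
  expect_error(build_multitask_table(rbind(recs, recs[1, ])), "duplicate")
  # empty input gives an empty table
  expect_equal(nrow(build_multitask_table(recs[0, ])$values), 0L)
})

test_that("coverage summary computes row-wise endpoint-count fractions", {
  recs <- rbind(
    fake_records("A", "Caco2ER"), fake_records("B", "Caco2Papp"),
    fake_records("C", c("Caco2ER", "MDCKER")),
    fake_records("D", endpoint_names()))
  cov <- coverage_summary(build_multitask_table(recs))
  expect_equal(unname(cov), c(0.5, 0.25, 0, 0.25))
  expect_equal(sum(cov), 1)
  full <- coverage_summary(fake_full_table(5))
  expect_equal(unname(full), c(0, 0, 0, 1))
  expect_error(coverage_summary(build_multitask_table(recs[0, ])), "empty")
})

test_that("curation is idempotent on an already-curated table", {
  fix <- small_dataset()
  rec1 <- fix$cur$records
  back <- data.frame(smiles = rec1$smiles_std, endpoint = rec1$endpoint,
                     value = 10^rec1$mean_log, date = rec1$earliest_date,
                     modality = rec1$modality, stringsAsFactors = FALSE)
  cur2 <- suppressWarnings(suppressMessages(curate(back)))
  expect_identical(rownames(cur2$table$values), rownames(fix$table$values))
  expect_identical(cur2$table$mask, fix$table$mask)
  expect_equal(cur2$table$values, fix$table$values, tolerance = 1e-12)
  expect_equal(nrow(cur2$outliers), 0L)
})

test_that("curation conserves accepted measurement counts", {
  fix <- small_dataset()
  n_meas <- nrow(fix$ds$measurements)
  expect_equal(fix$cur$n_accepted, n_meas)   # generator emits no invalid rows
  expect_equal(sum(fix$cur$records$n) + sum(fix$cur$outliers$n), n_meas)
})

test_that("external tables drop sentinel values and normalize units", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(SMILES = c("CCO", "c1ccccc1", "CCN", "CCC"),
                       Permeability = c(12.5, -0.001, 0.8, -5)),
            f, row.names = FALSE)
  ext <- ingest_external(f, "cycpeptmpdb")
  expect_equal(nrow(ext), 2L)                 # sentinel and negative dropped
  expect_equal(attr(ext, "dropped"), 2L)
  expect_equal(ext$value, c(12.5, 0.8))
  expect_true(all(ext$endpoint == "Caco2Papp"))
  # cm/s unit rescaling in the NMMPDB layout
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(SMILES = "CCO", Value = 2e-6, Endpoint = "Caco2Papp",
                       Unit = "cm/s"), f2, row.names = FALSE)
  ext2 <- ingest_external(f2, "nmmpdb")
  expect_equal(ext2$value, 2)
  # no valid rows warns; wrong layout errors
  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(SMILES = "CCO", Permeability = -0.001), f3, row.names = FALSE)
  expect_warning(ingest_external(f3, "cycpeptmpdb"), "no valid rows")
  expect_error(ingest_external(f3, "nmmpdb"), "layout")
})
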
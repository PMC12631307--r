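# Shared fixtures, built in code. The synthetic dataset and its derived
# features are expensive (OpenBabel round trips), so they are generated once
# per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memoise_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# mid-sized synthetic dataset for module tests
small_dataset <- function() {
  memoise_fixture("small_ds", function() {
    ds <- generate(generator_config(n_compounds = 500, seed = 7))
    cur <- suppressWarnings(suppressMessages(curate(ds$measurements)))
    list(ds = ds, cur = cur, table = cur$table)
  })
}

# build aggregated records directly (no chemistry) for table/split logic
fake_records <- function(smiles, endpoint, mean_log = 0, n = 1,
                         sd_log = NA_real_, date = as.Date("2020-01-01"),
                         modality = "small_molecule", any_qualifier = FALSE) {
  data.frame(smiles_std = smiles, endpoint = endpoint, mean_log = mean_log,
             sd_log = sd_log, n = n, earliest_date = as.Date(date),
             any_qualifier = any_qualifier, modality = modality,
             stringsAsFactors = FALSE)
}

# a table with n compounds, all four endpoints observed, equally spaced dates
fake_full_table <- function(n, prefix = "M") {
  smi <- sprintf("%s%03d", prefix, seq_len(n))
  recs <- do.call(rbind, lapply(endpoint_names(), function(ep) {
    fake_records(smi, ep, mean_log = seq_len(n) / n,
                 date = as.Date("2020-01-01") + seq_len(n))
  }))
  build_multitask_table(recs)
}

# independent Spearman implementation: Pearson correlation of average ranks
oracle_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# independent OLS via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# brute-force leakage numbers for small plans
oracle_leakage <- function(round, table) {
  train_smi <- unique(round$train$smiles_std)
  sapply(endpoint_names(), function(ep) {
    total <- sum(table$mask[, ep])
    test_ep <- unique(round$test$smiles_std[round$test$endpoint == ep])
    c(test_pct = if (total) 100 * length(test_ep) / total else NA,
      overlap = if (length(test_ep)) 100 * mean(test_ep %in% train_smi) else NA)
  })
}

run_python <- function(code) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  out <- tryCatch(system2(py, "-", input = code, stdout = TRUE, stderr = FALSE),
                  error = function(e) NULL)
  if (is.null(out) || !is.null(attr(out, "status"))) return(NULL)
  out
}
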
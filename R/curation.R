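#' Parse assay values with optional out-of-bound qualifiers
#'
#' Assay readings outside the quantifiable range are reported as
#' "lower than X" (`<X`) or "greater than X" (`>X`). The numeric payload is
#' retained as-is and the qualifier recorded alongside it; qualified values
#' are not excluded from downstream aggregation.
#'
#' @param raw character (or numeric) vector such as `"<0.1"`, `">50"`, `"3.2"`.
#' @return data.frame with columns `value` (numeric) and `qualifier`
#'   (`"none"`, `"lower_bound"` or `"upper_bound"`).
#' @examples
#' parse_bounded_value(c("<0.1", ">50", "3.2"))
#' @export
parse_bounded_value <- function(raw) {
  if (is.numeric(raw)) {
    return(data.frame(value = as.numeric(raw),
                      qualifier = rep("none", length(raw)),
                      stringsAsFactors = FALSE))
  }
  raw <- trimws(as.character(raw))
  qual <- ifelse(startsWith(raw, "<"), "lower_bound",
                 ifelse(startsWith(raw, ">"), "upper_bound", "none"))
  payload <- sub("^[<>]\\s*", "", raw)
  value <- suppressWarnings(as.numeric(payload))
  if (anyNA(value)) {
    stop("non-numeric value payload: ",
         paste(utils::head(raw[is.na(value)], 5), collapse = ", "))
  }
  data.frame(value = value, qualifier = qual, stringsAsFactors = FALSE)
}

#' Base-10 log transform of a positive assay value
#'
#' @param value positive numeric vector (permeability in 1e-6 cm/s or a
#'   dimensionless efflux ratio).
#' @return `log10(value)`.
#' @export
to_log <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("to_log requires strictly positive finite values")
  }
  log10(value)
}

#' Efflux ratio from directional apparent permeabilities
#'
#' The efflux ratio is the basolateral-to-apical apparent permeability
#' divided by the apical-to-basolateral one; values well above 1 indicate
#' active transporter-mediated efflux.
#'
#' @param papp_ba,papp_ab positive numerics, same units.
#' @return `papp_ba / papp_ab`.
#' @examples
#' efflux_ratio(10, 5)
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  if (any(papp_ba <= 0) || any(papp_ab <= 0)) {
    stop("directional permeabilities must be strictly positive")
  }
  papp_ba / papp_ab
}

validate_measurements <- function(measurements) {
  req <- c("smiles", "endpoint", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("measurements lack columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(measurements$endpoint), endpoint_names())
  if (length(bad)) stop("unknown endpoints: ", paste(bad, collapse = ", "))
  invisible(measurements)
}

#' Aggregate replicate measurements per compound and endpoint
#'
#' Groups log-transformed measurements by (standardized SMILES, endpoint) and
#' computes the arithmetic mean log value, the sample (n-1) standard
#' deviation when at least two replicates exist, the replicate count, the
#' earliest timestamp and whether any replicate carried an out-of-bound
#' qualifier. Records mixing `<` and `>` qualifiers within one group are
#' aggregated anyway with a warning.
#'
#' @param measurements data.frame with columns `smiles_std`, `endpoint`,
#'   `log_value`, and optionally `qualifier`, `date`, `modality`.
#' @return data.frame of aggregated records with columns `smiles_std`,
#'   `endpoint`, `mean_log`, `sd_log` (`NA` for singletons), `n`,
#'   `earliest_date`, `any_qualifier`, `modality`.
#' @export
aggregate_measurements <- function(measurements) {
  if (!nrow(measurements)) {
    return(data.frame(smiles_std = character(), endpoint = character(),
                      mean_log = numeric(), sd_log = numeric(), n = integer(),
                      earliest_date = as.Date(character()),
                      any_qualifier = logical(), modality = character(),
                      stringsAsFactors = FALSE))
  }
  m <- measurements
  if (is.null(m$qualifier)) m$qualifier <- "none"
  if (is.null(m$date)) m$date <- as.Date(NA)
  if (is.null(m$modality)) m$modality <- "unknown"
  key <- paste(m$smiles_std, m$endpoint, sep = "\r")
  grp <- split(seq_len(nrow(m)), key)
  mixed <- 0L
  rows <- lapply(grp, function(idx) {
    lv <- m$log_value[idx]
    q <- m$qualifier[idx]
    has_lo <- any(q == "lower_bound"); has_hi <- any(q == "upper_bound")
    if (has_lo && has_hi) mixed <<- mixed + 1L
    data.frame(
      smiles_std = m$smiles_std[idx[1]],
      endpoint = m$endpoint[idx[1]],
      mean_log = mean(lv),
      sd_log = if (length(lv) >= 2) stats::sd(lv) else NA_real_,
      n = length(lv),
      earliest_date = suppressWarnings(min(m$date[idx], na.rm = TRUE)),
      any_qualifier = any(q != "none"),
      modality = m$modality[idx[1]],
      stringsAsFactors = FALSE
    )
  })
  if (mixed > 0) {
    warning(sprintf("%d compound/endpoint group(s) mix < and > qualifiers; aggregated anyway", mixed))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$smiles_std, out$endpoint), , drop = FALSE]
}

#' Fit the replicate-variability regression for one endpoint
#'
#' Experimental noise in permeability data is heteroscedastic: replicate
#' standard deviations trend with the mean log value. Following the usual
#' assay-variability treatment, an ordinary-least-squares line is fitted with
#' the mean log value as independent variable and the replicate standard
#' deviation as dependent variable, using only compounds with at least two
#' measurements. The fitted line predicts the expected noise level at a given
#' mean and anchors the outlier rule in [flag_outliers()].
#'
#' @param records aggregated records (see [aggregate_measurements()]).
#' @param endpoint one of [endpoint_names()].
#' @param sigma_floor minimum predicted sigma, in log10 units; predictions
#'   are clipped from below so that the rule stays usable where the
#'   regression line approaches or crosses zero.
#' @return Object of class `sigma_model` with fields `intercept`, `slope`,
#'   `endpoint`, `n_fit`, `sigma_floor`.
#' @export
fit_sigma_model <- function(records, endpoint, sigma_floor = 0.01) {
  stopifnot(endpoint %in% endpoint_names())
  r <- records[records$endpoint == endpoint & records$n >= 2 & !is.na(records$sd_log), , drop = FALSE]
  if (nrow(r) < 3) {
    stop(sprintf("fit_sigma_model: need >= 3 records with replicates for %s, got %d",
                 endpoint, nrow(r)))
  }
  fit <- stats::lm(sd_log ~ mean_log, data = r)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 endpoint = endpoint, n_fit = nrow(r),
                 sigma_floor = sigma_floor),
            class = "sigma_model")
}

#' @export
print.sigma_model <- function(x, ...) {
  cat(sprintf("sigma model [%s]: sigma_hat(m) = %.4f %+.4f * m (floor %.3g, n = %d)\n",
              x$endpoint, x$intercept, x$slope, x$sigma_floor, x$n_fit))
  invisible(x)
}

#' Predicted replicate standard deviation at given mean log values
#' @param object a `sigma_model`.
#' @param mean_log numeric vector of mean log values.
#' @param ... ignored.
#' @return Predicted sigma, clipped below at the model's floor.
#' @export
predict.sigma_model <- function(object, mean_log, ...) {
  pmax(object$sigma_floor, object$intercept + object$slope * mean_log)
}

#' Flag high-variability outlier records
#'
#' A record with replicates is flagged when its observed replicate standard
#' deviation exceeds `k` times the sigma predicted by the endpoint's
#' variability regression at its mean log value (with the model's floor).
#' Singleton records carry no standard deviation and are never flagged:
#' their variability is assumed similar to that of replicated compounds and
#' they are retained.
#'
#' @param records aggregated records.
#' @param model a `sigma_model` for the records' endpoint.
#' @param k multiplier on the predicted sigma (default 2).
#' @return Logical vector along `records`: `TRUE` where flagged.
#' @export
flag_outliers <- function(records, model, k = 2) {
  stopifnot(inherits(model, "sigma_model"))
  idx <- records$endpoint == model$endpoint & records$n >= 2 & !is.na(records$sd_log)
  flag <- rep(FALSE, nrow(records))
  if (any(idx)) {
    pred <- predict(model, records$mean_log[idx])
    flag[idx] <- records$sd_log[idx] > k * pred
  }
  flag
}

#' Pivot aggregated records into a sparse multitask table
#'
#' One row per unique standardized SMILES, one column per endpoint in the
#' fixed released-model order, with an observation mask and per-cell
#' metadata (replicate count, earliest timestamp, qualifier flag) plus a
#' per-compound modality label.
#'
#' @param records aggregated, outlier-free records.
#' @return Object of class `multitask_table` with matrix fields `values`,
#'   `mask`, `n_meas`, `date` (numeric days since 1970-01-01), `any_qual`
#'   and vector field `modality`.
#' @export
build_multitask_table <- function(records) {
  eps <- endpoint_names()
  if (!nrow(records)) {
    empty <- matrix(numeric(0), 0, 4, dimnames = list(NULL, eps))
    return(structure(list(values = empty, mask = empty > 0, n_meas = empty,
                          date = empty, any_qual = empty > 0,
                          modality = character(0)),
                     class = "multitask_table"))
  }
  key <- paste(records$smiles_std, records$endpoint)
  if (anyDuplicated(key)) {
    stop("duplicate (smiles_std, endpoint) records: aggregation contract violated")
  }
  smi <- sort(unique(records$smiles_std))
  n <- length(smi)
  mk <- function(fill) matrix(fill, n, 4, dimnames = list(smi, eps))
  values <- mk(NA_real_); n_meas <- mk(0); date <- mk(NA_real_)
  any_qual <- mk(FALSE); mask <- mk(FALSE)
  i <- match(records$smiles_std, smi)
  j <- match(records$endpoint, eps)
  ij <- cbind(i, j)
  values[ij] <- records$mean_log
  mask[ij] <- TRUE
  n_meas[ij] <- records$n
  date[ij] <- as.numeric(records$earliest_date)
  any_qual[ij] <- records$any_qualifier
  modality <- rep("unknown", n)
  modality[i] <- records$modality
  structure(list(values = values, mask = mask, n_meas = n_meas, date = date,
                 any_qual = any_qual, modality = stats::setNames(modality, smi)),
            class = "multitask_table")
}

#' @export
print.multitask_table <- function(x, ...) {
  cat(sprintf("multitask_table: %d compounds x %d endpoints, %d observed cells\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  cat("  per endpoint:", paste(sprintf("%s=%d", colnames(x$mask), colSums(x$mask)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multitask_table <- function(x) dim(x$values)

#' Fraction of compounds by number of observed endpoints
#'
#' @param table a `multitask_table`.
#' @return Named numeric vector over endpoint counts 1..4; fractions sum to 1.
#' @export
coverage_summary <- function(table) {
  stopifnot(inherits(table, "multitask_table"))
  if (!nrow(table$values)) stop("coverage_summary: empty table")
  counts <- rowSums(table$mask)
  tab <- tabulate(counts, nbins = 4)
  stats::setNames(tab / nrow(table$values), as.character(1:4))
}

#' Flatten a multitask table to long-format aggregated records
#'
#' @param x a `multitask_table`.
#' @param ... ignored.
#' @return data.frame with one row per observed cell.
#' @export
as.data.frame.multitask_table <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  out <- data.frame(
    smiles_std = rownames(x$values)[idx[, 1]],
    endpoint = colnames(x$values)[idx[, 2]],
    mean_log = x$values[idx],
    n = x$n_meas[idx],
    earliest_date = as.Date(x$date[idx], origin = "1970-01-01"),
    any_qualifier = x$any_qual[idx],
    modality = unname(x$modality[idx[, 1]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$smiles_std, out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full curation pipeline on raw measurements
#'
#' Standardizes structures (rejecting unparsable SMILES with a reason),
#' parses qualified values, log-transforms, aggregates replicates, fits a
#' per-endpoint variability regression, removes high-variability outliers
#' and pivots the result into a sparse multitask table.
#'
#' @param measurements data.frame with columns `smiles`, `endpoint`, `value`
#'   (numeric, or character with optional `<`/`>` prefix), and optionally
#'   `qualifier`, `date`, `modality`.
#' @param sigma_k outlier multiplier passed to [flag_outliers()].
#' @param sigma_floor floor for predicted sigma, log10 units.
#' @return Object of class `curation_result`: list with `table`
#'   (`multitask_table`), `records` (clean aggregated records), `outliers`
#'   (removed records), `sigma_models`, `rejected` (rejected raw rows with
#'   reasons) and `n_accepted` (count of accepted raw measurements).
#' @export
curate <- function(measurements, sigma_k = 2, sigma_floor = 0.01) {
  validate_measurements(measurements)
  m <- measurements
  pv <- parse_bounded_value(m$value)
  if (!is.null(m$qualifier)) {
    override <- !is.na(m$qualifier) & m$qualifier != "none"
    pv$qualifier[override] <- m$qualifier[override]
  }
  m$value <- pv$value
  m$qualifier <- pv$qualifier

  rejected <- list()
  nonpos <- m$value <= 0 | !is.finite(m$value)
  if (any(nonpos)) {
    rejected$nonpositive <- data.frame(smiles = m$smiles[nonpos],
                                       reason = "nonpositive value",
                                       stringsAsFactors = FALSE)
    m <- m[!nonpos, , drop = FALSE]
  }
  std <- standardize_structure(m$smiles)
  bad <- is.na(std)
  if (any(bad)) {
    rejected$unparsable <- data.frame(smiles = m$smiles[bad],
                                      reason = "unparsable SMILES",
                                      stringsAsFactors = FALSE)
  }
  m <- m[!bad, , drop = FALSE]
  m$smiles_std <- std[!bad]
  m$log_value <- to_log(m$value)
  if (is.null(m$date)) m$date <- as.Date(NA)
  m$date <- as.Date(m$date)

  records <- aggregate_measurements(m)

  sigma_models <- list()
  out_flag <- rep(FALSE, nrow(records))
  for (ep in intersect(endpoint_names(), unique(records$endpoint))) {
    n_rep <- sum(records$endpoint == ep & records$n >= 2)
    if (n_rep >= 3) {
      sm <- fit_sigma_model(records, ep, sigma_floor = sigma_floor)
      sigma_models[[ep]] <- sm
      out_flag <- out_flag | flag_outliers(records, sm, k = sigma_k)
    } else {
      warning(sprintf("curate: too few replicated records for %s; no outlier filter applied", ep))
    }
  }
  outliers <- records[out_flag, , drop = FALSE]
  clean <- records[!out_flag, , drop = FALSE]

  structure(list(table = build_multitask_table(clean),
                 records = clean,
                 outliers = outliers,
                 sigma_models = sigma_models,
                 rejected = if (length(rejected)) do.call(rbind, rejected) else NULL,
                 n_accepted = nrow(m)),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("curation_result: %d accepted measurements -> %d records (%d outliers removed, %d raw rows rejected)\n",
              x$n_accepted, nrow(x$records), nrow(x$outliers),
              if (is.null(x$rejected)) 0L else nrow(x$rejected)))
  print(x$table)
  invisible(x)
}

#' Ingest an external permeability table
#'
#' Reads a public-database CSV export (CycPeptMPDB- or NMMPDB-style layout)
#' into the package's raw-measurement format. Sentinel permeabilities used by
#' CycPeptMPDB for out-of-range compounds (-10 x 10^-10 cm/s, i.e. -0.001 in
#' 1e-6 cm/s units) and any other non-positive values are dropped as
#' outliers. Values in cm/s are rescaled to 1e-6 cm/s.
#'
#' @param path CSV file path.
#' @param source `"cycpeptmpdb"` or `"nmmpdb"`; selects the built-in column
#'   mapping.
#' @param columns optional named character vector overriding the column
#'   mapping; recognised names are `smiles`, `value`, `endpoint`, `unit`.
#' @param endpoint for layouts without an endpoint column, the endpoint to
#'   assign (default `"Caco2Papp"`).
#' @return data.frame of raw measurements (`smiles`, `endpoint`, `value` in
#'   1e-6 cm/s or dimensionless, `qualifier`, `date`, `modality`), with the
#'   dropped rows attached as attribute `"dropped"`.
#' @export
ingest_external <- function(path, source = c("cycpeptmpdb", "nmmpdb"),
                            columns = NULL, endpoint = "Caco2Papp") {
  source <- match.arg(source)
  map <- switch(source,
    cycpeptmpdb = c(smiles = "SMILES", value = "Permeability"),
    nmmpdb = c(smiles = "SMILES", value = "Value", endpoint = "Endpoint",
               unit = "Unit"))
  if (!is.null(columns)) map[names(columns)] <- columns
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(map[c("smiles", "value")]), names(tab))
  if (length(miss)) {
    stop(sprintf("unknown %s layout: missing column(s) %s", source,
                 paste(miss, collapse = ", ")))
  }
  value <- as.numeric(tab[[map[["value"]]]])
  unit <- if (!is.na(map["unit"]) && map[["unit"]] %in% names(tab)) {
    tab[[map[["unit"]]]]
  } else {
    rep("1e-6 cm/s", nrow(tab))
  }
  cms <- unit %in% c("cm/s", "cm s-1")
  value[cms] <- value[cms] * 1e6
  ep <- if (!is.na(map["endpoint"]) && map[["endpoint"]] %in% names(tab)) {
    tab[[map[["endpoint"]]]]
  } else {
    rep(endpoint, nrow(tab))
  }
  keep <- is.finite(value) & value > 0
  k <- sum(keep)
  out <- data.frame(smiles = tab[[map[["smiles"]]]][keep],
                    endpoint = ep[keep],
                    value = value[keep],
                    qualifier = rep("none", k),
                    date = rep(as.Date(NA), k),
                    modality = rep("unknown", k),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) warning("ingest_external: no valid rows in ", path)
  attr(out, "dropped") <- sum(!keep)
  out
}
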
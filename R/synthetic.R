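# Synthetic assay-data generator. Produces raw measurement tables with the
# statistical structure of a large industrial permeability collection:
# four correlated endpoints observed sparsely per compound, heteroscedastic
# replicate noise, a late-introduced assay, modality labels dominated by
# small molecules, and out-of-bound (censored) readings. Molecules come from
# a packaged fragment-combination grammar, so no external source is needed
# and every structure parses.

#' Configuration of the synthetic assay-data generator
#'
#' Defaults encode the study conditions the generator is meant to emulate:
#' a 57/37/5/1 percent split of compounds having 1/2/3/4 endpoints, endpoint
#' prevalence proportional to the four assay volumes, pairwise endpoint
#' correlation 0.8 through a shared structure-derived latent factor,
#' heteroscedastic permeability noise (larger sigma at low log Papp) and
#' near-constant efflux noise calibrated so that most efflux replicate
#' groups have SD < 0.1 and most permeability groups SD < 0.2, a
#' late-starting NIH MDCK assay covering the last 45 percent of the
#' timeline, small-molecule-dominated modalities, and assay quantification
#' limits that censor a small fraction of readings.
#'
#' @param n_compounds number of distinct compounds.
#' @param coverage_probs probabilities of a compound having 1/2/3/4
#'   endpoints; must sum to 1.
#' @param latent_correlation target pairwise correlation between endpoint
#'   true values, in [0, 1].
#' @param endpoint_params per-endpoint list of `mu`, `scale`, `skew`
#'   (right-skew weight on the positive part of the latent),
#'   `noise_intercept`, `noise_slope`, `noise_floor` (replicate sigma as a
#'   function of the true mean, log10 units), `censor_lo`, `censor_hi`
#'   (raw-scale quantification limits).
#' @param endpoint_weights relative prevalence used when drawing which
#'   endpoints a compound has.
#' @param replicate_rate probability that a (compound, endpoint) record has
#'   replicates rather than a single measurement.
#' @param replicate_count_probs distribution of the replicate count 2/3/4
#'   given replicates (triplicate-centred by default).
#' @param late_endpoint endpoint whose assay starts late.
#' @param late_start fraction of the timeline at which the late assay
#'   starts.
#' @param timeline_start,timeline_end dates mapped to timeline fractions 0
#'   and 1.
#' @param modality_probs modality label distribution.
#' @param outlier_frac fraction of compounds planted as high-variability
#'   outliers (their replicate sigma is inflated and they are always
#'   re-measured).
#' @param outlier_inflation sigma multiplier for planted outliers.
#' @param seed integer seed; regeneration with the same config is
#'   byte-identical.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 2000,
                             coverage_probs = c(0.57, 0.37, 0.05, 0.01),
                             latent_correlation = 0.8,
                             endpoint_params = NULL,
                             endpoint_weights = c(Caco2ER = 12482, Caco2Papp = 13855,
                                                  MDCKER = 4801, NIHMDCKER = 3081),
                             replicate_rate = 0.3,
                             replicate_count_probs = c(`2` = 0.25, `3` = 0.5, `4` = 0.25),
                             late_endpoint = "NIHMDCKER",
                             late_start = 0.55,
                             timeline_start = as.Date("2015-01-01"),
                             timeline_end = as.Date("2024-05-05"),
                             modality_probs = c(small_molecule = 0.85, macrocycle = 0.07,
                                                peptide = 0.05, PROTAC = 0.03),
                             outlier_frac = 0,
                             outlier_inflation = 5,
                             seed = 1) {
  if (is.null(endpoint_params)) {
    endpoint_params <- list(
      Caco2ER = list(mu = 1.5, scale = 0.7, skew = 0.15,
                     noise_intercept = 0.04, noise_slope = 0, noise_floor = 0.02,
                     censor_lo = 0.05, censor_hi = 3000),
      Caco2Papp = list(mu = 1.0, scale = 0.45, skew = 0.35,
                       noise_intercept = 0.28, noise_slope = -0.12, noise_floor = 0.02,
                       censor_lo = 0.5, censor_hi = 100),
      MDCKER = list(mu = 0.6, scale = 0.5, skew = 0.1,
                    noise_intercept = 0.04, noise_slope = 0, noise_floor = 0.02,
                    censor_lo = 0.05, censor_hi = 300),
      NIHMDCKER = list(mu = 0.7, scale = 0.55, skew = 0.1,
                       noise_intercept = 0.04, noise_slope = 0, noise_floor = 0.02,
                       censor_lo = 0.05, censor_hi = 300)
    )
  }
  cfg <- structure(list(n_compounds = n_compounds, coverage_probs = coverage_probs,
                        latent_correlation = latent_correlation,
                        endpoint_params = endpoint_params,
                        endpoint_weights = endpoint_weights,
                        replicate_rate = replicate_rate,
                        replicate_count_probs = replicate_count_probs,
                        late_endpoint = late_endpoint, late_start = late_start,
                        timeline_start = timeline_start, timeline_end = timeline_end,
                        modality_probs = modality_probs,
                        outlier_frac = outlier_frac,
                        outlier_inflation = outlier_inflation, seed = seed),
                   class = "generator_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!is.numeric(cfg$n_compounds) || cfg$n_compounds < 1) bad <- c(bad, "n_compounds")
  if (length(cfg$coverage_probs) != 4 || any(cfg$coverage_probs < 0) ||
      abs(sum(cfg$coverage_probs) - 1) > 1e-8) bad <- c(bad, "coverage_probs")
  if (cfg$latent_correlation < 0 || cfg$latent_correlation > 1) bad <- c(bad, "latent_correlation")
  if (!all(endpoint_names() %in% names(cfg$endpoint_params))) bad <- c(bad, "endpoint_params")
  if (!all(endpoint_names() %in% names(cfg$endpoint_weights))) bad <- c(bad, "endpoint_weights")
  if (cfg$replicate_rate < 0 || cfg$replicate_rate > 1) bad <- c(bad, "replicate_rate")
  if (abs(sum(cfg$replicate_count_probs) - 1) > 1e-8) bad <- c(bad, "replicate_count_probs")
  if (!cfg$late_endpoint %in% endpoint_names()) bad <- c(bad, "late_endpoint")
  if (cfg$late_start < 0 || cfg$late_start >= 1) bad <- c(bad, "late_start")
  if (abs(sum(cfg$modality_probs) - 1) > 1e-8 || any(cfg$modality_probs < 0)) bad <- c(bad, "modality_probs")
  if (cfg$outlier_frac < 0 || cfg$outlier_frac > 0.5) bad <- c(bad, "outlier_frac")
  for (ep in endpoint_names()) {
    p <- cfg$endpoint_params[[ep]]
    if (is.null(p$noise_floor) || p$noise_floor <= 0) bad <- c(bad, paste0("endpoint_params$", ep, "$noise_floor"))
    if (!is.null(p$censor_lo) && !is.null(p$censor_hi) && p$censor_lo >= p$censor_hi) {
      bad <- c(bad, paste0("endpoint_params$", ep, "$censor limits"))
    }
  }
  if (length(bad)) stop("invalid generator_config field(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

load_grammar <- function() {
  path <- system.file("extdata", "fragment_grammar.tsv", package = "mtperm")
  if (path == "") path <- file.path("inst", "extdata", "fragment_grammar.tsv")
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  g$smiles[is.na(g$smiles)] <- ""
  split(g, g$role)
}

core_smiles <- function(core_row, digits, branch = "") {
  halves <- strsplit(core_row$smiles, "|", fixed = TRUE)[[1]]
  pre <- halves[1]; post <- halves[2]
  for (i in seq_along(digits)) {
    ph <- c("x", "y")[i]
    pre <- gsub(ph, digits[i], pre, fixed = TRUE)
    post <- gsub(ph, digits[i], post, fixed = TRUE)
  }
  if (nzchar(branch)) paste0(pre, "(", branch, ")", post) else paste0(pre, post)
}

#' Sample a synthetic compound library
#'
#' Draws distinct, parseable molecules from the packaged
#' fragment-combination grammar. Small molecules are one- or two-ring
#' assemblies of heteroaromatic and saturated cores with common
#' substituents and linkers; macrocycles use 12-16-membered rings; peptides
#' are di-/tripeptide backbones with natural side chains; PROTAC-like
#' molecules join two ring systems through a PEG linker to a third ring.
#' All SMILES are returned in canonical form.
#'
#' @param n number of distinct molecules.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param modality_probs distribution over modality classes.
#' @return data.frame with columns `smiles` (canonical, unique) and
#'   `modality`.
#' @export
sample_library <- function(n, seed = 1,
                           modality_probs = c(small_molecule = 0.85, macrocycle = 0.07,
                                              peptide = 0.05, PROTAC = 0.03)) {
  stopifnot(n >= 1)
  g <- load_grammar()
  pick <- function(df) df[sample(nrow(df), 1), , drop = FALSE]
  build_one <- function(modality) {
    if (modality == "macrocycle") {
      core <- pick(g$macro)
      branch <- if (stats::runif(1) < 0.7) pick(g$subb)$smiles else ""
      paste0(sample(g$suba$smiles, 1), core_smiles(core, "1", branch))
    } else if (modality == "peptide") {
      n_res <- sample(2:3, 1)
      sc <- sample(g$sidechain$smiles, n_res, replace = TRUE)
      paste0("C", paste0(vapply(sc, function(s) paste0("NC(", s, ")C(=O)"), ""),
                         collapse = ""), "O")
    } else if (modality == "PROTAC") {
      c1 <- pick(g$core); c2 <- pick(g$core); c3 <- pick(g$core)
      inner <- paste0("CCOCCOCC", core_smiles(c3, c("5", "6")))
      branch2 <- core_smiles(c2, c("3", "4"), inner)
      paste0(sample(g$suba$smiles, 1), core_smiles(c1, c("1", "2"), branch2))
    } else {
      c1 <- pick(g$core)
      a <- sample(g$suba$smiles, 1)
      if (stats::runif(1) < 0.55) {          # two-ring assembly
        c2 <- pick(g$core)
        lk <- if (stats::runif(1) < 0.7) pick(g$linker)$smiles else ""
        b2 <- if (stats::runif(1) < 0.5) pick(g$subb)$smiles else ""
        branch <- paste0(lk, core_smiles(c2, c("3", "4"), b2))
      } else {
        branch <- pick(g$subb)$smiles
      }
      paste0(a, core_smiles(c1, c("1", "2"), branch))
    }
  }
  with_seed(seed, {
    out_smiles <- character(0); out_mod <- character(0)
    attempts <- 0
    while (length(out_smiles) < n) {
      attempts <- attempts + 1
      if (attempts > 60) stop("sample_library: grammar capacity exhausted for n = ", n)
      k <- max(50, ceiling(1.3 * (n - length(out_smiles))))
      mods <- sample(names(modality_probs), k, replace = TRUE, prob = modality_probs)
      raw <- vapply(mods, build_one, "")
      can <- ob_convert_smiles(raw, "CAN")
      ok <- !is.na(can) & !duplicated(can) & !can %in% out_smiles
      out_smiles <- c(out_smiles, can[ok])
      out_mod <- c(out_mod, mods[ok])
    }
    data.frame(smiles = out_smiles[seq_len(n)], modality = out_mod[seq_len(n)],
               stringsAsFactors = FALSE)
  })
}

#' True endpoint values from a shared structure-derived latent factor
#'
#' Each compound gets a latent factor `z`: a standardized linear combination
#' of its physicochemical descriptors (lipophilicity up; polar surface
#' area, weight and H-bond donors down), so the truth is learnable from
#' structure. Endpoint j is
#' `mu_j + scale_j * g_j + skew_j * max(g_j, 0)` with
#' `g_j = sqrt(rho) * z + sqrt(1 - rho) * e_j`, giving pairwise endpoint
#' correlation close to `rho` and a right-skewed permeability distribution.
#'
#' @param descriptors matrix from [compute_descriptors()] (any set
#'   containing `LogDProxy`, `TPSA`, `MolWt`, `NHOHCount`, `RingCount`).
#' @param config a `generator_config`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return Matrix n x 4 of true log10 values, rownames from `descriptors`.
#' @export
latent_truth <- function(descriptors, config, seed = NULL) {
  need <- c("LogDProxy", "TPSA", "MolWt", "NHOHCount", "RingCount")
  miss <- setdiff(need, colnames(descriptors))
  if (length(miss)) stop("latent_truth: descriptors lack ", paste(miss, collapse = ", "))
  w <- c(LogDProxy = 0.5, TPSA = -0.35, MolWt = -0.25, NHOHCount = -0.2,
         RingCount = 0.15)
  x <- descriptors[, need, drop = FALSE]
  x <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(col * 0)
    (col - mean(col)) / s
  })
  z <- as.numeric(x %*% w[need])
  z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  rho <- config$latent_correlation
  with_seed(seed, {
    n <- length(z)
    truth <- sapply(endpoint_names(), function(ep) {
      p <- config$endpoint_params[[ep]]
      g <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      p$mu + p$scale * g + p$skew * pmax(g, 0)
    })
    rownames(truth) <- rownames(descriptors)
    truth
  })
}

#' Gaussian replicate measurements with mean-dependent sigma
#'
#' Replicate sigma follows the endpoint's heteroscedastic model
#' `sigma(m) = max(floor, intercept + slope * m)`. Each compound yields one
#' measurement with probability `1 - replicate_rate`, otherwise 2-4
#' replicates (triplicate-centred).
#'
#' @param true_log vector of true log10 values.
#' @param endpoint one of [endpoint_names()].
#' @param config a `generator_config`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param sigma_mult per-compound sigma multiplier (planted outliers).
#' @param force_replicates logical per compound: always draw >= 2 replicates.
#' @return data.frame with columns `index` (into `true_log`) and
#'   `log_value`.
#' @export
make_replicates <- function(true_log, endpoint, config, seed = NULL,
                            sigma_mult = 1, force_replicates = FALSE) {
  p <- config$endpoint_params[[endpoint]]
  sigma <- pmax(p$noise_floor, p$noise_intercept + p$noise_slope * true_log)
  sigma <- sigma * sigma_mult
  n <- length(true_log)
  force_replicates <- rep_len(force_replicates, n)
  with_seed(seed, {
    has_rep <- stats::runif(n) < config$replicate_rate | force_replicates
    counts <- ifelse(has_rep,
                     sample(as.integer(names(config$replicate_count_probs)),
                            n, replace = TRUE, prob = config$replicate_count_probs),
                     1L)
    idx <- rep(seq_len(n), counts)
    data.frame(index = idx,
               log_value = stats::rnorm(length(idx), true_log[idx], sigma[idx]))
  })
}

#' Assign endpoint coverage and timestamps
#'
#' Draws each compound's endpoint count from `coverage_probs`, chooses which
#' endpoints it has with probability proportional to the endpoint
#' prevalences, and assigns each (compound, endpoint) record a timestamp
#' uniform over the timeline - except the late endpoint, whose records all
#' postdate its start fraction.
#'
#' @param compounds character vector of compound identifiers (SMILES).
#' @param config a `generator_config`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return data.frame with columns `smiles`, `endpoint`, `time_frac`,
#'   `date`.
#' @export
assign_coverage_and_time <- function(compounds, config, seed = NULL) {
  eps <- endpoint_names()
  w <- config$endpoint_weights[eps] / sum(config$endpoint_weights[eps])
  n <- length(compounds)
  with_seed(seed, {
    counts <- sample(1:4, n, replace = TRUE, prob = config$coverage_probs)
    # weighted sampling without replacement via exponential-race keys,
    # vectorized over compounds
    keys <- matrix(stats::rexp(n * 4) / rep(w, each = n), n, 4)
    ord <- apply(keys, 1, order)            # 4 x n, best endpoint first
    sel_i <- rep(seq_len(n), counts)
    sel_rank <- unlist(lapply(counts, seq_len), use.names = FALSE)
    sel_ep <- eps[ord[cbind(sel_rank, sel_i)]]
    out <- data.frame(smiles = compounds[sel_i], endpoint = sel_ep,
                      stringsAsFactors = FALSE)
    m <- nrow(out)
    tf <- stats::runif(m)
    late <- out$endpoint == config$late_endpoint
    tf[late] <- config$late_start + tf[late] * (1 - config$late_start)
    out$time_frac <- tf
    span <- as.numeric(config$timeline_end - config$timeline_start)
    out$date <- config$timeline_start + round(tf * span)
    out
  })
}

#' Censor values at assay quantification limits
#'
#' Raw-scale values below the lower limit are reported as the limit with a
#' `lower_bound` qualifier; values above the upper limit as the limit with
#' `upper_bound`; in-range values pass through unchanged.
#'
#' @param values raw-scale (not log) measurement values.
#' @param lower,upper quantification limits.
#' @return data.frame with columns `value` and `qualifier`.
#' @export
censor <- function(values, lower, upper) {
  qual <- rep("none", length(values))
  qual[values < lower] <- "lower_bound"
  qual[values > upper] <- "upper_bound"
  data.frame(value = pmin(pmax(values, lower), upper), qualifier = qual,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic assay dataset
#'
#' Composes the library sampler, the latent truth model, coverage and
#' timestamp assignment, replicate generation and censoring into a raw
#' measurement table that round-trips through [curate()] with zero
#' unparsable structures. Regeneration with the same config is
#' byte-identical.
#'
#' @param config a [generator_config()].
#' @return Object of class `synthetic_dataset`: list with `measurements`
#'   (raw measurement data.frame), `truth` (n x 4 matrix of true log
#'   values), `outlier_smiles` (planted high-variability compounds),
#'   `descriptors` (the baseline descriptor matrix used for the truth) and
#'   `config`.
#' @export
generate <- function(config) {
  validate_config(config)
  with_seed(config$seed, {
    lib <- sample_library(config$n_compounds, seed = NULL,
                          modality_probs = config$modality_probs)
    desc <- compute_descriptors(lib$smiles, "baseline_full", impute = TRUE)
    truth <- latent_truth(desc, config, seed = NULL)
    cov <- assign_coverage_and_time(lib$smiles, config, seed = NULL)

    n_out <- round(config$outlier_frac * config$n_compounds)
    outlier_smiles <- if (n_out > 0) sample(lib$smiles, n_out) else character(0)

    meas <- lapply(endpoint_names(), function(ep) {
      sel <- cov[cov$endpoint == ep, , drop = FALSE]
      if (!nrow(sel)) return(NULL)
      i <- match(sel$smiles, lib$smiles)
      is_out <- sel$smiles %in% outlier_smiles
      reps <- make_replicates(truth[i, ep], ep, config, seed = NULL,
                              sigma_mult = ifelse(is_out, config$outlier_inflation, 1),
                              force_replicates = is_out)
      p <- config$endpoint_params[[ep]]
      cen <- censor(10^reps$log_value, p$censor_lo, p$censor_hi)
      data.frame(smiles = sel$smiles[reps$index],
                 endpoint = ep,
                 value = cen$value,
                 qualifier = cen$qualifier,
                 date = sel$date[reps$index],
                 modality = lib$modality[i][reps$index],
                 stringsAsFactors = FALSE)
    })
    meas <- do.call(rbind, meas)
    meas <- meas[order(meas$smiles, meas$endpoint, meas$date, meas$value), , drop = FALSE]
    rownames(meas) <- NULL
    structure(list(measurements = meas, truth = truth,
                   outlier_smiles = outlier_smiles,
                   descriptors = desc, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d measurements over %d compounds (seed %d)\n",
              nrow(x$measurements), nrow(x$truth), x$config$seed))
  print(table(x$measurements$endpoint))
  invisible(x)
}
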
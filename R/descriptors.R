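# Physicochemical descriptors and fingerprints. Bulk properties come from
# OpenBabel (propOB); counting descriptors are computed on the molfile graph;
# ionizable-group pKa proxies use SMARTS rules with group-typical values.

.acid_rules <- list(
  list(smarts = "[SX4](=O)(=O)[OX2H1]", pka = -1.0),   # sulfonic acid
  list(smarts = "[CX3](=O)[OX2H1]",     pka = 4.0),    # carboxylic acid
  list(smarts = "c1nn[nH]n1",           pka = 4.9),    # tetrazole
  list(smarts = "[OX2H][c]",            pka = 9.9)     # phenol
)

.base_rules <- list(
  list(smarts = "[NX3][CX3]=[NX2]",                          pka = 12.5), # amidine/guanidine
  list(smarts = "[NX3;H2,H1,H0;!$(NC=O);!$(N[c]);!$(N=*);!$(NS=O)]", pka = 10.0), # aliphatic amine
  list(smarts = "[nX2]",                                     pka = 5.2),  # azine nitrogen
  list(smarts = "[NX3;H2,H1][c]",                            pka = 4.6)   # aniline
)

smarts_counts <- function(sdf, smarts) {
  res <- tryCatch(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE),
                  error = function(e) rep(0L, length(sdf)))
  as.integer(res)
}

graph_descriptors <- function(smiles) {
  mf <- ob_molfiles(smiles)
  out <- matrix(NA_real_, length(smiles), 5,
                dimnames = list(NULL, c("RingCount", "HeavyAtoms", "RotBonds",
                                        "GraphComplexity", "HeteroAtoms")))
  for (i in seq_along(mf)) {
    if (is.na(mf[i])) next
    mol <- parse_molfile(mf[i])
    na <- mol$n_atoms
    nb <- nrow(mol$bonds)
    # standardized structures are single fragments: cyclomatic ring count
    ring <- nb - na + 1L
    deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = na)
    ringb <- ring_bonds(mol)
    rot <- sum(mol$bonds$order == 1 & !ringb &
                 deg[mol$bonds$a1] > 1 & deg[mol$bonds$a2] > 1)
    hetero <- sum(!mol$elem %in% c("C", "H"))
    out[i, ] <- c(ring, na, rot,
                  if (nb > 0) nb * log2(nb + 1) else 0,
                  hetero)
  }
  out
}

# a bond lies on a ring iff it is not a bridge: removing it leaves its two
# atoms connected; only framework bonds (rings + linkers) are candidates
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  res <- rep(FALSE, nb)
  if (nb == 0 || nb - mol$n_atoms + 1L <= 0) return(res)
  core <- murcko_core_only(mol)
  cand <- which(mol$bonds$a1 %in% core & mol$bonds$a2 %in% core)
  adj <- vector("list", mol$n_atoms)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  other <- function(k, v) if (mol$bonds$a1[k] == v) mol$bonds$a2[k] else mol$bonds$a1[k]
  for (k in cand) {
    src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
    seen <- rep(FALSE, mol$n_atoms); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- other(e, v)
        if (!seen[w]) {
          if (w == dst) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    res[k] <- found
  }
  res
}

# framework atoms without the exocyclic re-attachment (rings + linkers only)
murcko_core_only <- function(mol) {
  alive <- rep(TRUE, mol$n_atoms)
  adj <- mol$bonds
  repeat {
    act <- adj[alive[adj$a1] & alive[adj$a2], , drop = FALSE]
    tb <- tabulate(c(act$a1, act$a2), nbins = mol$n_atoms)
    terminal <- which(alive & tb <= 1)
    if (!length(terminal)) break
    alive[terminal] <- FALSE
    if (!any(alive)) break
  }
  which(alive)
}

#' Compute molecular descriptors for modeling
#'
#' Three descriptor sets are available, mirroring the three levels of
#' feature augmentation used by the multitask models:
#' \describe{
#'   \item{`"plus"`}{physchem proxies only: `LogDProxy` (computed
#'     octanol/water partition estimate standing in for measured LogD) and
#'     `PkaAcidProxy`/`PkaBaseProxy` (group-typical pKa values of the
#'     strongest acidic and basic ionizable group found by SMARTS rules;
#'     `NA` when the molecule has no such group).}
#'   \item{`"plusplus"`}{the proxies plus eight structural descriptors with
#'     established relevance to permeability: `MolWt`, `TPSA`, `RingCount`,
#'     `NHOHCount`, `HBA`, `MolarRefractivity`, `RotBonds`,
#'     `GraphComplexity` (a bond-count complexity index).}
#'   \item{`"baseline_full"`}{every descriptor the backend computes, with
#'     constant and all-missing columns dropped; used by the random-forest
#'     baseline.}
#' }
#'
#' @param smiles character vector of standardized SMILES.
#' @param set descriptor set, see above.
#' @param impute if `TRUE` (default), `NA` entries (e.g. pKa proxies of
#'   molecules without ionizable groups) are median-imputed column-wise and
#'   the affected columns gain a paired `_missing` indicator column.
#' @return Numeric matrix, one row per input SMILES (rownames = input),
#'   deterministic for a given input.
#' @export
compute_descriptors <- function(smiles,
                                set = c("plusplus", "plus", "baseline_full"),
                                impute = TRUE) {
  set <- match.arg(set)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  sdf <- smiles_to_sdfset(smiles)
  p <- ChemmineR::propOB(sdf)
  gd <- graph_descriptors(smiles)
  nhoh <- smarts_counts(sdf, "[#7;!H0]") + smarts_counts(sdf, "[#8;!H0]")

  acid <- rep(NA_real_, length(smiles))
  for (rule in .acid_rules) {
    hit <- smarts_counts(sdf, rule$smarts) > 0
    acid[hit & is.na(acid)] <- rule$pka
  }
  base <- rep(NA_real_, length(smiles))
  for (rule in .base_rules) {
    hit <- smarts_counts(sdf, rule$smarts) > 0
    base[hit & (is.na(base) | rule$pka > base)] <- rule$pka
  }

  full <- cbind(
    LogDProxy = p$logP,
    PkaAcidProxy = acid,
    PkaBaseProxy = base,
    MolWt = p$MW,
    TPSA = p$TPSA,
    RingCount = gd[, "RingCount"],
    NHOHCount = nhoh,
    HBA = p$HBA2,
    HBD = p$HBD,
    MolarRefractivity = p$MR,
    RotBonds = gd[, "RotBonds"],
    GraphComplexity = gd[, "GraphComplexity"],
    HeavyAtoms = gd[, "HeavyAtoms"],
    HeteroAtoms = gd[, "HeteroAtoms"],
    NumF = p$nF
  )
  rownames(full) <- smiles
  cols <- switch(set,
    plus = c("LogDProxy", "PkaAcidProxy", "PkaBaseProxy"),
    plusplus = c("LogDProxy", "PkaAcidProxy", "PkaBaseProxy", "MolWt", "TPSA",
                 "RingCount", "NHOHCount", "HBA", "MolarRefractivity",
                 "RotBonds", "GraphComplexity"),
    baseline_full = colnames(full))
  out <- full[, cols, drop = FALSE]
  if (set == "baseline_full") {
    keep <- apply(out, 2, function(x) {
      xf <- x[is.finite(x)]
      if (!length(xf)) return(FALSE)                  # all missing
      length(unique(xf)) > 1 || anyNA(x)              # not constant
    })
    if (nrow(out) > 1) out <- out[, keep, drop = FALSE]
  }
  if (impute) out <- impute_median(out)
  out
}

# median-impute NA cells, adding *_missing indicator columns; `stats` may
# carry training medians so test-fold imputation cannot leak
impute_median <- function(x, stats = NULL) {
  nas <- colSums(is.na(x)) > 0
  if (!any(nas) && is.null(stats)) return(x)
  med <- stats %||% apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  ind <- NULL
  for (j in which(colSums(is.na(x)) > 0)) {
    indicator <- as.numeric(is.na(x[, j]))
    ind <- cbind(ind, indicator)
    colnames(ind)[ncol(ind)] <- paste0(colnames(x)[j], "_missing")
    x[is.na(x[, j]), j] <- med[[colnames(x)[j]]]
  }
  attr(x, "impute_medians") <- med
  if (!is.null(ind)) x <- cbind(x, ind)
  x
}

#' Hashed structural fingerprints for the reference encoder
#'
#' Computes 1024-bit binary fingerprints from atom-pair descriptors. This is
#' the package's desk-scale molecular encoder; any function mapping SMILES
#' to a fixed-width numeric matrix can be plugged into [fit_mtl()] in its
#' place (e.g. a learned graph encoder).
#'
#' @param smiles character vector of standardized SMILES.
#' @param bits fingerprint width (default 1024).
#' @return Numeric 0/1 matrix, rownames = input SMILES.
#' @export
fingerprint_matrix <- function(smiles, bits = 1024) {
  sdf <- smiles_to_sdfset(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  # the default atom-pair vocabulary ships as a lazy data object; load it
  # explicitly so the call works without ChemmineR on the search path
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  vocab <- as.character(e$apfp$AP)[seq_len(bits)]
  fp <- ChemmineR::desc2fp(ap, descnames = vocab, type = "matrix")
  storage.mode(fp) <- "numeric"
  rownames(fp) <- smiles
  fp
}
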
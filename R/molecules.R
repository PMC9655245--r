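#' Read an activity table
#'
#' Reads a CSV in the style of a ChEMBL activity export with columns
#' `mol_id`, `smiles`, `activity_nM` (IC50, may be empty for untagged pool
#' molecules) and `target`. SMILES are canonicalized on load; records whose
#' SMILES do not parse are dropped with a warning.
#'
#' @param file path to a CSV file.
#' @return data.frame with columns mol_id, smiles (canonical), activity_nM,
#'   target.
#' @export
read_molecules <- function(file) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("mol_id", "smiles")
  if (!all(need %in% names(raw)))
    stop("activity CSV must have columns mol_id and smiles")
  if (is.null(raw$activity_nM)) raw$activity_nM <- NA_real_
  if (is.null(raw$target)) raw$target <- NA_character_
  if (anyDuplicated(raw$mol_id)) stop("duplicated mol_id in input")
  can <- canonical_smiles(raw$smiles, raw$mol_id)
  out <- raw[match(names(can), raw$mol_id),
             c("mol_id", "smiles", "activity_nM", "target")]
  out$smiles <- unname(can)
  out$activity_nM <- as.numeric(out$activity_nM)
  if (any(!is.na(out$activity_nM) & out$activity_nM <= 0))
    stop("activity_nM must be positive where present")
  rownames(out) <- NULL
  out
}

#' Remove duplicate structures
#'
#' Collapses records sharing a canonical SMILES to a single record. When the
#' duplicates carry different activities the retained activity follows
#' `rule` (geometric mean by default). Records with implausibly high reported
#' potency (probable unit errors) can be excluded via `min_activity_nM`.
#'
#' @param mol data.frame as returned by [read_molecules()] (smiles already
#'   canonical).
#' @param rule how to combine activities of duplicates: "geomean", "min" or
#'   "median".
#' @param min_activity_nM records with activity below this bound are dropped
#'   as probable unit errors; `NULL` disables the check.
#' @return data.frame with unique canonical SMILES; the lexicographically
#'   first mol_id of each duplicate group is retained.
#' @export
deduplicate <- function(mol, rule = c("geomean", "min", "median"),
                        min_activity_nM = 0.1) {
  rule <- match.arg(rule)
  if (nrow(mol) == 0) return(mol)
  if (!is.null(min_activity_nM)) {
    bad <- !is.na(mol$activity_nM) & mol$activity_nM < min_activity_nM
    if (any(bad)) {
      warning(sprintf("dropping %d record(s) with activity < %g nM",
                      sum(bad), min_activity_nM))
      mol <- mol[!bad, , drop = FALSE]
    }
  }
  if (nrow(mol) == 0) return(mol)
  combine <- switch(rule,
    geomean = function(a) exp(mean(log(a))),
    min     = min,
    median  = stats::median)
  parts <- split(mol, mol$smiles)
  out <- do.call(rbind, lapply(parts, function(g) {
    g <- g[order(g$mol_id), , drop = FALSE]
    r <- g[1, , drop = FALSE]
    act <- g$activity_nM[!is.na(g$activity_nM)]
    r$activity_nM <- if (length(act)) combine(act) else NA_real_
    r
  }))
  out <- out[order(out$mol_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Tanimoto similarity matrix
#'
#' Tanimoto index TI = |A intersect B| / |A union B| over fingerprint bit
#' sets. Molecules with an empty fingerprint get TI 0 against every other
#' molecule (with a warning); the diagonal is always 1.
#'
#' @param fp 0/1 fingerprint matrix (rows = molecules) as returned by
#'   [fingerprint_matrix()].
#' @return symmetric numeric matrix in \[0, 1\] with unit diagonal.
#' @export
tanimoto_matrix <- function(fp) {
  stopifnot(is.matrix(fp), nrow(fp) >= 1)
  fp <- fp > 0
  storage.mode(fp) <- "double"
  n_on <- rowSums(fp)
  inter <- tcrossprod(fp)
  union <- outer(n_on, n_on, `+`) - inter
  ti <- ifelse(union > 0, inter / union, 0)
  if (any(n_on == 0))
    warning(sprintf("%d molecule(s) with empty fingerprint; TI set to 0",
                    sum(n_on == 0)))
  diag(ti) <- 1
  dimnames(ti) <- list(rownames(fp), rownames(fp))
  ti
}

#' Diversity pruning by Tanimoto cutoff
#'
#' Greedy pruning: records are visited in mol_id order and a record is
#' dropped when its Tanimoto index to an already-kept record exceeds the
#' cutoff (fingerprint-identical pairs, TI = 1, are always collapsed, so at
#' cutoff 1.0 only exact fingerprint duplicates are removed). All surviving
#' pairs therefore satisfy TI <= cutoff.
#'
#' @param mol data.frame with mol_id and smiles columns.
#' @param cutoff Tanimoto cutoff in \[0.7, 1\].
#' @param ti optional precomputed Tanimoto matrix with mol_id dimnames;
#'   computed from FP2 fingerprints when missing.
#' @return the surviving subset of `mol`, in mol_id order.
#' @export
diversity_prune <- function(mol, cutoff, ti = NULL) {
  stopifnot(cutoff >= 0.7, cutoff <= 1.0)
  if (nrow(mol) == 0) return(mol)
  if (is.null(ti)) {
    fp <- fingerprint_matrix(mol$smiles, mol$mol_id)
    ti <- suppressWarnings(tanimoto_matrix(fp))
  }
  ids <- sort(mol$mol_id)
  kept <- character(0)
  for (id in ids) {
    if (!id %in% rownames(ti)) next
    if (length(kept) == 0 ||
        all(ti[id, kept] <= cutoff & ti[id, kept] < 1)) {
      kept <- c(kept, id)
    }
  }
  out <- mol[mol$mol_id %in% kept, , drop = FALSE]
  out <- out[order(out$mol_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define an activity labelling scheme
#'
#' Two schemes are supported. `"AvI"` (actives vs. inactives): molecules with
#' IC50 below `active_cutoff_nM` (default 10,000 nM) are class 1 and untagged
#' pool/decoy molecules are class 0, with the actives typically diluted
#' ~100:1. `"HvL"` (high vs. low): highly active molecules
#' (IC50 < `active_cutoff_nM`, default 100 nM) against low-activity ones
#' (IC50 > `low_cutoff_nM`, default 1000 nM; a 3000 nM variant is also used);
#' intermediate activities belong to neither class.
#'
#' @param type "AvI" or "HvL".
#' @param active_cutoff_nM upper IC50 bound for class 1.
#' @param low_cutoff_nM lower IC50 bound for class 0 (HvL only).
#' @param dilution_ratio decoy:active ratio (AvI only).
#' @return object of class `activity_scheme`.
#' @export
activity_scheme <- function(type = c("AvI", "HvL"),
                            active_cutoff_nM = if (type == "AvI") 10000 else 100,
                            low_cutoff_nM = 1000,
                            dilution_ratio = 100) {
  type <- match.arg(type)
  if (type == "HvL" && active_cutoff_nM >= low_cutoff_nM)
    stop("HvL requires active_cutoff_nM < low_cutoff_nM")
  structure(list(type = type, active_cutoff_nM = active_cutoff_nM,
                 low_cutoff_nM = low_cutoff_nM,
                 dilution_ratio = dilution_ratio),
            class = "activity_scheme")
}

#' Assign class labels under an activity scheme
#'
#' @param mol data.frame of molecule records; pool molecules have missing
#'   `activity_nM` (AvI only).
#' @param scheme an [activity_scheme()].
#' @return `mol` restricted to classifiable records, with an integer
#'   `class_label` column (1 active / 0 inactive-or-low).
#' @export
assign_classes <- function(mol, scheme) {
  stopifnot(inherits(scheme, "activity_scheme"))
  act <- mol$activity_nM
  if (scheme$type == "AvI") {
    lab <- ifelse(is.na(act), 0L,
                  ifelse(act < scheme$active_cutoff_nM, 1L, NA_integer_))
  } else {
    if (anyNA(act)) stop("HvL scheme requires activities for all records")
    lab <- ifelse(act < scheme$active_cutoff_nM, 1L,
                  ifelse(act > scheme$low_cutoff_nM, 0L, NA_integer_))
  }
  out <- mol[!is.na(lab), , drop = FALSE]
  out$class_label <- lab[!is.na(lab)]
  if (!any(out$class_label == 1L) || !any(out$class_label == 0L))
    stop("untrainable scheme: one class is empty after labelling")
  rownames(out) <- NULL
  out
}

#' Sample property-matched decoys
#'
#' Dilutes the actives with pool molecules whose H-bond donor count, acceptor
#' count, molecular weight and calculated logP each lie within
#' mean +/- `tolerance` * sd of the actives' distribution (the applicability
#' domain of the model). Sampling among eligible pool members is uniform
#' under the given seed.
#'
#' @param actives,pool data.frames with mol_id and smiles.
#' @param ratio decoys per active (default 100).
#' @param tolerance half-width of the property windows in active-sd units.
#' @param seed integer seed for reproducible sampling.
#' @param props_actives,props_pool optional precomputed descriptor tables
#'   (rows keyed by mol_id) to avoid recomputation.
#' @return data.frame of `ratio * nrow(actives)` pool records.
#' @export
sample_decoys <- function(actives, pool, ratio = 100, tolerance = 1.5,
                          seed = 1, props_actives = NULL, props_pool = NULL) {
  stopifnot(nrow(actives) >= 1, nrow(pool) >= 1, ratio > 0)
  keys <- c("HBD", "HBA", "weight", "logP")
  if (is.null(props_actives))
    props_actives <- descriptor_table(actives$smiles, actives$mol_id)
  if (is.null(props_pool))
    props_pool <- descriptor_table(pool$smiles, pool$mol_id)
  props_pool <- props_pool[pool$mol_id, , drop = FALSE]
  mu <- colMeans(props_actives[, keys, drop = FALSE])
  sg <- apply(props_actives[, keys, drop = FALSE], 2, sd)
  sg[sg == 0] <- .Machine$double.eps
  inside <- vapply(keys, function(k) {
    abs(props_pool[, k] - mu[k]) <= tolerance * sg[k]
  }, logical(nrow(props_pool)))
  inside <- matrix(inside, nrow = nrow(props_pool), dimnames = list(NULL, keys))
  ok <- rowSums(inside) == length(keys)
  n_needed <- round(ratio * nrow(actives))
  if (sum(ok) < n_needed) {
    short <- vapply(keys, function(k) sum(!inside[, k]), integer(1))
    stop(sprintf(
      "insufficient eligible pool: need %d, have %d (pool rejections per property: %s)",
      n_needed, sum(ok),
      paste(sprintf("%s=%d", keys, short), collapse = ", ")))
  }
  set.seed(seed)
  pick <- sort(sample(which(ok), n_needed))
  out <- pool[pick, , drop = FALSE]
  out$class_label <- 0L
  rownames(out) <- NULL
  out
}

#' Reject uninformative or redundant descriptors
#'
#' Drops columns with variance below `var_threshold`, then resolves highly
#' correlated pairs (|Pearson r| > `corr_threshold`) by keeping the column
#' with the larger variance (ties broken by lexicographically first name).
#' The operation is idempotent.
#'
#' @param x numeric data.frame or matrix of descriptors.
#' @param var_threshold minimum variance to survive.
#' @param corr_threshold maximum |r| tolerated between surviving columns.
#' @return `x` restricted to surviving columns (original column order).
#' @export
reject_descriptors <- function(x, var_threshold = 1e-8, corr_threshold = 0.95) {
  xm <- as.matrix(x)
  v <- apply(xm, 2, stats::var)
  keep <- colnames(xm)[v >= var_threshold]
  if (length(keep) == 0) stop("all descriptors rejected by variance filter")
  # visit in decreasing variance (ties: name order) and keep a column only if
  # it is not too correlated with anything already kept
  ord <- keep[order(-v[keep], keep)]
  kept <- character(0)
  for (cn in ord) {
    if (length(kept) == 0 ||
        all(abs(suppressWarnings(cor(xm[, cn], xm[, kept]))) <= corr_threshold,
            na.rm = TRUE)) {
      kept <- c(kept, cn)
    }
  }
  if (length(kept) == 0) stop("all descriptors rejected")
  x[, colnames(xm)[colnames(xm) %in% kept], drop = FALSE]
}

#' Stratified five-fold assignment
#'
#' Randomly partitions molecules into `k` folds so that each fold has the
#' same class proportion as the whole set to within one molecule per class.
#'
#' @param labels integer 0/1 class labels, named by mol_id (or unnamed).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k, same names as `labels`.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < k || n0 < k)
    stop(sprintf("each class must have at least k=%d members (have %d/%d)",
                 k, n1, n0))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  names(fold) <- names(labels)
  fold
}
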
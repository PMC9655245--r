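#' Normalize score components to \[0, 1\]
#'
#' Model indexes (in \[-1, 1\]) are mapped through (x + 1) / 2; pose counts
#' are divided by their declared maximum (10 per structure, e.g. 30 when
#' three structures were used); docked flags must already be 0/1. The
#' mapping is bijective on each component's range.
#'
#' @param x data.frame / matrix of raw components (rows = molecules).
#' @param index_cols names of index columns.
#' @param pose_cols named integer vector: column name -> maximum pose count.
#' @param flag_cols names of 0/1 flag columns.
#' @return numeric matrix of normalized components in \[0, 1\].
#' @export
normalize_components <- function(x, index_cols = character(),
                                 pose_cols = integer(),
                                 flag_cols = character()) {
  xm <- as.matrix(x[, c(index_cols, names(pose_cols), flag_cols),
                    drop = FALSE])
  for (cn in index_cols) {
    v <- xm[, cn]
    if (any(v < -1 - 1e-9 | v > 1 + 1e-9))
      stop("index component out of [-1, 1]: ", cn)
    xm[, cn] <- (v + 1) / 2
  }
  for (cn in names(pose_cols)) {
    v <- xm[, cn]
    if (any(v < 0 | v > pose_cols[[cn]]))
      stop("pose count out of bounds: ", cn)
    xm[, cn] <- v / pose_cols[[cn]]
  }
  for (cn in flag_cols) {
    if (!all(xm[, cn] %in% c(0, 1))) stop("flag component not binary: ", cn)
  }
  xm
}

#' Weighted candidate score
#'
#' Dot product of normalized components with a non-negative weight vector
#' (renormalized to sum to one), so a maximal component vector scores 1.
#'
#' @param x normalized component matrix (see [normalize_components()]).
#' @param weights named non-negative weights covering exactly the columns
#'   of `x`.
#' @return numeric score vector in \[0, 1\].
#' @export
weighted_score <- function(x, weights) {
  x <- as.matrix(x)
  if (!setequal(colnames(x), names(weights)))
    stop("component/weight name mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights[colnames(x)] / sum(weights)
  as.numeric(x %*% w)
}

#' Calibrate score weights on reference sets
#'
#' Seeded random search on the weight simplex maximizing the separation
#' objective: (fraction of known dual inhibitors scoring above the
#' threshold) minus (fraction of random molecules scoring above it). The
#' uniform weight vector is always among the candidates, so the returned
#' objective is never worse than uniform weighting.
#'
#' @param knowns,randoms normalized component matrices of the reference
#'   sets (known dual-target actives and random molecules).
#' @param threshold selection threshold the objective is evaluated at.
#' @param n_draws number of random simplex points tried.
#' @param seed integer seed.
#' @return list of class `weight_vector`: `weights` (sum to 1),
#'   `objective`, `frac_knowns`, `frac_randoms`.
#' @export
calibrate_weights <- function(knowns, randoms, threshold = 0.5,
                              n_draws = 2000, seed = 1) {
  knowns <- as.matrix(knowns); randoms <- as.matrix(randoms)
  stopifnot(nrow(knowns) >= 1, nrow(randoms) >= 1,
            identical(colnames(knowns), colnames(randoms)))
  p <- ncol(knowns)
  set.seed(seed)
  W <- matrix(rexp(n_draws * p), n_draws, p)
  W <- W / rowSums(W)
  W <- rbind(rep(1 / p, p), W)  # uniform candidate first
  colnames(W) <- colnames(knowns)
  obj <- vapply(seq_len(nrow(W)), function(i) {
    w <- W[i, ]
    mean(knowns %*% w > threshold) - mean(randoms %*% w > threshold)
  }, numeric(1))
  ibest <- which.max(obj)  # first max: deterministic, prefers uniform on tie
  w <- setNames(W[ibest, ], colnames(W))
  if (max(obj) <= 0) {
    warning("reference sets are not separable; returning uniform weights")
    w <- setNames(rep(1 / p, p), colnames(W))
  }
  structure(list(weights = w,
                 objective = max(obj, 0),
                 frac_knowns = mean(knowns %*% w > threshold),
                 frac_randoms = mean(randoms %*% w > threshold)),
            class = "weight_vector")
}

#' Select candidate molecules by weighted score and logP
#'
#' A molecule is selected when every score column strictly exceeds the
#' threshold and its calculated logP is strictly below `logp_max`. Rejected
#' molecules carry the reason of their first failed criterion.
#'
#' @param scored data.frame with `mol_id`, one or more score columns and a
#'   `logP` column.
#' @param score_cols names of the score columns thresholded (default: every
#'   column starting with "score").
#' @param threshold strict lower bound on every score.
#' @param logp_max strict upper bound on calculated logP.
#' @return `scored` sorted by the first score column descending, with
#'   logical `selected` and character `reason` columns.
#' @export
select_candidates <- function(scored, score_cols = NULL, threshold = 0.5,
                              logp_max = 4) {
  if (is.null(score_cols))
    score_cols <- grep("^score", names(scored), value = TRUE)
  stopifnot(length(score_cols) >= 1, "logP" %in% names(scored))
  reason <- rep("", nrow(scored))
  for (cn in score_cols) {
    fail <- scored[[cn]] <= threshold & reason == ""
    reason[fail] <- paste0("score:", cn)
  }
  fail <- scored$logP >= logp_max & reason == ""
  reason[fail] <- "logP"
  scored$selected <- reason == ""
  scored$reason <- reason
  out <- scored[order(-scored[[score_cols[1]]], scored$mol_id), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
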
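#' Matthews correlation coefficient from confusion rates
#'
#' MCC computed from the per-class percentages (or fractions) of a binary
#' classifier: P and N are the true-positive and true-negative rates, Pf and
#' Nf the false-positive and false-negative rates, each relative to its own
#' class (so P + Nf and N + Pf each sum to 100, or to 1 in the fraction
#' convention).
#'
#' \deqn{MCC = \frac{P\,N - P_f\,N_f}{\sqrt{(N+N_f)(N+P_f)(P+N_f)(P+P_f)}}}
#'
#' When any factor of the denominator is zero the coefficient is defined as
#' 0 (the degenerate everything-one-way classifier carries no signal).
#'
#' @param P,N,Pf,Nf non-negative rates (percent or fraction).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(P, N, Pf, Nf) {
  if (any(c(P, N, Pf, Nf) < 0)) stop("rates must be non-negative")
  tot <- P + Nf
  if (abs((N + Pf) - tot) > 1e-6)
    stop("inconsistent rates: P + Nf must equal N + Pf (percent or fraction)")
  den <- (N + Nf) * (N + Pf) * (P + Nf) * (P + Pf)
  if (den == 0) return(0)
  (P * N - Pf * Nf) / sqrt(den)
}

#' Construct a property-range filter
#'
#' A filter is a conjunction of five closed value ranges over five distinct
#' descriptors; a molecule passes iff all five ranges hold.
#'
#' @param descriptor character vector of five distinct descriptor names.
#' @param lo,hi numeric bounds, `lo <= hi` elementwise.
#' @return data.frame of class `ise_filter`.
#' @export
ise_filter <- function(descriptor, lo, hi) {
  stopifnot(length(descriptor) == length(lo), length(lo) == length(hi))
  if (anyDuplicated(descriptor)) stop("filter descriptors must be distinct")
  if (any(lo > hi)) stop("lo must not exceed hi")
  structure(data.frame(descriptor = descriptor, lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("ise_filter", "data.frame"))
}

# logical pass vector of one filter over a descriptor matrix
.filter_pass <- function(filter, x) {
  miss <- setdiff(filter$descriptor, colnames(x))
  if (length(miss))
    stop("descriptor(s) missing from table: ", paste(miss, collapse = ", "))
  pass <- rep(TRUE, nrow(x))
  for (j in seq_len(nrow(filter))) {
    v <- x[, filter$descriptor[j]]
    pass <- pass & v >= filter$lo[j] & v <= filter$hi[j]
  }
  pass
}

#' Evaluate a filter against labelled data
#'
#' @param filter an [ise_filter()].
#' @param x numeric descriptor matrix/data.frame.
#' @param y 0/1 labels, one per row of `x`.
#' @return list of class `filter_performance` with percentages P, N, Pf, Nf
#'   and the MCC.
#' @export
evaluate_filter <- function(filter, x, y) {
  x <- as.matrix(x)
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be represented")
  pass <- .filter_pass(filter, x)
  P <- 100 * mean(pass[y == 1])
  Pf <- 100 * mean(pass[y == 0])
  perf <- list(P = P, N = 100 - Pf, Pf = Pf, Nf = 100 - P)
  perf$mcc <- mcc(perf$P, perf$N, perf$Pf, perf$Nf)
  structure(perf, class = "filter_performance")
}

# candidate (descriptor, range) pool: quantile grid of the active class
# (deciles plus 2% and 5% tails, so mild cuts composable into conjunctions
# are representable), outermost bounds widened to act as one-sided ranges
.candidate_ranges <- function(x, y,
                              probs = c(0, 0.02, 0.05, seq(0.1, 0.9, 0.1),
                                        0.95, 0.98, 1),
                              min_span = 0.5) {
  big <- 1e30
  out <- list()
  for (d in colnames(x)) {
    q <- quantile(x[y == 1, d], probs = probs, names = FALSE)
    keep <- !duplicated(q)
    q <- q[keep]; pr <- probs[keep]
    if (length(q) < 2) next
    q[1] <- -big; q[length(q)] <- big
    pairs <- which(upper.tri(matrix(0, length(q), length(q))), arr.ind = TRUE)
    # only ranges retaining >= min_span of the active class: narrower ranges
    # cannot survive inside a five-way conjunction
    span_ok <- pr[pairs[, 2]] - pr[pairs[, 1]] >= min_span
    pairs <- pairs[span_ok, , drop = FALSE]
    if (nrow(pairs) == 0) next
    out[[d]] <- data.frame(descriptor = d, lo = q[pairs[, 1]],
                           hi = q[pairs[, 2]], stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, out)
  rownames(pool) <- NULL
  pool
}

#' Fit a filter-ensemble classification model by iterative stochastic elimination
#'
#' Builds a classification model made of multiple filters, each a conjunction
#' of five descriptor ranges, scored by the Matthews correlation coefficient.
#' The search discretizes every descriptor into candidate ranges (deciles of
#' the active class), then repeatedly samples random filters from the
#' candidate pool, scores them on the search portion of the data, and
#' stochastically eliminates the worst-contributing (descriptor, range)
#' candidates — elimination probability proportional to their rank in the
#' bottom quantile — until the iteration budget or the pool is exhausted.
#' Surviving top filters are re-evaluated on held-out data and those reaching
#' `mcc_min` are kept, sorted by held-out MCC.
#'
#' Each kept filter stores its held-out confusion rates, which drive the
#' per-molecule screening index (see [predict.ise()]): a molecule gains
#' min(P/Pf, cap) for every filter it passes and loses min(Nf/N, cap) for
#' every filter it fails, averaged over filters; zero denominators are
#' replaced by `eps` percentage points.
#'
#' @param x numeric descriptor matrix or data.frame (rows = molecules).
#' @param y integer 0/1 class labels.
#' @param n_filters maximum number of filters kept in the model.
#' @param mcc_min minimum held-out MCC a filter must reach.
#' @param n_iterations number of search generations.
#' @param gen_size filters sampled per generation.
#' @param elim_frac fraction of the candidate pool exposed to elimination
#'   after each generation.
#' @param holdout fraction of the data held out (stratified) for filter
#'   validation when `xval` is not supplied.
#' @param xval,yval optional explicit validation set (e.g. a cross-validation
#'   fold); overrides `holdout`.
#' @param cap per-filter contribution cap of the screening index (default 1,
#'   so indexes lie in \[-1, 1\]).
#' @param eps zero-denominator smoothing for the index ratios, in percentage
#'   points.
#' @param seed integer seed; the whole fit is deterministic under it.
#' @return object of class `ise`: list with `filters` (list of
#'   [ise_filter()]), `performance` (data.frame of held-out P/N/Pf/Nf/MCC per
#'   filter), `n`, `cap`, `eps`, `descriptors`, `seed` and the matched call.
#' @seealso [predict.ise()], [model_auc()], [screen_cascade()], [ise_cv()]
#' @export
ise <- function(x, y, n_filters = 10, mcc_min = 0.25, n_iterations = 20,
                gen_size = 300, elim_frac = 0.2, holdout = 0.25,
                xval = NULL, yval = NULL, cap = 1, eps = 0.5, seed = 1) {
  cl <- match.call()
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be non-empty")
  if (ncol(x) < 5) stop("need at least five descriptors")
  set.seed(seed)

  if (is.null(xval)) {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    v <- c(sample(idx1, max(1, round(holdout * length(idx1)))),
           sample(idx0, max(1, round(holdout * length(idx0)))))
    xval <- x[v, , drop = FALSE]; yval <- y[v]
    x <- x[-v, , drop = FALSE];   y <- y[-v]
  } else {
    xval <- as.matrix(xval); yval <- as.integer(yval)
  }
  if (!any(yval == 1) || !any(yval == 0))
    stop("validation set must contain both classes")

  pool <- .candidate_ranges(x, y)
  pool$alive <- TRUE
  pool$mcc_sum <- 0
  pool$n_used <- 0

  # pass matrix of every candidate range over the search set: filter
  # evaluation reduces to conjunctions of its columns
  M <- matrix(FALSE, nrow(x), nrow(pool))
  for (i in seq_len(nrow(pool))) {
    v <- x[, pool$descriptor[i]]
    M[, i] <- v >= pool$lo[i] & v <= pool$hi[i]
  }
  act <- y == 1
  n1 <- sum(act); n0 <- sum(!act)
  mcc_of_pass <- function(pass) {
    P <- 100 * sum(pass & act) / n1
    Pf <- 100 * sum(pass & !act) / n0
    mcc(P, 100 - Pf, Pf, 100 - P)
  }

  best <- list()   # signature -> list(rows, mcc_search)
  keep_best <- 5L * n_filters
  for (gen in seq_len(n_iterations)) {
    alive <- which(pool$alive)
    descs <- unique(pool$descriptor[alive])
    if (length(descs) < 5) break
    for (s in seq_len(gen_size)) {
      dsel <- sample(descs, 5)
      rows <- vapply(dsel, function(d) {
        cand <- alive[pool$descriptor[alive] == d]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, integer(1))
      pass <- M[, rows[1]] & M[, rows[2]] & M[, rows[3]] & M[, rows[4]] &
        M[, rows[5]]
      m <- mcc_of_pass(pass)
      pool$mcc_sum[rows] <- pool$mcc_sum[rows] + m
      pool$n_used[rows] <- pool$n_used[rows] + 1
      sig <- paste(sort(rows), collapse = ",")
      if (is.null(best[[sig]]))
        best[[sig]] <- list(rows = rows, mcc = m)
    }
    if (length(best) > 2L * keep_best) {
      ms <- vapply(best, `[[`, numeric(1), "mcc")
      best <- best[order(-ms)[seq_len(keep_best)]]
    }
    # stochastic elimination of the worst-contributing candidates
    used <- which(pool$alive & pool$n_used > 0)
    if (length(used) > 10) {
      avg <- pool$mcc_sum[used] / pool$n_used[used]
      n_bottom <- ceiling(elim_frac * length(used))
      bottom <- used[order(avg)][seq_len(n_bottom)]
      p_elim <- rev(seq_len(n_bottom)) / n_bottom  # worst candidate first
      drop <- bottom[runif(n_bottom) < p_elim]
      for (r in drop) {
        d <- pool$descriptor[r]
        still <- sum(pool$alive[pool$descriptor == d]) > 1 ||
          length(unique(pool$descriptor[pool$alive])) > 5
        if (still) pool$alive[r] <- FALSE
      }
    }
    if (sum(pool$alive) <= 5) break
  }

  if (length(best) == 0) stop("search produced no filters")
  ms <- vapply(best, `[[`, numeric(1), "mcc")
  best <- best[order(-ms)]
  best <- best[seq_len(min(length(best), keep_best))]

  # coordinate refinement: for each top filter, sweep its five slots and
  # greedily substitute the candidate (from any descriptor not already in
  # the filter) that maximizes the search-set MCC
  refine <- function(rows, m0) {
    repeat {
      improved <- FALSE
      for (s in 1:5) {
        others <- rows[-s]
        base <- M[, others[1]] & M[, others[2]] & M[, others[3]] &
          M[, others[4]]
        allowed <- which(!(pool$descriptor %in% pool$descriptor[others]))
        ba <- base & act; bi <- base & !act
        P <- 100 * (crossprod(M[, allowed, drop = FALSE], ba)) / n1
        Pf <- 100 * (crossprod(M[, allowed, drop = FALSE], bi)) / n0
        num <- P * (100 - Pf) - Pf * (100 - P)
        den <- sqrt(pmax((200 - P - Pf) * 100 * 100 * (P + Pf), 0))
        mv <- ifelse(den > 0, num / den, 0)
        ib <- which.max(mv)
        if (mv[ib] > m0 + 1e-9) {
          rows[s] <- allowed[ib]
          m0 <- mv[ib]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(rows = rows, mcc = m0)
  }
  n_refine <- min(length(best), 2L * n_filters)
  for (i in seq_len(n_refine)) best[[i]] <- refine(best[[i]]$rows,
                                                   best[[i]]$mcc)
  # drop duplicates created by refinement converging to the same optimum
  sigs <- vapply(best, function(b) paste(sort(b$rows), collapse = ","),
                 character(1))
  best <- best[!duplicated(sigs)]

  to_filter <- function(rows)
    ise_filter(pool$descriptor[rows], pool$lo[rows], pool$hi[rows])
  val <- lapply(best, function(b) evaluate_filter(to_filter(b$rows),
                                                  xval, yval))
  vm <- vapply(val, `[[`, numeric(1), "mcc")
  sm <- vapply(best, `[[`, numeric(1), "mcc")
  ok <- vm >= mcc_min
  if (!any(ok))
    stop(sprintf("no filter reached held-out MCC >= %.3f (best: %.3f)",
                 mcc_min, max(vm)))
  # rank by search-set MCC (selecting on the held-out estimate would bias
  # the reported held-out performance upward); held-out rates are stored
  ord <- order(-sm)
  ord <- ord[ok[ord]][seq_len(min(sum(ok), n_filters))]

  perf <- do.call(rbind, lapply(val[ord], function(p)
    data.frame(P = p$P, N = p$N, Pf = p$Pf, Nf = p$Nf, mcc = p$mcc)))
  rownames(perf) <- NULL
  structure(list(
    filters = lapply(best[ord], function(b) to_filter(b$rows)),
    performance = perf,
    n = length(ord),
    cap = cap, eps = eps,
    descriptors = colnames(x),
    seed = seed,
    call = cl
  ), class = "ise")
}

#' @export
print.ise <- function(x, ...) {
  cat("Filter-ensemble classification model (iterative stochastic elimination)\n")
  cat(sprintf("  %d filters over %d descriptors; index cap %g, eps %g%%\n",
              x$n, length(x$descriptors), x$cap, x$eps))
  cat(sprintf("  held-out filter MCC: best %.3f, median %.3f\n",
              max(x$performance$mcc), stats::median(x$performance$mcc)))
  invisible(x)
}

#' @export
summary.ise <- function(object, ...) {
  fl <- do.call(rbind, lapply(seq_along(object$filters), function(i) {
    f <- object$filters[[i]]
    data.frame(filter = i,
               ranges = paste(sprintf("%.3g<=%s<=%.3g", f$lo, f$descriptor,
                                      f$hi), collapse = " & "))
  }))
  out <- cbind(fl, object$performance)
  class(out) <- c("summary.ise", "data.frame")
  out
}

#' @export
print.summary.ise <- function(x, ...) {
  cat("ISE model filters (held-out rates in %):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.ise <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$filters), function(i)
    cbind(filter = i, as.data.frame(object$filters[[i]]))))
}

#' @export
plot.ise <- function(x, ...) {
  graphics::barplot(x$performance$mcc, names.arg = seq_len(x$n),
                    xlab = "filter", ylab = "held-out MCC",
                    main = "Filter performance", ...)
  invisible(x)
}

# per-filter capped ratio contributions of one model
.index_terms <- function(object) {
  p <- object$performance
  eps <- object$eps
  list(pass = pmin(p$P / pmax(p$Pf, eps), object$cap),
       fail = pmin(p$Nf / pmax(p$N, eps), object$cap))
}

#' Screening indexes and filter outcomes for new molecules
#'
#' Computes the per-molecule model index: the average over the model's
#' filters of + min(P/Pf, cap) when the molecule passes a filter and
#' - min(Nf/N, cap) when it fails it, where P, Pf, N, Nf are the filter's
#' stored held-out rates (zero denominators replaced by `eps`). With the
#' default cap of 1 the index lies in \[-1, 1\]; positive indexes mark
#' predicted actives.
#'
#' @param object an [ise()] model.
#' @param newdata descriptor matrix/data.frame containing all model
#'   descriptors.
#' @param type `"index"` for the numeric index, `"outcomes"` for the 0/1
#'   pass matrix (molecules x filters).
#' @param ... unused.
#' @return numeric vector of indexes, or integer matrix of outcomes.
#' @export
predict.ise <- function(object, newdata, type = c("index", "outcomes"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  pass <- vapply(object$filters, .filter_pass, logical(nrow(x)), x = x)
  pass <- matrix(pass, nrow = nrow(x))
  if (type == "outcomes") {
    storage.mode(pass) <- "integer"
    rownames(pass) <- rownames(newdata)
    return(pass)
  }
  tr <- .index_terms(object)
  idx <- (pass %*% tr$pass - (!pass) %*% tr$fail) / object$n
  setNames(as.numeric(idx), rownames(newdata))
}

#' Rank-based AUC of model indexes
#'
#' Area under the ROC curve computed from ranks (ties averaged); identical to
#' the Mann-Whitney U statistic divided by n1*n0.
#'
#' @param scores numeric scores (higher = more active).
#' @param y 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of an ISE model on labelled data
#'
#' @param object an [ise()] model.
#' @param x descriptor table.
#' @param y 0/1 labels.
#' @param folds optional fold assignment; when given, the AUC is computed on
#'   the pooled indexes of all rows (the combined test sets convention).
#' @return AUC in \[0, 1\].
#' @export
model_auc <- function(object, x, y, folds = NULL) {
  rank_auc(predict(object, x), y)
}

#' Screen a library through a model cascade
#'
#' The first model is the gate: molecules with a stage-1 index at or below
#' the stage-1 threshold are eliminated and receive no downstream indexes.
#' Survivors are scored by all remaining models in parallel; a molecule
#' passes the cascade when its index exceeds the threshold in every model.
#'
#' @param models ordered list of [ise()] models (first = gate); names are
#'   used as index column names.
#' @param x descriptor table for the library.
#' @param thresholds numeric vector of per-stage index thresholds, recycled
#'   (default 0: positive index required).
#' @return data.frame with one index column per model (NA where not
#'   computed), `eliminated_stage` (NA for cascade survivors) and logical
#'   `pass`.
#' @export
screen_cascade <- function(models, x, thresholds = 0) {
  stopifnot(length(models) >= 1)
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  thr <- rep_len(thresholds, length(models))
  n <- nrow(x)
  idx <- matrix(NA_real_, n, length(models), dimnames = list(rownames(x), nm))
  idx[, 1] <- predict(models[[1]], x)
  alive <- idx[, 1] > thr[1]
  elim <- ifelse(alive, NA_integer_, 1L)
  if (length(models) > 1 && any(alive)) {
    for (j in 2:length(models)) {
      idx[alive, j] <- predict(models[[j]], x[alive, , drop = FALSE])
    }
    for (j in 2:length(models)) {
      newly <- alive & idx[, j] <= thr[j]
      elim[newly & is.na(elim)] <- j
    }
  }
  out <- data.frame(idx, check.names = FALSE)
  out$eliminated_stage <- elim
  out$pass <- is.na(elim)
  out
}

#' Five-fold cross-validation harness
#'
#' Trains one model per 4-fold union with the held-out fold as validation
#' set, reporting each fold's best-filter MCC and model AUC — the spread
#' across folds is the bias check of the experimental design.
#'
#' @inheritParams ise
#' @param k number of folds.
#' @param ... further arguments passed to [ise()].
#' @return list with `models` (per fold), `stats` (data.frame fold / mcc /
#'   auc) and the fold assignment.
#' @export
ise_cv <- function(x, y, k = 5, seed = 1, ...) {
  x <- as.matrix(x)
  folds <- make_folds(as.integer(y), k = k, seed = seed)
  models <- vector("list", k)
  stats_df <- data.frame(fold = seq_len(k), mcc = NA_real_, auc = NA_real_)
  for (f in seq_len(k)) {
    tr <- folds != f
    models[[f]] <- ise(x[tr, , drop = FALSE], y[tr],
                       xval = x[!tr, , drop = FALSE], yval = y[!tr],
                       seed = seed + f, ...)
    stats_df$mcc[f] <- max(models[[f]]$performance$mcc)
    stats_df$auc[f] <- rank_auc(predict(models[[f]], x[!tr, , drop = FALSE]),
                                y[!tr])
  }
  list(models = models, stats = stats_df, folds = folds)
}

#' Merge fold models into one screening model
#'
#' Union of the filters (with their held-out performances) of several
#' models, used to screen with a single model after cross-validation.
#'
#' @param models list of [ise()] models sharing cap/eps.
#' @param n_filters optional cap on the number of filters kept (best by MCC).
#' @return an `ise` model.
#' @export
ise_merge <- function(models, n_filters = NULL) {
  stopifnot(length(models) >= 1)
  filters <- do.call(c, lapply(models, `[[`, "filters"))
  perf <- do.call(rbind, lapply(models, `[[`, "performance"))
  ord <- order(-perf$mcc)
  if (!is.null(n_filters)) ord <- ord[seq_len(min(length(ord), n_filters))]
  structure(list(filters = filters[ord], performance = perf[ord, ],
                 n = length(ord), cap = models[[1]]$cap,
                 eps = models[[1]]$eps,
                 descriptors = models[[1]]$descriptors,
                 seed = models[[1]]$seed, call = match.call()),
            class = "ise")
}

#' Write / read an ISE model as JSON
#'
#' @param object an [ise()] model.
#' @param path file path.
#' @return `read_ise` returns the reconstructed model; `write_ise` its path,
#'   invisibly.
#' @export
write_ise <- function(object, path) {
  payload <- list(
    filters = lapply(object$filters, function(f)
      list(descriptor = f$descriptor, lo = f$lo, hi = f$hi)),
    performance = object$performance,
    cap = object$cap, eps = object$eps,
    descriptors = object$descriptors,
    seed = object$seed,
    descriptor_set = "dualscreen-2d-v1",
    index_convention = "capped-ratio"
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ise
#' @export
read_ise <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  filters <- lapply(seq_len(nrow(p$performance)), function(i) {
    f <- p$filters[[i]]
    ise_filter(unlist(f$descriptor), unlist(f$lo), unlist(f$hi))
  })
  structure(list(filters = filters,
                 performance = as.data.frame(p$performance),
                 n = length(filters), cap = p$cap, eps = p$eps,
                 descriptors = p$descriptors, seed = p$seed,
                 call = NULL),
            class = "ise")
}
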
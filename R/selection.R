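#' Docking enrichment of a receptor structure
#'
#' True-positive / false-positive enrichment of a docking test set: the
#' fraction of actives successfully docked divided by the fraction of
#' inactives docked. Used to choose among candidate crystal structures.
#'
#' @param n_actives,docked_actives counts for the active class.
#' @param n_inactives,docked_inactives counts for the inactive class.
#' @return list of class `enrichment_result`: tp_rate, fp_rate, ratio
#'   (Inf flagged via `infinite`), specificity, and the ratio rounded to two
#'   significant figures for report printing.
#' @export
enrichment_ratio <- function(n_actives, docked_actives,
                             n_inactives, docked_inactives) {
  if (n_actives <= 0 || n_inactives <= 0) stop("class sizes must be positive")
  if (docked_actives > n_actives || docked_inactives > n_inactives)
    stop("docked count exceeds class size")
  if (any(c(docked_actives, docked_inactives) < 0)) stop("negative counts")
  tp <- docked_actives / n_actives
  fp <- docked_inactives / n_inactives
  structure(list(
    tp_rate = tp, fp_rate = fp,
    ratio = if (fp > 0) tp / fp else Inf,
    infinite = fp == 0,
    specificity = 1 - fp,
    ratio_2sf = if (fp > 0) signif(tp / fp, 2) else Inf
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("TP rate %.3f, FP rate %.3f, TP/FP %s, specificity %.0f%%\n",
              x$tp_rate, x$fp_rate,
              if (x$infinite) "Inf (no inactive docked)" else
                format(x$ratio_2sf), 100 * x$specificity))
  invisible(x)
}

#' Docking specificity of a structure
#'
#' Fraction of inactives correctly rejected by the docking rule:
#' (n_inactives - docked_inactives) / n_inactives.
#'
#' @param n_inactives number of inactive/random molecules docked.
#' @param docked_inactives how many of them passed the docking rule.
#' @return specificity in \[0, 1\].
#' @export
docking_specificity <- function(n_inactives, docked_inactives) {
  if (n_inactives <= 0) stop("n_inactives must be positive")
  if (docked_inactives > n_inactives || docked_inactives < 0)
    stop("docked_inactives must lie in [0, n_inactives]")
  (n_inactives - docked_inactives) / n_inactives
}

#' Rank receptor structures for screening
#'
#' Orders candidate structures by the chosen criterion (descending), with
#' ties broken by the other criterion and then by structure id.
#'
#' @param results data.frame with columns `structure`, `ratio` and
#'   `specificity` (one row per structure).
#' @param criterion "ratio" (TP/FP enrichment) or "specificity".
#' @return `results` reordered, best structure first.
#' @export
rank_structures <- function(results, criterion = c("ratio", "specificity")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(results) >= 2,
            all(c("structure", "ratio", "specificity") %in% names(results)))
  other <- setdiff(c("ratio", "specificity"), criterion)
  ord <- order(-results[[criterion]], -results[[other]], results$structure)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
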
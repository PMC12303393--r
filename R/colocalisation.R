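# Manders-style colocalisation with a random-overlap baseline (MCC_diff):
# whole-stack variant thresholded on a designated mid-border section, and a
# section-by-section cytoplasm-only variant that excludes a dilated border
# zone; plus the one-sample t test of per-sample MCC_diff against zero.

new_mcc_result <- function(mcc_pct, baseline_pct, n_query_positive,
                           thresholds, scope, baseline_mode,
                           per_section = NULL) {
  structure(list(
    mcc_pct = mcc_pct,
    baseline_pct = baseline_pct,
    mcc_diff_pct = mcc_pct - baseline_pct,
    n_query_positive = n_query_positive,
    thresholds = thresholds,
    scope = scope,
    baseline_mode = baseline_mode,
    per_section = per_section), class = "wq_mcc")
}

#' @export
print.wq_mcc <- function(x, ...) {
  cat(sprintf("<wq_mcc> %s: MCC %.2f%%, baseline %.2f%% (%s), MCC_diff %.2f%%, n+ = %d\n",
              x$scope, x$mcc_pct, x$baseline_pct, x$baseline_mode,
              x$mcc_diff_pct, x$n_query_positive))
  if (!is.null(x$per_section))
    cat(sprintf("  %d sections used, per-section MCC_diff mean %.2f%%\n",
                nrow(x$per_section), mean(x$per_section$mcc_diff_pct)))
  invisible(x)
}

stack_voxels <- function(x) {
  if (inherits(x, "wq_stack")) return(x$voxels)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  stopf("expected a wq_stack or a numeric array")
}

#' Whole-stack MCC_diff colocalisation
#'
#' Both channels are binarised with the isodata threshold computed on one
#' designated section (conventionally the section in the middle of the
#' border signal) and applied stack-wide. The co-positive mask is the
#' pixelwise AND of the two binary stacks. `mcc_pct` is the percentage of
#' query-positive voxels that are also partner-positive; the baseline is
#' the overlap percentage expected under random colocalisation, and
#' `MCC_diff = mcc_pct - baseline_pct`.
#'
#' The statistically correct independence baseline is the partner
#' channel's own positive fraction (`"partner_fraction"`, the default):
#' under independent placement the expected fraction of query-positive
#' voxels that hit a partner-positive voxel is exactly the partner's
#' positive fraction. `"query_fraction"` (the query channel's positive
#' fraction) is retained as an alternative convention.
#'
#' @param query,partner [image_stack()]s (or arrays) of equal dimensions.
#' @param threshold_section 1-based slice on which both thresholds are
#'   computed; see [suggest_border_section()] for a heuristic.
#' @param baseline_mode `"partner_fraction"` or `"query_fraction"`.
#' @return A `wq_mcc` result.
#' @export
mcc_diff_stack <- function(query, partner, threshold_section = 1L,
                           baseline_mode = c("partner_fraction", "query_fraction")) {
  baseline_mode <- match.arg(baseline_mode)
  q <- stack_voxels(query); p <- stack_voxels(partner)
  if (!identical(dim(q), dim(p)))
    stopf("query and partner stacks differ in dimensions")
  k <- as.integer(threshold_section)
  if (k < 1L || k > dim(q)[3])
    stopf("threshold_section %d outside 1..%d", k, dim(q)[3])
  tq <- isodata_threshold(q[, , k])
  tp <- isodata_threshold(p[, , k])
  qpos <- q > tq; ppos <- p > tp
  nq <- sum(qpos)
  if (nq == 0L) stopf("no query-positive voxel: MCC undefined")
  total <- length(q)
  mcc <- 100 * sum(qpos & ppos) / nq
  baseline <- switch(baseline_mode,
                     partner_fraction = 100 * sum(ppos) / total,
                     query_fraction = 100 * nq / total)
  new_mcc_result(mcc, baseline, nq, c(query = tq, partner = tp),
                 "whole", baseline_mode)
}

#' Section-by-section cytoplasm-only MCC_diff
#'
#' The junction skeleton, dilated by a city-block ball of the given
#' radius, defines an excluded border zone so that only intracellular
#' signal is compared. Each section is thresholded independently (isodata
#' per channel per section), border-zone pixels are removed, and MCC_diff
#' is computed on the remaining cytoplasmic pixels. Sections with no
#' query-positive cytoplasmic pixel (or with a constant channel) are
#' skipped; the stack-level value aggregates the per-section MCC_diff by
#' unweighted mean (default) or by pooling pixels across sections.
#'
#' @inheritParams mcc_diff_stack
#' @param skeleton logical junction-skeleton matrix matching the stack's
#'   x-y dimensions.
#' @param radius city-block dilation radius of the excluded zone.
#' @param aggregate `"mean"` of per-section values or `"pooled"` pixels.
#' @return A `wq_mcc` result with a `per_section` data frame.
#' @export
mcc_diff_cytoplasm <- function(query, partner, skeleton, radius = 3L,
                               baseline_mode = c("partner_fraction", "query_fraction"),
                               aggregate = c("mean", "pooled")) {
  baseline_mode <- match.arg(baseline_mode)
  aggregate <- match.arg(aggregate)
  q <- stack_voxels(query); p <- stack_voxels(partner)
  if (!identical(dim(q), dim(p)))
    stopf("query and partner stacks differ in dimensions")
  if (!is.logical(skeleton)) skeleton <- skeleton > 0
  if (!identical(dim(skeleton), dim(q)[1:2]))
    stopf("skeleton does not match the stacks' x-y dimensions")
  cyto <- if (any(skeleton)) !dilate_cityblock(skeleton, radius) else !skeleton
  n_cyto <- sum(cyto)
  rows <- list(); pooled <- c(q = 0, p = 0, co = 0, tot = 0)
  for (k in seq_len(dim(q)[3])) {
    qs <- q[, , k]; ps <- p[, , k]
    tq <- tryCatch(isodata_threshold(qs), error = function(e) NA_real_)
    tp <- tryCatch(isodata_threshold(ps), error = function(e) NA_real_)
    if (is.na(tq) || is.na(tp)) next
    qpos <- (qs > tq) & cyto
    ppos <- (ps > tp) & cyto
    nq <- sum(qpos)
    if (nq == 0L) next
    mcc <- 100 * sum(qpos & ppos) / nq
    baseline <- switch(baseline_mode,
                       partner_fraction = 100 * sum(ppos) / n_cyto,
                       query_fraction = 100 * nq / n_cyto)
    rows[[length(rows) + 1L]] <- data.frame(
      section = k, threshold_query = tq, threshold_partner = tp,
      n_query_positive = nq, mcc_pct = mcc, baseline_pct = baseline,
      mcc_diff_pct = mcc - baseline)
    pooled <- pooled + c(nq, sum(ppos), sum(qpos & ppos), n_cyto)
  }
  if (!length(rows))
    stopf("all sections skipped (no query-positive cytoplasmic pixels): MCC undefined")
  per_section <- do.call(rbind, rows)
  if (aggregate == "mean") {
    mcc <- mean(per_section$mcc_pct)
    baseline <- mean(per_section$baseline_pct)
  } else {
    mcc <- 100 * pooled[["co"]] / pooled[["q"]]
    baseline <- switch(baseline_mode,
                       partner_fraction = 100 * pooled[["p"]] / pooled[["tot"]],
                       query_fraction = 100 * pooled[["q"]] / pooled[["tot"]])
  }
  new_mcc_result(mcc, baseline, sum(per_section$n_query_positive),
                 c(query = NA_real_, partner = NA_real_),
                 "cytoplasm_only", baseline_mode, per_section)
}

#' Heuristic for the mid-border threshold section
#'
#' The published procedure picks "the section in the middle of the border
#' signal" by eye. As an optional automation, this returns the section
#' maximising the mean intensity over the skeleton pixels, i.e. the slice
#' where the junctional signal is brightest.
#'
#' @param stack a [image_stack()] of the border channel.
#' @param skeleton logical junction-skeleton matrix.
#' @return 1-based slice index.
#' @export
suggest_border_section <- function(stack, skeleton) {
  v <- stack_voxels(stack)
  if (!is.logical(skeleton)) skeleton <- skeleton > 0
  if (!any(skeleton)) stopf("empty skeleton")
  scores <- vapply(seq_len(dim(v)[3]),
                   function(k) mean(v[, , k][skeleton]), numeric(1))
  which.max(scores)
}

#' One-sample t test of MCC_diff values against zero
#'
#' Classical one-sample t test (df = n - 1) of per-sample MCC_diff values
#' against a population mean of zero, i.e. against no colocalisation
#' beyond random overlap.
#'
#' @param values numeric vector of per-sample MCC_diff values (>= 2
#'   values with nonzero variance).
#' @return List with `t`, `p` (two-sided), `df`, `mean`.
#' @export
t_test_zero <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stopf("need at least 2 values for a one-sample t test")
  if (sd(values) == 0)
    stopf("zero variance: t statistic undefined")
  ht <- t.test(values, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = unname(ht$estimate))
}
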
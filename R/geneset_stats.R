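# Differential-expression comparison layer: significance/direction calls at
# the standard thresholds, exact hypergeometric overlap and enrichment
# probabilities, direction-consistency fractions and log-fold-change
# concordance between experiments.

#' Call genes up, down or not significant
#'
#' A gene is called `up` when its FDR-adjusted p-value is below `alpha`
#' and its log2 fold change exceeds `lfc_cutoff`; `down` when the adjusted
#' p-value is below `alpha` and the fold change is below `-lfc_cutoff`;
#' otherwise `ns`. A missing adjusted p-value (e.g. removed by independent
#' filtering) yields `ns`, never a dropped row.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_cutoff absolute log2-fold-change cutoff (default 1).
#' @return The table with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(table, alpha = 0.05, lfc_cutoff = 1) {
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("DE table lacks column(s): %s", paste(miss, collapse = ", "))
  dup <- unique(table$gene_id[duplicated(table$gene_id)])
  if (length(dup))
    stopf("duplicate gene_id(s): %s",
          paste(utils::head(dup, 10L), collapse = ", "))
  if (any(!is.finite(table$log2fc) & !is.na(table$log2fc)))
    stopf("non-finite log2fc values present")
  sig <- !is.na(table$padj) & table$padj < alpha
  table$call <- ifelse(sig & table$log2fc > lfc_cutoff, "up",
                       ifelse(sig & table$log2fc < -lfc_cutoff, "down", "ns"))
  table
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of category members in a draw of `n` from a
#' universe of `N` containing `K` category members: the significance of
#' observing at least `k` shared genes between two sets. Computed through
#' R's log-space hypergeometric CDF, so it is exact to double precision
#' for the small tails that matter.
#'
#' @param N universe size.
#' @param K category (first set) size.
#' @param n draw (second set) size.
#' @param k observed overlap; must satisfy
#'   `max(0, n + K - N) <= k <= min(n, K)`.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (K < 0L || n < 0L || K > N || n > N)
    stopf("need 0 <= K, n <= N")
  if (k < max(0L, n + K - N) || k > min(n, K))
    stopf("overlap k = %d infeasible for N = %d, K = %d, n = %d", k, N, K, n)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Overlap, direction concordance and fold-change correlation of two
#' DE experiments
#'
#' Restricts both tables to a common universe (by default the genes
#' present in both, i.e. the mapped and tested genes), takes the genes
#' called significant in each (`call != "ns"`), and reports: the overlap
#' count with its hypergeometric upper-tail probability; the fraction of
#' shared significant genes whose fold changes agree in sign; and the
#' squared correlation of the two log2 fold changes over the shared
#' significant genes. With an empty overlap, consistency and r^2 are
#' undefined (`NA`), not zero.
#'
#' @param a,b DE tables (data frames); called with [call_degs()] first
#'   unless they already carry a `call` column.
#' @param universe `"intersection"` or a character vector of gene ids.
#' @param alpha,lfc_cutoff thresholds passed to [call_degs()] when calls
#'   are absent.
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A list of class `wq_overlap`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `p_hyper`, `consistent_n`, `consistent_frac`,
#'   `r_squared`, and `shared` (the per-gene data frame behind the
#'   concordance numbers).
#' @export
concordance <- function(a, b, universe = "intersection",
                        alpha = 0.05, lfc_cutoff = 1,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"call" %in% names(a)) a <- call_degs(a, alpha, lfc_cutoff)
  if (!"call" %in% names(b)) b <- call_degs(b, alpha, lfc_cutoff)
  if (identical(universe, "intersection")) {
    universe <- intersect(a$gene_id, b$gene_id)
  } else universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty gene universe")
  a <- a[a$gene_id %in% universe, ]
  b <- b[b$gene_id %in% universe, ]
  de_a <- a$gene_id[a$call != "ns"]
  de_b <- b$gene_id[b$call != "ns"]
  shared_ids <- intersect(de_a, de_b)
  n_overlap <- length(shared_ids)
  p_hyper <- hypergeom_tail(length(universe), length(de_a), length(de_b),
                            n_overlap)
  if (n_overlap > 0L) {
    la <- a$log2fc[match(shared_ids, a$gene_id)]
    lb <- b$log2fc[match(shared_ids, b$gene_id)]
    consistent <- sign(la) == sign(lb)
    consistent_n <- sum(consistent)
    consistent_frac <- consistent_n / n_overlap
    r_squared <- if (n_overlap >= 2L && sd(la) > 0 && sd(lb) > 0)
      cor(la, lb, method = method)^2 else NA_real_
    shared <- data.frame(gene_id = shared_ids, log2fc_a = la, log2fc_b = lb,
                         consistent = consistent)
  } else {
    consistent_n <- 0L
    consistent_frac <- NA_real_
    r_squared <- NA_real_
    shared <- data.frame(gene_id = character(), log2fc_a = numeric(),
                         log2fc_b = numeric(), consistent = logical())
  }
  structure(list(
    n_universe = length(universe), n_a = length(de_a), n_b = length(de_b),
    n_overlap = n_overlap, p_hyper = p_hyper,
    consistent_n = consistent_n, consistent_frac = consistent_frac,
    r_squared = r_squared, method = method, shared = shared),
    class = "wq_overlap")
}

#' @export
print.wq_overlap <- function(x, ...) {
  cat(sprintf(
    "<wq_overlap> universe %d; DE %d vs %d; overlap %d (p = %.3g); consistent %s; r^2 = %s\n",
    x$n_universe, x$n_a, x$n_b, x$n_overlap, x$p_hyper,
    if (is.na(x$consistent_frac)) "undefined"
    else sprintf("%d/%d (%.1f%%)", x$consistent_n, x$n_overlap,
                 100 * x$consistent_frac),
    if (is.na(x$r_squared)) "undefined" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Hypergeometric enrichment of a gene set in a list of called genes
#'
#' The probability of observing at least the realised overlap between a
#' called gene list (e.g. genes up-regulated in both experiments) and a
#' user-supplied category (e.g. JNK-cascade members) within a stated
#' universe.
#'
#' @param calls character vector of called gene ids.
#' @param gene_set character vector of category members.
#' @param universe character vector containing every id in `calls` and
#'   `gene_set`.
#' @return List with the counts and `p_hyper`.
#' @export
set_enrichment <- function(calls, gene_set, universe) {
  calls <- unique(as.character(calls))
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  out_set <- setdiff(gene_set, universe)
  out_calls <- setdiff(calls, universe)
  if (length(out_set) || length(out_calls))
    stopf("ids outside the universe: %s",
          paste(utils::head(c(out_set, out_calls), 10L), collapse = ", "))
  k <- length(intersect(calls, gene_set))
  list(n_universe = length(universe), n_set = length(gene_set),
       n_calls = length(calls), n_overlap = k,
       p_hyper = hypergeom_tail(length(universe), length(gene_set),
                                length(calls), k))
}

#' Pairwise and three-way overlap counts of DE call sets
#'
#' Region counts of a 2- or 3-set Venn partition, derived from set
#' intersections of the called gene ids (no graphics).
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return Named integer vector of disjoint region counts; names use `&`
#'   for intersections (e.g. `"a&b"`).
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || !length(names(sets)) || length(sets) < 2L ||
      length(sets) > 3L)
    stopf("'sets' must be a named list of 2 or 3 id vectors")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (!is.matrix(member)) member <- matrix(member, nrow = length(all_ids))
  pattern <- apply(member, 1L, function(z) paste(nm[z], collapse = "&"))
  counts <- table(pattern)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
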
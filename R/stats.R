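#' Relative quantification by the delta-delta-Ct method
#'
#' For each group, `dCt = mean(ct_target - ct_normalizer)`; the fold change
#' of the test condition relative to the reference is
#' `2^-(dCt_test - dCt_reference)`. The normalizer is a stably expressed
#' gene amplified alongside the target (e.g. rp49 for expression assays,
#' ecd for ChIP-qPCR enrichment).
#'
#' @param test,reference data.frames with numeric columns `ct_target` and
#'   `ct_normalizer` (one row per replicate).
#' @param per_replicate if `TRUE`, additionally return per-replicate fold
#'   changes of the test group against the reference-group mean dCt.
#' @return The fold change (a single number), or a list with `fold` and
#'   `replicate_folds` when `per_replicate = TRUE`.
#' @export
ddct_fold_change <- function(test, reference, per_replicate = FALSE) {
  check <- function(g, label) {
    if (!is.data.frame(g) || !nrow(g) ||
        !all(c("ct_target", "ct_normalizer") %in% names(g)))
      stop("ddct_fold_change: ", label,
           " group must be a non-empty data.frame with ct_target, ct_normalizer")
    if (any(!is.finite(g$ct_target)) || any(!is.finite(g$ct_normalizer)) ||
        any(g$ct_target <= 0) || any(g$ct_normalizer <= 0))
      stop("ddct_fold_change: Ct values must be positive and finite")
  }
  check(test, "test"); check(reference, "reference")
  dct_test <- mean(test$ct_target - test$ct_normalizer)
  dct_ref <- mean(reference$ct_target - reference$ct_normalizer)
  fold <- 2^(-(dct_test - dct_ref))
  if (!per_replicate) return(fold)
  rep_folds <- 2^(-((test$ct_target - test$ct_normalizer) - dct_ref))
  list(fold = fold, replicate_folds = rep_folds)
}

#' Split a gene table into up- and down-regulated lists by fold change
#'
#' Up: `fold_change >= fc_threshold`; down: `fold_change <= 1/fc_threshold`;
#' both additionally require `p_value < p_threshold` when a p-value column is
#' present. The boundary fold change is included (the filter reads ">=").
#'
#' @param gene_table data.frame with `gene_id`, positive `fold_change`, and
#'   optionally `p_value`.
#' @param fc_threshold fold-change cutoff (> 1).
#' @param p_threshold p-value cutoff; ignored if the table has no `p_value`.
#' @return list with character vectors `up` and `down`.
#' @export
filter_de_list <- function(gene_table, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(is.data.frame(gene_table),
            all(c("gene_id", "fold_change") %in% names(gene_table)),
            fc_threshold > 1)
  fc <- gene_table$fold_change
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("filter_de_list: fold changes must be positive")
  sig <- if ("p_value" %in% names(gene_table))
    gene_table$p_value < p_threshold else rep(TRUE, nrow(gene_table))
  list(up = gene_table$gene_id[fc >= fc_threshold & sig],
       down = gene_table$gene_id[fc <= 1 / fc_threshold & sig])
}

#' One-tailed Fisher exact test of the overlap of two gene lists
#'
#' Builds the 2x2 contingency table of membership in `list_a` and `list_b`
#' over a common universe and computes the enrichment tail
#' `P(overlap >= observed)` given the marginals (hypergeometric upper tail).
#'
#' @param list_a,list_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible elements.
#' @return list with `table` (2x2 matrix: rows in/out of A, columns in/out
#'   of B), `overlap`, and `p_value`.
#' @export
overlap_fisher <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  out_a <- setdiff(list_a, universe); out_b <- setdiff(list_b, universe)
  if (length(out_a) || length(out_b))
    stop("overlap_fisher: elements outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5L), collapse = ", "))
  n <- length(universe)
  k <- length(intersect(list_a, list_b))
  a <- length(list_a); b <- length(list_b)
  tab <- matrix(c(k, a - k, b - k, n - a - b + k), nrow = 2L,
                dimnames = list(A = c("in_A", "out_A"),
                                B = c("in_B", "out_B")))
  p <- stats::phyper(k - 1L, a, n - a, b, lower.tail = FALSE)
  list(table = tab, overlap = k, p_value = p)
}
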
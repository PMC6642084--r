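#' Log point probability of a 2xK contingency table
#'
#' Natural log of the conditional (multivariate hypergeometric) probability
#' of observing `positives[i]` positives in groups of sizes
#' `group_sizes[i]`, given both margins:
#' `ln( prod_i C(n_i, k_i) / C(N, T) )` with `N = sum(n_i)`,
#' `T = sum(k_i)`. Computed via log-gamma; no overflow for `N` up to 1e4.
#'
#' @param group_sizes Positive integer group sizes (length K >= 1).
#' @param positives Non-negative integers, `0 <= positives[i] <=
#'   group_sizes[i]`.
#' @return A single natural-log probability (0 for a one-group table, which
#'   is deterministic given its margins).
#' @export
#' @examples
#' log_table_prob(c(2, 2), c(1, 1))  # log(2/3)
log_table_prob <- function(group_sizes, positives) {
  validate_table2xk(group_sizes, positives)
  sum(lchoose(group_sizes, positives)) -
    lchoose(sum(group_sizes), sum(positives))
}

validate_table2xk <- function(group_sizes, positives) {
  if (length(group_sizes) < 1L || length(positives) != length(group_sizes)) {
    stop_param("group_sizes and positives must have equal length >= 1")
  }
  if (any(!is.finite(group_sizes)) || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes))) {
    stop_param("group_sizes must be positive integers")
  }
  if (any(!is.finite(positives)) || any(positives < 0) ||
      any(positives > group_sizes) || any(positives != round(positives))) {
    stop_param("positives must be integers with 0 <= positives <= group_sizes")
  }
  invisible(TRUE)
}

#' Exact two-sided Fisher test for a 2xK table
#'
#' Tests whether a binary trait (e.g. presence of an HMM hit) is
#' non-randomly distributed across K groups (clades or tree clusters),
#' conditioning on both margins. The two-sided p-value sums the conditional
#' probabilities of every table with the observed margins whose point
#' probability is at most the observed one (tables within a relative tie
#' tolerance of `tie_tol` are counted as ties and included).
#'
#' Enumeration is exhaustive and performed in natural-log space with
#' log-sum-exp accumulation, so p-values far smaller than 1e-300 are exact
#' on the log scale (`log10_p` is then the authoritative representation).
#' Groups of equal size are collapsed into probability classes, which makes
#' partitions with many small clusters enumerable; the `max_tables` guard
#' bounds the number of distinct probability configurations visited and the
#' function errors out (rather than approximating) when it is exceeded.
#'
#' @inheritParams log_table_prob
#' @param tie_tol Relative tie tolerance on the point probability
#'   (tables with probability `<= observed * (1 + tie_tol)` are included).
#' @param max_tables Enumeration guard (default 1e7 configurations).
#' @return A list of class `fisher2xk` with elements `p_value`,
#'   `log10_p` (log10 of the p-value, exact in extreme tails), `log_p`
#'   (natural log), and `n_tables` (configurations enumerated).
#' @export
#' @examples
#' fisher_exact_2xk(c(2, 2), c(2, 0))$p_value  # 1/3
fisher_exact_2xk <- function(group_sizes, positives, tie_tol = 1e-7,
                             max_tables = 1e7) {
  validate_table2xk(group_sizes, positives)
  res <- fisher2xk_enum(as.integer(group_sizes), as.integer(positives),
                        log1p(tie_tol), max_tables)
  log_p <- min(res$log_num_tail - res$log_denom, 0)
  structure(
    list(p_value = min(exp(log_p), 1),
         log10_p = log_p / log(10),
         log_p = log_p,
         n_tables = res$n_configs),
    class = "fisher2xk"
  )
}

#' @export
print.fisher2xk <- function(x, ...) {
  cat(sprintf("exact 2xK Fisher test: p = %.6g (log10 p = %.4f)\n",
              x$p_value, x$log10_p))
  invisible(x)
}

#' Scan every HMM for a skewed distribution across clades
#'
#' For each HMM in the presence matrix, builds the 2xK table of
#' positives-per-clade against clade sizes and computes the exact
#' two-sided Fisher p-value under the null hypothesis that hits are
#' distributed randomly across samples. Results are sorted by ascending
#' p (on the log scale, so extreme ties order correctly), ties broken
#' lexicographically by `hmm_id`.
#'
#' No multiple-testing correction is applied by default (ranked raw
#' p-values are reported); see [bh_adjust()].
#'
#' @param matrix A `presence_matrix`.
#' @param clades Clade map tibble covering every matrix sample.
#' @inheritParams fisher_exact_2xk
#' @return Tibble with columns `hmm_id`, `clade_counts` and `clade_sizes`
#'   (comma-joined, clades in clade-map order), `p_value`, `log10_p`.
#' @export
skew_scan <- function(matrix, clades, tie_tol = 1e-7, max_tables = 1e7) {
  unlabeled <- setdiff(rownames(matrix), clades$sample_id)
  if (length(unlabeled)) {
    stop_input("samples missing from the clade map: ",
               paste(unlabeled, collapse = ", "))
  }
  lab <- clades$clade[match(rownames(matrix), clades$sample_id)]
  clade_order <- unique(clades$clade[clades$sample_id %in% rownames(matrix)])
  lab <- factor(lab, levels = clade_order)
  sizes <- as.integer(table(lab))
  pos <- rowsum(unclass(matrix), lab)  # clade x hmm
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    k <- as.integer(pos[, j])
    ft <- fisher_exact_2xk(sizes, k, tie_tol = tie_tol,
                           max_tables = max_tables)
    tibble::tibble(
      hmm_id = colnames(matrix)[j],
      clade_counts = paste(k, collapse = ","),
      clade_sizes = paste(sizes, collapse = ","),
      p_value = ft$p_value,
      log10_p = ft$log10_p
    )
  })
  out <- dplyr::bind_rows(res)
  out[order(out$log10_p, out$hmm_id), ]
}

#' Test co-gain/co-loss concordance of two gene families
#'
#' Enzymes of one pathway (e.g. isocitrate lyase and malate synthase of the
#' glyoxylate shunt) are expected to be gained and lost together. This
#' builds the 2x2 table of joint presence calls over samples and computes
#' the exact two-sided Fisher p-value for the association.
#'
#' @param matrix A `presence_matrix` containing both HMMs.
#' @param hmm_a,hmm_b Column names of the two HMMs.
#' @inheritParams fisher_exact_2xk
#' @return List of class `concordance_result` with the four cell counts
#'   (`n_both`, `n_a_only`, `n_b_only`, `n_neither`), `p_value`, `log10_p`.
#' @export
concordance_test <- function(matrix, hmm_a, hmm_b, tie_tol = 1e-7,
                             max_tables = 1e7) {
  missing <- setdiff(c(hmm_a, hmm_b), colnames(matrix))
  if (length(missing)) {
    stop_input("HMM id(s) not in the presence matrix: ",
               paste(missing, collapse = ", "))
  }
  a <- matrix[, hmm_a] == 1L
  b <- matrix[, hmm_b] == 1L
  n_both <- sum(a & b)
  n_a_only <- sum(a & !b)
  n_b_only <- sum(!a & b)
  n_neither <- sum(!a & !b)
  ft <- fisher_2x2(n_both, n_a_only, n_b_only, n_neither,
                   tie_tol = tie_tol, max_tables = max_tables)
  structure(
    list(hmm_a = hmm_a, hmm_b = hmm_b,
         n_both = n_both, n_a_only = n_a_only,
         n_b_only = n_b_only, n_neither = n_neither,
         p_value = ft$p_value, log10_p = ft$log10_p),
    class = "concordance_result"
  )
}

# 2x2 helper: groups are the a-positive and a-negative samples, the tested
# trait is presence of b.
fisher_2x2 <- function(n_both, n_a_only, n_b_only, n_neither,
                       tie_tol = 1e-7, max_tables = 1e7) {
  sizes <- c(n_both + n_a_only, n_b_only + n_neither)
  if (any(sizes == 0L)) {
    # degenerate margin: only one table possible
    return(structure(list(p_value = 1, log10_p = 0, log_p = 0,
                          n_tables = 1), class = "fisher2xk"))
  }
  fisher_exact_2xk(sizes, c(n_both, n_b_only),
                   tie_tol = tie_tol, max_tables = max_tables)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance %s vs %s: both=%d neither=%d a_only=%d b_only=%d\n",
              x$hmm_a, x$hmm_b, x$n_both, x$n_neither, x$n_a_only,
              x$n_b_only))
  cat(sprintf("  two-sided exact p = %.6g (log10 p = %.4f)\n",
              x$p_value, x$log10_p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#' Provided as an optional utility; ranked raw p-values are the default
#' report.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values <= 0) || any(p_values > 1)) {
    stop_param("p_values must all lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
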
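#' Per-gene two-group test on an expression matrix
#'
#' The default method is classical one-way ANOVA (pooled-variance F test),
#' which with two groups is exactly the squared pooled two-sample t test.
#' Alternatives: Welch's t (`"welch"`) and the two-sample Kolmogorov-Smirnov
#' test (`"ks"`, via [ks_two_sample()]).
#'
#' Degenerate rows (zero pooled within-group variance) get p = 1 when the
#' group means are equal, p = 0 otherwise.
#'
#' @param mat numeric matrix, genes x samples, on a log scale.
#' @param groups named character/factor of length `ncol(mat)` (or named vector
#'   covering the column names) with exactly 2 levels, each n >= 2.
#' @param method `"anova"` (default), `"welch"` or `"ks"`.
#' @return named numeric vector of raw p-values in `[0,1]`.
#' @export
two_group_test <- function(mat, groups, method = c("anova", "welch", "ks")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat))
  if (!is.null(names(groups)) && !is.null(colnames(mat))) {
    groups <- groups[colnames(mat)]
  }
  if (length(groups) != ncol(mat)) stop("one group label per sample required")
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly 2 groups required")
  a <- mat[, groups == lv[1], drop = FALSE]
  b <- mat[, groups == lv[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  p <- switch(method,
    anova = {
      m1 <- rowMeans(a); m2 <- rowMeans(b)
      v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      pv <- stats::pf(tstat^2, 1, n1 + n2 - 2, lower.tail = FALSE)
      # sp2 == 0: identical values within both groups
      pv[sp2 == 0 & m1 == m2] <- 1
      pv[sp2 == 0 & m1 != m2] <- 0
      pv
    },
    welch = vapply(seq_len(nrow(mat)), function(i) {
      if (stats::var(a[i, ]) == 0 && stats::var(b[i, ]) == 0) {
        return(if (mean(a[i, ]) == mean(b[i, ])) 1 else 0)
      }
      stats::t.test(a[i, ], b[i, ], var.equal = FALSE)$p.value
    }, 0),
    ks = vapply(seq_len(nrow(mat)), function(i) {
      ks_two_sample(a[i, ], b[i, ])$p
    }, 0))
  stats::setNames(pmin(pmax(p, 0), 1), rownames(mat))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted q-values: monotone in p, each q >= its p, capped at 1.
#'
#' @param pvalues numeric vector of raw p-values in `[0,1]`.
#' @return numeric vector of q-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  stopifnot(is.numeric(pvalues))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Signed linear fold changes between two groups
#'
#' Group means are taken on the natural (unlogged) scale; the ratio
#' mean(A)/mean(B) is folded to a signed convention: values >= 1 stay as-is
#' (higher in the first group), ratios < 1 are reported as -1/ratio (higher
#' in the second group), so thresholds read symmetrically as ">1.5 / <-1.5".
#'
#' @param mat genes x samples matrix.
#' @param groups two-group labels (first unique label is group A).
#' @param log_base base of the log scale the matrix is on (`2` for log2
#'   microarray values); `NULL` if the matrix is already on natural scale.
#' @return named numeric vector of signed fold changes.
#' @export
fold_changes <- function(mat, groups, log_base = 2) {
  stopifnot(is.matrix(mat))
  if (!is.null(names(groups)) && !is.null(colnames(mat))) {
    groups <- groups[colnames(mat)]
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L)
  nat <- if (is.null(log_base)) mat else log_base^mat
  m1 <- rowMeans(nat[, groups == lv[1], drop = FALSE])
  m2 <- rowMeans(nat[, groups == lv[2], drop = FALSE])
  r <- m1 / m2
  stats::setNames(ifelse(r >= 1, r, -1 / r), rownames(mat))
}

#' Full differential-expression table for a two-group comparison
#'
#' Combines [two_group_test()], [bh_adjust()] and [fold_changes()] into the
#' per-gene table that seeds all prediction branches. Direction follows the
#' fold-change sign: positive = higher in group A (the first group label).
#'
#' @inheritParams two_group_test
#' @inheritParams fold_changes
#' @return data.frame with columns `gene`, `fc`, `p`, `q`, `direction`.
#' @export
run_de <- function(mat, groups, method = "anova", log_base = 2) {
  if (is.null(rownames(mat))) stop("expression matrix needs gene rownames")
  genes <- normalize_genes(rownames(mat))
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  rownames(mat) <- genes
  lv <- unique(as.character(if (!is.null(names(groups)) && !is.null(colnames(mat)))
    groups[colnames(mat)] else groups))
  p <- two_group_test(mat, groups, method = method)
  fc <- fold_changes(mat, groups, log_base = log_base)
  data.frame(gene = genes, fc = unname(fc), p = unname(p),
             q = bh_adjust(unname(p)),
             direction = ifelse(fc >= 1, paste0("higher-in-", lv[1]),
                                paste0("higher-in-", lv[2])),
             stringsAsFactors = FALSE)
}

#' Filter a DE table on FDR and fold-change gates
#'
#' Retains genes with `q < q_max` and `|fc| > fc_min` (signed linear fold
#' change, so the gate reads "fold change above 1.5 in either direction").
#' Relaxing either threshold can only grow the result.
#'
#' @param table DE data.frame with columns `gene`, `fc`, `p`, `q` (and
#'   optionally `direction`).
#' @param q_max FDR threshold (default 0.05).
#' @param fc_min linear fold-change threshold (default 1.5).
#' @return the filtered DE table (possibly zero rows).
#' @export
filter_de <- function(table, q_max = 0.05, fc_min = 1.5) {
  stopifnot(is.data.frame(table),
            all(c("gene", "fc", "p", "q") %in% names(table)))
  stopifnot(q_max > 0, q_max <= 1, fc_min >= 1)
  keep <- !is.na(table$q) & table$q < q_max & abs(table$fc) > fc_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
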
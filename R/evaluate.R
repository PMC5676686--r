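#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' distribution functions, evaluated at every observed point (ties are
#' handled by stepping through the pooled unique values). The p-value is
#' exact — the conditional probability over all label assignments of the
#' pooled sample, which respects ties — whenever `length(a) * length(b)`
#' is at most `exact_max`, and uses the asymptotic Kolmogorov distribution
#' otherwise.
#'
#' @param a,b numeric vectors, each nonempty.
#' @param exact_max size cutoff `|a|*|b|` for the exact p-value.
#' @return list with `D` (statistic in `[0,1]`), `p`, and `exact` (logical).
#' @export
ks_two_sample <- function(a, b, exact_max = 10000) {
  if (length(a) < 1L || length(b) < 1L) stop("empty sample")
  stopifnot(is.numeric(a), is.numeric(b), !anyNA(a), !anyNA(b))
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), 0)
  fb <- vapply(pts, function(t) mean(b <= t), 0)
  D <- max(abs(fa - fb))
  m <- length(a); n <- length(b)
  exact <- m * n <= exact_max
  p <- if (exact) {
    stats::psmirnov(D, sizes = c(m, n), z = c(a, b), two.sided = TRUE,
                    exact = TRUE, lower.tail = FALSE)
  } else {
    .kolmogorov_sf(sqrt(m * n / (m + n)) * D)
  }
  list(D = D, p = min(max(p, 0), 1), exact = exact)
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
.kolmogorov_sf <- function(t, terms = 100) {
  if (t <= 0) return(1)
  k <- seq_len(terms)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Log10 ratio of group means with absence substitution
#'
#' For plotting fold differences of measured lipids: an absent mean (NA or
#' zero) is substituted by a small constant before taking the ratio.
#'
#' @param mean_a,mean_b nonnegative group means (NA = absent).
#' @param absence_value substitution constant (default 0.0001).
#' @return `log10` of the substituted ratio.
#' @export
log_ratio <- function(mean_a, mean_b, absence_value = 0.0001) {
  sub <- function(x) ifelse(is.na(x) | x == 0, absence_value, x)
  log10(sub(mean_a) / sub(mean_b))
}

#' Per-species significance testing of a measured lipid table
#'
#' Each species present in both groups is tested with [ks_two_sample()]
#' (per-sample absences substituted by `absence_value` so partial presence
#' contributes to the distribution comparison); Benjamini-Hochberg adjustment
#' runs across all tested species in the table. Species detected in only one
#' group are not testable by KS and are flagged `differential_by_presence`
#' with their presence pattern; species absent from every sample are dropped
#' with a warning.
#'
#' @param table a `tdl_lipid_table`.
#' @param q_max FDR threshold for the `significant` flag (default 0.05).
#' @param absence_value per-sample absence substitution (default 0.0001).
#' @return data.frame, one row per retained species: `species`, `class`,
#'   `D`, `p`, `q`, `significant`, `presence` (`"both"`,
#'   `"<groupA>-only"`, `"<groupB>-only"`), `differential_by_presence`,
#'   `log_ratio` (log10 group-mean ratio, A over B), `mean_a`, `mean_b`.
#' @export
lipid_significance <- function(table, q_max = 0.05, absence_value = 0.0001) {
  stopifnot(inherits(table, "tdl_lipid_table"), q_max > 0, q_max <= 1)
  lv <- unique(table$groups)
  ia <- table$groups == lv[1]
  ib <- table$groups == lv[2]
  m <- table$intensities

  all_absent <- rowSums(!is.na(m)) == 0L
  if (any(all_absent)) {
    warning("dropping species absent in all samples: ",
            paste(rownames(m)[all_absent], collapse = ", "))
    m <- m[!all_absent, , drop = FALSE]
  }
  species <- rownames(m)
  cls <- unname(table$classes[species])

  a_present <- rowSums(!is.na(m[, ia, drop = FALSE])) > 0L
  b_present <- rowSums(!is.na(m[, ib, drop = FALSE])) > 0L
  presence <- ifelse(a_present & b_present, "both",
                     ifelse(a_present, paste0(lv[1], "-only"),
                            paste0(lv[2], "-only")))
  testable <- presence == "both"

  D <- p <- rep(NA_real_, length(species))
  for (i in which(testable)) {
    va <- m[i, ia]; vb <- m[i, ib]
    va[is.na(va)] <- absence_value
    vb[is.na(vb)] <- absence_value
    ks <- ks_two_sample(va, vb)
    D[i] <- ks$D; p[i] <- ks$p
  }
  q <- rep(NA_real_, length(species))
  q[testable] <- bh_adjust(p[testable])

  mean_a <- rowMeans(m[, ia, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(m[, ib, drop = FALSE], na.rm = TRUE)
  mean_a[!a_present] <- NA; mean_b[!b_present] <- NA

  data.frame(
    species = species, class = cls, D = D, p = p, q = q,
    significant = !is.na(q) & q < q_max,
    presence = presence,
    differential_by_presence = !testable,
    log_ratio = log_ratio(mean_a, mean_b, absence_value),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    stringsAsFactors = FALSE)
}

#' Per-class summary of species-level test results
#'
#' A class shows observed change when at least one member species is
#' KS-significant or differential by presence (detected in only one group).
#'
#' @param results output of [lipid_significance()].
#' @return data.frame per class: `class`, `n_measured`, `n_significant`,
#'   `n_presence_differential`, `observed_change`.
#' @export
class_summary <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("class", "significant", "differential_by_presence")
                %in% names(results)))
  cl <- sort(unique(results$class))
  out <- do.call(rbind, lapply(cl, function(k) {
    r <- results[results$class == k, ]
    data.frame(class = k, n_measured = nrow(r),
               n_significant = sum(r$significant),
               n_presence_differential = sum(r$differential_by_presence),
               stringsAsFactors = FALSE)
  }))
  out$observed_change <- (out$n_significant + out$n_presence_differential) >= 1L
  rownames(out) <- NULL
  out
}

#' Prediction-versus-observation category grid
#'
#' Scores each lipid class by how many branches predicted change versus
#' whether change was observed:
#' \describe{
#'   \item{1}{all three branches predicted change, change observed}
#'   \item{2}{one or two branches predicted change, change observed}
#'   \item{3}{no branch predicted change, no change observed}
#'   \item{4}{one or two branches predicted change, no change observed}
#'   \item{5}{all three branches predicted change, no change observed}
#'   \item{6}{no branch predicted change, change observed}
#' }
#' The six categories cover the 4 x 2 grid of (support count, observed)
#' exactly once.
#'
#' @param branch_support_count integer vector in `{0,1,2,3}`.
#' @param observed_change logical vector.
#' @return integer vector of categories 1-6.
#' @export
categorize <- function(branch_support_count, observed_change) {
  s <- as.integer(branch_support_count)
  if (any(is.na(s) | s < 0L | s > 3L)) {
    stop("branch_support_count must be in {0,1,2,3}")
  }
  o <- as.logical(observed_change)
  stopifnot(length(s) == length(o), !anyNA(o))
  ifelse(o,
         ifelse(s == 3L, 1L, ifelse(s >= 1L, 2L, 6L)),
         ifelse(s == 3L, 5L, ifelse(s >= 1L, 4L, 3L)))
}

#' Evaluate a measured lipidome against a consensus prediction
#'
#' Ties everything together: per-species KS testing of the measured table,
#' per-class summaries, branch-support counts from the consensus (strict or
#' permissive species-to-class implication), and the category grid.
#'
#' @param table a `tdl_lipid_table`.
#' @param consensus a `tdl_consensus` (may be `NULL` for a no-prediction run:
#'   all classes then have support 0).
#' @param q_max FDR threshold.
#' @param mode passed to [class_branch_support()].
#' @param absence_value per-sample absence substitution.
#' @return an object of class `tdl_evaluation`: list with `per_species`
#'   ([lipid_significance()] output) and `per_class` (class summary with
#'   `branch_support_count` and `category`).
#' @export
evaluate_lipidome <- function(table, consensus = NULL, q_max = 0.05,
                              mode = c("strict", "permissive"),
                              absence_value = 0.0001) {
  mode <- match.arg(mode)
  res <- lipid_significance(table, q_max = q_max,
                            absence_value = absence_value)
  cls <- class_summary(res)
  support <- if (is.null(consensus)) {
    stats::setNames(integer(0), character(0))
  } else {
    class_branch_support(consensus, mode = mode)
  }
  cls$branch_support_count <- ifelse(cls$class %in% names(support),
                                     support[cls$class], 0L)
  cls$category <- categorize(cls$branch_support_count, cls$observed_change)
  structure(list(per_species = res, per_class = cls),
            class = "tdl_evaluation")
}

#' @export
print.tdl_evaluation <- function(x, ...) {
  cat(sprintf("tdl evaluation: %d species (%d significant, %d presence-differential), %d classes\n",
              nrow(x$per_species), sum(x$per_species$significant),
              sum(x$per_species$differential_by_presence),
              nrow(x$per_class)))
  tab <- table(factor(x$per_class$category, levels = 1:6))
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
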
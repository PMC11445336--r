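new_test_result <- function(statistic_name, statistic, p, n,
                            test_chosen_by = NA_character_,
                            flag = NA_character_, extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic = unname(statistic), p = unname(p), n = n,
                   test_chosen_by = test_chosen_by, flag = flag), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$statistic_name, "=", signif(x$statistic, 4),
      ", p =", signif(x$p, 4),
      if (!is.na(x$test_chosen_by)) paste0(" [", x$test_chosen_by, "]"),
      "\n")
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Applies the Shapiro-Wilk test to each sample; when both pass at
#' \code{alpha_norm} the groups are compared with a two-sample t test
#' (unequal-variance Welch by default), otherwise with a two-sided
#' Mann-Whitney U test (first-sample orientation; exact when the combined n
#' is at most 20 and there are no ties, normal approximation with continuity
#' correction otherwise). A sample with zero variance cannot be assessed by
#' Shapiro-Wilk and routes to the rank test; two identical constant samples
#' give statistic 0, p = 1.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha_norm Normality gate level.
#' @param var_equal Use the pooled t statistic instead of Welch.
#' @return A \code{test_result}; \code{test_chosen_by} records the gate.
#' @export
shapiro_gate_compare <- function(x, y, alpha_norm = 0.05,
                                 var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs n >= 3")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1] == y[1])
    return(new_test_result("t_welch", 0, 1, c(length(x), length(y)),
                           "degenerate: both samples constant and equal"))
  normal <- function(v) stats::sd(v) > 0 &&
    stats::shapiro.test(v)$p.value >= alpha_norm
  both_normal <- normal(x) && normal(y)
  if (both_normal) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    new_test_result(if (var_equal) "t_student" else "t_welch",
                    tt$statistic, tt$p.value, c(length(x), length(y)),
                    "shapiro-wilk: both normal",
                    extra = list(df = unname(tt$parameter)))
  } else {
    exact <- (length(x) + length(y) <= 20) &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    new_test_result("U", wt$statistic, wt$p.value,
                    c(length(x), length(y)),
                    "shapiro-wilk: non-normal -> Mann-Whitney U")
  }
}

#' Welch t test from summary statistics
#'
#' Reconstructs the unequal-variance two-sample t statistic, the
#' Welch-Satterthwaite degrees of freedom and the two-sided p from printed
#' means, SDs, and group sizes (e.g. demographic table rows).
#'
#' @param m1,sd1,n1 First group mean, SD, size.
#' @param m2,sd2,n2 Second group mean, SD, size.
#' @return A \code{test_result} with \code{df} attached.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop("zero pooled variance")
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  new_test_result("t_welch", t, p, c(n1, n2), "summary statistics",
                  extra = list(df = df))
}

#' Bonferroni-Holm step-down correction
#'
#' Step-down adjusted p-values (monotonicity enforced, capped at 1);
#' rejection at \code{alpha} uses the adjusted values.
#'
#' @param raw_p Numeric vector of p-values in [0, 1].
#' @param alpha Family-wise level.
#' @return Object of class \code{holm_family}: \code{raw_p},
#'   \code{adjusted_p}, \code{alpha}, \code{rejected}.
#' @export
holm_correct <- function(raw_p, alpha = 0.05) {
  stopifnot(all(raw_p >= 0 & raw_p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(raw_p, method = "holm")
  structure(list(raw_p = raw_p, adjusted_p = adj, alpha = alpha,
                 rejected = !is.na(adj) & adj < alpha),
            class = "holm_family")
}

#' Spearman correlation against a severity score
#'
#' Tie-corrected Spearman rho with two-sided p: exact permutation null for
#' n <= 9 without ties, t approximation otherwise (cohort sizes here are
#' small, so the exact path matters).
#'
#' @param values Per-subject scalar (connectivity z or nodal degree).
#' @param severity Per-subject severity score, pairwise complete with
#'   \code{values}.
#' @return A \code{test_result} with \code{statistic_name = "rho"}.
#' @export
spearman_severity <- function(values, severity) {
  ok <- stats::complete.cases(values, severity)
  values <- values[ok]; severity <- severity[ok]
  if (length(values) < 4) stop("need >= 4 complete pairs")
  if (stats::sd(values) == 0 || stats::sd(severity) == 0)
    stop("constant input: rho undefined")
  ties <- anyDuplicated(values) || anyDuplicated(severity)
  exact <- length(values) <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(values, severity, method = "spearman", exact = exact))
  new_test_result("rho", ct$estimate, ct$p.value, length(values),
                  if (exact) "exact permutation p" else "t approximation")
}

#' Odds ratio and Fisher exact test for a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio under the noncentral
#' hypergeometric model with the exact two-sided p (base
#' \code{fisher.test}). A zero margin makes the OR degenerate; a zero cell
#' with nonzero margins yields 0 or +Inf, flagged.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A \code{test_result} with \code{statistic_name = "OR"}.
#' @export
fisher_or <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: odds ratio degenerate")
  ft <- stats::fisher.test(table)
  est <- unname(ft$estimate)
  flag <- if (!is.finite(est) || est == 0) "degenerate cell: OR at boundary"
          else NA_character_
  new_test_result("OR", est, ft$p.value, sum(table), flag = flag)
}

#' Cross-modal connectivity strength association
#'
#' Vectorizes the two results' connectivity strengths (Fisher z) over the
#' strict upper triangle and reports the Pearson correlation together with
#' the ordinary least-squares fit of the second modality's strength on the
#' first.
#'
#' @param res1,res2 \code{connectivity_result}s with identical roi_ids.
#' @param strength \code{"z"} (default, Fisher-transformed) or \code{"r"}.
#' @return List with \code{pearson_r}, \code{slope}, \code{intercept},
#'   \code{n_edges}.
#' @export
cross_modal_association <- function(res1, res2, strength = c("z", "r")) {
  strength <- match.arg(strength)
  if (!identical(res1$roi_ids, res2$roi_ids))
    stop("roi_id mismatch between results")
  ut <- upper.tri(res1$r)
  v1 <- if (strength == "z") res1$z[ut] else res1$r[ut]
  v2 <- if (strength == "z") res2$z[ut] else res2$r[ut]
  fit <- stats::lm(v2 ~ v1)
  list(pearson_r = stats::cor(v1, v2),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_edges = sum(ut))
}

#' Unit-degree group comparison with Holm correction
#'
#' For each functional unit, compares the per-region nodal degrees of two
#' group connectomes with the normality-gated two-sample test and corrects
#' the family of units with Bonferroni-Holm (the family is the set of units
#' tested within one connectome).
#'
#' @param deg1,deg2 Named per-region degree vectors for the two groups
#'   (same regions).
#' @param roi_table Atlas roi_table (roi_id, unit).
#' @param alpha Family-wise level.
#' @param min_n Units with fewer member regions are skipped.
#' @return data.frame: unit, statistic_name, statistic, p, p_holm,
#'   rejected, n.
#' @export
compare_unit_degrees <- function(deg1, deg2, roi_table, alpha = 0.05,
                                 min_n = 3L) {
  stopifnot(identical(names(deg1), names(deg2)))
  ids <- as.integer(names(deg1))
  unit <- roi_table$unit[match(ids, roi_table$roi_id)]
  units <- unique(unit)
  rows <- lapply(units, function(u) {
    i <- which(unit == u)
    if (length(i) < min_n) return(NULL)
    tr <- shapiro_gate_compare(deg1[i], deg2[i])
    data.frame(unit = u, statistic_name = tr$statistic_name,
               statistic = tr$statistic, p = tr$p, n = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) return(NULL)
  hf <- holm_correct(out$p, alpha)
  out$p_holm <- hf$adjusted_p
  out$rejected <- hf$rejected
  out
}
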
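shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  n <- length(x)
  if (n > 5000) x <- x[seq_len(5000)]
  stats::shapiro.test(x)$p.value
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at alpha 0.05: when both groups look normal, a
#' pooled-variance two-sample t-test; otherwise a Mann-Whitney U test.
#' Missing values are dropped pairwise (per-group n reported). Groups with an
#' undefined Shapiro-Wilk statistic (constant values) fall through to
#' Mann-Whitney.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector aligned with `values`.
#' @param normality_alpha gate threshold for Shapiro-Wilk (default 0.05).
#' @return list: `test` ("t" or "mann-whitney"), `statistic`, `p`, per-group
#'   `n`, the Shapiro-Wilk p-values, and `gate_degenerate` if the gate was
#'   undefined for either group.
#' @export
compare_groups <- function(values, groups, normality_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly 2 levels")
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  xs <- split(values, groups)
  if (any(lengths(xs) < 3L)) stop("need at least 3 values per group")
  sw <- vapply(xs, shapiro_p, numeric(1))
  degenerate <- any(is.na(sw))
  use_t <- !degenerate && all(sw > normality_alpha)
  if (use_t) {
    ht <- stats::t.test(values ~ groups, var.equal = TRUE)
    res <- list(test = "t", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values ~ groups))
    res <- list(test = "mann-whitney", statistic = unname(ht$statistic),
                p = ht$p.value)
  }
  c(res, list(n = lengths(xs), shapiro_p = sw, gate_degenerate = degenerate))
}

#' Pearson chi-square test of a 2x2 sex-by-group table
#'
#' Plain Pearson chi-square `sum((O - E)^2 / E)` without continuity
#' correction.
#'
#' @param counts 2x2 nonnegative integer matrix.
#' @return list with `statistic`, `p`, `df`.
#' @export
compare_sex <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("`counts` must be a nonnegative 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("a zero marginal makes the chi-square test undefined")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Normality-gated ROI-clinical correlation with Bonferroni flags
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Spearman
#' otherwise. Reports uncorrected (p < `alpha`) and Bonferroni-corrected
#' (p < `alpha / n_tests`) significance flags; with the conventional 7
#' clinical scales the corrected threshold is 0.05 / 7 = 0.007.
#'
#' @param roi_values per-subject ROI means.
#' @param clinical_values per-subject clinical scores (pairwise-complete).
#' @param alpha uncorrected significance level (default 0.05).
#' @param n_tests number of clinical comparisons in the family (default 7).
#' @param normality_alpha Shapiro-Wilk gate threshold (default 0.05).
#' @return list: `method` ("pearson" or "spearman"), `estimate`, `p`, `n`,
#'   `significant_uncorrected`, `significant_corrected`,
#'   `corrected_threshold`, `degenerate` (constant input: estimate NA,
#'   p = 1).
#' @export
roi_clinical_correlation <- function(roi_values, clinical_values,
                                     alpha = 0.05, n_tests = 7,
                                     normality_alpha = 0.05) {
  ok <- is.finite(roi_values) & is.finite(clinical_values)
  x <- roi_values[ok]; y <- clinical_values[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  thr <- bonferroni_threshold(alpha, n_tests)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(method = NA_character_, estimate = NA_real_, p = 1,
                n = length(x), significant_uncorrected = FALSE,
                significant_corrected = FALSE, corrected_threshold = thr,
                degenerate = TRUE))
  }
  swx <- shapiro_p(x); swy <- shapiro_p(y)
  use_pearson <- !is.na(swx) && !is.na(swy) &&
    swx > normality_alpha && swy > normality_alpha
  method <- if (use_pearson) "pearson" else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, estimate = unname(ht$estimate), p = ht$p.value,
       n = length(x),
       significant_uncorrected = ht$p.value < alpha,
       significant_corrected = ht$p.value < thr,
       corrected_threshold = thr, degenerate = FALSE)
}

#' Covariate-adjusted ROI sensitivity model
#'
#' Ordinary-least-squares fit of `roi ~ group + covariates` with an F-test of
#' the single-df group term (full vs group-free nested model, equivalent to a
#' type-III test here). Collinear covariate columns are dropped with a
#' warning.
#'
#' @param roi_values per-subject ROI means.
#' @param group two-level factor/vector.
#' @param covariates data frame or matrix of nuisance covariates (may be
#'   `NULL` for the unadjusted model).
#' @return list: `F`, `p`, `df` (c(1, residual df)), `dropped` (names of
#'   discarded covariate columns).
#' @export
roi_glm_sensitivity <- function(roi_values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly 2 levels")
  g <- as.numeric(group == levels(group)[2])
  x0 <- cbind(intercept = rep(1, length(g)))
  dropped <- character()
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    qr0 <- qr(cbind(x0, cv))
    if (qr0$rank < ncol(cbind(x0, cv))) {
      keep <- qr0$pivot[seq_len(qr0$rank)]
      all_cols <- cbind(x0, cv)
      dropped <- setdiff(colnames(all_cols), colnames(all_cols)[keep])
      warning(sprintf("dropping collinear covariate(s): %s",
                      paste(dropped, collapse = ", ")))
      cv <- cv[, setdiff(colnames(cv), dropped), drop = FALSE]
    }
    x0 <- cbind(x0, cv)
  }
  ok <- is.finite(roi_values) & stats::complete.cases(x0) & !is.na(g)
  y <- roi_values[ok]; x0 <- x0[ok, , drop = FALSE]; g <- g[ok]
  x1 <- cbind(x0, group = g)
  if (qr(x1)$rank < ncol(x1))
    stop("design is rank-deficient after covariate inclusion")
  rss <- function(x) sum(qr.resid(qr(x), y)^2)
  rss0 <- rss(x0); rss1 <- rss(x1)
  df2 <- length(y) - ncol(x1)
  tss <- sum((y - mean(y))^2)
  # covariates already explain the outcome to machine precision: the group
  # term cannot add anything, so its F is 0 rather than a 0/0 ratio
  f <- if (rss0 <= 1e-12 * tss) 0 else (rss0 - rss1) / (rss1 / df2)
  list(F = f, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       df = c(1, df2), dropped = dropped)
}

#' Group comparison of every numeric column of a clinical table
#'
#' Applies [compare_groups()] to each numeric variable and [compare_sex()]
#' to the sex column, returning one tidy row per variable.
#'
#' @param clinical a clinical table (see [generate_clinical_table()]).
#' @param group_col name of the group column (default `"group"`).
#' @return data frame: variable, test, statistic, p, n_a, n_b.
#' @export
compare_clinical_table <- function(clinical, group_col = "group") {
  groups <- clinical[[group_col]]
  vars <- setdiff(names(clinical)[vapply(clinical, is.numeric, logical(1))],
                  group_col)
  rows <- lapply(vars, function(v) {
    res <- compare_groups(clinical[[v]], groups)
    data.frame(variable = v, test = res$test, statistic = res$statistic,
               p = res$p, n_a = res$n[1], n_b = res$n[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(clinical)) {
    tab <- table(clinical[[group_col]], clinical$sex)
    res <- compare_sex(tab)
    out <- rbind(out, data.frame(variable = "sex", test = "chi-square",
                                 statistic = res$statistic, p = res$p,
                                 n_a = sum(tab[1, ]), n_b = sum(tab[2, ]),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
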
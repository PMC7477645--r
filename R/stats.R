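# Cohort statistics: NMF protein normalization, Shapiro-Wilk reporting,
# variance-gated Student/Welch comparisons, genotype-stratified
# comparisons, Spearman correlation matrix (exact permutation p for small
# n), and OLS regression.

#' Normalize an NMF amount by protein content
#'
#' Compensates for the variable amount of stratum corneum on a tape strip
#' by expressing NMF per gram of protein.
#'
#' @param nmf_amount NMF amount, mmol.
#' @param protein_amount protein amount, g (> 0; a non-positive value
#'   signals a failed protein assay and raises an error).
#' @return NMF concentration, mmol per g protein.
#' @examples
#' normalize_nmf(2, 4)   # 0.5
#' @export
normalize_nmf <- function(nmf_amount, protein_amount) {
  if (!is.numeric(nmf_amount) || !is.numeric(protein_amount))
    cm_abort("inputs must be numeric", "cm_domain_error")
  if (any(!is.finite(protein_amount)) || any(protein_amount <= 0))
    cm_abort("'protein_amount' must be > 0 (failed protein assay?)",
             "cm_domain_error")
  if (any(stats::na.omit(nmf_amount) < 0))
    cm_abort("'nmf_amount' must be >= 0", "cm_domain_error")
  structure(nmf_amount / protein_amount, units = "mmol/g protein")
}

#' Shapiro--Wilk normality check
#'
#' Reports (never gates) the normality of a sample; downstream parametric
#' tests are run regardless, with this p-value carried alongside.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return two-sided Shapiro--Wilk p-value.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    cm_abort(sprintf("Shapiro-Wilk needs 3 <= n <= 5000 (got %d)", n),
             "cm_domain_error")
  if (stats::sd(values) == 0)
    cm_abort("normality undefined for a constant sample", "cm_degenerate")
  stats::shapiro.test(values)$p.value
}

#' Two-group comparison with variance-gated Student/Welch selection
#'
#' Tests equality of variances first (two-sided F-test by default,
#' Brown--Forsythe Levene as alternative) at `alpha_var`; if equality is
#' rejected, Welch's t-test with Welch--Satterthwaite degrees of freedom
#' is used, otherwise Student's pooled t-test. Shapiro--Wilk p-values per
#' group are reported alongside, not used as a gate.
#'
#' @param x_values,y_values numeric vectors (n >= 2 each; NAs dropped).
#' @param alpha_var significance level of the variance-equality gate.
#' @param variance_gate `"ftest"` (default) or `"levene"`
#'   (Brown--Forsythe, absolute deviations from group medians).
#' @param variable optional label of the compared quantity.
#' @param groups length-2 labels of the two samples.
#' @return an object of class `"group_comparison"` with the test used
#'   (`"student"` or `"welch"`), statistic, df, two-sided p, group means,
#'   SDs, sizes, per-group normality p and the variance-test p.
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(11, 12, 13, 14))  # pooled t = -10.95
#' @export
compare_groups <- function(x_values, y_values, alpha_var = 0.05,
                           variance_gate = c("ftest", "levene"),
                           variable = NA_character_,
                           groups = c("x", "y")) {
  variance_gate <- match.arg(variance_gate)
  x <- x_values[!is.na(x_values)]
  y <- y_values[!is.na(y_values)]
  if (length(x) < 2 || length(y) < 2)
    cm_abort("each group needs at least 2 non-missing values",
             "cm_domain_error")
  var_p <- if (variance_gate == "ftest") {
    stats::var.test(x, y)$p.value
  } else {
    d <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
    g <- factor(rep(groups, c(length(x), length(y))))
    stats::anova(stats::lm(d ~ g))[["Pr(>F)"]][1]
  }
  welch <- is.finite(var_p) && var_p < alpha_var
  tt <- stats::t.test(x, y, var.equal = !welch)
  sw <- function(v) tryCatch(normality_check(v),
                             corneomech_error = function(e) NA_real_)
  structure(
    list(variable = variable,
         groups = groups,
         test_used = if (welch) "welch" else "student",
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_two_sided = tt$p.value,
         group_means = stats::setNames(c(mean(x), mean(y)), groups),
         group_sds = stats::setNames(c(stats::sd(x), stats::sd(y)), groups),
         n_per_group = stats::setNames(c(length(x), length(y)), groups),
         normality_p_per_group = stats::setNames(c(sw(x), sw(y)), groups),
         variance_test_p = var_p,
         variance_gate = variance_gate,
         alpha_var = alpha_var),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %s vs %s | %s t = %.3f, df = %.2f, p = %.3g %s\n",
    if (is.na(x$variable)) "comparison" else x$variable,
    x$groups[1], x$groups[2],
    x$test_used, x$statistic, x$df, x$p_two_sided, p_stars(x$p_two_sided)))
  cat(sprintf("  means %.4g / %.4g, SD %.3g / %.3g, n %d / %d (var-test p = %.3g)\n",
              x$group_means[1], x$group_means[2], x$group_sds[1],
              x$group_sds[2], x$n_per_group[1], x$n_per_group[2],
              x$variance_test_p))
  invisible(x)
}

as_row.group_comparison <- function(x) {
  data.frame(variable = x$variable, group1 = x$groups[1],
             group2 = x$groups[2], test_used = x$test_used,
             statistic = x$statistic, df = x$df,
             p_two_sided = x$p_two_sided,
             mean1 = unname(x$group_means[1]), mean2 = unname(x$group_means[2]),
             sd1 = unname(x$group_sds[1]), sd2 = unname(x$group_sds[2]),
             n1 = unname(x$n_per_group[1]), n2 = unname(x$n_per_group[2]),
             normality_p1 = unname(x$normality_p_per_group[1]),
             normality_p2 = unname(x$normality_p_per_group[2]),
             variance_test_p = x$variance_test_p)
}

#' Genotype-stratified comparisons against wild-type controls
#'
#' Compares AD patients without FLG mutations and AD mutation carriers
#' (heterozygous plus homozygous/compound) against FLG wild-type healthy
#' controls, for Ea and NMF. Strata with fewer than two subjects are
#' skipped with a warning and recorded.
#'
#' @param cohort data frame with columns `group`, `flg` and the compared
#'   variables.
#' @param variables columns to compare.
#' @param p_adjust `"none"` (default, matching unadjusted reporting) or
#'   any [stats::p.adjust()] method such as `"BH"`.
#' @param ... passed to [compare_groups()].
#' @return list of `"group_comparison"` objects (class
#'   `"genotype_comparisons"`), with skipped strata in
#'   `attr(, "skipped")` and adjusted p-values in `attr(, "p_adjusted")`
#'   when requested.
#' @export
compare_groups_by_genotype <- function(cohort, variables = c("ea", "nmf"),
                                       p_adjust = "none", ...) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "flg") %in% names(cohort)))
  ctrl_wt <- cohort$group == "control" & cohort$flg == "WT"
  strata <- list(
    AD_FLG_wt = cohort$group == "AD" & cohort$flg == "WT",
    AD_FLG_carrier = cohort$group == "AD" & cohort$flg != "WT")
  out <- list(); skipped <- character()
  for (v in variables) {
    for (s in names(strata)) {
      xs <- cohort[[v]][strata[[s]]]
      ys <- cohort[[v]][ctrl_wt]
      if (sum(!is.na(xs)) < 2 || sum(!is.na(ys)) < 2) {
        skipped <- c(skipped, paste(v, s, sep = ":"))
        cm_warn(sprintf("stratum '%s' too small for variable '%s'; skipped",
                        s, v))
        next
      }
      out[[paste(v, s, sep = ":")]] <-
        compare_groups(xs, ys, variable = v,
                       groups = c(s, "control_FLG_wt"), ...)
    }
  }
  attr(out, "skipped") <- skipped
  if (p_adjust != "none" && length(out)) {
    p <- vapply(out, function(gc) gc$p_two_sided, numeric(1))
    attr(out, "p_adjusted") <- stats::p.adjust(p, method = p_adjust)
  }
  class(out) <- "genotype_comparisons"
  out
}

#' @export
print.genotype_comparisons <- function(x, ...) {
  for (gc in x) print(gc)
  sk <- attr(x, "skipped")
  if (length(sk)) cat("skipped strata:", paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.genotype_comparisons <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as_row.group_comparison))
}

# Exact permutation distribution of the Spearman statistic.
#
# For rank vectors a, b the linear statistic S = sum(a_i * b_perm(i)) is
# monotone in rho; its full permutation distribution is computed by a
# subset-sum dynamic program: dp[mask] is the count vector over S of
# assignments of the b-values indexed by `mask` to the first
# popcount(mask) positions. Ties enter through average ranks, scaled by 2
# to stay on an integer lattice. Feasible up to n = 10 (2^10 masks).
spearman_exact_p <- function(x, y) {
  a <- as.integer(round(rank(x) * 2))
  b <- as.integer(round(rank(y) * 2))
  n <- length(a)
  stopifnot(n >= 2, n <= 10)
  smax <- sum(sort(a) * sort(b))
  dp <- vector("list", 2^n)
  dp[[1]] <- c(1, numeric(smax))
  bits <- 2^(seq_len(n) - 1L)
  masks <- order(vapply(0:(2^n - 1), function(m)
    sum(bitwAnd(m, bits) > 0), numeric(1)))[-1] - 1L
  for (m in masks) {
    k <- sum(bitwAnd(m, bits) > 0)           # position being filled
    acc <- numeric(smax + 1L)
    for (j in seq_len(n)) {
      if (bitwAnd(m, bits[j]) == 0) next
      prev <- dp[[m - bits[j] + 1L]]
      s <- a[k] * b[j]
      acc[(s + 1L):(smax + 1L)] <- acc[(s + 1L):(smax + 1L)] +
        prev[seq_len(smax + 1L - s)]
    }
    dp[[m + 1L]] <- acc
  }
  counts <- dp[[2^n]]
  s_obs <- sum(a * b)
  mu <- sum(a) * sum(b) / n
  svals <- 0:smax
  p <- sum(counts[abs(svals - mu) >= abs(s_obs - mu) - 1e-9]) / sum(counts)
  min(p, 1)
}

# rho and p for one pair of vectors (complete cases already taken)
spearman_pair <- function(x, y, exact_n = 10) {
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  if (!is.finite(rho)) return(c(rho = NA_real_, p = NA_real_))
  p <- if (n <= exact_n) {
    spearman_exact_p(x, y)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  c(rho = rho, p = p)
}

#' Spearman correlation matrix of the cohort variables
#'
#' Pairwise complete-case Spearman rank correlations of NMF, Ea, SCORAD
#' and TEWL with two-sided p-values; SCORAD pairs are restricted to
#' patients (controls carry no severity score). Cells with fewer than 4
#' complete pairs are flagged missing, never fabricated. P-values use the
#' exact permutation distribution for n <= 10 and the t-approximation
#' beyond.
#'
#' @param cohort data frame with (a subset of) the columns in
#'   `variables`, optionally a `group` column for the SCORAD
#'   restriction.
#' @param variables variables to correlate.
#' @param exact_n largest n for which the exact permutation p is used.
#' @return an object of class `"spearman_matrix"`: symmetric `rho`, `p`
#'   and complete-case `n` matrices. [plot()] draws the annotated
#'   heat-map.
#' @examples
#' spearman_matrix(data.frame(nmf = 1:5, ea = c(3, 1, 2, 5, 4)),
#'                 variables = c("nmf", "ea"))
#' @export
spearman_matrix <- function(cohort,
                            variables = c("nmf", "ea", "scorad", "tewl"),
                            exact_n = 10) {
  stopifnot(is.data.frame(cohort))
  variables <- intersect(variables, names(cohort))
  if (length(variables) < 2)
    cm_abort("need at least two of the requested variables",
             "cm_data_error")
  k <- length(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  nmat <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  patients_only <- "group" %in% names(cohort)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- cohort[[variables[i]]]; y <- cohort[[variables[j]]]
    if (patients_only && "scorad" %in% variables[c(i, j)]) {
      keep <- cohort$group == "AD"
      x <- x[keep]; y <- y[keep]
    }
    cc <- stats::complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(cc)
    if (sum(cc) < 4) next
    rp <- spearman_pair(x[cc], y[cc], exact_n)
    rho[i, j] <- rho[j, i] <- rp["rho"]
    p[i, j] <- p[j, i] <- rp["p"]
  }
  diag(nmat) <- vapply(variables, function(v)
    sum(!is.na(cohort[[v]])), integer(1))
  structure(list(variables = variables, rho = rho, p = p, n = nmat,
                 exact_n = exact_n),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 3, ...) {
  cat("Spearman rank correlations (pairwise complete cases)\n")
  print(round(x$rho, digits))
  cat("two-sided p-values\n")
  print(signif(x$p, digits))
  invisible(x)
}

#' OLS regression and coefficient of determination
#'
#' Ordinary least squares of `y` on `x` (canonically Ea on NMF),
#' reporting slope, intercept and R-squared.
#'
#' @param x predictor (e.g. NMF, mmol/g protein).
#' @param y response (e.g. Ea, MPa).
#' @return list of class `"cm_regression"` with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying [stats::lm()] fit.
#' @examples
#' regression_r2(c(1, 2, 3), c(2, 4, 5))$r_squared  # 27/28
#' @export
regression_r2 <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3)
    cm_abort("regression needs at least 3 complete pairs", "cm_domain_error")
  if (stats::var(x) == 0)
    cm_abort("zero variance in the predictor", "cm_degenerate")
  fit <- stats::lm(y ~ x)
  # direct R^2 (summary.lm warns on exact fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(x), model = fit),
            class = "cm_regression")
}

#' @export
print.cm_regression <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4g + %.4g x, R^2 = %.4f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Demographic descriptives of a cohort
#'
#' Per-group sample sizes, FLG genotype strata counts, and mean (range)
#' of TEWL, SCORAD, NMF and Ea, computed on complete cases.
#'
#' @param cohort data frame with columns `group`, `flg` and the
#'   measured variables.
#' @return list of class `"cohort_demographics"`.
#' @export
summarize_demographics <- function(cohort) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  mr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_))
    c(mean = mean(v), min = min(v), max = max(v))
  }
  per_group <- lapply(c(AD = "AD", control = "control"), function(g) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    flg <- if ("flg" %in% names(sub))
      table(factor(sub$flg, levels = c("WT", "het", "hom_or_compound")))
    else NULL
    list(n = nrow(sub),
         flg_counts = flg,
         tewl = mr(sub$tewl), scorad = mr(sub$scorad),
         nmf = mr(sub$nmf), ea = mr(sub$ea))
  })
  structure(per_group, class = "cohort_demographics")
}

#' @export
print.cohort_demographics <- function(x, ...) {
  for (g in names(x)) {
    s <- x[[g]]
    cat(sprintf("%s (n = %d)\n", g, s$n))
    if (!is.null(s$flg_counts))
      cat("  FLG WT/het/hom:", paste(s$flg_counts, collapse = "/"), "\n")
    for (v in c("tewl", "scorad", "nmf", "ea")) {
      m <- s[[v]]
      if (is.finite(m["mean"]))
        cat(sprintf("  %-6s mean %.3g (range %.3g-%.3g)\n",
                    toupper(v), m["mean"], m["min"], m["max"]))
    }
  }
  invisible(x)
}
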
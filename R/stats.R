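#' Bonferroni correction
#'
#' Adjusts p-values for a declared family of `m` comparisons:
#' `p_adj = min(1, m * p)`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p)` and must be at least
#'   that when declared externally.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m smaller than the number of p-values")
  pmin(1, m * p)
}

# internal: pooled-variance pairwise contrasts between group cell means,
# using the residual mean square of the fitted ANOVA model (the classical
# Bonferroni post-hoc test)
pairwise_contrasts <- function(values, groups, mse, df_resid,
                               strata = NULL) {
  groups <- as.character(groups)
  strata <- if (is.null(strata)) rep("", length(values)) else
    as.character(strata)
  rows <- list()
  for (st in unique(strata)) {
    v <- values[strata == st]
    g <- groups[strata == st]
    lev <- sort(unique(g))
    if (length(lev) < 2) next
    cmb <- utils::combn(lev, 2)
    for (j in seq_len(ncol(cmb))) {
      g1 <- cmb[1, j]; g2 <- cmb[2, j]
      n1 <- sum(g == g1); n2 <- sum(g == g2)
      est <- mean(v[g == g1]) - mean(v[g == g2])
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      tval <- if (se > 0) est / se else 0
      praw <- if (se > 0) 2 * pt(-abs(tval), df_resid) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, contrast = paste(g1, "-", g2), estimate = est,
        se = se, t = tval, df = df_resid, p_raw = praw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bonferroni <- bonferroni(out$p_raw, nrow(out))
  rownames(out) <- NULL
  out
}

# internal: TRUE when values have no usable variance (all equal up to
# floating-point rounding relative to their magnitude)
constant_values <- function(y) {
  sd(y) <= 1e-12 * (1 + abs(mean(y)))
}

# internal: significance tiers as printed on the figures
sig_marker <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.005, "***", ifelse(p < 0.05, "*", "")))
}

#' Two-way ANOVA with Bonferroni-corrected contrasts
#'
#' Fits `value ~ factor_a * factor_b` and reports Type II sums of
#' squares (appropriate for the unbalanced animal numbers typical of
#' mutant cohorts), F and p per factor and for the interaction, plus all
#' pairwise `factor_a` contrasts within each level of `factor_b`,
#' Bonferroni-adjusted over the whole family (all contrasts in the
#' analysis).  In the degenerate case of zero residual and effect
#' variance (all values identical), F is reported as 0 and p as 1.
#'
#' @param data data frame.
#' @param value,factor_a,factor_b column names (e.g. value = cell count,
#'   factor_a = genotype, factor_b = region).
#' @param contrasts compute pairwise contrasts (default TRUE; skipping
#'   them is faster for simulation studies).
#' @param alpha significance level recorded in the result.
#' @return an `anova_result`: list with `terms` (data frame of F, df, p
#'   per term), `contrasts`, `alpha`, `family_size`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "genotype",
                          factor_b = "region", contrasts = TRUE,
                          alpha = 0.05) {
  d <- data.frame(y = data[[value]],
                  A = factor(data[[factor_a]]),
                  B = factor(data[[factor_b]]))
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2) {
    stop("both factors need at least 2 levels")
  }
  cell_n <- table(d$A, d$B)
  if (any(cell_n == 0)) {
    stop("empty design cell: interaction not estimable")
  }
  a <- nlevels(d$A); b <- nlevels(d$B); n <- nrow(d)
  if (constant_values(d$y)) {
    # no variance anywhere: F is 0/0; report the conventional no-evidence
    # result rather than numerical noise
    terms <- data.frame(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      df = c(a - 1, b - 1, (a - 1) * (b - 1)),
      sum_sq = 0, F = 0, p = 1, stringsAsFactors = FALSE)
    ctr <- NULL
    if (contrasts) {
      ctr <- pairwise_contrasts(d$y, d$A, mse = 0, df_resid = n - a * b,
                                strata = d$B)
      names(ctr)[names(ctr) == "stratum"] <- factor_b
      ctr$marker <- sig_marker(ctr$p_bonferroni)
    }
    return(structure(list(terms = terms, contrasts = ctr, alpha = alpha,
                          family_size = if (is.null(ctr)) 0L else nrow(ctr),
                          residual_df = n - a * b),
                     class = "anova_result"))
  }
  fit <- lm(y ~ A * B, data = d)
  aov2 <- suppressWarnings(car::Anova(fit, type = 2))
  df_resid <- aov2["Residuals", "Df"]
  mse <- aov2["Residuals", "Sum Sq"] / df_resid
  keep <- rownames(aov2) != "Residuals"
  terms <- data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    df = aov2$Df[keep],
    sum_sq = aov2$`Sum Sq`[keep],
    F = aov2$`F value`[keep],
    p = aov2$`Pr(>F)`[keep],
    stringsAsFactors = FALSE)
  degen <- !is.finite(terms$F)
  terms$F[degen] <- 0
  terms$p[degen] <- 1
  ctr <- NULL
  if (contrasts) {
    ctr <- pairwise_contrasts(d$y, d$A, mse = max(mse, 0),
                              df_resid = df_resid, strata = d$B)
    if (!is.null(ctr)) {
      names(ctr)[names(ctr) == "stratum"] <- factor_b
      ctr$marker <- sig_marker(ctr$p_bonferroni)
    }
  }
  structure(list(terms = terms, contrasts = ctr, alpha = alpha,
                 family_size = if (is.null(ctr)) 0L else nrow(ctr),
                 residual_df = df_resid),
            class = "anova_result")
}

#' One-way ANOVA with Bonferroni-corrected contrasts
#'
#' Standard F test across groups, plus pooled-variance pairwise
#' contrasts Bonferroni-adjusted over all pairs.  With two groups the F
#' statistic equals the square of the pooled two-sample t statistic.
#'
#' @param data data frame.
#' @param value,group column names.
#' @param alpha significance level recorded in the result.
#' @return an `anova_result` (see [two_way_anova()]).
#' @export
one_way_anova <- function(data, value = "value", group = "group",
                          alpha = 0.05) {
  d <- data.frame(y = data[[value]], G = factor(data[[group]]))
  if (nlevels(d$G) < 2) stop("need at least 2 groups")
  if (any(table(d$G) < 2)) stop("need at least 2 observations per group")
  if (constant_values(d$y)) {
    terms <- data.frame(term = group, df = nlevels(d$G) - 1, sum_sq = 0,
                        F = 0, p = 1, stringsAsFactors = FALSE)
    ctr <- pairwise_contrasts(d$y, d$G, mse = 0,
                              df_resid = nrow(d) - nlevels(d$G))
    ctr$stratum <- NULL
    ctr$marker <- sig_marker(ctr$p_bonferroni)
    return(structure(list(terms = terms, contrasts = ctr, alpha = alpha,
                          family_size = nrow(ctr),
                          residual_df = nrow(d) - nlevels(d$G)),
                     class = "anova_result"))
  }
  fit <- lm(y ~ G, data = d)
  a <- anova(fit)
  df_resid <- a["Residuals", "Df"]
  mse <- a["Residuals", "Sum Sq"] / df_resid
  terms <- data.frame(term = group, df = a$Df[1], sum_sq = a$`Sum Sq`[1],
                      F = a$`F value`[1], p = a$`Pr(>F)`[1],
                      stringsAsFactors = FALSE)
  degen <- !is.finite(terms$F)
  terms$F[degen] <- 0
  terms$p[degen] <- 1
  ctr <- pairwise_contrasts(d$y, d$G, mse = max(mse, 0),
                            df_resid = df_resid)
  if (!is.null(ctr)) {
    ctr$stratum <- NULL
    ctr$marker <- sig_marker(ctr$p_bonferroni)
  }
  structure(list(terms = terms, contrasts = ctr, alpha = alpha,
                 family_size = if (is.null(ctr)) 0L else nrow(ctr),
                 residual_df = df_resid),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (alpha =", x$alpha, ")\n")
  print(x$terms, row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise contrasts (Bonferroni family of", x$family_size, "):\n")
    print(x$contrasts, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
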
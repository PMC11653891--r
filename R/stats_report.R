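#' Compare a metric between groups
#'
#' Thin reporting wrapper around standard test routines, mirroring the usual
#' workflow for these recordings: each group is checked for normality
#' (Shapiro-Wilk below 50 observations, otherwise Lilliefors-style
#' Kolmogorov-Smirnov against the fitted normal) and, for the parametric
#' branch, for variance homogeneity (Bartlett). If every group passes both at
#' `alpha`, the parametric branch runs (two groups: Student's t; more: one-way
#' ANOVA with the requested multiple-comparison correction); otherwise the
#' nonparametric branch (two groups: Mann-Whitney; more: Kruskal-Wallis with
#' Dunn's test).
#'
#' @param values numeric vector of metric values.
#' @param groups factor or character vector of group labels, same length.
#' @param policy `"auto"` (normality-driven), `"parametric"` or
#'   `"nonparametric"`.
#' @param correction multiple-comparison correction for >2 groups:
#'   `"tukey"`, `"dunnett"` (parametric; first group level is the control),
#'   `"dunn"` (nonparametric, Holm-adjusted), or `"none"`.
#' @param alpha significance level for the normality/homogeneity gate.
#' @return list of class `group_comparison`: `branch` (`parametric` or
#'   `nonparametric`), `test`, `statistic`, `p_value`, `pairwise` (data.frame
#'   `group1`, `group2`, `p_adj`; `NULL` for 2 groups), `normality_p`,
#'   `homogeneity_p`.
#' @export
compare_groups <- function(values, groups,
                           policy = c("auto", "parametric", "nonparametric"),
                           correction = c("tukey", "dunnett", "dunn", "none"),
                           alpha = 0.05) {
  policy <- match.arg(policy)
  correction <- match.arg(correction)
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("each group needs n >= 2")

  norm_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal
    if (length(x) < 50) {
      stats::shapiro.test(x)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
      )
    }
  }, numeric(1))
  hom_p <- tryCatch(stats::bartlett.test(values, groups)$p.value,
                    error = function(e) 0)

  branch <- switch(policy,
    parametric = "parametric",
    nonparametric = "nonparametric",
    auto = if (all(norm_p > alpha) && hom_p > alpha) "parametric"
           else "nonparametric"
  )

  two <- nlevels(groups) == 2
  pairwise <- NULL
  if (branch == "parametric") {
    if (two) {
      tt <- stats::t.test(values ~ groups, var.equal = TRUE)
      test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      test <- "anova"; statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      pairwise <- switch(correction,
        tukey = {
          th <- stats::TukeyHSD(fit)$groups
          pairs <- do.call(rbind, strsplit(rownames(th), "-", fixed = TRUE))
          data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                     p_adj = th[, "p adj"], row.names = NULL,
                     stringsAsFactors = FALSE)
        },
        dunnett = {
          gl <- multcomp::glht(fit, linfct = multcomp::mcp(groups = "Dunnett"))
          sm <- summary(gl)
          comp <- names(sm$test$coefficients)
          pairs <- do.call(rbind, strsplit(comp, " - ", fixed = TRUE))
          data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                     p_adj = as.numeric(sm$test$pvalues), row.names = NULL,
                     stringsAsFactors = FALSE)
        },
        dunn = stop("Dunn's test is a nonparametric correction"),
        none = NULL
      )
    }
  } else {
    if (two) {
      wt <- suppressWarnings(stats::wilcox.test(values ~ groups))
      test <- "mann_whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
    } else {
      kw <- stats::kruskal.test(values, groups)
      test <- "kruskal_wallis"; statistic <- unname(kw$statistic); p <- kw$p.value
      pairwise <- switch(correction,
        dunn = dunn_test(values, groups),
        none = NULL,
        stop("use correction = 'dunn' (or 'none') on the nonparametric branch")
      )
    }
  }
  structure(
    list(branch = branch, test = test, statistic = statistic, p_value = p,
         pairwise = pairwise, normality_p = norm_p, homogeneity_p = hom_p),
    class = "group_comparison"
  )
}

# Dunn's post-hoc test on pooled ranks after Kruskal-Wallis, with the usual
# tie correction and Holm adjustment across pairs.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  mean_rk <- tapply(rk, groups, mean)
  n_g <- table(groups)
  combs <- utils::combn(lv, 2)
  z <- apply(combs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
               (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    (mean_rk[[pr[1]]] - mean_rk[[pr[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(
    group1 = combs[1, ], group2 = combs[2, ],
    p_adj = stats::p.adjust(p_raw, method = "holm"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s branch, %s test, statistic = %.3f, p = %.4g\n",
              x$branch, x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}
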
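## Cohort demographic summaries, rank-correlation confounder screens, and
## per-feature group comparisons.

#' Ratio of two counts at a printed precision
#'
#' @param a,b numerator and denominator counts.
#' @param decimals digits the ratio is rounded to.
#' @return \code{round(a / b, decimals)}; \code{Inf} with a warning when
#'   \code{b} is zero.
#' @examples
#' groupRatio(141, 2, 1)    # 70.5 (drinkers : non-drinkers)
#' groupRatio(150, 137, 2)  # 1.09 (morbid : healthy)
#' @export
groupRatio <- function(a, b, decimals = 2L) {
  if (b == 0) {
    warning("denominator is zero; ratio undefined")
    return(Inf)
  }
  round(a / b, decimals)
}

#' Demographic cohort summary
#'
#' Per-group n, mean +/- SD (sample SD) for continuous variables, and
#' numerator:denominator ratio blocks for binary covariates. Records with a
#' missing covariate are excluded from that covariate's block and counted.
#'
#' @param samples data.frame of subject records (one row per subject) with a
#'   grouping column and the summarised covariates.
#' @param group name of the grouping column (default \code{"ethnicity"}).
#' @param continuous names of continuous covariates (default age, bmi).
#' @param binary named list of binary covariates: each element gives the
#'   column name; the ratio reported is TRUE:FALSE.
#' @param decimals digits for printed ratios.
#' @return list of class \code{"CohortSummary"}: per group, \code{n},
#'   \code{continuous} (mean/sd per variable) and \code{ratios} (per
#'   variable: \code{n_true}, \code{n_false}, \code{n_missing},
#'   \code{ratio}).
#' @export
cohortSummary <- function(samples, group = "ethnicity",
                          continuous = c("age", "bmi"),
                          binary = c("alcohol", "smoking", "morbid"),
                          decimals = 2L) {
  stopIf(!group %in% names(samples), "no grouping column '", group, "'")
  groups <- unique(samples[[group]])
  out <- list()
  for (g in groups) {
    sub <- samples[samples[[group]] == g, , drop = FALSE]
    cont <- lapply(continuous[continuous %in% names(sub)], function(v) {
      x <- sub[[v]][!is.na(sub[[v]])]
      list(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
           degenerate = length(x) <= 1L)
    })
    names(cont) <- continuous[continuous %in% names(sub)]
    rat <- list()
    for (v in binary) {
      if (!v %in% names(sub)) next
      x <- sub[[v]]
      n_missing <- sum(is.na(x))
      if (n_missing == length(x)) {
        message("group '", g, "': covariate '", v,
                "' entirely missing; block omitted")
        next
      }
      a <- sum(x, na.rm = TRUE)
      b <- sum(!x, na.rm = TRUE)
      rat[[v]] <- list(n_true = a, n_false = b, n_missing = n_missing,
                       ratio = groupRatio(a, b, decimals))
    }
    out[[g]] <- list(n = nrow(sub), continuous = cont, ratios = rat)
  }
  structure(out, class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("%s (n = %d)\n", g, x[[g]]$n))
    for (v in names(x[[g]]$continuous)) {
      ct <- x[[g]]$continuous[[v]]
      cat(sprintf("  %s: %.2f +/- %.2f\n", v, ct$mean, ct$sd))
    }
    for (v in names(x[[g]]$ratios)) {
      r <- x[[g]]$ratios[[v]]
      cat(sprintf("  %s: %d:%d (%g)%s\n", v, r$n_true, r$n_false, r$ratio,
                  if (r$n_missing) sprintf(" [%d missing]", r$n_missing)
                  else ""))
    }
  }
  invisible(x)
}

#' Spearman correlation matrix of cohort metadata
#'
#' Pairwise-complete Spearman rank correlations (tie-corrected via midranks)
#' across numeric covariates; cells with fewer than 3 complete pairs are NA.
#'
#' @param covariates data.frame or matrix of numeric covariates (columns are
#'   variables; logical columns are coerced).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(covariates) {
  m <- as.data.frame(covariates)
  m <- data.matrix(m)
  rho <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs"))
  for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) {
    if (sum(complete.cases(m[, c(i, j), drop = FALSE])) < 3L)
      rho[i, j] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Pairwise Welch t-tests with BH adjustment and boxplot statistics
#'
#' For every pair of groups a Welch (unequal-variance) two-sided t-test is
#' run; p-values are BH-adjusted across pairs. Per-group five-number boxplot
#' statistics use the 1.5 IQR whisker rule.
#'
#' @param values numeric vector (e.g. normalised intensities of one
#'   metabolite).
#' @param labels group labels (>= 2 per group).
#' @return list with \code{tests} (data.frame: group1, group2, t, df, p,
#'   p_adj) and \code{box} (data.frame per group: lower whisker, Q1, median,
#'   Q3, upper whisker, n).
#' @export
pairwiseGroupTest <- function(values, labels) {
  labels <- as.character(labels)
  stopIf(length(values) != length(labels), "lengths differ")
  counts <- table(labels)
  stopIf(any(counts < 2L), "every group needs >= 2 values")
  groups <- sort(names(counts))
  pairs <- combn(groups, 2L)
  tests <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    tt <- t.test(values[labels == pairs[1L, i]],
                 values[labels == pairs[2L, i]], var.equal = FALSE)
    tests$t[i] <- unname(tt$statistic)
    tests$df[i] <- unname(tt$parameter)
    tests$p[i] <- tt$p.value
  }
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  box <- do.call(rbind, lapply(groups, function(g) {
    st <- grDevices::boxplot.stats(values[labels == g])$stats
    data.frame(group = g, whisker_low = st[1L], q1 = st[2L],
               median = st[3L], q3 = st[4L], whisker_high = st[5L],
               n = sum(labels == g), stringsAsFactors = FALSE)
  }))
  list(tests = tests, box = box)
}
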
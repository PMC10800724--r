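#' Maximum-likelihood probit regression
#'
#' Fits a probit model with intercept by ML and reports coefficients,
#' standard errors, z and two-sided p values, and the AIC
#' (`2k - 2 logLik`, `k` counting the intercept). Perfect separation or a
#' degenerate outcome yields a result flagged `converged = FALSE`;
#' a rank-deficient design is an error naming the collinear columns.
#'
#' @param outcome binary 0/1 vector.
#' @param regressors data.frame of regressors (may be `NULL` or empty for
#'   an intercept-only fit).
#' @return object of class `regression_result` with elements
#'   `coefficients`, `standard_errors`, `z_values`, `p_values`, `aic`,
#'   `log_lik`, `n_obs`, `converged`.
#' @export
probit_fit <- function(outcome, regressors = NULL) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- length(outcome)
  if (is.null(regressors) || NCOL(regressors) == 0) {
    regressors <- data.frame(row.names = seq_len(n))
  }
  regressors <- as.data.frame(regressors)
  if (nrow(regressors) != n) stop("outcome/regressor length mismatch")
  k <- ncol(regressors) + 1L
  if (n <= k - 1L) stop("need more observations than regressors")
  X <- cbind(`(Intercept)` = 1, as.matrix(regressors))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  degenerate <- length(unique(outcome)) < 2
  dat <- data.frame(.y = outcome, regressors, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = binomial(link = "probit"),
               control = list(maxit = 100, epsilon = 1e-12))
  )
  mu <- stats::fitted(fit)
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
  co <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    coefficients = stats::setNames(co[, 1], rownames(co)),
    standard_errors = stats::setNames(co[, 2], rownames(co)),
    z_values = stats::setNames(co[, 3], rownames(co)),
    p_values = stats::setNames(co[, 4], rownames(co)),
    aic = 2 * nrow(co) - 2 * ll, log_lik = ll, n_obs = n,
    converged = fit$converged && !separated && !degenerate
  ), class = "regression_result")
}

#' Significance markers for a p value
#'
#' `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.1, else empty.
#'
#' @param p p values.
#' @return character vector of markers.
#' @export
significance_marker <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                        ifelse(p < 0.1, "*", ""))))
}

trait_regressor_names <- function() c(param_names(), "tab_performance")

join_cohort_fits <- function(cohort, fits) {
  subj <- cohort$subjects
  subj <- subj[subj$excluded_reason == "none", , drop = FALSE]
  orphans <- setdiff(subj$subject_id, fits$subject_id)
  if (length(orphans)) {
    stop("subjects missing from the fitted-parameter table: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) sprintf(" (and %d more)", length(orphans) - 5))
  }
  keep <- c("subject_id", param_names(),
            if ("converged" %in% names(fits)) "converged")
  df <- merge(subj[, c("subject_id", "tab_performance", "task_order",
                       "success_8coin", "success_9dot")],
              fits[, keep], by = "subject_id")
  if (!"converged" %in% names(df)) df$converged <- TRUE
  n_drop <- sum(!df$converged | !stats::complete.cases(df[param_names()]))
  if (n_drop > 0) {
    message(n_drop, " subjects without converged fits dropped listwise")
    df <- df[df$converged & stats::complete.cases(df[param_names()]), ,
             drop = FALSE]
  }
  df
}

four_probit_specs <- function(df) {
  reg <- df[trait_regressor_names()]
  list(
    coin8_base = probit_fit(df$success_8coin, reg),
    coin8_transfer = probit_fit(
      df$success_8coin, cbind(success_9dot = df$success_9dot, reg)),
    dot9_base = probit_fit(df$success_9dot, reg),
    dot9_transfer = probit_fit(
      df$success_9dot, cbind(success_8coin = df$success_8coin, reg))
  )
}

#' Full-sample probit regressions of insight success on learning traits
#'
#' Four specifications on the retained cohort joined with the fitted
#' traits: 8-coin success on the seven traits plus TAB performance,
#' without and with 9-dot success as a transfer regressor; likewise for
#' 9-dot success with 8-coin success.
#'
#' @param cohort a `cohort_table`.
#' @param fits fitted-parameter table ([fit_cohort()] output or
#'   [true_trait_table()]).
#' @return named list of four `regression_result`s:
#'   `coin8_base`, `coin8_transfer`, `dot9_base`, `dot9_transfer`.
#' @export
run_table3_analysis <- function(cohort, fits) {
  four_probit_specs(join_cohort_fits(cohort, fits))
}

#' Second-administered-task probit regressions
#'
#' The same four specifications, each restricted to the subjects for whom
#' the modeled task was administered second (so its success may carry a
#' transfer effect from the first task).
#'
#' @inheritParams run_table3_analysis
#' @return named list of four `regression_result`s.
#' @export
run_table4_analysis <- function(cohort, fits) {
  df <- join_cohort_fits(cohort, fits)
  second8 <- df[df$task_order == "9dot_first", , drop = FALSE]
  second9 <- df[df$task_order == "8coin_first", , drop = FALSE]
  if (nrow(second8) == 0 || nrow(second9) == 0) {
    stop("empty second-administered subsample")
  }
  reg8 <- second8[trait_regressor_names()]
  reg9 <- second9[trait_regressor_names()]
  list(
    coin8_base = probit_fit(second8$success_8coin, reg8),
    coin8_transfer = probit_fit(
      second8$success_8coin,
      cbind(success_9dot = second8$success_9dot, reg8)),
    dot9_base = probit_fit(second9$success_9dot, reg9),
    dot9_transfer = probit_fit(
      second9$success_9dot,
      cbind(success_8coin = second9$success_8coin, reg9))
  )
}

#' First- vs second-administration success rates and chi-square test
#'
#' Splits the retained cohort by task order and compares the task's
#' success proportion when administered first vs second with the Pearson
#' chi-square statistic on the 2x2 table (1 df, no continuity
#' correction).
#'
#' @param cohort a `cohort_table`.
#' @param task `"8coin"` or `"9dot"`.
#' @return list with `rate_first`, `rate_second`, `chi_square`,
#'   `p_value`, `n_first`, `n_second`, and `degenerate` (TRUE when a
#'   margin of the 2x2 table is zero).
#' @export
success_rate_comparison <- function(cohort, task = c("8coin", "9dot")) {
  task <- match.arg(task)
  df <- cohort$subjects
  df <- df[df$excluded_reason == "none", , drop = FALSE]
  success <- if (task == "8coin") df$success_8coin else df$success_9dot
  first <- if (task == "8coin") df$task_order == "8coin_first"
           else df$task_order == "9dot_first"
  if (!any(first) || all(first)) stop("both order groups must be non-empty")
  tab <- rbind(first = c(sum(success[first] == 1), sum(success[first] == 0)),
               second = c(sum(success[!first] == 1), sum(success[!first] == 0)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chi <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic); pv <- unname(ct$p.value)
  }
  list(rate_first = mean(success[first]), rate_second = mean(success[!first]),
       chi_square = chi, p_value = pv,
       n_first = sum(first), n_second = sum(!first), degenerate = degenerate)
}

#' Descriptive statistics and trait correlations
#'
#' Means, sample SDs (n-1 denominator) and the lower-triangular Pearson
#' correlation matrix, with two-sided significance markers, over the
#' analysis variables: the two task outcomes, the seven fitted traits and
#' TAB performance. A constant column gets `NA` correlations.
#'
#' @param cohort a `cohort_table`.
#' @param fits fitted-parameter table.
#' @return object of class `descriptive_table`: `summary` (variable,
#'   mean, sd), `correlations`, `p_values`, `markers` (lower-triangular
#'   matrices).
#' @export
descriptive_stats <- function(cohort, fits) {
  df <- join_cohort_fits(cohort, fits)
  vars <- c("success_8coin", "success_9dot", param_names(),
            "tab_performance")
  m <- as.matrix(df[vars])
  if (nrow(m) < 3) stop("need at least 3 rows")
  p <- ncol(m)
  cors <- pvals <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(cors) <- 1
  for (i in 2:p) for (j in 1:(i - 1)) {
    if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
    ct <- stats::cor.test(m[, i], m[, j])
    cors[i, j] <- unname(ct$estimate)
    pvals[i, j] <- ct$p.value
  }
  structure(list(
    summary = data.frame(variable = vars, mean = colMeans(m),
                         sd = apply(m, 2, stats::sd), row.names = NULL),
    correlations = cors, p_values = pvals,
    markers = matrix(significance_marker(pvals), p, p,
                     dimnames = dimnames(pvals))
  ), class = "descriptive_table")
}

#' Render a set of probit fits as an aligned text table
#'
#' Coefficients with significance markers and standard errors in
#' parentheses, one column per specification, with AIC and N rows.
#'
#' @param results named list of `regression_result`s.
#' @param digits decimals for display.
#' @return character vector of lines.
#' @export
render_regression_table <- function(results, digits = 2) {
  terms <- unique(unlist(lapply(results, function(r) names(r$coefficients))))
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  header <- c("term", names(results))
  rows <- list()
  for (tm in terms) {
    est <- vapply(results, function(r) {
      if (tm %in% names(r$coefficients)) {
        paste0(fmt(r$coefficients[[tm]]),
               significance_marker(r$p_values[[tm]]))
      } else ""
    }, character(1))
    se <- vapply(results, function(r) {
      if (tm %in% names(r$coefficients)) {
        paste0("(", fmt(r$standard_errors[[tm]]), ")")
      } else ""
    }, character(1))
    rows[[length(rows) + 1]] <- c(tm, est)
    rows[[length(rows) + 1]] <- c("", se)
  }
  rows[[length(rows) + 1]] <-
    c("AIC", vapply(results, function(r) fmt(r$aic), character(1)))
  rows[[length(rows) + 1]] <-
    c("N", vapply(results, function(r) as.character(r$n_obs), character(1)))
  mat <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(mat), 2, max)
  apply(mat, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
}
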
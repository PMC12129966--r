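# Inferential layer: group comparisons (chi-square / Fisher's exact for
# categorical variables, Mann-Whitney U for quantitative ones) and multiple
# logistic regression with forward stepwise selection for ADR risk factors.
# The 5% significance level is the package-wide default.

#' Patient-level analysis table
#'
#' One row per record with the covariates used by the inferential layer and
#' the ADR outcome flag.
#'
#' @param x an \code{icu_cohort}.
#' @param adrs adjudicated ADRs (optional; without it \code{has_adr} is
#'   \code{NA}).
#' @return data.frame with \code{patient_id, unit, sex, age, los_days,
#'   outcome, has_adr}.
#' @export
patient_table <- function(x, adrs = NULL) {
  stopifnot(inherits(x, "icu_cohort"))
  p <- x$patients
  los_days <- as.integer(ceiling(as.numeric(
    difftime(p$discharge_time, p$admit_time, units = "days"))))
  has_adr <- if (is.null(adrs)) NA else p$patient_id %in% adrs$patient_id
  data.frame(patient_id = p$patient_id,
             unit = factor(p$unit, levels = c("G_ICU", "C19_ICU")),
             sex = factor(p$sex, levels = c("female", "male")),
             age = p$age, los_days = los_days, outcome = p$outcome,
             has_adr = has_adr, stringsAsFactors = FALSE)
}

#' Compare a variable between two groups
#'
#' Categorical variables use the chi-square test, falling back to Fisher's
#' exact test when any expected cell count is below 5; quantitative
#' variables use the two-sided Mann-Whitney U test (exact for group sizes
#' up to 20 without ties, normal approximation with continuity and tie
#' correction otherwise).
#'
#' @param data patient-level data.frame (e.g. \code{\link{patient_table}}).
#' @param variable column to compare.
#' @param group column defining the two groups.
#' @return a \code{group_comparison}: list with \code{variable},
#'   \code{group}, \code{test_used}, \code{statistic}, \code{p_value}.
#' @export
compare_groups <- function(data, variable, group) {
  v <- data[[variable]]
  g <- data[[group]]
  if (is.null(v)) stop("no such variable: ", variable)
  if (is.null(g)) stop("no such grouping column: ", group)
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2) stop("grouping must have at least two non-empty groups")
  if (length(unique(v)) < 2) {
    stop("variable '", variable, "' is constant; the test is degenerate")
  }
  if (is.numeric(v)) {
    exact <- min(table(g)) <= 20 && !any(duplicated(v))
    ht <- suppressWarnings(stats::wilcox.test(v ~ g, exact = exact,
                                              correct = TRUE))
    test <- "mann_whitney"
  } else {
    tab <- table(v, g)
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(expected$expected < 5)) {
      ht <- stats::fisher.test(tab)
      test <- "fisher_exact"
    } else {
      ht <- expected
      test <- "chi_square"
    }
  }
  structure(list(variable = variable, group = group, test_used = test,
                 statistic = unname(ht$statistic %||% NA_real_),
                 p_value = unname(ht$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s: %s, p = %.4g\n", x$variable, x$group, x$test_used,
              x$p_value))
  invisible(x)
}

#' Stepwise logistic regression for ADR risk factors
#'
#' Forward selection with a backward check: at each step the candidate with
#' the smallest likelihood-ratio p-value enters if below \code{entry}, and
#' any included variable whose Wald p-value rises above \code{stay} is
#' removed, until the model is stable. Reports odds ratios with Wald 95\%
#' confidence intervals for the selected variables.
#'
#' @param data patient-level data.frame.
#' @param outcome name of the binary outcome column (default
#'   \code{"has_adr"}).
#' @param candidates candidate covariate names.
#' @param entry,stay entry and stay p-value thresholds (default 0.05/0.05).
#' @return an \code{adr_logistic} object with \code{selected},
#'   \code{coefficients} (OR, CI, p), and the underlying \code{glm} fit
#'   (\code{NULL} when nothing is selected).
#' @export
stepwise_logistic <- function(data, outcome = "has_adr",
                              candidates = c("age", "sex", "los_days",
                                             "unit"),
                              entry = 0.05, stay = 0.05) {
  if (!outcome %in% names(data)) stop("no such outcome column: ", outcome)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(y) <= 10 * length(candidates)) {
    stop("too few observations for ", length(candidates),
         " candidates (need > ", 10 * length(candidates), ")")
  }
  df <- data[, candidates, drop = FALSE]
  df$.y <- y
  for (ca in candidates) {
    if (is.character(df[[ca]])) df[[ca]] <- factor(df[[ca]])
    v <- df[[ca]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2) ||
        (is.numeric(v) && length(unique(v)) < 2)) {
      stop("candidate '", ca, "' is constant")
    }
  }
  # perfect collinearity among candidates is rejected up front
  mm <- stats::model.matrix(~ ., df[, candidates, drop = FALSE])
  if (qr(mm)$rank < ncol(mm)) {
    stop("candidates are collinear; remove redundant variables")
  }

  fit_formula <- function(vars) {
    f <- if (length(vars)) paste(".y ~", paste(vars, collapse = " + ")) else
      ".y ~ 1"
    glm(as.formula(f), family = binomial(), data = df)
  }
  check_separation <- function(fit) {
    p <- stats::fitted(fit)
    if (!fit$converged || any(abs(coef(fit)[-1] %||% 0) > 15) ||
        all(p < 1e-8 | p > 1 - 1e-8)) {
      stop("complete or quasi-complete separation detected; ",
           "coefficients are not identifiable")
    }
  }

  selected <- character(0)
  dropped <- character(0)  # removed in a backward step; not re-entered
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, c(selected, dropped))
    if (length(remaining)) {
      base_fit <- fit_formula(selected)
      pvals <- vapply(remaining, function(ca) {
        fit <- suppressWarnings(fit_formula(c(selected, ca)))
        check_separation(fit)
        an <- anova(base_fit, fit, test = "LRT")
        an$`Pr(>Chi)`[2]
      }, numeric(1))
      if (min(pvals) < entry) {
        selected <- c(selected, remaining[which.min(pvals)])
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- suppressWarnings(fit_formula(selected))
      # Wald p per variable (max across factor contrasts)
      sm <- summary(fit)$coefficients
      wp <- vapply(selected, function(ca) {
        rows <- grep(paste0("^", ca), rownames(sm))
        min(sm[rows, "Pr(>|z|)"])
      }, numeric(1))
      worst <- which.max(wp)
      if (wp[worst] > stay) {
        dropped <- c(dropped, selected[worst])
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (!length(selected)) {
    res <- structure(list(selected = character(0),
                          coefficients = data.frame(),
                          entry = entry, stay = stay, fit = NULL,
                          n = length(y)),
                     class = "adr_logistic")
    return(res)
  }
  fit <- suppressWarnings(fit_formula(selected))
  check_separation(fit)
  sm <- summary(fit)$coefficients
  est <- sm[-1, , drop = FALSE]  # drop intercept
  ci_lo <- est[, "Estimate"] - qnorm(0.975) * est[, "Std. Error"]
  ci_hi <- est[, "Estimate"] + qnorm(0.975) * est[, "Std. Error"]
  coefs <- data.frame(term = rownames(est),
                      odds_ratio = exp(est[, "Estimate"]),
                      ci95_low = exp(ci_lo), ci95_high = exp(ci_hi),
                      p_value = est[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(selected = selected, coefficients = coefs,
                 entry = entry, stay = stay, fit = fit, n = length(y)),
            class = "adr_logistic")
}

#' @export
print.adr_logistic <- function(x, ...) {
  cat("Stepwise logistic regression (entry/stay p =", x$entry, "/",
      x$stay, "), n =", x$n, "\n")
  if (!length(x$selected)) {
    cat("  no variables selected\n")
    return(invisible(x))
  }
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$coefficients))) {
    r <- x$coefficients[i, ]
    cat(sprintf("  %-12s OR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                r$term, r$odds_ratio, r$ci95_low, r$ci95_high, r$p_value))
  }
  invisible(x)
}

#' @export
summary.adr_logistic <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' @export
coef.adr_logistic <- function(object, ...) {
  if (is.null(object$fit)) return(numeric(0))
  coef(object$fit)
}
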
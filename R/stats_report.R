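#' Specify a mixed-effects analysis
#'
#' Describes one trial-level analysis: the response column, the family
#' (logistic for binary responses, gaussian for accuracy scores), the
#' fixed-effect terms (main effects and `a:b` interactions, all centred
#' before fitting) and the grouping factor of the participant random
#' intercept.  For gaussian fits, p-values are computed from the t
#' statistic with `df_for_t` degrees of freedom, conventionally the number
#' of observations minus the number of fixed parameters.
#'
#' @param response Response column name.
#' @param family `"binomial"` (logit link) or `"gaussian"`.
#' @param fixed_effects Character vector of predictor terms; interactions
#'   as `"a:b"`.  May be empty (intercept-only model).
#' @param group Column name of the random-intercept grouping factor.
#' @param df_for_t Degrees of freedom for gaussian t tests; default
#'   `n_obs - n_fixed_parameters`, resolved at fit time.
#' @param maximal If `TRUE`, attempt by-participant random slopes for all
#'   within-participant fixed effects, falling back to the random
#'   intercept on non-convergence.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, family = c("binomial", "gaussian"),
                       fixed_effects = character(0), group = "participant",
                       df_for_t = NULL, maximal = FALSE) {
  family <- match.arg(family)
  structure(list(response = response, family = family,
                 fixed_effects = fixed_effects, group = group,
                 df_for_t = df_for_t, maximal = maximal),
            class = "model_spec")
}

#' Centre the fixed-effect predictors of a table
#'
#' Every fixed-effect main-effect column is recoded to mean zero:
#' two-level factors and logicals become 0/1 first, then the column mean is
#' subtracted, so a balanced binary predictor becomes ±0.5 and a 2:1
#' unbalanced one \{+1/3, −2/3\}.  Interaction terms are formed from the
#' centred columns at fit time.  Centred columns are written as
#' `<name>_c`.
#'
#' @param table Data frame of trials.
#' @param spec A [model_spec()], or a character vector of column names.
#' @return The data frame with the centred columns appended.
#' @export
center_predictors <- function(table, spec) {
  cols <- if (inherits(spec, "model_spec")) {
    unique(unlist(strsplit(spec$fixed_effects, ":", fixed = TRUE)))
  } else {
    spec
  }
  for (col in cols) {
    if (!col %in% names(table)) stop("predictor column not found: ", col)
    x <- table[[col]]
    if (is.logical(x)) x <- as.integer(x)
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) != 2L) {
        stop("cannot centre non-binary categorical predictor '", col,
             "' with ", length(lev), " levels")
      }
      x <- as.integer(as.character(x) == lev[2L])
    }
    if (length(unique(x)) < 2L) {
      stop("predictor '", col, "' is constant; no contrast to centre")
    }
    table[[paste0(col, "_c")]] <- x - mean(x)
  }
  table
}

#' Fit a mixed-effects model with centred fixed effects
#'
#' Maximum-likelihood fit (lme4) of the specified family with a
#' participant random intercept, after centring every fixed-effect
#' predictor.  When `spec$maximal` is set, a by-participant random-slope
#' structure over the within-participant terms is attempted first and the
#' fit falls back to the intercept-only structure on non-convergence
#' (recorded in `converged`/`note`).  A likelihood-ratio test against the
#' matched null model (same random effects, intercept only) is always
#' computed.  Degenerate responses (constant column) are flagged rather
#' than fitted.
#'
#' @param table Data frame of trials.
#' @param spec A [model_spec()].
#' @return An object of class `model_summary`: a list with `coefficients`
#'   (data frame `term`, `beta`, `se`, `statistic`, `p`), `lrt` (list
#'   `chi_sq`, `df`, `p`), `n_obs`, `converged`, `note`, `family`, and the
#'   underlying `fit` and `null_fit` lme4 objects.
#' @export
fit_mixed_model <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$response %in% names(table)) {
    stop("response column not found: ", spec$response)
  }
  if (length(unique(table[[spec$group]])) < 2L) {
    stop("need at least 2 levels of '", spec$group, "'")
  }
  y <- table[[spec$response]]
  if (length(unique(y)) < 2L) {
    return(structure(list(coefficients = NULL, lrt = NULL,
                          n_obs = length(y), converged = FALSE,
                          note = "degenerate response (constant column)",
                          family = spec$family, fit = NULL, null_fit = NULL),
                     class = "model_summary"))
  }
  table <- center_predictors(table, spec)
  terms_c <- vapply(strsplit(spec$fixed_effects, ":", fixed = TRUE),
                    function(parts) paste(paste0(parts, "_c"), collapse = ":"),
                    "")
  rhs_fixed <- if (length(terms_c)) paste(terms_c, collapse = " + ") else "1"
  re_intercept <- paste0("(1 | ", spec$group, ")")
  fit_one <- function(rhs, re) {
    fml <- stats::as.formula(paste(spec$response, "~", rhs, "+", re))
    if (spec$family == "binomial") {
      lme4::glmer(fml, data = table, family = stats::binomial())
    } else {
      lme4::lmer(fml, data = table, REML = FALSE)
    }
  }
  note <- ""
  fit <- NULL
  if (spec$maximal && length(terms_c) > 0L) {
    slope_terms <- terms_c[!vapply(terms_c, function(tc) {
      base <- strsplit(tc, ":", fixed = TRUE)[[1]]
      # between-participant predictors get no by-participant slope
      any(vapply(base, function(b) {
        all(tapply(table[[b]], table[[spec$group]],
                   function(v) length(unique(v)) == 1L))
      }, logical(1)))
    }, logical(1))]
    if (length(slope_terms) > 0L) {
      re_max <- paste0("(1 + ", paste(slope_terms, collapse = " + "),
                       " | ", spec$group, ")")
      fit <- tryCatch(fit_one(rhs_fixed, re_max), error = function(e) NULL,
                      warning = function(w) NULL)
      if (is.null(fit) || !is_converged(fit)) {
        fit <- NULL
        note <- "maximal random-effect structure failed; intercept-only fallback"
      }
    }
  }
  if (is.null(fit)) fit <- fit_one(rhs_fixed, re_intercept)
  null_fit <- fit_one("1", re_intercept)
  co <- summary(fit)$coefficients
  coefficients <- data.frame(
    term = rownames(co),
    beta = co[, "Estimate"],
    se = co[, "Std. Error"],
    statistic = co[, 3L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (spec$family == "gaussian") {
    df_t <- spec$df_for_t %||% (stats::nobs(fit) - nrow(co))
    coefficients$p <- vapply(coefficients$statistic, t_to_p, numeric(1),
                             df = df_t)
  } else {
    coefficients$p <- 2 * stats::pnorm(-abs(coefficients$statistic))
  }
  lrt <- likelihood_ratio_test_fits(fit, null_fit)
  structure(list(coefficients = coefficients, lrt = lrt,
                 n_obs = stats::nobs(fit),
                 converged = is_converged(fit), note = note,
                 family = spec$family, fit = fit, null_fit = null_fit),
            class = "model_summary")
}

is_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs))
}

#' @export
print.model_summary <- function(x, ...) {
  cat("<model_summary>", x$family, "fit,", x$n_obs, "observations",
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (nzchar(x$note %||% "")) cat("note:", x$note, "\n")
  if (!is.null(x$coefficients)) {
    for (line in report_model(x)) cat(line, "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi_sq = 2 * (logLik(full) - logLik(null))`, with degrees of freedom
#' the difference in parameter counts and the p-value from the upper tail
#' of the chi-square distribution.
#'
#' @param full,null [fit_mixed_model()] summaries (or lme4 fits) on the
#'   same data, null nested in full.
#' @return List with `chi_sq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  f <- if (inherits(full, "model_summary")) full$fit else full
  n <- if (inherits(null, "model_summary")) null$fit else null
  likelihood_ratio_test_fits(f, n)
}

likelihood_ratio_test_fits <- function(full, null) {
  if (stats::nobs(full) != stats::nobs(null)) {
    stop("models were fitted to different numbers of observations")
  }
  ll_f <- stats::logLik(full)
  ll_n <- stats::logLik(null)
  df <- attr(ll_f, "df") - attr(ll_n, "df")
  if (df < 0L) stop("null model has more parameters than the full model")
  chi_sq <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_n)))
  list(chi_sq = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df = max(df, 1L), lower.tail = FALSE))
}

#' Convert a logit-scale coefficient to odds and probability
#'
#' `odds = exp(beta)` and `probability = plogis(beta)`; used to render
#' "x times as likely ... corresponding to an accuracy of y%" summaries
#' from fitted coefficients.
#'
#' @param beta Finite coefficient on the log-odds scale.
#' @return List with `odds` and `probability`.
#' @examples
#' logit_to_odds_prob(0.343)  # odds 1.41, probability 0.58
#' @export
logit_to_odds_prob <- function(beta) {
  stopifnot(is.finite(beta))
  list(odds = exp(beta), probability = stats::plogis(beta))
}

#' Two-sided p-value from a t statistic
#'
#' @param t The t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-sided tail probability.
#' @export
t_to_p <- function(t, df) {
  if (df < 1) stop("degrees of freedom must be >= 1")
  2 * stats::pt(-abs(t), df = df)
}

format_p <- function(p) {
  if (p < 0.001) "p <0.001" else sprintf("p = %.3f", p)
}

#' Render a fitted model as report sentences
#'
#' Produces the conventional reporting lines for a [fit_mixed_model()]
#' summary: the likelihood-ratio comparison against the null model, one
#' line per coefficient with beta, SE and p, and (for logistic fits) the
#' odds/accuracy rendering of each coefficient.  P-values below 0.001 are
#' printed as "<0.001"; exact values stay in the machine-readable summary.
#'
#' @param summary A `model_summary`.
#' @return Character vector of report lines.
#' @export
report_model <- function(summary) {
  stopifnot(inherits(summary, "model_summary"))
  if (is.null(summary$coefficients)) {
    return(paste("model not fitted:", summary$note))
  }
  lines <- sprintf("LRT vs null: chi-sq(%d) = %.3f, %s",
                   summary$lrt$df, summary$lrt$chi_sq, format_p(summary$lrt$p))
  for (i in seq_len(nrow(summary$coefficients))) {
    co <- summary$coefficients[i, ]
    line <- sprintf("%s: beta = %.3f, SE = %.3f, %s",
                    co$term, co$beta, co$se, format_p(co$p))
    if (summary$family == "binomial") {
      op <- logit_to_odds_prob(co$beta)
      line <- sprintf("%s (odds %.2f, accuracy %.0f%%)", line, op$odds,
                      100 * op$probability)
    }
    lines <- c(lines, line)
  }
  lines
}
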
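#  Overall-survival and response modeling: Kaplan-Meier estimation, log-rank
#  tests, crude 2-year survival rates, and univariate / multivariate-backward
#  Cox and logistic models with separation handling. Model fitting stands on
#  the survival package (Efron tie handling, Newton-Raphson partial
#  likelihood) and stats::glm; elimination, separation detection and
#  reporting are part of this module's contract.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator; at tied times events precede censorings. The
#' median is the first time at which the survival curve drops to 0.5 or
#' below (`NA` if it never does).
#'
#' @param times Non-negative follow-up times (days).
#' @param events 1 = death, 0 = censored.
#' @return A `km_fit` object; `tidy()` gives the step function
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `estimate`), `glance()` the
#'   median.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("empty input.")
  if (any(times < 0)) abort("times must be non-negative.")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1.")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(fit = fit, median = med, n = length(times),
                 n_events = sum(events)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n = ", x$n, ", events = ", x$n_events,
      ", median survival = ", ifelse(is.na(x$median), "not reached",
                                     paste(x$median, "days")), "\n", sep = "")
  invisible(x)
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                 n_censor = f$n.censor, estimate = f$surv,
                 std_error = f$std.err)
}

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, median_survival = x$median)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `km_fit`.
#' @param at Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities (S(0) = 1).
#' @export
km_survival_at <- function(km, at) {
  stopifnot(inherits(km, "km_fit"))
  st <- summary(km$fit, times = at, extend = TRUE)
  st$surv
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' df = number of groups - 1.
#'
#' @param times,events As in [km_estimate()].
#' @param group Group labels (2 or more nonempty groups).
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) == 0)) {
    abort("need at least 2 nonempty groups.")
  }
  if (sum(events) == 0) {
    warn("no events observed; p = 1.")
    return(tibble::tibble(chisq = 0, df = nlevels(group) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  tibble::tibble(chisq = sd$chisq, df = df,
                 p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Crude 2-year survival rate
#'
#' Numerator: patients with `survival_days >= cutoff` (alive at, or death
#' after, 2 years). Denominator: all patients in the group, including those
#' censored before the cutoff — a documented convention that can
#' underestimate the true rate (see `flag_censored_before_cutoff`).
#'
#' @param patients Tibble with `survival_days`, `event`.
#' @param group Optional grouping column name.
#' @param cutoff Days (default 730).
#' @return Tibble per group: `n_survivors`, `n_total`, `percent`,
#'   `flag_censored_before_cutoff` (count of denominator-only patients).
#' @export
two_year_survival <- function(patients, group = NULL, cutoff = 730) {
  df <- tibble::tibble(
    .surv = patients$survival_days >= cutoff,
    .cens_early = patients$survival_days < cutoff & patients$event == 0
  )
  if (!is.null(group)) df[[group]] <- patients[[group]]
  df |>
    dplyr::group_by(dplyr::across(dplyr::any_of(group))) |>
    dplyr::summarise(
      n_survivors = sum(.data$.surv),
      n_total = dplyr::n(),
      percent = 100 * sum(.data$.surv) / dplyr::n(),
      flag_censored_before_cutoff = sum(.data$.cens_early),
      .groups = "drop"
    )
}

# ---- model term preparation ------------------------------------------------

#  Cytogenetic risk enters models as poor = 1 vs intermediate = 0;
#  unevaluable patients are excluded from models containing the term.
prepare_terms <- function(data, terms) {
  if ("cyto_risk" %in% terms) {
    data <- data[data$cyto_risk %in% c("poor", "intermediate"), , drop = FALSE]
    data$cyto_risk <- as.integer(data$cyto_risk == "poor")
  }
  for (tm in terms) {
    if (is.logical(data[[tm]])) data[[tm]] <- as.integer(data[[tm]])
    if (is.character(data[[tm]]) || is.factor(data[[tm]])) {
      lv <- unique(as.character(data[[tm]]))
      if (length(lv) != 2) {
        abort(paste0("term `", tm, "` must be numeric or two-level."))
      }
      data[[tm]] <- as.integer(as.character(data[[tm]]) == sort(lv)[2])
    }
  }
  data
}

#  A binary predictor whose positive (or negative) level carries zero
#  outcome events produces a monotone likelihood; such terms are reported as
#  non-estimable rather than fitted.
#  For logistic models a level with zero events OR zero non-events
#  separates; for Cox only a level with zero events gives a monotone
#  partial likelihood (censoring is not an outcome class).
separated_terms <- function(data, terms, outcome, both_directions = TRUE) {
  vapply(terms, function(tm) {
    x <- data[[tm]]
    if (length(unique(x[!is.na(x)])) != 2) return(FALSE)
    any(vapply(unique(x[!is.na(x)]), function(v) {
      sum(outcome[x == v], na.rm = TRUE) == 0 ||
        (both_directions && sum(1 - outcome[x == v], na.rm = TRUE) == 0)
    }, logical(1)))
  }, logical(1))
}

model_report_row <- function(term, est, lo, hi, p, non_estimable = FALSE,
                             converged = TRUE) {
  tibble::tibble(term = term, estimate = est, conf.low = lo, conf.high = hi,
                 p = p, non_estimable = non_estimable, converged = converged)
}

backward_eliminate <- function(fit_fun, terms, stay_p = 0.05) {
  trace <- tibble::tibble(step = integer(), dropped = character(),
                          p_at_removal = numeric())
  step <- 0L
  current <- terms
  repeat {
    rep <- fit_fun(current)
    if (nrow(rep) == 0 || all(is.na(rep$p))) break
    worst <- which.max(replace(rep$p, is.na(rep$p), -Inf))
    if (rep$p[worst] >= stay_p && length(current) > 1) {
      step <- step + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, dropped = rep$term[worst], p_at_removal = rep$p[worst]))
      current <- setdiff(current, rep$term[worst])
    } else if (rep$p[worst] >= stay_p && length(current) == 1) {
      step <- step + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, dropped = rep$term[worst], p_at_removal = rep$p[worst]))
      current <- character(0)
      rep <- rep[0, ]
      break
    } else break
  }
  list(report = rep, trace = trace, terms = current)
}

#' Cox proportional-hazards regression for overall survival
#'
#' Partial-likelihood maximization with Efron tie handling (Newton-Raphson,
#' convergence tolerance 1e-9). `mode = "univariate"` fits each term alone;
#' `mode = "multivariate-backward"` starts from all terms and repeatedly
#' drops the largest-p term while any Wald p >= `stay_p`. Hazard ratios are
#' `exp(coef)` with Wald 95% CIs. Terms producing a monotone likelihood
#' (e.g. a binary group with no events) are flagged non-estimable.
#'
#' @param data Tibble with `survival_days`, `event` and the term columns.
#' @param terms Character vector of predictor columns.
#' @param mode `"univariate"` or `"multivariate-backward"`.
#' @param stay_p Backward-elimination stay threshold.
#' @param min_events Guard: minimum number of events for the multivariate
#'   mode.
#' @return A `surv_model` object (`tidy()`, `glance()`, elimination
#'   `$trace`).
#' @export
cox_regression <- function(data, terms,
                           mode = c("univariate", "multivariate-backward"),
                           stay_p = 0.05, min_events = 10) {
  mode <- match.arg(mode)
  data <- prepare_terms(data, terms)
  if (mode == "multivariate-backward" && sum(data$event) < min_events) {
    abort(paste0("multivariate mode requires at least ", min_events,
                 " events."))
  }
  sep <- separated_terms(data, terms, data$event, both_directions = FALSE)

  fit_terms <- function(tms) {
    tms <- tms[!sep[tms]]
    if (!length(tms)) return(model_report_row(character(0), numeric(0),
                                              numeric(0), numeric(0),
                                              numeric(0))[0, ])
    f <- stats::as.formula(paste("survival::Surv(survival_days, event) ~",
                                 paste(tms, collapse = " + ")))
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(f, data = data, ties = "efron",
                      control = survival::coxph.control(eps = 1e-9,
                                                        iter.max = 50)),
      warning = function(w) {
        if (grepl("converge|infinite", conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    s <- summary(fit)
    co <- s$coefficients
    model_report_row(rownames(co), exp(co[, "coef"]),
                     exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
                     exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
                     co[, "Pr(>|z|)"], converged = converged)
  }

  if (mode == "univariate") {
    report <- purrr::map_dfr(terms, function(tm) {
      if (sep[tm]) return(model_report_row(tm, NA, NA, NA, NA,
                                           non_estimable = TRUE))
      fit_terms(tm)
    })
    trace <- NULL
  } else {
    be <- backward_eliminate(fit_terms, terms[!sep], stay_p)
    report <- be$report
    if (any(sep)) {
      report <- dplyr::bind_rows(
        report, model_report_row(terms[sep], NA, NA, NA, NA,
                                 non_estimable = TRUE))
    }
    trace <- be$trace
  }
  structure(list(report = report, trace = trace, mode = mode,
                 effect = "hazard_ratio", n = nrow(data),
                 n_events = sum(data$event)),
            class = "surv_model")
}

#' Logistic regression for response
#'
#' Maximum-likelihood fit of a binary response (CR or composite CRc)
#' against clinical and molecular terms. Predictor levels with zero
#' responders (or zero non-responders) are detected as complete/quasi
#' separation and reported non-estimable rather than fitted; if every term
#' separates, a model-level non-estimable report is returned. Backward mode
#' as in [cox_regression()]. Odds ratios are `exp(coef)` with Wald CIs.
#'
#' @param data Tibble with `response` plus term columns.
#' @param outcome `"CR"` or `"CRc"`.
#' @param terms Character vector of predictor columns.
#' @param mode `"univariate"` or `"multivariate-backward"`.
#' @param stay_p Backward stay threshold.
#' @return A `surv_model` object with odds ratios.
#' @export
logistic_regression <- function(data, outcome = c("CRc", "CR"), terms,
                                mode = c("univariate",
                                         "multivariate-backward"),
                                stay_p = 0.05) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  data <- prepare_terms(data, terms)
  y <- if (outcome == "CRc") as.integer(data$response %in%
                                          c("CR", "CRp", "CRi"))
  else as.integer(data$response == "CR")
  if (length(unique(y)) < 2) abort("both outcome classes must be present.")
  data$.y <- y
  sep <- separated_terms(data, terms, y)
  if (all(sep)) {
    report <- model_report_row(terms, NA, NA, NA, NA, non_estimable = TRUE)
    return(structure(list(report = report, trace = NULL, mode = mode,
                          effect = "odds_ratio", n = nrow(data),
                          n_events = sum(y)),
                     class = "surv_model"))
  }

  fit_terms <- function(tms) {
    tms <- tms[!sep[tms]]
    if (!length(tms)) return(model_report_row(character(0), numeric(0),
                                              numeric(0), numeric(0),
                                              numeric(0))[0, ])
    f <- stats::as.formula(paste(".y ~", paste(tms, collapse = " + ")))
    fit <- glm(f, data = data, family = binomial())
    co <- summary(fit)$coefficients
    co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
    model_report_row(rownames(co), exp(co[, "Estimate"]),
                     exp(co[, "Estimate"] - qnorm(0.975) * co[, "Std. Error"]),
                     exp(co[, "Estimate"] + qnorm(0.975) * co[, "Std. Error"]),
                     co[, "Pr(>|z|)"], converged = fit$converged)
  }

  if (mode == "univariate") {
    report <- purrr::map_dfr(terms, function(tm) {
      if (sep[tm]) return(model_report_row(tm, NA, NA, NA, NA,
                                           non_estimable = TRUE))
      fit_terms(tm)
    })
    trace <- NULL
  } else {
    be <- backward_eliminate(fit_terms, terms[!sep], stay_p)
    report <- be$report
    if (any(sep)) {
      report <- dplyr::bind_rows(
        report, model_report_row(terms[sep], NA, NA, NA, NA,
                                 non_estimable = TRUE))
    }
    trace <- be$trace
  }
  structure(list(report = report, trace = trace, mode = mode,
                 effect = "odds_ratio", n = nrow(data), n_events = sum(y)),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat("<surv_model> ", x$mode, " (", x$effect, "), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(as.data.frame(x$report))
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("elimination trace:\n")
    print(as.data.frame(x$trace))
  }
  invisible(x)
}

#' @method tidy surv_model
#' @export
tidy.surv_model <- function(x, ...) x$report

#' @method glance surv_model
#' @export
glance.surv_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, effect = x$effect, n = x$n,
                 n_events = x$n_events,
                 n_terms = nrow(x$report),
                 n_non_estimable = sum(x$report$non_estimable))
}

#' Read a clinical CSV
#'
#' @param path CSV with the patient-record columns produced by
#'   [write_cohort()].
#' @return Tibble.
#' @export
read_clinical <- function(path) readr::read_csv(path, show_col_types = FALSE)
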
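#' Define an association model template
#'
#' The model is written once with the literal placeholder `term` standing in
#' for the genetic variable, e.g. `disease ~ term + sex + term:sex`; the
#' engine substitutes each tested variable for the placeholder. For Cox
#' models the left-hand side is a `survival::Surv(time, event)` outcome.
#'
#' @param formula Model formula containing the placeholder `term`.
#' @param family `"linear"`, `"logistic"` or `"cox"`.
#' @param conf_level Confidence level for reported intervals.
#' @return An `hla_model` list.
#' @examples
#' hla_model(disease ~ term + sex, family = "logistic")
#' @export
hla_model <- function(formula, family = c("linear", "logistic", "cox"),
                      conf_level = 0.95) {
  family <- match.arg(family)
  stopifnot(inherits(formula, "formula"))
  if (!"term" %in% all.vars(formula)) {
    stop("model formula must contain the placeholder variable 'term'",
         call. = FALSE)
  }
  structure(list(formula = formula, family = family,
                 conf_level = conf_level),
            class = "hla_model")
}

#' @export
print.hla_model <- function(x, ...) {
  cat("<hla_model> ", x$family, ": ", deparse(x$formula), "\n", sep = "")
  invisible(x)
}

fit_family <- function(formula, data, family) {
  switch(family,
         linear = stats::lm(formula, data = data),
         logistic = stats::glm(formula, data = data,
                               family = stats::binomial()),
         cox = survival::coxph(formula, data = data, ties = "efron"))
}

model_loglik_rank <- function(fit) {
  if (inherits(fit, "coxph")) {
    list(ll = as.numeric(stats::logLik(fit)),
         rank = sum(!is.na(stats::coef(fit))))
  } else {
    list(ll = as.numeric(stats::logLik(fit)), rank = fit$rank)
  }
}

# Fit one substituted model and extract the placeholder coefficient.
fit_one_term <- function(data, model) {
  empty <- list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_, n = NA_integer_,
                note = NA_character_)
  fit <- tryCatch(
    withCallingHandlers(
      fit_family(model$formula, data, model$family),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    empty$note <- paste0("fit error: ", conditionMessage(fit))
    return(empty)
  }
  co <- if (model$family == "cox") {
    s <- summary(fit)$coefficients
    if (!"term" %in% rownames(s)) NULL else
      c(s["term", "coef"], s["term", "se(coef)"], s["term", "Pr(>|z|)"])
  } else {
    s <- summary(fit)$coefficients
    if (!"term" %in% rownames(s)) NULL else
      c(s["term", 1], s["term", 2], s["term", 4])
  }
  if (is.null(co) || anyNA(co[1:2])) {
    empty$note <- "term aliased (collinear with covariates)"
    return(empty)
  }
  converged <- if (model$family == "logistic") fit$converged else TRUE
  q <- if (model$family == "linear") {
    stats::qt(1 - (1 - model$conf_level) / 2, stats::df.residual(fit))
  } else {
    stats::qnorm(1 - (1 - model$conf_level) / 2)
  }
  n <- if (model$family == "cox") fit$n else stats::nobs(fit)
  list(estimate = co[1], se = co[2], p = co[3],
       ci_lo = co[1] - q * co[2], ci_hi = co[1] + q * co[2],
       n = as.integer(n),
       note = if (converged) NA_character_ else "did not converge")
}

#' Run a per-variable association scan
#'
#' Iteratively substitutes every variable of an experiment for the model
#' placeholder, fits the model, and collects the placeholder's estimate
#' (beta, log-OR or log-HR), standard error, confidence interval and
#' p-value, with multiple-testing correction across the scanned variables.
#' Non-converging or aliased fits appear as flagged missing-statistic rows
#' rather than being dropped.
#'
#' @param ds An [hla_dataset()].
#' @param model An [hla_model()].
#' @param experiment Name of the experiment to scan.
#' @param inheritance Inheritance model for copy-count variables
#'   (`"additive"`, `"dominant"`, `"recessive"`, `"overdominant"`); binary
#'   and continuous variables are used as-is and accept only the encodings
#'   listed in their metadata.
#' @param correction Multiple-testing method, see [adjust_pvalues()].
#' @param lower_frequency,upper_frequency Frequency window passed to
#'   [frequency_filter()].
#' @param hwe_alpha When non-`NULL`, variables failing the chi-square HWE
#'   test at this threshold are removed before the scan.
#' @param condition_on Variable names (from the same experiment) added to
#'   every fit as covariates; used by [conditional_search()].
#' @param exclude Variable names to leave out of the scan.
#' @return An `hla_assoc` tibble, one row per variable, sorted by corrected
#'   then nominal p-value.
#' @export
run_association <- function(ds, model, experiment,
                            inheritance = "additive",
                            correction = "BH",
                            lower_frequency = 0, upper_frequency = 1,
                            hwe_alpha = NULL,
                            condition_on = character(),
                            exclude = character()) {
  exp <- get_experiment(ds, experiment)
  if (!is.null(hwe_alpha)) {
    exp <- hwe_test(exp, mode = "filter", alpha = hwe_alpha)
  }
  exp <- frequency_filter(exp, lower_frequency, upper_frequency)
  meta <- var_meta(exp)
  vars <- setdiff(experiment_variables(exp), c(exclude, condition_on))
  if (!length(vars)) {
    stop("no variable left to test in experiment '", experiment,
         "' (", nrow(var_meta(get_experiment(ds, experiment))),
         " before filtering)", call. = FALSE)
  }
  check_inheritance(meta[meta$variable %in% vars, ], inheritance)

  base <- ds$pheno
  cond_formula <- model$formula
  if (length(condition_on)) {
    for (v in condition_on) {
      base[[v]] <- encode_for_model(exp, meta, v, inheritance)
    }
    # conditioned variables are placed before the placeholder terms so that
    # a candidate collinear with an earlier selection is the column the fit
    # aliases, not the conditioning covariate
    labels <- attr(stats::terms(model$formula), "term.labels")
    term_labels <- grep("\\bterm\\b", labels, value = TRUE)
    rhs <- c(setdiff(labels, term_labels), paste0("`", condition_on, "`"),
             term_labels)
    cond_formula <- stats::as.formula(
      paste(deparse_formula(model$formula[[2]]), "~",
            paste(rhs, collapse = " + ")),
      env = environment(model$formula)
    )
  }
  fit_model <- model
  fit_model$formula <- cond_formula

  freqs <- experiment_frequencies(exp)
  rows <- lapply(vars, function(v) {
    data <- base
    data$term <- encode_for_model(exp, meta, v, inheritance)
    r <- fit_one_term(data, fit_model)
    type <- meta$type[meta$variable == v]
    tibble::tibble(
      variable = v,
      model = if (type == "count") inheritance else "asis",
      estimate = r$estimate, se = r$se,
      ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
      freq = freqs$frequency[freqs$variable == v],
      count = if (type == "continuous") NA_integer_ else
        sum(exp[[v]] >= 1, na.rm = TRUE),
      group = meta$group[meta$variable == v],
      n = r$n, note = r$note
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p, correction)
  out <- out[order(out$p_adj, out$p, out$variable), ]
  out <- out[c("variable", "model", "estimate", "se", "ci_lo", "ci_hi",
               "p", "p_adj", "freq", "count", "group", "n", "note")]
  new_hla_assoc(out, family = model$family, experiment = experiment,
                correction = correction, conf_level = model$conf_level,
                covariates = setdiff(all.vars(cond_formula), "term"))
}

encode_for_model <- function(exp, meta, v, inheritance) {
  type <- meta$type[meta$variable == v]
  if (type == "count") encode_inheritance(exp[[v]], inheritance)
  else exp[[v]]
}

check_inheritance <- function(meta, inheritance) {
  ok <- vapply(strsplit(meta$models, ","), function(m)
    inheritance %in% trimws(m), TRUE)
  # binary/continuous variables enter the model as-is under any requested
  # encoding that is listed for them; anything else is an applicability error
  bad <- meta$variable[!ok & meta$type != "count"]
  if (length(bad)) {
    stop("inheritance model '", inheritance, "' not applicable to: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

deparse_formula <- function(f) paste(deparse(f), collapse = " ")

new_hla_assoc <- function(tbl, ...) {
  structure(tbl, class = c("hla_assoc", class(tibble::as_tibble(tbl))),
            meta = list(...))
}

#' @export
print.hla_assoc <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<hla_assoc> ", m$family, " scan of '", m$experiment, "', ",
      nrow(x), " variables, correction ", m$correction, "\n", sep = "")
  NextMethod()
}

#' Tidy an association result
#'
#' The result is already tabular; `tidy()` returns it as a plain tibble so
#' it composes with broom-style pipelines.
#'
#' @param x An `hla_assoc`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hla_assoc
#' @export
tidy.hla_assoc <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "meta") <- NULL
  attr(out, "selected") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' Summarise an association scan
#'
#' @param x An `hla_assoc`.
#' @param alpha Significance threshold on corrected p-values.
#' @param ... Unused.
#' @return One-row tibble: numbers of variables tested, significant hits,
#'   failed fits, and the smallest corrected p.
#' @method glance hla_assoc
#' @export
glance.hla_assoc <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_significant = sum(!is.na(x$p_adj) & x$p_adj < alpha),
    n_failed = sum(!is.na(x$note)),
    min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE))
  )
}

#' Effect-estimate plot of an association scan
#'
#' Forest-style plot of the top associated variables: point estimate with
#' confidence interval, ordered by corrected p-value.
#'
#' @param object An `hla_assoc`.
#' @param top Number of variables to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hla_assoc
#' @export
autoplot.hla_assoc <- function(object, top = 20, ...) {
  m <- attr(object, "meta")
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$estimate), ]
  d <- utils::head(d[order(d$p_adj, d$p), ], top)
  xlab <- switch(m$family, logistic = "log odds ratio",
                 cox = "log hazard ratio", "effect estimate")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$variable, -.data$p_adj))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = NULL, title = m$experiment) +
    ggplot2::theme_minimal()
}
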
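#' Genetic inheritance encodings
#'
#' Recodes a 0/1/2 copy-count vector into the design variable of a genetic
#' inheritance model: `additive` keeps the copy number, `dominant` indicates
#' carrying at least one copy, `recessive` indicates two copies, and
#' `overdominant` indicates exactly one copy (heterozygote advantage).
#'
#' @param x Numeric vector of copy counts (0/1/2); `NA` propagates.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"overdominant"`.
#' @return Numeric design vector.
#' @export
encode_inheritance <- function(x, model = c("additive", "dominant",
                                            "recessive", "overdominant")) {
  model <- match.arg(model)
  switch(model,
         additive = x,
         dominant = as.numeric(x >= 1),
         recessive = as.numeric(x == 2),
         overdominant = as.numeric(x == 1))
}

#' Frequency filtering of experiment variables
#'
#' Keeps variables whose population frequency lies in `[lower, upper]`:
#' allele frequency (copies over 2n) for copy-count variables, carrier
#' frequency for binary ones. Continuous variables are exempt and always
#' kept. Rare-variable exclusion protects downstream model fits from
#' separation and power loss.
#'
#' @param experiment An [hla_experiment()].
#' @param lower,upper Frequency bounds, proportions in `[0, 1]`.
#' @param by `"auto"` (per-variable type, the default), or force
#'   `"allele"`/`"carrier"` frequency for count variables.
#' @return The filtered experiment.
#' @export
frequency_filter <- function(experiment, lower = 0, upper = 1,
                             by = c("auto", "allele", "carrier")) {
  by <- match.arg(by)
  stopifnot(lower >= 0, upper <= 1, lower <= upper)
  f <- experiment_frequencies(experiment, by = by)
  keep <- is.na(f$frequency) | (f$frequency >= lower & f$frequency <= upper)
  subset_experiment(experiment, f$variable[keep])
}

# Current frequencies of an experiment's variables (recomputed from the
# values, so they reflect any subsetting done since construction).
experiment_frequencies <- function(experiment, by = "auto") {
  meta <- var_meta(experiment)
  freq <- vapply(meta$variable, function(v) {
    type <- meta$type[meta$variable == v]
    if (by == "carrier" && type == "count") type <- "binary"
    if (by == "allele" && type == "binary") type <- "binary"
    variable_frequency(experiment[[v]], type)
  }, 0)
  tibble::tibble(variable = meta$variable, frequency = unname(freq))
}

#' Multiple-testing correction
#'
#' Thin validated wrapper around [stats::p.adjust()] for the correction
#' methods exposed by the association engine.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"holm"`, `"BH"`, `"BY"` or `"none"`.
#' @return Corrected p-values, capped at 1; `NA` entries propagate and do
#'   not count towards the number of tests.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm", "BY",
                                         "none")) {
  if (!is.character(method) || !method[1] %in% c("BH", "bonferroni", "holm",
                                                 "BY", "none")) {
    stop("unknown correction method: ", method[1], call. = FALSE)
  }
  method <- match.arg(method)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = method)
}

#' Compare dataset frequencies with a reference table
#'
#' Joins the experiment's variable frequencies against a locally supplied
#' reference table of published population frequencies and reports the
#' difference per population. Variables absent from the reference are kept
#' and flagged.
#'
#' @param experiment An [hla_experiment()].
#' @param reference A data frame with a `variable` column and one numeric
#'   column per reference population.
#' @return A long tibble: `variable`, `frequency` (dataset), `population`,
#'   `reference_frequency`, `difference`, `flagged` (no reference entry).
#' @export
compare_frequencies <- function(experiment, reference) {
  stopifnot("variable" %in% names(reference))
  freq <- experiment_frequencies(experiment)
  pops <- setdiff(names(reference), "variable")
  long <- tidyr::pivot_longer(tibble::as_tibble(reference), -"variable",
                              names_to = "population",
                              values_to = "reference_frequency")
  out <- tidyr::crossing(freq, population = pops)
  out <- dplyr::left_join(out, long, by = c("variable", "population"))
  out$difference <- out$frequency - out$reference_frequency
  out$flagged <- is.na(out$reference_frequency)
  dplyr::arrange(out, .data$variable, .data$population)
}
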
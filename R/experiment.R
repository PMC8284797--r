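#' Experiment tables
#'
#' An experiment is a tibble of association variables, one row per individual
#' (`ID` column) and one column per variable, carrying per-variable metadata
#' as an attribute: the omnibus group label (e.g. the amino-acid position a
#' residue variable belongs to), the genetic inheritance models applicable to
#' the variable, and its population frequency in the dataset. Values are
#' integer copy numbers (0/1/2), binary indicators (0/1) or continuous
#' scores, depending on the transform that produced the experiment.
#'
#' @param values A data frame: `ID` plus one numeric column per variable.
#' @param name Experiment label (e.g. `"hla_alleles"`, `"hla_aa"`).
#' @param var_meta A tibble with columns `variable`, `group`, `models`
#'   (comma-separated applicable inheritance models), `frequency` and
#'   `type` (`"count"`, `"binary"` or `"continuous"`). Missing columns are
#'   filled with defaults.
#' @return An `hla_experiment` tibble.
#' @export
hla_experiment <- function(values, name, var_meta = NULL) {
  values <- tibble::as_tibble(values)
  stopifnot("ID" %in% names(values))
  vars <- setdiff(names(values), "ID")
  if (anyDuplicated(vars)) {
    stop("duplicate variable names within experiment '", name, "'",
         call. = FALSE)
  }
  if (is.null(var_meta)) var_meta <- tibble::tibble(variable = vars)
  var_meta <- tibble::as_tibble(var_meta)
  if (!"group" %in% names(var_meta)) var_meta$group <- NA_character_
  if (!"models" %in% names(var_meta)) var_meta$models <- "additive"
  if (!"type" %in% names(var_meta)) var_meta$type <- "count"
  if (!"frequency" %in% names(var_meta)) {
    var_meta$frequency <- NA_real_
  }
  var_meta <- var_meta[match(vars, var_meta$variable), ]
  var_meta$variable <- vars
  var_meta$models[is.na(var_meta$models)] <- "additive"
  var_meta$type[is.na(var_meta$type)] <- "count"
  var_meta$frequency <- ifelse(
    is.na(var_meta$frequency),
    vapply(vars, function(v) {
      variable_frequency(values[[v]], var_meta$type[match(v, var_meta$variable)])
    }, 0),
    var_meta$frequency
  )
  structure(values,
            exp_name = name,
            var_meta = var_meta,
            class = c("hla_experiment", class(values)))
}

# Allele frequency for copy-count variables (copies / 2n), carrier frequency
# for binary ones; continuous variables have no defined frequency.
variable_frequency <- function(x, type) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  switch(type,
         count = sum(x) / (2 * length(x)),
         binary = mean(x >= 1),
         continuous = NA_real_,
         NA_real_)
}

#' @export
print.hla_experiment <- function(x, ...) {
  cat("<hla_experiment> '", attr(x, "exp_name"), "': ",
      nrow(x), " individuals x ", ncol(x) - 1L, " variables\n", sep = "")
  NextMethod()
}

#' Experiment variable metadata
#'
#' @param x An `hla_experiment`.
#' @return The `var_meta` tibble (`variable`, `group`, `models`, `type`,
#'   `frequency`).
#' @export
var_meta <- function(x) {
  attr(x, "var_meta")
}

#' Experiment name
#' @param x An `hla_experiment`.
#' @return The experiment's label.
#' @export
experiment_name <- function(x) attr(x, "exp_name")

experiment_variables <- function(x) setdiff(names(x), "ID")

# Subset an experiment to a set of variables, keeping metadata in step.
subset_experiment <- function(x, variables) {
  out <- dplyr::select(tibble::as_tibble(x), "ID",
                       dplyr::all_of(variables))
  meta <- var_meta(x)
  hla_experiment(out, attr(x, "exp_name"),
                 meta[meta$variable %in% variables, ])
}

#' Tidy an experiment into long format
#'
#' @param x An `hla_experiment`.
#' @param ... Unused.
#' @return A long tibble (`ID`, `variable`, `value`) joined with the
#'   per-variable metadata.
#' @method tidy hla_experiment
#' @export
tidy.hla_experiment <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"ID",
                              names_to = "variable", values_to = "value")
  dplyr::left_join(long, var_meta(x), by = "variable")
}

#' Summarise an experiment
#'
#' @param x An `hla_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: experiment name, numbers of individuals and
#'   variables, and the proportion of missing cells.
#' @method glance hla_experiment
#' @export
glance.hla_experiment <- function(x, ...) {
  vals <- as.matrix(tibble::as_tibble(x)[experiment_variables(x)])
  tibble::tibble(
    experiment = attr(x, "exp_name"),
    n_individuals = nrow(x),
    n_variables = ncol(vals),
    prop_missing = mean(is.na(vals))
  )
}

#' Variable frequency bar plot
#'
#' @param object An `hla_experiment`.
#' @param top Number of most frequent variables to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hla_experiment
#' @export
autoplot.hla_experiment <- function(object, top = 20, ...) {
  meta <- var_meta(object)
  meta <- meta[!is.na(meta$frequency), ]
  meta <- utils::head(meta[order(-meta$frequency), ], top)
  ggplot2::ggplot(meta, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$frequency),
    y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "frequency",
                  title = attr(object, "exp_name")) +
    ggplot2::theme_minimal()
}
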
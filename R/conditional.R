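#' Stepwise conditional association search
#'
#' Identifies statistically independent association signals by forward
#' selection: in each round the whole experiment is re-scanned with all
#' previously selected variables added to the model as covariates, and the
#' variable with the smallest corrected p-value is selected if it passes the
#' threshold (ties broken by variable name). The search stops when no
#' variable passes, when `max_rounds` is reached, or when no testable
#' variable remains. A would-be selection whose fit is aliased against the
#' already-selected covariates is skipped with a warning and the next-best
#' candidate considered. Corrected p-values are recomputed within each
#' round.
#'
#' @inheritParams run_association
#' @param threshold Corrected p-value selection cutoff, in `(0, 1)`;
#'   a threshold of 0 selects nothing.
#' @param max_rounds Maximum number of selection rounds.
#' @return An `hla_assoc` tibble with a `round` column stacking every
#'   round's full table; the selected variables, in selection order, are in
#'   `attr(x, "selected")` (also shown by [conditional_selection()]).
#' @export
conditional_search <- function(ds, model, experiment,
                               threshold = 0.05,
                               inheritance = "additive",
                               correction = "bonferroni",
                               max_rounds = 10,
                               lower_frequency = 0, upper_frequency = 1) {
  stopifnot(threshold >= 0, threshold < 1)
  selected <- character()
  tables <- list()
  for (r in seq_len(max_rounds)) {
    res <- run_association(ds, model, experiment,
                           inheritance = inheritance,
                           correction = correction,
                           lower_frequency = lower_frequency,
                           upper_frequency = upper_frequency,
                           condition_on = selected)
    tbl <- tibble::as_tibble(res)
    tbl$round <- r
    tables[[r]] <- tbl
    aliased <- !is.na(tbl$note) & startsWith(tbl$note, "term aliased")
    if (length(selected) && any(aliased)) {
      warning("candidate(s) collinear with earlier selections skipped: ",
              paste(tbl$variable[aliased], collapse = ", "),
              call. = FALSE)
    }
    cand <- tbl[!aliased & !is.na(tbl$p_adj) & tbl$p_adj < threshold, ]
    cand <- cand[order(cand$p_adj, cand$p, cand$variable), ]
    if (!nrow(cand)) break
    selected <- c(selected, cand$variable[1])
  }
  out <- dplyr::bind_rows(tables)
  res <- new_hla_assoc(out, family = model$family, experiment = experiment,
                       correction = correction,
                       conf_level = model$conf_level,
                       threshold = threshold)
  attr(res, "selected") <- selected
  res
}

#' Selected variables of a conditional search
#'
#' @param x The result of [conditional_search()].
#' @return Character vector of selected variable names, in round order.
#' @export
conditional_selection <- function(x) {
  attr(x, "selected") %||% character()
}
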
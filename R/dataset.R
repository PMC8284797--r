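#' Assemble experiments and phenotypes into a dataset
#'
#' Combines a phenotype/covariate table with one or more experiments into a
#' single analysis object. Individuals are matched by `ID` with an inner
#' join (dropped individuals are counted in a message); variable names must
#' be unique across all experiments and distinct from phenotype column
#' names. Optionally carries the raw calls and alignments so residue-level
#' results can be mapped back to alleles with [alleles_for_aa()].
#'
#' @param pheno A data frame: `ID`, outcome column(s) and covariates.
#' @param experiments A named list of [hla_experiment()] objects (names
#'   default to each experiment's own label).
#' @param calls Optional calls table, kept for allele back-mapping.
#' @param alignments Optional named alignment list, kept for back-mapping.
#' @return An `hla_dataset`.
#' @export
hla_dataset <- function(pheno, experiments, calls = NULL,
                        alignments = NULL) {
  stopifnot("ID" %in% names(pheno))
  pheno <- tibble::as_tibble(pheno)
  if (inherits(experiments, "hla_experiment")) {
    experiments <- list(experiments)
  }
  nms <- names(experiments) %||% rep("", length(experiments))
  nms[nms == ""] <- vapply(experiments[nms == ""], experiment_name, "")
  names(experiments) <- nms

  all_vars <- unlist(lapply(experiments, experiment_variables))
  dup <- unique(all_vars[duplicated(all_vars)])
  if (length(dup)) {
    stop("variable name(s) appear in more than one experiment: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  clash <- intersect(all_vars, names(pheno))
  if (length(clash)) {
    stop("variable name(s) clash with phenotype columns: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }

  ids <- Reduce(intersect, c(list(pheno$ID),
                             lapply(experiments, function(e) e$ID)))
  n_dropped <- length(unique(c(pheno$ID,
                               unlist(lapply(experiments,
                                             function(e) e$ID))))) -
    length(ids)
  if (n_dropped > 0) {
    message(n_dropped, " individual(s) absent from some table dropped")
  }
  pheno <- pheno[match(ids, pheno$ID), ]
  experiments <- lapply(experiments, function(e) {
    hla_experiment(tibble::as_tibble(e)[match(ids, e$ID), ],
                   attr(e, "exp_name"), var_meta(e))
  })
  structure(
    list(pheno = pheno, experiments = experiments, calls = calls,
         alignments = alignments),
    class = "hla_dataset"
  )
}

#' @export
print.hla_dataset <- function(x, ...) {
  cat("<hla_dataset> ", nrow(x$pheno), " individuals; experiments: ",
      paste(vapply(x$experiments, function(e)
        paste0(attr(e, "exp_name"), " (", ncol(e) - 1L, ")"), ""),
        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarise a dataset
#'
#' @param x An `hla_dataset`.
#' @param ... Unused.
#' @return One row per experiment with individual/variable counts.
#' @method glance hla_dataset
#' @export
glance.hla_dataset <- function(x, ...) {
  dplyr::bind_rows(lapply(x$experiments, glance))
}

get_experiment <- function(ds, experiment) {
  if (!experiment %in% names(ds$experiments)) {
    stop("experiment not found in dataset: ", experiment,
         " (available: ", paste(names(ds$experiments), collapse = ", "), ")",
         call. = FALSE)
  }
  ds$experiments[[experiment]]
}
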
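#' Omnibus likelihood-ratio tests over grouped variables
#'
#' Tests each variable group of an experiment (typically the residues of one
#' amino-acid position, grouped as `<GENE>_<position>`) jointly: the full
#' model contains the covariates plus all of the group's variables except a
#' reference level (the most frequent one, for stable conditioning; aliased
#' columns are dropped by the fit), the null model contains the covariates
#' only, and the statistic is `2 * (logLik_full - logLik_null)` on a
#' chi-square with the rank difference as degrees of freedom. Groups that
#' degenerate to a single non-reference level reduce to a 1-df test and are
#' flagged. Placeholder-containing terms of the template are replaced by the
#' group's variables as main effects.
#'
#' @param ds An [hla_dataset()].
#' @param model An [hla_model()].
#' @param experiment Name of an experiment whose variables carry omnibus
#'   group metadata (e.g. `"hla_aa"`).
#' @param correction Multiple-testing method applied across groups.
#' @param lower_frequency,upper_frequency Frequency window applied to the
#'   variables before grouping.
#' @return An `hla_omnibus` tibble: `group`, `df`, `statistic`, `p`,
#'   `p_adj`, `variables` (comma-separated, reference first), `note`;
#'   sorted by corrected then nominal p.
#' @export
omnibus_test <- function(ds, model, experiment, correction = "BH",
                         lower_frequency = 0, upper_frequency = 1) {
  exp <- get_experiment(ds, experiment)
  exp <- frequency_filter(exp, lower_frequency, upper_frequency)
  meta <- var_meta(exp)
  if (all(is.na(meta$group))) {
    stop("experiment '", experiment, "' has no omnibus group metadata",
         call. = FALSE)
  }
  freqs <- experiment_frequencies(exp)
  groups <- split(meta$variable[!is.na(meta$group)],
                  meta$group[!is.na(meta$group)])

  lhs <- deparse_formula(model$formula[[2]])
  covars <- setdiff(attr(stats::terms(model$formula), "term.labels"),
                    grep("\\bterm\\b",
                         attr(stats::terms(model$formula), "term.labels"),
                         value = TRUE))
  null_rhs <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  null_formula <- stats::as.formula(paste(lhs, "~", null_rhs),
                                    env = environment(model$formula))

  rows <- lapply(names(groups), function(g) {
    vars <- groups[[g]]
    f <- freqs$frequency[match(vars, freqs$variable)]
    ref <- vars[order(-f, vars)][1]
    test_vars <- setdiff(vars, ref)
    note <- NA_character_
    if (!length(test_vars)) {
      return(tibble::tibble(group = g, df = 0L, statistic = 0,
                            p = 1, variables = ref,
                            note = "single level, no test possible"))
    }
    if (length(test_vars) == 1) note <- "single non-reference level"
    data <- ds$pheno
    for (v in test_vars) data[[v]] <- exp[[v]]
    used <- unique(c(all.vars(null_formula), test_vars))
    data <- data[stats::complete.cases(data[intersect(used,
                                                      names(data))]), ]
    full_formula <- stats::as.formula(
      paste(lhs, "~", null_rhs, "+",
            paste0("`", test_vars, "`", collapse = " + ")),
      env = environment(model$formula)
    )
    r <- tryCatch({
      null_fit <- fit_family(null_formula, data, model$family)
      full_fit <- fit_family(full_formula, data, model$family)
      a <- model_loglik_rank(full_fit)
      b <- model_loglik_rank(null_fit)
      list(stat = max(0, 2 * (a$ll - b$ll)), df = a$rank - b$rank)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      return(tibble::tibble(group = g, df = NA_integer_,
                            statistic = NA_real_, p = NA_real_,
                            variables = paste(c(ref, test_vars),
                                              collapse = ","),
                            note = paste0("fit error: ",
                                          conditionMessage(r))))
    }
    p <- if (r$df <= 0) 1 else
      stats::pchisq(r$stat, df = r$df, lower.tail = FALSE)
    tibble::tibble(group = g, df = as.integer(max(r$df, 0)),
                   statistic = r$stat, p = p,
                   variables = paste(c(ref, test_vars), collapse = ","),
                   note = note)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p, correction)
  out <- out[order(out$p_adj, out$p, out$group),
             c("group", "df", "statistic", "p", "p_adj", "variables",
               "note")]
  structure(out, class = c("hla_omnibus", class(tibble::tibble())),
            meta = list(family = model$family, experiment = experiment,
                        correction = correction))
}

#' @export
print.hla_omnibus <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<hla_omnibus> ", m$family, " LRTs over '", m$experiment, "', ",
      nrow(x), " groups, correction ", m$correction, "\n", sep = "")
  NextMethod()
}

#' Map residues at an amino-acid position back to alleles
#'
#' Partitions the alleles observed in the dataset at one gene by their
#' residue at a position, so a residue-level association can be read as a
#' set of classical alleles. Alleles whose residue is unknown are listed
#' under the `unknown` bucket.
#'
#' @param ds An [hla_dataset()] built with `calls` and `alignments`.
#' @param gene Locus symbol, e.g. `"DQB1"`.
#' @param position Integer mature-protein position; must be variable in the
#'   dataset (i.e. expanded by [hla_aa_counts()] when an `hla_aa`
#'   experiment is present).
#' @return A tibble (`residue`, `allele`, `frequency`): each observed
#'   allele in exactly one residue bucket, with its allele frequency in the
#'   dataset.
#' @export
alleles_for_aa <- function(ds, gene, position) {
  if (is.null(ds$calls) || is.null(ds$alignments[[gene]])) {
    stop("dataset was not assembled with calls and an alignment for gene ",
         gene, call. = FALSE)
  }
  if ("hla_aa" %in% names(ds$experiments)) {
    groups <- var_meta(ds$experiments[["hla_aa"]])$group
    if (!paste0(gene, "_", position) %in% groups) {
      stop("position ", position, " is not variable at ", gene,
           " in this dataset", call. = FALSE)
    }
  }
  aln <- ds$alignments[[gene]]
  calls <- ds$calls[ds$calls$ID %in% ds$pheno$ID, ]
  obs <- c(calls[[paste0(gene, "_1")]], calls[[paste0(gene, "_2")]])
  obs <- obs[!is.na(obs)]
  alleles <- sort(unique(obs))
  if (!length(alleles)) stop("no observed allele at gene ", gene,
                             call. = FALSE)
  res <- residues_at(aln, alleles, position)[, 1]
  res <- ifelse(res == ALN_UNKNOWN, "unknown", residue_label(res))
  freq <- as.numeric(table(obs)[alleles]) / length(obs)
  out <- tibble::tibble(residue = res, allele = alleles, frequency = freq)
  dplyr::arrange(out, .data$residue, dplyr::desc(.data$frequency))
}
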
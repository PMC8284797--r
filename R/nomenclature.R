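#' Parse HLA allele names
#'
#' Splits allele strings written in official HLA nomenclature
#' (`GENE*ff:ff[:ff[:ff]][S]`, e.g. `"A*02:01:01:01"`) into their components:
#' locus symbol, one to four numeric fields of at least two digits each, and an
#' optional expression suffix (`N`, `L`, `S`, `C`, `A` or `Q`).
#'
#' @param x Character vector of allele names. `NA` entries stay `NA`.
#' @return A tibble with one row per input: `allele` (the input string),
#'   `gene`, `fields` (list column of character field vectors), `n_fields`,
#'   and `suffix` (`""` when absent). Rendering the components back with
#'   [render_allele()] reproduces the input exactly.
#' @seealso [reduce_allele()], [validate_hla_calls()]
#' @examples
#' parse_allele(c("A*02:01:01:01", "DQB1*03:01", "B*39:01:01:02N"))
#' @export
parse_allele <- function(x) {
  stopifnot(is.character(x))
  parsed <- parse_allele_quietly(x)
  bad <- !is.na(x) & is.na(parsed$gene)
  if (any(bad)) {
    stop("malformed HLA allele name(s): ",
         paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  parsed
}

# Non-throwing parser; malformed entries get NA components.
parse_allele_quietly <- function(x) {
  m <- regmatches(x, regexec(allele_regex(), x, perl = TRUE))
  gene <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  body <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
  suffix <- vapply(m, function(g) if (length(g)) g[4] else NA_character_, "")
  fields <- ifelse(is.na(body), list(NULL), strsplit(body, ":", fixed = TRUE))
  fields[is.na(body)] <- list(character(0))
  tibble::tibble(
    allele = x,
    gene = gene,
    fields = fields,
    n_fields = lengths(fields),
    suffix = suffix
  )
}

# Fields are 2-3 digits, so legacy run-together forms like "A*0201" fail.
allele_regex <- function() {
  "^([A-Z][A-Za-z0-9]*)\\*([0-9]{2,3}(?::[0-9]{2,3}){0,3})([NLSCAQ]?)$"
}

#' Render parsed alleles back to text
#'
#' Inverse of [parse_allele()]: `render_allele(parse_allele(x))` is `x` for
#' every well-formed name.
#'
#' @param parsed A tibble as returned by [parse_allele()].
#' @return Character vector of allele names.
#' @export
render_allele <- function(parsed) {
  out <- purrr::map2_chr(
    parsed$fields, seq_len(nrow(parsed)),
    function(f, i) {
      if (length(f) == 0) return(NA_character_)
      paste0(parsed$gene[i], "*", paste(f, collapse = ":"), parsed$suffix[i])
    }
  )
  out
}

#' Reduce allele resolution
#'
#' Truncates allele names to their first `n_fields` fields. Expression
#' suffixes are retained only at full (untruncated) resolution and dropped on
#' any truncation. An allele that already has `n_fields` fields is returned
#' unchanged, so the operation is idempotent.
#'
#' @param x Character vector of allele names.
#' @param n_fields Target number of fields, 1 to 4.
#' @param strict When `TRUE` (default) an allele with fewer than `n_fields`
#'   fields is an error -- resolution is never silently padded. When `FALSE`
#'   such alleles become `NA`.
#' @return Character vector of reduced allele names.
#' @examples
#' reduce_allele("A*02:01:01:01", 2)   # "A*02:01"
#' @export
reduce_allele <- function(x, n_fields, strict = TRUE) {
  stopifnot(length(n_fields) == 1, n_fields >= 1, n_fields <= 4)
  p <- parse_allele(x)
  short <- !is.na(x) & p$n_fields < n_fields
  if (any(short)) {
    if (strict) {
      stop("cannot reduce to ", n_fields, "-field resolution, insufficient ",
           "fields in: ", paste(unique(x[short]), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- purrr::map2_chr(p$fields, p$suffix, function(f, s) {
    if (length(f) == 0 || length(f) < n_fields) return(NA_character_)
    suf <- if (length(f) == n_fields) s else ""
    paste0(paste(f[seq_len(n_fields)], collapse = ":"), suf)
  })
  gene <- p$gene
  ifelse(is.na(out), NA_character_, paste0(gene, "*", out))
}

#' Validate an HLA calls table
#'
#' Checks every genotype cell of a calls table (`ID` plus `<GENE>_1`/
#' `<GENE>_2` columns) against the allele grammar and, optionally, against a
#' set of known allele names. Validation is advisory: the input is never
#' modified and unknown alleles are reported, not rejected, so partially
#' typed datasets remain usable.
#'
#' @param calls A data frame with an `ID` column and paired `<GENE>_1`/
#'   `<GENE>_2` allele columns.
#' @param known Optional character vector of known allele names; when given,
#'   parseable alleles absent from it are flagged as `unknown`.
#' @return A tibble of failures with columns `ID`, `column`, `allele` and
#'   `problem` (`"malformed"` or `"unknown"`); zero rows when everything
#'   passes.
#' @export
validate_hla_calls <- function(calls, known = NULL) {
  cols <- hla_call_columns(calls)
  long <- tidyr::pivot_longer(
    dplyr::select(calls, "ID", dplyr::all_of(cols)),
    cols = dplyr::all_of(cols), names_to = "column", values_to = "allele"
  )
  long <- dplyr::filter(long, !is.na(.data$allele), .data$allele != "")
  parsed <- parse_allele_quietly(long$allele)
  problem <- rep(NA_character_, nrow(long))
  problem[is.na(parsed$gene)] <- "malformed"
  if (!is.null(known)) {
    unknown <- !is.na(parsed$gene) & !(long$allele %in% known)
    problem[unknown] <- "unknown"
  }
  long$problem <- problem
  dplyr::filter(long, !is.na(.data$problem))
}

# Paired <GENE>_1/<GENE>_2 columns of a calls table, erroring on odd pairs.
hla_call_columns <- function(calls) {
  nm <- setdiff(names(calls), "ID")
  g1 <- sort(sub("_1$", "", nm[grepl("_1$", nm)]))
  g2 <- sort(sub("_2$", "", nm[grepl("_2$", nm)]))
  if (!identical(g1, g2)) {
    stop("unpaired allele columns for gene(s): ",
         paste(union(setdiff(g1, g2), setdiff(g2, g1)), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(nm, c(paste0(g1, "_1"), paste0(g1, "_2")))
  if (length(extra)) {
    stop("unexpected column(s) in calls table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  as.vector(rbind(paste0(g1, "_1"), paste0(g1, "_2")))
}

hla_call_genes <- function(calls) {
  unique(sub("_[12]$", "", hla_call_columns(calls)))
}
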
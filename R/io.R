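#' Read an HLA calls table
#'
#' Reads a delimited file (tab or comma, sniffed from the header line) with
#' an `ID` column and paired `<GENE>_1`/`<GENE>_2` allele columns. Blank and
#' `NA` cells become missing calls; every non-missing cell must parse under
#' the allele grammar. Unpaired gene columns and duplicate IDs are format
#' errors.
#'
#' @param path Path to the file.
#' @return A calls tibble.
#' @export
read_hla_table <- function(path) {
  tbl <- read_sniffed(path)
  if (!"ID" %in% names(tbl)) {
    stop("calls table must have an ID column: ", path, call. = FALSE)
  }
  if (anyDuplicated(tbl$ID)) {
    stop("duplicate ID(s) in calls table: ",
         paste(unique(tbl$ID[duplicated(tbl$ID)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- hla_call_columns(tbl)  # errors on unpaired columns
  for (cl in cols) {
    x <- as.character(tbl[[cl]])
    x[!is.na(x) & !nzchar(trimws(x))] <- NA
    tbl[[cl]] <- x
  }
  bad <- validate_hla_calls(tbl)
  bad <- bad[bad$problem == "malformed", ]
  if (nrow(bad)) {
    stop("malformed allele(s) in ", path, ": ",
         paste(utils::head(paste0(bad$ID, "/", bad$column, "=", bad$allele),
                           5), collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write an HLA calls table
#'
#' @param calls A calls tibble.
#' @param path Output path; written tab-separated.
#' @return `path`, invisibly. A write/read round trip is the identity.
#' @export
write_hla_table <- function(calls, path) {
  readr::write_tsv(calls, path, na = "")
  invisible(path)
}

#' Read a KIR gene-content table
#'
#' Delimited file with an `ID` column and one column per KIR gene, presence
#' coded `1`/`Y`, absence `0`/`N`. Codes are validated by [kir_presence()]
#' at transform time; this reader only checks the shape.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_kir_table <- function(path) {
  tbl <- read_sniffed(path)
  if (!"ID" %in% names(tbl)) {
    stop("KIR table must have an ID column: ", path, call. = FALSE)
  }
  if (anyDuplicated(tbl$ID)) {
    stop("duplicate ID(s) in KIR table", call. = FALSE)
  }
  for (cl in setdiff(names(tbl), "ID")) tbl[[cl]] <- as.character(tbl[[cl]])
  tbl
}

# Delimiter sniffing: tab wins if the header contains one, else comma.
read_sniffed <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header, fixed = TRUE)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
}

#' Write an association result table
#'
#' Writes the stable-column-order TSV used across the package: estimates in
#' fixed decimal notation, p-values switching to scientific below 1e-4 so
#' outputs are byte-stable across runs.
#'
#' @param x An `hla_assoc` or `hla_omnibus` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(x, path) {
  d <- tibble::as_tibble(x)
  num <- vapply(d, is.numeric, TRUE)
  for (cl in names(d)[num]) {
    if (cl %in% c("p", "p_adj")) {
      d[[cl]] <- format_pvalue(d[[cl]])
    } else {
      d[[cl]] <- ifelse(is.na(d[[cl]]), NA_character_,
                        formatC(d[[cl]], digits = 6, format = "fg"))
    }
  }
  readr::write_tsv(d, path, na = "NA")
  invisible(path)
}

format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4 & p > 0, formatC(p, digits = 4, format = "e"),
                formatC(p, digits = 6, format = "f")))
}
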
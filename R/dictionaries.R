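#' Allele grouping dictionaries
#'
#' A dictionary maps allele names (stated at a declared field resolution) to
#' group labels: supertypes, G groups, NK-cell ligand groups (Bw4/Bw6/C1/C2)
#' or any user-supplied custom grouping. Quantitative dictionaries carry an
#' additional numeric `value` per allele (e.g. allele-specific expression).
#'
#' @param entries A data frame with columns `group` and `allele` (and
#'   optionally `value`).
#' @param name Dictionary label, used as the experiment name prefix.
#' @param resolution Field resolution the allele names are stated at (1-4);
#'   query alleles are reduced to this resolution before lookup.
#' @return An `hla_dictionary`: a tibble with attributes `dict_name` and
#'   `resolution`.
#' @export
hla_dictionary <- function(entries, name, resolution = 2L) {
  stopifnot(all(c("group", "allele") %in% names(entries)))
  entries <- tibble::as_tibble(entries)
  if (any(!nzchar(entries$group)) || anyNA(entries$group)) {
    stop("dictionary group labels must be non-empty", call. = FALSE)
  }
  parse_allele(entries$allele)  # errors on unparseable names
  dup <- entries$allele[duplicated(entries$allele)]
  if (length(dup)) {
    stop("allele(s) listed under more than one group: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if ("value" %in% names(entries) && !is.numeric(entries$value)) {
    stop("quantitative dictionary column 'value' must be numeric",
         call. = FALSE)
  }
  structure(entries,
            dict_name = name,
            resolution = as.integer(resolution),
            class = c("hla_dictionary", class(entries)))
}

#' Read a dictionary file
#'
#' Dictionary files are tab-separated with two columns `group<TAB>allele`
#' (three with a numeric value for quantitative dictionaries) and
#' `#`-prefixed header lines carrying `name=` and `resolution=`. The same
#' format serves the bundled supertype, G-group and NK-ligand tables and any
#' custom user dictionary.
#'
#' @param path Path to a dictionary TSV.
#' @return An [hla_dictionary()].
#' @export
read_hla_dictionary <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- parse_header_keys(header)
  name <- meta[["name"]] %||% basename(path)
  resolution <- as.integer(meta[["resolution"]] %||% "2")
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1 || !ncols %in% 2:3) {
    stop("dictionary rows must have 2 or 3 tab-separated columns: ", path,
         call. = FALSE)
  }
  entries <- tibble::tibble(
    group = vapply(parts, `[[`, "", 1),
    allele = vapply(parts, `[[`, "", 2)
  )
  if (ncols == 3) {
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
    if (anyNA(val)) {
      stop("quantitative dictionary has non-numeric value(s): ", path,
           call. = FALSE)
    }
    entries$value <- val
  }
  hla_dictionary(entries, name = name, resolution = resolution)
}

#' Write a dictionary file
#'
#' @param dict An [hla_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hla_dictionary <- function(dict, path) {
  header <- c(paste0("# name=", attr(dict, "dict_name")),
              paste0("# resolution=", attr(dict, "resolution")))
  cols <- intersect(c("group", "allele", "value"), names(dict))
  rows <- do.call(paste, c(unname(as.list(dict[cols])), sep = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

parse_header_keys <- function(header) {
  kv <- sub("^#\\s*", "", header)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' Map alleles to dictionary groups
#'
#' Each query allele is reduced to the dictionary's declared resolution and
#' looked up; alleles that cannot be reduced (insufficient resolution) or are
#' absent from the dictionary map to `NA`.
#'
#' @param x Character vector of allele names.
#' @param dict An [hla_dictionary()].
#' @return Character vector of group labels (`NA` when unmapped).
#' @examples
#' d <- bundled_dictionary("supertypes")
#' map_to_group("A*02:01:01:01", d)   # "A02"
#' @export
map_to_group <- function(x, dict) {
  res <- attr(dict, "resolution")
  reduced <- reduce_allele(x, res, strict = FALSE)
  dict$group[match(reduced, dict$allele)]
}

#' Bundled dictionaries
#'
#' Curated subsets of the published allele groupings, shipped as editable TSV
#' files under `inst/extdata/`: `"supertypes"` (HLA class I supertype
#' assignments), `"g_groups"` (alleles sharing peptide-binding-domain
#' nucleotide sequence) and `"nk_ligands"` (Bw4/Bw6 epitopes of HLA-B and
#' some HLA-A alleles; C1/C2 groups of HLA-C defined by the position-80
#' dimorphism). The tables cover common Caucasoid alleles and are meant to be
#' extended by the user for production analyses.
#'
#' @param which One of `"supertypes"`, `"g_groups"`, `"nk_ligands"`.
#' @return An [hla_dictionary()].
#' @export
bundled_dictionary <- function(which = c("supertypes", "g_groups",
                                         "nk_ligands")) {
  which <- match.arg(which)
  read_hla_dictionary(
    system.file("extdata", paste0(which, ".tsv"), package = "hlakir",
                mustWork = TRUE)
  )
}

#' Bundled HLA-KIR interaction table
#'
#' The experimentally validated inhibitory and activating receptor-ligand
#' pairs between KIR and HLA class I ligand groups (KIR2DL1 with C2, KIR2DL2
#' and KIR2DL3 with C1, KIR3DL1 with Bw4, and the activating counterparts),
#' as an editable three-column TSV (`interaction`, `kir_gene`,
#' `ligand_variable`).
#'
#' @param path Optional path to a custom interaction table in the same
#'   format.
#' @return A tibble with columns `interaction`, `kir_gene`,
#'   `ligand_variable`.
#' @export
kir_interaction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "kir_ligand_interactions.tsv",
                                package = "hlakir", mustWork = TRUE)
  tbl <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("interaction", "kir_gene", "ligand_variable")
  if (!all(need %in% names(tbl))) {
    stop("interaction table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Peptide-binding region position presets
#'
#' Position lists for Grantham divergence over HLA class I molecules: the
#' full antigen-recognition domain (`ARD`, mature positions 1-182 spanning
#' the alpha-1/alpha-2 domains) and the B and F peptide-anchor pockets.
#' Shipped as an editable TSV (`region<TAB>position`).
#'
#' @param region `"ARD"`, `"B_pocket"` or `"F_pocket"`.
#' @return Integer vector of 1-based mature-protein positions.
#' @export
divergence_region <- function(region = c("ARD", "B_pocket", "F_pocket")) {
  region <- match.arg(region)
  path <- system.file("extdata", "pocket_positions.tsv", package = "hlakir",
                      mustWork = TRUE)
  tbl <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  pos <- tbl$position[tbl$region == region]
  if (!length(pos)) stop("region not found in preset table: ", region,
                         call. = FALSE)
  sort(as.integer(pos))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
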
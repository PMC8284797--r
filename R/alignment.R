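#' Protein alignment tables
#'
#' Per-gene protein alignments give a residue for every allele at every
#' position of the mature protein and are the substrate for amino-acid
#' expansion, Bw4 position-80 refinement and Grantham divergence. The
#' supported layout is a normalised text format derived from IPD-IMGT/HLA
#' style alignments: the reference allele's sequence comes first and is
#' fully explicit; subsequent rows use `-` for identity with the reference,
#' `*` for unknown and `.` for an indel. On parsing, identity codes are
#' resolved so every stored cell is explicit; `*` and `.` are kept as
#' distinct unknown/indel codes.
#'
#' @name hla_alignment
NULL

ALN_UNKNOWN <- "*"
ALN_INDEL <- "."

new_alignment <- function(gene, positions, alleles, residues) {
  stopifnot(ncol(residues) == length(positions),
            nrow(residues) == length(alleles))
  rownames(residues) <- alleles
  colnames(residues) <- as.character(positions)
  structure(
    list(gene = gene, positions = as.integer(positions), alleles = alleles,
         reference = alleles[1], residues = residues),
    class = "hla_alignment"
  )
}

#' @export
print.hla_alignment <- function(x, ...) {
  cat("<hla_alignment> gene", x$gene, "-", length(x$alleles), "alleles x",
      length(x$positions), "positions; reference", x$reference, "\n")
  invisible(x)
}

#' Read a protein alignment file
#'
#' The file format is plain text: `#` header lines carrying `gene=` and
#' `positions=` (comma-separated 1-based mature-protein position labels,
#' negatives allowed for the leader peptide), then one row per allele as
#' `allele<TAB>sequence`. The first sequence row is the reference and must be
#' fully explicit; later rows may use the `-`/`*`/`.` codes.
#'
#' @param path Path to an alignment file.
#' @return An `hla_alignment` object.
#' @export
read_hla_alignment <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- parse_header_keys(header)
  if (is.null(meta[["gene"]]) || is.null(meta[["positions"]])) {
    stop("alignment file missing gene=/positions= header: ", path,
         call. = FALSE)
  }
  positions <- as.integer(strsplit(meta[["positions"]], ",")[[1]])
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("alignment rows must be allele<TAB>sequence: ", path, call. = FALSE)
  }
  alleles <- vapply(parts, `[[`, "", 1)
  seqs <- vapply(parts, `[[`, "", 2)
  if (!length(alleles)) stop("alignment file has no sequence rows: ", path,
                             call. = FALSE)
  if (anyDuplicated(alleles)) {
    stop("duplicate allele row(s): ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "),
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1 || widths[1] != length(positions)) {
    stop("ragged alignment rows or position count mismatch: ", path,
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ref <- mat[1, ]
  if (any(ref %in% c("-", ALN_UNKNOWN, ALN_INDEL))) {
    stop("reference row must be fully explicit (no -, *, . codes): ", path,
         call. = FALSE)
  }
  for (i in seq_len(nrow(mat))[-1]) {
    id <- mat[i, ] == "-"
    mat[i, id] <- ref[id]
  }
  new_alignment(meta[["gene"]], positions, alleles, mat)
}

#' Write a protein alignment file
#'
#' Inverse of [read_hla_alignment()]: residues identical to the reference are
#' re-encoded as `-`, so a read/write round trip reproduces the original
#' identity pattern.
#'
#' @param aln An `hla_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hla_alignment <- function(aln, path) {
  mat <- aln$residues
  ref <- mat[1, ]
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    r <- mat[i, ]
    if (i > 1) {
      id <- r == ref & !(r %in% c(ALN_UNKNOWN, ALN_INDEL))
      r[id] <- "-"
    }
    paste(r, collapse = "")
  }, "")
  writeLines(c(
    paste0("# gene=", aln$gene),
    paste0("# positions=", paste(aln$positions, collapse = ",")),
    paste0(aln$alleles, "\t", rows)
  ), path)
  invisible(path)
}

# Match query alleles to alignment rows: reduce the query to 2-field, then
# take the longest-prefix match among rows (2-field reduction of each row);
# ties broken by file order. 1-field queries match on the 1-field prefix.
# Returns row indices, NA when unmatched.
match_alignment_row <- function(aln, alleles) {
  q2 <- reduce_query_2field(alleles)
  rows2 <- reduce_query_2field(aln$alleles)
  idx <- match(q2, rows2)
  one_field <- !is.na(alleles) & parse_allele_quietly(alleles)$n_fields == 1
  if (any(one_field)) {
    q1 <- reduce_allele(alleles[one_field], 1, strict = FALSE)
    rows1 <- vapply(aln$alleles,
                    function(a) reduce_allele(a, 1, strict = FALSE), "",
                    USE.NAMES = FALSE)
    idx[one_field] <- match(q1, rows1)
  }
  idx
}

# Reduce to at most 2 fields without erroring on 1-field input.
reduce_query_2field <- function(x) {
  p <- parse_allele_quietly(x)
  n <- pmin(p$n_fields, 2L)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(p$gene) & p$n_fields > 0
  out[ok] <- vapply(which(ok), function(i) {
    paste0(p$gene[i], "*", paste(p$fields[[i]][seq_len(n[i])], collapse = ":"))
  }, "")
  out
}

#' Residues of alleles at alignment positions
#'
#' Resolves each allele to an alignment row (2-field reduction, then
#' longest-prefix match, ties by file order) and returns its residue at the
#' requested positions. Unknown (`*`) and indel (`.`) codes are returned
#' as-is; downstream transforms treat unknowns as missing data.
#'
#' @param aln An `hla_alignment`.
#' @param alleles Character vector of allele names of the alignment's gene.
#' @param positions Integer vector of position labels.
#' @return A character matrix, `length(alleles)` rows by
#'   `length(positions)` columns.
#' @export
residues_at <- function(aln, alleles, positions) {
  idx <- match_alignment_row(aln, alleles)
  if (anyNA(idx[!is.na(alleles)])) {
    miss <- unique(alleles[!is.na(alleles) & is.na(idx)])
    stop("allele(s) not mappable to alignment rows for gene ", aln$gene,
         ": ", paste(miss, collapse = ", "), call. = FALSE)
  }
  pcol <- match(as.integer(positions), aln$positions)
  if (anyNA(pcol)) {
    stop("position(s) absent from alignment: ",
         paste(positions[is.na(pcol)], collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_character_, length(alleles), length(positions),
                dimnames = list(alleles, as.character(positions)))
  ok <- !is.na(idx)
  out[ok, ] <- aln$residues[idx[ok], pcol, drop = FALSE]
  out
}

#' Variable amino-acid positions
#'
#' Positions where at least two distinct non-unknown residues (indels count
#' as a residue state) occur among a restricted allele set, in ascending
#' order. Restricting to the alleles observed in a dataset keeps the
#' amino-acid expansion to positions that can actually vary in that dataset.
#'
#' @param aln An `hla_alignment`.
#' @param alleles Alleles to restrict to; default all alignment rows.
#' @return Integer vector of variable positions.
#' @export
variable_positions <- function(aln, alleles = aln$alleles) {
  res <- residues_at(aln, unique(alleles), aln$positions)
  keep <- apply(res, 2, function(col) {
    length(unique(col[!is.na(col) & col != ALN_UNKNOWN])) >= 2
  })
  sort(aln$positions[keep])
}
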
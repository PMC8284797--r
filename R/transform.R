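#' HLA allele copy counts
#'
#' Transforms a calls table into a counts experiment: one variable per
#' distinct allele at the requested field resolution, holding the number of
#' copies (0, 1 or 2) each individual carries. Cells that cannot be reduced
#' to the requested resolution become missing for that gene (a message
#' reports how many). All four inheritance models apply to count variables.
#'
#' @param calls A calls table (`ID` plus `<GENE>_1`/`<GENE>_2` columns).
#' @param resolution Field resolution (1-4) to count alleles at.
#' @return An [hla_experiment()] named `"hla_alleles"`.
#' @examples
#' calls <- tibble::tibble(ID = "S1", A_1 = "A*02:01:01:01", A_2 = "A*01:01")
#' hla_counts(calls, resolution = 2)
#' @export
hla_counts <- function(calls, resolution = 2) {
  pairs <- calls_long(calls)
  reduced <- reduce_allele(pairs$allele, resolution, strict = FALSE)
  n_lost <- sum(!is.na(pairs$allele) & is.na(reduced))
  if (n_lost > 0) {
    message(n_lost, " allele call(s) below ", resolution,
            "-field resolution treated as missing")
  }
  pairs$allele <- reduced
  counts_from_pairs(pairs, name = "hla_alleles")
}

#' Allele group copy counts
#'
#' Maps each allele through a grouping dictionary (supertypes, G groups or a
#' custom table) and counts copies per group. Alleles that map to no group
#' contribute to no variable; a message reports the unmapped tally.
#'
#' @param calls A calls table.
#' @param dict An [hla_dictionary()].
#' @param name Experiment name; defaults to `hla_<dictionary name>`.
#' @return An [hla_experiment()] of per-group copy counts.
#' @export
hla_group_counts <- function(calls, dict, name = NULL) {
  name <- name %||% paste0("hla_", attr(dict, "dict_name"))
  pairs <- calls_long(calls)
  grp <- map_to_group(pairs$allele, dict)
  n_unmapped <- sum(!is.na(pairs$allele) & is.na(grp))
  if (n_unmapped > 0) {
    message(n_unmapped, " allele call(s) not covered by dictionary '",
            attr(dict, "dict_name"), "'")
  }
  pairs$allele <- grp
  counts_from_pairs(pairs, name = name, count_unmapped_as_zero = TRUE)
}

#' Amino-acid residue copy counts
#'
#' Expands HLA calls to the amino-acid level: for every position that is
#' variable among the dataset's alleles, one copy-count variable per residue
#' observed there, named `<GENE>_<position>_<residue>` and grouped under
#' `<GENE>_<position>` for omnibus testing. Per individual and position the
#' residue counts sum to 2 when both calls are present and sequenced.
#' Unknown residues make the individual missing for that position's
#' variables; indels count as a residue state (`del`).
#'
#' @param calls A calls table.
#' @param alignments A named list of [read_hla_alignment()] objects, one per
#'   gene to expand (genes without an alignment are skipped with a message).
#' @return An [hla_experiment()] named `"hla_aa"`.
#' @export
hla_aa_counts <- function(calls, alignments) {
  genes <- intersect(hla_call_genes(calls), names(alignments))
  skipped <- setdiff(hla_call_genes(calls), genes)
  if (length(skipped)) {
    message("no alignment for gene(s), skipped: ",
            paste(skipped, collapse = ", "))
  }
  blocks <- list()
  meta <- list()
  for (g in genes) {
    aln <- alignments[[g]]
    a1 <- calls[[paste0(g, "_1")]]
    a2 <- calls[[paste0(g, "_2")]]
    observed <- unique(stats::na.omit(c(a1, a2)))
    if (!length(observed)) next
    pos <- variable_positions(aln, observed)
    if (!length(pos)) next
    r1 <- residues_at(aln, a1, pos)
    r2 <- residues_at(aln, a2, pos)
    for (j in seq_along(pos)) {
      res1 <- r1[, j]
      res2 <- r2[, j]
      res1[res1 == ALN_UNKNOWN] <- NA
      res2[res2 == ALN_UNKNOWN] <- NA
      lab1 <- residue_label(res1)
      lab2 <- residue_label(res2)
      levels <- sort(unique(stats::na.omit(c(lab1, lab2))))
      grp <- paste0(g, "_", pos[j])
      for (lv in levels) {
        nm <- paste0(grp, "_", lv)
        val <- (lab1 == lv) + (lab2 == lv)
        val[is.na(lab1) | is.na(lab2)] <- NA
        blocks[[nm]] <- as.numeric(val)
        meta[[nm]] <- grp
      }
    }
  }
  values <- tibble::as_tibble(c(list(ID = calls$ID), blocks))
  vm <- tibble::tibble(
    variable = names(blocks),
    group = unlist(meta, use.names = FALSE),
    models = "additive,dominant,recessive,overdominant",
    type = "count"
  )
  hla_experiment(values, "hla_aa", vm)
}

residue_label <- function(x) ifelse(x == ALN_INDEL, "del", x)

#' Per-gene heterozygosity indicators
#'
#' One binary variable per gene (`<GENE>_het`), 1 when the two alleles differ
#' at the requested resolution, 0 when identical, missing when either call
#' is missing or below the resolution.
#'
#' @param calls A calls table.
#' @param resolution Field resolution at which to compare the two alleles.
#' @return An [hla_experiment()] named `"hla_het"` of binary variables.
#' @export
hla_heterozygosity <- function(calls, resolution = 2) {
  genes <- hla_call_genes(calls)
  cols <- lapply(genes, function(g) {
    a1 <- reduce_allele(calls[[paste0(g, "_1")]], resolution, strict = FALSE)
    a2 <- reduce_allele(calls[[paste0(g, "_2")]], resolution, strict = FALSE)
    as.numeric(a1 != a2)
  })
  names(cols) <- paste0(genes, "_het")
  values <- tibble::as_tibble(c(list(ID = calls$ID), cols))
  vm <- tibble::tibble(variable = names(cols), models = "dominant",
                       type = "binary")
  hla_experiment(values, "hla_het", vm)
}

#' Grantham evolutionary divergence
#'
#' For each HLA class I gene, the mean Grantham distance between the residues
#' of an individual's two alleles over the positions of a peptide-binding
#' region: the full antigen-recognition domain (`"ARD"`), the B or F
#' peptide-anchor pocket, or a user-supplied position vector. Positions where
#' either residue is unknown or an indel are excluded from both numerator and
#' denominator; homozygotes score 0. Individuals with a missing call, or with
#' no usable position at all, are missing.
#'
#' @param calls A calls table.
#' @param alignments Named list of alignments for the class I genes.
#' @param region `"ARD"`, `"B_pocket"`, `"F_pocket"` or an integer vector of
#'   positions.
#' @param genes Genes to compute divergence for; defaults to the class I
#'   genes (A, B, C) present in both `calls` and `alignments`.
#' @param matrix Distance matrix; defaults to [grantham_matrix()].
#' @return An [hla_experiment()] named `"hla_divergence"` of continuous
#'   variables `<GENE>_divergence`.
#' @export
hla_divergence <- function(calls, alignments, region = "ARD",
                           genes = NULL, matrix = grantham_matrix()) {
  if (is.character(region)) region <- divergence_region(region)
  region <- as.integer(region)
  class1 <- c("A", "B", "C")
  genes <- genes %||%
    intersect(intersect(hla_call_genes(calls), class1), names(alignments))
  if (!length(genes)) stop("no class I gene with an alignment available",
                           call. = FALSE)
  cols <- lapply(genes, function(g) {
    aln <- alignments[[g]]
    pos <- intersect(region, aln$positions)
    if (!length(pos)) {
      message("no region position present in ", g, " alignment; ",
              g, "_divergence is missing")
      return(rep(NA_real_, nrow(calls)))
    }
    r1 <- residues_at(aln, calls[[paste0(g, "_1")]], pos)
    r2 <- residues_at(aln, calls[[paste0(g, "_2")]], pos)
    vapply(seq_len(nrow(calls)), function(i) {
      pair_divergence(r1[i, ], r2[i, ], matrix)
    }, 0)
  })
  names(cols) <- paste0(genes, "_divergence")
  values <- tibble::as_tibble(c(list(ID = calls$ID), cols))
  vm <- tibble::tibble(variable = names(cols), models = "additive",
                       type = "continuous")
  hla_experiment(values, "hla_divergence", vm)
}

# Mean Grantham distance over usable positions of one residue-vector pair.
pair_divergence <- function(res1, res2, matrix) {
  if (anyNA(res1) || anyNA(res2)) return(NA_real_)
  usable <- res1 %in% rownames(matrix) & res2 %in% rownames(matrix)
  if (!any(usable)) return(NA_real_)
  mean(matrix[cbind(res1[usable], res2[usable])])
}

#' NK-cell ligand group counts
#'
#' Assigns HLA-B (and some HLA-A) alleles to the Bw4 or Bw6 serological
#' epitope and HLA-C alleles to the C1 or C2 KIR-ligand group via the
#' bundled matching table, and counts copies. With `refine_bw4_80 = TRUE`
#' the Bw4 count is additionally split by the residue at mature position 80
#' (threonine vs isoleucine, which modulates KIR3DL1 binding) into
#' `Bw4_80T` and `Bw4_80I`, using the HLA-B alignment.
#'
#' @param calls A calls table.
#' @param dict NK-ligand dictionary; defaults to the bundled one.
#' @param alignments Named list of alignments; required (for gene B) only
#'   when `refine_bw4_80` is set.
#' @param refine_bw4_80 Split Bw4 by the position-80 residue.
#' @return An [hla_experiment()] named `"hla_NK_ligands"`.
#' @export
hla_nk_ligands <- function(calls, dict = bundled_dictionary("nk_ligands"),
                           alignments = NULL, refine_bw4_80 = FALSE) {
  exp <- hla_group_counts(calls, dict, name = "hla_NK_ligands")
  for (lg in c("Bw4", "Bw6", "C1", "C2")) {
    if (!lg %in% names(exp)) exp[[lg]] <- rep(0, nrow(exp))
  }
  nk_meta <- function(vars) {
    tibble::tibble(variable = vars,
                   models = "additive,dominant,recessive,overdominant",
                   type = "count")
  }
  exp <- hla_experiment(tibble::as_tibble(exp)[c("ID", "Bw4", "Bw6",
                                                 "C1", "C2")],
                        "hla_NK_ligands", nk_meta(c("Bw4", "Bw6", "C1", "C2")))
  if (!refine_bw4_80) return(exp)
  if (is.null(alignments[["B"]])) {
    stop("position-80 refinement requires an HLA-B alignment", call. = FALSE)
  }
  aln <- alignments[["B"]]
  split80 <- lapply(c("_1", "_2"), function(slot) {
    a <- calls[[paste0("B", slot)]]
    grp <- map_to_group(a, dict)
    r80 <- residues_at(aln, a, 80)[, 1]
    list(bw4 = !is.na(grp) & grp == "Bw4", r80 = r80)
  })
  t_count <- i_count <- rep(0, nrow(calls))
  for (s in split80) {
    t_count <- t_count + as.numeric(s$bw4 & !is.na(s$r80) & s$r80 == "T")
    i_count <- i_count + as.numeric(s$bw4 & !is.na(s$r80) & s$r80 == "I")
  }
  out <- tibble::as_tibble(exp)
  out$Bw4_80T <- t_count
  out$Bw4_80I <- i_count
  hla_experiment(out, "hla_NK_ligands",
                 nk_meta(c("Bw4", "Bw6", "C1", "C2", "Bw4_80T", "Bw4_80I")))
}

#' KIR gene presence
#'
#' Recodes a KIR gene-content table (one column per KIR gene, presence coded
#' `1`/`Y`, absence `0`/`N`, case-insensitive) into binary variables.
#' Unrecognised codes become missing with a warning; a column with no
#' recognisable code at all is a format error.
#'
#' @param kir A data frame: `ID` plus one column per KIR gene.
#' @return An [hla_experiment()] named `"kir_genes"` of binary variables.
#' @export
kir_presence <- function(kir) {
  stopifnot("ID" %in% names(kir))
  genes <- setdiff(names(kir), "ID")
  cols <- lapply(genes, function(g) {
    raw <- toupper(trimws(as.character(kir[[g]])))
    out <- rep(NA_real_, length(raw))
    out[raw %in% c("1", "Y")] <- 1
    out[raw %in% c("0", "N")] <- 0
    bad <- is.na(out) & !is.na(raw) & raw != "" & raw != "NA"
    if (all(is.na(out))) {
      stop("KIR column '", g, "' has no recognisable presence/absence code",
           call. = FALSE)
    }
    if (any(bad)) {
      warning("unrecognised KIR code(s) in column '", g, "' set to missing: ",
              paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
    }
    out
  })
  names(cols) <- genes
  values <- tibble::as_tibble(c(list(ID = kir$ID), cols))
  vm <- tibble::tibble(variable = genes, models = "dominant",
                       type = "binary")
  hla_experiment(values, "kir_genes", vm)
}

#' HLA-KIR interaction indicators
#'
#' Codes each validated receptor-ligand pair as a binary variable: 1 when
#' the KIR gene is present and the individual carries at least one copy of
#' the HLA ligand group, 0 otherwise, missing when either side is missing.
#'
#' @param ligands An NK-ligand experiment ([hla_nk_ligands()]).
#' @param kir A KIR presence experiment ([kir_presence()]).
#' @param interactions Interaction table; defaults to
#'   [kir_interaction_table()].
#' @return An [hla_experiment()] named `"hla_kir_interactions"`.
#' @export
hla_kir_interactions <- function(ligands, kir,
                                 interactions = kir_interaction_table()) {
  merged <- dplyr::inner_join(tibble::as_tibble(ligands),
                              tibble::as_tibble(kir), by = "ID")
  missing_kir <- setdiff(interactions$kir_gene, names(kir))
  missing_lig <- setdiff(interactions$ligand_variable, names(ligands))
  if (length(missing_kir) || length(missing_lig)) {
    stop("interaction table references absent column(s): ",
         paste(c(missing_kir, missing_lig), collapse = ", "), call. = FALSE)
  }
  cols <- lapply(seq_len(nrow(interactions)), function(i) {
    as.numeric(merged[[interactions$kir_gene[i]]] >= 1 &
               merged[[interactions$ligand_variable[i]]] >= 1)
  })
  names(cols) <- interactions$interaction
  values <- tibble::as_tibble(c(list(ID = merged$ID), cols))
  vm <- tibble::tibble(variable = interactions$interaction,
                       models = "dominant", type = "binary")
  hla_experiment(values, "hla_kir_interactions", vm)
}

#' Custom dictionary transform
#'
#' Applies a user dictionary in one of three modes: `"count"` (per-group copy
#' counts, identical to [hla_group_counts()]), `"binary"` (1 when any allele
#' maps to the group) or `"quantitative"` (per-individual sum of the
#' dictionary's numeric `value` over both alleles, e.g. for allele-specific
#' expression scores).
#'
#' @param calls A calls table.
#' @param dict An [hla_dictionary()]; quantitative mode requires its
#'   `value` column.
#' @param mode `"count"`, `"binary"` or `"quantitative"`.
#' @param name Experiment name; defaults to `hla_custom`.
#' @return An [hla_experiment()].
#' @export
hla_custom <- function(calls, dict, mode = c("count", "binary",
                                             "quantitative"),
                       name = "hla_custom") {
  mode <- match.arg(mode)
  if (mode == "quantitative" && !"value" %in% names(dict)) {
    stop("quantitative mode requires a dictionary with a numeric 'value' ",
         "column", call. = FALSE)
  }
  if (mode == "quantitative") {
    res <- attr(dict, "resolution")
    cols <- list()
    score <- rep(0, nrow(calls))
    miss <- rep(FALSE, nrow(calls))
    for (slot in c("_1", "_2")) {
      for (g in hla_call_genes(calls)) {
        a <- reduce_allele(calls[[paste0(g, slot)]], res, strict = FALSE)
        v <- dict$value[match(a, dict$allele)]
        miss <- miss | is.na(calls[[paste0(g, slot)]])
        score <- score + dplyr::coalesce(v, 0)
      }
    }
    score[miss] <- NA
    nm <- paste0(attr(dict, "dict_name"), "_score")
    values <- tibble::tibble(ID = calls$ID, !!nm := score)
    vm <- tibble::tibble(variable = nm, models = "additive",
                         type = "continuous")
    return(hla_experiment(values, name, vm))
  }
  exp <- hla_group_counts(calls, dict, name = name)
  if (mode == "binary") {
    out <- tibble::as_tibble(exp)
    for (v in experiment_variables(exp)) out[[v]] <- as.numeric(out[[v]] >= 1)
    vm <- var_meta(exp)
    vm$models <- "dominant"
    vm$type <- "binary"
    vm$frequency <- NA_real_
    exp <- hla_experiment(out, name, vm)
  }
  exp
}

# Long (ID, gene, slot, allele) view of a calls table.
calls_long <- function(calls) {
  cols <- hla_call_columns(calls)
  long <- tidyr::pivot_longer(
    dplyr::select(calls, "ID", dplyr::all_of(cols)),
    cols = dplyr::all_of(cols),
    names_to = c("gene", "slot"), names_pattern = "(.*)_([12])",
    values_to = "allele"
  )
  long$allele[!is.na(long$allele) & long$allele == ""] <- NA
  long
}

# Tally copy counts per (ID, value) from a long pairs table. An individual
# is missing for a gene's variables when either call of that gene is
# missing; with count_unmapped_as_zero, unmapped alleles simply contribute
# nothing (the slot still counts as observed).
counts_from_pairs <- function(pairs, name, count_unmapped_as_zero = FALSE) {
  gene_missing <- pairs |>
    dplyr::group_by(.data$ID, .data$gene) |>
    dplyr::summarise(missing = if (count_unmapped_as_zero) FALSE else
      anyNA(.data$allele), .groups = "drop")
  vars <- sort(unique(stats::na.omit(pairs$allele)))
  ids <- unique(pairs$ID)
  mat <- matrix(0, length(ids), length(vars),
                dimnames = list(ids, vars))
  ok <- !is.na(pairs$allele)
  tab <- table(pairs$ID[ok], pairs$allele[ok])
  mat[rownames(tab), colnames(tab)] <- as.matrix(tab)
  # blank out genes with a missing call for that individual
  var_gene <- sub("\\*.*$", "", vars)
  for (i in seq_len(nrow(gene_missing))) {
    if (gene_missing$missing[i]) {
      hit <- var_gene == gene_missing$gene[i]
      mat[gene_missing$ID[i], hit] <- NA
    }
  }
  values <- tibble::as_tibble(cbind(tibble::tibble(ID = ids),
                                    tibble::as_tibble(mat)))
  vm <- tibble::tibble(variable = vars,
                       models = "additive,dominant,recessive,overdominant",
                       type = "count")
  hla_experiment(values, name, vm)
}
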
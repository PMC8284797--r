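test_that("allele counts code homo/heterozygotes and match a brute tally", {
  calls <- tiny_calls()
  exp <- hla_counts(calls, resolution = 2)
  expect_equal(exp[["A*02:01"]][1], 2)                    # homozygote
  expect_equal(exp[["A*02:01"]][2], 1)                    # heterozygote
  expect_equal(exp[["A*01:01"]][2], 1)
  expect_true(is.na(exp[["A*02:01"]][6]))                 # missing call
  oracle <- oracle_allele_counts(calls, 2)
  for (v in setdiff(names(exp), "ID")) {
    for (i in seq_len(nrow(exp))) {
      expected <- oracle[[paste(exp$ID[i], v, sep = "|")]]
      got <- exp[[v]][i]
      if (!is.na(got)) expect_equal(got, expected %||% 0)
    }
  }
})

test_that("diploid conservation holds on randomized complete fixtures", {
  for (s in 1:20) {
    cfg <- sim_config(n_individuals = 30, seed = s)
    calls <- sim_hla_calls(cfg)
    exp <- hla_counts(calls, 2)
    vars <- setdiff(names(exp), "ID")
    genes <- sub("\\*.*", "", vars)
    for (g in unique(genes)) {
      sums <- rowSums(as.matrix(tibble::as_tibble(exp)[vars[genes == g]]))
      expect_true(all(sums == 2))
    }
  }
})

test_that("group counts equal a map-then-tally oracle", {
  calls <- tiny_calls()
  d <- bundled_dictionary("supertypes")
  suppressMessages(exp <- hla_group_counts(calls, d))
  for (i in seq_len(nrow(calls))) {
    tally <- table(stats::na.omit(map_to_group(
      c(calls$A_1[i], calls$A_2[i], calls$DQB1_1[i], calls$DQB1_2[i]), d)))
    for (v in setdiff(names(exp), "ID")) {
      expected <- if (v %in% names(tally)) as.numeric(tally[[v]]) else 0
      expect_equal(exp[[v]][i], expected, ignore_attr = TRUE)
    }
  }
  # one mapped + one unmapped allele yields count 1
  one <- tibble::tibble(ID = "x", A_1 = "A*02:01", A_2 = "A*80:01")
  suppressMessages(e1 <- hla_group_counts(one, d))
  expect_equal(e1[["A02"]], 1)
})

test_that("amino-acid expansion groups residues by position", {
  calls <- tiny_calls()
  aln <- dqb1_alignment()
  exp <- hla_aa_counts(calls, list(DQB1 = aln))
  meta <- var_meta(exp)
  # P1 homozygous DQB1*03:01 (Y at 9)
  expect_equal(exp[["DQB1_9_Y"]][1], 2)
  # P2 is DQB1*02:01/03:01 = F/Y heterozygote at position 9
  expect_equal(exp[["DQB1_9_F"]][2], 1)
  expect_equal(exp[["DQB1_9_Y"]][2], 1)
  expect_setequal(meta$group[startsWith(meta$variable, "DQB1_9")], "DQB1_9")
  expect_setequal(
    sub("DQB1_9_", "", meta$variable[meta$group == "DQB1_9"]),
    c("F", "Y", "L"))
  # residue counts sum to 2 per position for complete, sequenced genotypes
  for (g in unique(stats::na.omit(meta$group))) {
    vars <- meta$variable[meta$group == g]
    sums <- rowSums(as.matrix(tibble::as_tibble(exp)[vars]))
    expect_true(all(is.na(sums) | sums == 2))
  }
  # P3 carries DQB1*06:03 whose position 30 is unknown, but 30 is not
  # variable, so no variable exists for it
  expect_false(any(startsWith(meta$variable, "DQB1_30")))
})

test_that("unknown residues propagate as missing individuals", {
  # make position 23 vary via 03:01 (D) and give 06:03 unknown at 23
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# gene=DQB1", "# positions=9,23",
               "DQB1*02:01\tFV",
               "DQB1*03:01\tYD",
               "DQB1*06:03\tL*"), path)
  aln <- read_hla_alignment(path)
  calls <- tibble::tibble(ID = c("a", "b"),
                          DQB1_1 = c("DQB1*03:01", "DQB1*06:03"),
                          DQB1_2 = c("DQB1*02:01", "DQB1*02:01"))
  exp <- hla_aa_counts(calls, list(DQB1 = aln))
  expect_true(is.na(exp[["DQB1_23_D"]][2]))   # unknown side -> missing
  expect_equal(exp[["DQB1_23_D"]][1], 1)
  expect_equal(exp[["DQB1_9_L"]][2], 1)       # position 9 still observed
})

test_that("heterozygosity depends on the comparison resolution", {
  calls <- tibble::tibble(
    ID = c("a", "b", "c", "d"),
    A_1 = c("A*02:01", "A*02:01", "A*02:01:01:01", NA),
    A_2 = c("A*01:01", "A*02:01", "A*02:01:01:02", "A*02:01"))
  het2 <- hla_heterozygosity(calls, resolution = 2)
  expect_equal(het2$A_het, c(1, 0, 0, NA))
  het4 <- hla_heterozygosity(calls[3, ], resolution = 4)
  expect_equal(het4$A_het, 1)
})

test_that("Grantham divergence is zero for homozygotes, symmetric, and
           equals the per-position mean oracle", {
  m <- grantham_matrix()
  # matrix properties and formula anchors from the independent oracle
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m[upper.tri(m)] > 0))
  expect_equal(m["I", "L"], 5)
  expect_equal(m["L", "R"], 102)
  for (a in rownames(m)) for (b in colnames(m)) {
    expect_equal(m[a, b], oracle_grantham(a, b))
  }

  # 10-position alignment differing only Ile<->Leu at one position
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# gene=A", "# positions=1,2,3,4,5,6,7,8,9,10",
               "A*01:01\tIKAMVWYTSD",
               "A*02:01\tL---------",
               "A*03:01\t*---------"), path)
  aln <- read_hla_alignment(path)
  calls <- tibble::tibble(
    ID = c("hom", "het", "swap", "unk"),
    A_1 = c("A*01:01", "A*01:01", "A*02:01", "A*03:01"),
    A_2 = c("A*01:01", "A*02:01", "A*01:01", "A*01:01"))
  exp <- hla_divergence(calls, list(A = aln), region = 1:10)
  expect_equal(exp$A_divergence[1], 0)
  expect_equal(exp$A_divergence[2], 5 / 10)    # d(I,L) = 5 over 10 positions
  expect_equal(exp$A_divergence[3], exp$A_divergence[2])  # slot symmetry
  # unknown position excluded from numerator and denominator
  expect_equal(exp$A_divergence[4], 0)

  # brute-force oracle over explicit residue pairs on random genotypes
  cfg <- sim_config(n_individuals = 25, seed = 9)
  rc <- sim_hla_calls(cfg)[c("ID", "A_1", "A_2")]
  aln2 <- sim_alignment("A", names(default_allele_freqs()$A),
                        n_positions = 40, variable_positions =
                          list(`5` = c("F", "Y"), `11` = c("A", "S", "T"),
                               `20` = c("K", "R")),
                        unknown_rate = 0.03, seed = 10)
  got <- hla_divergence(rc, list(A = aln2), region = 1:40)$A_divergence
  r1 <- residues_at(aln2, rc$A_1, 1:40)
  r2 <- residues_at(aln2, rc$A_2, 1:40)
  for (i in seq_len(nrow(rc))) {
    ok <- r1[i, ] %in% rownames(m) & r2[i, ] %in% rownames(m)
    expect_equal(got[i], mean(m[cbind(r1[i, ok], r2[i, ok])]))
  }
})

test_that("NK ligand grouping counts copies and refines Bw4 by position 80", {
  calls <- tibble::tibble(
    ID = c("a", "b", "c"),
    B_1 = c("B*27:05", "B*07:02", "B*57:01"),
    B_2 = c("B*08:01", "B*07:02", "B*44:02"),
    C_1 = c("C*01:02", "C*04:01", "C*07:01"),
    C_2 = c("C*05:01", "C*06:02", "C*07:02"))
  suppressMessages(exp <- hla_nk_ligands(calls))
  expect_equal(exp$C1, c(1, 0, 2))
  expect_equal(exp$C2, c(1, 2, 0))
  expect_equal(exp$Bw4, c(1, 0, 2))
  expect_equal(exp$Bw6, c(1, 2, 0))

  # alignment with T/I dimorphism at 80: B*27:05 and B*57:01 carry T,
  # B*44:02 carries I, Bw6 alleles carry T but stay outside Bw4
  aln <- sim_alignment("B", c("B*07:02", "B*08:01", "B*27:05", "B*44:02",
                              "B*57:01"),
                       n_positions = 85,
                       variable_positions = list(`80` = c("T", "T", "T",
                                                          "I", "T")),
                       seed = 3)
  suppressMessages(ref <- hla_nk_ligands(calls, alignments = list(B = aln),
                                         refine_bw4_80 = TRUE))
  expect_equal(ref$Bw4_80T, c(1, 0, 1))
  expect_equal(ref$Bw4_80I, c(0, 0, 1))
  expect_equal(ref$Bw4_80T + ref$Bw4_80I, ref$Bw4)
})

test_that("KIR presence parsing accepts both dialects case-insensitively", {
  kir <- tibble::tibble(ID = c("a", "b", "c", "d"),
                        KIR2DL1 = c("Y", "0", "y", "1"),
                        KIR2DL3 = c("N", "n", "1", "2"))
  expect_warning(exp <- kir_presence(kir), "unrecognised")
  expect_equal(exp$KIR2DL1, c(1, 0, 1, 1))
  expect_equal(exp$KIR2DL3, c(0, 0, 1, NA))
  bad <- tibble::tibble(ID = "a", KIR2DL1 = "presence")
  expect_error(suppressWarnings(kir_presence(bad)), "no recognisable")
})

test_that("interaction coding is ligand-carrier AND receptor-presence", {
  lig <- hla_experiment(
    tibble::tibble(ID = c("a", "b", "c"), Bw4 = c(1, 0, 2),
                   Bw6 = c(1, 2, 0), C1 = c(1, 0, 0), C2 = c(1, 2, 0)),
    "hla_NK_ligands")
  kir <- kir_presence(tibble::tibble(
    ID = c("a", "b", "c"), KIR2DL1 = c("Y", "Y", "N"),
    KIR2DL2 = c("N", "Y", "Y"), KIR2DL3 = c("N", "N", "Y"),
    KIR2DS1 = c("N", "N", "N"), KIR2DS2 = c("N", "N", "N"),
    KIR3DL1 = c("Y", "N", "Y")))
  exp <- hla_kir_interactions(lig, kir)
  expect_equal(exp$KIR2DL1_C2, c(1, 1, 0))   # C2 carrier + receptor
  expect_equal(exp$KIR2DL3_C1, c(0, 0, 0))   # receptor absent or no ligand
  expect_equal(exp$KIR3DL1_Bw4, c(1, 0, 1))
  # all ligands zero -> all interactions zero
  expect_true(all(tibble::as_tibble(exp)[2, -1] %in%
                    c(0, exp$KIR2DL1_C2[2])))
  # absent receptor column is a configuration error
  expect_error(
    hla_kir_interactions(lig, subset_kir <- kir_presence(
      tibble::tibble(ID = "a", KIR2DL1 = "Y")),
      interactions = kir_interaction_table()),
    "absent column")
})

test_that("custom transforms honour binary, count and quantitative modes", {
  calls <- tibble::tibble(ID = c("x", "y"),
                          A_1 = c("A*01:01", "A*02:01"),
                          A_2 = c("A*02:01", "A*02:01"))
  d <- hla_dictionary(tibble::tibble(group = c("G", "G"),
                                     allele = c("A*01:01", "A*02:01")),
                      name = "toy")
  cnt <- hla_custom(calls, d, mode = "count")
  suppressMessages(ref <- hla_group_counts(calls, d, name = "hla_custom"))
  expect_equal(cnt$G, ref$G)
  bin <- hla_custom(calls, d, mode = "binary")
  expect_equal(bin$G, c(1, 1))
  q <- hla_dictionary(tibble::tibble(group = c("e", "e"),
                                     allele = c("A*01:01", "A*02:01"),
                                     value = c(1.5, 2.0)),
                      name = "expr")
  quant <- hla_custom(calls, q, mode = "quantitative")
  expect_equal(quant$expr_score, c(3.5, 4.0))
  no_val <- hla_dictionary(tibble::tibble(group = "e", allele = "A*01:01"),
                           name = "noval")
  expect_error(hla_custom(calls, no_val, mode = "quantitative"), "value")
})

test_that("dataset assembly enforces unique names and joins individuals", {
  calls <- tiny_calls()
  e1 <- hla_counts(calls, 2)
  e2 <- hla_heterozygosity(calls, 2)
  pheno <- tibble::tibble(ID = c(calls$ID, "P99"), outcome = rnorm(7))
  expect_message(ds <- hla_dataset(pheno, list(e1, e2)), "dropped")
  expect_equal(nrow(ds$pheno), 6)
  expect_named(ds$experiments, c("hla_alleles", "hla_het"))
  # duplicate variable names across experiments
  expect_error(hla_dataset(pheno, list(e1, e1)), "more than one experiment")
  # clash with phenotype columns
  ph2 <- dplyr::mutate(pheno, `A*02:01` = 1)
  expect_error(hla_dataset(ph2, list(e1)), "clash")
})
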
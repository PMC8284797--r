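# Small in-code fixtures and independent oracles shared across test files.

tiny_calls <- function() {
  tibble::tibble(
    ID = paste0("P", 1:6),
    A_1 = c("A*02:01", "A*02:01", "A*01:01", "A*03:01", "A*02:01", NA),
    A_2 = c("A*02:01", "A*01:01", "A*01:01", "A*11:01", "A*24:02", "A*02:01"),
    DQB1_1 = c("DQB1*03:01", "DQB1*02:01", "DQB1*05:01", "DQB1*03:01",
               "DQB1*06:02", "DQB1*02:01"),
    DQB1_2 = c("DQB1*03:01", "DQB1*03:01", "DQB1*06:03", "DQB1*02:01",
               "DQB1*06:02", "DQB1*02:01")
  )
}

dqb1_alignment <- function() {
  read_hla_alignment(system.file("extdata", "synthetic_DQB1_prot.txt",
                                 package = "hlakir", mustWork = TRUE))
}

# Independent recomputation of Grantham's distance straight from the
# published property table (kept separate from the package's matrix).
oracle_grantham <- function(a, b) {
  props <- data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F", "Y", "C", "H",
           "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0, 0.2, 2.75, 0.58,
          0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8, 8.6, 8.1, 5.9, 9, 5.2, 5.2, 6.2, 5.5, 10.4,
          10.5, 11.6, 11.3, 13, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132, 136, 55, 96, 85, 56,
          119, 54, 83, 105, 170)
  )
  i <- match(a, props$aa); j <- match(b, props$aa)
  round(50.723 * sqrt(1.833 * (props$c[i] - props$c[j])^2 +
                      0.1018 * (props$p[i] - props$p[j])^2 +
                      0.000399 * (props$v[i] - props$v[j])^2))
}

# Brute-force allele copy tally for one individual's reduced calls.
oracle_allele_counts <- function(calls, resolution) {
  genes <- unique(sub("_[12]$", "", setdiff(names(calls), "ID")))
  out <- list()
  for (i in seq_len(nrow(calls))) {
    for (g in genes) {
      a <- c(calls[[paste0(g, "_1")]][i], calls[[paste0(g, "_2")]][i])
      if (anyNA(a)) next
      a <- reduce_allele(a, resolution, strict = FALSE)
      if (anyNA(a)) next
      for (al in a) {
        key <- paste(calls$ID[i], al, sep = "|")
        out[[key]] <- (out[[key]] %||% 0) + 1
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact HWE heterozygote-count distribution by the Wigginton et al.
# recurrence, an independent route to the conditional probabilities.
oracle_hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  rare <- min(n1 + 2 * n2, n1 + 2 * n0)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  mid <- which.min(abs(hs - rare * (2 * n - rare) / (2 * n)))
  probs[mid] <- 1
  # downward recurrence: P(h-2)/P(h) = h(h-1) / (4 nhom1' nhom2')
  if (mid > 1) for (k in seq(mid, 2)) {
    h <- hs[k]
    nr <- (rare - h) / 2      # rare-allele homozygotes at h
    nc <- n - h - nr          # common homozygotes at h
    probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (nr + 1) * (nc + 1))
  }
  if (mid < length(hs)) for (k in seq(mid, length(hs) - 1)) {
    h <- hs[k]
    nr <- (rare - h) / 2
    nc <- n - h - nr
    probs[k + 1] <- probs[k] * 4 * nr * nc / ((h + 1) * (h + 2))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n1, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Independent single-fit oracle: fit the substituted model directly.
oracle_fit <- function(data, formula, family) {
  switch(family,
         linear = stats::lm(formula, data = data),
         logistic = stats::glm(formula, data = data, family = binomial()),
         cox = survival::coxph(formula, data = data, ties = "efron"))
}

# A ready-made small simulated dataset for engine tests.
small_sim_dataset <- function(n = 300, effects = c("A*02:01" = log(2)),
                              seed = 42, family = "binary",
                              covariate = TRUE) {
  cfg <- sim_config(n_individuals = n, effects = effects, family = family,
                    seed = seed)
  calls <- sim_hla_calls(cfg)
  alleles <- hla_counts(calls, resolution = 2)
  pheno <- sim_phenotype(alleles, cfg)
  if (covariate) {
    set.seed(seed + 7)
    pheno$age <- round(stats::rnorm(nrow(pheno), 50, 10), 1)
  }
  hla_dataset(pheno, list(hla_alleles = alleles), calls = calls)
}
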
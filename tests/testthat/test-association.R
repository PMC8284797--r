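test_that("inheritance encodings follow their definitions", {
  expect_equal(encode_inheritance(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_inheritance(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(encode_inheritance(c(0, 1, 2), "recessive"), c(0, 0, 1))
  expect_equal(encode_inheritance(c(0, 1, 2), "overdominant"), c(0, 1, 0))
  expect_equal(encode_inheritance(NA_real_, "dominant"), NA_real_)
})

test_that("p-value adjustment matches independent formulas and caps at 1", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.01, 10), "bonferroni"), rep(0.1, 10))
  expect_equal(adjust_pvalues(rep(0.4, 5), "bonferroni"), rep(1, 5))
  p <- c(0.3, 0.001, 0.05, 0.02)
  expect_equal(adjust_pvalues(p, "none"), p)
  expect_error(adjust_pvalues(p, "fdr_magic"), "unknown correction")
  # BH step-up computed independently on random vectors
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    m <- length(p)
    o <- order(p)
    bh <- numeric(m)
    bh[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
    expect_equal(adjust_pvalues(p, "BH"), pmin(1, bh))
    expect_true(all(adjust_pvalues(p, "holm") >= p))
  }
})

test_that("frequency filter splits on allele vs carrier frequency and is
           monotone in the window", {
  vals <- tibble::tibble(
    ID = paste0("i", 1:100),
    rare = rep(c(1, 0), c(2, 98)),       # allele freq 0.01
    common = rep(c(2, 1, 0), c(10, 30, 60)))  # allele freq 0.25
  exp <- hla_experiment(vals, "toy")
  kept <- frequency_filter(exp, lower = 0.02)
  expect_equal(setdiff(names(kept), "ID"), "common")
  expect_equal(setdiff(names(frequency_filter(exp, 0, 1)), "ID"),
               c("rare", "common"))
  # monotonicity: widening the window never removes a survivor
  for (lo in c(0.2, 0.1, 0.02, 0)) {
    wider <- setdiff(names(frequency_filter(exp, lo, 1)), "ID")
    expect_true(all(setdiff(names(kept), "ID") %in% wider) || lo > 0.02)
  }
  # continuous variables are exempt
  cont <- hla_experiment(
    tibble::tibble(ID = vals$ID, score = rnorm(100)), "div",
    tibble::tibble(variable = "score", type = "continuous"))
  expect_equal(setdiff(names(frequency_filter(cont, 0.4, 0.5)), "ID"),
               "score")
})

test_that("per-variable fits match independently scripted refits", {
  ds <- small_sim_dataset(n = 200, seed = 101)
  model <- hla_model(outcome ~ term + age, family = "logistic")
  res <- run_association(ds, model, "hla_alleles", lower_frequency = 0.05)
  exp <- ds$experiments$hla_alleles
  for (i in seq_len(nrow(res))) {
    v <- res$variable[i]
    d <- data.frame(y = ds$pheno$outcome, age = ds$pheno$age, x = exp[[v]])
    fit <- oracle_fit(d, y ~ x + age, "logistic")
    s <- summary(fit)$coefficients
    expect_equal(res$estimate[i], s["x", 1], tolerance = 1e-6)
    expect_equal(res$se[i], s["x", 2], tolerance = 1e-6)
    expect_equal(res$p[i], s["x", 4], tolerance = 1e-6)
  }
  expect_equal(res$p_adj, adjust_pvalues(res$p, "BH")[order(res$p_adj)],
               tolerance = 1e-12)
  expect_true(all(diff(res$p_adj) >= 0))
  expect_true(all(res$p_adj >= res$p))
})

test_that("linear and Cox families agree with direct refits", {
  cfg <- sim_config(n_individuals = 150, family = "continuous",
                    effects = c("A*02:01" = 0.5), seed = 77)
  calls <- sim_hla_calls(cfg)
  alleles <- hla_counts(calls, 2)
  pheno <- sim_phenotype(alleles, cfg)
  ds <- hla_dataset(pheno, list(alleles))
  res <- run_association(ds, hla_model(outcome ~ term, family = "linear"),
                         "hla_alleles", lower_frequency = 0.05)
  for (i in seq_len(nrow(res))) {
    d <- data.frame(y = ds$pheno$outcome,
                    x = ds$experiments$hla_alleles[[res$variable[i]]])
    s <- summary(oracle_fit(d, y ~ x, "linear"))$coefficients
    expect_equal(res$estimate[i], s["x", 1], tolerance = 1e-6)
    expect_equal(res$p[i], s["x", 4], tolerance = 1e-6)
  }

  cfgs <- sim_config(n_individuals = 150, family = "survival",
                     effects = c("A*02:01" = 0.6), seed = 78)
  callss <- sim_hla_calls(cfgs)
  alleless <- hla_counts(callss, 2)
  phenos <- sim_phenotype(alleless, cfgs)
  dss <- hla_dataset(phenos, list(alleless))
  ress <- run_association(
    dss, hla_model(survival::Surv(time, event) ~ term, family = "cox"),
    "hla_alleles", lower_frequency = 0.05)
  for (i in seq_len(nrow(ress))) {
    d <- data.frame(time = phenos$time, event = phenos$event,
                    x = alleless[[ress$variable[i]]])
    s <- summary(oracle_fit(d, survival::Surv(time, event) ~ x,
                            "cox"))$coefficients
    expect_equal(ress$estimate[i], s["x", "coef"], tolerance = 1e-6)
    expect_equal(ress$p[i], s["x", "Pr(>|z|)"], tolerance = 1e-6)
  }
})

test_that("interaction templates report the placeholder main effect", {
  ds <- small_sim_dataset(n = 200, seed = 103)
  ds$pheno$sex <- rep(c(0, 1), 100)
  model <- hla_model(outcome ~ term + sex + term:sex, family = "logistic")
  res <- run_association(ds, model, "hla_alleles", lower_frequency = 0.1)
  v <- res$variable[1]
  d <- data.frame(y = ds$pheno$outcome, sex = ds$pheno$sex,
                  x = ds$experiments$hla_alleles[[v]])
  s <- summary(oracle_fit(d, y ~ x + sex + x:sex, "logistic"))$coefficients
  expect_equal(res$estimate[1], s["x", 1], tolerance = 1e-6)
})

test_that("results are invariant to individual order and allele slot order", {
  ds <- small_sim_dataset(n = 150, seed = 104)
  model <- hla_model(outcome ~ term, family = "logistic")
  base <- tidy(run_association(ds, model, "hla_alleles",
                               lower_frequency = 0.05))

  # permute individuals everywhere
  set.seed(1)
  perm <- sample(nrow(ds$pheno))
  calls2 <- ds$calls[perm, ]
  pheno2 <- ds$pheno[perm, ]
  ds2 <- hla_dataset(pheno2, list(hla_counts(calls2, 2)))
  out2 <- tidy(run_association(ds2, model, "hla_alleles",
                               lower_frequency = 0.05))
  expect_equal(base, out2, tolerance = 1e-10)

  # swap _1/_2 slots
  calls3 <- ds$calls
  for (g in c("A", "B", "C", "DQB1")) {
    tmp <- calls3[[paste0(g, "_1")]]
    calls3[[paste0(g, "_1")]] <- calls3[[paste0(g, "_2")]]
    calls3[[paste0(g, "_2")]] <- tmp
  }
  ds3 <- hla_dataset(ds$pheno, list(hla_counts(calls3, 2)))
  out3 <- tidy(run_association(ds3, model, "hla_alleles",
                               lower_frequency = 0.05))
  expect_equal(base, out3, tolerance = 1e-10)
})

test_that("degenerate scans error informatively and rare fits are flagged", {
  ds <- small_sim_dataset(n = 100, seed = 105)
  model <- hla_model(outcome ~ term, family = "logistic")
  expect_error(run_association(ds, model, "hla_alleles",
                               lower_frequency = 0.999),
               "no variable left")
  expect_error(run_association(ds, model, "nonexistent"), "not found")
  # a constant variable gives an aliased, flagged row, not a crash
  exp <- ds$experiments$hla_alleles
  vals <- tibble::as_tibble(exp)
  vals$constant <- 1
  ds$experiments$hla_alleles <- hla_experiment(vals, "hla_alleles")
  res <- run_association(ds, model, "hla_alleles")
  row <- res[res$variable == "constant", ]
  expect_true(is.na(row$estimate))
  expect_match(row$note, "aliased")
})

test_that("planted logistic effects are recovered with near-nominal CI
           coverage and null p-values are uniform", {
  # CI coverage at the study condition: log-OR log(2) planted on a common
  # allele, checked over modest replicates (full-scale run in acceptance)
  hits <- 0
  reps <- 40
  for (s in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 600,
                      effects = c("A*02:01" = log(2)), seed = 2000 + s)
    calls <- sim_hla_calls(cfg)
    alleles <- hla_counts(calls, 2)
    pheno <- sim_phenotype(alleles, cfg)
    ds <- hla_dataset(pheno, list(alleles))
    res <- run_association(ds, hla_model(outcome ~ term, "logistic"),
                           "hla_alleles")
    row <- res[res$variable == "A*02:01", ]
    hits <- hits + (row$ci_lo <= log(2) && row$ci_hi >= log(2))
  }
  expect_gte(hits / reps, 0.80)   # 95% coverage; binomial noise at 40 reps

  # null uniformity via KS over pooled scans
  ps <- c()
  for (s in 1:10) {
    cfg <- sim_config(n_individuals = 300, seed = 3000 + s)
    calls <- sim_hla_calls(cfg)
    alleles <- hla_counts(calls, 2)
    pheno <- sim_phenotype(alleles, cfg)
    ds <- hla_dataset(pheno, list(alleles))
    res <- run_association(ds, hla_model(outcome ~ term, "logistic"),
                           "hla_alleles", lower_frequency = 0.05)
    ps <- c(ps, res$p)
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
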
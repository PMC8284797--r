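#' Simulation configuration
#'
#' Defines a synthetic immunogenetic study: cohort size, per-gene allele
#' frequency tables, KIR carrier frequencies, planted effects on the linear
#' predictor, the outcome family, and a mandatory seed. Every generator is a
#' pure function of this configuration -- the same config yields byte
#' identical data. The defaults sketch a small class I + DQB1 panel with a
#' common-to-rare allele frequency gradient, the shape typical of European
#' cohort data.
#'
#' @param n_individuals Cohort size.
#' @param allele_freqs Named list (by gene) of named numeric vectors of
#'   allele frequencies; each must sum to 1.
#' @param kir_freqs Named numeric vector of per-KIR-gene carrier
#'   frequencies.
#' @param effects Named numeric vector: planted effect sizes on the linear
#'   predictor scale (log-OR / beta / log-HR), keyed by variable name.
#' @param family Outcome family: `"binary"`, `"continuous"` or
#'   `"survival"`.
#' @param intercept Intercept of the linear predictor.
#' @param sigma Gaussian noise SD (continuous outcomes).
#' @param censor_max Upper bound of the uniform censoring time (survival).
#' @param ld_proxy Optional list `(source=, proxy=, correlation=)`: adds a
#'   proxy allele generated by copy-with-flip from an existing allele's
#'   carrier indicator at the flip rate matching the target correlation.
#' @param inbreeding Excess-homozygosity parameter in `[0, 1]` (0 = exact
#'   Hardy-Weinberg sampling by independent allele draws); used to test HWE
#'   power.
#' @param seed Integer seed; mandatory.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1000,
                       allele_freqs = default_allele_freqs(),
                       kir_freqs = default_kir_freqs(),
                       effects = numeric(),
                       family = c("binary", "continuous", "survival"),
                       intercept = 0, sigma = 1, censor_max = 10,
                       ld_proxy = NULL, inbreeding = 0, seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("sim_config requires an explicit seed",
                          call. = FALSE)
  for (g in names(allele_freqs)) {
    f <- allele_freqs[[g]]
    if (length(f) < 1 || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("allele frequencies for gene ", g, " must be non-negative and ",
           "sum to 1", call. = FALSE)
    }
  }
  structure(list(n_individuals = n_individuals,
                 allele_freqs = allele_freqs, kir_freqs = kir_freqs,
                 effects = effects, family = family, intercept = intercept,
                 sigma = sigma, censor_max = censor_max,
                 ld_proxy = ld_proxy, inbreeding = inbreeding,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_allele_freqs <- function() {
  list(
    A = c("A*01:01" = 0.18, "A*02:01" = 0.28, "A*03:01" = 0.14,
          "A*11:01" = 0.08, "A*24:02" = 0.12, "A*26:01" = 0.06,
          "A*32:01" = 0.05, "A*68:01" = 0.09),
    B = c("B*07:02" = 0.14, "B*08:01" = 0.12, "B*15:01" = 0.08,
          "B*27:05" = 0.05, "B*40:01" = 0.08, "B*44:02" = 0.12,
          "B*44:03" = 0.08, "B*51:01" = 0.10, "B*57:01" = 0.06,
          "B*58:01" = 0.17),
    C = c("C*01:02" = 0.06, "C*02:02" = 0.08, "C*03:04" = 0.10,
          "C*04:01" = 0.14, "C*05:01" = 0.10, "C*06:02" = 0.12,
          "C*07:01" = 0.18, "C*07:02" = 0.16, "C*12:03" = 0.06),
    DQB1 = c("DQB1*02:01" = 0.16, "DQB1*03:01" = 0.22,
             "DQB1*03:02" = 0.12, "DQB1*05:01" = 0.16,
             "DQB1*06:02" = 0.18, "DQB1*06:03" = 0.16)
  )
}

#' @rdname sim_config
#' @export
default_kir_freqs <- function() {
  c(KIR2DL1 = 0.97, KIR2DL2 = 0.55, KIR2DL3 = 0.88, KIR3DL1 = 0.94,
    KIR2DS1 = 0.40, KIR2DS2 = 0.55, KIR3DS1 = 0.40)
}

with_sim_seed <- function(cfg, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate an HLA calls table
#'
#' Draws two alleles per gene per individual independently from the gene's
#' frequency table (exact Hardy-Weinberg sampling), or with excess
#' homozygosity when the config's `inbreeding` parameter is positive (with
#' probability `inbreeding` the second allele copies the first). The
#' optional LD proxy adds one extra pseudo-gene whose carrier status equals
#' the source allele's indicator flipped at the rate matching the target
#' correlation.
#'
#' @param cfg A [sim_config()].
#' @return A calls tibble (`ID`, `<GENE>_1`, `<GENE>_2`).
#' @export
sim_hla_calls <- function(cfg) {
  with_sim_seed(cfg, 1L, {
    n <- cfg$n_individuals
    out <- tibble::tibble(ID = sprintf("S%04d", seq_len(n)))
    for (g in names(cfg$allele_freqs)) {
      f <- cfg$allele_freqs[[g]]
      a1 <- sample(names(f), n, replace = TRUE, prob = f)
      a2 <- sample(names(f), n, replace = TRUE, prob = f)
      if (cfg$inbreeding > 0) {
        copy <- stats::runif(n) < cfg$inbreeding
        a2[copy] <- a1[copy]
      }
      out[[paste0(g, "_1")]] <- a1
      out[[paste0(g, "_2")]] <- a2
    }
    if (!is.null(cfg$ld_proxy)) {
      out <- add_ld_proxy(out, cfg$ld_proxy)
    }
    out
  })
}

# Copy-with-flip proxy: carrier status of the source allele, flipped with
# probability (1 - r) / 2 to hit correlation ~ r, written as a biallelic
# pseudo-gene <proxy>_1/<proxy>_2 with presence/absence alleles.
add_ld_proxy <- function(calls, ld) {
  src <- ld$source
  gene <- sub("\\*.*$", "", src)
  carrier <- (calls[[paste0(gene, "_1")]] == src) |
    (calls[[paste0(gene, "_2")]] == src)
  flip <- stats::runif(nrow(calls)) < (1 - ld$correlation) / 2
  prox <- xor(carrier, flip)
  pg <- ld$proxy
  calls[[paste0(pg, "_1")]] <- ifelse(prox, paste0(pg, "*01:01"),
                                      paste0(pg, "*02:01"))
  calls[[paste0(pg, "_2")]] <- paste0(pg, "*02:01")
  calls
}

#' Simulate a KIR gene-content table
#'
#' Independent presence draws at the configured carrier frequencies,
#' emitted in the `Y`/`N` dialect so the presence parser is exercised.
#'
#' @param cfg A [sim_config()].
#' @return A tibble (`ID`, one `Y`/`N` column per KIR gene).
#' @export
sim_kir_calls <- function(cfg) {
  with_sim_seed(cfg, 2L, {
    n <- cfg$n_individuals
    out <- tibble::tibble(ID = sprintf("S%04d", seq_len(n)))
    for (g in names(cfg$kir_freqs)) {
      out[[g]] <- ifelse(stats::runif(n) < cfg$kir_freqs[[g]], "Y", "N")
    }
    out
  })
}

#' Simulate phenotypes with planted effects
#'
#' Builds the linear predictor `intercept + sum(effect * variable)` over the
#' configured planted-effect variables (looked up across the supplied
#' experiments) and draws the outcome: logistic link for binary, Gaussian
#' noise for continuous, exponential hazards with uniform censoring for
#' survival.
#'
#' @param experiments A named list of [hla_experiment()] objects containing
#'   every planted-effect variable.
#' @param cfg A [sim_config()].
#' @param covariates Optional tibble of extra covariate columns (with `ID`)
#'   to carry into the phenotype table.
#' @return A phenotype tibble: `ID` plus `outcome` (binary/continuous) or
#'   `time`/`event` (survival), plus any covariates.
#' @export
sim_phenotype <- function(experiments, cfg, covariates = NULL) {
  if (inherits(experiments, "hla_experiment")) {
    experiments <- list(experiments)
  }
  ids <- experiments[[1]]$ID
  lp <- rep(cfg$intercept, length(ids))
  for (v in names(cfg$effects)) {
    found <- FALSE
    for (e in experiments) {
      if (v %in% names(e)) {
        x <- e[[v]][match(ids, e$ID)]
        lp <- lp + cfg$effects[[v]] * ifelse(is.na(x), 0, x)
        found <- TRUE
        break
      }
    }
    if (!found) stop("planted-effect variable not found in experiments: ",
                     v, call. = FALSE)
  }
  with_sim_seed(cfg, 3L, {
    out <- tibble::tibble(ID = ids)
    if (cfg$family == "binary") {
      out$outcome <- stats::rbinom(length(ids), 1, stats::plogis(lp))
    } else if (cfg$family == "continuous") {
      out$outcome <- lp + stats::rnorm(length(ids), sd = cfg$sigma)
    } else {
      t_event <- stats::rexp(length(ids), rate = exp(lp))
      t_cens <- stats::runif(length(ids), 0, cfg$censor_max)
      out$time <- pmin(t_event, t_cens)
      out$event <- as.integer(t_event <= t_cens)
    }
    if (!is.null(covariates)) {
      out <- dplyr::left_join(out, covariates, by = "ID")
    }
    out
  })
}

#' Generate a synthetic protein alignment
#'
#' Writes a small alignment in the normalised text layout: an invented but
#' grammatically valid set of allele rows for one gene, a fully explicit
#' reference, and configurable variable positions with specified residue
#' sets (all other positions constant). Non-reference rows use the identity
#' code `-`; unknown (`*`) and indel (`.`) codes are injected at the given
#' rates.
#'
#' @param gene Locus symbol.
#' @param alleles Character vector of allele names to include (first is the
#'   reference).
#' @param n_positions Alignment width.
#' @param variable_positions Named list: position label -> character vector
#'   of residues to cycle through across alleles (e.g. `list(\`9\` =
#'   c("F", "Y", "L"))`).
#' @param unknown_rate,indel_rate Per-cell rates of `*` and `.` codes in
#'   non-reference rows (never at the configured variable positions).
#' @param seed Integer seed.
#' @return An `hla_alignment` (write it with [write_hla_alignment()]).
#' @export
sim_alignment <- function(gene, alleles, n_positions = 30,
                          variable_positions = list(),
                          unknown_rate = 0, indel_rate = 0, seed) {
  cfg <- list(seed = as.integer(seed))
  with_sim_seed(cfg, 4L, {
    aas <- rownames(grantham_matrix())
    positions <- seq_len(n_positions)
    ref <- sample(aas, n_positions, replace = TRUE)
    var_pos <- as.integer(names(variable_positions))
    stopifnot(all(var_pos %in% positions))
    for (k in seq_along(variable_positions)) {
      ref[var_pos[k]] <- variable_positions[[k]][1]
    }
    mat <- matrix(rep(ref, each = length(alleles)),
                  nrow = length(alleles))
    for (k in seq_along(variable_positions)) {
      res <- variable_positions[[k]]
      mat[, var_pos[k]] <- rep_len(res, length(alleles))
    }
    if (unknown_rate > 0 || indel_rate > 0) {
      for (i in seq_along(alleles)[-1]) {
        for (j in setdiff(positions, var_pos)) {
          u <- stats::runif(1)
          if (u < unknown_rate) mat[i, j] <- ALN_UNKNOWN
          else if (u < unknown_rate + indel_rate) mat[i, j] <- ALN_INDEL
        }
      }
    }
    new_alignment(gene, positions, alleles, mat)
  })
}
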
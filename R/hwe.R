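#' Hardy-Weinberg equilibrium testing
#'
#' Tests every copy-count variable of an experiment for deviation from
#' Hardy-Weinberg proportions, collapsing each allele to a biallelic
#' allele-vs-rest genotype table (n0, n1, n2). The default test is the 1-df
#' chi-square of observed against expected counts under the estimated allele
#' frequency; `test = "exact"` uses the Levene-Haldane conditional
#' distribution of the heterozygote count (two-sided, summing all outcomes
#' no more probable than the observed one). Variables with fewer than two
#' observed genotype classes are skipped and flagged.
#'
#' @param experiment A copy-count [hla_experiment()].
#' @param mode `"report"` returns the per-variable p-value table;
#'   `"filter"` returns the experiment with variables at `p < alpha`
#'   removed (skipped variables are retained).
#' @param alpha Filtering threshold.
#' @param test `"chisq"` or `"exact"`.
#' @return A tibble (`variable`, `n0`, `n1`, `n2`, `statistic`, `p`,
#'   `note`) in report mode; a filtered experiment in filter mode.
#' @export
hwe_test <- function(experiment, mode = c("report", "filter"),
                     alpha = 0.05, test = c("chisq", "exact")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  vars <- experiment_variables(experiment)
  meta <- var_meta(experiment)
  rows <- lapply(vars, function(v) {
    if (meta$type[meta$variable == v] != "count") {
      return(tibble::tibble(variable = v, n0 = NA_integer_,
                            n1 = NA_integer_, n2 = NA_integer_,
                            statistic = NA_real_, p = NA_real_,
                            note = "not a copy-count variable"))
    }
    x <- experiment[[v]]
    x <- x[!is.na(x)]
    n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
    if (sum(c(n0, n1, n2) > 0) < 2) {
      return(tibble::tibble(variable = v, n0 = n0, n1 = n1, n2 = n2,
                            statistic = NA_real_, p = NA_real_,
                            note = "fewer than 2 genotype classes"))
    }
    if (test == "chisq") {
      r <- hwe_chisq(n0, n1, n2)
    } else {
      r <- list(statistic = NA_real_, p = hwe_exact(n0, n1, n2))
    }
    tibble::tibble(variable = v, n0 = n0, n1 = n1, n2 = n2,
                   statistic = r$statistic, p = r$p, note = NA_character_)
  })
  report <- dplyr::bind_rows(rows)
  if (mode == "report") return(report)
  drop <- report$variable[!is.na(report$p) & report$p < alpha]
  if (length(drop)) {
    message(length(drop), " variable(s) removed at HWE p < ", alpha)
  }
  subset_experiment(experiment, setdiff(vars, drop))
}

# 1-df chi-square against expected genotype counts at the ML allele
# frequency (no continuity correction).
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Levene-Haldane exact test: the heterozygote count conditional on allele
# counts has P(h) = 2^h n! nA! nB! / (nAA! h! nBB! (2n)!); the two-sided
# p-value sums every outcome no more probable than the observed one.
hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2 * n2
  nB <- 2 * n - nA
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    h * log(2) + lgamma(n + 1) + lgamma(nA + 1) + lgamma(nB + 1) -
      lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) - lgamma(2 * n + 1)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n1, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}
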
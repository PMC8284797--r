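#' Grantham physicochemical distance matrix
#'
#' Grantham's distance between two amino acids combines their difference in
#' side-chain composition (c, the atomic weight ratio of non-carbon atoms),
#' polarity (p) and molecular volume (v):
#'
#'   d(i, j) = rho * sqrt(alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 +
#'                        gamma (v_i - v_j)^2)
#'
#' with alpha = 1.833, beta = 0.1018, gamma = 0.000399 and the scale factor
#' rho = 50.723 chosen so the mean inter-residue distance is 100. The matrix
#' is computed from the published property table and rounded to integers,
#' reproducing the published distances (e.g. d(Ile, Leu) = 5,
#' d(Leu, Arg) = 102). Averaged over aligned peptide-binding-region
#' positions of an individual's two alleles it measures HLA evolutionary
#' divergence.
#'
#' @return A symmetric 20x20 numeric matrix with zero diagonal, rows and
#'   columns named by one-letter amino-acid codes.
#' @export
grantham_matrix <- function() {
  props <- grantham_properties()
  d <- function(i, j) {
    sqrt(1.833 * (props$c[i] - props$c[j])^2 +
         0.1018 * (props$p[i] - props$p[j])^2 +
         0.000399 * (props$v[i] - props$v[j])^2) * 50.723
  }
  n <- nrow(props)
  m <- outer(seq_len(n), seq_len(n), d)
  m <- round(m)
  dimnames(m) <- list(props$aa, props$aa)
  m
}

# Grantham's 1974 side-chain property table: composition, polarity, volume.
grantham_properties <- function() {
  tibble::tribble(
    ~aa,  ~c,   ~p,   ~v,
    "S", 1.42,  9.2,  32,
    "R", 0.65, 10.5, 124,
    "L", 0.00,  4.9, 111,
    "P", 0.39,  8.0,  32.5,
    "T", 0.71,  8.6,  61,
    "A", 0.00,  8.1,  31,
    "V", 0.00,  5.9,  84,
    "G", 0.74,  9.0,   3,
    "I", 0.00,  5.2, 111,
    "F", 0.00,  5.2, 132,
    "Y", 0.20,  6.2, 136,
    "C", 2.75,  5.5,  55,
    "H", 0.58, 10.4,  96,
    "Q", 0.89, 10.5,  85,
    "N", 1.33, 11.6,  56,
    "K", 0.33, 11.3, 119,
    "D", 1.38, 13.0,  54,
    "E", 0.92, 12.3,  83,
    "M", 0.00,  5.7, 105,
    "W", 0.13,  5.4, 170
  )
}
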
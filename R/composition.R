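# Amino-acid composition tables.
#
# The vertebrate background is the reference expectation against which
# region-wide residue bias is judged ("noncharged" CB calls).  Values are
# average vertebrate/SwissProt frequencies; the constructor renormalises so
# downstream ratios are exact.

.AA_BACKGROUND_VERTEBRATE <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.025,
  Q = 0.040, E = 0.063, G = 0.074, H = 0.026, I = 0.045,
  L = 0.093, K = 0.057, M = 0.018, F = 0.039, P = 0.052,
  S = 0.081, T = 0.059, W = 0.013, Y = 0.032, V = 0.066)

#' Background amino-acid composition
#'
#' Returns the 20-entry amino-acid frequency table used as the "normally
#' expected" composition when scoring residue bias.  The built-in default is
#' an average vertebrate composition; supply `freq` (a named numeric vector
#' over the 20 canonical letters) to replace it, e.g. from a proteome-specific
#' count table.
#'
#' @param freq optional named numeric vector of residue frequencies.
#' @return named numeric vector over the 20 canonical amino acids, summing
#'   to 1.
#' @export
#' @examples
#' bg <- background_composition()
#' sum(bg)
background_composition <- function(freq = NULL) {
  f <- freq %||% .AA_BACKGROUND_VERTEBRATE
  if (!is.numeric(f) || is.null(names(f)))
    stopf("background composition must be a named numeric vector")
  missing <- setdiff(AA_CANONICAL, names(f))
  if (length(missing))
    stopf("background composition lacks residues: %s",
          paste(missing, collapse = ", "))
  f <- f[AA_CANONICAL]
  if (any(f <= 0)) stopf("background frequencies must be positive")
  f / sum(f)
}

#' Read a background composition from a two-column TSV
#'
#' Expects columns `residue` and `frequency`.
#'
#' @param path file path.
#' @return normalised named frequency vector (see [background_composition()]).
#' @export
read_background <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "frequency") %in% names(tab)))
    stopf("background TSV needs columns residue, frequency")
  background_composition(stats::setNames(tab$frequency, tab$residue))
}

# ---- generator compositions (documented constants) -------------------------
#
# Two backgrounds drive sequence emission in the synthetic module:
# disorder-promoting (enriched in P, Q, S, G, E, K, A, N; depleted in
# hydrophobics) and globular.  The disordered table is deliberately kept
# below every CB typing threshold in expectation so that planted segments,
# not background drift, carry the compositional signal (window-level tail
# probabilities are worked through in the methods vignette).

.SIM_COMP_DISORDERED <- c(
  A = 0.085, C = 0.005, D = 0.015, E = 0.035, F = 0.015,
  G = 0.040, H = 0.030, I = 0.025, K = 0.030, L = 0.055,
  M = 0.015, N = 0.090, P = 0.110, Q = 0.075, R = 0.010,
  S = 0.155, T = 0.050, V = 0.045, W = 0.005, Y = 0.020)

.SIM_COMP_ORDERED <- c(
  A = 0.080, C = 0.020, D = 0.050, E = 0.060, F = 0.050,
  G = 0.065, H = 0.022, I = 0.070, K = 0.058, L = 0.110,
  M = 0.024, N = 0.040, P = 0.040, Q = 0.035, R = 0.042,
  S = 0.060, T = 0.055, V = 0.080, W = 0.015, Y = 0.040)

# Planted compositionally biased segment emitters, one per CB subtype.
.SIM_COMP_PLANTED <- list(
  CB_RS = c(R = 0.36, S = 0.36, G = 0.04, P = 0.05, D = 0.04,
            E = 0.05, K = 0.04, A = 0.03, T = 0.03),
  CB_PQ = c(P = 0.28, Q = 0.28, S = 0.10, A = 0.08, G = 0.06,
            T = 0.06, N = 0.06, E = 0.04, H = 0.04),
  CB_G = c(G = 0.50, R = 0.12, S = 0.03, A = 0.06, Y = 0.03,
           F = 0.02, N = 0.06, Q = 0.05, P = 0.05, T = 0.04,
           D = 0.03),
  CB_CHARGED = c(E = 0.28, K = 0.24, D = 0.14, R = 0.06, S = 0.04,
                 P = 0.06, A = 0.06, G = 0.04, Q = 0.04, T = 0.04))

sim_composition <- function(which = c("disordered", "ordered")) {
  which <- match.arg(which)
  f <- if (which == "disordered") .SIM_COMP_DISORDERED else .SIM_COMP_ORDERED
  f / sum(f)
}
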
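# Internal helpers shared across modules.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(offset)
}

split_set <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_set <- function(x) paste(x, collapse = ";")

#' Named vector of protein sequence lengths
#'
#' @param proteins protein table with columns `id` and `sequence`
#'   (as returned by [read_fasta()] or [simulate_proteins()]).
#' @return integer vector of residue counts named by protein id.
#' @export
protein_lengths <- function(proteins) {
  stats::setNames(nchar(proteins$sequence), proteins$id)
}

new_stat_test <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n = n),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      "  p =", format(x$p_value, digits = 4),
      "  n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}
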
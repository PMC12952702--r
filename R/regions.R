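# Segmentation of per-residue disorder scores into ordered/disordered
# regions, and the per-group disorder summaries (per-protein vs per-residue
# means, box-plot five-number statistics).

new_region <- function(protein_id, start, end, kind) {
  data.frame(protein_id = protein_id, start = as.integer(start),
             end = as.integer(end), kind = kind, subtype = "NONE",
             cb_subtype = "NONE", alpha_frac = 0, beta_frac = 0,
             stringsAsFactors = FALSE)
}

#' Call ordered/disordered regions from a per-residue disorder profile
#'
#' Residues with score `>= threshold` are disorder-positive.  Maximal
#' positive runs separated by at most `max_gap` negative residues are merged
#' (the absorbed gap residues become part of the disordered region); merged
#' runs spanning fewer than `min_len` residues are dropped.  The complement
#' is emitted as ORDERED regions, so the result tiles `1..L` exactly.
#'
#' Binary 0/1 disorder labels pass through the same thresholding unchanged.
#'
#' @param scores numeric vector of per-residue scores in \[0,1\].
#' @param threshold binarisation threshold in (0,1); default 0.5.
#' @param min_len minimum disordered-region span; default 1.
#' @param max_gap largest run of negative residues bridged when merging;
#'   default 0 (no smoothing).
#' @param protein_id id recorded in the output rows.
#' @return region data.frame tiling `1..length(scores)`.
#' @export
#' @examples
#' call_regions(c(rep(0.9, 30), rep(0.1, 10), rep(0.9, 30)),
#'              threshold = 0.5, min_len = 25, protein_id = "P1")
call_regions <- function(scores, threshold = 0.5, min_len = 1L,
                         max_gap = 0L, protein_id = "protein") {
  if (!is.numeric(scores) || length(scores) < 1)
    stopf("scores must be a non-empty numeric vector")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stopf("scores must lie in [0,1]")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  if (min_len < 1) stopf("min_len must be >= 1")
  if (max_gap < 0) stopf("max_gap must be >= 0")
  L <- length(scores)
  pos <- scores >= threshold

  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dis <- which(runs$values)
  segs <- if (length(dis)) cbind(starts[dis], ends[dis]) else
    matrix(integer(0), ncol = 2)

  # merge positive runs across short internal gaps
  if (nrow(segs) > 1 && max_gap > 0) {
    merged <- segs[1, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      gap <- segs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap <= max_gap) merged[nrow(merged), 2] <- segs[i, 2]
      else merged <- rbind(merged, segs[i, ])
    }
    segs <- merged
  }
  if (nrow(segs))
    segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_len, , drop = FALSE]

  out <- list()
  cursor <- 1L
  if (nrow(segs)) for (i in seq_len(nrow(segs))) {
    if (segs[i, 1] > cursor)
      out[[length(out) + 1L]] <-
        new_region(protein_id, cursor, segs[i, 1] - 1L, "ORDERED")
    out[[length(out) + 1L]] <-
      new_region(protein_id, segs[i, 1], segs[i, 2], "DISORDERED")
    cursor <- segs[i, 2] + 1L
  }
  if (cursor <= L)
    out[[length(out) + 1L]] <- new_region(protein_id, cursor, L, "ORDERED")
  do.call(rbind, out)
}

#' @rdname call_regions
#' @param profiles named list of score vectors (one per protein).
#' @export
call_regions_all <- function(profiles, threshold = 0.5, min_len = 1L,
                             max_gap = 0L) {
  do.call(rbind, lapply(names(profiles), function(pid)
    call_regions(profiles[[pid]], threshold, min_len, max_gap, pid)))
}

# Check that `regions` for one protein tile 1..length exactly.
check_tiling <- function(regions, length, protein_id = NULL) {
  r <- regions[order(regions$start), , drop = FALSE]
  ok <- nrow(r) > 0 && r$start[1] == 1L && r$end[nrow(r)] == length &&
    (nrow(r) == 1 || all(r$start[-1] == r$end[-nrow(r)] + 1L))
  if (!ok)
    stopf("regions do not tile 1..%d%s", length,
          if (is.null(protein_id)) "" else sprintf(" for protein %s", protein_id))
  invisible(TRUE)
}

#' Percentage of disordered residues in a tiled region set
#'
#' @param regions regions of a single protein, tiling `1..length`.
#' @param length protein length.
#' @return percentage in \[0,100\].
#' @export
disorder_fraction <- function(regions, length) {
  check_tiling(regions, length)
  d <- regions$kind == "DISORDERED"
  100 * sum(regions$end[d] - regions$start[d] + 1L) / length
}

# Per-protein disorder percentages and lengths for a full region table.
per_protein_disorder <- function(proteins, regions) {
  len <- protein_lengths(proteins)
  pct <- vapply(proteins$id, function(pid) {
    r <- regions[regions$protein_id == pid, , drop = FALSE]
    if (!nrow(r)) stopf("protein %s has no regions", pid)
    disorder_fraction(r, len[[pid]])
  }, numeric(1))
  data.frame(protein_id = proteins$id, length = as.integer(len[proteins$id]),
             disorder_pct = pct, stringsAsFactors = FALSE, row.names = NULL)
}

#' Group-level disorder summaries (box-plot statistics)
#'
#' For each group the summary reports the unweighted mean of per-protein
#' disorder percentages (`per_protein_mean`), the residue-weighted
#' percentage (`per_residue_mean` = 100 x total disordered residues / total
#' residues), the five-number summary (min, Q1, median, Q3, max; quartiles
#' by the type-7 linear-interpolation convention) of the per-protein
#' percentages, and Tukey outliers beyond `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR`.
#'
#' A protein contributes to every complex it belongs to.  Empty groups
#' yield `n_proteins = 0` rows with NA statistics rather than an error.
#'
#' @param proteins protein table with metadata columns `group`, `complexes`.
#' @param regions tiled region table covering the proteins.
#' @param by `"complex"` (explode the complexes set) or `"class"` (the
#'   `group` column).
#' @return data.frame with one row per group.
#' @export
summarize_group <- function(proteins, regions, by = c("complex", "class")) {
  by <- match.arg(by)
  pp <- per_protein_disorder(proteins, regions)
  if (by == "complex") {
    labels <- lapply(proteins$complexes, split_set)
    expand <- data.frame(
      group = unlist(labels),
      protein_id = rep(proteins$id, lengths(labels)),
      stringsAsFactors = FALSE)
  } else {
    expand <- data.frame(group = proteins$group, protein_id = proteins$id,
                         stringsAsFactors = FALSE)
    expand <- expand[!is.na(expand$group), , drop = FALSE]
  }
  out <- lapply(sort(unique(expand$group)), function(g) {
    ids <- expand$protein_id[expand$group == g]
    sub <- pp[match(ids, pp$protein_id), , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(group = g, n_proteins = 0L, per_protein_mean = NA_real_,
                        per_residue_mean = NA_real_, min = NA_real_,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                        max = NA_real_, outliers = "", stringsAsFactors = FALSE))
    q <- stats::quantile(sub$disorder_pct, c(0.25, 0.5, 0.75),
                         type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    out_idx <- sub$disorder_pct < q[1] - 1.5 * iqr |
      sub$disorder_pct > q[3] + 1.5 * iqr
    data.frame(
      group = g, n_proteins = nrow(sub),
      per_protein_mean = mean(sub$disorder_pct),
      per_residue_mean = 100 * sum(sub$disorder_pct / 100 * sub$length) /
        sum(sub$length),
      min = min(sub$disorder_pct), q1 = q[1], median = q[2], q3 = q[3],
      max = max(sub$disorder_pct),
      outliers = join_set(sprintf("%s:%.2f", sub$protein_id[out_idx],
                                  sub$disorder_pct[out_idx])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sliding-window charge/hydropathy disorder heuristic (demo plumbing)
#'
#' A deliberately simple stand-in score for demonstrations and smoke tests:
#' over a centred window it combines low Kyte-Doolittle hydropathy with
#' charged-residue content, mapped through a logistic.  It is NOT a disorder
#' predictor and carries no benchmark claim; real analyses should consume
#' per-residue scores from a dedicated predictor via [read_profile_table()].
#'
#' @param sequence amino-acid string.
#' @param window odd window width (default 21).
#' @return numeric vector of per-residue scores in \[0,1\].
#' @export
fallback_disorder_score <- function(sequence, window = 21L) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  aa <- strsplit(toupper(sequence), "")[[1]]
  h <- kd[aa]; h[is.na(h)] <- 0
  chg <- as.numeric(aa %in% c("D", "E", "K", "R"))
  half <- (window - 1L) %/% 2L
  n <- length(aa)
  sm <- function(x) vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
  z <- -0.9 * sm(h) + 3.5 * sm(chg) - 0.4
  1 / (1 + exp(-2 * z))
}
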
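# PTM statistics: residue-level partition of PTM-bearing sites by region
# kind, Fisher exact enrichment on the pooled 2x2 table, per-protein PTM
# density comparison (paired Wilcoxon), and annotation-level type
# ratios/distributions.

# Logical disorder mask per protein from a tiled region table.
disorder_masks <- function(regions, lengths) {
  masks <- list()
  for (pid in names(lengths)) {
    r <- regions[regions$protein_id == pid, , drop = FALSE]
    if (!nrow(r)) next
    check_tiling(r, lengths[[pid]], pid)
    m <- rep(FALSE, lengths[[pid]])
    d <- r[r$kind == "DISORDERED", , drop = FALSE]
    for (i in seq_len(nrow(d))) m[d$start[i]:d$end[i]] <- TRUE
    masks[[pid]] <- m
  }
  masks
}

#' Partition PTM sites between disordered and ordered regions
#'
#' Counting is residue-level: a residue carrying one or more PTM annotations
#' is a single PTM-bearing site, and every other residue is a non-PTM site.
#' Per-protein counts therefore sum to the protein length, and the pooled
#' 2x2 table (a = PTM in IDR, b = no-PTM in IDR, c = PTM in ordered,
#' d = no-PTM in ordered) is the per-protein sum.
#'
#' @param sites validated PTM site table.
#' @param regions tiled region table.
#' @param lengths named protein lengths (see [protein_lengths()]).
#' @return object of class `ptm_partition`: list with `per_protein`
#'   (data.frame) and `pooled` (named vector a,b,c,d).
#' @export
partition_ptms <- function(sites, regions, lengths) {
  orphans <- setdiff(unique(sites$protein_id), unique(regions$protein_id))
  if (length(orphans))
    stopf("site(s) on protein(s) without regions: %s",
          paste(orphans, collapse = ", "))
  masks <- disorder_masks(regions, lengths)
  per <- lapply(names(masks), function(pid) {
    m <- masks[[pid]]
    ptm_pos <- unique(sites$position[sites$protein_id == pid])
    has <- rep(FALSE, length(m)); has[ptm_pos] <- TRUE
    data.frame(protein_id = pid,
               ptm_in_idr = sum(has & m), non_ptm_in_idr = sum(!has & m),
               ptm_in_ordered = sum(has & !m),
               non_ptm_in_ordered = sum(!has & !m),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  pooled <- c(a = sum(per$ptm_in_idr), b = sum(per$non_ptm_in_idr),
              c = sum(per$ptm_in_ordered), d = sum(per$non_ptm_in_ordered))
  structure(list(per_protein = per, pooled = pooled),
            class = "ptm_partition")
}

#' Fisher exact enrichment test on a 2x2 site table
#'
#' The p-value is the exact (conditional hypergeometric) Fisher test from
#' [stats::fisher.test()]; the reported statistic is the sample odds ratio
#' `(a d)/(b c)`, with the convention `Inf` when `b c = 0` and `a d > 0`
#' (the conditional-MLE odds ratio is not used).
#'
#' @param table a `ptm_partition`, or a numeric vector `c(a, b, c, d)` with
#'   a = feature-positive disordered, b = feature-negative disordered,
#'   c = feature-positive ordered, d = feature-negative ordered.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return [new_stat_test()] result with the odds ratio as statistic.
#' @export
#' @examples
#' fisher_enrichment(c(1012, 32068, 831, 78059))
fisher_enrichment <- function(table,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- if (inherits(table, "ptm_partition")) table$pooled else table
  if (length(x) != 4 || any(x < 0) || any(x != floor(x)))
    stopf("need four non-negative integer counts a, b, c, d")
  if (sum(x) < 1) stopf("all-zero contingency table")
  m <- matrix(as.numeric(x), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = sub("two_sided", "two.sided",
                                                alternative))
  or <- if (x[2] * x[3] == 0) {
    if (x[1] * x[4] > 0) Inf else NaN
  } else (x[1] * x[4]) / (x[2] * x[3])
  new_stat_test(or, ft$p.value,
                sprintf("Fisher exact test (%s), sample odds ratio",
                        alternative),
                n = sum(x))
}

#' Compare per-protein PTM densities between compartments
#'
#' Computes for each protein the PTM density in its disordered part
#' (`ptm_in_idr / idr_len`) and its ordered part, and tests the paired
#' differences with a Wilcoxon signed-rank test (zero differences dropped;
#' exact distribution for up to 25 informative pairs without rank ties,
#' normal approximation with continuity correction otherwise).  Proteins
#' lacking either compartment are excluded, with a message.  An unpaired
#' rank-sum variant is available via `paired = FALSE`.
#'
#' @param partition a `ptm_partition`.
#' @param alternative `"two_sided"`, `"greater"` (IDR density larger) or
#'   `"less"`.
#' @param paired use the paired signed-rank test (default TRUE).
#' @return [new_stat_test()] result.
#' @export
density_comparison <- function(partition,
                               alternative = c("two_sided", "greater", "less"),
                               paired = TRUE) {
  alternative <- match.arg(alternative)
  per <- partition$per_protein
  idr_len <- per$ptm_in_idr + per$non_ptm_in_idr
  ord_len <- per$ptm_in_ordered + per$non_ptm_in_ordered
  usable <- idr_len > 0 & ord_len > 0
  if (sum(!usable))
    message(sprintf("density_comparison: %d protein(s) lack a compartment; excluded",
                    sum(!usable)))
  d_idr <- per$ptm_in_idr[usable] / idr_len[usable]
  d_ord <- per$ptm_in_ordered[usable] / ord_len[usable]
  if (length(d_idr) < 2) stopf("fewer than 2 usable protein pairs")
  if (paired && all(d_idr == d_ord)) stopf("no nonzero pairs")
  n_inf <- sum(d_idr != d_ord)
  alt <- sub("two_sided", "two.sided", alternative)
  wt <- suppressWarnings(stats::wilcox.test(
    d_idr, d_ord, paired = paired, alternative = alt,
    exact = if (paired) n_inf <= 25 else NULL, correct = TRUE))
  new_stat_test(unname(wt$statistic), wt$p.value,
                paste0(wt$method, " on per-protein PTM densities"),
                n = length(d_idr))
}

# annotation-level in-IDR indicator for each site row
site_in_idr <- function(sites, regions) {
  d <- regions[regions$kind == "DISORDERED", , drop = FALSE]
  vapply(seq_len(nrow(sites)), function(i) {
    any(d$protein_id == sites$protein_id[i] &
          d$start <= sites$position[i] & d$end >= sites$position[i])
  }, logical(1))
}

#' Per-type ratio of PTMs falling inside IDRs
#'
#' Annotation-level: for each PTM type, the number of annotations in IDRs
#' divided by the total number of annotations of that type across the whole
#' sequence set.  Types with zero total are omitted.
#'
#' @param sites PTM site table.
#' @param regions tiled region table.
#' @return data.frame with columns `label`, `n_total`, `n_idr`, `ratio`,
#'   sorted by decreasing ratio.
#' @export
ptm_idr_ratio <- function(sites, regions) {
  if (!nrow(sites))
    return(data.frame(label = character(0), n_total = integer(0),
                      n_idr = integer(0), ratio = numeric(0)))
  inidr <- site_in_idr(sites, regions)
  tot <- table(sites$label)
  idr <- table(factor(sites$label[inidr], levels = names(tot)))
  out <- data.frame(label = names(tot), n_total = as.integer(tot),
                    n_idr = as.integer(idr),
                    ratio = as.integer(idr) / as.integer(tot),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$ratio, out$label), , drop = FALSE]
}

#' Percentage distribution of PTM types
#'
#' The percentage of each PTM type is its annotation count divided by the
#' total count of all PTM annotations in the chosen scope, times 100; the
#' column sums to 100 within every stratum.  With `groups` supplied the
#' distribution is additionally reported per protein class.
#'
#' @param sites PTM site table.
#' @param regions tiled region table (needed for `scope = "idr_only"`).
#' @param scope `"idr_only"` (PTMs inside IDRs) or `"all"`.
#' @param groups optional named vector mapping protein id to class label.
#' @return data.frame with columns `group` (`"(all)"` for the overall
#'   stratum), `label`, `n`, `percent`.
#' @export
ptm_type_distribution <- function(sites, regions,
                                  scope = c("idr_only", "all"),
                                  groups = NULL) {
  scope <- match.arg(scope)
  use <- if (scope == "idr_only" && nrow(sites))
    sites[site_in_idr(sites, regions), , drop = FALSE] else sites
  strata <- list(`(all)` = use)
  if (!is.null(groups) && nrow(use)) {
    g <- groups[use$protein_id]
    for (lab in sort(unique(g[!is.na(g)])))
      strata[[lab]] <- use[!is.na(g) & g == lab, , drop = FALSE]
  }
  rows <- lapply(names(strata), function(s) {
    sub <- strata[[s]]
    if (!nrow(sub)) return(NULL)
    tab <- table(sub$label)
    data.frame(group = s, label = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), label = character(0),
                      n = integer(0), percent = numeric(0))
  out
}
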
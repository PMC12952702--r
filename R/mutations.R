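# Cancer-associated mutation analysis: mapping variants onto regions,
# per-family and per-tumor-type summaries, and the PTM-flanking analysis
# ("within five residues") with a within-protein permutation null.

#' Map mutations onto called regions
#'
#' Labels each mutation record with the kind and subtype of the region it
#' falls in, and summarises (i) distinct mutated residues inside IDRs per
#' protein family and (ii) mutation records inside IDRs per tumor type.
#'
#' @param sites validated mutation site table.
#' @param regions tiled, typed region table.
#' @param groups optional named vector mapping protein id to family label.
#' @return list with `table` (the annotated mutation table),
#'   `family_counts` and `tumor_counts`.
#' @export
map_mutations <- function(sites, regions, groups = NULL) {
  kind <- character(nrow(sites)); subtype <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- regions[regions$protein_id == sites$protein_id[i] &
                   regions$start <= sites$position[i] &
                   regions$end >= sites$position[i], , drop = FALSE]
    kind[i] <- if (nrow(r)) r$kind[1] else NA_character_
    subtype[i] <- if (nrow(r)) r$subtype[1] else NA_character_
  }
  tab <- cbind(sites, region_kind = kind, region_subtype = subtype,
               stringsAsFactors = FALSE)
  in_idr <- !is.na(kind) & kind == "DISORDERED"

  fam <- NULL
  if (!is.null(groups)) {
    sub <- tab[in_idr, , drop = FALSE]
    key <- unique(sub[, c("protein_id", "position")])
    g <- groups[key$protein_id]
    g[is.na(g)] <- "(unassigned)"
    t <- table(g)
    fam <- data.frame(family = names(t), mutated_residues_in_idr = as.integer(t),
                      stringsAsFactors = FALSE, row.names = NULL)
    fam <- fam[order(-fam$mutated_residues_in_idr, fam$family), , drop = FALSE]
  }

  tt <- unlist(lapply(tab$tumor_types[in_idr], split_set))
  tumor <- if (length(tt)) {
    t <- table(tt)
    data.frame(tumor_type = names(t), mutations_in_idr = as.integer(t),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(tumor_type = character(0), mutations_in_idr = integer(0))

  list(table = tab, family_counts = fam, tumor_counts = tumor)
}

#' Enumerate PTM/mutation flanking pairs
#'
#' All (PTM, mutation) pairs on the same protein whose positions differ by
#' at most `window` residues (inclusive, absolute difference).  A mutation
#' may pair with several PTMs and vice versa.
#'
#' @param mutations mutation site table.
#' @param ptms PTM site table.
#' @param window flank width in residues; default 5.
#' @return data.frame of class pairs with columns `protein_id`,
#'   `ptm_position`, `mutation_position`, `distance`, `ptm_type`,
#'   `phenotype_ids`; the attribute `"proteins_with_pair"` carries the ids
#'   of proteins having at least one pair.
#' @export
flanking_pairs <- function(mutations, ptms, window = 5L) {
  if (window < 0) stopf("window must be >= 0")
  shared <- intersect(unique(mutations$protein_id), unique(ptms$protein_id))
  out <- list()
  for (pid in shared) {
    mp <- mutations[mutations$protein_id == pid, , drop = FALSE]
    pp <- ptms[ptms$protein_id == pid, , drop = FALSE]
    dmat <- abs(outer(pp$position, mp$position, "-"))
    hit <- which(dmat <= window, arr.ind = TRUE)
    if (nrow(hit))
      out[[pid]] <- data.frame(
        protein_id = pid,
        ptm_position = pp$position[hit[, 1]],
        mutation_position = mp$position[hit[, 2]],
        distance = dmat[hit],
        ptm_type = pp$label[hit[, 1]],
        phenotype_ids = mp$phenotype_ids[hit[, 2]],
        stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(0), ptm_position = integer(0),
               mutation_position = integer(0), distance = integer(0),
               ptm_type = character(0), phenotype_ids = character(0))
  rownames(pairs) <- NULL
  pairs <- pairs[order(pairs$protein_id, pairs$ptm_position,
                       pairs$mutation_position), , drop = FALSE]
  attr(pairs, "proteins_with_pair") <- unique(pairs$protein_id)
  pairs
}

#' Permutation test for mutation/PTM co-location
#'
#' The observed statistic is the number of proteins with at least one
#' mutation within `window` residues of a PTM.  The null redraws each
#' protein's mutation positions uniformly at random within that protein
#' (optionally restricted to positions of the same region kind, preserving
#' the ordered/disordered split), recomputing the statistic `n_perm` times;
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.  This permutation
#' scheme is this package's own procedure for the flanking question.
#'
#' @param mutations mutation site table.
#' @param ptms PTM site table.
#' @param lengths named protein lengths.
#' @param window flank width; default 5.
#' @param n_perm number of permutation replicates (>= 100).
#' @param seed RNG seed (results are reproducible bit-for-bit given
#'   `seed` and `n_perm`).
#' @param regions optional tiled region table; with `preserve_regions =
#'   TRUE` mutations are re-drawn within their original region kind.
#' @param preserve_regions see above.
#' @return [new_stat_test()] result; statistic = observed protein count.
#' @export
flanking_enrichment <- function(mutations, ptms, lengths, window = 5L,
                                n_perm = 999L, seed = 1L, regions = NULL,
                                preserve_regions = FALSE) {
  if (!nrow(mutations)) stopf("no mutations supplied")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  observed <- length(attr(flanking_pairs(mutations, ptms, window),
                          "proteins_with_pair"))
  masks <- if (preserve_regions) {
    if (is.null(regions)) stopf("preserve_regions requires a region table")
    disorder_masks(regions, lengths)
  } else NULL
  ids <- unique(mutations$protein_id)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(rep) {
    perm <- mutations
    for (pid in ids) {
      idx <- which(perm$protein_id == pid)
      L <- lengths[[pid]]
      if (is.null(L)) stopf("no length for protein %s", pid)
      if (preserve_regions && !is.null(masks[[pid]])) {
        m <- masks[[pid]]
        for (j in idx) {
          pool <- if (m[perm$position[j]]) which(m) else which(!m)
          perm$position[j] <- pool[sample.int(length(pool), 1L)]
        }
      } else {
        perm$position[idx] <- sample.int(L, length(idx), replace = TRUE)
      }
    }
    length(attr(flanking_pairs(perm, ptms, window), "proteins_with_pair"))
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  new_stat_test(observed, p,
                sprintf("within-protein permutation test (flank <= %d, %d perms)",
                        window, n_perm),
                n = c(length(ids), n_perm))
}
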
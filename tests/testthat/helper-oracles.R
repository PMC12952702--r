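# Independent reference implementations ("oracles") used to validate the
# package's algorithms.  They are intentionally naive: explicit scans,
# exhaustive enumeration, brute-force minimisation.

# Run-length segmentation by an explicit per-residue state machine.
oracle_call_regions <- function(scores, threshold, min_len, max_gap) {
  L <- length(scores)
  pos <- scores >= threshold
  # collect maximal positive runs
  runs <- list(); i <- 1
  while (i <= L) {
    if (pos[i]) {
      j <- i
      while (j < L && pos[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  # merge across small gaps
  merged <- list()
  for (r in runs) {
    if (length(merged) &&
        r[1] - merged[[length(merged)]][2] - 1 <= max_gap)
      merged[[length(merged)]][2] <- r[2]
    else merged[[length(merged) + 1]] <- r
  }
  merged <- Filter(function(r) r[2] - r[1] + 1 >= min_len, merged)
  # paint residue states and read regions back off
  state <- rep("ORDERED", L)
  for (r in merged) state[r[1]:r[2]] <- "DISORDERED"
  out <- list(); i <- 1
  while (i <= L) {
    j <- i
    while (j < L && state[j + 1] == state[j]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(start = i, end = j,
                                         kind = state[i],
                                         stringsAsFactors = FALSE)
    i <- j + 1
  }
  do.call(rbind, out)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities not exceeding the
# observed one, with the conventional 1 + 1e-7 relative slop).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # disordered sites
  n <- c + d          # ordered sites
  k <- a + c          # feature-positive sites
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# Brute-force minimum parsimony changes: enumerate every assignment of 0/1
# to the internal nodes and count mismatched edges.
oracle_fitch <- function(tree, states) {
  k <- tree$Nnode
  ntip <- length(tree$tip.label)
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  leaf_block <- matrix(rep(as.numeric(states[tree$tip.label]),
                           each = nrow(combos)), nrow = nrow(combos))
  full <- cbind(leaf_block, combos)
  e <- tree$edge
  min(rowSums(abs(full[, e[, 1], drop = FALSE] -
                    full[, e[, 2], drop = FALSE])))
}

# As above but for all 2^ntip leaf labelings at once; returns a vector of
# minima indexed by the labeling's binary code (leaf 1 = least significant).
oracle_fitch_all_labelings <- function(tree) {
  ntip <- length(tree$tip.label)
  k <- tree$Nnode
  all_nodes <- as.matrix(expand.grid(rep(list(0:1), ntip + k)))
  e <- tree$edge
  changes <- rowSums(abs(all_nodes[, e[, 1], drop = FALSE] -
                           all_nodes[, e[, 2], drop = FALSE]))
  code <- as.vector(all_nodes[, seq_len(ntip), drop = FALSE] %*%
                      2^(seq_len(ntip) - 1))
  out <- rep(Inf, 2^ntip)
  for (i in seq_along(changes))
    out[code[i] + 1] <- min(out[code[i] + 1], changes[i])
  out
}

# All (PTM, mutation) flanking pairs by a literal double loop.
oracle_flanking <- function(mutations, ptms, window) {
  hits <- 0
  pairs <- list()
  for (i in seq_len(nrow(ptms))) for (j in seq_len(nrow(mutations))) {
    if (ptms$protein_id[i] == mutations$protein_id[j] &&
        abs(ptms$position[i] - mutations$position[j]) <= window)
      pairs[[length(pairs) + 1]] <- c(ptms$protein_id[i], ptms$position[i],
                                      mutations$position[j])
  }
  pairs
}

# Minimal site-table constructor for fixtures.
make_sites <- function(protein_id, position, label = "phosphoserine",
                       site_class = "PTM", tumor_types = "",
                       phenotype_ids = "") {
  data.frame(protein_id = protein_id, position = as.integer(position),
             site_class = site_class, label = label,
             tumor_types = tumor_types, phenotype_ids = phenotype_ids,
             stringsAsFactors = FALSE)
}

# Residue-level disorder mask computed directly from a region table
# (independent of the package's internal helper).
make_mask <- function(regions, pid, L) {
  m <- rep(FALSE, L)
  r <- regions[regions$protein_id == pid & regions$kind == "DISORDERED", ]
  for (i in seq_len(nrow(r))) m[r$start[i]:r$end[i]] <- TRUE
  m
}
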
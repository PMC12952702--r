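# Disorder-to-order transition (DOT) analysis over ortholog families:
# mapping per-sequence disorder calls onto alignment columns, binary-state
# parsimony (Fitch sets with Hartigan counting, so polytomies are handled
# exactly), DELTRAN ancestral resolution for per-clade net gain of
# disorder, and the SS-IDR vs other-disordered-site rate comparison.

#' Build a binary disorder character matrix from an ortholog family
#'
#' Each aligned non-gap residue inherits the ordered(0)/disordered(1) state
#' of its sequence's region call; gaps become missing (NA).  Columns with
#' more than `max_missing_frac` missing states are flagged unscored.
#'
#' @param family an `ortholog_family`.
#' @param regions_by_sequence tiled region table covering every ortholog
#'   (ungapped coordinates).
#' @param max_missing_frac unscore columns above this missing fraction
#'   (default 0.5).
#' @return object of class `column_character_matrix`: list with `states`
#'   (leaves x columns matrix of 0/1/NA), `ref_map` (per column, the
#'   1-based ungapped reference residue index or NA), `scored` (logical per
#'   column) and `family_id`.
#' @export
build_character_matrix <- function(family, regions_by_sequence,
                                   max_missing_frac = 0.5) {
  aln <- family$alignment
  ids <- names(aln)
  width <- nchar(aln[[1]])
  states <- matrix(NA_real_, nrow = length(ids), ncol = width,
                   dimnames = list(ids, NULL))
  for (pid in ids) {
    chars <- strsplit(aln[[pid]], "")[[1]]
    ungapped <- which(chars != "-")
    L <- length(ungapped)
    r <- regions_by_sequence[regions_by_sequence$protein_id == pid, ,
                             drop = FALSE]
    if (!nrow(r)) stopf("no regions for ortholog %s", pid)
    check_tiling(r, L, pid)
    kinds <- rep(0, L)
    d <- r[r$kind == "DISORDERED", , drop = FALSE]
    for (i in seq_len(nrow(d))) kinds[d$start[i]:d$end[i]] <- 1
    states[pid, ungapped] <- kinds
  }
  ref_chars <- strsplit(aln[[family$reference_id]], "")[[1]]
  ref_map <- rep(NA_integer_, width)
  ref_map[ref_chars != "-"] <- seq_len(sum(ref_chars != "-"))
  missing_frac <- colMeans(is.na(states))
  structure(list(family_id = family$family_id, states = states,
                 ref_map = ref_map,
                 scored = missing_frac <= max_missing_frac &
                   colSums(!is.na(states)) >= 2),
            class = "column_character_matrix")
}

# Postorder bookkeeping reused by fitch_changes / ancestral passes.
tree_postorder <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  nodes <- unique(po$edge[, 1])              # internal nodes, children first
  children <- split(po$edge[, 2], factor(po$edge[, 1], levels = nodes))
  list(tree = po, nodes = nodes, children = children,
       ntip = length(tree$tip.label), root = nodes[length(nodes)])
}

#' Minimum parsimony changes for binary characters on a rooted tree
#'
#' Fitch-style small parsimony for a 0/1 character, with Hartigan counting
#' at internal nodes so multifurcations are scored exactly.  Missing leaf
#' states (NA) are treated as the full state set, which yields the
#' parsimony score of the pruned tree.  Columns with fewer than two
#' non-missing leaves are unscored (NA), not an error.
#'
#' @param tree rooted `phylo` whose tip labels name the rows of `states`.
#' @param states numeric vector (named by leaf) or leaves x columns matrix
#'   of 0/1/NA.
#' @return integer vector of minimum change counts, one per column.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_changes(tr, c(A = 1, B = 1, C = 0, D = 0))
fitch_changes <- function(tree, states) {
  if (is.vector(states)) states <- matrix(states, ncol = 1,
                                          dimnames = list(names(states), NULL))
  if (is.null(rownames(states)))
    stopf("states must be named by leaf label")
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss))
    stopf("no states for leaf/leaves: %s", paste(miss, collapse = ", "))
  bk <- tree_postorder(tree)
  states <- states[tree$tip.label, , drop = FALSE]
  ncols <- ncol(states)
  out <- integer(ncols)
  nnode <- bk$ntip + tree$Nnode
  for (col in seq_len(ncols)) {
    x <- states[, col]
    if (sum(!is.na(x)) < 2) { out[col] <- NA_integer_; next }
    # set codes: bit 1 = contains state 0, bit 2 = contains state 1
    set <- integer(nnode)
    set[seq_len(bk$ntip)] <- ifelse(is.na(x), 3L, ifelse(x == 1, 2L, 1L))
    cost <- 0L
    for (i in seq_along(bk$nodes)) {
      kids <- bk$children[[i]]
      ks <- set[kids]
      c0 <- sum(bitwAnd(ks, 1L) > 0L)
      c1 <- sum(bitwAnd(ks, 2L) > 0L)
      K <- max(c0, c1)
      cost <- cost + length(kids) - K
      set[bk$nodes[i]] <- (c0 == K) * 1L + (c1 == K) * 2L
    }
    out[col] <- cost
  }
  out
}

#' Most-parsimonious ancestral states with DELTRAN resolution
#'
#' After the Hartigan up-pass, states are assigned top-down: the root takes
#' state 0 (ordered) on a tie, and each node inherits its parent's state
#' whenever that state is in its optimal set, pushing changes toward the
#' leaves (DELTRAN).  Missing leaves inherit the parent state so no change
#' is counted on their edge.
#'
#' @param tree rooted `phylo`.
#' @param states named 0/1/NA vector over the leaves.
#' @return numeric vector of states for all nodes (tips then internals, in
#'   ape numbering), or NULL if fewer than two informative leaves.
#' @export
ancestral_states <- function(tree, states) {
  x <- states[tree$tip.label]
  if (sum(!is.na(x)) < 2) return(NULL)
  bk <- tree_postorder(tree)
  nnode <- bk$ntip + tree$Nnode
  set <- integer(nnode)
  set[seq_len(bk$ntip)] <- ifelse(is.na(x), 3L, ifelse(x == 1, 2L, 1L))
  for (i in seq_along(bk$nodes)) {
    ks <- set[bk$children[[i]]]
    c0 <- sum(bitwAnd(ks, 1L) > 0L)
    c1 <- sum(bitwAnd(ks, 2L) > 0L)
    K <- max(c0, c1)
    set[bk$nodes[i]] <- (c0 == K) * 1L + (c1 == K) * 2L
  }
  assign_state <- function(code, parent_state) {
    if (code == 3L) {
      if (is.na(parent_state)) 0 else parent_state   # tie -> parent (root: 0)
    } else if (code == 2L) 1 else 0
  }
  node_state <- rep(NA_real_, nnode)
  node_state[bk$root] <- assign_state(set[bk$root], NA)
  edges <- bk$tree$edge
  for (e in rev(seq_len(nrow(edges)))) {             # preorder
    parent <- edges[e, 1]; child <- edges[e, 2]
    ps <- node_state[parent]
    code <- set[child]
    node_state[child] <- if (bitwAnd(code, if (ps == 0) 1L else 2L) > 0L)
      ps else assign_state(code, ps)
  }
  node_state
}

#' Exact/approximate Mann-Whitney U test
#'
#' Two-sided (or one-sided) Mann-Whitney U.  When both groups have at most
#' `exact_max` observations the null distribution of U is enumerated over
#' all group assignments of the pooled values (ties allowed; U counts ties
#' as 1/2).  Otherwise the tie-corrected normal approximation with
#' continuity correction is used via [stats::wilcox.test()].
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (`x` shifted
#'   relative to `y`).
#' @param exact_max largest group size for the enumeration path (default 8).
#' @return [new_stat_test()] result; statistic is U for `x`.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "greater", "less"),
                         exact_max = 8L) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("both groups must be non-empty")
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- u_stat(x, y)
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) u_stat(pool[idx], pool[-idx]))
    mid <- n1 * n2 / 2
    p <- switch(alternative,
                two_sided = mean(abs(us - mid) >= abs(U - mid) - 1e-9),
                greater = mean(us >= U - 1e-9),
                less = mean(us <= U + 1e-9))
    return(new_stat_test(U, p, "Mann-Whitney U test (exact enumeration)",
                         n = c(n1, n2)))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = sub("two_sided", "two.sided", alternative),
    exact = FALSE, correct = TRUE))
  new_stat_test(U, wt$p.value,
                "Mann-Whitney U test (tie-corrected normal approximation)",
                n = c(n1, n2))
}

#' Reference SS-IDR site set for the DOT comparison
#'
#' An SS-IDR residue of the reference sequence enters the comparison set if
#' it is (i) within `adjacency_cols` alignment columns of a column mapping
#' to an ordered reference residue, or (ii) at a column where at least
#' `ortholog_ordered_frac` of the non-missing non-reference states are
#' ordered.
#'
#' @param reference_regions typed, tiled regions of the reference sequence.
#' @param matrix a `column_character_matrix`.
#' @param reference_id reference sequence id.
#' @param adjacency_cols adjacency window in alignment columns (default 1).
#' @param ortholog_ordered_frac ordered-ortholog fraction rule (default 0.5).
#' @return integer vector of qualifying reference residue positions.
#' @export
ss_idr_site_set <- function(reference_regions, matrix, reference_id,
                            adjacency_cols = 1L,
                            ortholog_ordered_frac = 0.5) {
  ref_map <- matrix$ref_map
  col_of <- match(seq_len(max(c(0L, ref_map), na.rm = TRUE)), ref_map)
  ss <- reference_regions[reference_regions$kind == "DISORDERED" &
                            reference_regions$subtype == "SS_IDR", ,
                          drop = FALSE]
  if (!nrow(ss)) return(integer(0))
  ord <- reference_regions[reference_regions$kind == "ORDERED", ,
                           drop = FALSE]
  ord_pos <- unlist(lapply(seq_len(nrow(ord)), function(i)
    ord$start[i]:ord$end[i]))
  ord_cols <- col_of[ord_pos]
  others <- setdiff(rownames(matrix$states), reference_id)
  qualifies <- function(pos) {
    col <- col_of[pos]
    if (is.na(col)) return(FALSE)
    if (length(ord_cols) && min(abs(ord_cols - col)) <= adjacency_cols)
      return(TRUE)
    st <- matrix$states[others, col]
    st <- st[!is.na(st)]
    length(st) > 0 && mean(st == 0) >= ortholog_ordered_frac
  }
  cand <- unlist(lapply(seq_len(nrow(ss)), function(i) ss$start[i]:ss$end[i]))
  sort(cand[vapply(cand, qualifies, logical(1))])
}

#' Summarise disorder-to-order transitions for one family
#'
#' Per-column minimum changes by [fitch_changes()] over scored columns;
#' `changes_per_node` = total changes / (edge count x scored columns).
#' Columns mapping to reference SS-IDR positions in `ss_idr_sites` (group
#' A) are compared with columns mapping to other disordered reference
#' positions (group B) by a two-sided Mann-Whitney U on per-column change
#' counts.  The comparison is omitted, with a message, when either group is
#' empty or when no column shows any change.
#'
#' @param matrix a `column_character_matrix`.
#' @param tree the family's rooted tree.
#' @param reference_regions typed, tiled reference regions.
#' @param ss_idr_sites reference positions from [ss_idr_site_set()].
#' @return object of class `dot_summary`: list with `per_column_changes`
#'   (NA at unscored columns), `changes_per_node`, `n_scored`, `n_edges`
#'   and `group_comparison` (a stat test result or NULL).
#' @export
dot_summary <- function(matrix, tree, reference_regions, ss_idr_sites) {
  scored <- which(matrix$scored)
  changes <- rep(NA_integer_, ncol(matrix$states))
  if (length(scored))
    changes[scored] <- fitch_changes(tree, matrix$states[, scored,
                                                         drop = FALSE])
  n_edges <- nrow(tree$edge)
  n_scored <- sum(!is.na(changes))
  cpn <- if (n_scored) sum(changes, na.rm = TRUE) / (n_edges * n_scored)
  else NA_real_

  dis <- reference_regions[reference_regions$kind == "DISORDERED", ,
                           drop = FALSE]
  dis_pos <- unlist(lapply(seq_len(nrow(dis)), function(i)
    dis$start[i]:dis$end[i]))
  ref_pos <- matrix$ref_map
  usable <- !is.na(changes) & !is.na(ref_pos)
  groupA <- usable & ref_pos %in% ss_idr_sites
  groupB <- usable & ref_pos %in% setdiff(dis_pos, ss_idr_sites)
  cmp <- NULL
  if (!any(groupA) || !any(groupB)) {
    message("dot_summary: SS-IDR/other-disorder comparison omitted (empty group)")
  } else if (all(changes[groupA | groupB] == 0)) {
    message("dot_summary: comparison omitted (no changes in either group)")
  } else {
    cmp <- mann_whitney(changes[groupA], changes[groupB],
                        alternative = "two_sided")
  }
  structure(list(family_id = matrix$family_id,
                 per_column_changes = changes, changes_per_node = cpn,
                 n_scored = n_scored, n_edges = n_edges,
                 group_comparison = cmp,
                 mean_changes_ss = if (any(groupA)) mean(changes[groupA]) else NA_real_,
                 mean_changes_other = if (any(groupB)) mean(changes[groupB]) else NA_real_),
            class = "dot_summary")
}

#' Net gain of disorder per clade
#'
#' Reconstructs ancestral states for every scored column
#' ([ancestral_states()], DELTRAN convention, root ties resolved to
#' ordered) and reports, for each clade (internal node, named by its
#' lexicographically smallest leaf label), the number of order-to-disorder
#' (gain) and disorder-to-order (loss) edge events within the clade summed
#' over columns, and their difference.
#'
#' @param tree rooted `phylo`.
#' @param matrix a `column_character_matrix`.
#' @return data.frame with columns `clade`, `n_leaves`, `gains`, `losses`,
#'   `net_gain`; the root clade row first.
#' @export
net_disorder_gain <- function(tree, matrix) {
  bk <- tree_postorder(tree)
  edges <- bk$tree$edge
  gain_edge <- numeric(nrow(edges))
  loss_edge <- numeric(nrow(edges))
  for (col in which(matrix$scored)) {
    ns <- ancestral_states(tree, matrix$states[, col])
    if (is.null(ns)) next
    ps <- ns[edges[, 1]]; cs <- ns[edges[, 2]]
    gain_edge <- gain_edge + (ps == 0 & cs == 1)
    loss_edge <- loss_edge + (ps == 1 & cs == 0)
  }
  # accumulate per-subtree sums bottom-up
  ntip <- bk$ntip
  nnode <- ntip + tree$Nnode
  sub_gain <- numeric(nnode); sub_loss <- numeric(nnode)
  leaves_below <- vector("list", nnode)
  leaves_below[seq_len(ntip)] <- as.list(tree$tip.label)
  edge_of_child <- match(seq_len(nnode), edges[, 2])
  for (i in seq_along(bk$nodes)) {
    v <- bk$nodes[i]
    for (k in bk$children[[i]]) {
      e <- edge_of_child[k]
      sub_gain[v] <- sub_gain[v] + sub_gain[k] + gain_edge[e]
      sub_loss[v] <- sub_loss[v] + sub_loss[k] + loss_edge[e]
      leaves_below[[v]] <- c(leaves_below[[v]], leaves_below[[k]])
    }
  }
  internal <- bk$nodes
  out <- data.frame(
    clade = vapply(leaves_below[internal],
                   function(l) min(sort(l)), character(1)),
    n_leaves = vapply(leaves_below[internal], length, integer(1)),
    gains = sub_gain[internal], losses = sub_loss[internal],
    net_gain = sub_gain[internal] - sub_loss[internal],
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_leaves, out$clade), , drop = FALSE]
}
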
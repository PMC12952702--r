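# Synthetic disordered-proteome generator.  Emits ground-truth-labelled
# sequences, disorder/SS profiles, PTM and mutation tables and ortholog
# families with the statistical structure the analysis stages assume:
# alternating ordered/disordered segments, planted compositionally biased
# segments, PTM placement at a controlled disordered-vs-ordered odds
# ratio, mutations drawn near PTMs at a controlled rate, and binary
# disorder characters evolved on Yule trees under gain/loss rates.
#
# One master seed drives independent per-stage streams (offsets 1..3 via
# derive_seed) so each stage regenerates identically in isolation.

.SIM_GROUPS <- c("SR protein", "SR-related", "hnRNP", "U1 snRNP",
                 "U2 snRNP", "U5 snRNP", "LSM", "Prp19 complex",
                 "RES complex", "EJC/mRNP")
.SIM_COMPLEXES <- c("E", "A", "pre-B", "B", "Bact", "Bstar", "C", "Cstar",
                    "P", "ILS")
.SIM_PTM_TYPES <- c(phosphoserine = 0.50, phosphothreonine = 0.15,
                    `N6-acetyllysine` = 0.10,
                    `omega-N-methylarginine` = 0.08,
                    `N-acetylalanine` = 0.07,
                    `asymmetric dimethylarginine` = 0.05,
                    citrulline = 0.05)

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic study: 500 proteins of
#' 200-600 residues with 30-70% disorder, 110 planted 50-residue segments
#' per CB subtype, PTMs at base rate 0.01 with a disordered/ordered odds
#' ratio of 3, a Poisson mean of 2 mutation records per protein of which
#' 30% are forced within 5 residues of a PTM, and 12-taxon Yule families
#' with per-edge disorder gain/loss probability 0.05.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer (min, max) protein length.
#' @param disorder_fraction_range (min, max) target disorder fraction.
#' @param motif_plan data.frame with columns `subtype`, `n_segments`,
#'   `length` for planted CB segments (at most one per protein).
#' @param ptm_base_rate per-residue PTM probability in ordered truth.
#' @param ptm_odds_ratio disordered/ordered PTM odds ratio.
#' @param ptm_types named probability vector over PTM type labels.
#' @param mutation_rate Poisson mean mutation records per protein.
#' @param flank_rate fraction of mutations placed within 5 residues of a
#'   randomly chosen PTM of the same protein.
#' @param n_taxa leaves per ortholog family.
#' @param n_families number of ortholog families (references are the first
#'   `n_families` simulated proteins).
#' @param birth_rate Yule birth rate for family trees.
#' @param gain_rate,loss_rate per-edge 0->1 and 1->0 flip probabilities for
#'   the binary disorder character.
#' @param ss_idr_fraction fraction of background disordered segments given
#'   a planted helical run (SS-IDR truth).
#' @param noise_sd Gaussian noise around the 0.9/0.1 score levels.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500L, length_range = c(200L, 600L),
                       disorder_fraction_range = c(0.3, 0.7),
                       motif_plan = NULL, ptm_base_rate = 0.01,
                       ptm_odds_ratio = 3.0, ptm_types = .SIM_PTM_TYPES,
                       mutation_rate = 2, flank_rate = 0.3,
                       n_taxa = 12L, n_families = 6L, birth_rate = 1,
                       gain_rate = 0.05, loss_rate = 0.05,
                       ss_idr_fraction = 0.25, noise_sd = 0.05, seed = 1L) {
  if (is.null(motif_plan))
    # 110 segments per subtype at the reference size of 500 proteins,
    # scaled proportionally for smaller runs (at most one per protein)
    motif_plan <- data.frame(
      subtype = c("CB_RS", "CB_PQ", "CB_G", "CB_CHARGED"),
      n_segments = max(1L, as.integer(floor(0.22 * n_proteins))),
      length = 50L, stringsAsFactors = FALSE)
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              disorder_fraction_range = disorder_fraction_range,
              motif_plan = motif_plan, ptm_base_rate = ptm_base_rate,
              ptm_odds_ratio = ptm_odds_ratio,
              ptm_types = ptm_types / sum(ptm_types),
              mutation_rate = mutation_rate, flank_rate = flank_rate,
              n_taxa = as.integer(n_taxa), n_families = as.integer(n_families),
              birth_rate = birth_rate, gain_rate = gain_rate,
              loss_rate = loss_rate, ss_idr_fraction = ss_idr_fraction,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_proteins < 1 || cfg$n_taxa < 1)
    stopf("n_proteins and n_taxa must be >= 1")
  if (ptm_base_rate <= 0 || ptm_base_rate >= 1)
    stopf("ptm_base_rate must be in (0,1)")
  if (ptm_odds_ratio <= 0) stopf("ptm_odds_ratio must be > 0")
  if (flank_rate < 0 || flank_rate > 1) stopf("flank_rate must be in [0,1]")
  if (gain_rate <= 0 || gain_rate >= 1 || loss_rate <= 0 || loss_rate >= 1)
    stopf("gain_rate and loss_rate must be in (0,1)")
  if (sum(motif_plan$n_segments) > cfg$n_proteins)
    stopf("motif_plan places more segments (%d) than proteins (%d); at most one per protein",
          sum(motif_plan$n_segments), cfg$n_proteins)
  min_disorder <- ceiling(disorder_fraction_range[1] * cfg$length_range[1])
  if (any(motif_plan$length > min_disorder))
    stopf("planted segment length exceeds the smallest possible disordered budget (%d)",
          min_disorder)
  structure(cfg, class = "sim_config")
}

draw_seq <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# Random composition of `total` into `k` parts, each >= minimum.
split_lengths <- function(total, k, minimum) {
  if (k == 0) return(integer(0))
  extra <- total - k * minimum
  if (extra < 0) stopf("cannot split %d into %d parts of >= %d", total, k,
                       minimum)
  cuts <- if (k > 1) sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  else integer(0)
  minimum + diff(c(0L, cuts, extra))
}

#' Simulate a disordered proteome with planted ground truth
#'
#' See [sim_config()] for the study conditions.  Each protein is an
#' alternating layout of ordered and disordered segments; disordered
#' residues are emitted from a disorder-promoting composition and ordered
#' residues from a globular one (constants documented in the methods
#' vignette), planted CB segments override the composition, and disorder
#' scores are `0.9 +/- noise` inside disordered truth and `0.1 +/- noise`
#' outside, clipped to \[0,1\].
#'
#' @param config a `sim_config`.
#' @return list with `proteins` (table with metadata), `profiles`
#'   (disorder score list), `ss` (state strings) and `truth` (list with the
#'   planted `regions` table and `disorder_fraction` table).
#' @export
simulate_proteins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_proteins
    ids <- sprintf("SIM%04d", seq_len(n))
    # planted-subtype assignment: at most one segment per protein
    planted <- rep(NA_character_, n)
    pool <- sample.int(n)
    k <- 0L
    for (i in seq_len(nrow(config$motif_plan))) {
      take <- config$motif_plan$n_segments[i]
      if (take > 0L) {
        planted[pool[(k + 1L):(k + take)]] <- config$motif_plan$subtype[i]
        k <- k + take
      }
    }
    plant_len <- stats::setNames(config$motif_plan$length,
                                 config$motif_plan$subtype)
    comp_d <- sim_composition("disordered")
    comp_o <- sim_composition("ordered")

    seqs <- character(n)
    profiles <- vector("list", n); names(profiles) <- ids
    ss <- character(n)
    region_rows <- list()
    truth_frac <- numeric(n)

    for (i in seq_len(n)) {
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      f <- stats::runif(1, config$disorder_fraction_range[1],
                        config$disorder_fraction_range[2])
      d_total <- round(f * L)
      seg_lens <- integer(0); seg_types <- character(0)
      if (!is.na(planted[i])) {
        seg_lens <- plant_len[[planted[i]]]
        seg_types <- planted[i]
      }
      rem <- d_total - sum(seg_lens)
      if (rem >= 15L) {
        k_bg <- max(1L, round(rem / 60))
        while (k_bg > 1L && rem / k_bg < 15L) k_bg <- k_bg - 1L
        bg <- split_lengths(rem, k_bg, 15L)
        seg_lens <- c(seg_lens, bg)
        seg_types <- c(seg_types,
                       ifelse(stats::runif(k_bg) < config$ss_idr_fraction,
                              "SS_IDR", "NONE"))
      }
      ord <- sample(seq_along(seg_lens))
      seg_lens <- seg_lens[ord]; seg_types <- seg_types[ord]
      m <- length(seg_lens)
      gap_lens <- split_lengths(L - sum(seg_lens), m + 1L, 10L)

      aa <- character(0); states1 <- logical(0); sstate <- character(0)
      add_ordered <- function(len) {
        s <- strsplit(draw_seq(len, comp_o), "")[[1]]
        st <- rep("C", len)
        if (len >= 12) {                       # realistic SS inside order
          hl <- max(4L, round(0.4 * len))
          hs <- sample.int(len - hl + 1L, 1L)
          st[hs:(hs + hl - 1L)] <- "H"
          if (hs >= 5L) st[1:4] <- "E"         # a short strand before it
          else if (hs + hl + 3L <= len) st[(len - 3L):len] <- "E"
        }
        list(aa = s, st = st)
      }
      for (j in seq_len(m)) {
        g <- add_ordered(gap_lens[j])
        aa <- c(aa, g$aa); states1 <- c(states1, rep(FALSE, gap_lens[j]))
        sstate <- c(sstate, g$st)
        len <- seg_lens[j]; ty <- seg_types[j]
        if (ty %in% names(.SIM_COMP_PLANTED)) {
          comp <- .SIM_COMP_PLANTED[[ty]]
          s <- strsplit(draw_seq(len, comp / sum(comp)), "")[[1]]
          if (ty == "CB_PQ") {                 # guarantee homorepeat runs
            qs <- sample.int(max(1L, len %/% 2L - 7L), 1L)
            s[qs:(qs + 6L)] <- "Q"
            ps <- len %/% 2L + sample.int(len %/% 2L - 6L, 1L)
            s[ps:(ps + 5L)] <- "P"
          }
          st <- rep("C", len)
        } else {
          s <- strsplit(draw_seq(len, comp_d), "")[[1]]
          st <- rep("C", len)
          if (ty == "SS_IDR") {
            hl <- max(4L, round(0.6 * len))
            hs <- sample.int(len - hl + 1L, 1L)
            st[hs:(hs + hl - 1L)] <- "H"
          }
        }
        aa <- c(aa, s); states1 <- c(states1, rep(TRUE, len))
        sstate <- c(sstate, st)
        start <- sum(gap_lens[seq_len(j)]) + sum(seg_lens[seq_len(j - 1)]) + 1L
        region_rows[[length(region_rows) + 1L]] <- data.frame(
          protein_id = ids[i], start = start, end = start + len - 1L,
          kind = "DISORDERED", subtype = ty, stringsAsFactors = FALSE)
      }
      g <- add_ordered(gap_lens[m + 1L])
      aa <- c(aa, g$aa); states1 <- c(states1, rep(FALSE, gap_lens[m + 1L]))
      sstate <- c(sstate, g$st)

      seqs[i] <- paste(aa, collapse = "")
      noise <- stats::rnorm(L, 0, config$noise_sd)
      profiles[[i]] <- pmin(1, pmax(0, ifelse(states1, 0.9, 0.1) + noise))
      ss[i] <- paste(sstate, collapse = "")
      truth_frac[i] <- sum(states1) / L
    }
    names(ss) <- ids

    proteins <- data.frame(
      id = ids, sequence = seqs,
      group = sample(.SIM_GROUPS, n, replace = TRUE),
      complexes = vapply(seq_len(n), function(i)
        join_set(sort(sample(.SIM_COMPLEXES,
                             sample.int(4L, 1L)))), character(1)),
      abundant = stats::runif(n) < 0.2, stringsAsFactors = FALSE)

    truth_regions <- disorder_truth_tiling(do.call(rbind, region_rows),
                                           protein_lengths(proteins))
    list(proteins = proteins, profiles = profiles, ss = ss,
         truth = list(
           regions = truth_regions,
           disorder_fraction = data.frame(protein_id = ids,
                                          fraction = truth_frac,
                                          stringsAsFactors = FALSE),
           config = config))
  })
}

# Complete a disordered-segment truth table into a full tiling with
# ORDERED complement rows.
disorder_truth_tiling <- function(dis_rows, lengths) {
  out <- list()
  for (pid in names(lengths)) {
    d <- dis_rows[dis_rows$protein_id == pid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cursor <- 1L
    for (i in seq_len(nrow(d))) {
      if (d$start[i] > cursor)
        out[[length(out) + 1L]] <- data.frame(
          protein_id = pid, start = cursor, end = d$start[i] - 1L,
          kind = "ORDERED", subtype = "NONE", stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- d[i, ]
      cursor <- d$end[i] + 1L
    }
    if (cursor <= lengths[[pid]])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = pid, start = cursor, end = lengths[[pid]],
        kind = "ORDERED", subtype = "NONE", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate PTM and mutation tables over a simulated proteome
#'
#' PTMs are residue-wise Bernoulli draws at rate `ptm_base_rate` in ordered
#' truth and at the rate solving
#' `odds(p_idr) = ptm_odds_ratio x odds(p_ord)` in disordered truth; types
#' follow `config$ptm_types`.  A `flank_rate` fraction of mutations is
#' placed uniformly within 5 residues of a randomly chosen PTM of the same
#' protein, the rest uniformly.
#'
#' @param config a `sim_config`.
#' @param sim result of [simulate_proteins()].
#' @return list with `ptms`, `mutations` (site tables) and `truth` extended
#'   with the realized 2x2 table (`ptm_table`), its sample odds ratio and
#'   the realized flanked-mutation count.
#' @export
simulate_ptms_and_mutations <- function(config, sim) {
  odds_ord <- config$ptm_base_rate / (1 - config$ptm_base_rate)
  odds_idr <- config$ptm_odds_ratio * odds_ord
  p_idr <- odds_idr / (1 + odds_idr)
  if (p_idr >= 1)
    stopf("implied disordered PTM rate >= 1; lower ptm_base_rate or the odds ratio")
  lengths <- protein_lengths(sim$proteins)
  masks <- disorder_masks(sim$truth$regions, lengths)
  with_seed(derive_seed(config$seed, 2L), {
    ptm_rows <- list(); mut_rows <- list()
    tab <- c(a = 0L, b = 0L, c = 0L, d = 0L)
    n_flanked <- 0L
    tumor_pool <- c("carcinoma", "lymphoma", "leukemia", "sarcoma",
                    "melanoma")
    pheno_pool <- c("HP:0000951", "HP:0002664", "HP:0004808")
    for (pid in sim$proteins$id) {
      L <- lengths[[pid]]; m <- masks[[pid]]
      p <- ifelse(m, p_idr, config$ptm_base_rate)
      hit <- stats::runif(L) < p
      tab <- tab + c(a = sum(hit & m), b = sum(!hit & m),
                     c = sum(hit & !m), d = sum(!hit & !m))
      pos <- which(hit)
      if (length(pos))
        ptm_rows[[pid]] <- data.frame(
          protein_id = pid, position = pos, site_class = "PTM",
          label = sample(names(config$ptm_types), length(pos),
                         replace = TRUE, prob = config$ptm_types),
          tumor_types = "", phenotype_ids = "", stringsAsFactors = FALSE)
      n_mut <- stats::rpois(1, config$mutation_rate)
      if (n_mut > 0) {
        mpos <- integer(n_mut)
        for (j in seq_len(n_mut)) {
          if (stats::runif(1) < config$flank_rate) {
            # flank-forced draws need an anchor; PTM-less proteins emit none
            if (!length(pos)) { mpos[j] <- NA_integer_; next }
            anchor <- pos[sample.int(length(pos), 1L)]
            mpos[j] <- min(L, max(1L, anchor + sample(-5:5, 1L)))
            n_flanked <- n_flanked + 1L
          } else mpos[j] <- sample.int(L, 1L)
        }
        mpos <- mpos[!is.na(mpos)]
        n_mut <- length(mpos)
      }
      if (n_mut > 0) {
        ref <- substring(sim$proteins$sequence[sim$proteins$id == pid],
                         mpos, mpos)
        mut_rows[[pid]] <- data.frame(
          protein_id = pid, position = mpos, site_class = "MUTATION",
          label = sprintf("p.%s%d%s", ref, mpos,
                          sample(AA_CANONICAL, n_mut, replace = TRUE)),
          tumor_types = vapply(seq_len(n_mut), function(x)
            join_set(sort(sample(tumor_pool, sample.int(2L, 1L)))),
            character(1)),
          phenotype_ids = vapply(seq_len(n_mut), function(x)
            join_set(sort(sample(pheno_pool, sample.int(2L, 1L)))),
            character(1)),
          stringsAsFactors = FALSE)
      }
    }
    truth <- sim$truth
    truth$ptm_table <- tab
    truth$ptm_odds_ratio <- (tab[["a"]] * tab[["d"]]) /
      (tab[["b"]] * tab[["c"]])
    truth$n_flanked_mutations <- n_flanked
    ptms <- do.call(rbind, ptm_rows); rownames(ptms) <- NULL
    muts <- do.call(rbind, mut_rows); rownames(muts) <- NULL
    list(ptms = ptms, mutations = muts, truth = truth)
  })
}

#' Evolve binary disorder characters along a tree
#'
#' Each column starts at `root_states` and flips along every edge with
#' probability `gain_rate` (0 to 1) or `loss_rate` (1 to 0).  Realized flip
#' events are recorded per column, providing the parsimony lower-bound
#' ground truth.
#'
#' @param tree rooted `phylo`.
#' @param root_states 0/1 vector, one entry per column.
#' @param gain_rate,loss_rate per-edge flip probabilities.
#' @return list with `states` (leaves x columns matrix), `events_per_column`
#'   and `events_per_edge`.
#' @export
simulate_characters <- function(tree, root_states, gain_rate, loss_rate) {
  bk <- tree_postorder(tree)
  edges <- bk$tree$edge
  ncols <- length(root_states)
  nnode <- bk$ntip + tree$Nnode
  node_states <- matrix(NA_real_, nnode, ncols)
  node_states[bk$root, ] <- root_states
  events_col <- integer(ncols)
  events_edge <- integer(nrow(edges))
  for (e in rev(seq_len(nrow(edges)))) {       # preorder
    ps <- node_states[edges[e, 1], ]
    flip_p <- ifelse(ps == 1, loss_rate, gain_rate)
    flip <- stats::runif(ncols) < flip_p
    node_states[edges[e, 2], ] <- ifelse(flip, 1 - ps, ps)
    events_col <- events_col + flip
    events_edge[e] <- sum(flip)
  }
  states <- node_states[seq_len(bk$ntip), , drop = FALSE]
  rownames(states) <- bk$tree$tip.label
  list(states = states, events_per_column = events_col,
       events_per_edge = events_edge)
}

#' Simulate ortholog families for the DOT stage
#'
#' For each of the first `n_families` simulated proteins, draws a Yule tree
#' with `n_taxa` leaves ([ape::rphylo()]), uses the protein's true
#' disorder states as the root character of every column, evolves them with
#' [simulate_characters()], and re-emits each ortholog's residues from the
#' state-appropriate composition table.  Alignments are gap-free, so column
#' k corresponds to reference residue k.
#'
#' @param config a `sim_config`.
#' @param sim result of [simulate_proteins()].
#' @return list with `families` (list of `ortholog_family`),
#'   `ortholog_regions` (tiled truth regions for every ortholog) and
#'   `events` (per family, realized flip events per column).
#' @export
simulate_families <- function(config, sim) {
  lengths <- protein_lengths(sim$proteins)
  masks <- disorder_masks(sim$truth$regions, lengths)
  refs <- sim$proteins$id[seq_len(min(config$n_families,
                                      nrow(sim$proteins)))]
  comp_d <- sim_composition("disordered")
  comp_o <- sim_composition("ordered")
  with_seed(derive_seed(config$seed, 3L), {
    families <- list(); events <- list(); reg_rows <- list()
    for (ref in refs) {
      tree <- ape::rphylo(config$n_taxa, birth = config$birth_rate,
                          death = 0)
      tree$tip.label <- c(ref, sprintf("%s_o%d", ref,
                                       seq_len(config$n_taxa - 1L) + 1L))
      root <- as.numeric(masks[[ref]])
      ch <- simulate_characters(tree, root, config$gain_rate,
                                config$loss_rate)
      aln <- vapply(rownames(ch$states), function(leaf) {
        st <- ch$states[leaf, ]
        aa <- character(length(st))
        aa[st == 1] <- sample(names(comp_d), sum(st == 1), replace = TRUE,
                              prob = comp_d)
        aa[st == 0] <- sample(names(comp_o), sum(st == 0), replace = TRUE,
                              prob = comp_o)
        paste(aa, collapse = "")
      }, character(1))
      families[[ref]] <- ortholog_family(ref, aln, tree, ref)
      events[[ref]] <- ch$events_per_column
      for (leaf in rownames(ch$states)) {
        st <- ch$states[leaf, ]
        r <- rle(st)
        e <- cumsum(r$lengths); s <- e - r$lengths + 1L
        reg_rows[[paste(ref, leaf)]] <- data.frame(
          protein_id = leaf, start = as.integer(s), end = as.integer(e),
          kind = ifelse(r$values == 1, "DISORDERED", "ORDERED"),
          subtype = "NONE", cb_subtype = "NONE", alpha_frac = 0,
          beta_frac = 0, stringsAsFactors = FALSE)
      }
    }
    orth_regions <- do.call(rbind, reg_rows)
    rownames(orth_regions) <- NULL
    list(families = families, ortholog_regions = orth_regions,
         events = events)
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits the flat files every pipeline stage consumes: `proteins.fasta`,
#' `disorder.tsv`, `ss.tsv`, `ptms.tsv`, `mutations.tsv`, `metadata.tsv`,
#' per-family `families/<id>.afa` / `families/<id>.nwk` plus
#' `families/references.tsv` and `families/ortholog_regions.tsv`, and
#' ground-truth tables under `ground_truth/`.  Identical configs (same
#' seed) produce byte-identical files.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created).
#' @return (invisibly) the in-memory simulation objects.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "families"), showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  sim <- simulate_proteins(config)
  pm <- simulate_ptms_and_mutations(config, sim)
  fams <- simulate_families(config, sim)

  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_profile_table(sim$profiles, file.path(dir, "disorder.tsv"))
  write_profile_table(sim$ss, file.path(dir, "ss.tsv"))
  write_site_table(pm$ptms, file.path(dir, "ptms.tsv"))
  write_site_table(pm$mutations, file.path(dir, "mutations.tsv"))
  utils::write.table(
    data.frame(protein_id = sim$proteins$id, group = sim$proteins$group,
               complexes = sim$proteins$complexes,
               abundant = sim$proteins$abundant),
    file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (ref in names(fams$families)) {
    fam <- fams$families[[ref]]
    write_fasta(data.frame(id = names(fam$alignment),
                           sequence = unname(fam$alignment)),
                file.path(dir, "families", paste0(ref, ".afa")))
    ape::write.tree(fam$tree, file.path(dir, "families",
                                        paste0(ref, ".nwk")))
  }
  utils::write.table(
    data.frame(family_id = names(fams$families),
               reference_id = names(fams$families)),
    file.path(dir, "families", "references.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  write_regions(fams$ortholog_regions,
                file.path(dir, "families", "ortholog_regions.tsv"))

  write_regions(pm$truth$regions, file.path(dir, "ground_truth",
                                            "regions.tsv"))
  utils::write.table(pm$truth$disorder_fraction,
                     file.path(dir, "ground_truth", "disorder_fraction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = names(pm$truth$ptm_table),
               count = as.integer(pm$truth$ptm_table)),
    file.path(dir, "ground_truth", "ptm_table.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  for (ref in names(fams$events))
    utils::write.table(
      data.frame(column = seq_along(fams$events[[ref]]),
                 events = fams$events[[ref]]),
      file.path(dir, "ground_truth", paste0("events_", ref, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, ptm = pm, families = fams))
}

#' Residue-level recovery of planted CB subtypes
#'
#' Compares called `cb_subtype` labels with the planted truth at residue
#' level, reporting precision and recall per subtype.
#'
#' @param truth_regions planted truth region table (with `subtype`).
#' @param called_regions typed called region table (with `cb_subtype`).
#' @param lengths named protein lengths.
#' @return data.frame with one row per CB subtype.
#' @export
subtype_recovery <- function(truth_regions, called_regions, lengths) {
  subtype_mask <- function(regions, col, value) {
    masks <- list()
    for (pid in names(lengths)) {
      m <- rep(FALSE, lengths[[pid]])
      r <- regions[regions$protein_id == pid & regions[[col]] == value, ,
                   drop = FALSE]
      for (i in seq_len(nrow(r))) m[r$start[i]:r$end[i]] <- TRUE
      masks[[pid]] <- m
    }
    unlist(masks)
  }
  out <- lapply(c("CB_RS", "CB_PQ", "CB_G", "CB_CHARGED"), function(sub) {
    truth <- subtype_mask(truth_regions, "subtype", sub)
    called <- subtype_mask(called_regions, "cb_subtype", sub)
    tp <- sum(truth & called)
    data.frame(subtype = sub, n_truth = sum(truth), n_called = sum(called),
               precision = if (sum(called)) tp / sum(called) else NA_real_,
               recall = if (sum(truth)) tp / sum(truth) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
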
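quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("character matrices map region calls through alignment gaps", {
  aln <- c(A = "MKLV", B = "MKLV")
  tree <- ape::read.tree(text = "(A,B);")
  regions <- data.frame(protein_id = c("A", "B"), start = 1L, end = 4L,
                        kind = "DISORDERED", stringsAsFactors = FALSE)
  fam <- ortholog_family("f", aln, tree, "A")
  cm <- build_character_matrix(fam, regions)
  expect_true(all(cm$states == 1))
  expect_equal(cm$ref_map, 1:4)

  aln2 <- c(A = "MK-V", B = "MKLV")
  regions2 <- rbind(
    data.frame(protein_id = "A", start = 1L, end = 3L, kind = "ORDERED",
               stringsAsFactors = FALSE),
    data.frame(protein_id = "B", start = 1L, end = 4L, kind = "DISORDERED",
               stringsAsFactors = FALSE))
  cm2 <- build_character_matrix(ortholog_family("f", aln2, tree, "A"),
                                regions2)
  expect_true(is.na(cm2$states["A", 3]))
  expect_equal(cm2$ref_map, c(1L, 2L, NA, 3L))

  # random fixture: states agree with an independent per-position lookup
  set.seed(70)
  seqs <- replicate(3, paste(sample(c("A", "-"), 30, TRUE, c(.8, .2)),
                             collapse = ""))
  names(seqs) <- c("A", "B", "C")
  tr3 <- ape::read.tree(text = "((A,B),C);")
  regs <- do.call(rbind, lapply(names(seqs), function(pid) {
    L <- sum(strsplit(seqs[[pid]], "")[[1]] != "-")
    call_regions(round(runif(L)), protein_id = pid)
  }))
  cm3 <- build_character_matrix(ortholog_family("f", seqs, tr3, "A"), regs)
  for (pid in names(seqs)) {
    chars <- strsplit(seqs[[pid]], "")[[1]]
    mask <- make_mask(regs, pid, sum(chars != "-"))
    expect_equal(cm3$states[pid, chars != "-"], as.numeric(mask))
    expect_true(all(is.na(cm3$states[pid, chars == "-"])))
  }
})

test_that("Fitch counts match hand-worked quartets", {
  expect_equal(fitch_changes(quartet, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(fitch_changes(quartet, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_equal(fitch_changes(quartet, c(A = 1, B = 1, C = 1, D = 1)), 0)
  # fewer than two informative leaves: unscored, not an error
  expect_true(is.na(fitch_changes(quartet, c(A = 1, B = NA, C = NA, D = NA))))
})

test_that("Fitch equals brute-force minimisation on all 5-leaf shapes", {
  skip_if_not_installed("phangorn")
  for (n in 3:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[1:n])
    for (ti in seq_along(trees)) {
      tree <- trees[[ti]]                # [[ restores compressed tip labels
      labelings <- as.matrix(expand.grid(rep(list(0:1), n)))
      states <- t(labelings)
      rownames(states) <- LETTERS[1:n]
      got <- fitch_changes(tree, states)
      want <- apply(labelings, 1, function(lab)
        oracle_fitch(tree, stats::setNames(lab, LETTERS[1:n])))
      expect_equal(got, as.integer(want))
    }
  }
})

test_that("polytomies are scored exactly (Hartigan counting)", {
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  expect_equal(fitch_changes(star, c(A = 1, B = 1, C = 0, D = 0, E = 0)), 2)
  expect_equal(fitch_changes(star, c(A = 1, B = 0, C = 0, D = 0, E = 0)), 1)
  mixed <- ape::read.tree(text = "((A,B,C),(D,E));")
  for (i in 0:31) {
    lab <- stats::setNames(as.numeric(intToBits(i)[1:5]), LETTERS[1:5])
    expect_equal(fitch_changes(mixed, lab), oracle_fitch(mixed, lab))
  }
})

test_that("missing leaves are equivalent to pruning them", {
  set.seed(71)
  for (rep in 1:20) {
    tree <- ape::rtree(7)
    states <- stats::setNames(sample(0:1, 7, TRUE), tree$tip.label)
    drop <- sample(tree$tip.label, 2)
    miss <- states; miss[drop] <- NA
    pruned <- ape::drop.tip(tree, drop)
    expect_equal(fitch_changes(tree, miss),
                 oracle_fitch(pruned, states[pruned$tip.label]))
  }
})

test_that("parsimony score is invariant to re-rooting", {
  skip_if_not_installed("phangorn")
  set.seed(72)
  tree <- ape::rtree(8)
  states <- stats::setNames(sample(0:1, 8, TRUE), tree$tip.label)
  base <- fitch_changes(tree, states)
  for (node in 10:14) {
    rerooted <- ape::root(tree, node = node, resolve.root = TRUE)
    expect_equal(fitch_changes(rerooted, states), base)
  }
})

test_that("Fitch agrees with phangorn's parsimony on random data", {
  skip_if_not_installed("phangorn")
  set.seed(73)
  for (rep in 1:10) {
    tree <- ape::rtree(10)
    states <- matrix(sample(0:1, 50, TRUE), nrow = 10,
                     dimnames = list(tree$tip.label, NULL))
    pd <- phangorn::phyDat(states, type = "USER", levels = 0:1)
    expect_equal(sum(fitch_changes(tree, states)),
                 phangorn::parsimony(tree, pd))
  }
})

test_that("Mann-Whitney exact path matches enumeration-free references", {
  # tie-free small samples: compare with wilcox.test's exact p
  set.seed(74)
  for (rep in 1:15) {
    x <- sample(1:100, sample(3:8, 1))
    y <- (2 * sample(1:150, sample(3:8, 1)) + 1) / 2   # half-integers: no ties
    got <- mann_whitney(x, y)
    want <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(want$statistic))
  }
  # heavily tied integer data still yields a valid exact distribution
  res <- mann_whitney(c(0, 0, 1, 2), c(2, 2, 3, 3))
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # large samples: tie-corrected normal approximation
  big <- mann_whitney(rep(c(0, 1), 30), rep(c(1, 2), 40))
  expect_match(big$method, "normal")
})

test_that("SS-IDR site qualification follows the adjacency/ortholog rules", {
  # reference: ordered 1-10, SS-IDR 11-20; 3 orthologs
  ref_reg <- rbind(
    data.frame(protein_id = "R", start = 1L, end = 10L, kind = "ORDERED",
               subtype = "NONE", stringsAsFactors = FALSE),
    data.frame(protein_id = "R", start = 11L, end = 20L,
               kind = "DISORDERED", subtype = "SS_IDR",
               stringsAsFactors = FALSE))
  states <- rbind(R = c(rep(0, 10), rep(1, 10)),
                  O1 = c(rep(0, 10), rep(0, 5), rep(1, 5)),
                  O2 = c(rep(0, 10), rep(0, 5), rep(1, 5)),
                  O3 = c(rep(0, 12), rep(1, 8)))
  cm <- structure(list(family_id = "f", states = states, ref_map = 1:20,
                       scored = rep(TRUE, 20)),
                  class = "column_character_matrix")
  sites <- ss_idr_site_set(ref_reg, cm, "R", adjacency_cols = 1,
                           ortholog_ordered_frac = 0.5)
  expect_true(11 %in% sites)          # borders the ordered region
  expect_true(all(12:15 %in% sites))  # 2-3 of 3 orthologs ordered there
  expect_false(18 %in% sites)         # interior, all orthologs disordered
})

test_that("DOT summary normalises changes per node and edge", {
  # 5-leaf rooted binary tree has 8 edges; craft columns with 0,0,2,2 changes
  tree <- ape::read.tree(text = "((((A,B),C),D),E);")
  states <- cbind(c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 0),
                  c(1, 0, 1, 0, 0), c(0, 1, 0, 1, 1))
  rownames(states) <- LETTERS[1:5]
  expect_equal(fitch_changes(tree, states), c(0L, 0L, 2L, 2L))
  ref_reg <- data.frame(protein_id = "A", start = 1L, end = 4L,
                        kind = "DISORDERED", subtype = "NONE",
                        stringsAsFactors = FALSE)
  cm <- structure(list(family_id = "f", states = states, ref_map = 1:4,
                       scored = rep(TRUE, 4)),
                  class = "column_character_matrix")
  ds <- suppressMessages(dot_summary(cm, tree, ref_reg, integer(0)))
  expect_equal(ds$changes_per_node, 4 / (8 * 4))
  expect_null(ds$group_comparison)    # group A empty -> omitted
})

test_that("simulated rate contrast separates column groups", {
  set.seed(80)
  tree <- ape::rphylo(16, 1, 0)
  set.seed(7)
  slow <- simulate_characters(tree, rep(1, 200), 0.01, 0.01)
  fast <- simulate_characters(tree, rep(1, 200), 0.1, 0.1)
  ca <- fitch_changes(tree, slow$states)
  cb <- fitch_changes(tree, fast$states)
  expect_gt(mean(cb), mean(ca))
  expect_lt(mann_whitney(ca, cb)$p_value, 0.01)
})

test_that("mean Fitch changes increase with the simulated flip rate", {
  set.seed(81)
  tree <- ape::rphylo(12, 1, 0)
  means <- vapply(c(0.01, 0.05, 0.2), function(rate) {
    m <- vapply(1:3, function(s) {
      set.seed(s)
      sim <- simulate_characters(tree, rep(1, 150), rate, rate)
      mean(fitch_changes(tree, sim$states))
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("net disorder gain localises single changes and signs trends", {
  cm0 <- structure(list(family_id = "f",
                        states = matrix(1, 4, 3,
                                        dimnames = list(LETTERS[1:4], NULL)),
                        ref_map = 1:3, scored = rep(TRUE, 3)),
                   class = "column_character_matrix")
  ng0 <- net_disorder_gain(quartet, cm0)
  expect_true(all(ng0$net_gain == 0))

  # single gain on the terminal edge to A: every clade containing that edge
  states <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(LETTERS[1:4], NULL))
  cm1 <- structure(list(family_id = "f", states = states, ref_map = 1,
                        scored = TRUE), class = "column_character_matrix")
  ng1 <- net_disorder_gain(quartet, cm1)
  expect_equal(ng1$net_gain[ng1$clade == "A" & ng1$n_leaves == 4], 1)
  expect_equal(ng1$net_gain[ng1$clade == "A" & ng1$n_leaves == 2], 1)
  expect_equal(ng1$net_gain[ng1$clade == "C"], 0)

  # gain-biased evolution yields positive root-level net gain in most runs
  set.seed(82)
  tree <- ape::rphylo(10, 1, 0)
  wins <- 0
  for (s in 1:40) {
    set.seed(s + 1000)
    sim <- simulate_characters(tree, rep(0, 120), 0.15, 0.05)
    cm <- structure(list(family_id = "f", states = sim$states,
                         ref_map = seq_len(120),
                         scored = rep(TRUE, 120)),
                    class = "column_character_matrix")
    ng <- net_disorder_gain(tree, cm)
    if (ng$net_gain[which.max(ng$n_leaves)] > 0) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})
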
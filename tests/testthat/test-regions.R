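test_that("segmentation handles the canonical cases", {
  # all-negative profile: one ORDERED region
  r <- call_regions(rep(0, 40), threshold = 0.5)
  expect_equal(nrow(r), 1)
  expect_equal(r$kind, "ORDERED")
  expect_equal(c(r$start, r$end), c(1, 40))

  scores <- c(rep(0.9, 30), rep(0.1, 10), rep(0.9, 30))
  r <- call_regions(scores, threshold = 0.5, min_len = 25, max_gap = 0)
  expect_equal(r$kind, c("DISORDERED", "ORDERED", "DISORDERED"))
  expect_equal(r$start, c(1, 31, 41))
  expect_equal(r$end, c(30, 40, 70))

  # a gap of 10 bridged when max_gap allows it
  r <- call_regions(scores, threshold = 0.5, min_len = 25, max_gap = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$kind, "DISORDERED")
  expect_equal(c(r$start, r$end), c(1, 70))
})

test_that("segmentation matches the brute-force scan on random profiles", {
  set.seed(20)
  for (rep in 1:300) {
    L <- sample(1:500, 1)
    scores <- round(runif(L), 3)
    thr <- runif(1, 0.05, 0.95)
    ml <- sample(1:30, 1)
    mg <- sample(0:5, 1)
    got <- call_regions(scores, thr, ml, mg)
    want <- oracle_call_regions(scores, thr, ml, mg)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$kind, want$kind)
    # tiling invariant
    expect_equal(sum(got$end - got$start + 1), L)
    expect_true(all(got$start[-1] == got$end[-nrow(got)] + 1))
  }
})

test_that("lowering the threshold never loses disordered residues", {
  set.seed(21)
  scores <- runif(200)
  dis_residues <- function(thr) {
    r <- call_regions(scores, thr, min_len = 1, max_gap = 0)
    d <- r$kind == "DISORDERED"
    sum(r$end[d] - r$start[d] + 1)
  }
  counts <- vapply(seq(0.9, 0.1, by = -0.1), dis_residues, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("disorder_fraction computes tiled percentages", {
  r <- call_regions(rep(1, 60))
  expect_equal(disorder_fraction(r, 60), 100)
  r <- call_regions(c(rep(0.9, 50), rep(0.1, 50)))
  expect_equal(disorder_fraction(r, 100), 50)
  r <- call_regions(rep(0, 10))
  expect_equal(disorder_fraction(r, 10), 0)
  expect_error(disorder_fraction(r[0, ], 10), "tile")
})

test_that("group summaries separate per-protein and per-residue means", {
  prot <- data.frame(
    id = c("P1", "P2"),
    sequence = c(strrep("A", 100), strrep("A", 300)),
    group = "g", complexes = c("E;A", "E"), abundant = FALSE,
    stringsAsFactors = FALSE)
  regions <- rbind(
    call_regions(c(rep(0.9, 50), rep(0.1, 50)), protein_id = "P1"),
    call_regions(c(rep(0.9, 30), rep(0.1, 270)), protein_id = "P2"))
  s <- summarize_group(prot, regions, by = "class")
  expect_equal(s$per_protein_mean, 30)           # mean(50, 10)
  expect_equal(s$per_residue_mean, 20)           # 80 / 400
  byc <- summarize_group(prot, regions, by = "complex")
  expect_equal(byc$n_proteins[byc$group == "E"], 2)
  expect_equal(byc$n_proteins[byc$group == "A"], 1)
})

test_that("five-number summary and outliers follow the box-plot convention", {
  pcts <- c(0, 10, 20, 30, 100)
  prot <- data.frame(
    id = paste0("P", 1:5), sequence = strrep("A", 100), group = "g",
    complexes = "", abundant = FALSE, stringsAsFactors = FALSE)
  regions <- do.call(rbind, lapply(1:5, function(i) {
    sc <- c(rep(0.9, pcts[i]), rep(0.1, 100 - pcts[i]))
    call_regions(sc, protein_id = paste0("P", i))
  }))
  s <- summarize_group(prot, regions, by = "class")
  expect_equal(unlist(s[, c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), c(0, 10, 20, 30, 100))
  expect_match(s$outliers, "P5:100")
})

test_that("per-residue mean ignores partitioning; per-protein mean ignores length", {
  # P1 split into many alternating regions vs one block: same residue mean
  sc1 <- rep(c(0.9, 0.1), 50)
  sc2 <- c(rep(0.9, 50), rep(0.1, 50))
  prot <- data.frame(id = c("P1", "P2"),
                     sequence = strrep("A", 100), group = "g",
                     complexes = "", abundant = FALSE,
                     stringsAsFactors = FALSE)
  r <- rbind(call_regions(sc1, protein_id = "P1"),
             call_regions(sc2, protein_id = "P2"))
  s <- summarize_group(prot, r, by = "class")
  expect_equal(s$per_residue_mean, 50)
  expect_equal(s$per_protein_mean, 50)
})
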
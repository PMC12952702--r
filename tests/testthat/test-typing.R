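test_that("motif search reports overlapping matches with 1-based spans", {
  m <- find_motifs("RGGRGG", "RGG")
  expect_equal(m$start, c(1, 4))
  expect_equal(m$end, c(3, 6))

  m <- find_motifs("RAT", "RXT")                # A in [AGT], T in [AGTFIVR]
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 3))

  m <- find_motifs("QQQQQQ", "POLY_Q", homorepeat_len = 5)
  expect_equal(nrow(m), 1)                      # maximal run, not sub-runs
  expect_equal(c(m$start, m$end), c(1, 6))

  m <- find_motifs("RSRS", "RS_DIPEPTIDE")      # overlapping RS/SR
  expect_equal(m$start, c(1, 2, 3))

  m <- find_motifs("SGGYGG", "XGG")
  expect_equal(m$start, c(1, 4))

  expect_error(find_motifs("AAA", "NOPE"), "unknown motif")
})

test_that("CB classification follows the precedence and threshold rules", {
  p <- typing_params()
  # RS-rich beats charged even though R is charged
  rs <- strrep("RS", 15)
  expect_equal(classify_cb(rs, params = p), "CB_RS")
  # alternating E/K is charged
  ek <- strrep("EK", 13)
  expect_equal(classify_cb(ek, params = p), "CB_CHARGED")
  # a glutamine homorepeat inside an otherwise bland region
  pq <- paste0(strrep("ATNAS", 5), "QQQQQ")
  expect_equal(classify_cb(pq, params = p), "CB_PQ")
  # G-rich via composition
  g <- strrep("GGAGN", 6)
  expect_equal(classify_cb(g, params = p), "CB_G")
  # short regions are never CB-typed
  expect_equal(classify_cb(strrep("RS", 10), params = p), "NONE")
  # out-of-range region errors
  expect_error(classify_cb("ACDE", start = 2, end = 9), "outside")
})

test_that("CB call ignores sequence context outside the region", {
  p <- typing_params()
  core <- strrep("EK", 15)
  left <- strrep("LIVALIVA", 10)
  seq1 <- paste0(left, core)
  expect_equal(classify_cb(seq1, start = nchar(left) + 1,
                           end = nchar(seq1), params = p),
               classify_cb(core, params = p))
})

test_that("noncharged bias needs a residue at bias_fold over background", {
  p <- typing_params()
  # asparagine at ~50% vastly exceeds 3x its background frequency, with no
  # charged/RS/G/PQ trigger (runs broken by alternation)
  n_rich <- strrep("NANT", 10)
  expect_equal(classify_cb(n_rich, params = p), "CB_NONCHARGED")
})

test_that("SS-IDR annotation counts only runs of qualifying length", {
  p <- typing_params()
  region <- data.frame(protein_id = "P1", start = 1L, end = 40L,
                       kind = "DISORDERED", stringsAsFactors = FALSE)
  states <- paste0(strrep("H", 30), strrep("C", 10))
  ann <- annotate_ss_idr(region, states, p)
  expect_true(ann$is_ss_idr)
  expect_equal(ann$alpha_frac, 0.75)
  expect_equal(ann$beta_frac, 0)

  ann <- annotate_ss_idr(region, strrep("C", 40), p)
  expect_false(ann$is_ss_idr)
  expect_equal(ann$alpha_frac + ann$beta_frac, 0)

  # an H-run of 3 is below ss_min_elem = 4 and contributes nothing
  states <- paste0("HHH", strrep("C", 37))
  ann <- annotate_ss_idr(region, states, p)
  expect_equal(ann$alpha_frac, 0)
  expect_false(ann$is_ss_idr)
})

test_that("SS-IDR overrides the primary subtype but keeps the CB call", {
  prot <- data.frame(id = "P1", sequence = strrep("RS", 30),
                     group = "g", complexes = "", abundant = FALSE,
                     stringsAsFactors = FALSE)
  regions <- call_regions(rep(1, 60), protein_id = "P1")
  ss <- c(P1 = strrep("H", 60))
  typed <- type_regions(prot, regions, ss)
  expect_equal(typed$subtype, "SS_IDR")
  expect_equal(typed$cb_subtype, "CB_RS")
})

test_that("typing report computes class percentages over class residues", {
  prot <- data.frame(id = "P1", sequence = paste0(strrep("RS", 25),
                                                  strrep("LIVAM", 10)),
                     group = "SR protein", complexes = "", abundant = FALSE,
                     stringsAsFactors = FALSE)
  regions <- call_regions(c(rep(0.9, 50), rep(0.1, 50)), protein_id = "P1")
  typed <- type_regions(prot, regions)
  rep <- typing_report(prot, typed)
  expect_equal(rep$cb_rs_pct, 50)
  expect_equal(rep$ss_idr_pct, 0)

  # no disordered regions: all zeros
  r0 <- call_regions(rep(0, 100), protein_id = "P1")
  rep0 <- typing_report(prot, r0)
  expect_true(all(rep0[, grepl("_pct$", names(rep0))] == 0))
})

test_that("raising a subtype threshold never yields more calls of it", {
  set.seed(31)
  segs <- replicate(60, paste(sample(c("R", "S", "G", "E", "K", "A", "N",
                                       "P", "Q", "T"), 40, replace = TRUE,
                                     prob = c(3, 3, 2, 2, 2, 2, 2, 2, 2, 2)),
                              collapse = ""))
  count_rs <- function(frac) {
    p <- typing_params(rs_frac = frac)
    sum(vapply(segs, function(s) classify_cb(s, params = p),
               character(1)) == "CB_RS")
  }
  counts <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.6), count_rs, numeric(1))
  expect_true(all(diff(counts) <= 0))

  count_chg <- function(frac) {
    p <- typing_params(charged_frac = frac)
    sum(vapply(segs, function(s) classify_cb(s, params = p),
               character(1)) == "CB_CHARGED")
  }
  counts <- vapply(c(0.2, 0.3, 0.4, 0.5), count_chg, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
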
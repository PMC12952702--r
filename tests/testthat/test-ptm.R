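test_that("PTM partition counts residues once and conserves totals", {
  regions <- rbind(
    data.frame(protein_id = "P1", start = 1L, end = 5L, kind = "DISORDERED",
               stringsAsFactors = FALSE),
    data.frame(protein_id = "P1", start = 6L, end = 10L, kind = "ORDERED",
               stringsAsFactors = FALSE))
  lengths <- c(P1 = 10L)
  sites <- make_sites("P1", c(2, 7))
  part <- partition_ptms(sites, regions, lengths)
  expect_equal(unname(part$pooled), c(1, 4, 1, 4))

  # two annotations on the same residue count once
  sites2 <- make_sites("P1", c(2, 2), label = c("phosphoserine", "citrulline"))
  part2 <- partition_ptms(sites2, regions, lengths)
  expect_equal(unname(part2$pooled), c(1, 4, 0, 5))

  # empty site list fills the complements
  part3 <- partition_ptms(sites[0, ], regions, lengths)
  expect_equal(unname(part3$pooled), c(0, 5, 0, 5))
  expect_equal(sum(part3$pooled), 10)

  # per-protein rows sum to the pooled table
  expect_equal(colSums(part$per_protein[, -1]), c(
    ptm_in_idr = 1, non_ptm_in_idr = 4, ptm_in_ordered = 1,
    non_ptm_in_ordered = 4))

  expect_error(partition_ptms(make_sites("PX", 1), regions, lengths), "PX")
})

test_that("Fisher enrichment reproduces arithmetic and degenerate cases", {
  res <- fisher_enrichment(c(1012, 32068, 831, 78059))
  expect_equal(res$statistic, (1012 * 78059) / (32068 * 831),
               tolerance = 1e-12)
  sym <- fisher_enrichment(c(10, 90, 10, 90))
  expect_equal(sym$statistic, 1)
  expect_equal(sym$p_value, 1)
  expect_error(fisher_enrichment(c(0, 0, 0, 0)), "zero")
  inf <- fisher_enrichment(c(5, 5, 0, 5))
  expect_identical(inf$statistic, Inf)
})

test_that("two-sided Fisher p matches hypergeometric enumeration", {
  expect_equal(fisher_enrichment(c(3, 7, 1, 9))$p_value,
               oracle_fisher_two_sided(3, 7, 1, 9), tolerance = 1e-12)
  set.seed(40)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    x <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    res <- fisher_enrichment(x)
    expect_equal(res$p_value,
                 oracle_fisher_two_sided(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-10)
  }
})

test_that("density comparison uses the exact paired signed-rank law", {
  # 6 proteins, IDR density uniformly higher: one-sided exact p = 1/2^6
  per <- data.frame(
    protein_id = paste0("P", 1:6),
    ptm_in_idr = c(5, 6, 7, 8, 9, 10), non_ptm_in_idr = 95 - c(5:10),
    ptm_in_ordered = 1:6, non_ptm_in_ordered = 99 - 1:6,
    stringsAsFactors = FALSE)
  part <- structure(list(per_protein = per), class = "ptm_partition")
  res <- density_comparison(part, alternative = "greater")
  expect_equal(res$p_value, 1 / 64, tolerance = 1e-12)
  expect_match(res$method, "signed rank")

  # identical densities in both compartments are degenerate
  same <- per
  same$ptm_in_ordered <- same$ptm_in_idr
  same$non_ptm_in_ordered <- same$non_ptm_in_idr
  expect_error(density_comparison(
    structure(list(per_protein = same), class = "ptm_partition")),
    "no nonzero pairs")
})

test_that("planted IDR enrichment is detected on synthetic data", {
  cfg <- sim_config(n_proteins = 120, seed = 19)
  sim <- simulate_proteins(cfg)
  pm <- simulate_ptms_and_mutations(cfg, sim)
  part <- partition_ptms(pm$ptms, sim$truth$regions,
                         protein_lengths(sim$proteins))
  expect_lt(density_comparison(part)$p_value, 1e-6)
  expect_lt(fisher_enrichment(part)$p_value, 1e-6)
})

test_that("PTM type ratios are annotation-level", {
  regions <- rbind(
    data.frame(protein_id = "P1", start = 1L, end = 50L,
               kind = "DISORDERED", stringsAsFactors = FALSE),
    data.frame(protein_id = "P1", start = 51L, end = 100L, kind = "ORDERED",
               stringsAsFactors = FALSE))
  sites <- make_sites("P1", c(10, 20, 60, 70, 5, 15),
                      label = c(rep("phosphoserine", 4), "citrulline",
                                "citrulline"))
  tab <- ptm_idr_ratio(sites, regions)
  expect_equal(tab$ratio[tab$label == "phosphoserine"], 0.5)
  expect_equal(tab$ratio[tab$label == "citrulline"], 1.0)
})

test_that("PTM type distribution sums to 100 percent in every stratum", {
  regions <- data.frame(protein_id = c("P1", "P2"), start = 1L, end = 40L,
                        kind = "DISORDERED", stringsAsFactors = FALSE)
  sites <- make_sites(rep(c("P1", "P2"), c(4, 3)), c(1:4, 1:3),
                      label = c(rep("phosphoserine", 3), "phosphothreonine",
                                rep("citrulline", 3)))
  dist <- ptm_type_distribution(sites, regions, "idr_only",
                                groups = c(P1 = "SR", P2 = "hnRNP"))
  for (g in unique(dist$group))
    expect_equal(sum(dist$percent[dist$group == g]), 100)
  all_row <- dist[dist$group == "(all)", ]
  expect_equal(all_row$percent[all_row$label == "phosphoserine"],
               100 * 3 / 7)
  # single type: 100%
  one <- ptm_type_distribution(make_sites("P1", 1), regions, "all")
  expect_equal(one$percent, 100)
  # empty scope: empty table
  none <- ptm_type_distribution(make_sites("P1", 1)[0, ], regions, "all")
  expect_equal(nrow(none), 0)
})

test_that("uniform within-protein permutation drives the odds ratio to 1", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_proteins(cfg)
  pm <- simulate_ptms_and_mutations(cfg, sim)
  lengths <- protein_lengths(sim$proteins)
  regions <- sim$truth$regions
  masks <- lapply(names(lengths), function(pid)
    make_mask(regions, pid, lengths[[pid]]))
  names(masks) <- names(lengths)
  n_ptm <- stats::setNames(rep(0L, length(lengths)), names(lengths))
  tab <- table(pm$ptms$protein_id)
  n_ptm[names(tab)] <- as.integer(tab)
  set.seed(77)
  ors <- vapply(1:200, function(rep) {
    a <- b <- c2 <- d <- 0
    for (pid in names(lengths)) {
      k <- n_ptm[[pid]]
      m <- masks[[pid]]
      hit <- rep(FALSE, lengths[[pid]])
      if (k > 0) hit[sample.int(lengths[[pid]], k)] <- TRUE
      a <- a + sum(hit & m); b <- b + sum(!hit & m)
      c2 <- c2 + sum(hit & !m); d <- d + sum(!hit & !m)
    }
    (a * d) / (b * c2)
  }, numeric(1))
  expect_gt(mean(ors), 0.9)
  expect_lt(mean(ors), 1.1)
})
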
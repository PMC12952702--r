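# End-to-end orchestration: region calling -> typing -> PTM analysis ->
# mutation analysis -> DOT (when ortholog families are supplied), with all
# summary tables written as TSV and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters.  Every value is echoed into
#' the run manifest so each run documents its own assumptions.
#'
#' @param fasta,scores,meta required input paths (sequences, disorder score
#'   table, protein metadata).
#' @param ss,ptms,mutations optional input paths.
#' @param families_dir optional directory holding `<family>.afa`,
#'   `<family>.nwk` and `references.tsv` (plus `ortholog_regions.tsv` with
#'   pre-called ortholog regions, or per-ortholog rows in `scores`).
#' @param out output directory.
#' @param threshold,min_len,max_gap region-calling parameters.
#' @param typing a [typing_params()] list.
#' @param flank_window,n_perm,perm_seed mutation-analysis options.
#' @param rank_cutoff disorder-percentage cutoff for the ranking table.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, scores, meta, out, ss = NULL,
                            ptms = NULL, mutations = NULL,
                            families_dir = NULL, threshold = 0.5,
                            min_len = 1L, max_gap = 0L,
                            typing = typing_params(), flank_window = 5L,
                            n_perm = 999L, perm_seed = 1L,
                            rank_cutoff = 70) {
  structure(list(fasta = fasta, scores = scores, meta = meta, out = out,
                 ss = ss, ptms = ptms, mutations = mutations,
                 families_dir = families_dir, threshold = threshold,
                 min_len = as.integer(min_len), max_gap = as.integer(max_gap),
                 typing = typing, flank_window = as.integer(flank_window),
                 n_perm = as.integer(n_perm), perm_seed = as.integer(perm_seed),
                 rank_cutoff = rank_cutoff),
            class = "pipeline_config")
}

write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

stat_test_row <- function(res)
  data.frame(method = res$method, statistic = res$statistic,
             p_value = res$p_value, n = paste(res$n, collapse = "/"),
             stringsAsFactors = FALSE)

#' Run the full analysis pipeline
#'
#' Executes region calling, IDR typing, PTM analysis, mutation analysis and
#' (when families are configured) the DOT stage, writing the figure-analogue
#' summary tables and `manifest.json` into `config$out`.  Outputs are a pure
#' function of inputs and configuration; re-running reproduces identical
#' tables (the manifest timestamp aside).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the output directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logi <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    logi("stage %-12s done in %.2fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  manifest <- list(package_version = as.character(utils::packageVersion("idrscope")),
                   config = config[setdiff(names(config), "typing")],
                   typing = unclass(config$typing),
                   timestamp = format(Sys.time()))

  proteins <- stage("load", {
    p <- read_fasta(config$fasta)
    read_metadata(config$meta, p)
  })
  profiles <- stage("scores", read_profile_table(config$scores, "disorder"))
  ss <- if (!is.null(config$ss))
    stage("ss", read_profile_table(config$ss, "ss")) else NULL

  regions <- stage("call_regions", {
    r <- call_regions_all(profiles[proteins$id], config$threshold,
                          config$min_len, config$max_gap)
    write_regions(r, file.path(out, "regions.tsv"))
    r
  })
  typed <- stage("typing", {
    ty <- type_regions(proteins, regions, ss, config$typing)
    write_regions(ty, file.path(out, "typed_regions.tsv"))
    write_tsv(typing_report(proteins, ty), file.path(out, "typing_report.tsv"))
    ty
  })
  stage("summaries", {
    write_tsv(summarize_group(proteins, typed, "complex"),
              file.path(out, "summary_by_complex.tsv"))
    write_tsv(summarize_group(proteins, typed, "class"),
              file.path(out, "summary_by_class.tsv"))
    write_tsv(rank_by_disorder(proteins, typed, config$rank_cutoff),
              file.path(out, "ranked_disorder.tsv"))
  })

  lengths <- protein_lengths(proteins)
  groups <- stats::setNames(proteins$group, proteins$id)
  ptms <- if (is.null(config$ptms)) NULL else stage("ptm", {
    ptms <- read_site_table(config$ptms, "PTM", proteins)
    part <- partition_ptms(ptms, typed, lengths)
    write_tsv(data.frame(cell = names(part$pooled),
                         count = as.integer(part$pooled)),
              file.path(out, "pooled_table.tsv"))
    write_tsv(stat_test_row(fisher_enrichment(part)),
              file.path(out, "fisher.tsv"))
    write_tsv(stat_test_row(density_comparison(part)),
              file.path(out, "density_test.tsv"))
    write_tsv(ptm_idr_ratio(ptms, typed), file.path(out, "type_ratios.tsv"))
    write_tsv(ptm_type_distribution(ptms, typed, "idr_only", groups),
              file.path(out, "type_distribution_by_class.tsv"))
    ptms
  })
  if (!is.null(config$mutations)) stage("mutations", {
    muts <- read_site_table(config$mutations, "MUTATION", proteins)
    mm <- map_mutations(muts, typed, groups)
    write_tsv(mm$table, file.path(out, "mutation_table.tsv"))
    if (!is.null(mm$family_counts))
      write_tsv(mm$family_counts, file.path(out, "family_counts.tsv"))
    write_tsv(mm$tumor_counts, file.path(out, "tumor_counts.tsv"))
    if (!is.null(ptms)) {
      write_tsv(flanking_pairs(muts, ptms, config$flank_window),
                file.path(out, "flanking_pairs.tsv"))
      write_tsv(stat_test_row(
        flanking_enrichment(muts, ptms, lengths, config$flank_window,
                            config$n_perm, config$perm_seed)),
        file.path(out, "flanking_test.tsv"))
    }
  })

  if (!is.null(config$families_dir)) stage("dot", {
    refs <- utils::read.delim(file.path(config$families_dir,
                                        "references.tsv"),
                              stringsAsFactors = FALSE)
    orth_path <- file.path(config$families_dir, "ortholog_regions.tsv")
    orth_regions <- if (file.exists(orth_path)) read_regions(orth_path)
    else typed
    rows <- list()
    for (i in seq_len(nrow(refs))) {
      fid <- refs$family_id[i]
      fam <- read_family(file.path(config$families_dir, paste0(fid, ".afa")),
                         file.path(config$families_dir, paste0(fid, ".nwk")),
                         refs$reference_id[i], fid)
      # reference regions carry the typing done on the main dataset
      fam_regions <- rbind(
        typed[typed$protein_id == fam$reference_id, ,
              drop = FALSE][, names(orth_regions)],
        orth_regions[orth_regions$protein_id %in%
                       setdiff(names(fam$alignment), fam$reference_id), ,
                     drop = FALSE])
      cm <- build_character_matrix(fam, fam_regions)
      ref_reg <- typed[typed$protein_id == fam$reference_id, , drop = FALSE]
      sss <- ss_idr_site_set(ref_reg, cm, fam$reference_id)
      ds <- dot_summary(cm, fam$tree, ref_reg, sss)
      write_tsv(data.frame(column = seq_along(ds$per_column_changes),
                           changes = ds$per_column_changes),
                file.path(out, paste0("dot_changes_", fid, ".tsv")))
      write_tsv(net_disorder_gain(fam$tree, cm),
                file.path(out, paste0("clade_gain_", fid, ".tsv")))
      rows[[fid]] <- data.frame(
        family_id = fid, n_scored = ds$n_scored, n_edges = ds$n_edges,
        changes_per_node = ds$changes_per_node,
        mean_changes_ss = ds$mean_changes_ss,
        mean_changes_other = ds$mean_changes_other,
        comparison_p = if (is.null(ds$group_comparison)) NA_real_
        else ds$group_comparison$p_value, stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, rows), file.path(out, "dot_summary.tsv"))
  }) else manifest$evolution <- "skipped"

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  logi("pipeline complete: %s", out)
  invisible(out)
}

#' Rank proteins by disorder fraction
#'
#' Sorts proteins by disorder percentage (descending; ties broken by
#' accession), keeps those at or above `cutoff`, and splits by the abundance
#' flag.
#'
#' @param proteins protein table with metadata.
#' @param regions tiled region table.
#' @param cutoff minimum disorder percentage retained (default 70).
#' @return data.frame with columns `abundance`, `protein_id`,
#'   `disorder_fraction`, `group`.
#' @export
rank_by_disorder <- function(proteins, regions, cutoff = 70) {
  pp <- per_protein_disorder(proteins, regions)
  pp$group <- proteins$group[match(pp$protein_id, proteins$id)]
  pp$abundance <- ifelse(proteins$abundant[match(pp$protein_id, proteins$id)],
                         "abundant", "non-abundant")
  pp <- pp[pp$disorder_pct >= cutoff, , drop = FALSE]
  pp <- pp[order(-pp$disorder_pct, pp$protein_id), , drop = FALSE]
  pp <- pp[order(match(pp$abundance, c("abundant", "non-abundant"))), ,
           drop = FALSE]
  data.frame(abundance = pp$abundance, protein_id = pp$protein_id,
             disorder_fraction = pp$disorder_pct, group = pp$group,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Validate a report directory's internal consistency
#'
#' Re-checks that the written tables reconcile: regions tile every protein,
#' the pooled PTM table matches the per-protein partition recomputed from
#' the written regions and sites, and the typing report denominators equal
#' the class residue totals.
#'
#' @param dir report directory produced by [run_all()].
#' @param fasta,meta,ptms the input paths used for the run.
#' @return TRUE invisibly; stops with a message on any inconsistency.
#' @export
report_validate <- function(dir, fasta, meta, ptms = NULL) {
  proteins <- read_metadata(meta, read_fasta(fasta))
  lengths <- protein_lengths(proteins)
  typed <- read_regions(file.path(dir, "typed_regions.tsv"))
  for (pid in proteins$id)
    check_tiling(typed[typed$protein_id == pid, , drop = FALSE],
                 lengths[[pid]], pid)
  if (!is.null(ptms) && file.exists(file.path(dir, "pooled_table.tsv"))) {
    pooled <- utils::read.delim(file.path(dir, "pooled_table.tsv"))
    sites <- read_site_table(ptms, "PTM", proteins)
    part <- partition_ptms(sites, typed, lengths)
    if (!all(part$pooled == pooled$count))
      stopf("pooled PTM table does not reconcile with regions + sites")
    if (sum(pooled$count) != sum(lengths))
      stopf("pooled PTM table does not sum to total residues")
  }
  invisible(TRUE)
}
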
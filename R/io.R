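# Readers and writers for the flat-file formats the pipeline exchanges:
# FASTA (sequences, alignments), Newick trees, and TSV tables for
# per-residue scores, secondary-structure states, PTM/mutation sites and
# protein metadata.  All coordinates are 1-based inclusive.

#' Read protein sequences from FASTA
#'
#' UniProt-style headers (`sp|ACC|NAME` or `tr|ACC|NAME`) yield the accession
#' as the record id; any other header uses its first whitespace-delimited
#' token.  Sequences are uppercased and residues outside the 20 canonical
#' letters are mapped to `X` with a warning (such positions are excluded from
#' composition denominators downstream).
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `sequence`, plus metadata
#'   placeholders `group` (NA), `complexes` (empty) and `abundant` (FALSE),
#'   to be filled from [read_metadata()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stopf("FASTA file %s contains no sequences", path)
  headers <- names(aa)
  ids <- vapply(headers, function(h) {
    tok <- strsplit(h, "[ \t]")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate sequence id(s): %s", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(aa))
  clean <- gsub(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")),
                "X", seqs)
  n_sub <- sum(nchar(gsub(sprintf("[%s]", paste(AA_CANONICAL, collapse = "")),
                          "", seqs)) > 0L)
  if (any(clean != seqs))
    warning(sprintf("%d sequence(s) contained non-canonical residues; mapped to X",
                    n_sub), call. = FALSE)
  if (any(nchar(clean) < 1)) stopf("zero-length sequence in %s", path)
  data.frame(id = ids, sequence = clean, group = NA_character_,
             complexes = "", abundant = FALSE, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins protein table (`id`, `sequence`).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-residue profile tables (disorder scores or SS states)
#'
#' The table must be TSV with columns `protein_id`, `position`, `value` and
#' 1-based positions covering exactly `1..L` for every protein.
#'
#' @param path TSV file.
#' @param kind `"disorder"` (numeric scores in \[0,1\]; binary 0/1 labels are
#'   admitted unchanged) or `"ss"` (states H/E/C).
#' @return for `"disorder"`, a named list of numeric vectors; for `"ss"`, a
#'   named character vector of state strings (one per protein).
#' @export
read_profile_table <- function(path, kind = c("disorder", "ss")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(value = "character"))
  need <- c("protein_id", "position", "value")
  if (!all(need %in% names(tab)))
    stopf("profile table needs columns: %s", paste(need, collapse = ", "))
  out <- list()
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, , drop = FALSE]
    pos <- as.integer(sub$position)
    if (anyDuplicated(pos))
      stopf("protein %s: duplicated position(s) %s", pid,
            paste(unique(pos[duplicated(pos)]), collapse = ", "))
    L <- max(pos)
    miss <- setdiff(seq_len(L), pos)
    if (length(miss))
      stopf("protein %s: missing position(s) %s", pid,
            paste(miss, collapse = ", "))
    o <- order(pos)
    vals <- sub$value[o]
    if (kind == "disorder") {
      v <- as.numeric(vals)
      if (anyNA(v) || any(v < 0 | v > 1))
        stopf("protein %s: disorder values must be numeric in [0,1]", pid)
      out[[pid]] <- v
    } else {
      if (!all(vals %in% c("H", "E", "C")))
        stopf("protein %s: SS states must be H, E or C", pid)
      out[[pid]] <- paste(vals, collapse = "")
    }
  }
  if (kind == "ss") unlist(out) else out
}

#' Write a per-residue profile table
#'
#' Inverse of [read_profile_table()].
#'
#' @param profiles named list of numeric score vectors, or named character
#'   vector of SS state strings.
#' @param path output TSV.
#' @export
write_profile_table <- function(profiles, path) {
  if (is.character(profiles)) profiles <- lapply(profiles, function(s)
    strsplit(s, "")[[1]])
  rows <- lapply(names(profiles), function(pid)
    data.frame(protein_id = pid, position = seq_along(profiles[[pid]]),
               value = profiles[[pid]], stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PTM or mutation site tables
#'
#' TSV with columns `protein_id`, `position`, `label`, and for mutations the
#' optional semicolon-delimited set columns `tumor_types` and
#' `phenotype_ids`.  When `proteins` is supplied, sites outside `1..L` are
#' dropped and reported in the `"rejected"` attribute of the result.
#'
#' @param path TSV file.
#' @param site_class `"PTM"` or `"MUTATION"`.
#' @param proteins optional protein table used to range-validate positions.
#' @return data.frame of annotated sites with columns `protein_id`,
#'   `position`, `site_class`, `label`, `tumor_types`, `phenotype_ids`.
#' @export
read_site_table <- function(path, site_class = c("PTM", "MUTATION"),
                            proteins = NULL) {
  site_class <- match.arg(site_class)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(position = "character"))
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab)))
    stopf("site table needs columns: %s", paste(need, collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(tab$position))
  if (anyNA(pos_num) || any(pos_num != floor(pos_num)))
    stopf("non-integer position(s) in %s", path)
  sites <- data.frame(
    protein_id = tab$protein_id,
    position = as.integer(pos_num),
    site_class = site_class,
    label = tab$label,
    tumor_types = if ("tumor_types" %in% names(tab)) tab$tumor_types else "",
    phenotype_ids = if ("phenotype_ids" %in% names(tab)) tab$phenotype_ids else "",
    stringsAsFactors = FALSE)
  if (any(!nzchar(sites$label))) stopf("empty site label(s) in %s", path)
  rejected <- sites[0, ]
  if (!is.null(proteins)) {
    len <- protein_lengths(proteins)
    known <- sites$protein_id %in% names(len)
    ok <- known & sites$position >= 1L &
      sites$position <= len[sites$protein_id]
    ok[is.na(ok)] <- FALSE
    rejected <- sites[!ok, , drop = FALSE]
    if (nrow(rejected))
      message(sprintf("read_site_table: rejected %d out-of-range site(s)",
                      nrow(rejected)))
    sites <- sites[ok, , drop = FALSE]
    rownames(sites) <- NULL
  }
  attr(sites, "rejected") <- rejected
  sites
}

#' @rdname read_site_table
#' @param sites site table to write.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(
    sites[, c("protein_id", "position", "label", "tumor_types",
              "phenotype_ids")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein metadata (class/family, complexes, abundance)
#'
#' TSV with columns `protein_id`, `group`, `complexes`
#' (semicolon-delimited), `abundant` (TRUE/FALSE).
#'
#' @param path TSV file.
#' @param proteins optional protein table to merge the metadata into.
#' @return the metadata table, or `proteins` with metadata columns filled.
#' @export
read_metadata <- function(path, proteins = NULL) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(complexes = "character"))
  need <- c("protein_id", "group", "complexes", "abundant")
  if (!all(need %in% names(meta)))
    stopf("metadata needs columns: %s", paste(need, collapse = ", "))
  meta$abundant <- as.logical(meta$abundant)
  meta$complexes[is.na(meta$complexes)] <- ""
  if (is.null(proteins)) return(meta)
  idx <- match(proteins$id, meta$protein_id)
  proteins$group <- meta$group[idx]
  proteins$complexes <- ifelse(is.na(idx), "", meta$complexes[idx])
  proteins$abundant <- ifelse(is.na(idx), FALSE, meta$abundant[idx])
  proteins
}

#' Assemble an ortholog family from an alignment and a rooted tree
#'
#' The alignment is FASTA with `-` gaps; the Newick tree's leaf set must
#' equal the alignment's sequence ids.  Unrooted trees are midpoint-rooted
#' with a logged notice (parsimony reconstruction downstream needs a root).
#'
#' @param alignment_path aligned FASTA.
#' @param tree_path Newick file.
#' @param reference_id id of the reference (e.g. human) sequence.
#' @param family_id optional label; defaults to the alignment file stem.
#' @return an object of class `ortholog_family`: list with `family_id`,
#'   `alignment` (named character vector of equal-length aligned strings),
#'   `tree` (rooted `phylo`) and `reference_id`.
#' @export
read_family <- function(alignment_path, tree_path, reference_id,
                        family_id = NULL) {
  aa <- Biostrings::readAAStringSet(alignment_path)
  if (length(aa) == 0) stopf("empty alignment: %s", alignment_path)
  aln <- toupper(as.character(aa))
  names(aln) <- vapply(strsplit(names(aa), "[ \t]"), `[[`, character(1), 1)
  if (length(unique(nchar(aln))) != 1)
    stopf("aligned sequences have unequal lengths in %s", alignment_path)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stopf("could not parse tree: %s", tree_path)
  if (!ape::is.rooted(tree)) {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stopf("tree is unrooted and phangorn is unavailable for midpoint rooting")
    message("read_family: input tree unrooted; midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  ortholog_family(family_id %||% sub("\\.[^.]*$", "", basename(alignment_path)),
                  aln, tree, reference_id)
}

#' @rdname read_family
#' @param alignment named character vector of aligned sequences.
#' @param tree rooted `phylo`.
#' @export
ortholog_family <- function(family_id, alignment, tree, reference_id) {
  extra_tree <- setdiff(tree$tip.label, names(alignment))
  extra_aln <- setdiff(names(alignment), tree$tip.label)
  if (length(extra_tree) || length(extra_aln))
    stopf("tree/alignment leaf mismatch; only in tree: {%s}; only in alignment: {%s}",
          paste(extra_tree, collapse = ","), paste(extra_aln, collapse = ","))
  if (!reference_id %in% names(alignment))
    stopf("reference id %s absent from alignment", reference_id)
  if (length(unique(nchar(alignment))) != 1)
    stopf("aligned sequences have unequal lengths")
  structure(list(family_id = family_id, alignment = alignment,
                 tree = tree, reference_id = reference_id),
            class = "ortholog_family")
}

#' Read / write region tables
#'
#' Regions are exchanged as TSV with columns `protein_id`, `start`, `end`,
#' `kind`, `subtype`, `cb_subtype`, `alpha_frac`, `beta_frac`.
#'
#' @param path TSV file.
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "kind")
  if (!all(need %in% names(tab)))
    stopf("region table needs columns: %s", paste(need, collapse = ", "))
  for (col in c("subtype", "cb_subtype"))
    if (!col %in% names(tab)) tab[[col]] <- "NONE"
  for (col in c("alpha_frac", "beta_frac"))
    if (!col %in% names(tab)) tab[[col]] <- 0
  tab
}

#' @rdname read_regions
#' @param regions region table.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
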
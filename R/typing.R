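# IDR typing: compositional-bias subtypes (RS-like, poly-P/Q, G-rich,
# charged, noncharged) for long (>= 25 residue) disordered regions, and
# SS-IDR annotation for disordered regions carrying predicted secondary
# structure.

CB_SUBTYPES <- c("CB_RS", "CB_G", "CB_PQ", "CB_CHARGED", "CB_NONCHARGED")

#' Typing parameters
#'
#' Thresholds driving CB and SS-IDR classification.  Only the >= 25 residue
#' minimum for compositionally biased IDRs is a literature constant; the
#' remaining values are this package's documented defaults (see the methods
#' vignette) and can all be overridden.
#'
#' @param cb_min_len minimum region span eligible for a CB subtype (25).
#' @param window sliding-window width for windowed fraction rules (25).
#' @param rs_frac minimum Arg+Ser fraction in some window for RS-like (0.40).
#' @param rs_min_dipeptides minimum RS/SR dipeptides in that window (3).
#' @param homorepeat_len minimum homorepeat run for poly-P/Q and poly-G (5).
#' @param g_frac minimum Gly fraction in some window for G-rich (0.30).
#' @param g_min_motifs minimum distinct G-motif matches (RGG, \[RSY\]GG,
#'   R\[AGT\]\[AGTFIVR\], Gly runs) in the region for G-rich (2).
#' @param charged_frac minimum D/E/K/R fraction in some window (0.35).
#' @param bias_fold fold-over-background residue frequency defining
#'   noncharged bias (3.0).
#' @param ss_min_elem minimum H/E run length counted as a secondary-structure
#'   element (4).
#' @param ss_overlap_frac minimum fraction of region residues inside such
#'   elements for an SS-IDR call (0.50).
#' @return list of class `typing_params`.
#' @export
typing_params <- function(cb_min_len = 25L, window = 25L, rs_frac = 0.40,
                          rs_min_dipeptides = 3L, homorepeat_len = 5L,
                          g_frac = 0.30, g_min_motifs = 2L,
                          charged_frac = 0.35, bias_fold = 3.0,
                          ss_min_elem = 4L, ss_overlap_frac = 0.50) {
  p <- list(cb_min_len = as.integer(cb_min_len), window = as.integer(window),
            rs_frac = rs_frac, rs_min_dipeptides = as.integer(rs_min_dipeptides),
            homorepeat_len = as.integer(homorepeat_len), g_frac = g_frac,
            g_min_motifs = as.integer(g_min_motifs),
            charged_frac = charged_frac, bias_fold = bias_fold,
            ss_min_elem = as.integer(ss_min_elem),
            ss_overlap_frac = ss_overlap_frac)
  fr <- c("rs_frac", "g_frac", "charged_frac", "ss_overlap_frac")
  if (any(unlist(p[fr]) <= 0 | unlist(p[fr]) > 1))
    stopf("fraction parameters must lie in (0, 1]")
  lens <- c("cb_min_len", "window", "rs_min_dipeptides", "homorepeat_len",
            "g_min_motifs", "ss_min_elem")
  if (any(unlist(p[lens]) < 1)) stopf("length parameters must be >= 1")
  structure(p, class = "typing_params")
}

#' Locate sequence motifs
#'
#' Reports all (including mutually overlapping) matches of the requested
#' motif classes.  `XGG` is the class \[RSY\]GG, `RXT` is
#' R\[AGT\]\[AGTFIVR\]; `POLY_P`/`POLY_Q`/`POLY_G` are maximal homorepeat
#' runs of length >= `homorepeat_len`; `RS_DIPEPTIDE` matches RS or SR.
#'
#' @param sequence uppercase amino-acid string.
#' @param motif_set character vector drawn from `RGG`, `XGG`, `RXT`,
#'   `POLY_P`, `POLY_Q`, `POLY_G`, `RS_DIPEPTIDE`.
#' @param homorepeat_len minimum homorepeat run length.
#' @return data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive), ordered by start.
#' @export
#' @examples
#' find_motifs("RGGRGG", "RGG")
find_motifs <- function(sequence, motif_set, homorepeat_len = 5L) {
  known <- c("RGG", "XGG", "RXT", "POLY_P", "POLY_Q", "POLY_G",
             "RS_DIPEPTIDE")
  bad <- setdiff(motif_set, known)
  if (length(bad)) stopf("unknown motif label(s): %s", paste(bad, collapse = ", "))
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  hits <- list()
  add <- function(motif, start, end) {
    if (length(start))
      hits[[length(hits) + 1L]] <<- data.frame(
        motif = motif, start = as.integer(start), end = as.integer(end),
        stringsAsFactors = FALSE)
  }
  # fixed-width classes scanned position-wise so overlaps are all reported
  scan_fixed <- function(classes) {
    w <- length(classes)
    if (n < w) return(integer(0))
    ok <- rep(TRUE, n - w + 1L)
    for (j in seq_len(w))
      ok <- ok & aa[seq(j, n - w + j)] %in% classes[[j]]
    which(ok)
  }
  for (m in motif_set) {
    if (m == "RGG") {
      s <- scan_fixed(list("R", "G", "G")); add(m, s, s + 2L)
    } else if (m == "XGG") {
      s <- scan_fixed(list(c("R", "S", "Y"), "G", "G")); add(m, s, s + 2L)
    } else if (m == "RXT") {
      s <- scan_fixed(list("R", c("A", "G", "T"),
                           c("A", "G", "T", "F", "I", "V", "R")))
      add(m, s, s + 2L)
    } else if (m == "RS_DIPEPTIDE") {
      s <- which(
        (aa[-n] == "R" & aa[-1] == "S") | (aa[-n] == "S" & aa[-1] == "R"))
      add(m, s, s + 1L)
    } else {                                   # POLY_*
      res <- substring(m, 6, 6)
      r <- rle(aa == res)
      e <- cumsum(r$lengths)
      st <- e - r$lengths + 1L
      keep <- r$values & r$lengths >= homorepeat_len
      add(m, st[keep], e[keep])
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), start = integer(0), end = integer(0))
  out[order(out$start, out$end, out$motif), , drop = FALSE]
}

# Windowed composition statistics over a residue-character vector.
# Returns, for each window of width w (step 1), the count of residues in
# `letters`. X residues never count toward any class.
window_counts <- function(aa, letters, w) {
  ind <- as.numeric(aa %in% letters)
  n <- length(ind)
  if (n <= w) return(sum(ind))
  cs <- cumsum(ind)
  cs[w:n] - c(0, cs[seq_len(n - w)])
}

#' Classify the compositional-bias subtype of a disordered region
#'
#' Applies the windowed composition rules with precedence
#' RS > G-rich > poly-P/Q > charged > noncharged; regions shorter than
#' `cb_min_len` receive `"NONE"`.  Only the residues `start..end` are
#' inspected, so the call is invariant to sequence context outside the
#' region.  `X` residues are excluded from composition denominators.
#'
#' @param sequence full protein sequence (uppercase).
#' @param start,end 1-based inclusive region bounds.
#' @param params [typing_params()].
#' @param background [background_composition()].
#' @return one of `"CB_RS"`, `"CB_G"`, `"CB_PQ"`, `"CB_CHARGED"`,
#'   `"CB_NONCHARGED"`, `"NONE"`.
#' @export
classify_cb <- function(sequence, start = 1L, end = nchar(sequence),
                        params = typing_params(),
                        background = background_composition()) {
  if (start < 1 || end > nchar(sequence) || start > end)
    stopf("region %d..%d outside sequence of length %d", start, end,
          nchar(sequence))
  len <- end - start + 1L
  if (len < params$cb_min_len) return("NONE")
  seg <- substr(sequence, start, end)
  aa <- strsplit(seg, "")[[1]]
  w <- min(params$window, len)
  denom <- pmin(w, len)                        # residues per window

  rs_cnt <- window_counts(aa, c("R", "S"), w)
  rs_dipep <- find_motifs(seg, "RS_DIPEPTIDE")
  if (any(rs_cnt / denom >= params$rs_frac)) {
    # dipeptide requirement checked inside the qualifying windows
    for (ws in which(rs_cnt / denom >= params$rs_frac)) {
      lo <- ws; hi <- ws + w - 1L
      ndp <- sum(rs_dipep$start >= lo & rs_dipep$end <= hi)
      if (ndp >= params$rs_min_dipeptides) return("CB_RS")
    }
  }

  g_cnt <- window_counts(aa, "G", w)
  g_hits <- find_motifs(seg, c("RGG", "XGG", "RXT", "POLY_G"),
                        homorepeat_len = params$homorepeat_len)
  # RGG matches are also XGG matches: count distinct spans only
  n_motifs <- nrow(unique(g_hits[, c("start", "end")]))
  if (any(g_cnt / denom >= params$g_frac) || n_motifs >= params$g_min_motifs)
    return("CB_G")

  pq <- find_motifs(seg, c("POLY_P", "POLY_Q"),
                    homorepeat_len = params$homorepeat_len)
  if (nrow(pq)) return("CB_PQ")

  chg_cnt <- window_counts(aa, c("D", "E", "K", "R"), w)
  if (any(chg_cnt / denom >= params$charged_frac)) return("CB_CHARGED")

  tab <- table(factor(aa[aa != "X"], levels = AA_CANONICAL))
  nn <- sum(tab)
  if (nn > 0) {
    freq <- as.numeric(tab) / nn
    if (any(freq >= params$bias_fold * background)) return("CB_NONCHARGED")
  }
  "NONE"
}

#' Annotate a disordered region's secondary-structure content
#'
#' Residues inside H-runs or E-runs of length >= `ss_min_elem` (runs taken
#' over the whole protein's state string) are counted within the region; if
#' their fraction reaches `ss_overlap_frac` the region qualifies as SS-IDR.
#' `alpha_frac` / `beta_frac` are the fractions of region residues inside
#' qualifying H and E runs regardless of the SS-IDR call.
#'
#' @param region one region row (kind DISORDERED).
#' @param states protein-length string over H/E/C.
#' @param params [typing_params()].
#' @return list with `is_ss_idr`, `alpha_frac`, `beta_frac`.
#' @export
annotate_ss_idr <- function(region, states, params = typing_params()) {
  if (nchar(states) < region$end)
    stopf("SS profile shorter than region end (%d < %d)", nchar(states),
          region$end)
  st <- strsplit(states, "")[[1]]
  qual <- function(letter) {
    r <- rle(st == letter)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values & r$lengths >= params$ss_min_elem
    mask <- rep(FALSE, length(st))
    for (i in which(keep)) mask[s[i]:e[i]] <- TRUE
    mask
  }
  idx <- region$start:region$end
  len <- length(idx)
  a <- sum(qual("H")[idx]) / len
  b <- sum(qual("E")[idx]) / len
  list(is_ss_idr = (a + b) >= params$ss_overlap_frac,
       alpha_frac = a, beta_frac = b)
}

#' Type all disordered regions of a dataset
#'
#' Runs [classify_cb()] on every disordered region and, when SS profiles are
#' available, [annotate_ss_idr()].  The SS-IDR call overrides the CB subtype
#' as the primary `subtype`, but the CB call is always retained in
#' `cb_subtype` so neither annotation is discarded.
#'
#' @param proteins protein table.
#' @param regions tiled region table.
#' @param ss optional named character vector of SS state strings.
#' @param params [typing_params()].
#' @param background [background_composition()].
#' @return the region table with `subtype`, `cb_subtype`, `alpha_frac`,
#'   `beta_frac` filled in.
#' @export
type_regions <- function(proteins, regions, ss = NULL,
                         params = typing_params(),
                         background = background_composition()) {
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  for (i in seq_len(nrow(regions))) {
    if (regions$kind[i] != "DISORDERED") next
    pid <- regions$protein_id[i]
    if (!pid %in% names(seqs)) stopf("no sequence for protein %s", pid)
    cb <- classify_cb(seqs[[pid]], regions$start[i], regions$end[i],
                      params, background)
    regions$cb_subtype[i] <- cb
    regions$subtype[i] <- cb
    if (!is.null(ss) && pid %in% names(ss)) {
      ann <- annotate_ss_idr(regions[i, ], ss[[pid]], params)
      regions$alpha_frac[i] <- ann$alpha_frac
      regions$beta_frac[i] <- ann$beta_frac
      if (ann$is_ss_idr) regions$subtype[i] <- "SS_IDR"
    }
  }
  regions
}

#' Per-class table of SS vs CB disorder content
#'
#' For each protein class the report gives the percentage of class residues
#' lying in SS-IDRs (split into alpha and beta contributions) and in each CB
#' subtype; denominators are the total residue counts of the class.
#'
#' @param proteins protein table with `group` metadata.
#' @param regions typed region table.
#' @return data.frame with one row per class.
#' @export
typing_report <- function(proteins, regions) {
  len <- protein_lengths(proteins)
  groups <- sort(unique(proteins$group[!is.na(proteins$group)]))
  rows <- lapply(groups, function(g) {
    ids <- proteins$id[!is.na(proteins$group) & proteins$group == g]
    tot <- sum(len[ids])
    r <- regions[regions$protein_id %in% ids &
                   regions$kind == "DISORDERED", , drop = FALSE]
    rl <- r$end - r$start + 1L
    ss <- r$subtype == "SS_IDR"
    out <- data.frame(
      group = g, n_proteins = length(ids), total_residues = tot,
      ss_idr_pct = 100 * sum(rl[ss]) / tot,
      ss_alpha_pct = 100 * sum(rl[ss] * r$alpha_frac[ss]) / tot,
      ss_beta_pct = 100 * sum(rl[ss] * r$beta_frac[ss]) / tot,
      stringsAsFactors = FALSE)
    for (sub in CB_SUBTYPES)
      out[[paste0(tolower(sub), "_pct")]] <-
        100 * sum(rl[r$cb_subtype == sub]) / tot
    out
  })
  do.call(rbind, rows)
}
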
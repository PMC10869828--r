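#' Assign a candidate protein to a chemoreceptor family
#'
#' Scores the protein against every reference-database record with the same
#' local aligner used by the translated search (protein-protein mode) and
#' returns the family of the top-scoring record. If the top record is an
#' outgroup or non-chemoreceptor GPCR decoy the candidate is rejected
#' (`family = NA`). Ties are broken by (score desc, ref_id lexicographic).
#'
#' @param protein Candidate protein string (non-empty).
#' @param refdb Reference database tibble (see [ref_db()]).
#' @return A one-row tibble: `family` (NA when rejected), `best_ref_id`,
#'   `score`, `identity` (fraction of identical residues on the local
#'   alignment), `coverage` (fraction of the candidate covered by that
#'   alignment), `rejected`.
#' @export
classify_family <- function(protein, refdb) {
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) == 0)
    abort("protein must be a single non-empty string")
  refdb <- ref_db(refdb)
  S <- blosum62()
  fallback <- which(rownames(S) == "X")[1] - 1L
  scores <- vapply(refdb$protein, function(r) {
    cpp_sw_score(toupper(protein), r, S, 11L, 1L, fallback)
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, refdb$ref_id)
  top <- ord[1]
  rejected <- refdb$role[top] != "family_query"
  best <- protein_align(protein, refdb$protein[top])
  tibble(
    family = if (rejected) NA_character_ else refdb$family[top],
    best_ref_id = refdb$ref_id[top],
    score = scores[top],
    identity = best$matches / max(1L, best$alen),
    coverage = best$alen / nchar(protein),
    rejected = rejected
  )
}

#' Detect loss-of-function mutations
#'
#' Aligns a candidate DNA sequence to a reference protein with a
#' frameshift-aware codon-level dynamic program (1-2 nt slips allowed) and
#' reports loss-of-function events: in-frame stop codons at least
#' `stop_margin` codons before the reference C-terminus (`premature_stop`)
#' and 1-2 nt slips inside the aligned coding span (`frameshift_insertion` /
#' `frameshift_deletion`). Events are sorted by reference codon position.
#'
#' @param candidate_nt Candidate DNA string.
#' @param ref_protein Reference protein string.
#' @param stop_margin Codons of C-terminal slack before a stop counts as
#'   premature.
#' @param fs_penalty,gap_codon Alignment penalties (positive numbers).
#' @param min_score Minimum alignment score; below it the candidate is
#'   considered unalignable and an error is raised.
#' @return Tibble of events (`kind`, `ref_codon`, `nt_pos`), with attributes
#'   `alignment` (score and span) and `repaired` (the translation with LoF
#'   mutations removed).
#' @export
detect_lof <- function(candidate_nt, ref_protein, stop_margin = 15,
                       fs_penalty = 25, gap_codon = 11, min_score = 40) {
  al <- lof_align(candidate_nt, ref_protein, fs_penalty, gap_codon)
  if (al$score < min_score)
    abort("candidate does not align to the reference protein")
  ev <- tibble(kind = al$kind, ref_codon = al$ref_codon, nt_pos = al$nt_pos)
  keep <- ev$kind != "premature_stop" |
    ev$ref_codon <= nchar(ref_protein) - stop_margin
  ev <- ev[keep, , drop = FALSE] |> arrange(.data$ref_codon)
  attr(ev, "alignment") <- al[c("score", "nt_start", "nt_end", "ref_start",
                                "ref_end")]
  attr(ev, "repaired") <- al$repaired
  ev
}

lof_align <- function(candidate_nt, ref_protein, fs_penalty = 25,
                      gap_codon = 11, stop_penalty = 18) {
  S <- blosum62()
  # reading through an in-frame stop must only pay off when a genuine coding
  # alignment continues behind it; the penalty stays below the cost of the
  # insertion+deletion detour (2 * gap_codon) that would otherwise let the
  # aligner hide a real stop codon
  S["*", ] <- -as.integer(stop_penalty)
  S[, "*"] <- -as.integer(stop_penalty)
  fallback <- which(rownames(S) == "X")[1] - 1L
  cpp_lof_align(toupper(candidate_nt), toupper(ref_protein), S, fallback,
                -abs(fs_penalty), abs(gap_codon))
}

lof_keys <- function(lof) {
  if (is.null(lof) || nrow(lof) == 0) return(character())
  paste0(lof$kind, "@", lof$ref_codon)
}

#' Count transmembrane helices by hydropathy
#'
#' Kyte-Doolittle hydropathy with a sliding window; a transmembrane segment
#' is a maximal run of window centers with mean hydropathy at or above the
#' threshold and at least `min_segment` residues long; segments separated by
#' fewer than `merge_gap` residues are merged. `tm_pass` indicates the
#' seven-transmembrane architecture typical of GPCRs (count >= `tm_min`).
#'
#' @param protein Protein string.
#' @param window Sliding-window width (residues).
#' @param threshold Mean-hydropathy cutoff for a window center.
#' @param min_segment Minimum segment length (window centers).
#' @param merge_gap Segments closer than this many residues are merged.
#' @param tm_min Minimum count for `tm_pass`.
#' @return A one-row tibble: `tm_count`, `tm_pass`.
#' @export
count_tm_helices <- function(protein, window = 19, threshold = 1.6,
                             min_segment = 15, merge_gap = 5, tm_min = 6) {
  aa <- strsplit(toupper(protein), "")[[1]]
  kd <- unname(KD_SCALE[aa])
  kd[is.na(kd)] <- 0
  if (length(kd) < window)
    return(tibble(tm_count = 0L, tm_pass = FALSE))
  # windows are truncated at the termini so terminal helices score fully
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, kd))
  lo <- pmax(seq_along(kd) - half, 1L)
  hi <- pmin(seq_along(kd) + half, length(kd))
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  centers <- which(means >= threshold)
  if (length(centers) == 0) return(tibble(tm_count = 0L, tm_pass = FALSE))
  # split into runs, merge near-adjacent, then apply the length floor
  gaps <- diff(centers)
  run_id <- cumsum(c(1L, as.integer(gaps >= merge_gap + 1L)))
  segs <- tapply(centers, run_id, function(p) c(min(p), max(p)))
  lens <- vapply(segs, function(s) s[2] - s[1] + 1L, numeric(1))
  count <- sum(lens >= min_segment)
  tibble(tm_count = as.integer(count), tm_pass = count >= tm_min)
}

#' Assign the five-way gene status
#'
#' Decision order: (1) any ambiguous nucleotide in the CDS -> `ambiguous`;
#' (2) intact CDS (ATG start, single terminal stop, length a multiple of 3
#' and at least the family minimum) -> `complete`; (3) any loss-of-function
#' event -> `pseudogene`; (4) no LoF but the region's flank extension was
#' clipped at a scaffold border -> `edge`; (5) otherwise `truncated`.
#'
#' @param cds_nt Candidate CDS (or candidate region span for incomplete
#'   sequences).
#' @param n_lof Number of loss-of-function events detected.
#' @param clipped Was the candidate's region clipped at a scaffold border?
#' @param params [family_params()] list (supplies `min_complete_nt`).
#' @param intact Optional override for the intact-CDS check.
#' @return One of `"complete"`, `"pseudogene"`, `"truncated"`, `"edge"`,
#'   `"ambiguous"`.
#' @export
assign_status <- function(cds_nt, n_lof, clipped, params, intact = NULL) {
  if (grepl("[^ACGT]", cds_nt)) return("ambiguous")
  if (is.null(intact)) intact <- is_intact_cds(cds_nt)
  if (intact && nchar(cds_nt) >= params$min_complete_nt) return("complete")
  if (n_lof > 0) return("pseudogene")
  if (isTRUE(clipped)) return("edge")
  "truncated"
}

# ATG start, terminal stop, no internal stop, length divisible by 3
is_intact_cds <- function(nt) {
  n <- nchar(nt)
  if (n < 6 || n %% 3 != 0) return(FALSE)
  if (substr(nt, 1, 3) != "ATG") return(FALSE)
  aa <- cpp_translate(nt)
  substr(aa, nchar(aa), nchar(aa)) == "*" &&
    !grepl("\\*", substr(aa, 1, nchar(aa) - 1))
}
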
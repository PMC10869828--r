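#' Screen mined candidates against a foreign-taxon database
#'
#' Flags candidates that look like cross-taxon contamination: each candidate
#' CDS is searched against a foreign nucleotide database at a permissive
#' expectation value (default 10); for candidates with a match, the sequence
#' identity between candidate and best foreign hit is computed on the
#' codon-threaded DNA alignment implied by their protein alignment (align
#' the translations, then read identity off the corresponding codons).
#' Candidates above `flag_identity` are marked suspect.
#'
#' @param candidates Named character vector of candidate CDSs.
#' @param foreign_db Named character vector of foreign nucleotide sequences.
#' @param max_evalue Nucleotide-search expectation cutoff.
#' @param flag_identity Identity above which a candidate is flagged.
#' @return Tibble: `candidate`, `foreign_hit`, `nt_score`, `evalue`,
#'   `identity`, `suspect`. Candidates without a qualifying match are absent.
#' @export
screen_contamination <- function(candidates, foreign_db, max_evalue = 10,
                                 flag_identity = 0.90) {
  if (length(candidates) == 0 || length(foreign_db) == 0)
    return(tibble(candidate = character(), foreign_hit = character(),
                  nt_score = numeric(), evalue = numeric(),
                  identity = numeric(), suspect = logical()))
  n_total <- sum(nchar(foreign_db))
  purrr::imap(candidates, function(cand, cand_id) {
    # word-seeded: without a shared exact word no alignment is attempted,
    # mirroring how nucleotide search tools behave on unrelated sequences
    seeded <- vapply(foreign_db, function(f) has_word_match(cand, f),
                     logical(1))
    if (!any(seeded)) return(NULL)
    als <- purrr::map(foreign_db[seeded], function(f) nt_align(cand, f))
    scores <- vapply(als, `[[`, numeric(1), "score")
    ord <- order(-scores, names(foreign_db)[seeded])
    best_name <- names(foreign_db)[seeded][ord[1]]
    best <- which(names(foreign_db) == best_name)[1]
    ev <- ka_evalue(scores[ord[1]], nchar(cand), n_total,
                    lambda = KA_LAMBDA_NT, K = KA_K_NT)
    if (!is.finite(ev) || ev > max_evalue || scores[ord[1]] <= 0)
      return(NULL)
    ident <- threaded_identity(cand, foreign_db[[best]])
    tibble(candidate = cand_id, foreign_hit = best_name,
           nt_score = scores[ord[1]], evalue = ev, identity = ident,
           suspect = ident > flag_identity)
  }) |> bind_rows()
}

# do two nucleotide sequences share an exact word of length k?
has_word_match <- function(a, b, k = 11) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  wa <- unique(substring(a, seq_len(nchar(a) - k + 1),
                         seq_len(nchar(a) - k + 1) + k - 1))
  any(vapply(wa, function(w) grepl(w, b, fixed = TRUE), logical(1)))
}

# DNA identity read through the protein alignment: align the frame-1
# translations locally, then compare the underlying codons column by column
threaded_identity <- function(a_nt, b_nt) {
  a_aa <- sub("\\*.*$", "", cpp_translate(a_nt))
  b_aa <- sub("\\*.*$", "", cpp_translate(b_nt))
  if (nchar(a_aa) == 0 || nchar(b_aa) == 0) return(0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a_aa), Biostrings::AAString(b_aa),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ai <- al@pattern@range@start
  bi <- al@subject@range@start
  nt_match <- 0L
  nt_cols <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-" && sa[k] != "-") {
      ca <- substr(a_nt, 3L * (ai - 1L) + 1L, 3L * ai)
      cb <- substr(b_nt, 3L * (bi - 1L) + 1L, 3L * bi)
      nt_cols <- nt_cols + 3L
      nt_match <- nt_match + sum(strsplit(ca, "")[[1]] ==
                                   strsplit(cb, "")[[1]])
    }
    if (pa[k] != "-") ai <- ai + 1L
    if (sa[k] != "-") bi <- bi + 1L
  }
  if (nt_cols == 0) return(0)
  nt_match / nt_cols
}
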
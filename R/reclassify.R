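#' Reclassify per-species gene status from all available evidence
#'
#' Four-way reclassification used for the taste-receptor loss analysis.
#' A gene is `complete` when the assembly carries a complete copy, when
#' truncated/edge fragments merge into a full CDS, or when a sibling
#' assembly of the same species carries a complete copy. It is a
#' `high_confidence_loss` when it is a pseudogene with at least two distant
#' LoF mutations (at least `distance_codons` reference codons apart), or
#' with a LoF corroborated by a sibling assembly or shared with a close
#' relative, or when the gene is absent while both flanking genes sit on one
#' scaffold (a true deletion). It is a `low_confidence_loss` when it is a
#' pseudogene with a single uncorroborated LoF, or absent with the flanking
#' genes missing or scattered. Everything else (unresolved edge / truncated /
#' ambiguous evidence) is `undetermined`.
#'
#' @param evidence Tibble with one row per species/gene and columns:
#'   `assembly_status` (miner status or `"absent"`), `lof` (list of LoF keys
#'   `"kind@codon"`), `sibling_statuses` (list), `sibling_lof` (list),
#'   `relative_lof` (list), `fragments_cover_complete` (logical),
#'   `flanking_same_scaffold` (logical). Missing list columns default to
#'   empty, missing logicals to `FALSE`.
#' @param distance_codons Two LoF mutations are "distant" when their
#'   reference codon positions differ by at least this much.
#' @return `evidence` with an added `reclassified` column.
#' @export
reclassify_gene_status <- function(evidence, distance_codons = 50) {
  ev <- as_tibble(evidence)
  n <- nrow(ev)
  fill_list <- function(col) {
    if (!col %in% names(ev)) rep(list(character()), n)
    else purrr::map(ev[[col]], function(x) {
      if (is.null(x)) character() else as.character(x)
    })
  }
  fill_lgl <- function(col) {
    if (!col %in% names(ev)) rep(FALSE, n)
    else dplyr::coalesce(ev[[col]], FALSE)
  }
  lof <- fill_list("lof")
  sib_status <- fill_list("sibling_statuses")
  sib_lof <- fill_list("sibling_lof")
  rel_lof <- fill_list("relative_lof")
  frag_complete <- fill_lgl("fragments_cover_complete")
  flank_same <- fill_lgl("flanking_same_scaffold")
  status <- ev$assembly_status
  ev$reclassified <- vapply(seq_len(n), function(i) {
    if (identical(status[i], "complete") || isTRUE(frag_complete[i]) ||
        any(sib_status[[i]] == "complete"))
      return("complete")
    absent <- identical(status[i], "absent")
    if (identical(status[i], "pseudogene") && length(lof[[i]]) > 0) {
      pos <- lof_key_positions(lof[[i]])
      distant <- length(pos) >= 2 && (max(pos) - min(pos)) >= distance_codons
      corroborated <- length(intersect(lof[[i]], sib_lof[[i]])) > 0 ||
        length(intersect(lof[[i]], rel_lof[[i]])) > 0
      if (distant || corroborated) return("high_confidence_loss")
      return("low_confidence_loss")
    }
    if (absent) {
      if (isTRUE(flank_same[i])) return("high_confidence_loss")
      return("low_confidence_loss")
    }
    "undetermined"
  }, character(1))
  ev
}

lof_key_positions <- function(keys) {
  as.integer(sub("^.*@", "", keys))
}
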
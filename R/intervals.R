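#' Merge overlapping hits into best-hit regions
#'
#' Clusters hits by transitive overlap per scaffold (strand-agnostic) and, for
#' each cluster, returns the interval of the single highest-scoring hit. Ties
#' are broken by (score desc, start asc, query_id lexicographic), so the
#' output is deterministic; it is sorted and pairwise non-overlapping.
#'
#' @param hits Tibble with at least `scaffold`, `start`, `end`, `score`;
#'   optional `strand` and `query_id` are carried through.
#' @return Tibble of non-overlapping intervals (`scaffold`, `start`, `end`,
#'   `strand`, `score`, `query_id`).
#' @export
merge_best_hit_regions <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(),
                  query_id = character()))
  }
  if (!"strand" %in% names(hits)) hits$strand <- "+"
  if (!"query_id" %in% names(hits)) hits$query_id <- ""
  hits |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(cluster = cumsum(.data$start >=
                              dplyr::lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$scaffold, .data$cluster) |>
    arrange(desc(.data$score), .data$start, .data$query_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("scaffold", "start", "end", "strand", "score", "query_id") |>
    arrange(.data$scaffold, .data$start)
}

#' Extend intervals by a flank and re-merge
#'
#' Widens each interval by `flank_bp` on both sides, truncating at scaffold
#' bounds (recorded in `clipped_start` / `clipped_end`), then unions
#' overlapping extended intervals so the result is non-overlapping.
#'
#' @param intervals Tibble with `scaffold`, `start`, `end`.
#' @param flank_bp Non-negative flank width in bp.
#' @param genome Genome whose scaffold lengths bound the extension.
#' @return Tibble `scaffold`, `start`, `end`, `clipped_start`, `clipped_end`.
#' @export
extend_intervals <- function(intervals, flank_bp, genome) {
  if (flank_bp < 0) abort("flank_bp must be >= 0")
  genome <- as_genome(genome)
  lens <- scaffold_lengths(genome)
  if (nrow(intervals) == 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  clipped_start = logical(), clipped_end = logical()))
  }
  bad <- setdiff(unique(intervals$scaffold), names(lens))
  if (length(bad) > 0) abort(paste0("unknown scaffold: ", bad[1]))
  ext <- intervals |>
    mutate(L = unname(lens[.data$scaffold]),
           raw_start = .data$start - as.integer(flank_bp),
           raw_end = .data$end + as.integer(flank_bp),
           start = pmax(0L, .data$raw_start),
           end = pmin(.data$L, .data$raw_end),
           clipped_start = .data$raw_start < 0L,
           clipped_end = .data$raw_end > .data$L)
  ext |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(cluster = cumsum(.data$start >
                              dplyr::lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$scaffold, .data$cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              clipped_start = any(.data$clipped_start),
              clipped_end = any(.data$clipped_end), .groups = "drop") |>
    select("scaffold", "start", "end", "clipped_start", "clipped_end") |>
    arrange(.data$scaffold, .data$start)
}

# do intervals a (single row) and any row of b overlap (same scaffold)?
overlaps_any <- function(scaffold, start, end, b) {
  if (nrow(b) == 0) return(FALSE)
  any(b$scaffold == scaffold & b$start < end & b$end > start)
}
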
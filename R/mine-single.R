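#' Mine a single-exon chemoreceptor family from a genome
#'
#' Two-round procedure for the single-exon families (OR, TAAR, T2R, and V1R
#' outside ray-finned fishes). Round one: translated search of the family
#' queries at the permissive E-value tier, merging of non-overlapping
#' best-hit regions, 1000 bp flank extension, ORF extraction at the family's
#' complete-length threshold, and family assignment by best database match;
#' intact ORFs become `complete` candidates (or `ambiguous` when the CDS
#' contains an ambiguity code). Round two: the complete candidates plus the
#' family references are re-searched at the stringent tier (1e-20), regions
#' already owned by round-one candidates are masked, and the remaining
#' regions are classified into `pseudogene` / `truncated` / `edge` /
#' `ambiguous` via frameshift-aware LoF detection. Seven-transmembrane
#' screening is recorded on every candidate but never changes its status.
#'
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param family Family to mine (must be a single-exon family here).
#' @param refdb Reference database (see [ref_db()]); must contain
#'   `family_query` records for `family` and decoy records.
#' @param params [family_params()] list; defaults to the family defaults.
#' @return Candidate tibble; see [empty_candidate_tbl()] for columns.
#' @export
mine_single_exon <- function(genome, family, refdb,
                             params = family_params(family, "single")) {
  stopifnot(params$exon_mode == "single")
  genome <- as_genome(genome)
  refdb <- ref_db(refdb)
  fam_refs <- refdb[refdb$role == "family_query" & refdb$family == family, ]
  if (nrow(fam_refs) == 0)
    abort(paste0("refdb has no family_query records for ", family))
  queries <- setNames(fam_refs$protein, fam_refs$ref_id)

  hits <- translated_search(queries, genome, params$search_evalue)
  if (nrow(hits) == 0) return(empty_candidate_tbl())
  regions <- merge_best_hit_regions(hits) |>
    extend_intervals(params$flank_bp, genome)

  round1 <- purrr::pmap(regions, function(scaffold, start, end, clipped_start,
                                          clipped_end) {
    orfs <- find_orfs(genome,
                      tibble(scaffold = scaffold, start = start, end = end),
                      min_len_nt = params$min_complete_nt,
                      require_start = params$orf_require_start)
    orfs <- orfs[orfs$has_start & orfs$has_stop, , drop = FALSE]
    if (nrow(orfs) == 0) return(NULL)
    # non-overlapping ORFs, longest first
    orfs <- orfs |> mutate(len = .data$end - .data$start) |>
      arrange(desc(.data$len), .data$start)
    kept <- orfs[0, ]
    for (i in seq_len(nrow(orfs))) {
      if (!overlaps_any(orfs$scaffold[i], orfs$start[i], orfs$end[i], kept))
        kept <- bind_rows(kept, orfs[i, ])
    }
    purrr::pmap(kept, function(scaffold, start, end, strand, frame, has_start,
                               has_stop, nt, aa, len) {
      cf <- classify_family(aa, refdb)
      if (is.na(cf$family) || cf$family != family) return(NULL)
      # a credible complete gene must be covered by its best-match alignment
      # and resemble the family beyond generic receptor similarity (proxy
      # for the discard-if-not-clustering-with-known-genes step)
      if (cf$coverage < params$min_complete_coverage ||
          cf$identity < params$min_family_identity) return(NULL)
      status <- assign_status(nt, 0L, clipped_start || clipped_end, params)
      tm <- count_tm_helices(aa, tm_min = params$tm_min)
      tibble(family = family, scaffold = scaffold, start = start, end = end,
             strand = strand, status = status, cds = nt, protein = aa,
             lof = list(tibble(kind = character(), ref_codon = integer(),
                               nt_pos = integer())),
             n_lof = 0L, tm_count = tm$tm_count, tm_pass = tm$tm_pass,
             best_ref_id = cf$best_ref_id, best_ref_identity = cf$identity,
             clipped_start = clipped_start, clipped_end = clipped_end,
             exon_count = 1L, score = cf$score)
    }) |> bind_rows()
  }) |> bind_rows()

  owned <- if (nrow(round1) > 0) round1[, c("scaffold", "start", "end")]
           else tibble(scaffold = character(), start = integer(),
                       end = integer())

  # second round at the stringent tier; completes (and family refs) as queries
  q2 <- queries
  if (nrow(round1) > 0) {
    comp <- round1[round1$status == "complete", ]
    if (nrow(comp) > 0)
      q2 <- c(q2, setNames(comp$protein,
                           paste0("cand", seq_len(nrow(comp)))))
  }
  hits2 <- translated_search(q2, genome, params$rescan_evalue)
  if (nrow(hits2) > 0) {
    keep <- !purrr::pmap_lgl(hits2[, c("scaffold", "start", "end")],
                             overlaps_any, b = owned)
    hits2 <- hits2[keep, , drop = FALSE]
  }
  round2 <- if (nrow(hits2) == 0) empty_candidate_tbl() else {
    regions2 <- merge_best_hit_regions(hits2) |>
      extend_intervals(params$flank_bp, genome)
    keep <- !purrr::pmap_lgl(regions2[, c("scaffold", "start", "end")],
                             overlaps_any, b = owned)
    regions2 <- regions2[keep, , drop = FALSE]
    purrr::pmap(regions2, classify_incomplete_region, genome = genome,
                family = family, refdb = refdb, fam_refs = fam_refs,
                hits = hits2, params = params) |>
      bind_rows()
  }
  bind_rows(round1, round2) |> arrange(.data$scaffold, .data$start)
}

# classify one round-two region into pseudogene/truncated/edge/ambiguous
classify_incomplete_region <- function(scaffold, start, end, clipped_start,
                                       clipped_end, genome, family, refdb,
                                       fam_refs, hits, params) {
  loc <- hits[hits$scaffold == scaffold & hits$start < end &
                hits$end > start, , drop = FALSE]
  if (nrow(loc) == 0) return(NULL)
  best <- loc[order(-loc$score, loc$start, loc$query_id), ][1, ]
  strand <- best$strand
  # align against the strongest family reference for this region
  ref_row <- best_family_ref(loc, fam_refs)
  region_nt <- genome_slice(genome, scaffold, start, end, strand)
  al <- lof_align(region_nt, ref_row$protein)
  if (al$score < 40) return(NULL)
  cand_nt <- substr(region_nt, al$nt_start, al$nt_end)
  ev <- tibble(kind = al$kind, ref_codon = al$ref_codon, nt_pos = al$nt_pos)
  keep <- ev$kind != "premature_stop" |
    ev$ref_codon <= nchar(ref_row$protein) - params$stop_margin
  ev <- ev[keep, , drop = FALSE] |> arrange(.data$ref_codon)
  # best-match filter on the repaired translation
  prot <- if (nchar(al$repaired) > 0) al$repaired else cpp_translate(cand_nt)
  cf <- classify_family(prot, refdb)
  if (is.na(cf$family) || cf$family != family) return(NULL)
  status <- assign_status(cand_nt, nrow(ev), clipped_start || clipped_end,
                          params, intact = FALSE)
  # forward-strand candidate coordinates
  if (strand == "+") {
    cstart <- start + al$nt_start - 1L
    cend <- start + al$nt_end
  } else {
    cend <- end - (al$nt_start - 1L)
    cstart <- end - al$nt_end
  }
  tm <- count_tm_helices(prot, tm_min = params$tm_min)
  tibble(family = family, scaffold = scaffold, start = cstart, end = cend,
         strand = strand, status = status, cds = cand_nt, protein = prot,
         lof = list(ev), n_lof = nrow(ev),
         tm_count = tm$tm_count, tm_pass = tm$tm_pass,
         best_ref_id = cf$best_ref_id, best_ref_identity = cf$identity,
         clipped_start = clipped_start, clipped_end = clipped_end,
         exon_count = 1L, score = al$score)
}

# family reference with the best hit score among hits in a region (fallback:
# first family reference)
best_family_ref <- function(loc_hits, fam_refs) {
  famhits <- loc_hits[loc_hits$query_id %in% fam_refs$ref_id, , drop = FALSE]
  if (nrow(famhits) > 0) {
    best <- famhits[order(-famhits$score, famhits$query_id), ][1, ]
    fam_refs[fam_refs$ref_id == best$query_id, ][1, ]
  } else fam_refs[1, ]
}

#' An empty candidate table (column contract of the miners)
#' @return Zero-row candidate tibble.
#' @export
empty_candidate_tbl <- function() {
  tibble(family = character(), scaffold = character(), start = integer(),
         end = integer(), strand = character(), status = character(),
         cds = character(), protein = character(), lof = list(),
         n_lof = integer(), tm_count = integer(), tm_pass = logical(),
         best_ref_id = character(), best_ref_identity = numeric(),
         clipped_start = logical(), clipped_end = logical(),
         exon_count = integer(), score = numeric())
}

#' Summarise candidates into a per-family repertoire table
#'
#' @param candidates Candidate tibble (possibly several families).
#' @param species_id Optional species label column value.
#' @return Tibble with one row per family: counts per status and `total`.
#' @export
repertoire <- function(candidates, species_id = NA_character_) {
  statuses <- c("complete", "pseudogene", "truncated", "edge", "ambiguous")
  if (nrow(candidates) == 0) {
    return(tibble(species_id = character(), family = character(),
                  !!!setNames(rep(list(integer()), length(statuses)),
                              statuses),
                  total = integer()))
  }
  candidates |>
    group_by(.data$family) |>
    summarise(!!!setNames(
      purrr::map(statuses, function(s) rlang::quo(sum(.data$status == !!s))),
      statuses), .groups = "drop") |>
    mutate(total = rowSums(across(all_of(statuses))),
           species_id = species_id) |>
    select("species_id", "family", all_of(statuses), "total")
}
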
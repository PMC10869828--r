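#' Infer the expected exon count of a region from translated-search hits
#'
#' Applies the tblastn exon-inference rule: hits shorter than
#' `exon_hit_min_bp` are dropped, remaining hits closer than
#' `exon_gap_min_bp` are merged into one putative exon, and the number of
#' merged blocks is returned.
#'
#' @param hits Tibble with `start` and `end` (consistent coordinates).
#' @param min_bp,gap_bp Rule parameters (50 bp and 100 bp by default).
#' @return Integer exon count (0 for no qualifying hits).
#' @export
infer_exon_count <- function(hits, min_bp = 50, gap_bp = 100) {
  if (is.null(hits) || nrow(hits) == 0) return(0L)
  h <- hits[hits$end - hits$start >= min_bp, , drop = FALSE]
  if (nrow(h) == 0) return(0L)
  h <- h[order(h$start, h$end), , drop = FALSE]
  blocks <- 1L
  cur_end <- h$end[1]
  for (i in seq_len(nrow(h))[-1]) {
    if (h$start[i] - cur_end >= gap_bp) blocks <- blocks + 1L
    cur_end <- max(cur_end, h$end[i])
  }
  blocks
}

#' Predict spliced gene models in a genomic region
#'
#' Exon seeds are local protein-to-DNA alignments of the reference proteins
#' against the region (both strands) above a score floor; collinear,
#' non-overlapping seeds on one strand are chained by dynamic programming
#' maximizing total seed score minus an intron penalty per junction, with a
#' bonus when the intron is GT..AG. Junctions where adjacent seeds overlap on
#' the query are trimmed, preferring the split that restores a GT..AG intron.
#' Each maximal chain is emitted as a gene model. Externally produced spliced
#' predictions can be supplied as GFF3 via [gene_models_from_gff()] instead.
#'
#' @param genome Genome object.
#' @param region One-row tibble `scaffold`, `start`, `end`.
#' @param ref_proteins Named proteins (or refdb rows) used as seeds.
#' @param seed_evalue E-value tier for the seed alignments.
#' @param intron_penalty,gtag_bonus Chaining parameters.
#' @param max_intron_bp Maximum intron length bridged by a junction.
#' @param hits Optional precomputed hit tibble (genome coordinates) to use
#'   as exon seeds instead of re-running the translated search.
#' @return Tibble of gene models: `scaffold`, `strand`, `exons` (list of
#'   forward-coordinate exon tibbles in transcription order), `exon_count`,
#'   `cds`, `score`, `query_id`, `start`, `end`.
#' @export
predict_gene_models <- function(genome, region, ref_proteins,
                                seed_evalue = 10, intron_penalty = 20,
                                gtag_bonus = 10, max_intron_bp = 2000,
                                hits = NULL) {
  genome <- as_genome(genome)
  queries <- as_protein_set(ref_proteins)
  sc <- region$scaffold[1]
  rs <- region$start[1]; re <- region$end[1]
  W <- re - rs
  models <- list()
  fwd <- genome_slice(genome, sc, rs, re, "+")
  all_hits <- if (is.null(hits)) {
    translated_search(queries, setNames(fwd, "region"),
                      max_evalue = seed_evalue)
  } else {
    # reuse genome-coordinate hits, shifted into region-local coordinates
    h <- hits[hits$scaffold == sc & hits$start >= rs & hits$end <= re, ,
              drop = FALSE]
    h$start <- h$start - rs
    h$end <- h$end - rs
    h
  }
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") fwd else revcomp(fwd)
    hits <- all_hits[all_hits$strand == strand, , drop = FALSE]
    if (nrow(hits) == 0) next
    if (strand == "-") {
      # express minus-strand hits in revcomp-oriented coordinates
      s2 <- W - hits$end
      hits$end <- W - hits$start
      hits$start <- s2
    }
    for (q in unique(hits$query_id)) {
      hq <- hits[hits$query_id == q, , drop = FALSE]
      hq <- hq[order(hq$start, hq$end), , drop = FALSE]
      chains <- chain_seeds(hq, intron_penalty, gtag_bonus, max_intron_bp,
                            oriented)
      for (ch in chains) {
        md <- build_model(ch, oriented, strand, sc, rs, W, q)
        if (!is.null(md)) models[[length(models) + 1L]] <- md
      }
    }
  }
  if (length(models) == 0) return(empty_model_tbl())
  bind_rows(models) |>
    arrange(.data$scaffold, .data$start, desc(.data$score), .data$query_id)
}

empty_model_tbl <- function() {
  tibble(scaffold = character(), strand = character(), exons = list(),
         exon_count = integer(), cds = character(), score = numeric(),
         query_id = character(), start = integer(), end = integer())
}

# DP chaining of seed hits of one query in oriented coordinates; returns a
# list of chains, each a tibble of (possibly trimmed) exon spans
chain_seeds <- function(hq, intron_penalty, gtag_bonus, max_intron_bp,
                        oriented) {
  n <- nrow(hq)
  dp <- hq$score
  parent <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      gap <- hq$start[j] - hq$end[i]
      if (gap <= 0 || gap > max_intron_bp) next
      if (hq$qstart[j] <= hq$qstart[i] || hq$qend[j] <= hq$qend[i]) next
      if (hq$qstart[j] < hq$qend[i] - 40) next   # too much query overlap
      cand <- dp[i] + hq$score[j] - intron_penalty +
        if (has_gtag(oriented, hq$end[i], hq$start[j])) gtag_bonus else 0
      if (cand > dp[j]) { dp[j] <- cand; parent[j] <- i }
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  for (j in order(-dp, hq$start)) {
    if (used[j]) next
    path <- integer()
    k <- j
    while (!is.na(k) && !used[k]) { path <- c(k, path); used[k] <- TRUE
      k <- parent[k] }
    chains[[length(chains) + 1L]] <- hq[path, , drop = FALSE]
  }
  chains
}

# is there a canonical GT..AG intron between oriented positions e (exclusive
# exon end) and s (exon start), 0-based half-open coords?
has_gtag <- function(oriented, e, s) {
  if (s - e < 4) return(FALSE)
  substr(oriented, e + 1, e + 2) == "GT" &&
    substr(oriented, s - 1, s) == "AG"
}

# assemble a chain into a gene model, trimming query-overlapping junctions
# toward GT..AG intron boundaries
build_model <- function(ch, oriented, strand, scaffold, region_start, W, q) {
  k <- nrow(ch)
  starts <- ch$start; ends <- ch$end
  score <- sum(ch$score)
  if (k > 1) {
    for (j in 2:k) {
      o <- ch$qend[j - 1] - ch$qstart[j] + 1L
      o <- max(0L, o)
      pick <- NA_integer_
      for (a in 0:o) {   # trim a codons from exon j-1, o-a from exon j
        e2 <- ends[j - 1] - 3L * a
        s2 <- starts[j] + 3L * (o - a)
        if (e2 <= starts[j - 1] || s2 >= ends[j]) next
        if (has_gtag(oriented, e2, s2)) { pick <- a; break }
      }
      if (is.na(pick)) pick <- o   # default: keep the downstream seed intact
      ends[j - 1] <- ends[j - 1] - 3L * pick
      starts[j] <- starts[j] + 3L * (o - pick)
      score <- score - intron_junction_cost(oriented, ends[j - 1], starts[j])
    }
  }
  if (any(ends <= starts)) return(NULL)
  # complete the CDS through the terminal stop codon (the protein queries
  # carry no stop, so the alignment always ends one codon short); scan a few
  # codons downstream in case the reference ended slightly early
  for (jj in 1:5) {
    cod <- substr(oriented, ends[k] + 1L, ends[k] + 3L)
    if (nchar(cod) < 3) break
    ends[k] <- ends[k] + 3L
    if (cod %in% c("TAA", "TAG", "TGA")) break
    if (jj == 5L) ends[k] <- ends[k] - 15L  # no stop found: keep as aligned
  }
  cds <- paste0(vapply(seq_len(k), function(i) {
    substr(oriented, starts[i] + 1L, ends[i])
  }, character(1)), collapse = "")
  # map oriented coords back to forward scaffold coordinates
  if (strand == "+") {
    fs <- region_start + starts; fe <- region_start + ends
  } else {
    fe <- region_start + (W - starts); fs <- region_start + (W - ends)
  }
  exon_tbl <- tibble(start = as.integer(pmin(fs, fe)),
                     end = as.integer(pmax(fs, fe)))
  span_start <- min(exon_tbl$start)
  span_end <- max(exon_tbl$end)
  if (strand == "-") exon_tbl <- exon_tbl[rev(seq_len(k)), , drop = FALSE]
  tibble(scaffold = scaffold, strand = strand, exons = list(exon_tbl),
         exon_count = k, cds = cds, score = score, query_id = q,
         start = span_start, end = span_end)
}

intron_junction_cost <- function(oriented, e, s) {
  if (has_gtag(oriented, e, s)) 10 else 20
}

#' Iteratively select accepted gene models
#'
#' Discards predictions whose exon count exceeds the cap inferred from the
#' translated-search hits, then runs the descending-length-threshold loop:
#' starting at the family's mean expected gene length, keep predictions at
#' least that long, retain the best-scoring prediction among overlapping
#' survivors, remove everything overlapping an accepted model, halve the
#' threshold (never below the family reporting floor) and repeat until an
#' iteration at the floor accepts nothing.
#'
#' @param predictions Model tibble from [predict_gene_models()].
#' @param exon_cap Maximum exon count (from [infer_exon_count()]).
#' @param params [family_params()] list.
#' @return Tibble of accepted, pairwise non-overlapping models.
#' @export
select_gene_models <- function(predictions, exon_cap, params) {
  if (nrow(predictions) == 0) return(predictions)
  preds <- predictions |>
    filter(.data$exon_count <= exon_cap) |>
    mutate(len = nchar(.data$cds)) |>
    arrange(desc(.data$score), .data$start, .data$query_id)
  accepted <- preds[0, ]
  floor_nt <- max(params$min_report_nt, 1L)
  L <- params$mean_expected_nt
  if (is.na(L)) L <- params$min_complete_nt
  repeat {
    free <- preds[!purrr::pmap_lgl(preds[, c("scaffold", "start", "end")],
                                   overlaps_any, b = accepted), ,
                  drop = FALSE]
    pool <- free[free$len >= L, , drop = FALSE]
    if (nrow(pool) > 0) {
      clusters <- merge_best_hit_regions(
        pool |> mutate(query_id = as.character(row_number())))
      take <- as.integer(clusters$query_id)
      accepted <- bind_rows(accepted, pool[take, , drop = FALSE])
    }
    if (L <= floor_nt && nrow(pool) == 0) break
    L <- max(floor_nt, L %/% 2L)
  }
  accepted |> select(-"len") |> arrange(.data$scaffold, .data$start)
}

#' Mine a multi-exon chemoreceptor family from a genome
#'
#' Procedure for V2R, T1R and the multi-exon (ray-finned fish) V1R genes:
#' translated search at the permissive tier, 30 kb extension and union of
#' hit regions, per-region exon-count inference, spliced gene-model
#' prediction and iterative selection, frameshift-aware LoF detection and
#' status assignment (complete requires an intact CDS at the family length
#' threshold), family assignment on the translated models (LoF mutations are
#' removed from pseudogenes before translation), and removal of V2R/T1R
#' sequences shorter than 400 bp.
#'
#' @inheritParams mine_single_exon
#' @param gff_models Optional model tibble from [gene_models_from_gff()];
#'   when given, these predictions replace the built-in exon chaining.
#' @return Candidate tibble (same contract as [mine_single_exon()]).
#' @export
mine_multi_exon <- function(genome, family, refdb,
                            params = family_params(family, "multi"),
                            gff_models = NULL) {
  stopifnot(params$exon_mode == "multi")
  genome <- as_genome(genome)
  refdb <- ref_db(refdb)
  fam_refs <- refdb[refdb$role == "family_query" & refdb$family == family, ]
  if (nrow(fam_refs) == 0)
    abort(paste0("refdb has no family_query records for ", family))
  queries <- setNames(fam_refs$protein, fam_refs$ref_id)
  hits <- translated_search(queries, genome, params$search_evalue)
  if (nrow(hits) == 0) return(empty_candidate_tbl())
  regions <- extend_intervals(hits[, c("scaffold", "start", "end")],
                              params$flank_bp, genome)
  lens <- scaffold_lengths(genome)
  out <- purrr::pmap(regions, function(scaffold, start, end, clipped_start,
                                       clipped_end) {
    loc <- hits[hits$scaffold == scaffold & hits$start < end &
                  hits$end > start, , drop = FALSE]
    cap <- infer_exon_count(loc, params$exon_hit_min_bp,
                            params$exon_gap_min_bp)
    if (cap == 0L) return(NULL)
    region <- tibble(scaffold = scaffold, start = start, end = end)
    preds <- if (!is.null(gff_models)) {
      gff_models[gff_models$scaffold == scaffold & gff_models$start < end &
                   gff_models$end > start, , drop = FALSE]
    } else {
      predict_gene_models(genome, region, queries,
                          max_intron_bp = params$max_intron_bp, hits = hits)
    }
    sel <- select_gene_models(preds, cap, params)
    if (nrow(sel) == 0) return(NULL)
    L <- unname(lens[[scaffold]])
    purrr::map(seq_len(nrow(sel)), function(i) {
      # a candidate is border-clipped when its own span runs closer to a
      # scaffold end than the single-exon flank margin
      cs <- sel$start[i] < params$edge_margin_bp
      ce <- sel$end[i] > L - params$edge_margin_bp
      model_to_candidate(sel[i, ], family, refdb, fam_refs, params, cs, ce)
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0) return(empty_candidate_tbl())
  out |> arrange(.data$scaffold, .data$start)
}

model_to_candidate <- function(model, family, refdb, fam_refs, params,
                               clipped_start, clipped_end) {
  cds <- model$cds
  if (nchar(cds) < params$min_report_nt) return(NULL)
  ref_row <- fam_refs[fam_refs$ref_id == model$query_id, ]
  if (nrow(ref_row) == 0) ref_row <- fam_refs[1, ]
  al <- lof_align(cds, ref_row$protein[1])
  if (al$score < 40) return(NULL)
  ev <- tibble(kind = al$kind, ref_codon = al$ref_codon, nt_pos = al$nt_pos)
  keep <- ev$kind != "premature_stop" |
    ev$ref_codon <= nchar(ref_row$protein[1]) - params$stop_margin
  ev <- ev[keep, , drop = FALSE] |> arrange(.data$ref_codon)
  status <- assign_status(cds, nrow(ev), clipped_start || clipped_end, params)
  prot <- if (nrow(ev) > 0 && nchar(al$repaired) > 0) al$repaired
          else sub("\\*$", "", cpp_translate(cds))
  cf <- classify_family(prot, refdb)
  if (is.na(cf$family) || cf$family != family) return(NULL)
  # confidence floor on the best-match identity: stands in for the
  # discard-if-not-clustering-with-known-genes step of the full pipeline
  if (cf$identity < params$min_family_identity) return(NULL)
  if (status == "complete" && cf$coverage < params$min_complete_coverage)
    status <- "truncated"
  tm <- count_tm_helices(prot, tm_min = params$tm_min)
  tibble(family = family, scaffold = model$scaffold, start = model$start,
         end = model$end, strand = model$strand, status = status, cds = cds,
         protein = prot, lof = list(ev), n_lof = nrow(ev),
         tm_count = tm$tm_count, tm_pass = tm$tm_pass,
         best_ref_id = cf$best_ref_id, best_ref_identity = cf$identity,
         clipped_start = clipped_start, clipped_end = clipped_end,
         exon_count = model$exon_count, score = model$score)
}

#' Load externally predicted spliced gene models from GFF3
#'
#' Accepts spliced-alignment output (one gene or mRNA feature per model with
#' CDS/exon children). Exon coordinates are converted to the package's
#' 0-based half-open convention and the CDS is extracted from the genome.
#'
#' @param path GFF3 file.
#' @param genome Genome object the coordinates refer to.
#' @return Model tibble with the [predict_gene_models()] contract (`score`
#'   comes from the GFF score column, 0 when absent).
#' @export
gene_models_from_gff <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("GFF3 import requires the rtracklayer package")
  genome <- as_genome(genome)
  gr <- rtracklayer::import(path, format = "gff3")
  feat <- gr[tolower(as.character(gr$type)) %in% c("cds", "exon")]
  if (length(feat) == 0) return(empty_model_tbl())
  parent <- vapply(seq_along(feat), function(i) {
    p <- feat$Parent[[i]]
    if (length(p) == 0) {
      id <- feat$ID[i]
      if (is.na(id)) paste0("model", i) else id
    } else as.character(p[1])
  }, character(1))
  df <- tibble(
    scaffold = as.character(GenomicRanges::seqnames(feat)),
    start = GenomicRanges::start(feat) - 1L,
    end = GenomicRanges::end(feat),
    strand = as.character(GenomicRanges::strand(feat)),
    score = ifelse(is.na(feat$score), 0, as.numeric(feat$score)),
    type = tolower(as.character(feat$type)),
    parent = parent)
  # prefer CDS rows when both are present for a model
  df <- df |> group_by(.data$parent) |>
    dplyr::filter(if (any(.data$type == "cds")) .data$type == "cds"
                  else TRUE) |>
    ungroup()
  purrr::map(split(df, df$parent), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    strand <- g$strand[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    ord <- if (strand == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
    cds <- paste0(vapply(ord, function(i) {
      genome_slice(genome, g$scaffold[i], g$start[i], g$end[i], strand)
    }, character(1)), collapse = "")
    tibble(scaffold = g$scaffold[1], strand = strand,
           exons = list(tibble(start = g$start, end = g$end)),
           exon_count = nrow(g), cds = cds,
           score = max(g$score), query_id = g$parent[1],
           start = min(g$start), end = max(g$end))
  }) |> bind_rows()
}
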
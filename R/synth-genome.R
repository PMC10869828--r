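# amino-acid alphabets used to build receptor-like proteins; transmembrane
# stretches use the strongly hydrophobic residues and the short inter-helix
# loops only mildly polar ones, so the Kyte-Doolittle screen sees seven
# clean helices
HYDROPHOBIC_AA <- c("I", "L", "F", "V", "A", "C")
# strongly hydrophobic residues dominate so every helix clears the
# hydropathy threshold, but all six letters occur
HYDROPHOBIC_W <- c(0.26, 0.22, 0.18, 0.18, 0.10, 0.06)
LOOP_AA <- c("S", "T", "G")
HYDROPHILIC_AA <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G", "P", "H",
                    "Y", "W")

# guard planted around fragments: stop codons in all three frames, so
# background read-through can never assemble a spuriously long ORF
ORF_GUARD <- "TTAATTAATTAA"

# target mature-protein lengths (aa, excluding the stop codon) per family
FAMILY_AA_LEN <- c(OR = 312L, TAAR = 330L, V1R = 300L, V2R = 830L,
                   T1R = 845L, T2R = 308L)

#' Specify one planted gene for the synthetic-genome generator
#'
#' @param family Chemoreceptor family of the plant.
#' @param target_status Intended miner status (`complete`, `pseudogene`,
#'   `truncated`, `edge`, `ambiguous`).
#' @param exon_mode `"single"` or `"multi"` (defaults to the family mode).
#' @param strand `"+"` or `"-"`.
#' @param placement `"free"` (mid-scaffold), `"near_border"` (only for
#'   `edge` plants) or `"with_ambiguity"` (only for `ambiguous` plants).
#' @param lof Tibble (`kind`, `codon`) of loss-of-function mutations to
#'   plant; required non-empty exactly for pseudogenes (a default two-stop
#'   recipe is filled in when omitted).
#' @param n_introns Number of introns for multi-exon plants (`NA` picks the
#'   family default: 5 for V2R/T1R, 1 for V1R).
#' @return One-row spec tibble; rows can be `bind_rows()`-ed together.
#' @export
plant_spec <- function(family, target_status = "complete", exon_mode = NULL,
                       strand = "+", placement = NULL, lof = NULL,
                       n_introns = NA_integer_) {
  family <- match.arg(family, CHEMO_FAMILIES)
  target_status <- match.arg(target_status,
                             c("complete", "pseudogene", "truncated",
                               "edge", "ambiguous"))
  if (is.null(exon_mode)) {
    exon_mode <- c(OR = "single", TAAR = "single", V1R = "single",
                   V2R = "multi", T1R = "multi", T2R = "single")[[family]]
  }
  if (is.null(placement)) {
    placement <- switch(target_status, edge = "near_border",
                        ambiguous = "with_ambiguity", "free")
  }
  placement <- match.arg(placement,
                         c("free", "near_border", "with_ambiguity"))
  if ((placement == "near_border") != (target_status == "edge"))
    abort("near_border placement is for edge plants (and edge plants only)")
  if (placement == "with_ambiguity" && target_status != "ambiguous")
    abort("with_ambiguity placement requires target_status = ambiguous")
  if (target_status == "pseudogene") {
    if (is.null(lof)) lof <- NA  # filled in by the generator
  } else if (!is.null(lof) && !all(is.na(lof)) &&
             nrow(as_tibble(lof)) > 0) {
    abort("a LoF recipe is only allowed for pseudogene plants")
  } else lof <- NULL
  tibble(family = family, exon_mode = exon_mode,
         target_status = target_status, strand = strand,
         placement = placement, lof = list(lof),
         n_introns = as.integer(n_introns))
}

#' Random plant specification covering all statuses and both exon modes
#'
#' @param n Number of plants.
#' @param families Families to draw from.
#' @return Spec tibble for [generate_synthetic_genome()].
#' @export
random_plant_specs <- function(n, families = c("OR", "V2R")) {
  statuses <- c("complete", "pseudogene", "truncated", "edge", "ambiguous")
  # guarantee coverage of every status, then fill randomly
  st <- c(statuses, sample(statuses, max(0, n - length(statuses)),
                           replace = TRUE))[seq_len(n)]
  fam <- sample(families, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  purrr::pmap(list(fam, st, strands), function(f, s, sd) {
    plant_spec(f, s, strand = sd)
  }) |> bind_rows()
}

#' Generate a synthetic genome with planted chemoreceptor genes
#'
#' Builds receptor-like reference proteins per family (seven hydrophobic
#' 21-mers joined by hydrophilic loops, plus family-appropriate N-/C-termini),
#' reverse-translates them with uniformly drawn synonymous codons, applies
#' each plant's status recipe (LoF mutations for pseudogenes, fragment
#' truncation, border placement, ambiguity runs, intron insertion at codon
#' boundaries with GT..AG splice sites), and embeds the plants into an iid
#' background at non-overlapping positions. Edge plants get their own small
#' scaffold with the fragment flush against the border. The matching
#' reference database carries three clean family queries per planted family
#' plus non-chemoreceptor GPCR decoys and outgroup records. Fully
#' deterministic under `seed`.
#'
#' @param specs Spec tibble from [plant_spec()] rows.
#' @param background_kb Main-scaffold background size (kb).
#' @param gc Background GC content.
#' @param seed Optional integer seed.
#' @return List: `genome` (DNAStringSet), `truth` (truth-table tibble),
#'   `refdb` (reference database), `params` (echo of generator inputs).
#' @export
generate_synthetic_genome <- function(specs, background_kb = 200, gc = 0.41,
                                      seed = NULL) {
  if (nrow(specs) == 0) abort("specs must be non-empty")
  build <- function() {
    fams <- sort(unique(specs$family))
    profiles <- lapply(setNames(fams, fams), make_family_profile)
    refdb <- build_reference_db(profiles)
    plants <- purrr::map(seq_len(nrow(specs)), function(i) {
      build_plant(specs[i, ], profiles[[specs$family[i]]])
    })
    assemble_genome(specs, plants, background_kb, gc, refdb)
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  out$params <- list(background_kb = background_kb, gc = gc, seed = seed,
                     n_plants = nrow(specs))
  out
}

# receptor-like protein: M + nterm + 7 x (TM21 + loop11) + tail
make_family_profile <- function(family) {
  target <- FAMILY_AA_LEN[[family]]
  nterm <- if (family %in% c("V2R", "T1R")) 480L else 20L
  # loop lengths vary so the helix/loop pattern is aperiodic, as in real
  # receptors; a periodic pattern would make off-phase self-alignments
  # nearly as good as the true register
  loop_lens <- sample(10:16, 6, replace = TRUE)
  core <- 7L * 21L + sum(loop_lens)
  tail <- target - 1L - nterm - core
  stopifnot(tail >= 5)
  tm <- replicate(7, paste(sample(HYDROPHOBIC_AA, 21, replace = TRUE,
                                  prob = HYDROPHOBIC_W), collapse = ""))
  loops <- vapply(loop_lens, function(l) {
    paste(sample(LOOP_AA, l, replace = TRUE), collapse = "")
  }, character(1))
  protein <- paste0("M",
                    paste(sample(HYDROPHILIC_AA, nterm, replace = TRUE),
                          collapse = ""),
                    paste(rbind(tm, c(loops, "")), collapse = ""),
                    paste(sample(HYDROPHILIC_AA, tail, replace = TRUE),
                          collapse = ""))
  list(family = family, protein = protein)
}

# codons per amino acid under the standard genetic code
codon_options <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      aa <- vapply(codons, cpp_translate, character(1))
      cache <<- split(codons, aa)
    }
    cache
  }
})

reverse_translate <- function(protein) {
  opts <- codon_options()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    ch <- opts[[a]]
    ch[sample.int(length(ch), 1)]
  }, character(1)), collapse = "")
}

# mutate-to-variant: substitute a fraction of residues within their own
# polarity class so hydropathy structure is preserved
protein_variant <- function(protein, rate = 0.08) {
  aa <- strsplit(protein, "")[[1]]
  idx <- which(runif(length(aa)) < rate & aa != "M")
  for (i in idx) {
    pool <- if (aa[i] %in% HYDROPHOBIC_AA) HYDROPHOBIC_AA else HYDROPHILIC_AA
    aa[i] <- sample(setdiff(pool, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

build_reference_db <- function(profiles) {
  fam_rows <- purrr::imap(profiles, function(p, fam) {
    tibble(ref_id = paste0(fam, "_ref", 1:3),
           protein = c(p$protein, protein_variant(p$protein),
                       protein_variant(p$protein)),
           family = fam, role = "family_query", subclade = NA_character_)
  }) |> bind_rows()
  decoys <- tibble(
    ref_id = paste0("nonchemo_gpcr", 1:3),
    protein = replicate(3, make_family_profile("OR")$protein),
    family = NA_character_, role = "nonchemo_gpcr",
    subclade = NA_character_)
  outgroup <- tibble(
    ref_id = paste0("outgroup", 1:2),
    protein = replicate(2, make_family_profile("T2R")$protein),
    family = NA_character_, role = "outgroup", subclade = NA_character_)
  ref_db(bind_rows(fam_rows, decoys, outgroup))
}

# default LoF recipe: two premature stops well inside the CDS (multi-exon
# safe); single-exon plants additionally work with frameshifts
default_lof_recipe <- function(n_codons, exon_mode) {
  if (exon_mode == "multi") {
    tibble(kind = c("premature_stop", "premature_stop"),
           codon = c(floor(0.45 * n_codons), floor(0.65 * n_codons)))
  } else {
    tibble(kind = c("premature_stop", "frameshift_deletion"),
           codon = c(floor(0.45 * n_codons), floor(0.65 * n_codons)))
  }
}

apply_lof <- function(cds, lof) {
  stopifnot(nchar(cds) %% 3 == 0)
  subs <- lof[lof$kind == "premature_stop", , drop = FALSE]
  for (cdn in subs$codon) {
    substr(cds, 3 * (cdn - 1) + 1, 3 * cdn) <- "TAA"
  }
  indels <- lof[lof$kind != "premature_stop", , drop = FALSE]
  for (i in order(-indels$codon)) {
    pos <- 3 * (indels$codon[i] - 1) + 1
    if (indels$kind[i] == "frameshift_deletion") {
      cds <- paste0(substr(cds, 1, pos - 1), substr(cds, pos + 1, nchar(cds)))
    } else {
      ins <- sample(c("A", "C", "G", "T"), 1)
      cds <- paste0(substr(cds, 1, pos), ins,
                    substr(cds, pos + 1, nchar(cds)))
    }
  }
  cds
}

random_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  idx <- sample.int(4L, n, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  intToUtf8(c(65L, 67L, 71L, 84L)[idx])
}

random_intron <- function(len) {
  stopifnot(len >= 6)
  paste0("GT", random_dna(len - 4), "AG")
}

# construct one plant; returns list(seq = forward-strand genomic sequence of
# the gene span, truth = bookkeeping row)
build_plant <- function(spec, profile) {
  fam <- spec$family
  mode <- spec$exon_mode
  status <- spec$target_status
  protein <- profile$protein
  R <- nchar(protein) + 1L            # codons incl. stop
  params <- family_params(fam, mode)
  cds <- paste0(reverse_translate(protein), "TAA")
  lof_keys <- character()
  n_exons <- 1L
  genic <- NULL

  if (status == "pseudogene") {
    lof <- spec$lof[[1]]
    if (is.null(lof) || all(is.na(lof)))
      lof <- default_lof_recipe(R, mode)
    cds <- apply_lof(cds, lof)
    lof_keys <- paste0(lof$kind, "@", lof$codon)
  }
  if (status == "ambiguous") {
    # keep the ambiguity run well inside one exon so intron insertion and
    # junction refinement can never excise it
    at <- 3L * (floor(0.1 * R) + 1L) + 1L
    substr(cds, at, at + 20) <- paste(rep("N", 21), collapse = "")
  }
  if (status %in% c("truncated", "edge")) {
    frag_codons <- floor(0.55 * params$min_complete_nt / 3)
    if (status == "truncated") {
      from <- floor(0.2 * R)
      cds <- substr(cds, 3 * (from - 1) + 1, 3 * (from - 1 + frag_codons))
    } else {
      # suffix fragment: the 5' end is lost beyond the scaffold border
      cds <- substr(cds, nchar(cds) - 3 * frag_codons + 1, nchar(cds))
    }
  }

  if (mode == "multi" && status %in% c("complete", "pseudogene",
                                       "ambiguous")) {
    k <- spec$n_introns
    if (is.na(k)) k <- if (fam == "V1R") 1L else 5L
    n_exons <- k + 1L
    n_cod <- nchar(cds) %/% 3
    cuts <- floor(seq_len(k) * n_cod / (k + 1L)) * 3L
    pieces <- substring(cds, c(1, cuts + 1), c(cuts, nchar(cds)))
    introns <- vapply(sample(200:600, k, replace = TRUE), random_intron,
                      character(1))
    genic <- paste0(paste0(pieces[-length(pieces)], introns,
                           collapse = ""), pieces[length(pieces)])
  } else {
    genic <- cds
  }
  fwd <- if (spec$strand == "+") genic else revcomp(genic)
  list(seq = fwd,
       truth = tibble(family = fam, exon_mode = mode,
                      target_status = status, strand = spec$strand,
                      placement = spec$placement,
                      lof_keys = list(lof_keys),
                      cds_len = nchar(cds), n_exons = n_exons,
                      span_len = nchar(genic)))
}

assemble_genome <- function(specs, plants, background_kb, gc, refdb) {
  is_edge <- specs$target_status == "edge"
  main <- which(!is_edge)
  min_gap <- 4000L
  widths <- vapply(plants, function(p) nchar(p$seq), integer(1)) +
    2L * nchar(ORF_GUARD)
  need <- sum(widths[main]) + (length(main) + 1L) * min_gap
  total <- as.integer(background_kb * 1000)
  if (need > total)
    abort("background too small to host all plants without overlap")
  truth <- list()
  # main scaffold: random order, random extra spacing
  ord <- sample(main)
  slack <- total - need
  extra <- if (length(ord) > 0) {
    u <- c(sort(runif(length(ord))), 1)
    diff(c(0, u)) * slack
  } else numeric()
  pieces <- character()
  cursor <- 0L
  for (k in seq_along(ord)) {
    i <- ord[k]
    gap <- min_gap + floor(extra[k])
    pieces <- c(pieces, random_dna(gap, gc), ORF_GUARD)
    cursor <- cursor + gap + nchar(ORF_GUARD)
    start <- cursor
    pieces <- c(pieces, plants[[i]]$seq)
    cursor <- cursor + nchar(plants[[i]]$seq)
    truth[[i]] <- plants[[i]]$truth |>
      mutate(scaffold = "sc1", start = start, end = cursor, plant = i)
    pieces <- c(pieces, ORF_GUARD)
    cursor <- cursor + nchar(ORF_GUARD)
  }
  tail_len <- total - cursor
  if (tail_len > 0) pieces <- c(pieces, random_dna(tail_len, gc))
  scaffolds <- c(sc1 = paste(pieces, collapse = ""))
  # one small scaffold per edge plant, fragment flush at the border
  for (j in seq_along(which(is_edge))) {
    i <- which(is_edge)[j]
    sc <- paste0("sc_edge", j)
    seqi <- paste0(plants[[i]]$seq, ORF_GUARD, random_dna(3000L, gc))
    scaffolds[[sc]] <- seqi
    truth[[i]] <- plants[[i]]$truth |>
      mutate(scaffold = sc, start = 0L, end = nchar(plants[[i]]$seq),
             plant = i)
  }
  list(genome = as_genome(scaffolds), truth = bind_rows(truth) |>
         arrange(.data$plant), refdb = refdb)
}
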
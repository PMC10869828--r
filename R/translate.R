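#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stop codons are rendered `"*"`; any codon containing
#' an ambiguity code is rendered `"X"`; trailing partial codons are dropped.
#'
#' @param dna A nucleotide string.
#' @return A tibble with columns `strand` (`"+"`/`"-"`), `frame` (1-3, relative
#'   to the strand) and `protein`.
#' @export
six_frame_translate <- function(dna) {
  if (!is.character(dna) || length(dna) != 1 || nchar(dna) == 0)
    abort("dna must be a single non-empty string")
  dna <- toupper(dna)
  rc <- revcomp(dna)
  frames <- tidyr::expand_grid(strand = c("+", "-"), frame = 1:3)
  frames$protein <- purrr::map2_chr(frames$strand, frames$frame, function(s, f) {
    src <- if (s == "+") dna else rc
    cpp_translate(substr(src, f, nchar(src)))
  })
  frames
}

# nt coordinates (0-based half-open, forward strand) of aa positions
# [aa_start, aa_end] (1-based) in frame `frame` of strand `strand` on a
# scaffold of length L
aa_to_nt <- function(aa_start, aa_end, strand, frame, L) {
  if (strand == "+") {
    start <- (frame - 1L) + 3L * (aa_start - 1L)
    end <- (frame - 1L) + 3L * aa_end
  } else {
    end <- L - (frame - 1L) - 3L * (aa_start - 1L)
    start <- L - (frame - 1L) - 3L * aa_end
  }
  c(start = start, end = end)
}

#' Find open reading frames in a genomic region
#'
#' Scans all six frames of a region. In the default (`require_start = TRUE`,
#' the convention for receptor CDSs) an ORF runs from an ATG to the next
#' in-frame stop; with `require_start = FALSE` the whole stop-bounded span is
#' reported. The reported nucleotide length includes the terminal stop codon.
#' Spans that run into the region boundary without a stop (or, for
#' `require_start = FALSE`, without a preceding stop) are reported with the
#' corresponding flag unset.
#'
#' @param genome A genome (`DNAStringSet` or named character vector).
#' @param region One-row interval tibble (`scaffold`, `start`, `end`), or
#'   `NULL` to scan whole scaffolds.
#' @param min_len_nt Minimum ORF length in nucleotides (>= 3).
#' @param require_start If `TRUE`, ORFs are anchored at ATG.
#' @return Tibble of ORFs: `scaffold`, `start`, `end` (0-based half-open,
#'   forward strand), `strand`, `frame`, `nt`, `aa`, `has_start`, `has_stop`.
#' @export
find_orfs <- function(genome, region = NULL, min_len_nt = 750,
                      require_start = TRUE) {
  if (min_len_nt < 3) abort("min_len_nt must be >= 3")
  genome <- as_genome(genome)
  if (is.null(region)) {
    region <- tibble(scaffold = names(genome), start = 0L,
                     end = unname(scaffold_lengths(genome)))
  }
  out <- purrr::pmap(region[, c("scaffold", "start", "end")],
                     function(scaffold, start, end) {
    seq <- genome_slice(genome, scaffold, start, end)
    L <- nchar(seq)
    frames <- six_frame_translate(seq)
    purrr::pmap(frames, function(strand, frame, protein) {
      sp <- orf_spans(protein, require_start)
      if (nrow(sp) == 0) return(NULL)
      # drop below-threshold ORFs before any sequence extraction
      sp <- sp[3L * (sp$aa_end - sp$aa_start + 1L) >= min_len_nt, ,
               drop = FALSE]
      if (nrow(sp) == 0) return(NULL)
      if (strand == "+") {
        nt_start <- (frame - 1L) + 3L * (sp$aa_start - 1L)
        nt_end <- (frame - 1L) + 3L * sp$aa_end
      } else {
        nt_end <- L - (frame - 1L) - 3L * (sp$aa_start - 1L)
        nt_start <- L - (frame - 1L) - 3L * sp$aa_end
      }
      gstart <- start + nt_start
      gend <- start + nt_end
      tibble(scaffold = scaffold, start = gstart, end = gend,
             strand = strand, frame = frame,
             has_start = sp$has_start, has_stop = sp$has_stop)
    }) |> bind_rows()
  }) |> bind_rows()
  if (is.null(out) || nrow(out) == 0) return(empty_orf_tbl())
  out$nt <- vapply(seq_len(nrow(out)), function(i) {
    genome_slice(genome, out$scaffold[i], out$start[i], out$end[i],
                 out$strand[i])
  }, character(1))
  out$aa <- vapply(out$nt, function(s) {
    sub("\\*$", "", cpp_translate(s))
  }, character(1), USE.NAMES = FALSE)
  out |> arrange(.data$scaffold, .data$start, .data$strand)
}

empty_orf_tbl <- function() {
  tibble(scaffold = character(), start = integer(), end = integer(),
         strand = character(), frame = integer(), has_start = logical(),
         has_stop = logical(), nt = character(), aa = character())
}

# aa-coordinate ORF spans within one translated frame (vectorised)
orf_spans <- function(protein, require_start) {
  L <- nchar(protein)
  stop_pos <- as.integer(stringr::str_locate_all(protein, "\\*")[[1]][, 1])
  seg_start <- c(1L, stop_pos + 1L)
  seg_stop <- c(stop_pos, L + 1L)     # stop position (L+1 = runs off the end)
  keep <- seg_start <= pmin(seg_stop - 1L + 1L, L)
  seg_start <- seg_start[keep]; seg_stop <- seg_stop[keep]
  has_stop <- seg_stop <= L
  if (length(seg_start) == 0)
    return(tibble(aa_start = integer(), aa_end = integer(),
                  has_start = logical(), has_stop = logical()))
  if (require_start) {
    segs <- substring(protein, seg_start, pmin(seg_stop - 1L, L))
    m <- regexpr("M", segs, fixed = TRUE)
    keep <- m > 0
    aa_start <- seg_start[keep] + as.integer(m[keep]) - 1L
    aa_end <- ifelse(has_stop[keep], seg_stop[keep], L)
    tibble(aa_start = as.integer(aa_start), aa_end = as.integer(aa_end),
           has_start = TRUE, has_stop = has_stop[keep])
  } else {
    aa_end <- ifelse(has_stop, seg_stop, L)
    keep <- aa_end >= seg_start
    tibble(aa_start = seg_start[keep], aa_end = as.integer(aa_end[keep]),
           has_start = FALSE, has_stop = has_stop[keep])
  }
}
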
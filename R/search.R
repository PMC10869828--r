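blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

# simple nucleotide scoring matrix over the IUPAC alphabet (match +2,
# mismatch -3, ambiguity row/col 0)
nt_score_matrix <- function(match = 2L, mismatch = -3L) {
  al <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(al, al))
  diag(m) <- match
  m["N", ] <- 0L
  m[, "N"] <- 0L
  m
}

#' Karlin-Altschul expectation value
#'
#' @param score Raw alignment score(s).
#' @param m,n Summed query and subject lengths (the search space is `m * n`).
#' @param lambda,K Karlin-Altschul parameters.
#' @return E-value(s).
#' @export
ka_evalue <- function(score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

min_score_for_evalue <- function(max_evalue, m, n, lambda = KA_LAMBDA,
                                 K = KA_K) {
  ceiling(log(K * as.numeric(m) * as.numeric(n) / max_evalue) / lambda)
}

as_protein_set <- function(ref_proteins) {
  if (is.data.frame(ref_proteins)) {
    p <- setNames(ref_proteins$protein, ref_proteins$ref_id)
  } else if (methods::is(ref_proteins, "AAStringSet")) {
    p <- setNames(as.character(ref_proteins), names(ref_proteins))
  } else p <- ref_proteins
  if (length(p) == 0) abort("no reference proteins given")
  if (is.null(names(p)) || anyDuplicated(names(p)))
    abort("reference proteins must have unique names")
  toupper(p)
}

# search matrix: BLOSUM62 with in-frame stops penalized heavily, so local
# alignments terminate at reading-frame boundaries instead of running on
# through stop-containing off-frame sequence
blosum62_search <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- blosum62()
      m["*", ] <- -30L
      m[, "*"] <- -30L
      cache <<- m
    }
    cache
  }
})

#' Translated homology search (protein queries vs genome six-frame)
#'
#' Seed-and-extend local alignment of protein queries against the six-frame
#' translation of every scaffold (BLOSUM62, affine gaps, k-mer seeding), with
#' a Karlin-Altschul expectation value computed over the search space of
#' summed query length times summed scaffold length. Only hits with
#' `evalue <= max_evalue` are returned, sorted by (scaffold, start, -score).
#'
#' @param ref_proteins Named character vector, `AAStringSet`, or tibble with
#'   `ref_id` and `protein` columns.
#' @param genome A genome (`DNAStringSet` / named character vector).
#' @param max_evalue Expectation-value cutoff (> 0).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param seed_k Seed word size for the k-mer stage.
#' @return Tibble of hits: `query_id`, `scaffold`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame`, `score`, `evalue`,
#'   `identity`, `qstart`, `qend`, `alen`.
#' @export
translated_search <- function(ref_proteins, genome, max_evalue = 1e-5,
                              gap_open = 11, gap_extend = 1, seed_k = 4) {
  if (max_evalue <= 0) abort("max_evalue must be > 0")
  queries <- as_protein_set(ref_proteins)
  genome <- as_genome(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    return(empty_hit_tbl())
  m <- sum(nchar(queries))
  n <- sum(Biostrings::width(genome))
  min_score <- min_score_for_evalue(max_evalue, m, n)
  S <- blosum62_search()
  fallback <- which(rownames(S) == "X")[1] - 1L
  res <- list()
  for (sc in names(genome)) {
    seq <- as.character(genome[[sc]])
    frames <- six_frame_translate(seq)
    L <- nchar(seq)
    for (r in seq_len(nrow(frames))) {
      subject <- frames$protein[r]
      if (nchar(subject) < seed_k) next
      df <- cpp_seed_search(subject, unname(queries), S, gap_open, gap_extend,
                            fallback, seed_k, min_score)
      if (nrow(df) == 0) next
      strand <- frames$strand[r]
      frame <- frames$frame[r]
      nt <- purrr::map2(df$sstart, df$send, function(a, b) {
        aa_to_nt(a, b, strand, frame, L)
      })
      res[[length(res) + 1L]] <- tibble(
        query_id = names(queries)[df$query],
        scaffold = sc,
        start = vapply(nt, `[[`, integer(1), "start"),
        end = vapply(nt, `[[`, integer(1), "end"),
        strand = strand, frame = frame,
        score = df$score,
        evalue = ka_evalue(df$score, m, n),
        identity = df$matches / df$alen,
        qstart = df$qstart, qend = df$qend, alen = df$alen)
    }
  }
  if (length(res) == 0) return(empty_hit_tbl())
  bind_rows(res) |>
    filter(.data$evalue <= max_evalue) |>
    distinct(.data$query_id, .data$scaffold, .data$strand, .data$frame,
             .data$start, .data$end, .keep_all = TRUE) |>
    arrange(.data$scaffold, .data$start, desc(.data$score), .data$query_id)
}

empty_hit_tbl <- function() {
  tibble(query_id = character(), scaffold = character(), start = integer(),
         end = integer(), strand = character(), frame = integer(),
         score = numeric(), evalue = numeric(), identity = numeric(),
         qstart = integer(), qend = integer(), alen = integer())
}

#' Import externally computed translated-search hits
#'
#' Reads the conventional 12-column tabular homology format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' `sstart > send` encodes a minus-strand hit; subject coordinates are 1-based
#' inclusive on import and converted to the package's 0-based half-open,
#' forward-strand convention.
#'
#' @param path Path to a tab-separated hit table without header.
#' @param genome Optional genome, used to derive the reading frame; when
#'   absent `frame` is `NA`.
#' @return Hit tibble in the same shape as [translated_search()].
#' @export
read_tabular_hits <- function(path, genome = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                      stringsAsFactors = FALSE),
    error = function(e) abort(paste0("invalid tabular hit file '", path,
                                     "': ", conditionMessage(e)))
  )
  if (nrow(df) == 0) return(empty_hit_tbl())
  if (!is.numeric(df$sstart) || !is.numeric(df$send) ||
      !is.numeric(df$evalue))
    abort(paste0("invalid tabular hit file '", path,
                 "': non-numeric coordinates"))
  minus <- df$sstart > df$send
  start0 <- ifelse(minus, df$send, df$sstart) - 1L
  end0 <- ifelse(minus, df$sstart, df$send)
  frame <- rep(NA_integer_, nrow(df))
  if (!is.null(genome)) {
    lens <- scaffold_lengths(as_genome(genome))
    L <- unname(lens[df$sseqid])
    frame <- ifelse(minus, (L - end0) %% 3L + 1L, start0 %% 3L + 1L)
  }
  tibble(query_id = df$qseqid, scaffold = df$sseqid,
         start = as.integer(start0), end = as.integer(end0),
         strand = ifelse(minus, "-", "+"), frame = as.integer(frame),
         score = df$bitscore, evalue = df$evalue,
         identity = df$pident / 100,
         qstart = as.integer(df$qstart), qend = as.integer(df$qend),
         alen = as.integer(df$length)) |>
    arrange(.data$scaffold, .data$start, desc(.data$score))
}

# protein-protein local alignment (BLOSUM62 affine); returns list with score,
# coordinates, matches, alen
protein_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- blosum62()
  fallback <- which(rownames(S) == "X")[1] - 1L
  cpp_sw(toupper(a), toupper(b), S, gap_open, gap_extend, fallback)
}

nt_align <- function(a, b, gap_open = 5, gap_extend = 2) {
  S <- nt_score_matrix()
  cpp_sw(toupper(a), toupper(b), S, gap_open, gap_extend, 4L)
}
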
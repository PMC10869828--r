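#' Write mined candidates to disk (TSV + FASTA + GFF3)
#'
#' Writes a flat candidate table (LoF events serialised as
#' `kind@codon` keys), CDS and protein FASTA files, and — when rtracklayer
#' is available — a GFF3 with one gene feature per candidate and exon
#' children, carrying `status` and `lof` attributes.
#'
#' @param candidates Candidate tibble from the miners.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_candidates <- function(candidates, dir, prefix = "candidates") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("%s_%s_%04d", candidates$family, candidates$status,
                 seq_len(max(1, nrow(candidates))))[seq_len(nrow(candidates))]
  flat <- candidates |>
    mutate(candidate_id = ids,
           lof = vapply(.data$lof, function(x) {
             paste(lof_keys(x), collapse = ";")
           }, character(1))) |>
    select("candidate_id", dplyr::everything())
  paths <- c(tsv = file.path(dir, paste0(prefix, ".tsv")),
             cds = file.path(dir, paste0(prefix, "_cds.fasta")),
             protein = file.path(dir, paste0(prefix, "_protein.fasta")),
             gff = file.path(dir, paste0(prefix, ".gff3")))
  readr::write_tsv(flat, paths[["tsv"]])
  if (nrow(candidates) > 0) {
    write_fasta(setNames(candidates$cds, ids), paths[["cds"]], "dna")
    write_fasta(setNames(candidates$protein, ids), paths[["protein"]], "aa")
  } else {
    file.create(paths[["cds"]]); file.create(paths[["protein"]])
  }
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      nrow(candidates) > 0) {
    rtracklayer::export(candidates_to_granges(candidates, ids),
                        paths[["gff"]], format = "gff3")
  } else paths <- paths[names(paths) != "gff"]
  invisible(paths)
}

candidates_to_granges <- function(candidates, ids) {
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    exons <- if (!"exons" %in% names(cd) || is.null(cd$exons[[1]])) {
      tibble(start = cd$start, end = cd$end)
    } else cd$exons[[1]]
    bind_rows(
      tibble(scaffold = cd$scaffold, start = cd$start, end = cd$end,
             strand = cd$strand, type = "gene", ID = ids[i],
             Parent = NA_character_, status = cd$status,
             lof = paste(lof_keys(cd$lof[[1]]), collapse = ";")),
      tibble(scaffold = cd$scaffold, start = exons$start, end = exons$end,
             strand = cd$strand, type = "exon",
             ID = paste0(ids[i], ".exon", seq_len(nrow(exons))),
             Parent = ids[i], status = NA_character_, lof = NA_character_))
  }) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$scaffold,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand)
  gr$type <- rows$type
  gr$ID <- rows$ID
  gr$Parent <- ifelse(is.na(rows$Parent), NA_character_, rows$Parent)
  gr$status <- rows$status
  gr$lof <- rows$lof
  gr
}

#' Read a per-tip annotation table (TSV keyed by node/tip label)
#' @param path TSV with a first column of labels.
#' @return Tibble.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Serialize a simulation or fit summary to JSON
#' @param x A list or glance-able object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
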
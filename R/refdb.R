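#' Reference protein database
#'
#' A reference database is a tibble with columns `ref_id`, `protein`,
#' `family` (one of OR, TAAR, V1R, V2R, T1R, T2R, or `NA` for non-family
#' records), `role` (`family_query`, `outgroup` or `nonchemo_gpcr`) and an
#' optional `subclade` tag. `ref_id`s must be unique and every mined family
#' needs at least one `family_query` record.
#'
#' @param x Tibble (or data frame) with the columns above.
#' @return Validated reference-database tibble.
#' @export
ref_db <- function(x) {
  x <- as_tibble(x)
  need <- c("ref_id", "protein", "family", "role")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort(paste0("ref db is missing columns: ", paste(miss, collapse = ", ")))
  if (!"subclade" %in% names(x)) x$subclade <- NA_character_
  if (anyDuplicated(x$ref_id))
    abort(paste0("duplicate ref_id: ", x$ref_id[duplicated(x$ref_id)][1]))
  bad <- setdiff(x$role, c("family_query", "outgroup", "nonchemo_gpcr"))
  if (length(bad) > 0) abort(paste0("unknown ref role: ", bad[1]))
  x$protein <- unname(toupper(x$protein))
  x$ref_id <- unname(x$ref_id)
  x[, c("ref_id", "protein", "family", "role", "subclade")]
}

#' Read a reference database from FASTA
#'
#' Headers carry `family=... role=... subclade=...` tokens after the id, e.g.
#' `>OR_ref1 family=OR role=family_query subclade=alpha`.
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Reference-database tibble (see [ref_db()]).
#' @export
read_refdb_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  hdr <- names(x)
  token <- function(h, key) {
    m <- stringr::str_match(h, paste0(key, "=(\\S+)"))[, 2]
    m
  }
  ref_db(tibble(
    ref_id = sub("\\s.*$", "", hdr),
    protein = as.character(x),
    family = token(hdr, "family"),
    role = dplyr::coalesce(token(hdr, "role"), "family_query"),
    subclade = token(hdr, "subclade")
  ))
}

#' Write a reference database to FASTA
#' @param refdb Reference-database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refdb_fasta <- function(refdb, path) {
  refdb <- ref_db(refdb)
  hdr <- paste0(refdb$ref_id,
                ifelse(is.na(refdb$family), "",
                       paste0(" family=", refdb$family)),
                " role=", refdb$role,
                ifelse(is.na(refdb$subclade), "",
                       paste0(" subclade=", refdb$subclade)))
  write_fasta(setNames(refdb$protein, hdr), path, type = "aa")
}

#' Mining parameters for one chemoreceptor family
#'
#' Returns the per-family parameter set used by the two mining procedures:
#' search and rescan E-value tiers (1e-5 / 1e-20), flank extension (1000 bp
#' single-exon / 30000 bp multi-exon), minimum complete-CDS lengths (750 nt
#' for OR and T2R, 810 for V1R, 850 for TAAR; 810/2100/2200 nt for multi-exon
#' V1R/V2R/T1R), the mean expected gene length that starts the iterative
#' model-selection loop (900 nt for V1R, 2700 nt for V2R and T1R), the 400 bp
#' reporting floor for V2R/T1R, and the tblastn exon-inference rule (hits of
#' at least 50 bp, merged when closer than 100 bp).
#'
#' @param family One of `"OR"`, `"TAAR"`, `"V1R"`, `"V2R"`, `"T1R"`, `"T2R"`.
#' @param exon_mode `"single"` or `"multi"`; defaults to the family's usual
#'   mode (V1R supports both: single-exon in most clades, multi-exon in
#'   ray-finned fishes).
#' @param ... Named overrides of individual parameters.
#' @return A list of parameters (class `family_params`).
#' @export
family_params <- function(family, exon_mode = NULL, ...) {
  family <- match.arg(family, CHEMO_FAMILIES)
  default_mode <- c(OR = "single", TAAR = "single", V1R = "single",
                    V2R = "multi", T1R = "multi", T2R = "single")[[family]]
  if (is.null(exon_mode)) exon_mode <- default_mode
  exon_mode <- match.arg(exon_mode, c("single", "multi"))
  if (exon_mode == "multi" && !family %in% c("V1R", "V2R", "T1R"))
    abort(paste0(family, " is mined as a single-exon family"))
  if (exon_mode == "single" && family %in% c("V2R", "T1R"))
    abort(paste0(family, " is mined as a multi-exon family"))
  min_complete <- if (exon_mode == "single") {
    c(OR = 750L, T2R = 750L, V1R = 810L, TAAR = 850L)[[family]]
  } else {
    c(V1R = 810L, V2R = 2100L, T1R = 2200L)[[family]]
  }
  mean_expected <- if (exon_mode == "multi") {
    c(V1R = 900L, V2R = 2700L, T1R = 2700L)[[family]]
  } else NA_integer_
  p <- list(
    family = family,
    exon_mode = exon_mode,
    search_evalue = 1e-5,
    rescan_evalue = 1e-20,
    flank_bp = if (exon_mode == "single") 1000L else 30000L,
    min_complete_nt = min_complete,
    mean_expected_nt = mean_expected,
    min_report_nt = if (family %in% c("V2R", "T1R")) 400L else 0L,
    exon_hit_min_bp = 50L,
    exon_gap_min_bp = 100L,
    orf_require_start = TRUE,
    stop_margin = 15L,
    tm_min = 6L,
    edge_margin_bp = 1000L,
    max_intron_bp = 2000L,
    min_family_identity = 0.35,
    min_complete_coverage = 0.8
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0) abort(paste0("unknown parameter: ", bad[1]))
  p[names(dots)] <- dots
  if (p$min_report_nt > p$min_complete_nt)
    abort("min_report_nt must be <= min_complete_nt")
  structure(p, class = "family_params")
}
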
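#' Read a genome assembly from FASTA
#'
#' Loads a (possibly multi-scaffold) genome assembly into a
#' [Biostrings::DNAStringSet]. Sequences are uppercased, scaffold ids must be
#' unique and sequences non-empty; the alphabet is restricted to the IUPAC
#' nucleotide codes.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per scaffold, names = scaffold ids.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("genome FASTA not found: ", path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  # keep only the first header token as the scaffold id
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(setNames(toupper(as.character(x)), names(x)))
}

#' Build a genome object from named sequences
#'
#' @param x Named character vector of nucleotide sequences, or a
#'   `DNAStringSet`.
#' @return A validated `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) == 0) return(x)
    # already validated on construction; re-validating (and re-uppercasing)
    # a large genome on every call would dominate the runtime
    if (is.null(names(x)) || anyDuplicated(names(x)))
      abort("scaffold ids must be present and unique")
    return(x)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    abort("all scaffolds must be named")
  if (anyDuplicated(names(x)))
    abort(paste0("duplicate scaffold id: ",
                 names(x)[duplicated(names(x))][1]))
  x <- toupper(x)
  if (any(nchar(x) == 0)) abort("scaffold sequences must be non-empty")
  Biostrings::DNAStringSet(x)
}

scaffold_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# 0-based half-open slice of one scaffold, as character; strand "-" returns
# the reverse complement of the forward slice
genome_slice <- function(genome, scaffold, start, end, strand = "+") {
  if (!scaffold %in% names(genome))
    abort(paste0("unknown scaffold: ", scaffold))
  s <- Biostrings::subseq(genome[[scaffold]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a genome (or any named sequence set) to FASTA
#' @param x Named character vector or `XStringSet`.
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (methods::is(x, "XStringSet")) x
         else if (type == "dna") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
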
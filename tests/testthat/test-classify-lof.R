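mini_refdb <- function(seed = 21) {
  withr::with_seed(seed, {
    profs <- lapply(stats::setNames(c("OR", "TAAR"), c("OR", "TAAR")),
                    chemomine:::make_family_profile)
    chemomine:::build_reference_db(profs)
  })
}

test_that("family assignment returns the best-matching family", {
  refdb <- mini_refdb()
  or_ref <- refdb$protein[refdb$ref_id == "OR_ref1"]
  cf <- classify_family(or_ref, refdb)
  expect_equal(cf$family, "OR")
  expect_equal(cf$best_ref_id, "OR_ref1")
  expect_equal(cf$identity, 1)
  # closest to a decoy -> rejected
  decoy <- refdb$protein[refdb$role == "nonchemo_gpcr"][1]
  cf2 <- classify_family(decoy, refdb)
  expect_true(cf2$rejected)
  expect_true(is.na(cf2$family))
  expect_error(classify_family("", refdb), "non-empty")
})

test_that("exact score ties break by lexicographic ref_id", {
  shared <- "MKLLIVFSTWYRDEQNHKLVFFIL"
  db <- ref_db(tibble::tibble(
    ref_id = c("zzz", "aaa"),
    protein = shared,
    family = c("TAAR", "OR"),
    role = "family_query"))
  cf <- classify_family(shared, db)
  expect_equal(cf$best_ref_id, "aaa")
  expect_equal(cf$family, "OR")
})

test_that("LoF detection finds planted stops and frameshifts", {
  withr::with_seed(31, {
    ref <- chemomine:::make_family_profile("OR")$protein   # 312 aa
    cds <- paste0(chemomine:::reverse_translate(ref), "TAA")
    # premature stop at codon 50
    mut <- cds
    substr(mut, 148, 150) <- "TAA"
    ev <- detect_lof(mut, ref)
    expect_equal(ev$kind, "premature_stop")
    expect_equal(ev$ref_codon, 50L)
    # single-nucleotide deletion at nt 100 -> frameshift at codon 34
    del <- paste0(substr(cds, 1, 99), substr(cds, 101, nchar(cds)))
    ev2 <- detect_lof(del, ref)
    expect_true("frameshift_deletion" %in% ev2$kind)
    fs <- ev2[ev2$kind == "frameshift_deletion", ]
    # nt 100 sits in codon 34; in repetitive context the slip position is
    # only defined up to alignment equivalence, hence the one-codon window
    expect_true(abs(fs$ref_codon[1] - 34L) <= 1L)
    # unmutated copy is clean
    expect_equal(nrow(detect_lof(cds, ref)), 0L)
    # C-terminal stops inside the margin are not called premature
    late <- cds
    substr(late, nchar(cds) - 14, nchar(cds) - 12) <- "TAA"
    expect_equal(nrow(detect_lof(late, ref)), 0L)
    expect_error(detect_lof("ACGTACGTACGT", ref), "does not align")
  })
})

test_that("LoF positions are reported on the reference scale", {
  withr::with_seed(32, {
    ref <- chemomine:::make_family_profile("T2R")$protein
    cds <- paste0(chemomine:::reverse_translate(ref), "TAA")
    mut <- cds
    substr(mut, 3 * 119 + 1, 3 * 120) <- "TAA"   # codon 120
    ins <- paste0(substr(mut, 1, 450), "G", substr(mut, 451, nchar(mut)))
    ev <- detect_lof(ins, ref)
    expect_setequal(ev$kind, c("premature_stop", "frameshift_insertion"))
    expect_equal(ev$ref_codon[ev$kind == "premature_stop"], 120L)
    # the insertion after nt 450 belongs at codon 151, up to alignment
    # equivalence across compatible neighbouring codons
    expect_true(abs(ev$ref_codon[ev$kind == "frameshift_insertion"] -
                      151L) <= 4L)
  })
})

test_that("hydropathy screen counts seven clean helices", {
  tm7 <- paste(rep(c(strrep("L", 21), strrep("S", 10)), 7), collapse = "")
  res <- count_tm_helices(tm7)
  expect_equal(res$tm_count, 7L)
  expect_true(res$tm_pass)
  res2 <- count_tm_helices(strrep("E", 300))
  expect_equal(res2$tm_count, 0L)
  expect_false(res2$tm_pass)
  # generator template passes the screen
  prof <- withr::with_seed(4, chemomine:::make_family_profile("OR"))
  expect_true(count_tm_helices(prof$protein)$tm_pass)
  # shorter than the window
  expect_equal(count_tm_helices("MKLV")$tm_count, 0L)
})

test_that("status assignment follows the documented decision order", {
  params <- family_params("OR")
  intact <- withr::with_seed(33, {
    paste0(chemomine:::reverse_translate(
      chemomine:::make_family_profile("OR")$protein), "TAA")
  })
  expect_equal(assign_status(intact, 0, FALSE, params), "complete")
  expect_equal(assign_status(substr(intact, 1, 600), 1, FALSE, params),
               "pseudogene")
  expect_equal(assign_status(substr(intact, 1, 600), 0, TRUE, params),
               "edge")
  expect_equal(assign_status(substr(intact, 1, 600), 0, FALSE, params),
               "truncated")
  # ambiguity dominates everything
  ambig <- intact
  substr(ambig, 100, 102) <- "NNN"
  expect_equal(assign_status(ambig, 2, TRUE, params), "ambiguous")
  # LoF dominates the border for fragments
  expect_equal(assign_status(substr(intact, 1, 600), 1, TRUE, params),
               "pseudogene")
})
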
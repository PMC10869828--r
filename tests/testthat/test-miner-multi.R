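test_that("exon-count inference applies the 50 bp / 100 bp rule", {
  h <- tibble::tibble(start = c(0L, 200L, 300L), end = c(60L, 290L, 360L))
  expect_equal(infer_exon_count(h), 2L)
  expect_equal(infer_exon_count(tibble::tibble(start = 0L, end = 40L)), 0L)
  expect_equal(infer_exon_count(tibble::tibble(start = integer(),
                                               end = integer())), 0L)
})

multi_exon_fixture <- function() {
  specs <- dplyr::bind_rows(
    plant_spec("V2R", "complete"),
    plant_spec("V2R", "pseudogene"),
    plant_spec("V2R", "truncated"),
    plant_spec("V1R", "complete", exon_mode = "multi"),
    plant_spec("T1R", "complete", strand = "-"))
  generate_synthetic_genome(specs, background_kb = 80, seed = 7)
}

test_that("spliced prediction recovers a planted multi-exon CDS", {
  syn <- multi_exon_fixture()
  tr <- syn$truth[syn$truth$family == "V2R" &
                    syn$truth$target_status == "complete", ]
  refdb <- syn$refdb
  fam <- refdb[refdb$role == "family_query" & refdb$family == "V2R", ]
  region <- tibble::tibble(scaffold = tr$scaffold,
                           start = max(0L, tr$start - 1000L),
                           end = tr$end + 1000L)
  preds <- predict_gene_models(syn$genome, region,
                               stats::setNames(fam$protein, fam$ref_id))
  best <- preds[which.max(preds$score), ]
  expect_equal(best$exon_count, tr$n_exons)
  expect_equal(c(best$start, best$end), c(tr$start, tr$end))
  # junctions are resolved up to GT..AG-equivalent splice variants, so the
  # CDS must be intact and essentially identical but may differ by a codon
  # or two at a junction
  expect_true(chemomine:::is_intact_cds(best$cds))
  expect_lte(abs(nchar(best$cds) - tr$cds_len), 6L)
  prot <- sub("\\*$", "", chemomine:::cpp_translate(best$cds))
  al <- chemomine:::protein_align(prot, fam$protein[1])
  expect_gte(al$matches / al$alen, 0.98)
})

test_that("seeds in reversed genomic order are never chained", {
  # two 'exons' whose query order contradicts genomic order
  hq <- tibble::tibble(start = c(0L, 500L), end = c(300L, 800L),
                       qstart = c(200L, 1L), qend = c(300L, 100L),
                       score = c(100, 100), query_id = "q")
  chains <- chemomine:::chain_seeds(hq, 20, 10, 2000, strrep("A", 1000))
  expect_equal(length(chains), 2L)
  expect_true(all(vapply(chains, nrow, integer(1)) == 1L))
})

test_that("model selection honours cap, length loop and score tie-break", {
  params <- family_params("V2R")
  base <- tibble::tibble(scaffold = "s1", strand = "+", exons = list(NULL),
                         query_id = "q")
  p1 <- base |> dplyr::mutate(exon_count = 2L, cds = strrep("A", 2700),
                              score = 120, start = 0L, end = 4000L)
  p2 <- base |> dplyr::mutate(exon_count = 2L, cds = strrep("A", 2700),
                              score = 90, start = 100L, end = 4100L)
  sel <- select_gene_models(dplyr::bind_rows(p1, p2), 3L, params)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$score, 120)
  # exon cap discards
  p3 <- base |> dplyr::mutate(exon_count = 5L, cds = strrep("A", 2700),
                              score = 500, start = 0L, end = 4000L)
  expect_equal(nrow(select_gene_models(p3, 3L, params)), 0L)
  # a shorter disjoint prediction is accepted once the threshold drops
  p4 <- base |> dplyr::mutate(exon_count = 1L, cds = strrep("A", 1500),
                              score = 60, start = 8000L, end = 9600L)
  sel2 <- select_gene_models(dplyr::bind_rows(p1, p2, p4), 3L, params)
  expect_equal(sort(sel2$score), c(60, 120))
  # selection is invariant to input ordering
  sel3 <- select_gene_models(dplyr::bind_rows(p4, p2, p1), 3L, params)
  expect_equal(sort(sel3$score), sort(sel2$score))
})

test_that("multi-exon mining classifies planted genes correctly", {
  syn <- multi_exon_fixture()
  for (fam in c("V2R", "V1R", "T1R")) {
    params <- family_params(fam, "multi")
    cands <- mine_multi_exon(syn$genome, fam, syn$refdb, params)
    truth <- syn$truth[syn$truth$family == fam, ]
    got <- vapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      hit <- cands[cands$scaffold == tr$scaffold & cands$start < tr$end &
                     cands$end > tr$start, ]
      if (nrow(hit) == 0) NA_character_ else hit$status[1]
    }, character(1))
    expect_equal(got, truth$target_status)
  }
})

test_that("V2R/T1R fragments below 400 bp are discarded", {
  syn <- multi_exon_fixture()
  params <- family_params("V2R", min_report_nt = 400L)
  cands <- mine_multi_exon(syn$genome, "V2R", syn$refdb, params)
  expect_true(all(nchar(cands$cds) >= 400))
  # select_gene_models never accepts below the reporting floor
  base <- tibble::tibble(scaffold = "s1", strand = "+", exons = list(NULL),
                         query_id = "q", exon_count = 1L,
                         cds = strrep("A", 350), score = 50, start = 0L,
                         end = 350L)
  expect_equal(nrow(select_gene_models(base, 3L, params)), 0L)
})

test_that("externally supplied GFF3 models bypass the built-in predictor", {
  skip_if_not_installed("rtracklayer")
  syn <- multi_exon_fixture()
  tr <- syn$truth[syn$truth$family == "V2R" &
                    syn$truth$target_status == "complete", ]
  # write the true exon structure as GFF3 and re-import
  fam <- syn$refdb[syn$refdb$role == "family_query" &
                     syn$refdb$family == "V2R", ]
  region <- tibble::tibble(scaffold = tr$scaffold, start = tr$start - 500L,
                           end = tr$end + 500L)
  preds <- predict_gene_models(syn$genome, region,
                               stats::setNames(fam$protein, fam$ref_id))
  best <- preds[which.max(preds$score), ]
  gff <- withr::local_tempfile(fileext = ".gff3")
  ex <- best$exons[[1]]
  lines <- c("##gff-version 3",
             sprintf("%s\tchemomine\tCDS\t%d\t%d\t%s\t%s\t.\tID=m1.%d;Parent=m1",
                     tr$scaffold, ex$start + 1L, ex$end, format(best$score),
                     best$strand, seq_len(nrow(ex))))
  writeLines(lines, gff)
  models <- gene_models_from_gff(gff, syn$genome)
  expect_equal(nrow(models), 1L)
  expect_equal(models$exon_count, best$exon_count)
  expect_equal(models$cds, best$cds)
  cands <- mine_multi_exon(syn$genome, "V2R", syn$refdb,
                           gff_models = models)
  expect_true(any(cands$status == "complete" & cands$start == tr$start))
})
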
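test_that("the genome generator is deterministic under a seed", {
  specs <- dplyr::bind_rows(plant_spec("OR", "complete"),
                            plant_spec("OR", "pseudogene"),
                            plant_spec("OR", "edge"))
  a <- generate_synthetic_genome(specs, background_kb = 40, seed = 12)
  b <- generate_synthetic_genome(specs, background_kb = 40, seed = 12)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$refdb, b$refdb)
  c <- generate_synthetic_genome(specs, background_kb = 40, seed = 13)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("the truth table records every plant with consistent coordinates", {
  specs <- dplyr::bind_rows(
    plant_spec("OR", "complete"), plant_spec("OR", "complete"),
    plant_spec("OR", "complete"), plant_spec("OR", "pseudogene"),
    plant_spec("OR", "edge"))
  syn <- generate_synthetic_genome(specs, background_kb = 60, seed = 3)
  expect_equal(nrow(syn$truth), 5L)
  lens <- scaffold_lengths(syn$genome)
  expect_true(all(syn$truth$end <= lens[syn$truth$scaffold]))
  expect_true(all(syn$truth$start >= 0))
  # the planted sequence really sits at the recorded coordinates
  tr <- syn$truth[syn$truth$target_status == "complete", ][1, ]
  cds <- chemomine:::genome_slice(syn$genome, tr$scaffold, tr$start, tr$end,
                                  tr$strand)
  expect_true(chemomine:::is_intact_cds(cds))
})

test_that("pseudogene recipes are applied constructively", {
  specs <- plant_spec("OR", "pseudogene",
                      lof = tibble::tibble(kind = "premature_stop",
                                           codon = 50L))
  syn <- generate_synthetic_genome(specs, background_kb = 30, seed = 5)
  tr <- syn$truth
  expect_equal(tr$lof_keys[[1]], "premature_stop@50")
  cds <- chemomine:::genome_slice(syn$genome, tr$scaffold, tr$start, tr$end,
                                  tr$strand)
  expect_equal(substr(cds, 148, 150), "TAA")
})

test_that("multi-exon plants respect intron bookkeeping", {
  specs <- plant_spec("V2R", "complete", n_introns = 2L)
  syn <- generate_synthetic_genome(specs, background_kb = 40, seed = 6)
  tr <- syn$truth
  expect_equal(tr$n_exons, 3L)
  expect_gt(tr$span_len, tr$cds_len)
  genic <- chemomine:::genome_slice(syn$genome, tr$scaffold, tr$start,
                                    tr$end, tr$strand)
  # excising GT..AG introns restores a cleanly translating CDS
  m <- gregexpr("GT", genic)[[1]]
  expect_true(length(m) >= 2)
})

test_that("overcrowded backgrounds are rejected", {
  specs <- dplyr::bind_rows(lapply(1:8, function(i) {
    plant_spec("V2R", "complete")
  }))
  expect_error(generate_synthetic_genome(specs, background_kb = 20,
                                         seed = 1),
               "too small")
})

test_that("loss scenarios are deterministic and internally consistent", {
  a <- generate_loss_scenario(n_tips = 16, n_losses = 2, seed = 4)
  b <- generate_loss_scenario(n_tips = 16, n_losses = 2, seed = 4)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$lof_sets, b$lof_sets)
  expect_identical(a$loss_branches, b$loss_branches)
  expect_equal(length(a$loss_branches), 2L)
  # every branch carries a category
  br <- phylo_branches(a$tree)
  expect_true(all(br$branch %in% names(a$categories)))
  # zero planted losses leave every tip LoF-free
  z <- generate_loss_scenario(n_tips = 8, n_losses = 0, seed = 5)
  expect_true(all(vapply(z$lof_sets, length, integer(1)) == 0))
  expect_error(generate_loss_scenario(n_tips = 4, n_losses = 50, seed = 1),
               "smaller")
})

test_that("planted losses are recovered exactly by inference", {
  for (s in 1:25) {
    sc <- generate_loss_scenario(n_tips = 16, n_losses = sample(1:3, 1),
                                 seed = s)
    inf <- infer_loss_branches(sc$tree, sc$lof_sets)
    expect_setequal(inf$branch, sc$loss_branches)
    counts <- count_losses_by_category(sc$tree, inf$branch, sc$categories)
    expect_equal(counts, sc$counts)
  }
})
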
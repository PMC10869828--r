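tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
}
cats4 <- c(A = "carnivore", B = "carnivore", ab = "carnivore",
           C = "herbivore", D = "herbivore", cd = "herbivore")

test_that("shared LoF keys place losses on the clade's stem branch", {
  lof <- list(A = c("premature_stop@120", "frameshift_insertion@7"),
              B = "premature_stop@120", C = character(), D = character())
  inf <- infer_loss_branches(tree4(), lof)
  expect_equal(inf$branch, "ab")
  expect_equal(inf$shared_keys[[1]], "premature_stop@120")
  # a private LoF maps to the terminal branch
  lof2 <- list(A = "frameshift_deletion@55")
  inf2 <- infer_loss_branches(tree4(), lof2)
  expect_equal(inf2$branch, "A")
  # no LoF anywhere -> empty inference
  expect_equal(nrow(infer_loss_branches(tree4(), list())), 0L)
  expect_error(infer_loss_branches(tree4(), list(Z = "premature_stop@1")),
               "not in tree")
})

test_that("sister clades with different shared keys give separate losses", {
  lof <- list(A = "premature_stop@10", B = "premature_stop@10",
              C = "premature_stop@20", D = "premature_stop@20")
  inf <- infer_loss_branches(tree4(), lof)
  expect_setequal(inf$branch, c("ab", "cd"))
  # no loss branch nests inside another
  br <- phylo_branches(tree4())
  topo <- chemomine:::branch_topology(br)
  idx <- match(inf$node, br$node)
  for (i in idx) expect_false(any(idx %in% topo$anc[[i]]))
})

test_that("independent losses and intact branches count correctly", {
  counts <- count_losses_by_category(tree4(), "ab", cats4)
  expect_equal(counts$independent_losses, c(1L, 0L))
  expect_equal(counts$intact_branches, c(0L, 3L))
  # no losses: every branch is intact
  c0 <- count_losses_by_category(tree4(), character(), cats4)
  expect_equal(c0$intact_branches, c(3L, 3L))
  # nested losses collapse to one independent event
  c2 <- count_losses_by_category(tree4(), c("ab", "A"), cats4)
  expect_equal(c2$independent_losses[c2$category == "carnivore"], 1L)
  expect_error(count_losses_by_category(tree4(), "ab", cats4[-1]),
               "without category")
})

test_that("counting agrees with a brute-force reimplementation", {
  set.seed(303)
  for (r in 1:60) {
    n <- sample(4:12, 1)
    tr <- ape::rphylo(n, 1, 0)
    tr <- chemomine:::ensure_node_labels(tr)
    br <- phylo_branches(tr)
    cats <- stats::setNames(sample(c("a", "b", "c"), nrow(br),
                                   replace = TRUE), br$branch)
    losses <- sample(br$branch, sample(0:3, 1))
    got <- count_losses_by_category(tr, losses, cats)
    bf <- bf_count_losses(tr, losses, cats)
    expect_equal(stats::setNames(got$independent_losses, got$category),
                 bf$independent)
    expect_equal(stats::setNames(got$intact_branches, got$category),
                 bf$intact)
  }
})

test_that("contingency tests match closed-form results", {
  t1 <- contingency_tests(matrix(c(1, 0, 0, 3), 2, 2))
  expect_equal(t1$fisher_p, 0.25)
  t2 <- contingency_tests(matrix(c(2, 2, 2, 2), 2, 2))
  expect_equal(t2$chi2_stat, 0)
  expect_equal(t2$chi2_p, 1)
  t3 <- contingency_tests(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(t3$fisher_p, 2 / choose(20, 10), tolerance = 1e-12)
  # the tibble interface matches the matrix interface
  tb <- tibble::tibble(category = c("x", "y"),
                       independent_losses = c(1L, 0L),
                       intact_branches = c(0L, 3L))
  expect_equal(contingency_tests(tb)$fisher_p, 0.25)
  expect_error(contingency_tests(matrix(c(-1, 0, 0, 1), 2, 2)),
               "non-negative")
})

test_that("gene-status reclassification follows the evidence hierarchy", {
  ev <- tibble::tibble(
    species = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8"),
    assembly_status = c("complete", "truncated", "pseudogene", "pseudogene",
                        "pseudogene", "absent", "absent", "edge"),
    lof = list(character(), character(),
               c("premature_stop@40", "premature_stop@200"),
               "premature_stop@77", "premature_stop@91",
               character(), character(), character()),
    sibling_statuses = list(character(), "complete", character(),
                            character(), character(), character(),
                            character(), character()),
    sibling_lof = list(character(), character(), character(),
                       "premature_stop@77", character(), character(),
                       character(), character()),
    relative_lof = list(character(), character(), character(), character(),
                        character(), character(), character(), character()),
    fragments_cover_complete = FALSE,
    flanking_same_scaffold = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                               FALSE, FALSE))
  out <- reclassify_gene_status(ev)
  expect_equal(out$reclassified,
               c("complete",               # complete in the assembly
                 "complete",               # sibling assembly has it complete
                 "high_confidence_loss",   # two distant LoF
                 "high_confidence_loss",   # corroborated by sibling
                 "low_confidence_loss",    # single uncorroborated LoF
                 "high_confidence_loss",   # deletion with flanking genes
                 "low_confidence_loss",    # absent, flanks scattered
                 "undetermined"))          # unresolved edge evidence
  # two close LoF mutations are not "distant"
  ev2 <- tibble::tibble(species = "x", assembly_status = "pseudogene",
                        lof = list(c("premature_stop@40",
                                     "premature_stop@60")))
  expect_equal(reclassify_gene_status(ev2)$reclassified,
               "low_confidence_loss")
  # fragments merging into a full CDS count as complete
  ev3 <- tibble::tibble(species = "y", assembly_status = "truncated",
                        lof = list(character()),
                        fragments_cover_complete = TRUE)
  expect_equal(reclassify_gene_status(ev3)$reclassified, "complete")
})
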
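two_tip <- function() ape::read.tree(text = "(A:3,B:1);")
cats2 <- c(A = "carnivore", B = "herbivore")

test_that("single-draw probabilities match the analytic values", {
  sim <- simulate_random_losses(two_tip(), 1, cats2,
                                observed_counts = c(carnivore = 1),
                                n_sims = 40000, seed = 1)
  p <- sim$p$p_value[sim$p$category == "carnivore"]
  expect_equal(p, 0.5, tolerance = 0.02)
  simw <- simulate_random_losses(two_tip(), 1, cats2,
                                 observed_counts = c(carnivore = 1),
                                 weighted = TRUE, n_sims = 40000, seed = 1)
  pw <- simw$p$p_value[simw$p$category == "carnivore"]
  expect_equal(pw, 0.75, tolerance = 0.02)
})

test_that("guards reject impossible draws", {
  expect_error(simulate_random_losses(two_tip(), 3, cats2, n_sims = 10),
               "cannot place")
  expect_error(simulate_random_losses(two_tip(), 0, cats2, n_sims = 10),
               ">= 1")
})

test_that("fixed seeds give bit-identical simulations", {
  a <- simulate_random_losses(two_tip(), 1, cats2, n_sims = 500, seed = 7)
  b <- simulate_random_losses(two_tip(), 1, cats2, n_sims = 500, seed = 7)
  expect_identical(a$counts, b$counts)
  s1 <- simulate_shared_missing(1:10, c(3, 4), n_sims = 200, seed = 9)
  s2 <- simulate_shared_missing(1:10, c(3, 4), n_sims = 200, seed = 9)
  expect_identical(s1$shared, s2$shared)
})

test_that("p-values are monotone non-increasing in the observed counts", {
  tr <- withr::with_seed(2, ape::rphylo(12, 1, 0))
  br <- phylo_branches(chemomine:::ensure_node_labels(tr))
  cats <- stats::setNames(rep(c("x", "y"), length.out = nrow(br)),
                          br$branch)
  p_at <- function(k) {
    sim <- simulate_random_losses(chemomine:::ensure_node_labels(tr), 3,
                                  cats, observed_counts = c(x = k),
                                  n_sims = 4000, seed = 11)
    sim$p$p_value[sim$p$category == "x"]
  }
  ps <- vapply(0:3, p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[1], 1)
})

test_that("first draws are uniform over branches when unweighted", {
  tr <- chemomine:::ensure_node_labels(
    withr::with_seed(5, ape::rphylo(6, 1, 0)))
  br <- phylo_branches(tr)
  # give every branch its own category so counts identify the first draw
  cats <- stats::setNames(paste0("b", seq_len(nrow(br))), br$branch)
  sim <- simulate_random_losses(tr, 1, cats, n_sims = 40000, seed = 3)
  first <- colSums(sim$counts)
  gof <- stats::chisq.test(first)
  expect_gt(gof$p.value, 0.001)
})

test_that("shared-missing simulation matches its analytic mean", {
  sm <- simulate_shared_missing(rep(100, 2), rep(1, 5), n_sims = 40000,
                                seed = 1)
  expect_equal(sm$mean, 2 * (1 / 2)^5, tolerance = 3 * sqrt(0.06 / 40000) +
                 0.005)
  # all genes missing in every species -> shared always G
  sm2 <- simulate_shared_missing(rep(10, 4), rep(4, 3), n_sims = 50,
                                 seed = 2)
  expect_true(all(sm2$shared == 4))
  # zero-length genes are never drawn under weighting
  sm3 <- simulate_shared_missing(c(5, 5, 0), c(2, 2), weighted = TRUE,
                                 n_sims = 200, seed = 3)
  expect_true(all(sm3$shared == 2))
  expect_error(simulate_shared_missing(1:3, 5, n_sims = 10), "cannot miss")
})

test_that("simulation objects expose tidy summaries and plots", {
  sim <- simulate_random_losses(two_tip(), 1, cats2,
                                observed_counts = c(carnivore = 1),
                                n_sims = 200, seed = 1)
  expect_s3_class(tidy(sim), "tbl_df")
  expect_equal(glance(sim)$n_sims, 200)
  expect_s3_class(autoplot(sim), "ggplot")
})
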
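test_that("best-hit region merging keeps the top-scoring hit per cluster", {
  expect_equal(nrow(merge_best_hit_regions(tibble::tibble())), 0L)
  h <- tibble::tibble(scaffold = "sc1", start = c(100L, 200L),
                      end = c(250L, 300L), score = c(80, 95),
                      query_id = c("a", "b"))
  m <- merge_best_hit_regions(h)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(200L, 300L))
  # disjoint hits pass through unchanged
  h2 <- tibble::tibble(scaffold = "sc1", start = c(0L, 500L),
                       end = c(100L, 600L), score = c(5, 7),
                       query_id = "q")
  expect_equal(merge_best_hit_regions(h2)$start, c(0L, 500L))
  # deterministic tie-break: equal score and start -> lexicographic query
  h3 <- tibble::tibble(scaffold = "sc1", start = c(10L, 10L),
                       end = c(50L, 60L), score = c(9, 9),
                       query_id = c("zeta", "alpha"))
  expect_equal(merge_best_hit_regions(h3)$query_id, "alpha")
})

test_that("merging is idempotent, disjoint, and agrees with brute force", {
  set.seed(202)
  for (r in 1:200) {
    h <- random_hits(sample(1:25, 1))
    m <- merge_best_hit_regions(h)
    # pairwise disjoint per scaffold
    for (sc in unique(m$scaffold)) {
      g <- m[m$scaffold == sc, ]
      if (nrow(g) > 1) {
        expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
    # idempotent
    expect_equal(merge_best_hit_regions(m)[, c("scaffold", "start", "end")],
                 m[, c("scaffold", "start", "end")])
    # brute-force agreement
    bf <- bf_merge_best_hits(h)
    expect_equal(as.data.frame(m[, c("scaffold", "start", "end")]),
                 as.data.frame(bf), ignore_attr = TRUE)
  }
})

test_that("interval extension clips at scaffold bounds and re-merges", {
  g <- as_genome(c(sc1 = strrep("A", 10000)))
  e1 <- extend_intervals(tibble::tibble(scaffold = "sc1", start = 1500L,
                                        end = 2300L), 1000, g)
  expect_equal(c(e1$start, e1$end), c(500L, 3300L))
  expect_false(e1$clipped_start || e1$clipped_end)
  e2 <- extend_intervals(tibble::tibble(scaffold = "sc1", start = 300L,
                                        end = 900L), 1000, g)
  expect_equal(c(e2$start, e2$end), c(0L, 1900L))
  expect_true(e2$clipped_start)
  expect_false(e2$clipped_end)
  # overlapping extensions union
  e3 <- extend_intervals(tibble::tibble(scaffold = "sc1",
                                        start = c(3000L, 4500L),
                                        end = c(3100L, 4600L)), 1000, g)
  expect_equal(nrow(e3), 1L)
  expect_equal(c(e3$start, e3$end), c(2000L, 5600L))
  expect_error(extend_intervals(tibble::tibble(scaffold = "nope", start = 1L,
                                               end = 2L), 10, g),
               "unknown scaffold")
})

test_that("extended intervals always stay inside scaffold bounds", {
  set.seed(9)
  g <- as_genome(c(s1 = strrep("A", 800), s2 = strrep("C", 1200)))
  lens <- scaffold_lengths(g)
  for (r in 1:100) {
    h <- random_hits(sample(1:10, 1), n_scaffold = 2, span = 700)
    ext <- extend_intervals(h[, c("scaffold", "start", "end")],
                            sample(0:500, 1), g)
    expect_true(all(ext$start >= 0))
    expect_true(all(ext$end <= lens[ext$scaffold]))
    # a clip flag is set exactly when truncation occurred at that bound
    expect_true(all(!ext$clipped_start | ext$start == 0))
    expect_true(all(!ext$clipped_end | ext$end == lens[ext$scaffold]))
    ext0 <- extend_intervals(h[, c("scaffold", "start", "end")], 0, g)
    expect_false(any(ext0$clipped_start | ext0$clipped_end))
  }
})
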
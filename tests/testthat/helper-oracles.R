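# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's own rule implementations.

# transitive-overlap clustering + single best hit per cluster
bf_merge_best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits[, c("scaffold", "start", "end")])
  out <- list()
  for (sc in unique(hits$scaffold)) {
    h <- hits[hits$scaffold == sc, , drop = FALSE]
    n <- nrow(h)
    cl <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (cl[i] != cl[j] && h$start[i] < h$end[j] && h$end[i] > h$start[j]) {
          cl[cl == cl[j]] <- cl[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(cl)) {
      g <- h[cl == cc, , drop = FALSE]
      g <- g[order(-g$score, g$start, g$query_id), , drop = FALSE]
      out[[length(out) + 1L]] <- g[1, c("scaffold", "start", "end")]
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), , drop = FALSE]
}

# the 50 bp / 100 bp exon-count rule, applied literally
bf_exon_count <- function(starts, ends, min_bp = 50, gap_bp = 100) {
  keep <- (ends - starts) >= min_bp
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  blocks <- list(c(starts[1], ends[1]))
  for (i in seq_along(starts)[-1]) {
    last <- blocks[[length(blocks)]]
    if (starts[i] - last[2] < gap_bp) {
      blocks[[length(blocks)]] <- c(last[1], max(last[2], ends[i]))
    } else {
      blocks[[length(blocks) + 1L]] <- c(starts[i], ends[i])
    }
  }
  length(blocks)
}

# iterative length-threshold model selection, re-derived step by step
bf_select_models <- function(models, exon_cap, mean_expected, min_report) {
  accepted <- integer()
  floor_nt <- max(min_report, 1)
  L <- mean_expected
  repeat {
    pool <- c()
    for (i in seq_len(nrow(models))) {
      if (models$exon_count[i] > exon_cap) next
      if (i %in% accepted) next
      ov_acc <- FALSE
      for (a in accepted) {
        if (models$scaffold[i] == models$scaffold[a] &&
            models$start[i] < models$end[a] &&
            models$end[i] > models$start[a]) ov_acc <- TRUE
      }
      if (!ov_acc && nchar(models$cds[i]) >= L) pool <- c(pool, i)
    }
    if (length(pool) > 0) {
      # winners: best score among each overlap cluster of the pool
      remaining <- pool
      while (length(remaining) > 0) {
        # build one transitive cluster from the first element
        cl <- remaining[1]
        repeat {
          grew <- FALSE
          for (i in remaining) {
            if (i %in% cl) next
            for (j in cl) {
              if (models$scaffold[i] == models$scaffold[j] &&
                  models$start[i] < models$end[j] &&
                  models$end[i] > models$start[j]) {
                cl <- c(cl, i); grew <- TRUE; break
              }
            }
          }
          if (!grew) break
        }
        g <- models[cl, , drop = FALSE]
        win <- cl[order(-g$score, g$start)][1]
        accepted <- c(accepted, win)
        remaining <- setdiff(remaining, cl)
      }
    }
    if (L <= floor_nt && length(pool) == 0) break
    L <- max(floor_nt, L %/% 2)
  }
  sort(accepted)
}

# independent losses / intact branches, walking parent pointers explicitly
bf_count_losses <- function(tree, loss_branches, categories) {
  br <- chemomine::phylo_branches(tree)
  parent_of <- stats::setNames(br$parent, br$node)
  node_of <- stats::setNames(br$node, br$branch)
  loss_nodes <- unname(node_of[loss_branches])
  has_loss_ancestor <- function(nd) {
    p <- parent_of[[as.character(nd)]]
    while (!is.null(p) && as.character(p) %in% names(parent_of)) {
      if (p %in% loss_nodes) return(TRUE)
      p <- parent_of[[as.character(p)]]
    }
    # the root itself owns no branch
    FALSE
  }
  cats <- sort(unique(unname(categories[br$branch])))
  indep <- intact <- stats::setNames(rep(0L, length(cats)), cats)
  for (i in seq_len(nrow(br))) {
    cc <- categories[[br$branch[i]]]
    is_loss <- br$node[i] %in% loss_nodes
    anc_loss <- has_loss_ancestor(br$node[i])
    if (is_loss && !anc_loss) indep[cc] <- indep[cc] + 1L
    if (!is_loss && !anc_loss) intact[cc] <- intact[cc] + 1L
  }
  list(independent = indep, intact = intact)
}

# exact distribution of per-category independent-loss counts under the
# sequential branch-drawing scheme (conditioning on completed replicates)
enumerate_loss_distribution <- function(tree, categories, n_draws,
                                        weighted = FALSE) {
  br <- chemomine::phylo_branches(tree)
  topo_desc <- lapply(seq_len(nrow(br)), function(i) {
    which(vapply(seq_len(nrow(br)), function(j) {
      # j descends from i when i is on j's ancestor path
      nd <- br$node[j]
      parent_of <- stats::setNames(br$parent, br$node)
      p <- parent_of[[as.character(nd)]]
      while (!is.null(p) && as.character(p) %in% names(parent_of)) {
        if (p == br$node[i]) return(TRUE)
        p <- parent_of[[as.character(p)]]
      }
      FALSE
    }, logical(1)))
  })
  w <- if (weighted) br$length else rep(1, nrow(br))
  cats <- sort(unique(unname(categories[br$branch])))
  dist <- list()
  add <- function(key, p) {
    dist[[key]] <<- (if (is.null(dist[[key]])) 0 else dist[[key]]) + p
  }
  recurse <- function(complete, drawn, p) {
    if (length(drawn) == n_draws) {
      counts <- stats::setNames(rep(0L, length(cats)), cats)
      for (b in drawn) {
        anc_drawn <- any(vapply(drawn, function(a) b %in% topo_desc[[a]],
                                logical(1)))
        if (!anc_drawn) {
          cc <- categories[[br$branch[b]]]
          counts[cc] <- counts[cc] + 1L
        }
      }
      add(paste(counts, collapse = ","), p)
      return(invisible())
    }
    cand <- which(complete)
    if (length(cand) == 0) { add("DISCARD", p); return(invisible()) }
    tot <- sum(w[cand])
    for (b in cand) {
      nc <- complete
      nc[b] <- FALSE
      nc[topo_desc[[b]]] <- FALSE
      recurse(nc, c(drawn, b), p * w[b] / tot)
    }
  }
  recurse(rep(TRUE, nrow(br)), integer(), 1)
  disc <- if (is.null(dist[["DISCARD"]])) 0 else dist[["DISCARD"]]
  dist[["DISCARD"]] <- NULL
  # renormalize over completed replicates, as the simulator redraws discards
  lapply(dist, function(p) p / (1 - disc))
}

# random hit table generator used by several property tests
random_hits <- function(n, n_scaffold = 2, span = 1000) {
  starts <- sample.int(span, n, replace = TRUE)
  widths <- sample(10:120, n, replace = TRUE)
  tibble::tibble(
    scaffold = paste0("s", sample.int(n_scaffold, n, replace = TRUE)),
    start = starts, end = starts + widths,
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = stats::runif(n, 10, 500),
    query_id = paste0("q", sample.int(5, n, replace = TRUE)))
}
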
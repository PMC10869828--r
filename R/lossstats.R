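#' Branch table of a rooted phylogeny
#'
#' Every non-root node owns the branch above it. Branches are labelled by the
#' subtended node: tip labels for terminal branches, node labels (assigned
#' `n<number>` when absent) for internal ones.
#'
#' @param tree An `ape` "phylo" object (rooted).
#' @return Tibble: `branch` (label), `node` (ape node id), `parent`,
#'   `length`, `is_tip`, `tips` (list of subtended tip labels).
#' @export
phylo_branches <- function(tree) {
  # the node Ntip+1 is taken as the root; basal polytomies (as produced by
  # majority-rule consensus trees) are accepted
  tree <- ensure_node_labels(tree)
  nt <- length(tree$tip.label)
  lab <- c(tree$tip.label, tree$node.label)
  edges <- tree$edge
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(edges))
         else tree$edge.length
  tips <- purrr::map(edges[, 2], function(nd) {
    if (nd <= nt) tree$tip.label[nd]
    else tree$tip.label[descendant_tips(tree, nd)]
  })
  tibble(branch = lab[edges[, 2]], node = edges[, 2], parent = edges[, 1],
         length = len, is_tip = edges[, 2] <= nt, tips = tips) |>
    arrange(.data$node)
}

ensure_node_labels <- function(tree) {
  if (is.null(tree$node.label) || any(is.na(tree$node.label)) ||
      any(tree$node.label == "")) {
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  }
  tree
}

descendant_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  out <- integer()
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    if (is.null(ch)) out <- c(out, nd)
    else stack <- c(stack, ch)
  }
  sort(out[out <= nt])
}

# descendant *branches* (node ids of subtended nodes) per branch, and
# ancestor branches per branch, as indices into the branch table
branch_topology <- function(branches) {
  idx <- setNames(seq_len(nrow(branches)), branches$node)
  parent_of <- setNames(branches$parent, branches$node)
  anc <- purrr::map(branches$node, function(nd) {
    out <- integer()
    p <- parent_of[[as.character(nd)]]
    while (!is.null(p) && as.character(p) %in% names(idx)) {
      out <- c(out, idx[[as.character(p)]])
      p <- parent_of[[as.character(p)]]
      p <- if (is.na(p)) NULL else p
    }
    out
  })
  desc <- vector("list", nrow(branches))
  for (i in seq_len(nrow(branches))) desc[[i]] <- integer()
  for (i in seq_len(nrow(branches))) {
    for (a in anc[[i]]) desc[[a]] <- c(desc[[a]], i)
  }
  list(anc = anc, desc = desc)
}

#' Infer gene-loss branches from shared loss-of-function mutations
#'
#' For each maximal clade whose non-functional tips (tips with a non-empty
#' LoF set) all share at least one identical LoF key, one loss is placed on
#' the branch above the clade's most recent common ancestor; non-functional
#' tips that share no LoF key with their relatives receive a terminal-branch
#' loss. The result contains no loss branch nested inside another.
#'
#' @param tree Rooted "phylo".
#' @param lof_sets Named list (by tip label) of character LoF keys
#'   (`"kind@codon"`); tips absent from the list or with empty sets are
#'   considered functional.
#' @return Tibble: `branch`, `node`, `n_tips`, `shared_keys` (list).
#' @export
infer_loss_branches <- function(tree, lof_sets) {
  tree <- ensure_node_labels(tree)
  extra <- setdiff(names(lof_sets), tree$tip.label)
  if (length(extra) > 0)
    abort(paste0("tip not in tree: ", extra[1]))
  nt <- length(tree$tip.label)
  lab <- c(tree$tip.label, tree$node.label)
  nonfunc <- vapply(tree$tip.label, function(t) {
    length(lof_sets[[t]]) > 0
  }, logical(1))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- nt + 1L
  out <- list()
  recurse <- function(nd) {
    if (nd <= nt) {
      if (nonfunc[[nd]]) {
        out[[length(out) + 1L]] <<- tibble(
          branch = lab[nd], node = nd, n_tips = 1L,
          shared_keys = list(sort(unique(lof_sets[[tree$tip.label[nd]]]))))
      }
      return(invisible())
    }
    tips <- descendant_tips(tree, nd)
    if (all(nonfunc[tips])) {
      shared <- Reduce(intersect, lof_sets[tree$tip.label[tips]])
      if (length(shared) > 0 && nd != root) {
        out[[length(out) + 1L]] <<- tibble(
          branch = lab[nd], node = nd, n_tips = length(tips),
          shared_keys = list(sort(shared)))
        return(invisible())
      }
    }
    for (ch in kids[[as.character(nd)]]) recurse(ch)
    invisible()
  }
  recurse(root)
  if (length(out) == 0)
    return(tibble(branch = character(), node = integer(), n_tips = integer(),
                  shared_keys = list()))
  bind_rows(out) |> arrange(.data$node)
}

#' Count independent losses and intact branches per category
#'
#' `independent_losses` counts loss branches per category;
#' `intact_branches` counts branches of a category excluding the loss
#' branches and all their descendant branches.
#'
#' @param tree Rooted "phylo".
#' @param loss_branches Character vector of branch labels (see
#'   [phylo_branches()]) carrying a loss.
#' @param categories Named character vector: branch label -> category; every
#'   branch must be categorised.
#' @return Tibble: `category`, `independent_losses`, `intact_branches`.
#' @export
count_losses_by_category <- function(tree, loss_branches, categories) {
  br <- phylo_branches(tree)
  miss <- setdiff(br$branch, names(categories))
  if (length(miss) > 0)
    abort(paste0("branch without category: ", miss[1]))
  bad <- setdiff(loss_branches, br$branch)
  if (length(bad) > 0) abort(paste0("unknown loss branch: ", bad[1]))
  topo <- branch_topology(br)
  cat_of <- unname(categories[br$branch])
  is_loss <- br$branch %in% loss_branches
  # independent = loss branches with no loss ancestor
  indep <- is_loss & !vapply(seq_len(nrow(br)), function(i) {
    any(is_loss[topo$anc[[i]]])
  }, logical(1))
  # excluded from "intact": loss branches and all their descendants
  excluded <- is_loss
  for (i in which(is_loss)) excluded[topo$desc[[i]]] <- TRUE
  cats <- sort(unique(cat_of))
  tibble(category = cats,
         independent_losses = vapply(cats, function(cc) {
           sum(indep & cat_of == cc)
         }, integer(1), USE.NAMES = FALSE),
         intact_branches = vapply(cats, function(cc) {
           sum(!excluded & cat_of == cc)
         }, integer(1), USE.NAMES = FALSE))
}

#' Chi-squared and Fisher tests on a loss/intact contingency table
#'
#' @param counts Either a 2 x k matrix (rows = lost, intact) or the tibble
#'   returned by [count_losses_by_category()].
#' @return One-row tibble: `chi2_stat`, `chi2_p`, `fisher_p`.
#' @export
contingency_tests <- function(counts) {
  if (is.data.frame(counts)) {
    m <- rbind(lost = counts$independent_losses,
               intact = counts$intact_branches)
    colnames(m) <- counts$category
  } else m <- as.matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(!is.finite(m))) abort("counts must be finite")
  chi <- suppressWarnings(chisq.test(m, correct = FALSE))
  fisher <- if (prod(dim(m)) <= 2 * 6 && sum(m) <= 2000) {
    fisher.test(m)
  } else {
    withr::with_seed(1L, fisher.test(m, simulate.p.value = TRUE, B = 1e5))
  }
  tibble(chi2_stat = unname(chi$statistic), chi2_p = unname(chi$p.value),
         fisher_p = unname(fisher$p.value))
}

#' Sequential branch-drawing loss simulation
#'
#' Per replicate every branch starts with a complete gene; `n_draws` branches
#' are drawn sequentially among the branches still complete (uniformly, or
#' with probability proportional to branch length), and each drawn branch and
#' all its descendants are set to the lost state. Replicates that run out of
#' complete branches before all draws are placed are discarded and redrawn
#' until `n_sims` completed replicates exist. The per-category independent
#' loss count of a replicate is the number of drawn branches of that category
#' with no drawn ancestor. The p-value for a category is the fraction of
#' replicates with a count at least as large as the observed one.
#'
#' @param tree Rooted "phylo" (branch lengths required when `weighted`).
#' @param n_draws Number of sequential draws (<= number of branches).
#' @param categories Named character vector: branch label -> category.
#' @param observed_counts Named numeric vector of observed independent losses
#'   per category (missing categories count as observed 0).
#' @param weighted Draw proportional to branch length?
#' @param n_sims Number of completed replicates.
#' @param seed Optional integer seed (recorded in the result).
#' @return Object of class `loss_simulation`: `counts` (replicate x category
#'   tibble), `p` (per-category tibble), `n_sims`, `n_discarded`, `seed`.
#' @export
simulate_random_losses <- function(tree, n_draws, categories,
                                   observed_counts = NULL, weighted = FALSE,
                                   n_sims = 10000, seed = NULL) {
  br <- phylo_branches(tree)
  if (n_draws > nrow(br))
    abort("cannot place losses: n_draws exceeds the number of branches")
  if (n_draws < 1 || n_sims < 1) abort("n_draws and n_sims must be >= 1")
  miss <- setdiff(br$branch, names(categories))
  if (length(miss) > 0) abort(paste0("branch without category: ", miss[1]))
  cat_of <- unname(categories[br$branch])
  cats <- sort(unique(cat_of))
  cat_idx <- match(cat_of, cats)
  topo <- branch_topology(br)
  w <- br$length
  if (weighted && (any(is.na(w)) || any(w < 0)))
    abort("weighted draws require non-negative branch lengths")
  if (!weighted) w <- rep(1, nrow(br))
  run <- function() {
    cpp_sim_losses(nrow(br), lapply(topo$desc, as.integer),
                   lapply(topo$anc, as.integer), cat_idx, w, weighted,
                   as.integer(n_draws), as.integer(n_sims), length(cats))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  counts <- as_tibble(as.data.frame(res$counts))
  names(counts) <- cats
  obs <- setNames(rep(0, length(cats)), cats)
  if (!is.null(observed_counts)) {
    keep <- intersect(names(observed_counts), cats)
    obs[keep] <- observed_counts[keep]
  }
  p <- tibble(category = cats,
              observed = unname(obs[cats]),
              p_value = vapply(cats, function(cc) {
                mean(counts[[cc]] >= obs[[cc]])
              }, numeric(1), USE.NAMES = FALSE))
  structure(list(counts = counts, p = p, n_sims = n_sims,
                 n_discarded = res$n_discarded, n_draws = n_draws,
                 weighted = weighted, seed = seed),
            class = "loss_simulation")
}

#' @export
print.loss_simulation <- function(x, ...) {
  cat("Branch-drawing loss simulation: ", x$n_sims, " replicates (",
      x$n_discarded, " discarded), ", x$n_draws, " draws, ",
      if (x$weighted) "weighted" else "unweighted", "\n", sep = "")
  print(x$p)
  invisible(x)
}

#' @export
tidy.loss_simulation <- function(x, ...) x$p

#' @export
glance.loss_simulation <- function(x, ...) {
  tibble(n_sims = x$n_sims, n_discarded = x$n_discarded, n_draws = x$n_draws,
         weighted = x$weighted,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Histogram of simulated independent-loss counts per category
#' @param object A `loss_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loss_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$counts, cols = dplyr::everything(),
                              names_to = "category", values_to = "count")
  obs <- object$p
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count,
                                     fill = .data$category)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed,
                                     colour = .data$category),
                        linetype = "dashed") +
    ggplot2::labs(x = "independent losses per replicate", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Shared-missing-gene simulation
#'
#' Each replicate draws, for every species, `missing_counts[i]` distinct
#' genes from the `G` genes of the reference set (uniformly, or sequentially
#' without replacement with probability proportional to gene length) and
#' records how many genes all species drew in common.
#'
#' @param gene_lengths Numeric vector of gene lengths (defines `G`).
#' @param missing_counts Integer vector, one entry per species.
#' @param weighted Weight draws by gene length?
#' @param n_sims Number of replicates.
#' @param seed Optional seed.
#' @param observed Optional observed shared-missing count for a p-value.
#' @return Object of class `shared_missing_sim`: `shared` (vector), `mean`,
#'   `p_value` (`NA` without `observed`), `seed`.
#' @export
simulate_shared_missing <- function(gene_lengths, missing_counts,
                                    weighted = FALSE, n_sims = 10000,
                                    seed = NULL, observed = NULL) {
  G <- length(gene_lengths)
  if (any(missing_counts > G))
    abort("a species cannot miss more genes than exist")
  if (any(missing_counts < 0)) abort("missing_counts must be >= 0")
  if (weighted && any(gene_lengths < 0))
    abort("gene lengths must be non-negative")
  run <- function() {
    vapply(seq_len(n_sims), function(r) {
      tally <- integer(G)
      for (ni in missing_counts) {
        if (ni == 0) return(0L)
        drawn <- if (weighted) {
          sample.int(G, ni, replace = FALSE, prob = gene_lengths)
        } else sample.int(G, ni, replace = FALSE)
        tally[drawn] <- tally[drawn] + 1L
      }
      sum(tally == length(missing_counts))
    }, integer(1))
  }
  shared <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(shared = shared, mean = mean(shared),
                 p_value = if (is.null(observed)) NA_real_
                           else mean(shared >= observed),
                 n_sims = n_sims, weighted = weighted, seed = seed,
                 G = G, missing_counts = missing_counts),
            class = "shared_missing_sim")
}

#' @export
print.shared_missing_sim <- function(x, ...) {
  cat("Shared-missing-gene simulation: G = ", x$G, ", ", x$n_sims,
      " replicates, mean shared = ", signif(x$mean, 4), sep = "")
  if (!is.na(x$p_value)) cat(", p = ", signif(x$p_value, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
glance.shared_missing_sim <- function(x, ...) {
  tibble(mean_shared = x$mean, p_value = x$p_value, n_sims = x$n_sims,
         weighted = x$weighted, G = x$G,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}
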
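#' Generate a synthetic gene-loss scenario on a random phylogeny
#'
#' Simulates a Yule (pure-birth) tree, assigns branch categories by a
#' root-to-tip Markov relabeling (each branch keeps its parent's category or
#' switches to another with probability `category_switch_prob`), draws loss
#' branches with the same sequential scheme as [simulate_random_losses()]
#' (redrawing the whole sequence until the drawn branches are mutually
#' independent, so exactly `n_losses` maximal lost clades exist), and gives
#' every tip below a loss branch that branch's shared LoF key plus 0-2
#' private LoF mutations with globally unique positions.
#'
#' @param n_tips Number of tips.
#' @param birth_rate Yule birth rate.
#' @param category_switch_prob Per-branch category switch probability.
#' @param n_losses Number of independent losses to plant (< number of
#'   branches).
#' @param categories Category labels to use.
#' @param seed Optional seed.
#' @return List: `tree` (with node labels), `loss_branches` (branch labels),
#'   `lof_sets` (named list per tip), `categories` (named by branch label),
#'   `counts` (generator's own per-category loss/intact bookkeeping),
#'   `seed`.
#' @export
generate_loss_scenario <- function(n_tips = 32, birth_rate = 1,
                                   category_switch_prob = 0.15, n_losses = 2,
                                   categories = c("carnivore", "herbivore",
                                                  "omnivore"),
                                   seed = NULL) {
  build <- function() {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    tree <- ensure_node_labels(tree)
    br <- phylo_branches(tree)
    if (n_losses >= nrow(br))
      abort("n_losses must be smaller than the number of branches")
    topo <- branch_topology(br)
    # root-to-tip Markov categories (branch inherits from parent branch)
    cat_of <- character(nrow(br))
    root <- length(tree$tip.label) + 1L
    root_cat <- sample(categories, 1)
    for (i in order(vapply(topo$anc, length, integer(1)))) {
      parent_cat <- if (br$parent[i] == root || length(topo$anc[[i]]) == 0) {
        root_cat
      } else cat_of[topo$anc[[i]][1]]
      cat_of[i] <- if (runif(1) < category_switch_prob) {
        sample(setdiff(categories, parent_cat), 1)
      } else parent_cat
    }
    # sequential draws, rejected until mutually independent
    repeat {
      complete <- rep(TRUE, nrow(br))
      drawn <- integer()
      ok <- TRUE
      for (d in seq_len(n_losses)) {
        cand <- which(complete)
        if (length(cand) == 0) { ok <- FALSE; break }
        pick <- cand[sample.int(length(cand), 1)]
        drawn <- c(drawn, pick)
        complete[pick] <- FALSE
        complete[topo$desc[[pick]]] <- FALSE
      }
      if (!ok) next
      indep <- vapply(drawn, function(b) !any(drawn %in% topo$anc[[b]]),
                      logical(1))
      if (all(indep)) break
    }
    drawn <- sort(drawn)
    # unique LoF positions: one shared key per loss branch + private keys
    kinds <- c("premature_stop", "frameshift_insertion",
               "frameshift_deletion")
    pos_pool <- sample(10:5000)
    next_pos <- 0L
    take_pos <- function() {
      next_pos <<- next_pos + 1L
      pos_pool[next_pos]
    }
    lof_sets <- setNames(vector("list", n_tips), tree$tip.label)
    for (t in tree$tip.label) lof_sets[[t]] <- character()
    for (b in drawn) {
      key <- paste0(sample(kinds, 1), "@", take_pos())
      for (t in br$tips[[b]]) {
        lof_sets[[t]] <- c(lof_sets[[t]], key)
      }
    }
    for (t in tree$tip.label) {
      if (length(lof_sets[[t]]) == 0) next
      k <- sample(0:2, 1)
      if (k > 0) {
        lof_sets[[t]] <- c(lof_sets[[t]], vapply(seq_len(k), function(z) {
          paste0(sample(kinds, 1), "@", take_pos())
        }, character(1)))
      }
    }
    categories_named <- setNames(cat_of, br$branch)
    counts <- count_losses_by_category(tree, br$branch[drawn],
                                       categories_named)
    list(tree = tree, loss_branches = br$branch[drawn], lof_sets = lof_sets,
         categories = categories_named, counts = counts)
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  out$seed <- seed
  out
}
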
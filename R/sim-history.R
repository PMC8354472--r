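## Ground-truth simulation of IES gain/loss histories along a (gene or
## species) tree.  Gains arise as a Poisson process with rate
## gain_rate_per_kb * n_kb per unit branch length, each creating a new
## locus (infinite-sites: a lost locus is not regained); every existing
## locus is lost at rate loss_rate_per_ies.  The full event list and the
## true state at every node are recorded so that downstream inference can
## be validated against the truth.

#' Simulate an IES gain/loss history on a tree
#'
#' @param tree node table (gene tree or species tree)
#' @param gain_rate_per_kb gains per kb of alignment per unit branch length
#' @param loss_rate_per_ies losses per existing IES per unit branch length
#' @param n_kb alignment length in kb over which gains accumulate
#' @param seed integer seed
#' @param n_ancestral loci already present at the root (the root IES
#'   density is a free parameter of the generator)
#' @param uncertain_frac fraction of (locus, tip) entries masked as
#'   uncertain ("?") in the emitted presence matrix
#' @return list with `tip_states` (loci x tips matrix, 0/1/2 for
#'   absent/present/uncertain), `true_states` (loci x nodes), `events`
#'   (branch, type, time, locus), `branch_counts` (per-branch gain/loss
#'   tallies) and the tree
#' @export
simulate_ies_history <- function(tree, gain_rate_per_kb, loss_rate_per_ies,
                                 n_kb, seed = 1L, n_ancestral = 0L,
                                 uncertain_frac = 0) {
  stopifnot(gain_rate_per_kb >= 0, loss_rate_per_ies >= 0, n_kb > 0)
  set.seed(as.integer(seed))
  nn <- nrow(tree)
  root <- tree_root(tree)
  kids <- tree_children(tree)
  ord <- rev(tree_postorder(tree)) # preorder
  g <- gain_rate_per_kb * n_kb
  l <- loss_rate_per_ies

  states <- matrix(0L, nrow = n_ancestral, ncol = nn)
  if (n_ancestral > 0) states[, match(root, tree$node)] <- 1L
  born <- rep(root, n_ancestral) # node above which each locus appeared
  ev <- list()

  for (v in ord) {
    if (v == root) next
    r <- tree[tree$node == v, ]
    t <- r$length
    pcol <- match(r$parent, tree$node)
    vcol <- match(v, tree$node)
    # losses of loci present at the parent
    pres <- which(states[, pcol] == 1L)
    if (length(pres)) {
      lost <- runif(length(pres)) < (1 - exp(-l * t))
      states[pres[!lost], vcol] <- 1L
      for (ix in pres[lost]) {
        ev[[length(ev) + 1L]] <- data.frame(branch = v, type = "loss",
                                            time = trunc_exp(l, t),
                                            locus = ix)
      }
    }
    # new gains on this branch
    n_new <- rpois(1, g * t)
    if (n_new > 0) {
      u <- runif(n_new, 0, t)
      for (k in seq_len(n_new)) {
        states <- rbind(states, rep(0L, nn))
        born <- c(born, v)
        ix <- nrow(states)
        ev[[length(ev) + 1L]] <- data.frame(branch = v, type = "gain",
                                            time = u[k], locus = ix)
        survives <- runif(1) >= (1 - exp(-l * (t - u[k])))
        if (survives) {
          states[ix, vcol] <- 1L
        } else {
          ev[[length(ev) + 1L]] <- data.frame(branch = v, type = "loss",
                                              time = u[k] + trunc_exp(l, t - u[k]),
                                              locus = ix)
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = integer(0), type = character(0),
               time = numeric(0), locus = integer(0))
  tips <- tree_tips(tree)
  tip_states <- states[, match(tips, tree$node), drop = FALSE]
  colnames(tip_states) <- tree$label[match(tips, tree$node)]
  if (uncertain_frac > 0 && length(tip_states)) {
    mask <- runif(length(tip_states)) < uncertain_frac
    tip_states[mask] <- 2L
  }
  branches <- tree$node[!is.na(tree$parent)]
  branch_counts <- data.frame(
    branch = branches,
    gains = vapply(branches, function(b)
      sum(events$branch == b & events$type == "gain"), numeric(1)),
    losses = vapply(branches, function(b)
      sum(events$branch == b & events$type == "loss"), numeric(1)))
  colnames(states) <- tree$node
  list(tip_states = tip_states, true_states = states, events = events,
       branch_counts = branch_counts, born = born, tree = tree)
}

## exponential waiting time truncated to (0, t)
trunc_exp <- function(rate, t) {
  if (rate <= 0) return(runif(1, 0, t))
  u <- runif(1)
  -log(1 - u * (1 - exp(-rate * t))) / rate
}

#' Restrict a simulated history to observable loci
#'
#' Loci absent from every tip cannot be observed; this keeps loci with at
#' least one present (or uncertain) tip, as any real IES catalog would.
#'
#' @param hist result of [simulate_ies_history()]
#' @return same structure with unobservable loci dropped
#' @export
observable_loci <- function(hist) {
  keep <- rowSums(hist$tip_states == 1L) > 0L
  hist$tip_states <- hist$tip_states[keep, , drop = FALSE]
  hist$true_states <- hist$true_states[keep, , drop = FALSE]
  hist$born <- hist$born[keep]
  hist$locus_map <- which(keep)
  hist
}
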
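## End-to-end inference validation study: simulate reconciled families and
## IES histories with known per-branch rates on the reference phylogeny,
## run the MCMC ancestral reconstruction per family, and compare the
## branch-rate estimators (and insertion dating) against the simulation
## truth.  This is the package's parameter-recovery harness; the defaults
## are the study conditions discussed in the methods vignette.

#' Simulate-and-recover study for branch gain/loss rates
#'
#' For each family a reconciled gene tree is simulated by birth-death
#' expansion of the species tree, an IES history with the given true
#' rates is laid down, and the gain/loss model is sampled by MCMC.  The
#' presence matrix of each family carries, besides the observable IES
#' loci, one collapsed all-absent site pattern weighted by the number of
#' well-aligned TA sites without an IES, so the fitted per-locus gain
#' rate reflects the rarity of insertion per site; the root occupancy is
#' sampled as a free parameter (`root_prior = "sampled"`) because the
#' simulated root is seeded above the stationary frequency.
#'
#' @param stree species tree (default [species_tree()])
#' @param n_families number of gene families (default 500)
#' @param gain_rate true gain rate, gains/kb/unit branch length
#' @param loss_rate true loss rate, losses/IES/unit branch length
#' @param n_kb well-aligned alignment length per family, kb
#' @param ancestral_per_kb IES loci present at the root, per kb
#' @param sites_per_kb TA-site panel density per kb (weights the
#'   all-absent pattern)
#' @param dup_rate,loss_rate_genes gene-level birth-death rates; the
#'   default study uses duplication-free families because with
#'   duplications the paths spanning a species branch share their
#'   pre-duplication segment, so the per-branch event expectation k x b
#'   over-counts shared history and branch-level truth becomes ambiguous
#'   (duplication-aware path enumeration is validated separately against
#'   worked examples and a DFS oracle)
#' @param n_iter,tuning_iter,tuning_interval,thin MCMC settings per family
#' @param seed integer seed
#' @return list: `families` (tree, ancestral posterior, truth per
#'   family), `rates` (branch rate table with `true_gain`, `true_loss`,
#'   `expected_gain_events`, `expected_loss_events` columns), `stree`
#' @export
recovery_study <- function(stree = species_tree(), n_families = 500L,
                           gain_rate = 1.0, loss_rate = 0.2, n_kb = 5,
                           ancestral_per_kb = 40L, sites_per_kb = 100L,
                           dup_rate = 0, loss_rate_genes = 0,
                           n_iter = 2000L, tuning_iter = 400L,
                           tuning_interval = 100L, thin = 10L, seed = 1L) {
  fams <- simulate_gene_families(stree, n_families, dup_rate = dup_rate,
                                 loss_rate_genes = loss_rate_genes,
                                 seed = sub_seed(seed, "fams"), n_codons = 50L)
  n_anc <- round(ancestral_per_kb * n_kb)
  families <- lapply(seq_along(fams), function(k) {
    gt <- fams[[k]]$tree
    hist <- observable_loci(simulate_ies_history(
      gt, gain_rate, loss_rate, n_kb, seed = sub_seed(seed, paste0("h", k)),
      n_ancestral = n_anc))
    ts <- hist$tip_states
    if (nrow(ts) == 0L) {
      return(list(tree = gt,
                  ancestral = matrix(numeric(0), 0, nrow(gt),
                                     dimnames = list(NULL, gt$node)),
                  n_kb = n_kb, truth = hist))
    }
    n_absent <- max(0, round(n_kb * sites_per_kb) - nrow(ts))
    ts2 <- rbind(ts, matrix(0L, 1L, ncol(ts),
                            dimnames = list(NULL, colnames(ts))))
    fit <- mcmc_sample(ts2, gt, n_iter = n_iter, tuning_iter = tuning_iter,
                       tuning_interval = tuning_interval, thin = thin,
                       seed = sub_seed(seed, paste0("m", k)),
                       weights = c(rep(1, nrow(ts)), n_absent),
                       root_prior = "sampled")
    list(tree = gt,
         ancestral = fit$ancestral[seq_len(nrow(ts)), , drop = FALSE],
         n_kb = n_kb, truth = hist)
  })
  rates <- branch_rate_table(families, stree)
  rates$true_gain <- gain_rate
  rates$true_loss <- loss_rate
  rates$expected_gain_events <- rates$sum_nk * rates$b * gain_rate
  rates$expected_loss_events <- rates$sum_Ik * rates$b * loss_rate
  list(families = families, rates = rates, stree = stree)
}

#' Insertion-dating accuracy on a recovery study
#'
#' For every gained locus the inferred age (MRCA of nodes with posterior
#' above the threshold, mapped to the species tree) is compared with the
#' species node of the gene-tree node directly below the true gain
#' event.  Loci are `eligible` when their posteriors are decisive — above
#' the threshold at every truly present node and below its complement at
#' every truly absent one — since dating is only meaningful for
#' well-reconstructed loci.
#'
#' @param study result of [recovery_study()]
#' @param threshold posterior presence threshold (default 0.99)
#' @return data.frame: family, locus, true_node, assigned_node,
#'   age_class, eligible, correct
#' @export
dating_study <- function(study, threshold = 0.99) {
  stree <- study$stree
  rows <- list()
  for (k in seq_along(study$families)) {
    fam <- study$families[[k]]
    hist <- fam$truth
    if (is.null(hist) || nrow(fam$ancestral) == 0L) next
    gt <- fam$tree
    kept <- hist$locus_map %||% seq_len(nrow(fam$ancestral))
    gained <- which(hist$born[] != tree_root(gt))
    for (i in gained) {
      post <- fam$ancestral[i, ]
      truth_states <- hist$true_states[i, as.character(gt$node)]
      eligible <- all(post[truth_states == 1L] > threshold) &&
        all(post[truth_states == 0L] < 1 - threshold)
      true_node <- map_to_species_node(gt, stree, hist$born[i])
      dt <- date_insertion(post, gt, stree, threshold = threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        family = k, locus = i, true_node = true_node,
        assigned_node = dt$species_node %||% NA_integer_,
        age_class = dt$age_class, eligible = eligible,
        correct = !is.na(dt$species_node) && dt$species_node == true_node)
    }
  }
  if (!length(rows)) {
    return(data.frame(family = integer(0), locus = integer(0),
                      true_node = integer(0), assigned_node = integer(0),
                      age_class = character(0), eligible = logical(0),
                      correct = logical(0)))
  }
  do.call(rbind, rows)
}
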
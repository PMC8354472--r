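## Mapping ancestral-posterior changes onto species-tree branches.  A
## species-tree branch i -> j corresponds, in a reconciled gene tree, to
## every path that connects a node labelled speciation(i) to a node
## labelled speciation(j) while crossing only duplication nodes;
## duplications multiply the number of such paths.  The per-branch rate
## estimators divide cumulated posterior increments by path count x
## alignment length (kb) x branch length.

#' Enumerate gene-tree paths spanning a species-tree branch
#'
#' @param gtree reconciled gene tree (node table with `event`/`snode`)
#' @param stree species tree
#' @param i,j parent and child species-tree node ids of the branch
#' @param validate check reconciliation-label consistency first
#' @return list of integer vectors (gene-tree node paths, both speciation
#'   endpoints included); `length()` of the result is k_gij
#' @export
enumerate_paths <- function(gtree, stree, i, j, validate = TRUE) {
  if (validate) validate_reconciliation(gtree, stree)
  kids <- tree_children(gtree)
  target_species <- stree$species[stree$node == j]
  is_end <- function(v) {
    r <- gtree[gtree$node == v, ]
    if (r$event == "speciation" && !is.na(r$snode) && r$snode == j) return(TRUE)
    if (r$event == "leaf" && length(target_species) == 1L &&
        !is.na(target_species) && r$species == target_species) return(TRUE)
    FALSE
  }
  starts <- gtree$node[gtree$event == "speciation" & !is.na(gtree$snode) &
                         gtree$snode == i]
  paths <- list()
  walk <- function(v, acc) {
    for (ch in kids[[as.character(v)]]) {
      r <- gtree[gtree$node == ch, ]
      if (is_end(ch)) {
        paths[[length(paths) + 1L]] <<- c(acc, ch)
      } else if (r$event == "duplication") {
        walk(ch, c(acc, ch))
      }
      # any other speciation node or foreign leaf ends the path without a
      # speciation(j) endpoint (gene loss): dropped
    }
  }
  for (s in starts) walk(s, s)
  paths
}

## sanity of speciation labels: a child speciation node must map to a
## descendant (or the same) species node of its parent's mapping
validate_reconciliation <- function(gtree, stree) {
  anc <- lapply(setNames(stree$node, stree$node),
                function(v) c(v, tree_ancestors(stree, v)))
  par <- setNames(gtree$parent, gtree$node)
  map <- setNames(gtree$snode, gtree$node)
  tipmap <- species_tip_map(stree)
  map[gtree$event == "leaf"] <- tipmap[gtree$species[gtree$event == "leaf"]]
  for (v in gtree$node) {
    if (is.na(map[[as.character(v)]])) next
    p <- par[[as.character(v)]]
    while (!is.na(p) && is.na(map[[as.character(p)]])) p <- par[[as.character(p)]]
    if (is.na(p)) next
    sv <- map[[as.character(v)]]
    sp <- map[[as.character(p)]]
    if (!(sp %in% anc[[as.character(sv)]])) {
      stop("inconsistent reconciliation: node ", v, " maps to species node ",
           sv, " which does not descend from its ancestor's species node ", sp)
    }
  }
  invisible(TRUE)
}

#' Posterior increment sums along a gene-tree path
#'
#' p+ accumulates the positive per-edge increases in the probability of
#' presence, p- the decreases, over consecutive nodes of the path (so a
#' path with several switches counts each of them).
#'
#' @param posterior named numeric vector, P(present) per gene-tree node id
#' @param path integer vector of node ids (from [enumerate_paths()])
#' @return c(p_plus, p_minus)
#' @export
accumulate_deltas <- function(posterior, path) {
  key <- as.character(path)
  if (any(!key %in% names(posterior))) {
    stop("posterior missing for node(s) ",
         paste(setdiff(key, names(posterior)), collapse = ", "))
  }
  p <- posterior[key]
  d <- diff(p)
  c(p_plus = sum(pmax(d, 0)), p_minus = sum(pmax(-d, 0)))
}

#' Per-branch gain and loss rate table
#'
#' For every species-tree branch i -> j accumulates, over gene families,
#' the posterior increment sums of every locus along every path, the
#' denominator terms n_g * k_gij (alignment kb x paths) and I_g * k_gij
#' (loci x paths), and computes
#' G_ij = sum(p+) / (sum(n_g k_gij) * b_ij)  (gains /kb /unit time) and
#' L_ij = sum(p-) / (sum(I_g k_gij) * b_ij)  (losses /IES /unit time).
#'
#' @param families list; each element needs `tree` (reconciled gene tree),
#'   `ancestral` (loci x nodes posterior matrix, columns named by node
#'   id) and `n_kb` (well-aligned alignment length in kb)
#' @param stree species tree
#' @return data.frame, one row per branch: i, j, branch label, sum_p_plus,
#'   sum_p_minus, sum_nk (kb x paths), sum_Ik (loci x paths), b, G, L
#' @export
branch_rate_table <- function(families, stree) {
  br <- species_branches(stree)
  for (fam in families) validate_reconciliation(fam$tree, stree)
  out <- lapply(seq_len(nrow(br)), function(bi) {
    i <- br$i[bi]; j <- br$j[bi]
    b <- stree$length[stree$node == j]
    sp <- sm <- nk <- ik <- 0
    for (fam in families) {
      paths <- enumerate_paths(fam$tree, stree, i, j, validate = FALSE)
      k <- length(paths)
      if (k == 0L) next
      nloci <- nrow(fam$ancestral)
      nk <- nk + fam$n_kb * k
      ik <- ik + nloci * k
      for (pth in paths) {
        P <- fam$ancestral[, as.character(pth), drop = FALSE]
        if (ncol(P) > 1L && nloci > 0L) {
          d <- P[, -1L, drop = FALSE] - P[, -ncol(P), drop = FALSE]
          sp <- sp + sum(pmax(d, 0))
          sm <- sm + sum(pmax(-d, 0))
        }
      }
    }
    data.frame(i = i, j = j,
               branch = stree$label[stree$node == j],
               sum_p_plus = sp, sum_p_minus = sm,
               sum_nk = nk, sum_Ik = ik, b = b,
               G = if (nk > 0 && b > 0) sp / (nk * b) else NA_real_,
               L = if (ik > 0 && b > 0) sm / (ik * b) else NA_real_)
  })
  do.call(rbind, out)
}

#' Gain rate on one species-tree branch
#' @inheritParams branch_rate_table
#' @param i,j branch endpoints
#' @export
gain_rate <- function(families, stree, i, j) {
  tab <- branch_rate_table(families, stree)
  tab$G[tab$i == i & tab$j == j]
}

#' Loss rate on one species-tree branch
#' @inheritParams gain_rate
#' @export
loss_rate <- function(families, stree, i, j) {
  tab <- branch_rate_table(families, stree)
  tab$L[tab$i == i & tab$j == j]
}

## species-tree node a gene-tree node maps to (leaves via species, others
## via snode; duplications via the LCA of their descendant species)
map_to_species_node <- function(gtree, stree, v) {
  r <- gtree[gtree$node == v, ]
  tipmap <- species_tip_map(stree)
  if (r$event == "leaf") return(unname(tipmap[r$species]))
  if (!is.na(r$snode)) return(r$snode)
  tips <- tree_clade_tips(gtree, v)
  sp <- unique(gtree$species[match(tips, gtree$node)])
  tree_mrca(stree, unname(tipmap[sp]))
}

#' Date an IES insertion from ancestral posteriors
#'
#' Collects every gene-tree node (tips included) where the IES is present
#' with posterior probability above `threshold`, takes their MRCA, maps it
#' to the species tree, and classifies the insertion age: "New" when the
#' supported nodes are confined to a single species, "Old" when the MRCA
#' predates the aurelia/caudatum split (the species-tree root), otherwise
#' the species-tree node label.
#'
#' @param posterior named P(present) per gene-tree node (one locus)
#' @param gtree reconciled gene tree
#' @param stree species tree
#' @param threshold posterior threshold (default 0.99)
#' @return list(age_class, species_node); age_class NA when no node
#'   passes the threshold (undatable)
#' @export
date_insertion <- function(posterior, gtree, stree, threshold = 0.99) {
  nodes <- as.integer(names(posterior)[posterior > threshold])
  if (!length(nodes)) {
    return(list(age_class = NA_character_, species_node = NA_integer_,
                reason = "no node above threshold"))
  }
  sp <- unique(gtree$species[match(unlist(lapply(nodes, function(v)
    tree_clade_tips(gtree, v))), gtree$node)])
  if (length(sp) == 1L) {
    tipmap <- species_tip_map(stree)
    return(list(age_class = "New", species_node = unname(tipmap[sp])))
  }
  mrca_g <- tree_mrca(gtree, nodes)
  snode <- map_to_species_node(gtree, stree, mrca_g)
  if (snode == tree_root(stree)) {
    return(list(age_class = "Old", species_node = snode))
  }
  list(age_class = stree$label[stree$node == snode], species_node = snode)
}
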
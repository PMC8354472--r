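# Shared fixtures and independent oracles used across test files.

## small unbalanced 4-tip tree for likelihood tests
tiny_tree <- function() {
  read_nhx("((a:0.3,b:0.5)x:0.2,(c:0.4,d:0.1)y:0.6)r;")
}

## random rooted binary tree as a node table (labels t1..tn)
random_tree <- function(n_tips, max_bl = 0.8) {
  stopifnot(n_tips >= 2)
  nodes <- list(list(id = 1L, tips = n_tips))
  rows <- list()
  nid <- 1L
  tipc <- 0L
  grow <- function(id, tips, parent) {
    len <- if (is.na(parent)) NA_real_ else runif(1, 0.05, max_bl)
    if (tips == 1L) {
      tipc <<- tipc + 1L
      rows[[id]] <<- data.frame(node = id, parent = parent, length = len,
                                label = paste0("t", tipc), event = "leaf",
                                species = paste0("t", tipc),
                                snode = NA_integer_)
      return(invisible())
    }
    rows[[id]] <<- data.frame(node = id, parent = parent, length = len,
                              label = NA_character_, event = "speciation",
                              species = NA_character_, snode = NA_integer_)
    left <- sample.int(tips - 1L, 1L)
    a <- nid + 1L; nid <<- nid + 1L
    grow(a, left, id)
    b <- nid + 1L; nid <<- nid + 1L
    grow(b, tips - left, id)
  }
  grow(1L, n_tips, NA_integer_)
  iesevo:::new_tree(do.call(rbind, rows[order(vapply(rows, function(r)
    r$node, numeric(1)))]))
}

## exhaustive-enumeration log-likelihood over internal state assignments
brute_loglik <- function(tree, states, g, l, rootp) {
  internals <- tree$node[tree$event != "leaf"]
  tips <- tree$node[tree$event == "leaf"]
  labs <- tree$label[match(tips, tree$node)]
  edges <- tree[!is.na(tree$parent), c("node", "parent", "length")]
  P <- lapply(seq_len(nrow(edges)), function(i)
    transition_matrix(g, l, edges$length[i]))
  combs <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  lik <- 0
  # tips may be uncertain (2): sum over their states too
  unc <- tips[states[labs] == 2L]
  tipcombs <- if (length(unc)) {
    as.matrix(expand.grid(rep(list(0:1), length(unc))))
  } else matrix(0L, 1, 0)
  for (r in seq_len(nrow(combs))) {
    for (tr in seq_len(nrow(tipcombs))) {
      full <- integer(nrow(tree))
      names(full) <- tree$node
      full[as.character(internals)] <- combs[r, ]
      full[as.character(tips)] <- states[labs]
      if (length(unc)) full[as.character(unc)] <- tipcombs[tr, ]
      pr <- rootp[full[[as.character(iesevo:::tree_root(tree))]] + 1]
      for (i in seq_len(nrow(edges))) {
        pr <- pr * P[[i]][full[[as.character(edges$parent[i])]] + 1,
                          full[[as.character(edges$node[i])]] + 1]
      }
      lik <- lik + pr
    }
  }
  log(lik)
}

## exhaustive marginal P(present) at one node
brute_marginal <- function(tree, states, g, l, rootp, node) {
  internals <- tree$node[tree$event != "leaf"]
  tips <- tree$node[tree$event == "leaf"]
  labs <- tree$label[match(tips, tree$node)]
  edges <- tree[!is.na(tree$parent), c("node", "parent", "length")]
  P <- lapply(seq_len(nrow(edges)), function(i)
    transition_matrix(g, l, edges$length[i]))
  combs <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  num <- den <- 0
  for (r in seq_len(nrow(combs))) {
    full <- integer(nrow(tree))
    names(full) <- tree$node
    full[as.character(internals)] <- combs[r, ]
    full[as.character(tips)] <- states[labs]
    pr <- rootp[full[[as.character(iesevo:::tree_root(tree))]] + 1]
    for (i in seq_len(nrow(edges))) {
      pr <- pr * P[[i]][full[[as.character(edges$parent[i])]] + 1,
                        full[[as.character(edges$node[i])]] + 1]
    }
    den <- den + pr
    if (full[[as.character(node)]] == 1L) num <- num + pr
  }
  num / den
}

## single-pass exhaustive enumeration: log-likelihood and every node's
## marginal presence probability
brute_all <- function(tree, states, g, l, rootp) {
  internals <- tree$node[tree$event != "leaf"]
  tips <- tree$node[tree$event == "leaf"]
  labs <- tree$label[match(tips, tree$node)]
  edges <- tree[!is.na(tree$parent), c("node", "parent", "length")]
  P <- lapply(seq_len(nrow(edges)), function(i)
    transition_matrix(g, l, edges$length[i]))
  combs <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  den <- 0
  mass <- setNames(numeric(nrow(tree)), tree$node)
  root_chr <- as.character(iesevo:::tree_root(tree))
  epar <- as.character(edges$parent)
  echi <- as.character(edges$node)
  full <- integer(nrow(tree))
  names(full) <- tree$node
  full[as.character(tips)] <- states[labs]
  for (r in seq_len(nrow(combs))) {
    full[as.character(internals)] <- combs[r, ]
    pr <- rootp[full[[root_chr]] + 1]
    for (i in seq_len(nrow(edges))) {
      pr <- pr * P[[i]][full[[epar[i]]] + 1, full[[echi[i]]] + 1]
    }
    den <- den + pr
    mass[full == 1L] <- mass[full == 1L] + pr
  }
  list(loglik = log(den), marginals = mass / den)
}

## brute-force excision-equivalence enumeration on a local MIC context
brute_floating <- function(ctx, p, len, window = 10L) {
  L <- stringi::stri_length(ctx)
  cut <- function(q) paste0(stringi::stri_sub(ctx, 1, q),
                            stringi::stri_sub(ctx, q + len + 1, L))
  base <- cut(p)
  keep <- integer(0)
  for (d in -window:window) {
    q <- p + d
    if (q < 0 || q + len + 2 > L) next
    if (stringi::stri_sub(ctx, q + 1, q + 2) != "TA") next
    if (stringi::stri_sub(ctx, q + len + 1, q + len + 2) != "TA") next
    if (cut(q) == base) keep <- c(keep, d)
  }
  keep
}

## naive R k-mer histogram (canonical) for cross-checking the compiled one
naive_kmer_hist <- function(reads, k) {
  all <- character(0)
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- revcomp(w)
      all <- c(all, if (w <= rc) w else rc)
    }
  }
  tab <- table(table(all))
  setNames(as.numeric(tab), names(tab))
}

## congruent reconciled gene tree built from a species tree
congruent_gene_tree <- function(stree) {
  gt <- stree
  gt$snode <- ifelse(gt$event == "speciation", stree$node, NA_integer_)
  gt
}

## small genome-pair config for fast tests
small_pair <- function(seed = 1, ...) {
  build_genome_pair(genome_config(scaffold_bp = 8000L, ies_per_kb = 1.5, ...),
                    seed = seed)
}
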
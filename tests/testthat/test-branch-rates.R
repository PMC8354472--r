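## Worked example: a family with one speciation at the ancestor of
## pse/pso, a duplication on the pso lineage (two paralogs), and one
## pse gene; the focal species branch n8 -> pso has k = 2 paths.
s8_setup <- function() {
  st <- species_tree()
  n8 <- st$node[st$label == "n8"]
  pso <- st$node[st$label == "pso" & st$event == "leaf"]
  gt <- read_nhx(paste0(
    "((pso__g1:0.05,pso__g2:0.05)[&&NHX:D=Y]:0.05,pse__g1:0.1)",
    sprintf("[&&NHX:D=N:S=%d];", n8)))
  list(st = st, gt = gt, n8 = n8, pso = pso)
}

test_that("duplication-aware path enumeration counts paths correctly", {
  s <- s8_setup()
  paths <- enumerate_paths(s$gt, s$st, s$n8, s$pso)
  expect_length(paths, 2L)
  # each path runs speciation(n8) -> duplication -> a pso leaf
  for (p in paths) {
    expect_equal(p[1], 1L)
    expect_equal(s$gt$event[s$gt$node == p[2]], "duplication")
    expect_equal(s$gt$species[s$gt$node == p[length(p)]], "pso")
  }
  # the pse branch has a single path
  pse <- s$st$node[s$st$label == "pse"]
  expect_length(enumerate_paths(s$gt, s$st, s$n8, pse), 1L)
  # a congruent gene tree has k = 1 on every branch
  st <- s$st
  gt0 <- congruent_gene_tree(st)
  br <- iesevo:::species_branches(st)
  for (i in seq_len(nrow(br))) {
    expect_length(enumerate_paths(gt0, st, br$i[i], br$j[i],
                                  validate = FALSE), 1L)
  }
})

test_that("path enumeration equals brute-force DFS on random reconciled trees", {
  st <- species_tree()
  set.seed(17)
  fams <- simulate_gene_families(st, 40, dup_rate = 0.6,
                                 loss_rate_genes = 0.3, seed = 18)
  ## oracle: DFS collecting all speciation(i)->speciation(j) node paths
  brute_paths <- function(gt, i, j) {
    kids <- iesevo:::tree_children(gt)
    tipmap <- iesevo:::species_tip_map(st)
    target <- st$species[st$node == j]
    ends <- function(v) {
      r <- gt[gt$node == v, ]
      (r$event == "speciation" && !is.na(r$snode) && r$snode == j) ||
        (r$event == "leaf" && !is.na(target) && r$species == target)
    }
    res <- 0L
    dfs <- function(v) {
      for (ch in kids[[as.character(v)]]) {
        if (ends(ch)) res <<- res + 1L
        else if (gt$event[gt$node == ch] == "duplication") dfs(ch)
      }
    }
    for (s0 in gt$node[gt$event == "speciation" & !is.na(gt$snode) &
                         gt$snode == i]) dfs(s0)
    res
  }
  br <- iesevo:::species_branches(st)
  for (fam in fams[1:25]) {
    for (bi in sample(nrow(br), 6)) {
      expect_length(
        enumerate_paths(fam$tree, st, br$i[bi], br$j[bi], validate = FALSE),
        brute_paths(fam$tree, br$i[bi], br$j[bi]))
    }
  }
})

test_that("inconsistent reconciliation labels are rejected", {
  st <- species_tree()
  n8 <- st$node[st$label == "n8"]
  # a child speciation mapped to a species node that is NOT a descendant
  bad <- read_nhx(paste0(
    sprintf("((ppr__g1:0.1,pbi__g1:0.1)[&&NHX:D=N:S=%d]:0.1,",
            st$node[st$label == "n6"]),
    sprintf("pse__g1:0.2)[&&NHX:D=N:S=%d];", n8)))
  expect_error(enumerate_paths(bad, st, n8, st$node[st$label == "pse"]),
               "inconsistent reconciliation")
})

test_that("posterior increments follow the per-edge sum rule", {
  post <- c("1" = 0, "2" = 0.5)
  expect_equal(accumulate_deltas(post, c(1, 2)),
               c(p_plus = 0.5, p_minus = 0))
  post <- c("1" = 1, "2" = 0.6)
  expect_equal(accumulate_deltas(post, c(1, 2)),
               c(p_plus = 0, p_minus = 0.4))
  post <- c("1" = 0.3, "2" = 0.3, "3" = 0.3)
  expect_equal(accumulate_deltas(post, 1:3), c(p_plus = 0, p_minus = 0))
  # multiple switches on a long path each count
  post <- c("1" = 0, "2" = 1, "3" = 0)
  expect_equal(accumulate_deltas(post, 1:3), c(p_plus = 1, p_minus = 1))
  expect_error(accumulate_deltas(post, 1:4), "missing")
})

test_that("the two-path worked configuration yields G = 5 and L = 2 exactly", {
  s <- s8_setup()
  gt <- s$gt
  # locus A gained towards pso with probability 0.5 at both paralog tips;
  # locus B ancestrally present, partially lost at both paralog tips
  anc <- rbind(
    A = c("1" = 0,   "2" = 0,   "3" = 0.5, "4" = 0.5, "5" = 0),
    B = c("1" = 1,   "2" = 1,   "3" = 0.6, "4" = 0.6, "5" = 1))
  colnames(anc) <- as.character(gt$node)
  fam <- list(tree = gt, ancestral = anc, n_kb = 1)
  # focal branch n8 -> pso: b must be 0.1 for the worked numbers
  st <- s$st
  st$length[st$node == s$pso] <- 0.1
  expect_equal(gain_rate(list(fam), st, s$n8, s$pso), 5.0)
  expect_equal(loss_rate(list(fam), st, s$n8, s$pso), 2.0)
})

test_that("0/1 posteriors count switches and rates vanish without change", {
  st <- species_tree()
  gt <- congruent_gene_tree(st)
  anc <- matrix(1, 2, nrow(gt), dimnames = list(NULL, gt$node))
  fam <- list(tree = gt, ancestral = anc, n_kb = 1)
  tab <- branch_rate_table(list(fam), st)
  expect_true(all(tab$G == 0))
  expect_true(all(tab$L == 0))
})

test_that("rates are invariant under duplicating every family", {
  s <- s8_setup()
  anc <- rbind(c("1" = 0, "2" = 0.2, "3" = 0.9, "4" = 0.7, "5" = 0.1))
  colnames(anc) <- as.character(s$gt$node)
  fam <- list(tree = s$gt, ancestral = anc, n_kb = 1)
  t1 <- branch_rate_table(list(fam), s$st)
  t2 <- branch_rate_table(list(fam, fam), s$st)
  expect_equal(t1$G, t2$G)
  expect_equal(t1$L, t2$L)
})

test_that("insertion dating maps MRCA of supported nodes onto the species tree", {
  st <- species_tree()
  gt <- congruent_gene_tree(st)
  # present only in the two pso/pse tips and their ancestor n8
  n8 <- st$node[st$label == "n8"]
  post <- setNames(rep(0, nrow(gt)), gt$node)
  clade <- c(n8, iesevo:::tree_clade_tips(st, n8))
  post[as.character(clade)] <- 0.999
  dt <- date_insertion(post, gt, st)
  expect_equal(dt$age_class, "n8")
  expect_equal(dt$species_node, n8)
  # confined to one species -> New
  post2 <- setNames(rep(0, nrow(gt)), gt$node)
  post2[as.character(st$node[st$label == "pso"])] <- 1
  expect_equal(date_insertion(post2, gt, st)$age_class, "New")
  # spanning both sides of the root -> Old
  post3 <- setNames(rep(0.9999, nrow(gt)), gt$node)
  expect_equal(date_insertion(post3, gt, st)$age_class, "Old")
  # nothing above threshold -> undatable
  expect_true(is.na(date_insertion(post2 * 0, gt, st)$age_class))
})
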
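test_that("event-free gene families mirror the species tree", {
  st <- species_tree()
  fams <- simulate_gene_families(st, 3, dup_rate = 0, loss_rate_genes = 0,
                                 seed = 2)
  for (fam in fams) {
    gt <- fam$tree
    expect_equal(sum(gt$event == "leaf"), 9L)
    expect_equal(sum(gt$event == "duplication"), 0L)
    # speciation nodes map onto the species-tree internals one-to-one
    expect_setequal(gt$snode[gt$event == "speciation"],
                    st$node[st$event == "speciation"])
    # branch lengths inherit the species-tree lengths
    tip <- gt$node[which(gt$label == "pca__g1")]
    expect_equal(gt$length[match(tip, gt$node)], 0.45)
  }
})

test_that("duplications create extra in-paralogs and labelled nodes", {
  st <- species_tree()
  fams <- simulate_gene_families(st, 12, dup_rate = 0.5,
                                 loss_rate_genes = 0.05, seed = 5)
  n_dup <- vapply(fams, function(f) sum(f$tree$event == "duplication"),
                  numeric(1))
  expect_gt(sum(n_dup), 0)
  for (fam in fams) {
    expect_gte(sum(fam$tree$event == "leaf"), 3L)
    expect_true(all(fam$tree$event %in% c("leaf", "speciation", "duplication")))
    expect_equal(nchar(fam$alignment[[1]]) %% 3, 0)
    expect_equal(length(fam$block_mask), nchar(fam$proteins[[1]]))
  }
})

test_that("generators are deterministic under a fixed seed", {
  st <- species_tree()
  f1 <- simulate_gene_families(st, 2, seed = 7)
  f2 <- simulate_gene_families(st, 2, seed = 7)
  expect_identical(f1, f2)
  p1 <- small_pair(4)
  p2 <- small_pair(4)
  expect_identical(p1$mic, p2$mic)
  expect_identical(p1$catalog, p2$catalog)
  r1 <- simulate_reads(p1, depth = 3, seed = 8)
  r2 <- simulate_reads(p2, depth = 3, seed = 8)
  expect_identical(r1$reads, r2$reads)
})

test_that("gain events are Poisson with mean rate x kb x branch length", {
  two <- read_nhx("(a:0.5,b:1.5)r;")
  g <- 2; n_kb <- 1
  n_rep <- 4000
  gains_a <- gains_b <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    h <- simulate_ies_history(two, g, 0, n_kb, seed = r)
    ga <- h$branch_counts$gains[h$branch_counts$branch ==
                                  two$node[two$label == "a"]]
    gb <- h$branch_counts$gains[h$branch_counts$branch ==
                                  two$node[two$label == "b"]]
    gains_a[r] <- ga; gains_b[r] <- gb
  }
  for (x in list(list(gains_a, 2 * 0.5), list(gains_b, 2 * 1.5))) {
    se <- sqrt(x[[2]] / n_rep)
    expect_lt(abs(mean(x[[1]]) - x[[2]]), 3 * se)
    # Poisson: variance equals the mean (loose factor-level check)
    expect_equal(stats::var(x[[1]]), x[[2]], tolerance = 0.15)
  }
})

test_that("rate limits of the history simulator behave", {
  st <- species_tree()
  h0 <- simulate_ies_history(st, 0, 0, 1, seed = 1)
  expect_equal(nrow(h0$tip_states), 0L)
  # overwhelming loss on every branch wipes all ancestral loci from tips
  h <- simulate_ies_history(st, 0, 1e6, 1, seed = 2, n_ancestral = 50)
  expect_true(all(h$tip_states == 0L))
})

test_that("event lists and per-branch counts agree", {
  st <- species_tree()
  h <- simulate_ies_history(st, 2, 0.5, 1, seed = 3, n_ancestral = 5)
  for (type in c("gain", "loss")) {
    col <- if (type == "gain") "gains" else "losses"
    tallied <- table(factor(h$events$branch[h$events$type == type],
                            levels = h$branch_counts$branch))
    expect_equal(as.numeric(tallied), h$branch_counts[[col]])
  }
  # states on a path are consistent with the events: a present tip locus
  # must have no loss after its gain on the path
  expect_true(all(h$true_states[, 1] %in% 0:1))
})

test_that("uncertain masking hits the requested fraction", {
  st <- species_tree()
  h <- simulate_ies_history(st, 5, 0.1, 2, seed = 4, n_ancestral = 40,
                            uncertain_frac = 0.3)
  frac <- mean(h$tip_states == 2L)
  expect_lt(abs(frac - 0.3), 0.06)
})

test_that("zero IES density gives identical MIC and MAC", {
  pair <- build_genome_pair(genome_config(scaffold_bp = 5000L,
                                          ies_per_kb = 0,
                                          floating_fraction = 0), seed = 6)
  expect_identical(pair$mic, pair$mac)
})

test_that("the mobile burst places exactly the requested tagged copies", {
  pair <- build_genome_pair(
    genome_config(scaffold_bp = 60000L, ies_per_kb = 1.2,
                  mobile = mobile_config(n_copies = 37L, n_nested = 5L)),
    seed = 12)
  expect_equal(sum(pair$catalog$role == "mobile"), 37L)
  expect_equal(sum(pair$catalog$role == "nested_host"), 5L)
  # all excised sequences are TA-bounded
  expect_true(all(startsWith(pair$catalog$excised_sequence, "TA")))
})

test_that("excessive density fails loudly", {
  expect_error(build_genome_pair(genome_config(scaffold_bp = 2000L,
                                               ies_per_kb = 500),
                                 seed = 1),
               "density too high")
})

test_that("pure MIC error-free reads are exact MIC substrings", {
  pair <- small_pair(9)
  run <- simulate_reads(pair, depth = 2, error_rate = 0,
                        mac_contamination_fraction = 0, read_len = 60L,
                        seed = 10)
  mic <- pair$mic
  for (i in sample(length(run$reads), 40)) {
    r <- run$reads[[i]]
    hit <- any(vapply(mic, function(s)
      stringi::stri_detect_fixed(s, r) ||
        stringi::stri_detect_fixed(s, revcomp(r)), logical(1)))
    expect_true(hit)
  }
})

test_that("read mass over IES interiors matches the contamination split", {
  pair <- build_genome_pair(genome_config(scaffold_bp = 50000L,
                                          ies_per_kb = 2,
                                          peak_weights = rep(1, 20)),
                            seed = 13)
  f <- 0.6
  run <- simulate_reads(pair, depth = 20, mac_contamination_fraction = f,
                        read_len = 80L, seed = 14)
  # fraction of reads whose start lies inside an IES interior (MIC reads
  # only can): expected (1 - f) x (IES fraction of MIC)
  mic_len <- sum(nchar(pair$mic))
  ies_frac <- sum(pair$catalog$length) / mic_len
  sub <- run$sources
  pos <- mic_positions(pair$catalog)
  inside <- logical(nrow(sub))
  for (sc in names(pair$mic)) {
    rows <- pair$catalog$scaffold == sc
    iv <- cbind(pos[rows], pos[rows] + pair$catalog$length[rows])
    sel <- sub$scaffold == sc & sub$origin == "MIC"
    if (!any(sel)) next
    starts <- sub$start[sel]
    inside[sel] <- vapply(starts, function(s)
      any(s >= iv[, 1] & s < iv[, 2]), logical(1))
  }
  p_obs <- sum(inside) / nrow(sub)
  p_exp <- (1 - f) * ies_frac
  se <- sqrt(p_exp * (1 - p_exp) / nrow(sub))
  expect_lt(abs(p_obs - p_exp), 4 * se + 0.01)
})
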
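test_that("families are connected components of the hit graph", {
  hits <- data.frame(a = c("A", "B"), b = c("B", "C"))
  fams <- cluster_families(hits, genes = c("A", "B", "C", "D"))
  expect_setequal(fams[[1]], c("A", "B", "C"))
  expect_equal(fams[[2]], "D")
})

test_that("clustering agrees with a union-find oracle on random graphs", {
  uf_components <- function(edges, verts) {
    parent <- setNames(verts, verts)
    find <- function(x) {
      while (parent[[x]] != x) x <- parent[[x]]
      x
    }
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$a[i]); rb <- find(edges$b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
    split(verts, vapply(verts, find, character(1)))
  }
  set.seed(3)
  for (rep in 1:10) {
    verts <- paste0("g", 1:25)
    edges <- data.frame(a = sample(verts, 20, TRUE),
                        b = sample(verts, 20, TRUE))
    edges <- edges[edges$a != edges$b, ]
    fams <- cluster_families(edges, genes = verts)
    oracle <- uf_components(edges, verts)
    key <- function(part) sort(unname(vapply(part, function(p)
      paste(sort(p), collapse = ","), character(1))))
    expect_identical(key(fams), key(oracle))
  }
})

test_that("size and identity filters remove weak families", {
  prot <- c(A = "MKLV", B = "MKLV", C = "MKIV", X = "MKLV", Y = "QQQQ")
  fams <- list(c("A", "B", "C"), c("X", "Y"), c("A", "B", "Y"))
  kept <- filter_families(fams, prot)
  expect_length(kept, 1L)
  expect_setequal(kept[[1]], c("A", "B", "C"))
  # three members but identity below 50% is dropped (A/B identical, Y alien)
  prot2 <- c(A = "MKLVMKLV", B = "MKLVMKLV", Y = "QQQQQQQQ")
  expect_length(filter_families(list(c("A", "B", "Y")), prot2), 0L)
})

test_that("back-translation expands residues to codons and gaps to ---", {
  prot <- c(s1 = "M-A", s2 = "MKA")
  cds <- c(s1 = "ATGGCA", s2 = "ATGAAAGCA")
  out <- backtranslate(prot, cds)
  expect_equal(out[["s1"]], "ATG---GCA")
  expect_equal(out[["s2"]], "ATGAAAGCA")
  # degapping the output recovers the CDS on random families
  set.seed(8)
  st <- species_tree()
  fam <- simulate_gene_families(st, 1, dup_rate = 0, loss_rate_genes = 0,
                                seed = 9, n_codons = 30)[[1]]
  cds0 <- setNames(gsub("-", "", fam$alignment), names(fam$alignment))
  bt <- backtranslate(fam$proteins, cds0)
  expect_identical(gsub("-", "", bt), cds0[names(bt)])
  # length mismatch excludes the gene with a message
  expect_message(out2 <- backtranslate(prot, c(s1 = "ATGGCA", s2 = "ATG")),
                 "mismatch")
  expect_named(out2, "s1")
})

test_that("conserved blocks require long runs of clean columns", {
  aln <- c(a = strrep("M", 30), b = strrep("M", 30), c = strrep("M", 30))
  expect_true(all(conserved_blocks(aln)))
  # a 50%-gap column breaks the run; short fragments are discarded
  mid <- paste0(strrep("M", 5), "-", strrep("M", 24))
  aln2 <- c(a = mid, b = mid, c = strrep("M", 30), d = strrep("M", 30))
  mask <- conserved_blocks(aln2, min_block = 10, max_gap_fraction = 0.2)
  expect_false(mask[6])
  expect_false(any(mask[1:5])) # 5-column fragment below min_block
  expect_true(all(mask[7:30]))
  # independent per-column recomputation
  set.seed(10)
  rand <- vapply(1:6, function(i)
    paste(sample(c(LETTERS[1:4], "-"), 40, TRUE), collapse = ""),
    character(1))
  names(rand) <- paste0("s", 1:6)
  mask2 <- conserved_blocks(rand, min_block = 3, max_gap_fraction = 0.2,
                            min_column_identity = 0.5)
  m <- do.call(rbind, strsplit(unname(rand), ""))
  colok <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (mean(col == "-") > 0.2) return(FALSE)
    res <- col[col != "-"]
    max(table(res)) / length(res) >= 0.5
  }, logical(1))
  r <- rle(colok); r$values[r$values & r$lengths < 3] <- FALSE
  expect_identical(mask2, inverse.rle(r))
})

test_that("IES positions project onto the T and A columns across gaps", {
  # ungapped: TA at CDS nt 10-11 -> columns 10, 11 (0-based)
  aln <- paste(rep("ACG", 10), collapse = "")
  out <- map_ies_to_alignment(110, 0L, cds_start = 100, aligned_cds = aln)
  expect_equal(out$col_start, 10L)
  expect_equal(out$col_end, 11L)
  # a gap between the T and the A widens the locus interval
  gapped <- paste0(substr(aln, 1, 11), "---", substr(aln, 12, 30))
  out2 <- map_ies_to_alignment(110, 0L, 100, gapped)
  expect_equal(out2$col_start, 10L)
  expect_equal(out2$col_end, 14L)
  # outside the CDS -> not mappable
  expect_null(map_ies_to_alignment(500, 0L, 100, aln))
  # floating alternatives produce one interval each
  out3 <- map_ies_to_alignment(110, c(-2L, 0L, 2L), 100, aln)
  expect_equal(nrow(out3), 3L)
})

test_that("co-ortholog groups share columns and obey the floating discard rule", {
  mask <- rep(TRUE, 20)
  loci <- data.frame(
    ies = c("i1", "i2", "i3"), gene = c("g1", "g2", "g3"),
    offset = 0L, col_start = c(9L, 9L, 50L), col_end = c(10L, 10L, 51L))
  loci$col_start[3] <- 15L; loci$col_end[3] <- 16L
  gr <- group_co_orthologs(loci, mask)
  key <- vapply(gr, function(g) paste(sort(g), collapse = ","), character(1))
  expect_setequal(key, c("i1,i2", "i3"))
  # floating alternative off the mask discards the whole group
  mask2 <- mask; mask2[2] <- FALSE # protein column 1 -> codon cols 3..5
  loci2 <- rbind(loci,
                 data.frame(ies = "i1", gene = "g1", offset = -6L,
                            col_start = 3L, col_end = 4L))
  gr2 <- group_co_orthologs(loci2, mask2)
  expect_false(any(vapply(gr2, function(g) "i1" %in% g, logical(1))))
  expect_false(any(vapply(gr2, function(g) "i2" %in% g, logical(1))))
  expect_length(attr(gr2, "discarded"), 1L)
})

test_that("grouping equals brute-force pairwise closure on simulated loci", {
  set.seed(12)
  n <- 120
  loci <- data.frame(ies = paste0("i", seq_len(n)), gene = "g",
                     offset = 0L,
                     col_start = sample(0:300, n, TRUE))
  loci$col_end <- loci$col_start + 1L
  mask <- rep(TRUE, 150)
  gr <- group_co_orthologs(loci, mask)
  # oracle: transitive closure of pairwise interval overlap
  adj <- outer(seq_len(n), seq_len(n), function(a, b)
    loci$col_start[a] <= loci$col_end[b] & loci$col_start[b] <= loci$col_end[a])
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
  oracle_groups <- unique(apply(reach, 1, function(r)
    paste(sort(loci$ies[r]), collapse = ",")))
  key <- vapply(gr, function(g) paste(sort(g), collapse = ","), character(1))
  expect_setequal(key, oracle_groups)
})

test_that("conserved cross-subclade groups require 5 species and 70% identity", {
  seqs <- c(a1 = "TACCATTTGGAATTACGGATTT", a2 = "TACCATTTGGAATTACGGATTT",
            b1 = "TACCATTTGGAATTACGGATTT", b2 = "TACCATTTGGAATTACGGATTT",
            b3 = "TACCATTTGGAATTACGGATTT")
  sp <- c(a1 = "pso", a2 = "pse", b1 = "pte", b2 = "poc", b3 = "ppr")
  out <- find_conserved_ies(list(names(seqs)), seqs, sp)
  expect_equal(nrow(out), 1L)
  expect_equal(out$best_cross_identity, 1.0)
  expect_equal(out$n_species, 5L)
  # four species only -> not reported
  out4 <- find_conserved_ies(list(names(seqs)[1:4]), seqs, sp)
  expect_equal(nrow(out4), 0L)
  # no member in one subclade -> ineligible
  spB <- sp; spB[] <- c("pte", "poc", "ppr", "pbi", "ppe")
  expect_equal(nrow(find_conserved_ies(list(names(seqs)), seqs, spB)), 0L)
})

test_that("global identity agrees with a hand alignment", {
  # identical sequences -> 1; one substitution in 20 -> 0.95
  x <- "TACCATTTGGAATTACGGAT"
  y <- sub("GGAAT", "GGTAT", x)
  expect_equal(iesevo:::global_identity(x, x), 1.0)
  expect_equal(iesevo:::global_identity(x, y), 0.95)
})
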
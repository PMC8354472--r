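test_that("identical sequences give a reciprocal full-length hit", {
  set.seed(2)
  s <- paste0("TA", random_dna(1, 198, at = 0.75))
  decoys <- setNames(random_dna(8, 200, at = 0.75), paste0("d", 1:8))
  seqs <- c(x = s, y = s, decoys)
  hits <- all_vs_all(seqs, max_evalue = 1e-8)
  xy <- hits[(hits$query == "x" & hits$subject == "y") |
               (hits$query == "y" & hits$subject == "x"), ]
  expect_equal(nrow(xy), 1L)
  expect_equal(xy$identity, 100)
  expect_equal(xy$length, 200L)
  expect_true(boundary_rule(xy$qstart, xy$qend, xy$sstart, xy$send, 200L, 200L))
})

test_that("reverse-complement homologs are found on the minus strand", {
  set.seed(3)
  s <- paste0("TA", random_dna(1, 198, at = 0.75))
  seqs <- c(x = s, y = revcomp(s),
            setNames(random_dna(6, 200, at = 0.75), paste0("d", 1:6)))
  hits <- all_vs_all(seqs, max_evalue = 1e-8)
  xy <- hits[(hits$query == "x" & hits$subject == "y") |
               (hits$query == "y" & hits$subject == "x"), ]
  expect_equal(nrow(xy), 1L)
  expect_equal(xy$strand, "-")
})

test_that("unrelated AT-rich sequences rarely reach the stringent threshold", {
  set.seed(4)
  seqs <- setNames(random_dna(60, 200, at = 0.8), paste0("r", 1:60))
  hits <- all_vs_all(seqs, max_evalue = 1e-8)
  # 1770 possible pairs; fewer than 1% may slip through
  expect_lt(nrow(hits), 18)
})

test_that("the boundary rule demands both extremities of both sequences", {
  expect_false(boundary_rule(0L, 50L, 0L, 50L, 60L, 60L))  # misses last 20
  expect_true(boundary_rule(0L, 60L, 0L, 60L, 60L, 60L))
  expect_false(boundary_rule(5L, 60L, 0L, 60L, 60L, 60L))  # misses first 20
  # short sequences degenerate to full-length coverage
  expect_true(boundary_rule(0L, 30L, 0L, 30L, 30L, 30L))
  expect_false(boundary_rule(2L, 30L, 0L, 30L, 30L, 30L))
  # brute-force interval check on random hits
  set.seed(5)
  for (i in 1:200) {
    len <- sample(40:300, 2, TRUE)
    qs <- sample(0:10, 1); qe <- sample.int(len[1], 1)
    ss <- sample(0:10, 1); se <- sample.int(len[2], 1)
    oracle <- qs <= 0 && qe >= 20 && qs <= len[1] - 20 && qe >= len[1] &&
      ss <= 0 && se >= 20 && ss <= len[2] - 20 && se >= len[2]
    expect_identical(boundary_rule(qs, qe, ss, se, len[1], len[2]), oracle)
  }
})

test_that("flank comparison separates homologous loci from mobile candidates", {
  set.seed(6)
  fl <- random_dna(1, 200, at = 0.72)
  expect_equal(as.character(locus_class(fl, fl)), "homologous_locus")
  other <- random_dna(1, 200, at = 0.72)
  expect_equal(as.character(locus_class(fl, other)), "candidate_mobile")
  # truncated flank flagged partial
  cls <- locus_class(substr(fl, 1, 120), fl)
  expect_true(attr(cls, "partial"))
})

test_that("single-linkage candidate clustering and the profile-size rule", {
  pairs <- data.frame(query = c("a", "b", "d", "e"),
                      subject = c("b", "c", "e", "f"))
  fams <- cluster_candidates(pairs, min_profile = 3L)
  key <- vapply(fams, function(f) paste(sort(f), collapse = ","), character(1))
  expect_setequal(key, c("a,b,c", "d,e,f"))
  expect_true(all(attr(fams, "profiled")))
  fams9 <- cluster_candidates(data.frame(query = paste0("m", 1:9),
                                         subject = "m1"), min_profile = 10L)
  expect_false(any(attr(fams9, "profiled")))
})

test_that("profiles from identical members reproduce the sequence", {
  set.seed(7)
  s <- paste0("TA", random_dna(1, 120, at = 0.75))
  members <- setNames(rep(s, 10), paste0("m", 1:10))
  prof <- build_profile(members)
  expect_equal(prof$consensus, s)
  expect_equal(prof$mean_identity, 1)
  expect_false(prof$composition_suspect)
  # every consensus column carries the top log-odds score
  top <- apply(prof$pwm, 2, which.max)
  expect_equal(paste(c("A", "C", "G", "T")[top], collapse = ""), s)
})

test_that("very AT-rich consensus is flagged composition-suspect", {
  set.seed(8)
  s <- paste0("TA", random_dna(1, 100, at = 0.98))
  prof <- build_profile(setNames(rep(s, 10), paste0("m", 1:10)))
  expect_true(prof$composition_suspect)
})

test_that("profile scanning classifies planted mobile and nested copies", {
  set.seed(9)
  cons <- paste0("TA", random_dna(1, 148, at = 0.75))
  mut <- function(x) iesevo:::mutate_copy(x, 0.12)
  mobile <- setNames(vapply(1:25, function(i) mut(cons), character(1)),
                     paste0("mob", 1:25))
  nested <- setNames(vapply(1:6, function(i)
    paste0("TA", random_dna(1, 20, 0.8), mut(cons), random_dna(1, 20, 0.8)),
    character(1)), paste0("nst", 1:6))
  bg <- setNames(random_dna(40, 150, at = 0.8), paste0("bg", 1:40))
  seqs <- c(mobile, nested, bg)
  prof <- build_profile(mobile, background = iesevo:::base_composition(seqs))
  scan <- scan_profiles(list(FAM = prof), seqs)
  got <- setNames(scan$class, scan$ies)
  expect_true(all(got[names(mobile)] == "mobile", na.rm = FALSE))
  expect_true(all(got[names(nested)] == "nested"))
  expect_false(any(startsWith(names(got), "bg")))
})

test_that("per-species summaries apply the 10-mobile-copy retention rule", {
  hits <- data.frame(
    ies = paste0("i", 1:30), family = "FAM_1",
    score = 50, evalue = 1e-9, start = 0L, end = 100L, strand = "+",
    class = c(rep("mobile", 24), rep("nested", 6)))
  sp <- setNames(rep(c("pso", "ptr"), 15), paste0("i", 1:30))
  out <- summarize_mobile_families(hits, sp)
  tot <- out[out$species == "TOTAL", ]
  expect_equal(tot$mobile, 24L)
  expect_equal(tot$nested, 6L)
  expect_equal(sum(out$mobile[out$species != "TOTAL"]), tot$mobile)
  # a family with at most 9 mobile copies everywhere is excluded
  hits9 <- hits[1:9, ]
  hits9$class <- "mobile"
  expect_equal(nrow(summarize_mobile_families(hits9, sp)), 0L)
})

test_that("shuffled decoy catalogs yield no mobile families", {
  set.seed(10)
  seqs <- setNames(random_dna(80, 160, at = 0.78), paste0("s", 1:80))
  shuf <- vapply(seqs, iesevo:::markov_shuffle, character(1))
  hits <- all_vs_all(shuf, max_evalue = 1e-8)
  if (nrow(hits)) {
    qlen <- nchar(shuf)[match(hits$query, names(shuf))]
    slen <- nchar(shuf)[match(hits$subject, names(shuf))]
    ok <- boundary_rule(hits$qstart, hits$qend, hits$sstart, hits$send,
                        qlen, slen)
    fams <- cluster_candidates(hits[ok, , drop = FALSE], min_profile = 10L)
    expect_false(any(attr(fams, "profiled")))
  } else succeed()
})
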
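## Discovery of interspersed (mobile) IES families.  Pairwise similarity
## uses k-mer-seeded local alignments with empirical expectation scores
## calibrated on composition-matched shuffled decoys; families are
## single-linkage clusters of boundary-complete candidate-mobile pairs;
## each large family yields a per-column log-odds profile that is scanned
## over the whole catalog to classify copies as bona fide mobile (profile
## reaches both IES extremities) or nested (internal match only).

BASES <- c("A", "C", "G", "T")

## first-order-Markov "dinucleotide shuffle": a random sequence with the
## dinucleotide transition frequencies and length of the input
markov_shuffle <- function(x) {
  s <- strsplit(x, "")[[1]]
  s <- s[s %in% BASES]
  n <- length(s)
  if (n < 10) return(paste(sample(s), collapse = ""))
  tr <- matrix(1e-9, 4, 4, dimnames = list(BASES, BASES))
  from <- s[-n]; to <- s[-1]
  for (a in BASES) for (b in BASES) tr[a, b] <- tr[a, b] + sum(from == a & to == b)
  tr <- tr / rowSums(tr)
  out <- character(n)
  out[1] <- sample(BASES, 1, prob = table(factor(s, BASES)) + 1e-9)
  for (i in 2:n) out[i] <- sample(BASES, 1, prob = tr[out[i - 1], ])
  paste(out, collapse = "")
}

## Gumbel tail fitted by moments; returns function s -> P(S >= s)
gumbel_tail <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 10 || sd(scores) == 0) {
    mx <- if (length(scores)) max(scores) else 0
    return(function(s) ifelse(s > mx, 1e-12, 1))
  }
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  function(s) {
    p <- 1 - exp(-exp(-(s - mu) / beta))
    pmin(pmax(p, 1e-300), 1)
  }
}

## k-mer seeded candidate pairs (both strands)
seed_pairs <- function(seqs, word_size = 12L) {
  ids <- names(seqs)
  kmers_of <- function(s) {
    L <- stri_length(s)
    if (L < word_size) return(character(0))
    unique(stri_sub(s, seq_len(L - word_size + 1L),
                    seq_len(L - word_size + 1L) + word_size - 1L))
  }
  fw <- lapply(seqs, kmers_of)
  rc <- lapply(revcomp(seqs), kmers_of)
  # index: kmer -> sequence indices (forward index; queries use fw + rc)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(fw)) {
    for (k in fw[[i]]) {
      assign(k, c(get0(k, envir = idx, ifnotfound = integer(0)), i), envir = idx)
    }
  }
  pairs <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    hits <- integer(0)
    for (k in unique(c(fw[[i]], rc[[i]]))) {
      hits <- c(hits, get0(k, envir = idx, ifnotfound = integer(0)))
    }
    for (j in unique(hits)) {
      if (j <= i) next
      assign(sprintf("%d_%d", i, j), TRUE, envir = pairs)
    }
  }
  keys <- ls(pairs)
  if (!length(keys)) {
    return(data.frame(qi = integer(0), si = integer(0)))
  }
  m <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  data.frame(qi = as.integer(m[, 1]), si = as.integer(m[, 2]))
}

#' All-vs-all IES sequence comparison
#'
#' Gapped local alignments (both strands) of every k-mer-seeded sequence
#' pair, scored blastn-like (match +2, mismatch -3, gap open 5, gap extend
#' 2).  Expectation values are calibrated empirically: the best local
#' scores of first-order-Markov shuffled decoy pairs (matched AT content)
#' are fitted with a Gumbel tail, and E(s) is the fitted tail probability
#' times the number of possible sequence pairs.
#'
#' @param seqs named character vector of IES sequences (>= 20 nt)
#' @param max_evalue expectation threshold (default 1e-8 as used for
#'   mobile-element discovery; use 1e-5 for permissive homolog counting)
#' @param word_size seed length (default 12)
#' @param n_decoys decoy pairs used for calibration (default 200)
#' @return data.frame: query, subject, qstart, qend, sstart, send
#'   (0-based half-open, query coordinates), identity (0-100), length,
#'   score, evalue, strand
#' @export
all_vs_all <- function(seqs, max_evalue = 1e-8, word_size = 12L,
                       n_decoys = 200L) {
  if (any(stri_length(seqs) < 20)) stop("sequences must be >= 20 nt")
  ids <- names(seqs)
  cand <- seed_pairs(seqs, word_size)
  if (!nrow(cand)) return(empty_hits())
  # decoy calibration
  pick <- sample(seq_along(seqs), min(2L * n_decoys, length(seqs) * 2L),
                 replace = TRUE)
  dec <- vapply(seqs[pick], markov_shuffle, character(1))
  d1 <- dec[seq_len(length(dec) %/% 2)]
  d2 <- dec[(length(dec) %/% 2 + 1):length(dec)]
  n_d <- min(length(d1), length(d2), n_decoys)
  dal <- align_local(d1[seq_len(n_d)], d2[seq_len(n_d)])
  tail_p <- gumbel_tail(dal$score)
  n_pairs <- length(seqs) * (length(seqs) - 1) / 2
  # forward and reverse alignment of candidates, keep the better strand
  q <- seqs[cand$qi]
  s_fw <- seqs[cand$si]
  s_rc <- revcomp(s_fw)
  al_f <- align_local(q, s_fw)
  al_r <- align_local(q, s_rc)
  use_r <- al_r$score > al_f$score
  al <- al_f
  al[use_r, ] <- al_r[use_r, ]
  strand <- ifelse(use_r, "-", "+")
  # reverse-strand subject coordinates back onto the forward subject
  slen <- stri_length(seqs)[cand$si]
  sstart <- ifelse(strand == "-", slen - al$send, al$sstart)
  send <- ifelse(strand == "-", slen - al$sstart, al$send)
  ev <- tail_p(al$score) * n_pairs
  keep <- ev <= max_evalue
  data.frame(query = ids[cand$qi[keep]], subject = ids[cand$si[keep]],
             qstart = al$qstart[keep], qend = al$qend[keep],
             sstart = sstart[keep], send = send[keep],
             identity = al$identity[keep], length = al$length[keep],
             score = al$score[keep], evalue = ev[keep],
             strand = strand[keep], stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), identity = numeric(0), length = integer(0),
             score = numeric(0), evalue = numeric(0), strand = character(0))
}

## vectorized local alignment; returns 0-based half-open coordinates
align_local <- function(x, y) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(x, y, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  pr <- methods::slot(methods::slot(al, "pattern"), "range")
  sr <- methods::slot(methods::slot(al, "subject"), "range")
  data.frame(score = Biostrings::score(al),
             identity = Biostrings::pid(al, type = "PID1"),
             length = Biostrings::nchar(al),
             qstart = IRanges::start(pr) - 1L, qend = IRanges::end(pr),
             sstart = IRanges::start(sr) - 1L, send = IRanges::end(sr))
}

#' Boundary-completeness rule for a similarity hit
#'
#' A hit counts as whole-element homology only when the alignment
#' encompasses the first and last `margin` nt of both sequences (so the
#' homology includes the IES boundaries and is not merely an internal
#' repeat).  For sequences shorter than `2 * margin` this degenerates to a
#' full-length coverage requirement.
#'
#' @param qstart,qend,sstart,send 0-based half-open aligned intervals
#' @param query_len,subject_len sequence lengths
#' @param margin boundary width (default 20)
#' @return logical
#' @export
boundary_rule <- function(qstart, qend, sstart, send, query_len, subject_len,
                          margin = 20L) {
  covers <- function(a, b, len) {
    m <- pmin(margin, len %/% 2L + len %% 2L)
    a <= 0L & b >= m & a <= pmax(len - m, 0L) & b >= len
  }
  covers(qstart, qend, query_len) & covers(sstart, send, subject_len)
}

#' Classify a homologous IES pair by its flanking regions
#'
#' Homologous IESs at the same genomic locus have homologous MAC-side
#' flanks; candidate mobile copies sit at unrelated loci.  The
#' concatenated 100-nt left + right flanks of the two IESs are aligned
#' locally; identity >= `min_identity` over >= `min_length` aligned nt
#' calls the pair `homologous_locus`, anything else `candidate_mobile`.
#'
#' @param flank_a,flank_b concatenated flank sequences
#' @param min_identity percent identity threshold (default 75)
#' @param min_length minimum alignment length (default 150)
#' @return "homologous_locus" or "candidate_mobile"; attribute `partial`
#'   is TRUE when a flank was truncated by a scaffold edge
#' @export
locus_class <- function(flank_a, flank_b, min_identity = 75,
                        min_length = 150L) {
  partial <- stri_length(flank_a) < 200L || stri_length(flank_b) < 200L
  al <- align_local(flank_a, flank_b)
  cls <- if (al$identity >= min_identity && al$length >= min_length) {
    "homologous_locus"
  } else "candidate_mobile"
  structure(cls, partial = partial)
}

#' Single-linkage clustering of candidate-mobile pairs
#'
#' @param pairs data.frame with `query`, `subject`
#' @param min_profile members needed before a profile is built (default 10)
#' @return list of families (character vectors), largest first; attribute
#'   `profiled` flags families with >= `min_profile` members
#' @export
cluster_candidates <- function(pairs, min_profile = 10L) {
  fams <- cluster_families(data.frame(a = pairs$query, b = pairs$subject))
  structure(fams, profiled = lengths(fams) >= min_profile)
}

#' Build a repeat-family profile from member sequences
#'
#' Members are aligned to the most representative member (star alignment
#' on the best-connected center); the per-column log-odds profile is
#' computed against the supplied background composition, and edge columns
#' with more than 50% gaps are trimmed.  Families whose members are too
#' divergent to align (mean identity to the center < 0.4) yield NULL with
#' a message (such families need re-clustering at higher stringency).
#' Consensus A+T above `at_suspect` flags the family as
#' composition-suspect (similarity possibly compositional, not
#' homologous), mirroring the manual exclusion of very AT-rich clusters.
#'
#' @param members named member sequences (>= 2)
#' @param background length-4 base composition of all IESs (A,C,G,T)
#' @param at_suspect consensus-AT flag threshold (default 0.92)
#' @param max_center_candidates members tried as center (default 12)
#' @return list(pwm, consensus, members, mean_identity,
#'   composition_suspect) or NULL
#' @export
build_profile <- function(members, background = c(0.4, 0.1, 0.1, 0.4),
                          at_suspect = 0.92, max_center_candidates = 12L) {
  if (length(members) < 2L) stop("need >= 2 members")
  background <- background / sum(background)
  cand <- sample(seq_along(members), min(max_center_candidates,
                                         length(members)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  med_id <- vapply(cand, function(ci) {
    others <- members[-ci]
    others <- others[sample(seq_along(others), min(8L, length(others)))]
    al <- Biostrings::pairwiseAlignment(others, members[[ci]],
                                        type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    mean(Biostrings::pid(al, type = "PID1"))
  }, numeric(1))
  center <- members[[cand[which.max(med_id)]]]
  W <- stri_length(center)
  al <- Biostrings::pairwiseAlignment(members, center, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  # project every member onto center coordinates (insertions dropped)
  proj <- matrix("-", nrow = length(members), ncol = W)
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))
  for (i in seq_along(members)) {
    pc <- strsplit(pat[i], "")[[1]]
    sc <- strsplit(sub[i], "")[[1]]
    keep <- sc != "-"
    proj[i, ] <- pc[keep]
  }
  mean_identity <- mean(vapply(seq_len(nrow(proj)), function(i)
    mean(proj[i, ] == strsplit(center, "")[[1]]), numeric(1)))
  if (mean_identity < 0.4) {
    message("family too divergent to align (mean identity ",
            round(mean_identity, 2), "); re-cluster at higher stringency")
    return(NULL)
  }
  counts <- t(apply(proj, 2, function(col) {
    tabulate(factor(col, BASES), nbins = 4L)
  }))
  # trim edge columns dominated by gaps
  gapfrac <- 1 - rowSums(counts) / length(members)
  ok <- gapfrac <= 0.5
  first <- which(ok)[1]
  last <- tail(which(ok), 1)
  counts <- counts[first:last, , drop = FALSE]
  freq <- (counts + 0.5) / (rowSums(counts) + 2)
  lo <- log2(freq) - matrix(log2(background), nrow(counts), 4L, byrow = TRUE)
  pwm <- t(lo) # 4 x W, rows A,C,G,T
  rownames(pwm) <- BASES
  consensus <- paste(BASES[max.col(counts)], collapse = "")
  at <- at_content(consensus)
  list(pwm = pwm, consensus = consensus, members = names(members),
       mean_identity = mean_identity,
       composition_suspect = at > at_suspect,
       trim = c(first, last))
}

#' Scan profiles over a whole IES catalog
#'
#' Each profile is slid over every sequence on both strands; per-sequence
#' best scores are converted to expectation values with a Gumbel tail
#' fitted on Markov-shuffled decoys.  A significant hit is `mobile` when
#' the matched window reaches both IES extremities within
#' `extremity_tol` bp, `nested` otherwise.
#'
#' @param profiles named list of [build_profile()] results
#' @param ies_seqs named IES sequences
#' @param max_evalue threshold (default 1e-3)
#' @param extremity_tol extremity tolerance in bp (default 3)
#' @param n_decoys decoys per profile (default 150)
#' @return data.frame: ies, family, score, evalue, start, end, strand,
#'   class
#' @export
scan_profiles <- function(profiles, ies_seqs, max_evalue = 1e-3,
                          extremity_tol = 3L, n_decoys = 150L) {
  out <- list()
  lens <- stri_length(ies_seqs)
  for (fam in names(profiles)) {
    prof <- profiles[[fam]]
    if (is.null(prof)) next
    pwm <- prof$pwm
    W <- ncol(pwm)
    scannable <- which(lens >= W)
    if (!length(scannable)) next
    # decoys of representative length
    dlen <- max(W + 20L, as.integer(median(lens[scannable])))
    base <- sample(ies_seqs[scannable], min(n_decoys, length(scannable)),
                   replace = length(scannable) < n_decoys)
    dec <- vapply(base, function(s) markov_shuffle(
      if (stri_length(s) >= dlen) s else strrep(s, ceiling(dlen / stri_length(s)))),
      character(1))
    dec <- stri_sub(dec, 1, dlen)
    dscore <- pmax(pwm_scan_cpp(pwm, dec)$score,
                   pwm_scan_cpp(pwm, revcomp(dec))$score)
    tail_p <- gumbel_tail(dscore)
    fw <- pwm_scan_cpp(pwm, ies_seqs[scannable])
    rv <- pwm_scan_cpp(pwm, revcomp(ies_seqs[scannable]))
    use_r <- rv$score > fw$score
    score <- ifelse(use_r, rv$score, fw$score)
    # reverse-strand offsets back to forward coordinates
    off <- ifelse(use_r, lens[scannable] - W - rv$offset, fw$offset)
    ev <- tail_p(score) * length(scannable)
    hit <- which(is.finite(score) & ev <= max_evalue)
    if (!length(hit)) next
    L <- lens[scannable][hit]
    st <- off[hit]
    en <- st + W
    cls <- ifelse(st <= extremity_tol & en >= L - extremity_tol,
                  "mobile", "nested")
    out[[fam]] <- data.frame(
      ies = names(ies_seqs)[scannable][hit], family = fam,
      score = score[hit], evalue = ev[hit], start = st, end = en,
      strand = ifelse(use_r[hit], "-", "+"), class = cls,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(ies = character(0), family = character(0),
                      score = numeric(0), evalue = numeric(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), class = character(0)))
  }
  rn <- do.call(rbind, out)
  # one call per IES: overlapping profiles (split clusters of the same
  # underlying family) must not double-count a copy
  rn <- rn[order(rn$ies, -rn$score), ]
  rn <- rn[!duplicated(rn$ies), ]
  rownames(rn) <- NULL
  rn
}

#' Per-species mobile-IES family summary
#'
#' Counts mobile and nested copies per family and species and retains
#' families with at least `min_copies` bona fide mobile copies in at
#' least one species (the reporting rule of the taxonomic summary table).
#'
#' @param hits classified hits from [scan_profiles()]
#' @param ies_species named species code per IES id
#' @param min_copies retention threshold (default 10)
#' @return data.frame: family, species, mobile, nested, plus a `TOTAL`
#'   row per family
#' @export
summarize_mobile_families <- function(hits, ies_species, min_copies = 10L) {
  if (!nrow(hits)) {
    return(data.frame(family = character(0), species = character(0),
                      mobile = integer(0), nested = integer(0)))
  }
  hits$species <- ies_species[hits$ies]
  rows <- list()
  for (fam in unique(hits$family)) {
    h <- hits[hits$family == fam, ]
    tab <- table(h$species, factor(h$class, c("mobile", "nested")))
    if (max(tab[, "mobile"]) < min_copies) next
    for (sp in rownames(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, species = sp,
        mobile = unname(tab[sp, "mobile"]), nested = unname(tab[sp, "nested"]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, species = "TOTAL",
      mobile = sum(tab[, "mobile"]), nested = sum(tab[, "nested"]))
  }
  if (!length(rows)) {
    return(data.frame(family = character(0), species = character(0),
                      mobile = integer(0), nested = integer(0)))
  }
  do.call(rbind, rows)
}

#' Full mobile-IES discovery pipeline on a genome pair
#'
#' all-vs-all comparison, boundary rule, flank-based locus classification,
#' single-linkage clustering, profile building and catalog-wide profile
#' scanning, in that order.
#'
#' @param pair genome pair from [build_genome_pair()]
#' @param max_evalue all-vs-all threshold (default 1e-8)
#' @param scan_evalue profile-scan threshold (default 1e-3)
#' @param flank_nt MAC flank length per side (default 100)
#' @param min_profile minimum members for a profile (default 10)
#' @return list: hits, pairs (boundary-complete candidate-mobile pairs),
#'   families, profiles, scan (classified copies), summary
#' @export
discover_mobile_families <- function(pair, max_evalue = 1e-8,
                                     scan_evalue = 1e-3, flank_nt = 100L,
                                     min_profile = 10L) {
  cat <- pair$catalog
  seqs <- setNames(cat$excised_sequence, cat$id)
  hits <- all_vs_all(seqs, max_evalue = max_evalue)
  if (nrow(hits)) {
    qlen <- stri_length(seqs)[match(hits$query, cat$id)]
    slen <- stri_length(seqs)[match(hits$subject, cat$id)]
    hits$boundary_ok <- boundary_rule(hits$qstart, hits$qend, hits$sstart,
                                      hits$send, qlen, slen)
  } else hits$boundary_ok <- logical(0)
  flanks <- ies_flanks(pair, flank_nt)
  cand <- hits[hits$boundary_ok, , drop = FALSE]
  if (nrow(cand)) {
    cand$locus <- vapply(seq_len(nrow(cand)), function(i) {
      as.character(locus_class(flanks[[cand$query[i]]],
                               flanks[[cand$subject[i]]]))
    }, character(1))
    cand <- cand[cand$locus == "candidate_mobile", , drop = FALSE]
  }
  fams <- cluster_candidates(cand, min_profile)
  prof_idx <- which(attr(fams, "profiled"))
  bg <- base_composition(seqs)
  profiles <- list()
  for (k in prof_idx) {
    profiles[[sprintf("FAM_%d", k)]] <- build_profile(seqs[fams[[k]]],
                                                      background = bg)
  }
  scan <- scan_profiles(profiles, seqs, max_evalue = scan_evalue)
  summary <- summarize_mobile_families(scan, setNames(cat$species, cat$id))
  list(hits = hits, pairs = cand, families = fams, profiles = profiles,
       scan = scan, summary = summary)
}

## empirical A,C,G,T composition of a sequence set
base_composition <- function(seqs) {
  s <- paste(seqs, collapse = "")
  n <- vapply(BASES, function(b) stri_count_fixed(s, b), numeric(1))
  n / sum(n)
}

## concatenated MAC-side flanks (left 100 + right 100, junction TA skipped)
ies_flanks <- function(pair, flank_nt = 100L) {
  cat <- pair$catalog
  out <- setNames(vector("list", nrow(cat)), cat$id)
  for (i in seq_len(nrow(cat))) {
    mac <- pair$mac[[cat$scaffold[i]]]
    j <- cat$mac_position[i]
    left <- stri_sub(mac, max(1L, j - flank_nt + 1L), j)
    right <- stri_sub(mac, j + 3L, min(stri_length(mac), j + 2L + flank_nt))
    out[[i]] <- paste0(left, right)
  }
  out
}
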
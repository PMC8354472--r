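## Read simulation from a MIC/MAC genome pair.  A fraction
## `mac_contamination_fraction` of the read mass is drawn from the MAC
## (somatic contamination), the rest from the MIC.  Per-IES true retention
## support is tallied from the known read sources: MIC reads anchoring an
## IES boundary support retention, MAC reads anchoring the excised junction
## support excision; their ratio is the true IRS of the simulated sample.

#' Simulate a (possibly MAC-contaminated) MIC sequencing run
#'
#' @param pair genome pair from [build_genome_pair()]
#' @param depth total read mass divided by MIC genome length
#' @param error_rate per-base substitution error probability
#' @param mac_contamination_fraction fraction f of read mass of MAC origin
#'   (0 <= f < 1)
#' @param read_len read length (default 100)
#' @param seed integer seed
#' @param anchor minimum bp a read must extend past a junction on both
#'   sides to count as support (default 5)
#' @return list with `reads` (named character vector), `sources`
#'   (data.frame: origin, scaffold, start), and `irs_table`
#'   (id, retained, excised, irs)
#' @export
simulate_reads <- function(pair, depth, error_rate = 0,
                           mac_contamination_fraction = 0,
                           read_len = 100L, seed = 1L, anchor = 5L) {
  f <- mac_contamination_fraction
  stopifnot(f >= 0, f < 1, depth > 0)
  set.seed(as.integer(seed))
  mic <- pair$mic
  mac <- pair$mac
  if (sum(stri_length(mic)) == 0) stop("empty genome")
  n_reads <- round(depth * sum(stri_length(mic)) / read_len)
  n_mac <- rbinom(1, n_reads, f)
  n_mic <- n_reads - n_mac

  draw <- function(genome, n, origin) {
    if (n == 0L) {
      return(data.frame(origin = character(0), scaffold = character(0),
                        start = integer(0), seq = character(0),
                        stringsAsFactors = FALSE))
    }
    lens <- stri_length(genome)
    ok <- lens >= read_len
    if (!any(ok)) stop("no scaffold is as long as one read")
    w <- pmax(lens - read_len + 1L, 0L)
    idx <- sample.int(length(genome), n, replace = TRUE, prob = w)
    sc <- names(genome)[idx]
    start <- floor(runif(n) * w[idx]) # 0-based
    seqs <- stri_sub(genome[sc], start + 1L, start + read_len)
    data.frame(origin = origin, scaffold = sc, start = start,
               seq = seqs, stringsAsFactors = FALSE)
  }
  reads <- rbind(draw(mic, n_mic, "MIC"), draw(mac, n_mac, "MAC"))
  # random strand
  flip <- runif(nrow(reads)) < 0.5
  reads$seq[flip] <- revcomp(reads$seq[flip])
  # substitution errors
  if (error_rate > 0) {
    n_err <- rbinom(nrow(reads), read_len, error_rate)
    for (i in which(n_err > 0)) {
      p <- sample.int(read_len, n_err[i])
      s <- reads$seq[i]
      for (q in p) {
        stri_sub(s, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                            stri_sub(s, q, q)), 1L)
      }
      reads$seq[i] <- s
    }
  }

  irs_table <- true_irs(pair, reads, read_len, anchor)
  out <- setNames(reads$seq, sprintf("%s_%07d", tolower(reads$origin),
                                     seq_len(nrow(reads))))
  list(reads = out,
       sources = reads[c("origin", "scaffold", "start")],
       irs_table = irs_table)
}

## per-IES true junction support from read sources
true_irs <- function(pair, reads, read_len, anchor) {
  cat <- pair$catalog
  retained <- integer(nrow(cat))
  excised <- integer(nrow(cat))
  for (sc in unique(cat$scaffold)) {
    rows <- which(cat$scaffold == sc)
    sub <- cat[rows, , drop = FALSE]
    micpos <- mic_positions(sub)
    mic_starts <- sort(reads$start[reads$origin == "MIC" &
                                     reads$scaffold == sc])
    mac_starts <- sort(reads$start[reads$origin == "MAC" &
                                     reads$scaffold == sc])
    count_cover <- function(starts, j) {
      # reads covering [j - anchor, j + anchor): start in
      # (j + anchor - read_len, j - anchor]
      lo <- j + anchor - read_len
      hi <- j - anchor
      pmax(0L, findInterval(hi, starts) - findInterval(lo, starts))
    }
    for (k in seq_along(rows)) {
      left <- micpos[k]                  # MIC boundary: prefix | excised
      right <- micpos[k] + sub$length[k] # MIC junction: excised | TA
      retained[rows[k]] <- count_cover(mic_starts, left) +
        count_cover(mic_starts, right)
      excised[rows[k]] <- 2L * count_cover(mac_starts, sub$mac_position[k] + 1L)
    }
  }
  data.frame(id = cat$id, retained = retained, excised = excised,
             irs = compute_irs(retained, excised))
}
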
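## Assembly-free genome-size estimation from k-mer multiplicity histograms,
## with a correction for contaminating somatic (MAC) DNA in germline (MIC)
## read sets.  The histogram convention follows the two-column
## `multiplicity<TAB>count` dialect of jellyfish histo.

#' Construct a k-mer histogram object
#'
#' @param counts numeric vector of distinct-k-mer counts, named by
#'   multiplicity (coverage depth of the k-mer)
#' @param k k-mer size (odd, >= 11)
#' @param instances optional total number of k-mer instances emitted
#' @param skipped number of windows skipped for non-ACGT symbols
#' @return object of class `kmer_histogram`
#' @export
kmer_histogram <- function(counts, k = 17L, instances = NULL, skipped = 0) {
  m <- as.integer(names(counts))
  if (any(is.na(m)) || any(m < 1L)) stop("multiplicities must be integers >= 1")
  if (any(counts < 0)) stop("counts must be >= 0")
  o <- order(m)
  structure(list(multiplicity = m[o], count = as.numeric(counts)[o],
                 k = as.integer(k),
                 instances = instances %||% sum(m * counts),
                 skipped = skipped),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> k=%d, %d multiplicity classes, %.4g instances\n",
              x$k, length(x$multiplicity), x$instances))
  invisible(x)
}

## dense count vector over multiplicities 1..max
dense_counts <- function(hist) {
  v <- numeric(max(hist$multiplicity))
  v[hist$multiplicity] <- hist$count
  v
}

#' Count canonical k-mers in a read set
#'
#' Every k-length window of every read is collapsed with its reverse
#' complement onto the lexicographically smaller of the two (canonical
#' counting).  Windows containing non-ACGT symbols are skipped and reported
#' in the `skipped` field.
#'
#' @param reads character vector of reads, or a FASTQ path
#' @param k k-mer size (default 17)
#' @return a [kmer_histogram()]
#' @export
count_kmers <- function(reads, k = 17L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  if (any(stri_length(reads) < k)) {
    reads <- reads[stri_length(reads) >= k]
  }
  if (length(reads) == 0L) stop("no read is as long as k")
  res <- count_kmers_cpp(reads, as.integer(k))
  if (res$skipped > 0) {
    message(sprintf("count_kmers: skipped %.0f windows with non-ACGT symbols",
                    res$skipped))
  }
  kmer_histogram(setNames(res$count, res$multiplicity), k = k,
                 instances = res$instances, skipped = res$skipped)
}

#' Locate the sequencing-depth peak of a k-mer histogram
#'
#' The error cloud near the origin is delimited by the first local minimum
#' after multiplicity 1; the sequencing depth is the multiplicity with the
#' largest count beyond that cutoff.
#'
#' @param hist a [kmer_histogram()]
#' @return list with `depth` and `error_cutoff`
#' @export
find_depth_peak <- function(hist) {
  v <- dense_counts(hist)
  M <- length(v)
  if (M < 1L || all(v == 0)) stop("empty histogram")
  cutoff <- 0L
  if (M >= 2L && v[1] > v[2]) {
    m <- 1L
    while (m < M && v[m] > v[m + 1L]) m <- m + 1L
    if (m == M) stop("no genomic peak: histogram decreases monotonically")
    cutoff <- m
  }
  region <- seq.int(cutoff + 1L, M)
  if (all(v[region] == 0)) stop("no genomic peak beyond the error cutoff")
  depth <- region[which.max(v[region])]
  list(depth = depth, error_cutoff = cutoff)
}

## local maxima of the (lightly smoothed) histogram beyond the cutoff
find_peaks <- function(hist, cutoff, min_rel = 0.01) {
  v <- dense_counts(hist)
  M <- length(v)
  if (M < 3L) return(integer(0))
  s <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  s[is.na(s)] <- v[is.na(s)]
  cand <- integer(0)
  for (m in seq.int(max(2L, cutoff + 1L), M - 1L)) {
    win <- s[max(1L, m - 3L):min(M, m + 3L)]
    if (s[m] > 0 && s[m] >= max(win)) cand <- c(cand, m)
  }
  big <- max(v[seq.int(cutoff + 1L, M)])
  cand <- cand[v[cand] >= min_rel * big]
  # collapse plateaus
  if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) > 3L)]
  cand
}

#' Raw genome-size estimate from a k-mer histogram
#'
#' Total k-mer mass beyond the error cutoff divided by the sequencing depth.
#'
#' @param hist a [kmer_histogram()]
#' @return object of class `size_estimate` with fields `depth`,
#'   `error_cutoff`, `raw_size_bp`, `corrected_size_bp` (equal to raw here)
#'   and `mac_fraction` (0)
#' @export
estimate_genome_size <- function(hist) {
  pk <- find_depth_peak(hist)
  keep <- hist$multiplicity > pk$error_cutoff
  mass <- sum(hist$multiplicity[keep] * hist$count[keep])
  structure(list(depth = pk$depth, error_cutoff = pk$error_cutoff,
                 raw_size_bp = mass / pk$depth,
                 corrected_size_bp = mass / pk$depth,
                 mac_fraction = 0),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf(paste0("<size_estimate> depth=%d, error cutoff=%d, raw=%.0f bp, ",
                     "corrected=%.0f bp (MAC fraction %.2f)\n"),
              x$depth, x$error_cutoff, x$raw_size_bp, x$corrected_size_bp,
              x$mac_fraction))
  invisible(x)
}

#' IES retention score
#'
#' IRS = retained / (retained + excised) read support per IES; both zero is
#' undefined and returned as NA.
#'
#' @param retained,excised non-negative read counts
#' @return numeric vector in \[0, 1\] with NA where undefined
#' @export
compute_irs <- function(retained, excised) {
  if (any(retained < 0) || any(excised < 0)) stop("counts must be >= 0")
  tot <- retained + excised
  ifelse(tot == 0, NA_real_, retained / tot)
}

#' Estimate the MAC-DNA fraction of a MIC sample from its IRS distribution
#'
#' In a pure MIC sample IESs are retained in every read (IRS near 1); MAC
#' contamination contributes excised reads and shifts the IRS peak towards
#' 0.  The mode of the IRS distribution (histogram mode, bin width 0.05)
#' estimates the MIC fraction; the MAC fraction is its complement.
#'
#' @param irs_values numeric vector of IRS values in \[0,1\] (NA dropped);
#'   at least 100 values required
#' @param bin histogram bin width
#' @return MAC fraction in \[0,1); attributes `mode` and `mean_irs` carry
#'   the IRS mode and mean (the mean is a reported diagnostic only)
#' @export
estimate_mac_fraction <- function(irs_values, bin = 0.05) {
  irs_values <- irs_values[!is.na(irs_values)]
  if (length(irs_values) < 100L) stop("need at least 100 IRS values")
  if (any(irs_values < 0 | irs_values > 1)) stop("IRS values must be in [0,1]")
  centers <- seq(0, 1, by = bin)
  cls <- pmin(length(centers), pmax(1L, round(irs_values / bin) + 1L))
  cnt <- tabulate(cls, nbins = length(centers))
  best <- which.max(cnt)
  # bimodal ambiguity: a non-adjacent near-equal mode
  rival <- which(cnt >= 0.8 * cnt[best] & abs(seq_along(cnt) - best) > 1L)
  if (length(rival)) {
    warning("bimodal IRS distribution; taking the larger-IRS mode")
    best <- max(c(best, rival))
  }
  mode <- centers[best]
  structure(1 - mode, mode = mode, mean_irs = mean(irs_values))
}

#' Correct a contaminated MIC k-mer histogram for MAC DNA
#'
#' In a MIC read set contaminated by MAC DNA, MAC-destined k-mers receive
#' coverage from both sources and pile up in a second peak above the true
#' MIC depth.  For multiplicities m in (mic_depth, mac_attribution_max_depth]
#' the excess mass (m - mic_depth)/m is attributed to contaminating MAC
#' reads and removed, i.e. those k-mers are counted at the MIC depth;
#' k-mers deeper than `mac_attribution_max_depth` are genuinely repeated
#' germline sequence and are kept whole.  With `mac_fraction = 0` the raw
#' estimate is returned unchanged.
#'
#' @param hist a [kmer_histogram()]
#' @param mac_fraction MAC-DNA fraction of the sample in \[0,1), typically
#'   from [estimate_mac_fraction()]
#' @param mic_depth depth of the MIC (first) peak; autodetected as the first
#'   local maximum beyond the error cutoff when NULL
#' @param mac_attribution_max_depth multiplicity above which k-mers are
#'   treated as purely of MIC origin (default 500)
#' @return `size_estimate` with both raw and corrected sizes
#' @export
correct_for_mac_contamination <- function(hist, mac_fraction,
                                          mic_depth = NULL,
                                          mac_attribution_max_depth = 500L) {
  if (mac_fraction < 0 || mac_fraction >= 1) stop("mac_fraction must be in [0,1)")
  pk <- find_depth_peak(hist)
  if (is.null(mic_depth)) {
    peaks <- find_peaks(hist, pk$error_cutoff)
    if (length(peaks) == 0L) {
      if (mac_fraction == 0) return(estimate_genome_size(hist))
      stop("cannot resolve the MIC depth: no peak beyond the error cutoff")
    }
    mic_depth <- peaks[1L]
  }
  d <- mic_depth
  m <- hist$multiplicity
  cnt <- hist$count
  keep <- m > pk$error_cutoff
  # with no claimed contamination nothing is attributed away, but the raw
  # and corrected sizes are still both normalized by the MIC depth so the
  # estimate is continuous (and non-increasing) in mac_fraction
  eff <- if (mac_fraction == 0) m else
    ifelse(m <= d | m > mac_attribution_max_depth, m, d)
  mass <- sum(m[keep] * cnt[keep])
  # in a contaminated sample both the raw and the corrected estimate are
  # normalized by the MIC depth (the first peak), so the uncorrected value
  # overestimates the germline size and the corrected one is never larger
  corrected <- sum(eff[keep] * cnt[keep]) / d
  implied <- 1 - corrected * d / mass
  structure(list(depth = d, error_cutoff = pk$error_cutoff,
                 raw_size_bp = mass / d,
                 corrected_size_bp = corrected,
                 mac_fraction = mac_fraction,
                 mic_depth = d,
                 implied_mac_mass_fraction = implied),
            class = "size_estimate")
}
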
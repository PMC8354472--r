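## The IES data model.  An IES catalog is a data.frame with one row per IES:
##   id, species, scaffold,
##   mac_position      0-based index of the retained TA in the MAC scaffold
##   excised_sequence  the removed fragment; always starts with "TA"
##   length            nchar(excised_sequence)
##   floating_offsets  list column of signed bp offsets (0 always included)
##   compartment       exon | intron | intergenic (NA until assigned)
##   irs, weak, uncertain
## The excision convention: MIC = prefix + excised + "TA" + suffix and
## MAC = prefix + "TA" + suffix, i.e. one TA of the boundary pair is left at
## the junction.  All coordinates are 0-based half-open internally.

#' MIC-coordinate start of each excised fragment
#'
#' IESs on the same scaffold shift each other: the n-th fragment starts at
#' its MAC position plus the total length of the preceding fragments.
#'
#' @param catalog an IES catalog (rows of one or more scaffolds)
#' @return integer vector aligned with `catalog` rows
#' @export
mic_positions <- function(catalog) {
  out <- integer(nrow(catalog))
  for (sc in unique(catalog$scaffold)) {
    i <- which(catalog$scaffold == sc)
    i <- i[order(catalog$mac_position[i])]
    out[i] <- catalog$mac_position[i] +
      c(0L, cumsum(catalog$length[i][-length(i)]))
  }
  out
}

#' Excise all catalogued IESs from a MIC scaffold
#'
#' @param mic_scaffold MIC sequence (single string)
#' @param catalog catalog rows for this scaffold
#' @return the MAC sequence
#' @export
excise <- function(mic_scaffold, catalog) {
  if (nrow(catalog) == 0L) return(mic_scaffold)
  o <- order(catalog$mac_position)
  catalog <- catalog[o, ]
  pos <- mic_positions(catalog)
  stored <- stri_sub(mic_scaffold, pos + 1L, pos + catalog$length)
  if (!all(stored == catalog$excised_sequence)) {
    stop("integrity failure: MIC does not contain the recorded excised sequence")
  }
  junction <- stri_sub(mic_scaffold, pos + catalog$length + 1L,
                       pos + catalog$length + 2L)
  if (!all(junction == "TA")) {
    stop("integrity failure: no TA retained at the excision junction")
  }
  keep_start <- c(1L, pos + catalog$length + 1L)
  keep_end <- c(pos, stri_length(mic_scaffold))
  paste(stri_sub(mic_scaffold, keep_start, keep_end), collapse = "")
}

#' Reinsert all catalogued IESs into a MAC scaffold
#'
#' Inverse of [excise()]: `insert(excise(mic)) == mic`, bit-exact.
#'
#' @param mac_scaffold MAC sequence
#' @param catalog catalog rows for this scaffold
#' @return the MIC sequence
#' @export
insert <- function(mac_scaffold, catalog) {
  if (nrow(catalog) == 0L) return(mac_scaffold)
  o <- order(catalog$mac_position)
  catalog <- catalog[o, ]
  p <- catalog$mac_position
  if (!all(startsWith(catalog$excised_sequence, "TA"))) {
    stop("integrity failure: excised sequence must start with TA")
  }
  at <- stri_sub(mac_scaffold, p + 1L, p + 2L)
  if (!all(at == "TA")) {
    stop("integrity failure: MAC lacks TA at the recorded junction")
  }
  pieces <- character(2L * nrow(catalog) + 1L)
  pieces[seq(1L, length(pieces), 2L)] <-
    stri_sub(mac_scaffold, c(1L, p + 1L), c(p, stri_length(mac_scaffold)))
  pieces[seq(2L, length(pieces), 2L)] <- catalog$excised_sequence
  paste(pieces, collapse = "")
}

#' Detect floating (ambiguously located) IESs
#'
#' An IES is floating when its boundaries overlap a tandemly repeated motif,
#' so that excising an equally long TA-bounded fragment at a shifted
#' position yields the identical MAC sequence.  Offsets d in
#' \[-window, +window\] are reported iff the shifted fragment starts with
#' TA, is followed by TA, and excision at d gives the same MAC as at 0.
#'
#' @param mic_context MIC sequence context; must cover the annotated
#'   fragment plus `window + 2` bp on each side
#' @param prefix_len 0-based offset of the annotated fragment start within
#'   `mic_context`
#' @param ies_length fragment length
#' @param window maximum absolute offset considered (default 10)
#' @return sorted integer offsets; always contains 0
#' @export
detect_floating <- function(mic_context, prefix_len, ies_length, window = 10L) {
  n <- length(mic_context)
  p <- rep_len(prefix_len, n)
  L <- rep_len(ies_length, n)
  if (any(p - window < 0L) ||
      any(p + L + window + 2L > stri_length(mic_context))) {
    stop("context too short for the requested window")
  }
  offs <- vector("list", n)
  for (i in seq_len(n)) offs[[i]] <- 0L
  for (d in setdiff(seq.int(-window, window), 0L)) {
    q <- p + d
    ok <- stri_sub(mic_context, q + 1L, q + 2L) == "TA" &
      stri_sub(mic_context, q + L + 1L, q + L + 2L) == "TA"
    if (d > 0L) {
      ok <- ok & stri_sub(mic_context, p + 1L, p + d) ==
        stri_sub(mic_context, p + L + 1L, p + L + d)
    } else {
      ok <- ok & stri_sub(mic_context, q + 1L, p) ==
        stri_sub(mic_context, q + L + 1L, p + L)
    }
    for (i in which(ok)) offs[[i]] <- c(offs[[i]], d)
  }
  offs <- lapply(offs, sort)
  if (n == 1L) offs[[1L]] else offs
}

#' Annotate a whole catalog with floating offsets
#'
#' @param mic named character of MIC scaffolds
#' @param catalog IES catalog
#' @param window maximum offset
#' @return catalog with a refreshed `floating_offsets` list column
#' @export
detect_floating_catalog <- function(mic, catalog, window = 10L) {
  pos <- mic_positions(catalog)
  pad <- window + 2L
  scaff_len <- stri_length(mic)[match(catalog$scaffold, names(mic))]
  lo <- pmax(0L, pos - pad)
  hi <- pmin(scaff_len, pos + catalog$length + pad)
  ctx <- stri_sub(mic[catalog$scaffold], lo + 1L, hi)
  # clamp the window where the scaffold edge truncates the context
  w_ok <- pmin(window, pos - lo, hi - (pos + catalog$length) - 2L)
  offs <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    offs[[i]] <- detect_floating(ctx[i], pos[i] - lo[i], catalog$length[i],
                                 window = max(0L, w_ok[i]))
  }
  catalog$floating_offsets <- offs
  catalog
}

#' Genomic compartment of the retained TA
#'
#' The compartment is decided by the base at the retained-TA position:
#' inside an annotated CDS interval it is `exon`, inside an intron interval
#' `intron`, anywhere else `intergenic`.
#'
#' @param catalog IES catalog
#' @param gene_annotation data.frame with columns scaffold, gene, type
#'   ("CDS" or "intron"), start, end (0-based half-open)
#' @return catalog with `compartment` and `gene` columns filled
#' @export
assign_compartment <- function(catalog, gene_annotation) {
  catalog$compartment <- "intergenic"
  catalog$gene <- NA_character_
  for (sc in unique(catalog$scaffold)) {
    ci <- which(catalog$scaffold == sc)
    gi <- which(gene_annotation$scaffold == sc)
    if (!length(ci) || !length(gi)) next
    q <- IRanges::IRanges(start = catalog$mac_position[ci] + 1L, width = 1L)
    s <- IRanges::IRanges(start = gene_annotation$start[gi] + 1L,
                          end = gene_annotation$end[gi])
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    type <- gene_annotation$type[gi][sh]
    catalog$compartment[ci[qh]] <- ifelse(type == "CDS", "exon", "intron")
    catalog$gene[ci[qh]] <- gene_annotation$gene[gi][sh]
  }
  catalog
}

#' Length-peak classification of an IES
#'
#' IES lengths fall into ~10-bp periodic peaks; peak k covers
#' \[25 + 10(k-1), 34 + 10(k-1)\] bp.  IESs shorter than 35 bp are `short`,
#' longer than 100 bp `long`, otherwise `mid`.
#'
#' @param length integer vector of IES lengths (>= 2)
#' @return data.frame with `peak` (NA below 25 bp) and `class`
#' @export
classify_length <- function(length) {
  if (any(length < 2)) stop("IES length must be >= 2")
  peak <- ifelse(length >= 25, (length - 25) %/% 10 + 1L, NA_integer_)
  cls <- ifelse(length < 35, "short", ifelse(length > 100, "long", "mid"))
  data.frame(length = length, peak = peak, class = cls)
}

#' Weak-IES call
#'
#' Weak IESs are retained in more than 10% of wild-type somatic copies:
#' strictly IRS > 0.10.  Missing IRS gives NA (excluded from proportions).
#'
#' @param irs numeric vector in \[0,1\]
#' @return logical vector
#' @export
call_weak <- function(irs) {
  if (any(irs < 0 | irs > 1, na.rm = TRUE)) stop("irs must be in [0,1]")
  irs > 0.10
}

#' Reliability filters on an IES catalog
#'
#' Drops IESs on scaffolds shorter than `min_scaffold` bp; marks IESs in
#' genes with extreme MIC-read coverage (below the 10th or above the 90th
#' per-species percentile, or absolute coverage below `min_reads`) as
#' uncertain; flagged genes without any annotated IES are reported as
#' potentially containing undetected IESs.  Idempotent.
#'
#' @param catalog IES catalog with `gene` assigned
#' @param coverage data.frame with columns species, gene, depth (mean
#'   per-gene mapped MIC read depth)
#' @param scaffold_lengths named integer vector
#' @param min_scaffold minimum scaffold length (default 10 kb)
#' @param min_reads absolute minimum coverage (default 15)
#' @param percentiles lower/upper depth percentiles (default 0.1, 0.9)
#' @return filtered catalog; attributes `flagged_genes` and
#'   `genes_potentially_with_ies` list the affected genes
#' @export
apply_reliability_filters <- function(catalog, coverage, scaffold_lengths,
                                      min_scaffold = 10000L, min_reads = 15,
                                      percentiles = c(0.1, 0.9)) {
  keep <- scaffold_lengths[catalog$scaffold] >= min_scaffold
  catalog <- catalog[keep, , drop = FALSE]
  flagged <- character(0)
  for (sp in unique(coverage$species)) {
    cv <- coverage[coverage$species == sp, ]
    qs <- quantile(cv$depth, percentiles, names = FALSE)
    bad <- cv$depth < qs[1] | cv$depth > qs[2] | cv$depth < min_reads
    flagged <- c(flagged, cv$gene[bad])
  }
  catalog$uncertain <- (catalog$uncertain %||% FALSE) |
    (!is.na(catalog$gene) & catalog$gene %in% flagged)
  potential <- setdiff(flagged, catalog$gene)
  attr(catalog, "flagged_genes") <- unique(flagged)
  attr(catalog, "genes_potentially_with_ies") <- unique(potential)
  catalog
}

#' Call MAC-variable regions at scaffold extremities
#'
#' Sliding windows of `window` bp are examined inward from each scaffold
#' extremity; the extremity region extends to the first window whose mean
#' depth reaches `min_expected_depth`.  Only regions of at least
#' `min_region` bp are reported.
#'
#' @param depth per-base depth vector of one scaffold
#' @param min_expected_depth depth threshold
#' @param window window size (default 2000)
#' @param min_region minimum reported size (default 4000)
#' @return data.frame with 0-based half-open `start`, `end` and `side`
#' @export
call_mac_variable_regions <- function(depth, min_expected_depth,
                                      window = 2000L, min_region = 4000L) {
  n <- length(depth)
  nw <- n %/% window
  out <- list()
  if (nw >= 1L) {
    wmean <- vapply(seq_len(nw), function(i) {
      mean(depth[((i - 1L) * window + 1L):(i * window)])
    }, numeric(1))
    lo <- which(wmean >= min_expected_depth)
    left_end <- if (length(lo)) (min(lo) - 1L) * window else n
    if (left_end >= min_region) {
      out[[length(out) + 1L]] <- data.frame(start = 0L, end = left_end,
                                            side = "left")
    }
    hi <- which(rev(wmean) >= min_expected_depth)
    right_len <- if (length(hi)) (min(hi) - 1L) * window else n
    right_start <- n - right_len
    if (right_len >= min_region && right_start > left_end) {
      out[[length(out) + 1L]] <- data.frame(start = right_start, end = n,
                                            side = "right")
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      side = character(0)))
  }
  do.call(rbind, out)
}
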
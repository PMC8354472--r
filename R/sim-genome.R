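## Paired germline/somatic genome simulation.  The MAC (somatic) sequence
## is drawn first; IESs are then inserted at TA junctions to produce the
## MIC (germline) sequence, so the excision round trip holds by
## construction and is re-checked on output.

#' Default configuration for [build_genome_pair()]
#'
#' Peak weights follow the shape of the aurelia IES length distribution
#' (~35% of IESs in the first, sub-35 bp peak, decaying 10-bp-periodic
#' peaks above); IES interiors are 80% A+T, the MAC backbone 72% A+T.
#'
#' @param ... overrides for any default field
#' @return config list
#' @export
genome_config <- function(...) {
  cfg <- list(
    n_scaffolds = 1L,
    scaffold_bp = 20000L,
    at_mac = 0.72,
    at_ies = 0.80,
    ies_per_kb = 1.0,
    peak_weights = c(0.35, 0.13, 0.11, 0.09, 0.08, 0.07, 0.06, 0.05,
                     0.04, 0.02),
    floating_fraction = 0.07,
    floating_periods = c("2" = 0.86, "3" = 0.06, "4" = 0.04, "5" = 0.03,
                         "6" = 0.01),
    species = "pso",
    min_spacing = 12L,
    genes = list(exon1 = 600L, intron = 25L, exon2 = 875L, gap = 400L),
    mobile = NULL)
  modifyList(cfg, list(...))
}

#' Mobile-element burst configuration
#'
#' Template: a 233-bp nonautonomous element present in hundreds of copies
#' at ~70% within-family identity, partly nested inside pre-existing IESs.
#'
#' @param n_copies bona fide mobile copies (inserted as whole IESs)
#' @param n_nested copies nested inside other IESs
#' @param consensus_length element length (default 233)
#' @param divergence per-copy substitution probability from the consensus
#'   (0.15 gives ~72% mean pairwise identity between copies)
#' @param species optional species label(s) sampled per copy
#' @param family family id recorded in the truth columns
#' @export
mobile_config <- function(n_copies = 200L, n_nested = 50L,
                          consensus_length = 233L, divergence = 0.15,
                          species = NULL, family = "FAM1") {
  list(n_copies = n_copies, n_nested = n_nested,
       consensus_length = consensus_length, divergence = divergence,
       species = species, family = family)
}

## logical subset of sorted positions keeping pairwise gaps >= spacing
spaced_subset <- function(pos, spacing) {
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= spacing) { keep[i] <- TRUE; last <- pos[i] }
  }
  keep
}

## draw IES lengths from the 10-bp-periodic peak mixture
draw_peak_lengths <- function(n, weights) {
  k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  lo <- 25L + 10L * (k - 1L)
  lo + sample.int(10L, n, replace = TRUE) - 1L
}

## substitution-mutated copy of a consensus, extremity "TA" preserved
mutate_copy <- function(consensus, divergence) {
  s <- strsplit(consensus, "")[[1]]
  hit <- which(runif(length(s)) < divergence)
  hit <- hit[hit > 2L]
  if (length(hit)) {
    repl <- vapply(s[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    s[hit] <- repl
  }
  paste(s, collapse = "")
}

#' Simulate a MIC/MAC genome pair with an IES catalog
#'
#' @param config from [genome_config()]
#' @param seed integer seed
#' @return list with `mic` and `mac` (named scaffold sequences), `catalog`
#'   (IES catalog data.frame with generator-truth columns `role`, `family`,
#'   `float_period`, `compartment_truth`, `nested_from`), `genes` (gene
#'   annotation: scaffold, gene, type, start, end; 0-based half-open) and
#'   the config
#' @export
build_genome_pair <- function(config = genome_config(), seed = 1L) {
  set.seed(as.integer(seed))
  cfg <- config
  mac <- setNames(random_dna(cfg$n_scaffolds, cfg$scaffold_bp, cfg$at_mac),
                  sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds)))
  genes <- make_gene_annotation(mac, cfg$genes)

  n_std <- round(cfg$ies_per_kb * cfg$scaffold_bp / 1000) * cfg$n_scaffolds
  n_mob <- if (!is.null(cfg$mobile)) cfg$mobile$n_copies else 0L
  n_tot <- n_std + n_mob

  # candidate TA junctions per scaffold, thinned to the minimum spacing;
  # "qualified" junctions (a second TA 2 bp downstream) can host an
  # engineered floating IES
  cand <- do.call(rbind, lapply(names(mac), function(sc) {
    m <- stri_locate_all_fixed(mac[[sc]], "TA")[[1]]
    if (is.na(m[1, 1])) return(NULL)
    pos <- m[, 1] - 1L # 0-based
    pos <- pos[pos > 12L & pos < stri_length(mac[[sc]]) - 30L]
    keep <- spaced_subset(pos, cfg$min_spacing)
    pos <- pos[keep]
    data.frame(scaffold = sc, mac_position = pos,
               qualified = stri_sub(mac[[sc]], pos + 3L, pos + 4L) == "TA",
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n_tot) {
    stop("IES density too high: not enough spaced TA junctions for placement")
  }
  n_float <- round(cfg$floating_fraction * n_std)
  qi <- which(cand$qualified)
  if (length(qi) < n_float) {
    stop("IES density too high: not enough tandem-TA junctions for the ",
         "requested floating fraction")
  }
  float_rows <- qi[sample.int(length(qi), n_float)]
  rest <- setdiff(seq_len(nrow(cand)), float_rows)
  other_rows <- rest[sample.int(length(rest), n_tot - n_float)]
  catalog <- cand[c(float_rows, other_rows), c("scaffold", "mac_position")]
  catalog$float_site <- rep(c(TRUE, FALSE), c(n_float, n_tot - n_float))
  catalog <- catalog[order(catalog$scaffold, catalog$mac_position), ]
  rownames(catalog) <- NULL
  is_float_site <- catalog$float_site
  catalog$float_site <- NULL
  n_tot <- nrow(catalog)
  consensus <- if (!is.null(cfg$mobile)) {
    paste0("TA", random_dna(1, cfg$mobile$consensus_length - 2L, at = 0.75))
  }
  is_mob <- rep(FALSE, n_tot)
  if (n_mob > 0) {
    free <- which(!is_float_site)
    is_mob[free[sample.int(length(free), n_mob)]] <- TRUE
  }
  lens <- draw_peak_lengths(n_tot, cfg$peak_weights)
  float <- is_float_site & !is_mob
  stored <- character(n_tot)
  fper <- rep(NA_integer_, n_tot)
  for (i in seq_len(n_tot)) {
    sc <- catalog$scaffold[i]
    j <- catalog$mac_position[i]
    if (is_mob[i]) {
      stored[i] <- mutate_copy(consensus, cfg$mobile$divergence)
      next
    }
    L <- max(lens[i], 25L)
    if (float[i]) {
      d <- as.integer(sample(names(cfg$floating_periods), 1L,
                             prob = cfg$floating_periods))
      # engineered float requires a TA d bp downstream of the junction
      has_ta <- function(dd) stri_sub(mac[[sc]], j + dd + 1L, j + dd + 2L) == "TA"
      ds <- c(d, 2:8)
      d <- NA_integer_
      for (dd in ds) if (has_ta(dd)) { d <- dd; break }
      if (!is.na(d)) {
        motif <- stri_sub(mac[[sc]], j + 1L, j + d)
        L <- max(L, d + 4L)
        stored[i] <- paste0(motif, "TA", random_dna(1, L - d - 2L, cfg$at_ies))
        fper[i] <- d
        next
      }
    }
    stored[i] <- paste0("TA", random_dna(1, L - 2L, cfg$at_ies))
  }
  catalog$excised_sequence <- stored
  catalog$role <- ifelse(is_mob, "mobile", "standard")
  catalog$family <- ifelse(is_mob, cfg$mobile$family %||% NA_character_,
                           NA_character_)
  catalog$float_period <- fper

  # nested copies: splice a mutated element into existing standard IESs
  if (!is.null(cfg$mobile) && cfg$mobile$n_nested > 0) {
    host_ok <- which(catalog$role == "standard" &
                       stri_length(catalog$excised_sequence) >= 33L)
    if (length(host_ok) < cfg$mobile$n_nested) {
      stop("not enough standard IESs to host the requested nested copies")
    }
    hosts <- host_ok[sample.int(length(host_ok), cfg$mobile$n_nested)]
    for (h in hosts) {
      s <- catalog$excised_sequence[h]
      q <- sample(seq.int(4L, stri_length(s) - 4L), 1L)
      copy <- mutate_copy(consensus, cfg$mobile$divergence)
      catalog$excised_sequence[h] <-
        paste0(stri_sub(s, 1L, q), copy, stri_sub(s, q + 1L))
      catalog$role[h] <- "nested_host"
      catalog$family[h] <- cfg$mobile$family %||% "FAM1"
    }
  }

  catalog$length <- stri_length(catalog$excised_sequence)
  catalog$id <- sprintf("%s.%s.%06d", catalog$scaffold,
                        "ies", catalog$mac_position)
  sp_pool <- if (!is.null(cfg$mobile) && !is.null(cfg$mobile$species))
    cfg$mobile$species else cfg$species
  catalog$species <- rep(cfg$species[1L], nrow(catalog))
  mobrows <- catalog$role == "mobile"
  if (any(mobrows) && length(sp_pool) > 1L) {
    catalog$species[mobrows] <- sample(sp_pool, sum(mobrows), replace = TRUE)
  }
  catalog$compartment_truth <- compartment_truth(catalog, genes)
  catalog$irs <- rep(NA_real_, nrow(catalog))
  catalog$uncertain <- rep(FALSE, nrow(catalog))

  mic <- mac
  for (sc in names(mac)) {
    rows <- catalog[catalog$scaffold == sc, , drop = FALSE]
    mic[[sc]] <- insert(mac[[sc]], rows)
    stopifnot(identical(excise(mic[[sc]], rows), mac[[sc]]))
  }
  ord <- order(catalog$scaffold, catalog$mac_position)
  catalog <- catalog[ord, ]
  rownames(catalog) <- NULL
  if (!is.null(consensus)) attr(catalog, "mobile_consensus") <- consensus
  list(mic = mic, mac = mac, catalog = catalog, genes = genes, config = cfg)
}

make_gene_annotation <- function(mac, g) {
  out <- list()
  for (sc in names(mac)) {
    len <- stri_length(mac[[sc]])
    glen <- g$exon1 + g$intron + g$exon2
    s <- g$gap %/% 2L
    k <- 0L
    while (s + glen <= len - g$gap %/% 2L) {
      k <- k + 1L
      gene <- sprintf("%s.g%03d", sc, k)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, gene = gene,
        type = c("CDS", "intron", "CDS"),
        start = c(s, s + g$exon1, s + g$exon1 + g$intron),
        end = c(s + g$exon1, s + g$exon1 + g$intron, s + glen),
        stringsAsFactors = FALSE)
      s <- s + glen + g$gap
    }
  }
  do.call(rbind, out)
}

## generator-side compartment truth by direct interval arithmetic
compartment_truth <- function(catalog, genes) {
  vapply(seq_len(nrow(catalog)), function(i) {
    p <- catalog$mac_position[i]
    gi <- genes[genes$scaffold == catalog$scaffold[i], , drop = FALSE]
    inside <- gi$start <= p & p < gi$end
    if (!any(inside)) return("intergenic")
    if (gi$type[which(inside)[1]] == "CDS") "exon" else "intron"
  }, character(1))
}
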
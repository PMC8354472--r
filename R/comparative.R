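## Gene-family handling and projection of IES insertion sites into
## alignment coordinates.  An IES insertion site spans the two nucleotides
## of the retained TA; in a gapped codon alignment the locus can span
## additional gap columns (T--A).  Two loci are co-orthologous when they
## share at least one alignment column.

#' Single-linkage gene families from pairwise protein hits
#'
#' Connected components of the (symmetrized) hit graph, as produced by
#' single-linkage clustering of an all-vs-all protein similarity search.
#'
#' @param hits data.frame with columns `a`, `b` (gene ids)
#' @param genes optional character vector of all gene ids, so that
#'   singletons (no hits) are returned too
#' @return list of character vectors (families), largest first
#' @export
cluster_families <- function(hits, genes = NULL) {
  verts <- unique(c(hits$a, hits$b, genes))
  g <- igraph::graph_from_data_frame(hits[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  fams <- split(names(comp$membership), comp$membership)
  fams <- unname(fams)
  fams[order(-lengths(fams))]
}

#' Filter families by size and mean pairwise protein identity
#'
#' Families with fewer than `min_genes` members or mean pairwise identity
#' below `min_identity` (computed on the aligned proteins, gaps excluded
#' from the pair length) are removed.
#'
#' @param families list of member-id vectors
#' @param proteins named aligned protein sequences
#' @param min_genes minimum members (default 3)
#' @param min_identity minimum mean pairwise identity (default 0.5)
#' @return filtered list
#' @export
filter_families <- function(families, proteins, min_genes = 3L,
                            min_identity = 0.5) {
  keep <- vapply(families, function(f) {
    if (length(f) < min_genes) return(FALSE)
    mean_pairwise_identity(proteins[f]) >= min_identity
  }, logical(1))
  families[keep]
}

## mean pairwise identity of aligned sequences (matches / columns where
## not both gaps)
mean_pairwise_identity <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  n <- nrow(m)
  tot <- 0
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- m[i, ] != "-" | m[j, ] != "-"
      tot <- tot + sum(m[i, use] == m[j, use]) / sum(use)
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Every residue column expands to its source codon; gaps expand to `---`.
#' Genes whose CDS length does not equal three times their ungapped
#' protein length are excluded with a message.
#'
#' @param protein_alignment named aligned proteins
#' @param cds_sequences named unaligned CDSs (no stop codon)
#' @return named codon alignment (character vector)
#' @export
backtranslate <- function(protein_alignment, cds_sequences) {
  out <- list()
  for (nm in names(protein_alignment)) {
    aa <- strsplit(protein_alignment[[nm]], "")[[1]]
    cds <- cds_sequences[[nm]]
    if (is.null(cds)) { message("backtranslate: no CDS for ", nm); next }
    n_res <- sum(aa != "-")
    if (stri_length(cds) != 3L * n_res) {
      message("backtranslate: length mismatch for ", nm, ", excluded")
      next
    }
    cod <- character(length(aa))
    cod[aa == "-"] <- "---"
    idx <- which(aa != "-")
    cod[idx] <- stri_sub(cds, 3L * seq_along(idx) - 2L, 3L * seq_along(idx))
    out[[nm]] <- paste(cod, collapse = "")
  }
  unlist(out)
}

#' Conserved-block column mask of a protein alignment
#'
#' A deterministic stand-in for conserved-block filtering: maximal runs of
#' at least `min_block` columns in which every column has at most
#' `max_gap_fraction` gaps and a majority-residue fraction of at least
#' `min_column_identity`.
#'
#' @param protein_alignment named aligned proteins
#' @param min_block minimum run length (columns)
#' @param max_gap_fraction maximum per-column gap fraction
#' @param min_column_identity minimum per-column majority-residue fraction
#'   (computed over non-gap residues)
#' @return logical vector, one element per alignment column
#' @export
conserved_blocks <- function(protein_alignment, min_block = 10L,
                             max_gap_fraction = 0.2,
                             min_column_identity = 0.5) {
  m <- do.call(rbind, strsplit(unname(protein_alignment), ""))
  ncol_aln <- ncol(m)
  good <- logical(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- m[, j]
    gf <- mean(col == "-")
    if (gf > max_gap_fraction) next
    res <- col[col != "-"]
    good[j] <- length(res) > 0 && max(table(res)) / length(res) >= min_column_identity
  }
  # keep only runs of length >= min_block
  r <- rle(good)
  r$values[r$values & r$lengths < min_block] <- FALSE
  inverse.rle(r)
}

#' Map an IES to protein-alignment codon columns
#'
#' Converts the MAC position of the retained TA into coordinates of the
#' gapped codon alignment of its gene: the columns of the T and the A plus
#' any gap columns between them.  One interval is returned per floating
#' alternative.
#'
#' @param mac_position 0-based retained-TA position on the MAC scaffold
#' @param floating_offsets signed offsets (0 included)
#' @param cds_start 0-based scaffold position where the gene CDS begins
#'   (the gene is assumed unspliced here or the position pre-projected
#'   into CDS coordinates)
#' @param aligned_cds the gene's row of the codon alignment (with gaps)
#' @return data.frame with `offset`, `col_start`, `col_end`
#'   (0-based, inclusive alignment columns); NULL when outside the CDS
#' @export
map_ies_to_alignment <- function(mac_position, floating_offsets = 0L,
                                 cds_start, aligned_cds) {
  chars <- strsplit(aligned_cds, "")[[1]]
  notgap <- which(chars != "-")
  n_nt <- length(notgap)
  out <- list()
  for (d in floating_offsets) {
    nt <- mac_position + d - cds_start # 0-based CDS position of the T
    if (nt < 0 || nt + 1 >= n_nt) next
    colT <- notgap[nt + 1L] - 1L
    colA <- notgap[nt + 2L] - 1L
    out[[length(out) + 1L]] <- data.frame(offset = d, col_start = colT,
                                          col_end = colA)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Group co-orthologous IES loci by shared alignment columns
#'
#' Loci (within one gene family) are connected when any of their column
#' intervals — including floating alternatives — overlap; groups are the
#' connected components.  Loci outside the conserved-block mask are
#' excluded beforehand, and any group containing a floating member with an
#' alternative outside the mask is discarded entirely, because presence or
#' absence at such a locus cannot be assessed reliably in the other
#' sequences.
#'
#' @param loci data.frame with columns `ies`, `gene`, `offset`,
#'   `col_start`, `col_end` (one row per floating alternative)
#' @param block_mask logical per protein column; codon column c is inside
#'   a block iff protein column `c %/% 3` is TRUE
#' @return list of groups (character vectors of IES ids); attribute
#'   `discarded` lists groups dropped under the floating rule
#' @export
group_co_orthologs <- function(loci, block_mask) {
  in_block <- function(cs, ce) {
    pc <- unique(c(cs %/% 3L, ce %/% 3L))
    all(pc + 1L <= length(block_mask)) && all(block_mask[pc + 1L])
  }
  loci$ok <- mapply(in_block, loci$col_start, loci$col_end)
  # primary location outside a block -> locus excluded beforehand
  primary_ok <- tapply(loci$ok & loci$offset == 0, loci$ies, any)
  loci <- loci[loci$ies %in% names(primary_ok)[primary_ok], , drop = FALSE]
  if (!nrow(loci)) return(structure(list(), discarded = list()))
  ids <- unique(loci$ies)
  # connect loci sharing any column across any alternative
  edges <- list()
  for (i in seq_along(ids)) {
    ri <- loci[loci$ies == ids[i], ]
    for (j in seq_len(i - 1L)) {
      rj <- loci[loci$ies == ids[j], ]
      hit <- any(outer(seq_len(nrow(ri)), seq_len(nrow(rj)), function(a, b) {
        ri$col_start[a] <= rj$col_end[b] & rj$col_start[b] <= ri$col_end[a]
      }))
      if (hit) edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2)
  g <- igraph::graph_from_data_frame(
    data.frame(a = ed[, 1], b = ed[, 2]), directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  groups <- unname(split(names(comp$membership), comp$membership))
  # discard whole groups containing a floating alternative off the mask
  bad_ies <- unique(loci$ies[!loci$ok])
  drop <- vapply(groups, function(gr) any(gr %in% bad_ies), logical(1))
  structure(groups[!drop], discarded = groups[drop])
}

#' Highly conserved cross-subclade IES groups
#'
#' Reports co-ortholog groups represented in at least `min_species`
#' distinct aurelia species whose best cross-subclade (A vs B) pairwise
#' identity reaches `min_cross_identity`.  Identity is computed from a
#' global alignment as matches divided by alignment length (internal gaps
#' included); both the best and the mean cross-subclade identity are
#' reported.
#'
#' @param groups list of IES-id vectors
#' @param ies_sequences named excised sequences
#' @param ies_species named species code per IES
#' @param subclades list with `A` and `B` species vectors
#'   (default [species_subclades()])
#' @param min_species minimum distinct aurelia species (default 5)
#' @param min_cross_identity minimum best A-vs-B identity (default 0.70)
#' @return data.frame: group, n_species, best_cross_identity,
#'   mean_cross_identity
#' @export
find_conserved_ies <- function(groups, ies_sequences, ies_species,
                               subclades = species_subclades(),
                               min_species = 5L, min_cross_identity = 0.70) {
  rows <- list()
  for (gi in seq_along(groups)) {
    gr <- groups[[gi]]
    sp <- ies_species[gr]
    aurelia <- c(subclades$A, subclades$B)
    n_sp <- length(unique(sp[sp %in% aurelia]))
    if (n_sp < min_species) next
    a_ids <- gr[sp %in% subclades$A]
    b_ids <- gr[sp %in% subclades$B]
    if (!length(a_ids) || !length(b_ids)) next # cross identity undefined
    idents <- c()
    for (a in a_ids) {
      for (b in b_ids) {
        idents <- c(idents, global_identity(ies_sequences[[a]],
                                            ies_sequences[[b]]))
      }
    }
    if (max(idents) < min_cross_identity) next
    rows[[length(rows) + 1L]] <- data.frame(
      group = gi, n_species = n_sp, best_cross_identity = max(idents),
      mean_cross_identity = mean(idents))
  }
  if (!length(rows)) {
    return(data.frame(group = integer(0), n_species = integer(0),
                      best_cross_identity = numeric(0),
                      mean_cross_identity = numeric(0)))
  }
  do.call(rbind, rows)
}

## global-alignment identity: matches / alignment length (with gaps)
global_identity <- function(x, y) {
  al <- Biostrings::pairwiseAlignment(x, y, type = "global",
                                      gapOpening = 10, gapExtension = 0.5)
  p <- as.character(Biostrings::alignedPattern(al))
  s <- as.character(Biostrings::alignedSubject(al))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  sum(pc == sc & pc != "-") / length(pc)
}
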
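## Reconciled gene-family simulation: a birth-death expansion of the species
## tree (duplication/loss along branches), with internal nodes labelled as
## speciation (mapped to a species-tree node) or duplication, plus a codon
## alignment evolved along the gene tree.  Stands in for reconciled gene
## trees inferred by species-tree/gene-tree reconciliation.

#' Simulate reconciled gene families on a species tree
#'
#' Each family starts as a single lineage at the species-tree root.  Along
#' every branch the lineage duplicates at rate `dup_rate` and dies at rate
#' `loss_rate_genes` (per unit branch length); duplication nodes split the
#' branch at the event time, and surviving lineages speciate at species
#' nodes.  Families with fewer than `min_genes` surviving genes are
#' rejected and resimulated, mirroring the downstream gene-family filter.
#'
#' @param stree species tree (node table, see [species_tree()])
#' @param n_families number of families
#' @param dup_rate,loss_rate_genes per-lineage event rates (>= 0)
#' @param seed integer seed
#' @param n_codons codons in the simulated alignment (default 100)
#' @param subst_rate nucleotide substitution probability per unit branch
#'   length used to evolve the family CDS (default 0.5)
#' @param noisy_frac fraction of codon columns randomized per sequence so
#'   the conserved-block mask has something to exclude (default 0.1)
#' @param min_genes minimum surviving genes per family (default 3)
#' @return list of families; each has `tree` (reconciled node table),
#'   `alignment` (named codon alignment, characters), `proteins`,
#'   `block_mask` (logical per protein column)
#' @export
simulate_gene_families <- function(stree, n_families, dup_rate = 0.2,
                                   loss_rate_genes = 0.1, seed = 1L,
                                   n_codons = 100L, subst_rate = 0.5,
                                   noisy_frac = 0.1, min_genes = 3L) {
  stopifnot(dup_rate >= 0, loss_rate_genes >= 0, n_families >= 1)
  set.seed(as.integer(seed))
  lapply(seq_len(n_families), function(fi) {
    for (try in 1:200) {
      fam <- sim_one_genetree(stree, dup_rate, loss_rate_genes)
      if (!is.null(fam) && sum(fam$event == "leaf") >= min_genes) {
        aln <- evolve_codon_alignment(fam, n_codons, subst_rate, noisy_frac)
        prot <- translate_cds(aln)
        mask <- conserved_blocks(prot)
        return(list(id = sprintf("fam%04d", fi), tree = fam,
                    alignment = aln, proteins = prot, block_mask = mask))
      }
    }
    stop("could not simulate a family with >= ", min_genes, " genes in 200 tries")
  })
}

## one gene tree as a nested list, then flattened to a node table
sim_one_genetree <- function(stree, dup, loss) {
  kids <- tree_children(stree)
  counter <- new.env()
  descend <- function(snode, t_left, above) {
    rate <- dup + loss
    t_ev <- if (rate > 0) rexp(1, rate) else Inf
    if (t_ev < t_left) {
      if (runif(1) < ifelse(rate > 0, dup / rate, 0)) {
        a <- descend(snode, t_left - t_ev, 0)
        b <- descend(snode, t_left - t_ev, 0)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(add_len(b, above + t_ev))
        if (is.null(b)) return(add_len(a, above + t_ev))
        return(list(event = "duplication", snode = NA_integer_,
                    len = above + t_ev, children = list(a, b)))
      }
      return(NULL) # gene loss
    }
    # reached species node snode
    ch <- kids[[as.character(snode)]]
    if (length(ch) == 0L) { # species tip
      sp <- stree$species[stree$node == snode]
      k <- get0(sp, envir = counter, inherits = FALSE, ifnotfound = 0L) + 1L
      assign(sp, k, envir = counter)
      return(list(event = "leaf", snode = snode, len = above + t_left,
                  label = sprintf("%s__g%d", sp, k), children = list()))
    }
    subs <- lapply(ch, function(s) {
      descend(s, stree$length[stree$node == s], 0)
    })
    alive <- !vapply(subs, is.null, logical(1))
    if (!any(alive)) return(NULL)
    if (sum(alive) == 1L) {
      return(add_len(subs[alive][[1L]], above + t_left))
    }
    list(event = "speciation", snode = snode, len = above + t_left,
         children = subs[alive])
  }
  root <- descend(tree_root(stree), 0, 0)
  if (is.null(root) || root$event == "leaf") return(NULL)
  flatten_genetree(root)
}

add_len <- function(node, extra) { node$len <- node$len + extra; node }

flatten_genetree <- function(root) {
  rows <- list()
  nid <- 0L
  walk <- function(nd, parent) {
    nid <<- nid + 1L
    me <- nid
    rows[[me]] <<- data.frame(
      node = me, parent = if (is.na(parent)) NA_integer_ else parent,
      length = if (is.na(parent)) NA_real_ else nd$len,
      label = nd$label %||% NA_character_,
      event = nd$event, species = if (nd$event == "leaf")
        sub("__.*$", "", nd$label) else NA_character_,
      snode = nd$snode, stringsAsFactors = FALSE)
    for (ch in nd$children) walk(ch, me)
    me
  }
  walk(root, NA_integer_)
  new_tree(do.call(rbind, rows))
}

codon_alphabet <- function() {
  nt <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(nt, nt, paste0)), nt, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

## evolve a CDS (vector of codons) down the gene tree by per-codon
## substitution; stop codons are resampled
evolve_codon_alignment <- function(gtree, n_codons, subst_rate, noisy_frac) {
  codons <- codon_alphabet()
  root_seq <- sample(codons, n_codons, replace = TRUE)
  kids <- tree_children(gtree)
  seqs <- list()
  walk <- function(v, s) {
    r <- gtree[gtree$node == v, ]
    if (!is.na(r$parent)) {
      p_mut <- 1 - exp(-subst_rate * r$length)
      hit <- runif(n_codons) < p_mut
      if (any(hit)) s[hit] <- sample(codons, sum(hit), replace = TRUE)
    }
    ch <- kids[[as.character(v)]]
    if (length(ch) == 0L) {
      seqs[[r$label]] <<- s
    } else {
      for (k in ch) walk(k, s)
    }
  }
  walk(tree_root(gtree), root_seq)
  # per-sequence randomized columns simulate poorly aligned stretches
  n_noisy <- round(noisy_frac * n_codons)
  if (n_noisy > 0) {
    noisy <- sample.int(n_codons, n_noisy)
    for (nm in names(seqs)) {
      seqs[[nm]][noisy] <- sample(codons, n_noisy, replace = TRUE)
    }
  }
  vapply(seqs, paste, character(1), collapse = "")
}

#' Translate an (aligned) CDS to protein
#'
#' Gap codons `---` become `-`; incomplete or stop codons become `X`/`*`.
#' @param cds named character vector of codon-aligned sequences
#' @return named character vector of protein sequences
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    ncod <- stri_length(s) %/% 3L
    cods <- stri_sub(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    aa <- character(ncod)
    gap <- cods == "---"
    aa[gap] <- "-"
    if (any(!gap)) {
      tr <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(cods[!gap]), no.init.codon = TRUE))
      aa[!gap] <- tr
    }
    paste(aa, collapse = "")
  }, character(1))
}
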
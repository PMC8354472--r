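## Trees are stored as "node tables": a data.frame with one row per node and
## columns
##   node    integer id (1..N, row order)
##   parent  integer id of the parent, NA for the root
##   length  branch length above the node (substitutions/site), NA for root
##   label   node label (species code for tips, "n1".. for species-tree
##           internals, free-form for gene trees)
##   event   "leaf", "speciation" or "duplication"
##   species species code for tips, NA otherwise
##   snode   species-tree node id this node maps to (reconciled trees;
##           for the species tree itself, snode == node)
## This flat form keeps duplication/speciation annotations, path enumeration
## and simulation simple; conversion to ape::phylo is provided for plotting.

new_tree <- function(df) {
  stopifnot(all(c("node", "parent", "length", "label", "event",
                  "species", "snode") %in% names(df)))
  if (anyDuplicated(df$node)) stop("node ids must be unique")
  if (sum(is.na(df$parent)) != 1L) stop("tree must have exactly one root")
  bl <- df$length[!is.na(df$parent)]
  if (any(!is.na(bl) & bl < 0)) stop("branch lengths must be >= 0")
  class(df) <- c("ies_tree", "data.frame")
  df
}

#' @export
print.ies_tree <- function(x, ...) {
  cat(sprintf("<ies_tree> %d nodes, %d tips\n", nrow(x),
              sum(x$event == "leaf")))
  NextMethod()
}

tree_root <- function(tree) tree$node[is.na(tree$parent)]

tree_tips <- function(tree) tree$node[tree$event == "leaf"]

tree_children <- function(tree) {
  split(tree$node[!is.na(tree$parent)], factor(tree$parent[!is.na(tree$parent)],
                                               levels = tree$node))
}

## postorder node ids (children before parents)
tree_postorder <- function(tree) {
  kids <- tree_children(tree)
  out <- integer(0)
  walk <- function(v) {
    for (k in kids[[as.character(v)]]) walk(k)
    out[[length(out) + 1L]] <<- v
  }
  walk(tree_root(tree))
  unlist(out)
}

## all ancestors of a node, nearest first, root last
tree_ancestors <- function(tree, v) {
  parent <- setNames(tree$parent, tree$node)
  out <- integer(0)
  p <- parent[[as.character(v)]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parent[[as.character(p)]]
  }
  out
}

## most recent common ancestor of a set of node ids
tree_mrca <- function(tree, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1L) return(nodes)
  paths <- lapply(nodes, function(v) c(rev(tree_ancestors(tree, v)), v))
  k <- min(lengths(paths))
  keep <- 1L
  for (d in seq_len(k)) {
    lvl <- vapply(paths, `[`, integer(1), d)
    if (all(lvl == lvl[1L])) keep <- d else break
  }
  paths[[1L]][keep]
}

## tip ids descending from node v (v itself if a tip)
tree_clade_tips <- function(tree, v) {
  kids <- tree_children(tree)
  out <- integer(0)
  walk <- function(u) {
    ch <- kids[[as.character(u)]]
    if (length(ch) == 0L) out[[length(out) + 1L]] <<- u
    else for (k in ch) walk(k)
  }
  walk(v)
  unlist(out)
}

## ---------------------------------------------------------------------------
## Newick / NHX input-output.  Supports the NHX comment dialect used for
## reconciled gene trees: [&&NHX:D=Y] marks duplications, [&&NHX:S=<id>]
## speciation nodes mapped to species-tree node <id>.

#' Parse a Newick (optionally NHX-annotated) tree
#'
#' @param text a single Newick string, terminated by `;`
#' @return a node table (`ies_tree`)
#' @export
read_nhx <- function(text) {
  text <- gsub("\\s", "", text)
  text <- sub(";$", "", text)
  pos <- 1L
  n <- nchar(text)
  rows <- list()
  nid <- 0L
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  take_until <- function(stops) {
    start <- pos
    while (pos <= n && !(substr(text, pos, pos) %in% stops)) pos <<- pos + 1L
    substr(text, start, pos - 1L)
  }
  parse_node <- function(parent) {
    nid <<- nid + 1L
    me <- nid
    children <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_node(me))
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed newick near position ", pos)
      }
    }
    label <- take_until(c(":", "[", ",", ")", ";"))
    len <- NA_real_
    nhx <- character(0)
    if (peek() == ":") {
      pos <<- pos + 1L
      len <- as.numeric(take_until(c("[", ",", ")", ";")))
    }
    if (peek() == "[") {
      com <- take_until(c("]"))
      pos <<- pos + 1L # consume ]
      com <- sub("^\\[&&NHX:?", "", paste0(com, ""))
      com <- sub("^\\[", "", com)
      nhx <- strsplit(com, ":", fixed = TRUE)[[1]]
      # a length may follow the comment in some writers
      if (peek() == ":") {
        pos <<- pos + 1L
        len <- as.numeric(take_until(c(",", ")", ";")))
      }
    }
    tags <- list()
    for (kv in nhx) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L) tags[[p[1]]] <- p[2]
    }
    is_leaf <- length(children) == 0L
    event <- if (is_leaf) "leaf"
      else if (identical(tags$D, "Y")) "duplication" else "speciation"
    snode <- if (!is.null(tags$S)) as.integer(tags$S) else NA_integer_
    rows[[me]] <<- data.frame(
      node = me, parent = if (is.na(parent)) NA_integer_ else parent,
      length = len, label = if (nzchar(label)) label else NA_character_,
      event = event,
      species = if (is_leaf) sub("__.*$", "", label) else NA_character_,
      snode = snode, stringsAsFactors = FALSE)
    me
  }
  parse_node(NA_integer_)
  new_tree(do.call(rbind, rows))
}

#' Serialize a node table to Newick/NHX
#'
#' @param tree a node table
#' @param nhx emit `[&&NHX:...]` duplication/speciation tags
#' @return a Newick string
#' @export
write_nhx <- function(tree, nhx = TRUE) {
  kids <- tree_children(tree)
  row <- function(v) tree[tree$node == v, ]
  fmt <- function(v) {
    r <- row(v)
    ch <- kids[[as.character(v)]]
    core <- if (length(ch)) {
      paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")")
    } else ""
    lab <- if (!is.na(r$label)) r$label else ""
    len <- if (!is.na(r$length)) sprintf(":%.10g", r$length) else ""
    tag <- ""
    if (nhx && r$event != "leaf") {
      parts <- c(if (r$event == "duplication") "D=Y" else "D=N",
                 if (!is.na(r$snode)) sprintf("S=%d", r$snode))
      tag <- paste0("[&&NHX:", paste(parts, collapse = ":"), "]")
    }
    paste0(core, lab, len, tag)
  }
  paste0(fmt(tree_root(tree)), ";")
}

## ---------------------------------------------------------------------------

#' The nine-species \emph{Paramecium} reference phylogeny
#'
#' A fixed rooted binary tree over the eight species of the \emph{aurelia}
#' complex plus \emph{P. caudatum} as outgroup, with internal nodes labelled
#' n1..n8 in preorder.  Subclade A of the \emph{aurelia} complex contains
#' \code{pso} and \code{pse}; subclade B the six remaining \emph{aurelia}
#' species.  Branch lengths are in substitutions/site and serve as the time
#' proxy in all rate computations.
#'
#' @return a node table (`ies_tree`) whose `snode` column equals `node`
#' @export
species_tree <- function() {
  nwk <- paste0(
    "(((((ppr:0.08,(pbi:0.06,ppe:0.06)n6:0.03)n5:0.02,",
    "(pte:0.07,poc:0.07)n7:0.03)n4:0.03,ptr:0.12)n3:0.05,",
    "(pse:0.10,pso:0.10)n8:0.07)n2:0.25,pca:0.45)n1;")
  tr <- read_nhx(nwk)
  tr$snode <- tr$node
  tr
}

#' Species subclade membership used in conservation tests
#'
#' @return named list with character vectors `A`, `B` (aurelia subclades)
#'   and `outgroup`
#' @export
species_subclades <- function() {
  list(A = c("pse", "pso"),
       B = c("ppr", "pbi", "ppe", "pte", "poc", "ptr"),
       outgroup = "pca")
}

## map: species code -> species-tree tip node id
species_tip_map <- function(stree) {
  setNames(stree$node[stree$event == "leaf"], stree$species[stree$event == "leaf"])
}

## edges of the species tree as (parent i, child j) pairs
species_branches <- function(stree) {
  e <- stree[!is.na(stree$parent), c("parent", "node")]
  names(e) <- c("i", "j")
  rownames(e) <- NULL
  e
}

## convert a node table to ape::phylo (plotting convenience)
#' @export
as_phylo <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for as_phylo()")
  }
  tips <- tree_tips(tree)
  internals <- setdiff(tree$node, tips)
  id <- integer(nrow(tree))
  id[match(tips, tree$node)] <- seq_along(tips)
  id[match(internals, tree$node)] <- length(tips) + seq_along(internals)
  has_par <- !is.na(tree$parent)
  edge <- cbind(id[match(tree$parent[has_par], tree$node)], id[has_par])
  structure(list(edge = edge,
                 edge.length = tree$length[has_par],
                 Nnode = length(internals),
                 tip.label = tree$label[match(tips, tree$node)]),
            class = "phylo", order = "cladewise")
}
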
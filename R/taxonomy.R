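#' Read a species taxonomy from Newick
#'
#' Leaf labels are genome ids; labeled internal nodes define orthology
#' levels. Every label must be unique. Unlabeled internal nodes are
#' tolerated but cannot be requested as levels.
#'
#' @param path Newick file, or a Newick string when `text = TRUE`.
#' @param text interpret `path` as a literal Newick string.
#' @return an object of class `ortho_taxonomy`: the `ape::phylo` tree
#'   plus a named list `levels` mapping each level id to its member
#'   genome ids, and `parent`, the enclosing labeled level of each level.
#' @export
read_taxonomy <- function(path, text = FALSE) {
  tree <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick taxonomy")
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else character(0))
  labels <- labels[nzchar(labels)]
  if (anyDuplicated(labels))
    stop("duplicate label in taxonomy: ", labels[duplicated(labels)][[1L]])
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  node_label <- if (is.null(tree$node.label)) rep("", nnode) else tree$node.label
  levels <- list()
  for (k in seq_len(nnode)) {
    lab <- node_label[[k]]
    if (!nzchar(lab)) next
    tips <- tip_descendants(tree, ntip + k)
    levels[[lab]] <- sort(tree$tip.label[tips])
  }
  parent <- vapply(names(levels), function(lab) {
    node <- ntip + match(lab, node_label)
    anc <- node
    repeat {
      e <- tree$edge[tree$edge[, 2L] == anc, 1L]
      if (length(e) == 0L) return(NA_character_)
      anc <- e
      plab <- node_label[[anc - ntip]]
      if (nzchar(plab)) return(plab)
    }
  }, character(1))
  structure(list(tree = tree, levels = levels, parent = parent,
                 genomes = sort(tree$tip.label)),
            class = "ortho_taxonomy")
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Genomes belonging to a taxonomy level
#' @param taxonomy an `ortho_taxonomy`.
#' @param level_id internal-node label.
#' @return character vector of genome ids under the node.
#' @export
level_genomes <- function(taxonomy, level_id) {
  g <- taxonomy$levels[[level_id]]
  if (is.null(g))
    stop("unknown taxonomy level: ", level_id)
  g
}

#' @export
print.ortho_taxonomy <- function(x, ...) {
  cat("ortho_taxonomy:", length(x$genomes), "genomes,",
      length(x$levels), "labeled levels\n")
  for (lv in names(x$levels))
    cat("  ", lv, ": ", paste(x$levels[[lv]], collapse = ","), "\n", sep = "")
  invisible(x)
}
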
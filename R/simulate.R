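# Synthetic proteomes with known ortholog ground truth: gene families
# evolve down a species tree under a birth-death process (whole-gene
# duplication and loss, Poisson in branch length) with a per-site
# Poisson substitution model. Every labeled internal node doubles as an
# orthology level; the copy present at a level's LCA defines the
# ground-truth group of its extant descendants.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# six genomes, two-three radiations deep; pairwise divergence spans
# roughly 0.4-1.0 expected substitutions/site (~40-70% identity)
DEFAULT_SIM_TREE <- paste0("(((A:0.2,B:0.2)AB:0.15,(C:0.2,D:0.2)CD:0.15)",
                           "ABCD:0.15,(E:0.3,F:0.3)EF:0.2)ROOT;")

#' Simulation configuration
#'
#' @param tree_newick species tree as a Newick string with branch
#'   lengths (expected substitutions per site) and labeled internal
#'   nodes; the default is a six-genome tree with moderate divergence.
#' @param n_families number of independent gene families.
#' @param root_length mean and sd (aa) of the Normal root sequence
#'   length, floored at 50 aa.
#' @param dup_rate,loss_rate whole-gene duplication / loss events per
#'   unit branch length.
#' @param n_shared_domains number of domain identifiers shared between
#'   random family pairs (creates sibling-group structure in the
#'   metadata); each family additionally carries one private domain.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree_newick = DEFAULT_SIM_TREE, n_families = 100L,
                       root_length = c(300, 50), dup_rate = 0.1,
                       loss_rate = 0.05, n_shared_domains = 5L,
                       seed = 42L) {
  stopifnot(n_families >= 1L, dup_rate >= 0, loss_rate >= 0,
            length(root_length) == 2L, root_length[[1L]] > 0)
  structure(list(tree_newick = tree_newick,
                 n_families = as.integer(n_families),
                 root_length = as.numeric(root_length),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 n_shared_domains = as.integer(n_shared_domains),
                 seed = as.integer(seed)),
            class = "sim_config")
}

mutate_seq <- function(res, t) {
  # per site: substituted with prob 1 - exp(-t); replacement drawn
  # uniformly from the 20 residues (may redraw the same one)
  p <- 1 - exp(-t)
  hit <- runif(length(res)) < p
  if (any(hit)) res[hit] <- sample(AA20, sum(hit), replace = TRUE)
  res
}

#' Simulate proteomes with ortholog ground truth
#'
#' Per family one root sequence is drawn i.i.d. uniform over the 20
#' residues and evolved down the tree. Along each branch of length t a
#' lineage is lost with one or more Poisson(loss_rate * t) loss events,
#' otherwise it yields 1 + Poisson(dup_rate * t) copies, each mutated
#' independently over the branch. Exon counts are drawn once per family
#' (uniform 1..10) and inherited unchanged. Every lineage passing a
#' labeled internal node records which gene copy it descends from at
#' that node; that record is the ortholog ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `ortho_sim`: `genes` (gene table with
#'   sequences), `metadata` (lengths, exon counts, domains), `truth`
#'   (`level_id, family_group_id, gene_id`), `taxonomy`
#'   (an `ortho_taxonomy`), and the `config`.
#' @export
simulate_proteomes <- function(config = sim_config()) {
  taxonomy <- read_taxonomy(config$tree_newick, text = TRUE)
  tree <- taxonomy$tree
  if (is.null(tree$edge.length))
    stop("simulation tree must have branch lengths")
  set.seed(config$seed)
  ntip <- length(tree$tip.label)
  node_label <- tree$node.label %||% rep("", tree$Nnode)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  genes <- list()
  truth_rows <- list()
  gene_counter <- new.env(parent = emptyenv())

  for (fam in seq_len(config$n_families)) {
    L <- max(50L, round(rnorm(1, config$root_length[[1L]],
                              config$root_length[[2L]])))
    root_seq <- sample(AA20, L, replace = TRUE)
    exon_n <- sample.int(10L, 1L)
    copy_counter <- 0L
    # depth-first descent; each frame carries the surviving lineages
    descend <- function(node, lineages) {
      if (length(lineages) == 0L) return(invisible(NULL))
      if (node > ntip) {
        lab <- node_label[[node - ntip]]
        if (nzchar(lab)) {
          for (k in seq_along(lineages)) {
            copy_counter <<- copy_counter + 1L
            lineages[[k]]$anc[[lab]] <- copy_counter
          }
        }
        for (ei in children[[as.character(node)]]) {
          child <- tree$edge[ei, 2L]
          t <- tree$edge.length[[ei]]
          nxt <- list()
          for (ln in lineages) {
            if (rpois(1L, config$loss_rate * t) > 0L) next
            n_copies <- 1L + rpois(1L, config$dup_rate * t)
            for (cp in seq_len(n_copies)) {
              nxt[[length(nxt) + 1L]] <-
                list(seq = mutate_seq(ln$seq, t), anc = ln$anc)
            }
          }
          descend(child, nxt)
        }
      } else {
        tip <- tree$tip.label[[node]]
        key <- paste0(tip, ".", fam)
        for (ln in lineages) {
          idx <- (gene_counter[[key]] %||% 0L) + 1L
          assign(key, idx, envir = gene_counter)
          gid <- sprintf("%s_f%03d_%d", tip, fam, idx)
          genes[[length(genes) + 1L]] <<- list(
            gene_id = gid, genome_id = tip,
            sequence = paste(ln$seq, collapse = ""),
            family = fam, exon_count = exon_n, anc = ln$anc)
        }
      }
      invisible(NULL)
    }
    root_lineage <- list(list(seq = root_seq, anc = list()))
    descend(ntip + 1L, root_lineage)
  }

  gene_tab <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    genome_id = vapply(genes, `[[`, character(1), "genome_id"),
    sequence = vapply(genes, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  gene_tab$protein_length <- nchar(gene_tab$sequence)
  gene_tab$family <- vapply(genes, `[[`, integer(1), "family")
  ord <- order(gene_tab$genome_id, gene_tab$gene_id)
  gene_tab <- gene_tab[ord, , drop = FALSE]
  genes <- genes[ord]
  rownames(gene_tab) <- NULL

  # ground truth per labeled level: genes grouped by the copy id their
  # lineage carried at the level's node
  for (lv in names(taxonomy$levels)) {
    gms <- taxonomy$levels[[lv]]
    in_level <- gene_tab$genome_id %in% gms
    anc_ids <- vapply(genes, function(g)
      as.integer(g$anc[[lv]] %||% NA_integer_), integer(1))
    sel <- which(in_level & !is.na(anc_ids))
    if (length(sel) == 0L) next
    truth_rows[[lv]] <- data.frame(
      level_id = lv,
      family_group_id = sprintf("F%03d_%s_c%d",
                                gene_tab$family[sel], lv, anc_ids[sel]),
      gene_id = gene_tab$gene_id[sel], stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$level_id, truth$family_group_id,
                       truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL

  # metadata: one private domain per family, plus shared domains linking
  # random family pairs so sibling-group detection has structure
  fam_domains <- lapply(seq_len(config$n_families), function(f)
    sprintf("DOMF%03d", f))
  if (config$n_shared_domains > 0L && config$n_families >= 2L) {
    for (k in seq_len(config$n_shared_domains)) {
      pair <- sample.int(config$n_families, 2L)
      for (f in pair)
        fam_domains[[f]] <- c(fam_domains[[f]], sprintf("DOMSH%03d", k))
    }
  }
  exon_counts <- vapply(genes, `[[`, integer(1), "exon_count")
  metadata <- data.frame(
    gene_id = gene_tab$gene_id, genome_id = gene_tab$genome_id,
    protein_length = gene_tab$protein_length,
    exon_count = exon_counts,
    domains = vapply(gene_tab$family, function(f)
      paste(fam_domains[[f]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  structure(list(genes = gene_tab, metadata = metadata, truth = truth,
                 taxonomy = taxonomy, config = config),
            class = "ortho_sim")
}

#' Ground-truth partition at one level
#'
#' Groups are the extant descendants of each gene copy present at the
#' level's LCA, restricted to genomes under the level. A family
#' duplicated before the LCA therefore yields several groups at that
#' level but a single group at older levels.
#'
#' @param sim an `ortho_sim`.
#' @param level_id a labeled level of the simulated taxonomy.
#' @return a [partition()] whose universe is every simulated gene in the
#'   level's genomes.
#' @export
truth_at_level <- function(sim, level_id) {
  gms <- level_genomes(sim$taxonomy, level_id)
  tr <- sim$truth[sim$truth$level_id == level_id, , drop = FALSE]
  universe <- sim$genes$gene_id[sim$genes$genome_id %in% gms]
  partition(split(tr$gene_id, tr$family_group_id), universe)
}

#' Write simulation outputs to a directory
#'
#' Produces one FASTA per genome, `meta.tsv`, `truth.tsv` and
#' `tree.nwk`.
#'
#' @param sim an `ortho_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gm in sort(unique(sim$genes$genome_id))) {
    g <- sim$genes[sim$genes$genome_id == gm, , drop = FALSE]
    lines <- as.vector(rbind(paste0(">", g$gene_id), g$sequence))
    writeLines(lines, file.path(dir, paste0(gm, ".fasta")))
  }
  write_metadata_tsv(sim$metadata, file.path(dir, "meta.tsv"))
  write_pipeline_tsv(sim$truth, file.path(dir, "truth.tsv"),
                     c("level_id", "family_group_id", "gene_id"))
  writeLines(ape::write.tree(sim$taxonomy$tree), file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Read a simulation truth table back
#' @param path `truth.tsv` written by [write_simulation()].
#' @return `data.frame` with `level_id, family_group_id, gene_id`.
#' @export
read_truth_tsv <- function(path) {
  read_pipeline_tsv(path, c("level_id", "family_group_id", "gene_id"))
}

#' @export
print.ortho_sim <- function(x, ...) {
  cat("ortho_sim:", nrow(x$genes), "genes,",
      x$config$n_families, "families,",
      length(x$taxonomy$genomes), "genomes\n")
  invisible(x)
}
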
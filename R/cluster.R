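# Ortholog delineation: best reciprocal hits between genomes, in-paralog
# detection within genomes, then triangulation clustering into groups,
# re-run independently at every requested taxonomy level.

# one row per ordered gene pair: when external hits files carry
# duplicates, keep the strongest (then most identical) hit
dedupe_hits <- function(hits) {
  hits <- as.data.table(hits)
  setorder(hits, query_id, subject_id, -raw_score, -pct_identity)
  unique(hits, by = c("query_id", "subject_id"))
}

#' Best reciprocal hits between two genomes
#'
#' A gene's best-hit set against a partner genome is every partner gene
#' attaining its maximal raw score (ties kept). An undirected edge
#' (a, b) is emitted iff b is in a's best-hit set and a is in b's.
#' The edge score is the minimum of the two directed raw scores, the
#' edge identity the mean of the two directed percent identities.
#'
#' @param hits directed hits table (hits-TSV columns).
#' @param gene2genome named character vector mapping gene_id to
#'   genome_id.
#' @param genome_a,genome_b the genome pair.
#' @return `data.table` of BRH edges: `gene_a, gene_b` (gene_a < gene_b),
#'   `genome_a, genome_b`, `score`, `identity`.
#' @export
best_reciprocal_hits <- function(hits, gene2genome, genome_a, genome_b) {
  e <- brh_edges(hits, gene2genome, c(genome_a, genome_b))
  keep <- (e$genome_a == genome_a & e$genome_b == genome_b) |
    (e$genome_a == genome_b & e$genome_b == genome_a)
  e[which(keep)]
}

#' Best reciprocal hits over all genome pairs of a level
#'
#' @param hits directed hits table.
#' @param gene2genome named gene_id -> genome_id map.
#' @param genomes genomes of the level; hits outside are ignored.
#' @return `data.table` of BRH edges (see [best_reciprocal_hits()]).
#' @export
brh_edges <- function(hits, gene2genome, genomes) {
  empty <- data.table(gene_a = character(0), gene_b = character(0),
                      genome_a = character(0), genome_b = character(0),
                      score = integer(0), identity = numeric(0))
  if (nrow(hits) == 0L) return(empty)
  h <- dedupe_hits(hits)
  h[, `:=`(gq = unname(gene2genome[query_id]),
           gs = unname(gene2genome[subject_id]))]
  h <- h[!is.na(gq) & !is.na(gs) & gq %in% genomes & gs %in% genomes &
           gq != gs]
  if (nrow(h) == 0L) return(empty)
  h[, best := max(raw_score), by = .(query_id, gs)]
  b <- h[raw_score == best]
  fwd <- b[, .(query_id, subject_id, raw_score, pct_identity)]
  rev <- b[, .(query_id = subject_id, subject_id = query_id,
               raw_score_rev = raw_score, pct_identity_rev = pct_identity)]
  e <- merge(fwd, rev, by = c("query_id", "subject_id"))
  e <- e[query_id < subject_id]
  if (nrow(e) == 0L) return(empty)
  out <- data.table(gene_a = e$query_id, gene_b = e$subject_id,
                    genome_a = unname(gene2genome[e$query_id]),
                    genome_b = unname(gene2genome[e$subject_id]),
                    score = pmin(e$raw_score, e$raw_score_rev),
                    identity = (e$pct_identity + e$pct_identity_rev) / 2)
  setorder(out, gene_a, gene_b)
  out[]
}

#' In-paralog (co-ortholog) links within one genome
#'
#' An intra-genome pair more similar than the best reciprocal matches
#' across the level's deepest radiation represents a duplication after
#' the level's speciation point. Writing T(x) for gene x's weakest
#' per-genome best-BRH score -- the minimum over partner genomes of the
#' maximal BRH edge score between x and that genome, +Inf when x has no
#' BRH edge at all, so that BRH-less genes never recruit in-paralogs --
#' a link is emitted for pair (g, h) with intra score s iff
#' s > min(T(g), T(h)). The min over genomes (rather than the max)
#' makes T measure similarity across the oldest speciation of the
#' level: a duplication predating a child level's LCA but postdating an
#' ancestral one is then linked at the ancestral level only, which is
#' exactly the level-dependence co-orthology requires. The lower-T gene
#' is reported as `gene`, the other as `anchor` (ties resolved
#' lexicographically).
#'
#' @param hits directed hits table (must include intra-genome hits).
#' @param brh BRH edge table for the level (see [brh_edges()]).
#' @param gene2genome named gene_id -> genome_id map.
#' @param genome the genome to scan.
#' @return `data.table` with columns `gene`, `anchor`, `score`.
#' @export
in_paralogs <- function(hits, brh, gene2genome, genome) {
  empty <- data.table(gene = character(0), anchor = character(0),
                      score = integer(0))
  h <- dedupe_hits(hits)
  h[, `:=`(gq = unname(gene2genome[query_id]),
           gs = unname(gene2genome[subject_id]))]
  h <- h[gq == genome & gs == genome]
  if (nrow(h) == 0L) return(empty)
  pairs <- h[, .(score = max(raw_score)),
             by = .(g = pmin(query_id, subject_id),
                    p = pmax(query_id, subject_id))]
  # T(x): per partner genome take the best BRH score, then the weakest
  # genome; Inf for genes with no BRH edge
  long <- data.table(gene = c(brh$gene_a, brh$gene_b),
                     partner = c(brh$genome_b, brh$genome_a),
                     score = c(brh$score, brh$score))
  tmin <- numeric(0)
  if (nrow(long)) {
    per <- long[, .(best = max(score)), by = .(gene, partner)]
    tv <- per[, .(t = min(best)), by = gene]
    tmin <- setNames(tv$t, tv$gene)
  }
  tof <- function(x) {
    v <- tmin[x]
    ifelse(is.na(v), Inf, v)
  }
  tg <- tof(pairs$g); tp <- tof(pairs$p)
  thr <- pmin(tg, tp)
  keep <- pairs$score > thr
  pairs <- pairs[keep]; tg <- tg[keep]; tp <- tp[keep]
  if (nrow(pairs) == 0L) return(empty)
  gene_is_g <- tg < tp | (tg == tp & pairs$g < pairs$p)
  out <- data.table(gene = ifelse(gene_is_g, pairs$g, pairs$p),
                    anchor = ifelse(gene_is_g, pairs$p, pairs$g),
                    score = pairs$score)
  setorder(out, -score, gene, anchor)
  out[]
}

# deterministic edge ordering used by the stage machine
order_edges <- function(brh) {
  brh[order(-brh$score, brh$gene_a, brh$gene_b), , drop = FALSE]
}

#' Triangulate and cluster BRH edges and in-paralog links into groups
#'
#' The staged procedure: (1) every BRH triangle (three genes in three
#' genomes with all three pairwise edges) seeds or merges a cluster;
#' clusters are the connected components of the triangle-edge subgraph.
#' (2) Each remaining (non-triangle) BRH edge, visited by descending
#' score, attaches its free endpoint(s) to a touched cluster, forms a
#' new two-gene group when it touches none, and is recorded as
#' unverified -- without merging -- when it bridges two clusters.
#' (3) In-paralog links, by descending score and transitively, attach
#' their ungrouped endpoint to the grouped endpoint's cluster, and merge
#' two clusters when a link bridges them (unlike the unverified BRH
#' edges of stage 2, in-paralog links are corroborated by the threshold
#' test, so they are trusted to join co-ortholog clusters).
#' (4) Absorbed near-identical copies are re-expanded into their
#' representative's group. `closure = "naive"` replaces stages 1-2 with
#' plain connected components of the BRH graph, for comparison.
#'
#' @param brh BRH edge table for the level.
#' @param in_links in-paralog link table (may be empty).
#' @param level_id label of the level (used in og ids).
#' @param gene2genome named gene_id -> genome_id map.
#' @param expansion optional collapse expansion map (`genome_id,
#'   representative_id, absorbed_id`).
#' @param closure `"triangulate"` (default) or `"naive"`.
#' @return `data.frame` of cluster rows `level_id, og_id, gene_id,
#'   genome_id`, carrying the unverified bridge edges in
#'   `attr(, "unverified_edges")`.
#' @export
triangulate_and_cluster <- function(brh, in_links = NULL, level_id = "ROOT",
                                    gene2genome = NULL, expansion = NULL,
                                    closure = c("triangulate", "naive")) {
  closure <- match.arg(closure)
  brh <- as.data.frame(brh)
  membership <- new.env(hash = TRUE, parent = emptyenv())
  clusters <- list()
  unverified <- character(0)
  assign_gene <- function(gene, ci) {
    clusters[[ci]] <<- c(clusters[[ci]], gene)
    assign(gene, ci, envir = membership)
  }
  cl_of <- function(gene) membership[[gene]]

  if (nrow(brh) > 0L && closure == "naive") {
    g <- igraph::graph_from_data_frame(brh[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      members <- sort(names(comp$membership)[comp$membership == ci])
      clusters[[length(clusters) + 1L]] <- character(0)
      for (m in members) assign_gene(m, length(clusters))
    }
  } else if (nrow(brh) > 0L) {
    ekey <- paste(brh$gene_a, brh$gene_b)
    g <- igraph::graph_from_data_frame(brh[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    tri <- igraph::triangles(g)
    in_triangle <- rep(FALSE, nrow(brh))
    if (length(tri)) {
      tm <- matrix(igraph::V(g)$name[tri], ncol = 3L, byrow = TRUE)
      tri_edges <- unique(c(
        paste(pmin(tm[, 1L], tm[, 2L]), pmax(tm[, 1L], tm[, 2L])),
        paste(pmin(tm[, 1L], tm[, 3L]), pmax(tm[, 1L], tm[, 3L])),
        paste(pmin(tm[, 2L], tm[, 3L]), pmax(tm[, 2L], tm[, 3L]))))
      in_triangle <- ekey %in% tri_edges
      # stage 1: components of the triangle-edge subgraph
      tg <- igraph::graph_from_data_frame(
        brh[in_triangle, c("gene_a", "gene_b")], directed = FALSE)
      comp <- igraph::components(tg)
      for (ci in seq_len(comp$no)) {
        members <- sort(names(comp$membership)[comp$membership == ci])
        clusters[[length(clusters) + 1L]] <- character(0)
        for (m in members) assign_gene(m, length(clusters))
      }
    }
    # stage 2: remaining edges, strongest first
    rest <- order_edges(brh[!in_triangle, , drop = FALSE])
    for (k in seq_len(nrow(rest))) {
      a <- rest$gene_a[[k]]; b <- rest$gene_b[[k]]
      ca <- cl_of(a); cb <- cl_of(b)
      if (is.null(ca) && is.null(cb)) {
        clusters[[length(clusters) + 1L]] <- character(0)
        assign_gene(a, length(clusters)); assign_gene(b, length(clusters))
      } else if (is.null(cb)) {
        assign_gene(b, ca)
      } else if (is.null(ca)) {
        assign_gene(a, cb)
      } else if (ca != cb) {
        unverified <- c(unverified, paste(a, b))
      }
    }
  }
  # stage 3: in-paralog attachment, strongest link first, to a fixpoint
  if (!is.null(in_links) && nrow(in_links) > 0L) {
    il <- as.data.frame(in_links)
    il <- il[order(-il$score, il$gene, il$anchor), , drop = FALSE]
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(il))) {
        gn <- il$gene[[k]]; an <- il$anchor[[k]]
        cg <- cl_of(gn); ca <- cl_of(an)
        if (is.null(cg) && !is.null(ca)) {
          assign_gene(gn, ca); changed <- TRUE
        } else if (!is.null(cg) && is.null(ca)) {
          assign_gene(an, cg); changed <- TRUE
        } else if (!is.null(cg) && !is.null(ca) && cg != ca) {
          for (m in clusters[[cg]]) assign(m, ca, envir = membership)
          clusters[[ca]] <- c(clusters[[ca]], clusters[[cg]])
          clusters[[cg]] <- character(0)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # stage 4: re-expand collapsed near-identical copies
  if (!is.null(expansion) && nrow(expansion) > 0L) {
    for (k in seq_len(nrow(expansion))) {
      rep_id <- expansion$representative_id[[k]]
      ab <- expansion$absorbed_id[[k]]
      cr <- cl_of(rep_id)
      if (!is.null(cr) && is.null(cl_of(ab))) assign_gene(ab, cr)
    }
  }
  clusters <- lapply(clusters, sort)
  clusters <- clusters[lengths(clusters) > 0L]
  og_ids <- assign_og_ids(clusters, level_id)
  out <- data.frame(
    level_id = rep(level_id, sum(lengths(clusters))),
    og_id = rep(og_ids, lengths(clusters)),
    gene_id = unlist(clusters) %||% character(0),
    stringsAsFactors = FALSE)
  out$genome_id <- if (is.null(gene2genome)) NA_character_ else
    unname(gene2genome[out$gene_id])
  out <- out[order(out$og_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unverified_edges") <- unverified
  out
}

#' Delineate orthologous groups at each requested taxonomy level
#'
#' Each level is computed independently on the hits restricted to its
#' genomes: BRH detection, in-paralog identification and triangulation
#' clustering are all re-run per level, because best-hit sets and
#' in-paralog thresholds change with the species set.
#'
#' @param hits directed hits table over gene representatives.
#' @param genes gene table (`gene_id`, `genome_id`).
#' @param taxonomy an [read_taxonomy()] object.
#' @param levels character vector of level ids; default all labeled
#'   levels.
#' @param expansion optional collapse expansion map.
#' @param closure clustering closure mode, see
#'   [triangulate_and_cluster()].
#' @return `data.frame` of cluster rows across levels, sorted by
#'   `(level_id, og_id, gene_id)`.
#' @export
cluster_all_levels <- function(hits, genes, taxonomy,
                               levels = names(taxonomy$levels),
                               expansion = NULL,
                               closure = c("triangulate", "naive")) {
  closure <- match.arg(closure)
  gene2genome <- setNames(genes$genome_id, genes$gene_id)
  hits <- as.data.table(hits)
  per_level <- lapply(levels, function(lv) {
    gms <- level_genomes(taxonomy, lv)
    if (length(gms) < 2L)
      stop("level ", lv, " has fewer than 2 genomes")
    keep <- genes$gene_id[genes$genome_id %in% gms]
    if (!is.null(expansion) && nrow(expansion))
      keep <- setdiff(keep, expansion$absorbed_id)
    h <- hits[query_id %in% keep & subject_id %in% keep]
    brh <- brh_edges(h, gene2genome, gms)
    il <- rbindlist(lapply(sort(gms), function(gm)
      in_paralogs(h, brh, gene2genome, gm)))
    exp_lv <- if (is.null(expansion)) NULL else
      expansion[expansion$genome_id %in% gms, , drop = FALSE]
    triangulate_and_cluster(brh, il, lv, gene2genome, exp_lv, closure)
  })
  out <- do.call(rbind, per_level)
  out <- out[order(out$level_id, out$og_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of genes assigned to an orthologous group at a level
#'
#' @param clusters cluster table (one level's rows are selected).
#' @param genes gene table for the genomes of the level.
#' @param level_id the level.
#' @return fraction in `[0, 1]`.
#' @export
fraction_clustered <- function(clusters, genes, level_id) {
  cl <- clusters[clusters$level_id == level_id, , drop = FALSE]
  length(unique(cl$gene_id)) / nrow(genes)
}
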
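# Independent reference implementations used as oracles. These are
# deliberately written with different data structures and control flow
# than the package code they check.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n) paste(sample(AA20_TEST, n, TRUE), collapse = "")

# naive full-matrix affine-gap local alignment, scores only; gap of
# length L costs go + L * ge
naive_sw_score <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# build a directed hits table; coordinates default to full-length spans
make_hits <- function(q, s, score, ident = 90, alen = NULL, lens = NULL) {
  n <- length(q)
  if (n == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = integer(0), pct_identity = numeric(0),
                      aln_len = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), stringsAsFactors = FALSE))
  if (is.null(alen)) alen <- rep(100L, n)
  ident <- rep_len(ident, n)
  qlen <- if (is.null(lens)) alen else unname(lens[q])
  slen <- if (is.null(lens)) alen else unname(lens[s])
  data.frame(query_id = q, subject_id = s, raw_score = as.integer(score),
             pct_identity = ident, aln_len = as.integer(alen),
             q_start = 1L, q_end = as.integer(qlen),
             s_start = 1L, s_end = as.integer(slen),
             stringsAsFactors = FALSE)
}

# symmetric directed hits for a set of undirected scored pairs
make_sym_hits <- function(a, b, score, ident = 90, alen = NULL, lens = NULL) {
  rbind(make_hits(a, b, score, ident, alen, lens),
        make_hits(b, a, score, ident, alen, lens))
}

# --- brute-force reference for the clustering stage machine ------------
# membership vector + explicit relabeling; triangles by triple loop over
# gene combinations
oracle_stage_machine <- function(brh, il) {
  brh <- as.data.frame(brh)
  il <- if (is.null(il)) data.frame(gene = character(0),
                                    anchor = character(0),
                                    score = numeric(0)) else as.data.frame(il)
  genes <- sort(unique(c(brh$gene_a, brh$gene_b, il$gene, il$anchor)))
  memb <- setNames(rep(NA_integer_, length(genes)), genes)
  next_id <- 0L
  merge_into <- function(from, to) {
    memb[!is.na(memb) & memb == from] <<- to
  }
  put <- function(g, id) memb[g] <<- id
  ekey <- character(0)
  if (nrow(brh))
    ekey <- paste(pmin(brh$gene_a, brh$gene_b), pmax(brh$gene_a, brh$gene_b))
  has_edge <- function(x, y) paste(min(x, y), max(x, y)) %in% ekey
  tri_edges <- character(0)
  if (length(genes) >= 3 && nrow(brh) >= 3) {
    cmb <- utils::combn(genes, 3)
    for (k in seq_len(ncol(cmb))) {
      u <- cmb[1, k]; v <- cmb[2, k]; w <- cmb[3, k]
      if (has_edge(u, v) && has_edge(u, w) && has_edge(v, w))
        tri_edges <- c(tri_edges, paste(u, v), paste(u, w), paste(v, w))
    }
  }
  tri_edges <- unique(tri_edges)
  # stage 1: closure over triangle edges
  if (nrow(brh)) {
    for (k in seq_len(nrow(brh))) {
      if (!(ekey[k] %in% tri_edges)) next
      a <- brh$gene_a[k]; b <- brh$gene_b[k]
      ca <- memb[[a]]; cb <- memb[[b]]
      if (is.na(ca) && is.na(cb)) {
        next_id <- next_id + 1L; put(a, next_id); put(b, next_id)
      } else if (is.na(cb)) put(b, ca)
      else if (is.na(ca)) put(a, cb)
      else if (ca != cb) merge_into(cb, ca)
    }
  }
  # stage 2: remaining edges by descending score then lexicographic
  rest <- brh[!(ekey %in% tri_edges), , drop = FALSE]
  rest <- rest[order(-rest$score, rest$gene_a, rest$gene_b), , drop = FALSE]
  for (k in seq_len(nrow(rest))) {
    a <- rest$gene_a[k]; b <- rest$gene_b[k]
    ca <- memb[[a]]; cb <- memb[[b]]
    if (is.na(ca) && is.na(cb)) {
      next_id <- next_id + 1L; put(a, next_id); put(b, next_id)
    } else if (is.na(cb)) put(b, ca)
    else if (is.na(ca)) put(a, cb)
    # two different clusters: unverified, no merge
  }
  # stage 3: in-paralog links, strongest first, to fixpoint; bridging
  # links merge
  il <- il[order(-il$score, il$gene, il$anchor), , drop = FALSE]
  repeat {
    moved <- FALSE
    for (k in seq_len(nrow(il))) {
      g <- il$gene[k]; a <- il$anchor[k]
      cg <- memb[[g]]; ca <- memb[[a]]
      if (is.na(cg) && !is.na(ca)) { put(g, ca); moved <- TRUE }
      else if (!is.na(cg) && is.na(ca)) { put(a, cg); moved <- TRUE }
      else if (!is.na(cg) && !is.na(ca) && cg != ca) {
        merge_into(cg, ca); moved <- TRUE
      }
    }
    if (!moved) break
  }
  out <- split(names(memb)[!is.na(memb)], memb[!is.na(memb)])
  canonical_groups(out)
}

# canonical form of a grouping: sorted list of sorted member vectors
canonical_groups <- function(groups) {
  groups <- lapply(groups, sort)
  groups <- groups[lengths(groups) > 0]
  unname(groups[order(vapply(groups, `[[`, character(1), 1))])
}

groups_from_table <- function(cl, level) {
  canonical_groups(split(cl$gene_id[cl$level_id == level],
                         cl$og_id[cl$level_id == level]))
}

# random clustering instance: 3-4 genomes, <= 12 genes, random
# inter-genome BRH edges and intra-genome in-paralog links
random_instance <- function() {
  n_genomes <- sample(3:4, 1)
  genomes <- LETTERS[seq_len(n_genomes)]
  genes <- character(0)
  for (gm in genomes) {
    k <- sample(1:4, 1)
    genes <- c(genes, paste0(gm, seq_len(k)))
  }
  genes <- head(genes, 12)
  gm_of <- substr(genes, 1, 1)
  pairs <- utils::combn(genes, 2)
  inter <- pairs[, gm_of[match(pairs[1, ], genes)] !=
                   gm_of[match(pairs[2, ], genes)], drop = FALSE]
  intra <- pairs[, gm_of[match(pairs[1, ], genes)] ==
                   gm_of[match(pairs[2, ], genes)], drop = FALSE]
  pick <- function(m, p) m[, runif(ncol(m)) < p, drop = FALSE]
  e <- pick(inter, 0.45)
  brh <- data.frame(gene_a = pmin(e[1, ], e[2, ]),
                    gene_b = pmax(e[1, ], e[2, ]),
                    genome_a = gm_of[match(pmin(e[1, ], e[2, ]), genes)],
                    genome_b = gm_of[match(pmax(e[1, ], e[2, ]), genes)],
                    score = sample(50:500, ncol(e), TRUE),
                    identity = runif(ncol(e), 30, 100),
                    stringsAsFactors = FALSE)
  li <- pick(intra, 0.3)
  il <- data.frame(gene = li[1, ] %||% character(0),
                   anchor = li[2, ] %||% character(0),
                   score = sample(50:500, ncol(li), TRUE),
                   stringsAsFactors = FALSE)
  list(brh = brh, il = il)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# --- VI oracle: entropies from a membership contingency table ---------
membership_of <- function(p) {
  blocks <- p$blocks
  assigned <- unlist(blocks)
  singles <- setdiff(p$universe, assigned)
  lab <- c(rep(names(blocks), lengths(blocks)),
           paste0("s", seq_along(singles)))
  setNames(lab, c(assigned, singles))[p$universe]
}

vi_oracle <- function(px, py, base = 2) {
  mx <- membership_of(px); my <- membership_of(py)
  tab <- table(mx, my)
  n <- sum(tab)
  hx <- -sum((rowSums(tab) / n) * log(rowSums(tab) / n, base))
  hy <- -sum((colSums(tab) / n) * log(colSums(tab) / n, base))
  p <- tab / n
  hxy <- -sum(p[p > 0] * log(p[p > 0], base))
  2 * hxy - hx - hy   # VI = H(X,Y) - I = H(X)+H(Y)-2I = 2H(X,Y)-H(X)-H(Y)
}

random_partition_of <- function(universe, max_blocks = 5) {
  k <- sample(seq_len(max_blocks), 1)
  memb <- sample(seq_len(k), length(universe), TRUE)
  partition(split(universe, memb), universe)
}

# small deterministic simulation shared by several tests
cached_sim <- local({
  cache <- new.env()
  function(key = "clean20") {
    if (!is.null(cache[[key]])) return(cache[[key]])
    sim <- switch(key,
      clean20 = {
        s <- simulate_proteomes(sim_config(n_families = 20L, dup_rate = 0,
                                           loss_rate = 0, seed = 42L))
        h <- all_vs_all(s$genes)
        list(sim = s, hits = h)
      },
      duploss20 = {
        s <- simulate_proteomes(sim_config(n_families = 20L, seed = 7L))
        h <- all_vs_all(s$genes)
        list(sim = s, hits = h)
      },
      clean100 = {
        s <- simulate_proteomes(sim_config(n_families = 100L, dup_rate = 0,
                                           loss_rate = 0, seed = 42L))
        h <- all_vs_all(s$genes)
        list(sim = s, hits = h)
      },
      duploss100 = {
        s <- simulate_proteomes(sim_config(n_families = 100L, seed = 42L))
        h <- all_vs_all(s$genes)
        list(sim = s, hits = h)
      },
      stop("unknown sim key"))
    cache[[key]] <- sim
    sim
  }
})
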
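# Evolutionary annotations of orthologous groups: phyletic profiles
# (universality / duplicability / copy-number class), BRH-normalized
# evolutionary rates, gene architecture statistics and sibling groups.

#' Phyletic profile and copy-number summary of one group
#'
#' The profile counts group members per genome over all genomes of the
#' level (zero for absent genomes). Universality is the fraction of
#' level genomes with at least one member; duplicability the fraction of
#' *present* genomes with at least two (duplicate retention is
#' conditional on presence). The copy-number class is
#' `single_copy_in_all` when every genome has exactly one member,
#' `multi_copy_in_all` when every genome has two or more,
#' `present_in_all` when every genome has at least one, else `patchy`.
#'
#' @param member_genomes character vector: genome of each group member
#'   (one entry per gene, repeats allowed).
#' @param genomes all genomes of the level.
#' @return list with `counts` (named integer vector over `genomes`),
#'   `universality`, `duplicability`, `copy_number_class`.
#' @export
phyletic_profile <- function(member_genomes, genomes) {
  if (length(member_genomes) == 0L) stop("empty group")
  unknown <- setdiff(member_genomes, genomes)
  if (length(unknown))
    stop("group member genome outside the level: ", unknown[[1L]])
  counts <- table(factor(member_genomes, levels = sort(genomes)))
  counts <- setNames(as.integer(counts), names(counts))
  present <- sum(counts >= 1L)
  universality <- present / length(genomes)
  duplicability <- if (present == 0L) 0 else sum(counts >= 2L) / present
  cls <- if (all(counts == 1L)) "single_copy_in_all"
  else if (all(counts >= 2L)) "multi_copy_in_all"
  else if (all(counts >= 1L)) "present_in_all"
  else "patchy"
  list(counts = counts, universality = universality,
       duplicability = duplicability, copy_number_class = cls)
}

#' Mean BRH identity per genome pair (evolutionary-rate baseline)
#'
#' @param brh BRH edge table for the level (see [brh_edges()]).
#' @return `data.table` with `genome_a, genome_b` (sorted within pair)
#'   and `baseline` = mean BRH edge identity.
#' @export
brh_baseline <- function(brh) {
  if (nrow(brh) == 0L)
    return(data.table(genome_a = character(0), genome_b = character(0),
                      baseline = numeric(0)))
  b <- as.data.table(brh)
  b[, .(baseline = mean(identity)),
    by = .(genome_a = pmin(genome_a, genome_b),
           genome_b = pmax(genome_a, genome_b))]
}

#' Relative evolutionary rate of a group
#'
#' The mean, over all inter-species member pairs with a stored
#' alignment, of the pair's percent identity divided by the mean
#' identity of all BRH edges between the same two genomes at this level.
#' 1.0 therefore marks the lineage-average divergence; lower values mean
#' faster-than-average sequence evolution of the group. Pairs whose
#' genome pair has no BRH baseline are skipped; `NA` when no pair
#' qualifies.
#'
#' @param members gene ids of the group.
#' @param gene2genome named gene_id -> genome_id map.
#' @param hits directed hits table (stored alignments).
#' @param baseline output of [brh_baseline()].
#' @return a single number, or `NA_real_`.
#' @export
evolutionary_rate <- function(members, gene2genome, hits, baseline) {
  h <- dedupe_hits(hits)
  h <- h[query_id %in% members & subject_id %in% members]
  if (nrow(h) == 0L) return(NA_real_)
  h[, `:=`(gq = unname(gene2genome[query_id]),
           gs = unname(gene2genome[subject_id]))]
  h <- h[gq != gs]
  if (nrow(h) == 0L) return(NA_real_)
  # one identity per unordered pair: mean of the stored directions
  p <- h[, .(ident = mean(pct_identity),
             genome_a = pmin(gq[1L], gs[1L]), genome_b = pmax(gq[1L], gs[1L])),
         by = .(a = pmin(query_id, subject_id),
                b = pmax(query_id, subject_id))]
  p <- merge(p, baseline, by = c("genome_a", "genome_b"))
  if (nrow(p) == 0L) return(NA_real_)
  mean(p$ident / p$baseline)
}

#' Gene architecture statistics of a group
#'
#' Medians and population standard deviations (n denominator, so a
#' single-member group has sd 0) of protein length and exon count over
#' members with data. Members whose length deviates from the median by
#' more than `k` spreads are flagged as deviants -- indicative of
#' inaccurate gene models -- but never removed. `method = "sd"` uses the
#' population SD as the spread (floored at 1 aa); `method = "mad"` uses
#' the median absolute deviation scaled by 1.4826, which keeps single
#' large outliers from inflating their own threshold.
#'
#' @param lengths integer protein lengths of the members.
#' @param exons integer exon counts (`NA` allowed), parallel to
#'   `lengths`; may be `NULL`.
#' @param gene_ids member ids, parallel to `lengths`.
#' @param k deviation multiplier (default 3).
#' @param method `"sd"` or `"mad"`.
#' @return list with `length_median`, `length_sd`, `exon_median`,
#'   `exon_sd` (both `NA` when no exon data), `deviants` (gene ids).
#' @export
gene_architecture <- function(lengths, exons = NULL, gene_ids = NULL,
                              k = 3, method = c("sd", "mad")) {
  method <- match.arg(method)
  stopifnot(length(lengths) >= 1L)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(lengths))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  lmed <- median(lengths)
  lsd <- pop_sd(lengths)
  spread <- if (method == "sd") max(lsd, 1) else
    max(mad(lengths, constant = 1.4826), 1)
  deviants <- gene_ids[abs(lengths - lmed) > k * spread]
  emed <- esd <- NA_real_
  if (!is.null(exons) && any(!is.na(exons))) {
    e <- exons[!is.na(exons)]
    emed <- median(e)
    esd <- pop_sd(e)
  }
  list(length_median = lmed, length_sd = lsd, exon_median = emed,
       exon_sd = esd, deviants = sort(deviants))
}

#' @importFrom stats mad
NULL

#' Sibling groups by shared domain content
#'
#' Two groups at the same level are siblings when at least one domain
#' identifier is carried, in each group, by genes from at least two
#' distinct genomes. Organisms are counted as genomes, not genes, so a
#' domain present twice in one genome does not qualify.
#'
#' @param clusters one level's cluster table (`og_id, gene_id,
#'   genome_id`).
#' @param metadata metadata table with `gene_id` and `domains`.
#' @return `data.frame` with `group_a, group_b` (group_a < group_b) and
#'   `shared_domains` (semicolon-joined).
#' @export
sibling_groups <- function(clusters, metadata) {
  empty <- data.frame(group_a = character(0), group_b = character(0),
                      shared_domains = character(0), stringsAsFactors = FALSE)
  md <- metadata[match(clusters$gene_id, metadata$gene_id), , drop = FALSE]
  doms <- split_domains(md$domains)
  n <- lengths(doms)
  if (sum(n) == 0L) return(empty)
  long <- data.table(og_id = rep(clusters$og_id, n),
                     genome_id = rep(clusters$genome_id, n),
                     domain = unlist(doms))
  # domains backed by >= 2 genomes within a group
  qual <- unique(long[, .(og_id, genome_id, domain)])
  qual <- qual[, .(n_org = .N), by = .(og_id, domain)][n_org >= 2L]
  if (nrow(qual) == 0L) return(empty)
  pairs <- merge(qual[, .(og_id, domain)], qual[, .(og_id2 = og_id, domain)],
                 by = "domain", allow.cartesian = TRUE)
  pairs <- pairs[og_id < og_id2]
  if (nrow(pairs) == 0L) return(empty)
  out <- pairs[, .(shared_domains = paste(sort(unique(domain)),
                                          collapse = ";")),
               by = .(group_a = og_id, group_b = og_id2)]
  setorder(out, group_a, group_b)
  as.data.frame(out)
}

#' Annotate every group at one level
#'
#' @param clusters cluster table (all levels; rows of `level_id` are
#'   used).
#' @param level_id the level to annotate.
#' @param genomes genomes of the level.
#' @param hits directed hits table.
#' @param brh BRH edge table for the level.
#' @param metadata optional metadata table (lengths, exons, domains).
#' @param deviant_k,deviant_method see [gene_architecture()].
#' @return `data.frame`, one row per group: `og_id`, `n_members`,
#'   `universality`, `duplicability`, `copy_number_class`, `evol_rate`,
#'   `length_median`, `length_sd`, `exon_median`, `exon_sd`, `deviants`,
#'   `siblings` (semicolon-joined og ids).
#' @export
annotate_level <- function(clusters, level_id, genomes, hits, brh,
                           metadata = NULL, deviant_k = 3,
                           deviant_method = "sd") {
  cl <- clusters[clusters$level_id == level_id, , drop = FALSE]
  if (nrow(cl) == 0L)
    return(data.frame(og_id = character(0)))
  gene2genome <- setNames(cl$genome_id, cl$gene_id)
  base <- brh_baseline(brh)
  hits <- as.data.table(hits)
  sib <- if (is.null(metadata)) NULL else sibling_groups(cl, metadata)
  rows <- lapply(split(cl, cl$og_id), function(grp) {
    prof <- phyletic_profile(grp$genome_id, genomes)
    rate <- evolutionary_rate(grp$gene_id, gene2genome, hits, base)
    arch <- list(length_median = NA_real_, length_sd = NA_real_,
                 exon_median = NA_real_, exon_sd = NA_real_,
                 deviants = character(0))
    if (!is.null(metadata)) {
      md <- metadata[metadata$gene_id %in% grp$gene_id, , drop = FALSE]
      if (nrow(md))
        arch <- gene_architecture(md$protein_length, md$exon_count,
                                  md$gene_id, k = deviant_k,
                                  method = deviant_method)
    }
    sibs <- character(0)
    if (!is.null(sib) && nrow(sib))
      sibs <- sort(c(sib$group_b[sib$group_a == grp$og_id[[1L]]],
                     sib$group_a[sib$group_b == grp$og_id[[1L]]]))
    data.frame(og_id = grp$og_id[[1L]], n_members = nrow(grp),
               universality = prof$universality,
               duplicability = prof$duplicability,
               copy_number_class = prof$copy_number_class,
               evol_rate = rate,
               length_median = arch$length_median,
               length_sd = arch$length_sd,
               exon_median = arch$exon_median, exon_sd = arch$exon_sd,
               deviants = paste(arch$deviants, collapse = ";"),
               siblings = paste(sibs, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$og_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Query groups by copy-number profile
#'
#' Either a named class (`"single_copy_in_all"`, `"multi_copy_in_all"`,
#' `"present_in_all"`, `"patchy"`) or a per-genome pattern such as
#' `"A=1,B>=2,C=0"` (operators `=`, `>=`, `<=`).
#'
#' @param clusters cluster table for the level.
#' @param level_id the level.
#' @param genomes genomes of the level.
#' @param query class name or pattern string.
#' @return character vector of matching og ids (possibly empty).
#' @export
query_by_profile <- function(clusters, level_id, genomes, query) {
  cl <- clusters[clusters$level_id == level_id, , drop = FALSE]
  ogs <- sort(unique(cl$og_id))
  profs <- lapply(ogs, function(og)
    phyletic_profile(cl$genome_id[cl$og_id == og], genomes))
  classes <- c("single_copy_in_all", "multi_copy_in_all", "present_in_all",
               "patchy")
  if (query %in% classes) {
    return(ogs[vapply(profs, function(p) p$copy_number_class == query,
                      logical(1))])
  }
  if (!grepl("[=<>]", query))
    stop("unknown profile class: ", query)
  terms <- strsplit(query, ",", fixed = TRUE)[[1L]]
  m <- regmatches(terms, regexec("^\\s*([^=<>]+?)\\s*(>=|<=|=)\\s*(\\d+)\\s*$",
                                 terms))
  if (any(lengths(m) != 4L)) stop("malformed profile pattern: ", query)
  gm <- vapply(m, `[[`, character(1), 2L)
  op <- vapply(m, `[[`, character(1), 3L)
  val <- as.integer(vapply(m, `[[`, character(1), 4L))
  bad <- setdiff(gm, genomes)
  if (length(bad)) stop("unknown genome in pattern: ", bad[[1L]])
  ok <- vapply(profs, function(p) {
    all(mapply(function(g, o, v) {
      cnt <- p$counts[[g]]
      switch(o, "=" = cnt == v, ">=" = cnt >= v, "<=" = cnt <= v)
    }, gm, op, val))
  }, logical(1))
  ogs[ok]
}
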
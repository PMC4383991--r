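# Benchmarking a predicted clustering against a reference clustering:
# per-reference-group precision/recall/F1, a six-way event
# classification (Exact, Akin, Fused, Split, Missed, Complex) and the
# Variation of Information partition distance.

#' Build a partition
#'
#' @param blocks named list of disjoint element sets.
#' @param universe optional universe; elements outside all blocks become
#'   singletons by convention. Defaults to the union of the blocks.
#' @return object of class `partition`: list with `blocks` and
#'   `universe`.
#' @export
partition <- function(blocks, universe = NULL) {
  blocks <- lapply(blocks, function(b) sort(unique(as.character(b))))
  all_el <- unlist(blocks) %||% character(0)
  if (anyDuplicated(all_el))
    stop("partition blocks overlap: ", all_el[duplicated(all_el)][[1L]])
  if (is.null(universe)) universe <- all_el
  universe <- sort(unique(as.character(universe)))
  if (!all(all_el %in% universe))
    stop("block element outside the universe")
  structure(list(blocks = blocks, universe = universe), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", length(x$blocks), "blocks over",
      length(x$universe), "elements\n")
  invisible(x)
}

# blocks plus one singleton per unassigned universe element
complete_blocks <- function(p) {
  assigned <- unlist(p$blocks) %||% character(0)
  singles <- setdiff(p$universe, assigned)
  if (length(singles) == 0L) return(p$blocks)
  c(p$blocks, setNames(as.list(singles), paste0(".single.", singles)))
}

#' Partition from a clusters table
#'
#' @param clusters cluster table (`og_id`/`refog_id` and `gene_id`).
#' @param id_col name of the block-id column.
#' @param universe optional universe of gene ids.
#' @return a [partition()].
#' @export
partition_from_clusters <- function(clusters, id_col = "og_id",
                                    universe = NULL) {
  partition(split(clusters$gene_id, clusters[[id_col]]), universe)
}

#' Restrict a predicted partition to a reference universe
#'
#' Every block is intersected with the universe; empty intersections are
#' dropped and unassigned universe elements become singletons when the
#' partition is completed downstream.
#'
#' @param pred a [partition()].
#' @param ref_universe character vector of reference elements.
#' @return a [partition()] over `ref_universe`.
#' @export
restrict_to_universe <- function(pred, ref_universe) {
  ref_universe <- sort(unique(as.character(ref_universe)))
  blocks <- lapply(pred$blocks, function(b) intersect(b, ref_universe))
  blocks <- blocks[lengths(blocks) > 0L]
  partition(blocks, ref_universe)
}

#' Precision, recall and F1 of one cluster against one reference group
#'
#' precision = |ref n cl| / |cl|, recall = |ref n cl| / |ref|,
#' F1 = 2pr/(p+r) (0 when p + r = 0).
#'
#' @param ref,cluster element sets (character vectors).
#' @return named numeric vector `precision, recall, f1`.
#' @export
confusion <- function(ref, cluster) {
  if (length(cluster) == 0L) stop("empty cluster")
  if (length(ref) == 0L) stop("empty reference group")
  ov <- length(intersect(ref, cluster))
  p <- ov / length(cluster)
  r <- ov / length(ref)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Classify each reference group against a predicted partition
#'
#' Each reference group is matched to its best predicted cluster
#' (maximal F1; ties to the larger intersection, then the
#' lexicographically smallest cluster id) and labeled by the first
#' matching rule of the precedence Exact > Akin > Fused > Split >
#' Missed > Complex:
#' \itemize{
#'   \item Exact: precision and recall both 1.
#'   \item Akin: precision and recall both > 0.85.
#'   \item Fused: this and at least one other reference group each have
#'     recall > 0.85 inside one shared predicted cluster whose summed
#'     precision over those co-fused groups exceeds 0.85.
#'   \item Split: the group is covered by two or more predicted
#'     clusters, each piece with precision > 0.85 w.r.t. the group, the
#'     pieces jointly recalling > 0.85 of it; the number of pieces is
#'     recorded as split events.
#'   \item Missed: recall of the best cluster < 0.5.
#'   \item Complex: anything else.
#' }
#' Fused and Split are tested before Missed because a cleanly split
#' group can have per-piece recall below 0.5.
#'
#' @param ref a [partition()] of reference groups.
#' @param pred a [partition()] of predicted clusters (restricted to the
#'   reference universe first; see [restrict_to_universe()]).
#' @return list with `records` (one `data.frame` row per reference
#'   group: `refog_id, best_cluster_id, precision, recall, f1, event,
#'   n_split_events, n_fuse_events`), `event_counts`, `n_fuse_total`
#'   (co-fused groups beyond the first, per fusing cluster),
#'   `n_split_total` (pieces, summed over Split groups).
#' @export
classify_events <- function(ref, pred) {
  if (length(ref$blocks) == 0L) stop("empty reference partition")
  pred <- restrict_to_universe(pred, ref$universe)
  pblocks <- complete_blocks(pred)
  rblocks <- ref$blocks
  pids <- names(pblocks)
  # recall of every reference group inside every overlapping cluster
  fused_cluster <- setNames(rep(NA_character_, length(rblocks)),
                            names(rblocks))
  for (rid in names(rblocks)) {
    R <- rblocks[[rid]]
    for (pid in pids) {
      if (length(intersect(R, pblocks[[pid]])) / length(R) > 0.85) {
        fused_cluster[[rid]] <- pid
        break  # recalls sum to <= 1, at most one cluster can exceed 0.85
      }
    }
  }
  records <- lapply(names(rblocks), function(rid) {
    R <- rblocks[[rid]]
    stats <- vapply(pids, function(pid) confusion(R, pblocks[[pid]]),
                    numeric(3))
    ov <- vapply(pids, function(pid)
      length(intersect(R, pblocks[[pid]])), numeric(1))
    ord <- order(-stats["f1", ], -ov, pids)
    best <- ord[[1L]]
    p <- stats["precision", best]; r <- stats["recall", best]
    f1 <- stats["f1", best]
    n_split <- 0L; n_fuse <- 0L
    event <- if (p == 1 && r == 1) "Exact"
    else if (p > 0.85 && r > 0.85) "Akin"
    else NA_character_
    if (is.na(event)) {
      # Fused: co-resident reference groups in one engulfing cluster
      fc <- fused_cluster[[rid]]
      if (!is.na(fc)) {
        cofused <- names(fused_cluster)[!is.na(fused_cluster) &
                                          fused_cluster == fc]
        if (length(cofused) >= 2L) {
          summed_p <- sum(vapply(cofused, function(r2)
            length(intersect(rblocks[[r2]], pblocks[[fc]])),
            numeric(1))) / length(pblocks[[fc]])
          if (summed_p > 0.85) {
            event <- "Fused"
            n_fuse <- length(cofused) - 1L
          }
        }
      }
    }
    if (is.na(event)) {
      # Split: high-precision pieces jointly recalling the group
      piece_p <- ov / lengths(pblocks)
      pieces <- which(ov > 0 & piece_p > 0.85)
      if (length(pieces) >= 2L &&
          sum(ov[pieces]) / length(R) > 0.85) {
        event <- "Split"
        n_split <- length(pieces)
      }
    }
    if (is.na(event)) event <- if (r < 0.5) "Missed" else "Complex"
    data.frame(refog_id = rid, best_cluster_id = pids[[best]],
               precision = p, recall = r, f1 = f1, event = event,
               n_split_events = n_split, n_fuse_events = n_fuse,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, records)
  records <- records[order(records$refog_id), , drop = FALSE]
  rownames(records) <- NULL
  event_levels <- c("Exact", "Akin", "Fused", "Split", "Missed", "Complex")
  counts <- table(factor(records$event, levels = event_levels))
  # fuse events are counted once per fusing cluster
  fused_recs <- records[records$event == "Fused", , drop = FALSE]
  fuse_total <- 0L
  if (nrow(fused_recs)) {
    per_cluster <- tapply(fused_recs$n_fuse_events,
                          fused_cluster[fused_recs$refog_id], max)
    fuse_total <- sum(per_cluster)
  }
  list(records = records,
       event_counts = setNames(as.integer(counts), event_levels),
       n_fuse_total = as.integer(fuse_total),
       n_split_total = sum(records$n_split_events),
       n_clusters_pred = length(pred$blocks))
}

#' Variation of Information between two partitions
#'
#' VI(X, Y) = H(X) + H(Y) - 2 I(X; Y), computed from block-overlap
#' counts with block probabilities |block|/|universe|. Unassigned
#' universe elements count as singleton blocks. VI is a metric on
#' partitions: 0 iff the partitions are identical, bounded by
#' log(|universe|).
#'
#' @param x,y [partition()] objects over the same universe.
#' @param base logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @return nonnegative number.
#' @export
variation_of_information <- function(x, y, base = 2) {
  if (!setequal(x$universe, y$universe))
    stop("partitions have different universes")
  n <- length(x$universe)
  if (n == 0L) stop("empty universe")
  bx <- complete_blocks(x)
  by <- complete_blocks(y)
  lg <- function(v) log(v, base = base)
  hx <- -sum(vapply(bx, function(b) {
    p <- length(b) / n; p * lg(p)
  }, numeric(1)))
  hy <- -sum(vapply(by, function(b) {
    p <- length(b) / n; p * lg(p)
  }, numeric(1)))
  mi <- 0
  for (a in bx) {
    pa <- length(a) / n
    for (b in by) {
      ov <- length(intersect(a, b))
      if (ov == 0L) next
      pab <- ov / n
      mi <- mi + pab * lg(pab / (pa * (length(b) / n)))
    }
  }
  max(hx + hy - 2 * mi, 0)
}

#' Full benchmark of a predicted clustering against a reference
#'
#' @param pred_clusters predicted cluster table (one level).
#' @param refogs reference table (`refog_id, gene_id`).
#' @param base VI logarithm base.
#' @return list of class `benchmark_report`: `records`, `event_counts`,
#'   `n_fuse_total`, `n_split_total`, `n_clusters_pred`, `vi`,
#'   `n_refogs`, plus the counts of reference groups reaching F1,
#'   precision and recall of at least 0.85 against their best cluster.
#' @export
benchmark_clustering <- function(pred_clusters, refogs, base = 2) {
  ref <- partition_from_clusters(refogs, "refog_id")
  pred <- partition_from_clusters(pred_clusters, "og_id")
  pred <- restrict_to_universe(pred, ref$universe)
  cls <- classify_events(ref, pred)
  vi <- variation_of_information(
    partition(complete_blocks(pred), ref$universe),
    partition(ref$blocks, ref$universe), base = base)
  rec <- cls$records
  out <- c(cls, list(
    vi = vi, n_refogs = nrow(rec),
    n_f1_ge_85 = sum(rec$f1 >= 0.85),
    n_precision_ge_85 = sum(rec$precision >= 0.85),
    n_recall_ge_85 = sum(rec$recall >= 0.85)))
  class(out) <- "benchmark_report"
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark:", x$n_refogs, "reference groups vs",
      x$n_clusters_pred, "predicted clusters\n")
  cat("  events:", paste(names(x$event_counts), x$event_counts,
                         sep = "=", collapse = " "), "\n")
  cat(sprintf("  split events: %d  fuse events: %d  VI: %.4f\n",
              x$n_split_total, x$n_fuse_total, x$vi))
  invisible(x)
}
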
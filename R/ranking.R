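#' @include scan.R
NULL

#' Combine and rank motif hit lists
#'
#' Concatenates one or more hit tables (e.g. the 2 bp and 3 bp
#' double-box scans), removes duplicates, and sorts by score descending
#' with ties broken by p-value ascending, then start ascending, then
#' strand (`+` before `-`). Ranks 1..n are assigned in that order.
#' Duplicates are entries with identical `(start, strand, motif_id)`, and
#' additionally identical `(start, stop, strand)` across motif lists
#' (the same genomic locus must not be counted twice in a combined
#' ranking); the higher-scoring entry is kept.
#'
#' @param ... Hit data frames from [scan_genome()].
#' @return One hit table with a `rank` column, sorted by rank.
#' @export
rank_hits <- function(...) {
  lists <- list(...)
  lists <- lists[!vapply(lists, is.null, logical(1))]
  hits <- do.call(rbind, lists)
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- empty_hits()
    out$rank <- integer(0)
    return(out)
  }
  ord0 <- order(-hits$score, hits$p_value, hits$start,
                factor(hits$strand, levels = c("+", "-")))
  hits <- hits[ord0, , drop = FALSE]
  dup <- duplicated(hits[, c("start", "strand", "motif_id")]) |
    duplicated(hits[, c("start", "stop", "strand")])
  hits <- hits[!dup, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

hit_region_distance <- function(start, stop, centre, reference = "nearest") {
  switch(reference,
         nearest = ifelse(centre < start, start - centre,
                          ifelse(centre > stop, centre - stop, 0L)),
         start = abs(start - centre),
         midpoint = abs(floor((start + stop) / 2) - centre),
         stop("unknown reference point: ", reference))
}

#' Associate ranked hits with bound regions
#'
#' A hit is eligible for a region when the distance from the hit to the
#' region centre is at most `within` bp; each region receives the
#' eligible hit with the smallest (best) rank, or none. By default
#' distance is measured from the nearest base of the hit (0 when the
#' centre falls inside the match).
#'
#' @param ranked_hits Output of [rank_hits()].
#' @param regions Region table ([retained_regions()] of a filtered set).
#' @param within Maximum distance in bp (default 100).
#' @param reference `"nearest"` (default), `"start"` or `"midpoint"`.
#' @return Data frame with one row per region: `centre`, `label`,
#'   `best_rank` (NA when no eligible hit), `best_hit_start`,
#'   `best_hit_strand`, `best_hit_score`, `best_hit_motif`.
#' @export
associate_hits <- function(ranked_hits, regions, within = 100L,
                           reference = "nearest") {
  n <- nrow(regions)
  out <- data.frame(centre = regions$centre,
                    label = if ("label" %in% names(regions)) regions$label else NA_character_,
                    best_rank = NA_integer_,
                    best_hit_start = NA_integer_,
                    best_hit_strand = NA_character_,
                    best_hit_score = NA_real_,
                    best_hit_motif = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(ranked_hits) == 0L) return(out)
  for (i in seq_len(n)) {
    d <- hit_region_distance(ranked_hits$start, ranked_hits$stop,
                             regions$centre[i], reference)
    elig <- which(d <= within)
    if (length(elig) == 0L) next
    best <- elig[which.min(ranked_hits$rank[elig])]
    out$best_rank[i] <- ranked_hits$rank[best]
    out$best_hit_start[i] <- ranked_hits$start[best]
    out$best_hit_strand[i] <- ranked_hits$strand[best]
    out$best_hit_score[i] <- ranked_hits$score[best]
    out$best_hit_motif[i] <- ranked_hits$motif_id[best]
  }
  out
}

#' Cumulative recovery curve of bound regions over hit ranks
#'
#' For each rank r = 1..`n_total_hits`, the number (and fraction) of
#' regions whose best associated hit has rank <= r: the cumulative
#' frequency curve used to compare the predictive power of motif models.
#'
#' @param associations Output of [associate_hits()].
#' @param n_total_hits Number of ranked hits (the curve's x-extent).
#' @param motif_label Label attached to the curve.
#' @return Data frame of class `"recovery_curve"`: `rank`, `count`,
#'   `fraction`; attributes `motif_label` and `n_regions`.
#' @export
recovery_curve <- function(associations, n_total_hits,
                           motif_label = "motif") {
  n_regions <- nrow(associations)
  n_total_hits <- max(as.integer(n_total_hits), 0L)
  ranks <- associations$best_rank[!is.na(associations$best_rank)]
  counts <- if (n_total_hits > 0L) {
    cumsum(tabulate(ranks[ranks <= n_total_hits], nbins = n_total_hits))
  } else integer(0)
  out <- data.frame(rank = seq_len(n_total_hits), count = counts,
                    fraction = if (n_regions > 0) counts / n_regions else rep(0, n_total_hits))
  attr(out, "motif_label") <- motif_label
  attr(out, "n_regions") <- n_regions
  class(out) <- c("recovery_curve", "data.frame")
  out
}

rank_at_fraction <- function(curve, frac) {
  idx <- which(curve$fraction >= frac)
  if (length(idx) == 0L) NA_integer_ else curve$rank[idx[1L]]
}

#' Compare two recovery curves
#'
#' Summarizes the predictive-power difference between two motif models
#' over the same region set: per-rank difference in recovered fraction,
#' the rank at which each curve reaches 50/80/100 % of regions (NA when
#' never reached), and the area between the curves (sum of per-rank
#' fraction differences, second minus first) up to `rank_cap`.
#'
#' @param curve_a,curve_b [recovery_curve()]s over the same regions
#'   (e.g. single-box and double-box).
#' @param rank_cap Rank limit for the per-rank comparison; default the
#'   shorter curve.
#' @return List with `summary` (data frame: threshold, rank_a, rank_b),
#'   `area_between` (positive when `curve_b` dominates), `per_rank`
#'   (rank, fraction_a, fraction_b, difference), `labels`.
#' @export
compare_motifs <- function(curve_a, curve_b, rank_cap = NULL) {
  if (!identical(attr(curve_a, "n_regions"), attr(curve_b, "n_regions"))) {
    stop("curves computed over different region sets", call. = FALSE)
  }
  if (is.null(rank_cap)) rank_cap <- min(nrow(curve_a), nrow(curve_b))
  rank_cap <- min(rank_cap, nrow(curve_a), nrow(curve_b))
  r <- seq_len(rank_cap)
  per_rank <- data.frame(rank = r,
                         fraction_a = curve_a$fraction[r],
                         fraction_b = curve_b$fraction[r],
                         difference = curve_b$fraction[r] - curve_a$fraction[r])
  summary <- data.frame(
    threshold = c(0.5, 0.8, 1.0),
    rank_a = vapply(c(0.5, 0.8, 1.0), function(f) rank_at_fraction(curve_a, f), integer(1)),
    rank_b = vapply(c(0.5, 0.8, 1.0), function(f) rank_at_fraction(curve_b, f), integer(1)))
  list(summary = summary,
       area_between = sum(per_rank$difference),
       per_rank = per_rank,
       labels = c(a = attr(curve_a, "motif_label"),
                  b = attr(curve_b, "motif_label")))
}
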
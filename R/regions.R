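#' @include genome.R
NULL

mean_track <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  vals <- lapply(tracks, function(t) {
    stopifnot(inherits(t, "coverage_track"))
    t$values
  })
  if (length(unique(lengths(vals))) != 1L) {
    stop("tracks differ in length", call. = FALSE)
  }
  Reduce(`+`, vals) / length(vals)
}

running_mean <- function(x, bw) {
  if (bw <= 1L) return(x)
  k <- rep(1 / bw, bw)
  sm <- stats::filter(x, k, sides = 2)
  as.numeric(sm)  # NA at the edges: never called as peaks
}

#' Detect candidate peaks from signal vs control coverage
#'
#' A simple deterministic point-peak detector: replicate tracks are
#' averaged, smoothed with a running mean, and the ratio
#' `smoothed(signal) / (smoothed(control) + pseudocount)` is computed
#' per base. Strict local maxima of the ratio exceeding `min_fold` are
#' candidate peaks, greedily thinned (best ratio first) so no two
#' reported peaks are closer than `min_separation`. Intended as a
#' stand-in for an external peak caller; a user-supplied peak list can
#' bypass it entirely.
#'
#' @param chip_tracks List of signal [coverage_track()]s (replicates).
#' @param control_tracks List of control tracks.
#' @param min_fold Minimum smoothed ratio at a peak (default 3).
#' @param min_separation Minimum distance between reported peaks (bp).
#' @param smooth_bw Running-mean bandwidth (bp).
#' @param pseudocount Added to the smoothed control before division.
#' @return Data frame of peaks: `position` (1-based), `ratio`, `source`.
#' @export
detect_peaks <- function(chip_tracks, control_tracks, min_fold = 3,
                         min_separation = 200L, smooth_bw = 101L,
                         pseudocount = 0.25) {
  stopifnot(min_fold > 1)
  chip <- running_mean(mean_track(chip_tracks), smooth_bw)
  ctrl <- running_mean(mean_track(control_tracks), smooth_bw)
  if (length(chip) != length(ctrl)) stop("signal and control tracks differ in length", call. = FALSE)
  ratio <- chip / (ctrl + pseudocount)
  n <- length(ratio)
  if (n < 3L) return(empty_peaks())
  mid <- 2:(n - 1L)
  is_max <- !is.na(ratio[mid]) & !is.na(ratio[mid - 1L]) & !is.na(ratio[mid + 1L]) &
    ratio[mid] > ratio[mid - 1L] & ratio[mid] >= ratio[mid + 1L] &
    ratio[mid] >= min_fold
  cand <- mid[is_max]
  if (length(cand) == 0L) return(empty_peaks())
  ord <- cand[order(-ratio[cand], cand)]
  kept <- integer(0)
  for (pos in ord) {
    if (length(kept) == 0L || min(abs(kept - pos)) >= min_separation) {
      kept <- c(kept, pos)
    }
  }
  kept <- sort(kept)
  data.frame(position = kept, ratio = ratio[kept], source = "detect_peaks",
             stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(position = integer(), ratio = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' Aggregate peaks into bound regions
#'
#' Single-linkage merge: consecutive peaks less than `max_gap` apart
#' (strict inequality; a gap of exactly `max_gap` splits) join one
#' region. The region centre is the midpoint of the first and last member
#' peaks, rounded half up.
#'
#' @param peaks Data frame with a `position` column (sorted or not).
#' @param max_gap Merge threshold in bp (default 100).
#' @return Data frame of unscored regions: `centre`, `n_peaks`,
#'   `first_peak`, `last_peak`, `peaks` (list column of member
#'   positions), `relative_coverage` (NA), `label`, `excluded`, `reason`.
#' @export
aggregate_peaks <- function(peaks, max_gap = 100L) {
  if (nrow(peaks) == 0L) return(empty_regions())
  pos <- sort(peaks$position)
  grp <- cumsum(c(1L, as.integer(diff(pos) >= max_gap)))
  members <- split(pos, grp)
  first <- vapply(members, function(m) m[1L], numeric(1))
  last <- vapply(members, function(m) m[length(m)], numeric(1))
  centre <- floor((first + last) / 2 + 0.5)  # round half up
  data.frame(centre = as.integer(centre),
             n_peaks = lengths(members),
             first_peak = as.integer(first), last_peak = as.integer(last),
             peaks = I(unname(members)),
             relative_coverage = NA_real_,
             label = NA_character_,
             excluded = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_regions <- function() {
  data.frame(centre = integer(), n_peaks = integer(), first_peak = integer(),
             last_peak = integer(), peaks = I(list()),
             relative_coverage = numeric(), label = character(),
             excluded = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Score regions by coverage relative to control
#'
#' For each region, the mean over the `window` bp centred on the region
#' centre of the replicate-averaged normalized signal coverage, divided
#' by the same quantity for the control (plus a pseudocount in the
#' denominator). The window mean is used rather than the sum; for a fixed
#' window length the ratio is identical either way.
#'
#' @param regions Region table from [aggregate_peaks()].
#' @param chip_tracks,control_tracks Lists of replicate
#'   [coverage_track()]s.
#' @param window Odd window width in bp (default 201).
#' @param pseudocount Added to the control window mean (default 0.25
#'   normalized units) so zero-coverage control windows stay finite.
#' @return The region table with `relative_coverage` filled in.
#' @export
score_regions <- function(regions, chip_tracks, control_tracks,
                          window = 201L, pseudocount = 0.25) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  chip <- mean_track(chip_tracks)
  ctrl <- mean_track(control_tracks)
  half <- (window - 1L) %/% 2L
  n <- length(chip)
  if (nrow(regions) == 0L) return(regions)
  regions$relative_coverage <- vapply(regions$centre, function(cc) {
    from <- cc - half
    to <- cc + half
    if (from < 1L || to > n) {
      stop(sprintf("scoring window [%d,%d] out of range for centre %d", from, to, cc),
           call. = FALSE)
    }
    mean(chip[from:to]) / (mean(ctrl[from:to]) + pseudocount)
  }, numeric(1))
  regions
}

#' Filter scored regions by coverage ratio and exclusion intervals
#'
#' Regions with `relative_coverage` strictly below `min_ratio` are
#' excluded (a ratio exactly at the threshold is retained), as are
#' regions whose centre falls inside an exclusion interval (e.g.
#' repetitive sequence prone to misalignment artefacts). Excluded regions
#' are kept in the table with `excluded = TRUE` and a reason.
#'
#' @param regions Scored region table.
#' @param min_ratio Minimum retained coverage ratio (default 3).
#' @param exclusion Optional data frame of 1-based inclusive `start`,
#'   `end` intervals.
#' @return The region table with `excluded`/`reason` filled in.
#' @export
filter_regions <- function(regions, min_ratio = 3, exclusion = NULL) {
  if (nrow(regions) == 0L) return(regions)
  if (any(is.na(regions$relative_coverage))) {
    stop("regions must be scored before filtering", call. = FALSE)
  }
  low <- regions$relative_coverage < min_ratio
  regions$excluded <- low
  regions$reason[low] <- sprintf("coverage ratio %.3f below %g",
                                 regions$relative_coverage[low], min_ratio)
  if (!is.null(exclusion) && nrow(exclusion) > 0L) {
    in_excl <- vapply(regions$centre, function(cc) {
      any(cc >= exclusion$start & cc <= exclusion$end)
    }, logical(1))
    regions$excluded <- regions$excluded | in_excl
    regions$reason[in_excl] <- "centre in exclusion interval"
  }
  regions
}

#' Retained (non-excluded) regions
#'
#' @param regions A filtered region table.
#' @return The rows with `excluded == FALSE`.
#' @export
retained_regions <- function(regions) {
  out <- regions[!regions$excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call bound regions from coverage in one step
#'
#' Convenience wrapper: [detect_peaks()] (unless `peaks` is supplied),
#' [aggregate_peaks()], [score_regions()], [filter_regions()].
#'
#' @param chip_tracks,control_tracks Replicate track lists.
#' @param peaks Optional precomputed peak table (bypasses detection).
#' @param max_gap,window,min_ratio,exclusion,min_fold,min_separation,pseudocount
#'   Passed to the component steps.
#' @return A filtered region table (all regions, with `excluded` flags).
#' @export
call_regions <- function(chip_tracks, control_tracks, peaks = NULL,
                         max_gap = 100L, window = 201L, min_ratio = 3,
                         exclusion = NULL, min_fold = 3,
                         min_separation = 200L, smooth_bw = 101L,
                         pseudocount = 0.25) {
  if (is.null(peaks)) {
    peaks <- detect_peaks(chip_tracks, control_tracks, min_fold = min_fold,
                          min_separation = min_separation,
                          smooth_bw = smooth_bw,
                          pseudocount = pseudocount)
  }
  regions <- aggregate_peaks(peaks, max_gap = max_gap)
  if (nrow(regions) == 0L) return(regions)
  regions <- score_regions(regions, chip_tracks, control_tracks,
                           window = window, pseudocount = pseudocount)
  filter_regions(regions, min_ratio = min_ratio, exclusion = exclusion)
}
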
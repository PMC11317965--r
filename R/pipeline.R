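#' @include regions.R ranking.R synthetic.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' peaks less than `max_gap` bp apart merge into one region; coverage is
#' scored over a `window` bp window around the region centre and regions
#' below `min_ratio` are discarded; motif discovery uses `motif_window`
#' bp windows and motifs of `motif_width` columns; double-box PWMs are
#' built at core `spacings`; scan hits require p-value at most `p_max`;
#' hits within `within` bp of a region centre are associated with it.
#'
#' @param max_gap,window,min_ratio,motif_window,motif_width,spacings,p_max,within
#'   See description.
#' @param min_fold,min_separation,smooth_bw Peak-detector settings.
#' @param pseudocount Control-denominator pseudocount (normalized units).
#' @param pwm_pseudocount Pseudocount in PWM construction.
#' @param seed Seed for the motif-discovery stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(max_gap = 100L, window = 201L, min_ratio = 3,
                            motif_window = 101L, motif_width = 11L,
                            spacings = c(2L, 3L), p_max = 1e-4,
                            within = 100L, min_fold = 3,
                            min_separation = 200L, smooth_bw = 101L,
                            pseudocount = 0.25, pwm_pseudocount = 0.1,
                            seed = 1L) {
  structure(list(max_gap = max_gap, window = window, min_ratio = min_ratio,
                 motif_window = motif_window, motif_width = motif_width,
                 spacings = as.integer(spacings), p_max = p_max,
                 within = within, min_fold = min_fold,
                 min_separation = min_separation, smooth_bw = smooth_bw,
                 pseudocount = pseudocount, pwm_pseudocount = pwm_pseudocount,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end double-box analysis
#'
#' Stages: region calling (peak detection unless `peaks` is given,
#' aggregation, scoring, filtering); extraction of `motif_window` bp
#' windows around retained region centres; motif discovery; composition
#' of double-box PWMs at the configured spacings; genome scans with the
#' single and double PWMs; ranking, region association and recovery
#' curves for both motif models. With zero retained regions the run
#' returns cleanly with empty downstream tables.
#'
#' @param g A [genome()].
#' @param chip_tracks,control_tracks Replicate [coverage_track()] lists.
#' @param peaks Optional precomputed peak table (bypasses detection).
#' @param exclusion Optional exclusion interval table (`start`, `end`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage table plus
#'   a JSON run manifest is written there.
#' @return List: `regions` (all, with exclusion flags), `retained`,
#'   `motif` (discovery result or NULL), `pwm_single`, `pwm_double`
#'   (list by spacing), `hits_single`, `hits_double` (list), `ranked_single`,
#'   `ranked_double` (combined over spacings), `assoc_single`,
#'   `assoc_double`, `curve_single`, `curve_double`, `comparison`,
#'   `config`.
#' @export
run_pipeline <- function(g, chip_tracks, control_tracks, peaks = NULL,
                         exclusion = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(g, "genome"), inherits(config, "pipeline_config"))
  regions <- call_regions(chip_tracks, control_tracks, peaks = peaks,
                          max_gap = config$max_gap, window = config$window,
                          min_ratio = config$min_ratio, exclusion = exclusion,
                          min_fold = config$min_fold,
                          min_separation = config$min_separation,
                          smooth_bw = config$smooth_bw,
                          pseudocount = config$pseudocount)
  kept <- retained_regions(regions)
  res <- list(regions = regions, retained = kept, config = config,
              motif = NULL, pwm_single = NULL, pwm_double = list(),
              hits_single = empty_hits(), hits_double = list(),
              ranked_single = NULL, ranked_double = NULL,
              assoc_single = NULL, assoc_double = NULL,
              curve_single = NULL, curve_double = NULL, comparison = NULL)
  half <- (config$motif_window - 1L) %/% 2L
  usable <- kept[kept$centre - half >= 1L & kept$centre + half <= g$length, ,
                 drop = FALSE]
  if (nrow(usable) >= 4L) {
    windows <- vapply(usable$centre, function(cc) {
      extract_window(g, cc, config$motif_window, wrap = FALSE)
    }, "")
    set.seed(config$seed)
    res$motif <- discover_motif(windows, width = config$motif_width,
                                pseudocount = config$pwm_pseudocount)
    res$pwm_single <- res$motif$pwm
    res$pwm_single$id <- "single_box"
    res$pwm_double <- lapply(config$spacings, function(sp) {
      make_double_pwm(res$pwm_single, sp)
    })
    names(res$pwm_double) <- sprintf("spacing_%d", config$spacings)

    res$hits_single <- scan_genome(g, res$pwm_single, p_max = config$p_max)
    res$hits_double <- lapply(res$pwm_double, function(p) {
      scan_genome(g, p, p_max = config$p_max)
    })
    res$ranked_single <- rank_hits(res$hits_single)
    res$ranked_double <- do.call(rank_hits, unname(res$hits_double))
    res$assoc_single <- associate_hits(res$ranked_single, kept,
                                       within = config$within)
    res$assoc_double <- associate_hits(res$ranked_double, kept,
                                       within = config$within)
    n_max <- max(nrow(res$ranked_single), nrow(res$ranked_double), 1L)
    res$curve_single <- recovery_curve(res$assoc_single, n_max, "single_box")
    res$curve_double <- recovery_curve(res$assoc_double, n_max, "double_box")
    res$comparison <- compare_motifs(res$curve_single, res$curve_double)
  }
  if (!is.null(out_dir)) write_pipeline_outputs(res, g, out_dir)
  res
}

write_pipeline_outputs <- function(res, g, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$regions, file.path(out_dir, "regions.tsv"))
  if (nrow(res$retained) > 0L) {
    write_bed(data.frame(start = pmax(res$retained$centre - 100L, 1L),
                         end = pmin(res$retained$centre + 100L, g$length),
                         name = sprintf("region_%d", seq_len(nrow(res$retained))),
                         score = res$retained$relative_coverage),
              file.path(out_dir, "regions.bed"), genome_name = g$name)
  }
  if (!is.null(res$pwm_single)) {
    write_meme(c(list(res$pwm_single), res$pwm_double),
               file.path(out_dir, "motifs.meme"))
    write_tsv(res$ranked_single, file.path(out_dir, "hits_single_ranked.tsv"))
    write_tsv(res$ranked_double, file.path(out_dir, "hits_double_ranked.tsv"))
    write_tsv(res$assoc_single, file.path(out_dir, "associations_single.tsv"))
    write_tsv(res$assoc_double, file.path(out_dir, "associations_double.tsv"))
    write_tsv(as.data.frame(res$curve_single), file.path(out_dir, "curve_single.tsv"))
    write_tsv(as.data.frame(res$curve_double), file.path(out_dir, "curve_double.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("doublebox")),
    r_version = as.character(getRversion()),
    genome = list(name = g$name, length = g$length, circular = g$circular),
    config = unclass(res$config),
    n_regions_total = nrow(res$regions),
    n_regions_retained = nrow(res$retained))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Bound-region annotation table bundled with the package
#'
#' The 16 experimentally mapped DnaA-bound regions of the E. coli MG1655
#' genome (NC_000913.2 coordinates) with their coverage-relative-to-control
#' scores and double-box annotation strings (upper case marks the two 9 bp
#' boxes; NA where no double box was found; `box_shared` marks regions
#' annotated with the same double box as a neighbouring region).
#'
#' @return Data frame: `coordinate`, `locus`, `intragenic`,
#'   `coverage_ratio`, `double_box`, `box_shared`.
#' @export
bound_regions_table <- function() {
  path <- system.file("extdata", "dnaa_bound_regions.tsv",
                      package = "doublebox", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$double_box[tab$double_box == "na"] <- NA_character_
  tab
}
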
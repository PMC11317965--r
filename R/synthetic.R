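#' @include motif.R
NULL

#' Specify a planted DnaA box site
#'
#' Describes one site to plant in a synthetic genome: a single 9-mer box
#' or a double box (two 9-mer cores separated by `spacing` random spacer
#' bases), each box carrying a requested number of random mismatches from
#' the consensus, on either strand, with a relative enrichment strength
#' used by the coverage simulator.
#'
#' @param centre 1-based coordinate the site is centred on.
#' @param kind `"single"` or `"double"`.
#' @param spacing Spacer length in bp between the two 9-mer cores
#'   (double only; 2 and 3 are the biologically preferred spacings, 4 a
#'   spacing perturbation).
#' @param mismatches_upstream,mismatches_downstream Number of random base
#'   changes (0..9) in the upstream / downstream box (`mismatches_upstream`
#'   is the only one used for singles).
#' @param strand `"+"` or `"-"`.
#' @param strength Relative enrichment multiplier for the coverage
#'   simulation (bump height = `strength` x background mean).
#' @return One-row data frame; rbind rows to build a plant table.
#' @export
plant_spec <- function(centre, kind = c("single", "double"), spacing = NA_integer_,
                       mismatches_upstream = 0L, mismatches_downstream = 0L,
                       strand = "+", strength = 10) {
  kind <- match.arg(kind)
  if (kind == "double" && (is.na(spacing) || spacing < 0L)) {
    stop("double plants need a non-negative spacing", call. = FALSE)
  }
  if (mismatches_upstream > 9L || mismatches_downstream > 9L ||
      mismatches_upstream < 0L || mismatches_downstream < 0L) {
    stop("mismatch counts must be in 0..9", call. = FALSE)
  }
  stopifnot(strand %in% c("+", "-"), strength >= 0)
  data.frame(centre = as.integer(centre), kind = kind,
             spacing = as.integer(spacing),
             mismatches_upstream = as.integer(mismatches_upstream),
             mismatches_downstream = as.integer(mismatches_downstream),
             strand = strand, strength = strength,
             stringsAsFactors = FALSE)
}

mutate_box <- function(box, n_mismatches) {
  if (n_mismatches == 0L) return(box)
  chars <- strsplit(box, "")[[1L]]
  at <- sample.int(length(chars), n_mismatches)
  for (i in at) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

realize_plant <- function(spec) {
  up <- mutate_box(DNAA_BOX_CONSENSUS, spec$mismatches_upstream)
  if (spec$kind == "single") {
    core <- up
    down <- NA_character_
    spacer <- NA_character_
  } else {
    down <- mutate_box(DNAA_BOX_CONSENSUS, spec$mismatches_downstream)
    spacer <- paste(sample(BASES, spec$spacing, replace = TRUE), collapse = "")
    core <- paste0(up, spacer, down)
  }
  list(core = core, upstream_box = up, downstream_box = down, spacer = spacer)
}

#' Generate a synthetic genome with planted sites
#'
#' Background bases are drawn i.i.d. at the requested GC fraction; each
#' plant is realized (consensus boxes with the requested mismatches and
#' spacer) and written over the background centred on its coordinate, on
#' the requested strand. Deterministic given the seed: the background and
#' each plant use fixed substreams derived from it.
#'
#' @param length Genome length in bp.
#' @param gc_fraction Background GC content (default 0.5).
#' @param plants Plant table (rbind of [plant_spec()] rows).
#' @param seed Integer master seed.
#' @param name Genome name.
#' @return List with `genome` (a [genome()]) and `truth` (data frame of
#'   realized plants: the spec columns plus `start`, `end`, `sequence`
#'   (forward-strand substring as placed), `upstream_box`,
#'   `downstream_box` (oriented 9-mers); the seed as attribute `seed`).
#' @export
generate_genome <- function(length, gc_fraction = 0.5, plants, seed,
                            name = "synthetic") {
  stopifnot(length >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  chars <- sample(BASES, length, replace = TRUE, prob = probs)

  n <- nrow(plants)
  truth <- plants
  truth$start <- NA_integer_
  truth$end <- NA_integer_
  truth$sequence <- NA_character_
  truth$upstream_box <- NA_character_
  truth$downstream_box <- NA_character_
  for (i in seq_len(n)) {
    set.seed(seed + 1000L + i)
    r <- realize_plant(plants[i, ])
    core <- r$core
    if (plants$strand[i] == "-") core <- reverse_complement(core)
    len <- nchar(core)
    start <- plants$centre[i] - len %/% 2L
    end <- start + len - 1L
    if (start < 1L || end > length) {
      stop(sprintf("plant %d extends outside the genome [%d,%d]", i, start, end),
           call. = FALSE)
    }
    chars[start:end] <- strsplit(core, "")[[1L]]
    truth$start[i] <- start
    truth$end[i] <- end
    truth$sequence[i] <- core
    truth$upstream_box[i] <- r$upstream_box
    truth$downstream_box[i] <- r$downstream_box
  }
  # overlap check on realized intervals
  if (n > 1L) {
    ord <- order(truth$start)
    s <- truth$start[ord]; e <- truth$end[ord]
    if (any(s[-1L] <= e[-n])) stop("planted sites overlap", call. = FALSE)
  }
  attr(truth, "seed") <- seed
  list(genome = genome(name, paste(chars, collapse = "")), truth = truth)
}

gaussian_bump <- function(length, centre, height, sd) {
  lo <- max(1L, as.integer(floor(centre - 6 * sd)))
  hi <- min(length, as.integer(ceiling(centre + 6 * sd)))
  idx <- lo:hi
  val <- height * exp(-((idx - centre)^2) / (2 * sd^2))
  list(idx = idx, val = val)
}

#' Simulate replicate signal and control coverage for planted sites
#'
#' Control tracks are negative-binomial noise around `background_mean`
#' (overdispersed, as real ChIP input coverage is); signal tracks add a
#' Gaussian-shaped enrichment bump at each plant with height
#' `strength * background_mean` and width `peak_width_sd`. Replicates use
#' distinct substreams of the seed. All tracks are normalized to mean
#' depth 1 so replicate averaging and signal/control ratios are
#' well-defined.
#'
#' @param g The synthetic [genome()].
#' @param truth Truth table from [generate_genome()].
#' @param background_mean Mean background depth (raw units, default 20).
#' @param dispersion Negative-binomial dispersion (default 0.2; variance
#'   = mu + dispersion * mu^2).
#' @param peak_width_sd Bump standard deviation in bp (default 75,
#'   emulating fragment-length smearing).
#' @param replicates Number of replicate pairs (default 2).
#' @param seed Integer master seed.
#' @return List with `chip` and `control`, each a list of `replicates`
#'   normalized [coverage_track()]s.
#' @export
generate_coverage <- function(g, truth, background_mean = 20, dispersion = 0.2,
                              peak_width_sd = 75, replicates = 2L, seed = 1L) {
  stopifnot(inherits(g, "genome"), background_mean > 0, dispersion > 0)
  L <- g$length
  mu_chip <- rep(background_mean, L)
  for (i in seq_len(nrow(truth))) {
    if (truth$strength[i] <= 0) next
    b <- gaussian_bump(L, truth$centre[i],
                       truth$strength[i] * background_mean, peak_width_sd)
    mu_chip[b$idx] <- mu_chip[b$idx] + b$val
  }
  size <- 1 / dispersion
  chip <- vector("list", replicates)
  ctrl <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + 101L * r)
    chip[[r]] <- normalize_track(coverage_track(
      g$name, rnbinom(L, mu = mu_chip, size = size)))
    set.seed(seed + 101L * r + 50L)
    ctrl[[r]] <- normalize_track(coverage_track(
      g$name, rnbinom(L, mu = background_mean, size = size)))
  }
  list(chip = chip, control = ctrl)
}

#' Plant layout for a named fixture profile
#'
#' `"small"` is an 8-plant layout for a 50 kb genome; `"paper-like"` is a
#' 30-plant layout for a 500 kb genome mixing single and double boxes at
#' spacings 2, 3 and 4 with a mismatch series (0, 1 or 2 changes per box,
#' plus fully mutated boxes) and graded strengths, including a few plants
#' too weak to be detected. Plants are spread evenly across the genome.
#'
#' @param profile `"small"` or `"paper-like"`.
#' @return List with `genome_length` and `plants` (plant table).
#' @export
fixture_profile <- function(profile = c("small", "paper-like")) {
  profile <- match.arg(profile)
  d <- function(sp, mu, md, strand, strength) {
    plant_spec(0L, "double", spacing = sp, mismatches_upstream = mu,
               mismatches_downstream = md, strand = strand, strength = strength)
  }
  s <- function(mm, strand, strength) {
    plant_spec(0L, "single", mismatches_upstream = mm, strand = strand,
               strength = strength)
  }
  # Strengths encode the binding model the data emulate: pairs of boxes at
  # 2-3 bp core spacing are bound strongly (degraded by mismatches), while
  # single boxes and pairs with perturbed spacing are bound weakly enough
  # to fall below the region-calling threshold.
  if (profile == "small") {
    L <- 50000L
    specs <- rbind(
      d(2L, 0L, 0L, "+", 12), d(3L, 0L, 0L, "-", 12), d(4L, 0L, 0L, "+", 2),
      d(3L, 2L, 0L, "-", 8), d(2L, 0L, 2L, "+", 8),
      s(0L, "+", 2), s(0L, "-", 3), s(2L, "+", 1))
  } else {
    L <- 500000L
    specs <- rbind(
      # consensus doubles at the preferred spacings, both strands
      d(2L, 0L, 0L, "+", 15), d(2L, 0L, 0L, "-", 8),
      d(3L, 0L, 0L, "+", 15), d(3L, 0L, 0L, "-", 8),
      d(3L, 0L, 0L, "+", 20), d(2L, 0L, 0L, "-", 20),
      # spacing perturbation: one extra base between the boxes
      # greatly reduces binding
      d(4L, 0L, 0L, "+", 2), d(4L, 0L, 0L, "-", 2),
      # mismatch series (per-box changes, as in a mutational series)
      d(3L, 1L, 0L, "+", 12), d(3L, 2L, 0L, "+", 10), d(3L, 0L, 2L, "-", 10),
      d(3L, 2L, 2L, "+", 6), d(3L, 9L, 9L, "+", 1),
      d(2L, 1L, 0L, "-", 12), d(2L, 2L, 0L, "-", 10), d(2L, 0L, 2L, "+", 10),
      d(2L, 2L, 2L, "-", 6),
      # more strong consensus doubles
      d(3L, 0L, 0L, "+", 12), d(2L, 0L, 0L, "-", 12), d(3L, 0L, 0L, "-", 9),
      # single boxes: bound too weakly to be called, even at consensus
      s(0L, "+", 2), s(0L, "-", 3), s(0L, "+", 2), s(0L, "-", 1),
      s(0L, "+", 3), s(2L, "+", 1), s(2L, "-", 1), s(2L, "+", 2),
      # fully consensus single on each strand, zero binding
      s(0L, "+", 0), s(0L, "-", 0))
  }
  n <- nrow(specs)
  specs$centre <- as.integer(round(L * seq_len(n) / (n + 1L)))
  list(genome_length = L, plants = specs)
}

#' Simulate a complete dataset for a fixture profile
#'
#' Convenience wrapper: [fixture_profile()], [generate_genome()],
#' [generate_coverage()].
#'
#' @param profile `"small"` or `"paper-like"`.
#' @param seed Integer master seed.
#' @param ... Passed to [generate_coverage()].
#' @return List with `genome`, `truth`, `chip`, `control`.
#' @export
simulate_dataset <- function(profile = c("small", "paper-like"), seed = 1L, ...) {
  prof <- fixture_profile(profile)
  gen <- generate_genome(prof$genome_length, gc_fraction = 0.5,
                         plants = prof$plants, seed = seed)
  cov <- generate_coverage(gen$genome, gen$truth, seed = seed, ...)
  list(genome = gen$genome, truth = gen$truth,
       chip = cov$chip, control = cov$control)
}

#' Write a fixture dataset to disk
#'
#' Emits the genome FASTA, two signal and two control bedGraph tracks,
#' and the truth as BED6 plus TSV, all parseable back through the
#' package's readers.
#'
#' @param profile `"small"` or `"paper-like"`.
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, with the in-memory dataset as
#'   attribute `"dataset"`, invisibly.
#' @export
make_fixture <- function(profile = c("small", "paper-like"), seed = 1L, dir) {
  ds <- simulate_dataset(profile, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    chip = file.path(dir, sprintf("chip_rep%d.bedGraph", seq_along(ds$chip))),
    control = file.path(dir, sprintf("control_rep%d.bedGraph", seq_along(ds$control))),
    truth_bed = file.path(dir, "truth.bed"),
    truth_tsv = file.path(dir, "truth.tsv"))
  write_fasta(ds$genome, paths$genome)
  for (i in seq_along(ds$chip)) write_bedgraph(ds$chip[[i]], paths$chip[i])
  for (i in seq_along(ds$control)) write_bedgraph(ds$control[[i]], paths$control[i])
  tr <- ds$truth
  write_bed(data.frame(start = tr$start, end = tr$end,
                       name = sprintf("%s_%d", tr$kind, seq_len(nrow(tr))),
                       score = tr$strength, strand = tr$strand),
            paths$truth_bed, genome_name = ds$genome$name)
  write_tsv(tr, paths$truth_tsv)
  out <- paths
  attr(out, "dataset") <- ds
  invisible(out)
}
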
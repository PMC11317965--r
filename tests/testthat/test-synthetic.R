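test_that("planted double boxes echo the construction at the plant centre", {
  plants <- plant_spec(5000L, "double", spacing = 3L, strand = "+", strength = 10)
  gen <- generate_genome(10000L, 0.5, plants, seed = 99)
  win <- extract_window(gen$genome, 5000L, 41L)
  expect_equal(length(gregexpr("TTATCCACA", win)[[1L]]), 2L)
  expect_equal(gen$truth$sequence[1], substr(gen$genome$sequence,
                                             gen$truth$start[1], gen$truth$end[1]))
  boxes <- gregexpr("TTATCCACA", gen$truth$sequence[1])[[1L]]
  expect_equal(as.integer(boxes[2] - (boxes[1] + 9L)), 3L)
})

test_that("genome generation is deterministic and truth-consistent", {
  prof <- fixture_profile("small")
  g1 <- generate_genome(prof$genome_length, 0.5, prof$plants, seed = 7)
  g2 <- generate_genome(prof$genome_length, 0.5, prof$plants, seed = 7)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_genome(prof$genome_length, 0.5, prof$plants, seed = 8)
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
  # every realized interval re-extracts to the recorded sequence
  for (i in seq_len(nrow(g1$truth))) {
    expect_identical(substr(g1$genome$sequence, g1$truth$start[i], g1$truth$end[i]),
                     g1$truth$sequence[i])
  }
})

test_that("requested mismatch counts are realized in the planted boxes", {
  plants <- rbind(
    plant_spec(2000L, "double", spacing = 2L, mismatches_upstream = 2L,
               mismatches_downstream = 0L),
    plant_spec(6000L, "single", mismatches_upstream = 3L),
    plant_spec(9000L, "double", spacing = 3L, mismatches_upstream = 0L,
               mismatches_downstream = 1L, strand = "-"))
  gen <- generate_genome(12000L, 0.5, plants, seed = 123)
  tr <- gen$truth
  expect_equal(count_consensus_matches(tr$upstream_box[1]), 7L)
  expect_equal(count_consensus_matches(tr$downstream_box[1]), 9L)
  expect_equal(count_consensus_matches(tr$upstream_box[2]), 6L)
  expect_equal(count_consensus_matches(tr$upstream_box[3]), 9L)
  expect_equal(count_consensus_matches(tr$downstream_box[3]), 8L)
  # minus-strand plant: forward-strand substring is the reverse complement
  core <- paste0(tr$upstream_box[3],
                 substr(reverse_complement(tr$sequence[3]), 10, 12),
                 tr$downstream_box[3])
  expect_identical(reverse_complement(core), tr$sequence[3])
})

test_that("overlapping or out-of-range plants are rejected", {
  plants <- rbind(plant_spec(1000L, "single"), plant_spec(1005L, "single"))
  expect_error(generate_genome(5000L, 0.5, plants, seed = 1), "overlap")
  expect_error(generate_genome(5000L, 0.5, plant_spec(2L, "double", spacing = 3L),
                               seed = 1), "outside")
})

test_that("coverage simulation: null case has equal expected means, plants enrich", {
  plants <- plant_spec(10000L, "double", spacing = 3L, strength = 0)
  gen <- generate_genome(20000L, 0.5, plants, seed = 3)
  cov <- generate_coverage(gen$genome, gen$truth, seed = 3)
  chip <- (cov$chip[[1]]$values + cov$chip[[2]]$values) / 2
  ctrl <- (cov$control[[1]]$values + cov$control[[2]]$values) / 2
  # both normalized to mean 1; ratio of window means near 1 everywhere
  expect_equal(mean(chip), 1, tolerance = 1e-12)
  expect_equal(mean(ctrl), 1, tolerance = 1e-12)
  expect_lt(abs(mean(chip[9900:10100]) / mean(ctrl[9900:10100]) - 1), 0.2)

  # strength-10 plant: relative coverage at the centre well above the
  # calling threshold, and near 1 far from the plant (Monte-Carlo over seeds)
  plants10 <- plant_spec(10000L, "double", spacing = 3L, strength = 10)
  gen10 <- generate_genome(20000L, 0.5, plants10, seed = 3)
  ratios_centre <- ratios_far <- numeric(30)
  for (s in 1:30) {
    cv <- generate_coverage(gen10$genome, gen10$truth, seed = 100 + s)
    ch <- (cv$chip[[1]]$values + cv$chip[[2]]$values) / 2
    ct <- (cv$control[[1]]$values + cv$control[[2]]$values) / 2
    ratios_centre[s] <- mean(ch[9900:10100]) / mean(ct[9900:10100])
    ratios_far[s] <- mean(ch[2000:2200]) / mean(ct[2000:2200])
  }
  expect_gt(mean(ratios_centre), 3)
  # library-size normalization spreads the planted bump mass over the whole
  # track, so the expected far-field ratio is 1 / (1 + bump mass fraction)
  mass <- 10 * sum(exp(-((1:20000 - 10000)^2) / (2 * 75^2))) / 20000
  se <- sd(ratios_far) / sqrt(length(ratios_far))
  expect_lt(abs(mean(ratios_far) - 1 / (1 + mass)), 3 * se + 0.02)
})

test_that("coverage generation is deterministic given the seed", {
  ds1 <- simulate_dataset("small", seed = 5)
  ds2 <- simulate_dataset("small", seed = 5)
  expect_identical(ds1$chip[[1]]$values, ds2$chip[[1]]$values)
  expect_identical(ds1$control[[2]]$values, ds2$control[[2]]$values)
  expect_false(identical(ds1$chip[[1]]$values, ds1$chip[[2]]$values))
})

test_that("fixture files parse back through the package readers", {
  dir <- withr::local_tempdir()
  paths <- make_fixture("small", seed = 2, dir = dir)
  ds <- attr(paths, "dataset")
  g <- read_fasta(paths$genome)
  expect_identical(g$sequence, ds$genome$sequence)
  tr1 <- read_bedgraph(paths$chip[1], g)
  expect_equal(tr1$values, ds$chip[[1]]$values, tolerance = 1e-6)
  bed <- read_bed(paths$truth_bed)
  expect_equal(bed$start, ds$truth$start)
  expect_equal(bed$end, ds$truth$end)
  tsv <- read_tsv(paths$truth_tsv)
  expect_equal(tsv$centre, ds$truth$centre)
  expect_equal(tsv$sequence, ds$truth$sequence)
})

test_that("fixture profiles cover every planted kind and spacing", {
  for (profile in c("small", "paper-like")) {
    prof <- fixture_profile(profile)
    tr <- prof$plants
    expect_true(any(tr$kind == "single"))
    for (sp in c(2, 3, 4)) {
      expect_true(any(tr$kind == "double" & tr$spacing == sp),
                  label = sprintf("%s has a double at spacing %d", profile, sp))
    }
    expect_true(all(tr$centre > 1 & tr$centre < prof$genome_length))
  }
  expect_equal(nrow(fixture_profile("paper-like")$plants), 30L)
})
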
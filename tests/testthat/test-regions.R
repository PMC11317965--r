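test_that("peak aggregation merges below the gap threshold and splits at it", {
  expect_equal(aggregate_peaks(data.frame(position = 1000L))$centre, 1000L)

  r <- aggregate_peaks(data.frame(position = c(1000L, 1099L, 1300L)))
  expect_equal(nrow(r), 2L)
  expect_equal(r$centre, c(1050L, 1300L))  # midpoint 1049.5 rounds half up
  expect_equal(r$n_peaks, c(2L, 1L))

  # gap of exactly max_gap is NOT < max_gap: split
  r2 <- aggregate_peaks(data.frame(position = c(1000L, 1100L)))
  expect_equal(nrow(r2), 2L)

  expect_equal(nrow(aggregate_peaks(data.frame(position = integer()))), 0L)
})

test_that("aggregation is permutation-invariant and idempotent on its centres", {
  set.seed(17)
  pos <- sort(sample(1:50000, 40))
  a <- aggregate_peaks(data.frame(position = pos))
  b <- aggregate_peaks(data.frame(position = sample(pos)))
  expect_equal(a$centre, b$centre)
  again <- aggregate_peaks(data.frame(position = a$centre))
  expect_equal(nrow(again), nrow(a))
})

test_that("region count is monotone non-increasing in max_gap", {
  set.seed(19)
  pos <- sort(sample(1:20000, 60))
  gaps <- c(10L, 50L, 100L, 500L, 2000L)
  counts <- vapply(gaps, function(gp) {
    nrow(aggregate_peaks(data.frame(position = pos), max_gap = gp))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region scoring matches closed-form ratios on constant tracks", {
  regions <- aggregate_peaks(data.frame(position = 500L))
  chip <- constant_tracks(30, 1000)
  ctrl <- constant_tracks(10, 1000)
  scored <- score_regions(regions, chip, ctrl, window = 201L, pseudocount = 0)
  expect_equal(scored$relative_coverage, 3.0)

  same <- score_regions(regions, chip, chip, window = 201L, pseudocount = 0)
  expect_equal(same$relative_coverage, 1.0)

  expect_error(score_regions(aggregate_peaks(data.frame(position = 50L)),
                             chip, ctrl, window = 201L), "out of range")
})

test_that("filtering applies a strict ratio boundary and exclusion intervals", {
  regions <- aggregate_peaks(data.frame(position = c(1000L, 5000L, 9000L)))
  regions$relative_coverage <- c(2.999, 3.0, 4.0)
  out <- filter_regions(regions, min_ratio = 3)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  expect_match(out$reason[1], "below")
  # a ratio-4 region is retained: the weakest retained bound region
  expect_false(out$excluded[3])

  excl <- data.frame(start = 4900L, end = 5100L)
  out2 <- filter_regions(regions, min_ratio = 3, exclusion = excl)
  expect_equal(out2$excluded, c(TRUE, TRUE, FALSE))
  expect_match(out2$reason[2], "exclusion")
  expect_equal(retained_regions(out2)$centre, 9000L)
})

test_that("retained-region count is monotone non-increasing in min_ratio", {
  set.seed(29)
  regions <- aggregate_peaks(data.frame(position = sort(sample(1:100000, 20)) ))
  regions$relative_coverage <- runif(nrow(regions), 1, 10)
  counts <- vapply(c(1, 2, 3, 5, 8), function(mr) {
    nrow(retained_regions(filter_regions(regions, min_ratio = mr)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak detection: flat tracks give no peaks, bumps give localized peaks", {
  chip <- constant_tracks(5, 4000)
  ctrl <- constant_tracks(5, 4000)
  expect_equal(nrow(detect_peaks(chip, ctrl)), 0L)
  # all-zero control with all-zero signal: empty list, not an error
  expect_equal(nrow(detect_peaks(constant_tracks(0, 4000),
                                 constant_tracks(0, 4000))), 0L)

  # one planted bump of strength 10: exactly one peak within 25 bp (10 seeds)
  plants <- plant_spec(10000L, "single", strength = 10)
  gen <- generate_genome(20000L, 0.5, plants, seed = 1)
  hits <- 0L
  for (s in 1:10) {
    cov <- generate_coverage(gen$genome, gen$truth, seed = 400 + s)
    pk <- detect_peaks(cov$chip, cov$control)
    if (nrow(pk) == 1L && abs(pk$position - 10000L) <= 25L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # two bumps 2 kb apart resolve into two peaks
  plants2 <- rbind(plant_spec(8000L, "single", strength = 10),
                   plant_spec(10000L, "single", strength = 10))
  gen2 <- generate_genome(20000L, 0.5, plants2, seed = 2)
  cov2 <- generate_coverage(gen2$genome, gen2$truth, seed = 77)
  pk2 <- detect_peaks(cov2$chip, cov2$control)
  expect_equal(nrow(pk2), 2L)
  expect_true(all(abs(sort(pk2$position) - c(8000L, 10000L)) <= 50L))
})

test_that("scored synthetic regions agree with the simulation's expectation", {
  plants <- plant_spec(10000L, "single", strength = 10)
  gen <- generate_genome(20000L, 0.5, plants, seed = 6)
  ratios <- numeric(25)
  for (s in 1:25) {
    cov <- generate_coverage(gen$genome, gen$truth, seed = 500 + s)
    regions <- aggregate_peaks(data.frame(position = 10000L))
    scored <- score_regions(regions, cov$chip, cov$control)
    ratios[s] <- scored$relative_coverage
  }
  # expectation: window-average bump factor / (1 + pseudocount)
  x <- (-100):100
  expected <- (1 + 10 * mean(exp(-x^2 / (2 * 75^2)))) / 1.25
  expect_lt(abs(mean(ratios) - expected) / expected, 0.2)
})
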
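test_that("consensus match counting reproduces the annotated box counts", {
  tab <- bound_regions_table()
  expect_equal(nrow(tab), 16L)
  purh <- parse_double_box(tab$double_box[tab$locus == "purH"])
  expect_equal(count_consensus_matches(purh$upstream), 7L)
  expect_equal(count_consensus_matches(purh$downstream), 9L)
  expect_equal(purh$spacing, 3L)

  expect_equal(count_consensus_matches("TTATCCACA"), 9L)
  expect_equal(count_consensus_matches("GGGGGGGGG"), 0L)
  expect_error(count_consensus_matches("TTAT"), "length mismatch")
})

test_that("the annotated double boxes parse with core spacings of 2 or 3", {
  tab <- bound_regions_table()
  boxes <- tab$double_box[!is.na(tab$double_box)]
  expect_equal(length(boxes), 15L)
  spacings <- vapply(boxes, function(b) parse_double_box(b)$spacing, integer(1))
  expect_true(all(spacings %in% c(2L, 3L)))
  expect_error(parse_double_box("ttatccaca"), "two upper-case box runs")
})

test_that("PWM construction follows the pseudocount formula", {
  p <- build_pwm(c("AAAA", "AAAA"), pseudocount = 0)
  expect_equal(unname(p$probs[, "A"]), rep(1, 4))

  p2 <- build_pwm(c("AAAA", "CCCC"), pseudocount = 0)
  expect_equal(unname(p2$probs[, "A"]), rep(0.5, 4))
  expect_equal(unname(p2$probs[, "C"]), rep(0.5, 4))

  # hand arithmetic: n=2, pseudocount 1, uniform background, column 2 of {AA, AC}
  p3 <- build_pwm(c("AA", "AC"), pseudocount = 1)
  expect_equal(unname(p3$probs[2, ]),
               c(1.25 / 3, 1.25 / 3, 0.25 / 3, 0.25 / 3))

  expect_error(build_pwm(character(0)), "at least 2|empty")
  expect_error(build_pwm(c("AAA", "AAAA")), "ragged")
})

test_that("PWMs estimated from sites drawn from a known PWM converge to it", {
  set.seed(101)
  true_pwm <- word_pwm("TTATCCACA", p = 0.8)
  draw_sites <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(apply(true_pwm$probs, 1L, function(pr) {
        sample(c("A", "C", "G", "T"), 1L, prob = pr)
      }), collapse = "")
    }, "")
  }
  kl <- vapply(c(10, 100, 1000), function(n) {
    est <- build_pwm(draw_sites(n), pseudocount = 0.1)
    mean(true_pwm$probs * log2(true_pwm$probs / est$probs))
  }, numeric(1))
  expect_true(all(diff(kl) < 0))
  expect_lt(kl[3], 0.01)
})

test_that("double-PWM geometry: widths, core spacing, background spacer column", {
  single <- build_pwm(c("ATTATCCACAG", "CTTATCCACAT", "GTTATCCACAA",
                        "TTTATCCACAC"), pseudocount = 0.1)
  expect_equal(single$width, 11L)
  expect_equal(single$core_offset, 1L)

  d2 <- make_double_pwm(single, 2)
  d3 <- make_double_pwm(single, 3)
  expect_equal(d2$width, 22L)
  expect_equal(d3$width, 23L)
  expect_equal(d2$core_spacing, 2L)
  expect_equal(d3$core_spacing, 3L)
  # middle column of the 3 bp form is exactly the background
  expect_equal(unname(d3$probs[12L, ]), unname(d3$background))
  # consensus cores sit 2 and 3 columns apart
  cons2 <- consensus_string(d2)
  cons3 <- consensus_string(d3)
  expect_equal(unlist(gregexpr("TTATCCACA", cons2)), c(2L, 13L))
  expect_equal(unlist(gregexpr("TTATCCACA", cons3)), c(2L, 14L))

  expect_error(make_double_pwm(single, 5), "unsupported")

  # column-sum invariant and information content additivity
  expect_true(all(abs(rowSums(d3$probs) - 1) < 1e-9))
  expect_equal(information_content(d2), 2 * information_content(single),
               tolerance = 1e-9)
  expect_equal(information_content(d3), 2 * information_content(single),
               tolerance = 1e-9)
})

test_that("EM motif discovery recovers a planted box from random windows", {
  set.seed(303)
  recovered <- 0L
  for (rep in 1:10) {
    windows <- vapply(1:16, function(i) {
      w <- random_dna(101)
      at <- sample(101 - 8, 1)
      paste0(substr(w, 1, at - 1), "TTATCCACA", substr(w, at + 9, 101))
    }, "")
    fit <- discover_motif(windows, width = 11)
    core <- substr(consensus_string(fit$pwm), fit$pwm$core_offset + 1,
                   fit$pwm$core_offset + 9)
    if (core %in% c("TTATCCACA", reverse_complement("TTATCCACA"))) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered, 9L)
})

test_that("motif discovery: planted motifs carry more information than noise", {
  set.seed(404)
  planted <- vapply(1:12, function(i) {
    w <- random_dna(60)
    at <- sample(60 - 8, 1)
    paste0(substr(w, 1, at - 1), "TTATCCACA", substr(w, at + 9, 60))
  }, "")
  noise <- vapply(1:12, function(i) random_dna(60), "")
  ic_planted <- discover_motif(planted, width = 11)$ic
  ic_noise <- discover_motif(noise, width = 11)$ic
  expect_gt(ic_planted, ic_noise)
})

test_that("motif discovery is strand-symmetric and rejects degenerate input", {
  set.seed(505)
  windows <- vapply(1:10, function(i) {
    w <- random_dna(50)
    paste0(substr(w, 1, 20), "TTATCCACA", substr(w, 30, 50))
  }, "")
  fwd <- discover_motif(windows, width = 11)
  rc <- discover_motif(vapply(windows, reverse_complement, ""), width = 11)
  expect_equal(fwd$ic, rc$ic, tolerance = 1e-6)
  cons_f <- consensus_string(fwd$pwm)
  cons_r <- consensus_string(rc$pwm)
  expect_true(cons_r %in% c(cons_f, reverse_complement(cons_f)))

  expect_error(discover_motif(rep(strrep("A", 20), 5), width = 5),
               "no informative motif")
  expect_error(discover_motif(rep("ACGT", 5), width = 11), "width exceeds")
  expect_error(discover_motif(c("ACGTACGT", "ACGTACGT"), width = 4),
               "at least 4 windows")
})

test_that("MEME minimal format round-trips single and double PWMs", {
  single <- build_pwm(c("ATTATCCACAG", "CTTATCCACAT", "GTTATCCACAA",
                        "TTTATCCACAC"), pseudocount = 0.1,
                      background = c(0.3, 0.2, 0.2, 0.3))
  d3 <- make_double_pwm(single, 3)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(single, d3), path)
  back <- read_meme(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$probs, single$probs, tolerance = 1e-5)
  expect_equal(unname(back[[1]]$background), c(0.3, 0.2, 0.2, 0.3),
               tolerance = 1e-5)
  expect_equal(back[[2]]$width, 23L)
  expect_equal(consensus_string(back[[2]]), consensus_string(d3))
})
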
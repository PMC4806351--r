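# ZOOPS EM motif discovery.

plantMotif <- function(n, len, motif, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(.mybkit_aa(), len, replace = TRUE), collapse = "")
      p <- sample.int(len - nchar(motif) + 1L, 1L)
      substr(s, p, p + nchar(motif) - 1L) <- motif
      s
    }, character(1))
  })
}

consensusPwm <- function(motif) {
  w <- nchar(motif)
  m <- matrix(0, 20, w, dimnames = list(.mybkit_aa(), NULL))
  for (j in seq_len(w)) m[substr(motif, j, j), j] <- 1
  m
}

test_that("a planted exact width-8 motif is recovered with PWM correlation >= 0.95", {
  motif <- "WKRPYCED"
  seqs <- plantMotif(50, 60, motif, seed = 51)
  m <- zoopsEM(seqs, 8, seed = 1)
  expect_equal(motifConsensus(m), motif)
  expect_gte(stats::cor(as.vector(consensusPwm(motif)), as.vector(m@pwm)),
             0.95)
  expect_gte(m@prior, 0.9)
})

test_that("the EM objective is monotone non-decreasing on every run", {
  motif <- "LIVHQWDK"
  seqs <- plantMotif(30, 50, motif, seed = 52)
  for (s in 1:3) {
    m <- zoopsEM(seqs, 8, seed = s)
    expect_true(all(diff(m@objective) >= -1e-6 * pmax(1, abs(m@objective[-1]))))
  }
})

test_that("same seed and data give a bit-identical model", {
  seqs <- plantMotif(20, 40, "WWKKPPYY", seed = 53)
  m1 <- zoopsEM(seqs, 8, seed = 4)
  m2 <- zoopsEM(seqs, 8, seed = 4)
  expect_identical(m1@pwm, m2@pwm)
  expect_identical(m1@logLik, m2@logLik)
})

test_that("random sequences score far below the planted-motif regime", {
  withr::with_seed(54, {
    rand <- vapply(1:30, function(i)
      paste(sample(.mybkit_aa(), 50, replace = TRUE), collapse = ""),
      character(1))
  })
  mNull <- zoopsEM(rand, 8, seed = 5)
  planted <- plantMotif(30, 50, "WKRPYCED", seed = 55)
  mAlt <- zoopsEM(planted, 8, seed = 5)
  expect_lt(mNull@significance, mAlt@significance / 3)
})

test_that("width must fit the shortest sequence", {
  expect_error(zoopsEM(c("MKVAW", "MKVAWDE"), 6), "width")
})

test_that("two disjoint planted motifs are both discovered and ranked", {
  m1 <- "WKRPYCED"; m2 <- "HHLLTTNN"
  withr::with_seed(56, {
    seqs <- vapply(1:40, function(i) {
      s <- paste(sample(.mybkit_aa(), 70, replace = TRUE), collapse = "")
      substr(s, 5, 12) <- m1
      substr(s, 40, 47) <- m2
      s
    }, character(1))
  })
  found <- discoverMotifs(seqs, maxMotifs = 3, widthRange = 8, seed = 6)
  cons <- vapply(found, motifConsensus, character(1))
  expect_true(m1 %in% cons)
  expect_true(m2 %in% cons)
  sig <- vapply(found, function(m) m@significance, numeric(1))
  expect_true(all(diff(sig) <= 0))
})

test_that("maxMotifs = 1 returns exactly one motif", {
  seqs <- plantMotif(30, 50, "WKRPYCED", seed = 57)
  found <- discoverMotifs(seqs, maxMotifs = 1, widthRange = 8, seed = 7)
  expect_equal(length(found), 1)
})

test_that("no-motif data with a calibrated threshold yields an empty list", {
  withr::with_seed(58, {
    rand <- vapply(1:25, function(i)
      paste(sample(.mybkit_aa(), 60, replace = TRUE), collapse = ""),
      character(1))
  })
  found <- discoverMotifs(rand, maxMotifs = 3, widthRange = 8, seed = 8)
  expect_equal(length(found), 0)
})

test_that("occurrence table decodes planted sites and has one row per sequence x motif", {
  motif <- "WKRPYCED"
  seqs <- plantMotif(25, 60, motif, seed = 59)
  names(seqs) <- paste0("seq", seq_along(seqs))
  m <- zoopsEM(seqs, 8, seed = 9)
  occ <- motifOccurrence(list(m), seqs)
  expect_equal(nrow(occ), 25)
  expect_true(all(occ$present))
  # decoded sites carry the exact motif
  hits <- vapply(seq_len(nrow(occ)), function(i)
    substr(seqs[occ$sequence[i]], occ$start[i], occ$start[i] + 7L),
    character(1))
  expect_true(mean(hits == motif) >= 0.95)
  # unrelated sequence: absent
  withr::with_seed(60, {
    noise <- paste(sample(setdiff(.mybkit_aa(), c("W", "K")), 60,
                          replace = TRUE), collapse = "")
  })
  occ2 <- motifOccurrence(list(m), c(x = noise))
  expect_false(occ2$present)
})
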
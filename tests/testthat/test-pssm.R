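# Hand-written three-position ASCII fixture in PSI-BLAST layout, with
# distinct values per column so the column remap is observable.
pssm_fixture_lines <- function() {
  order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  label <- paste0("           ", paste(sprintf("%3s", c(order, order)), collapse = " "))
  row <- function(pos, res, scores) {
    paste0(sprintf("%5d %s ", pos, res),
           paste(sprintf("%3d", scores), collapse = " "), "  ",
           paste(sprintf("%3d", integer(20)), collapse = " "), "  0.00 0.00")
  }
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    label,
    row(1, "A", 1:20),
    row(2, "C", 20:1),
    row(3, "D", c(-10:9)),
    "",
    "                      K         Lambda")
}

test_that("parser reads positions in order and remaps columns alphabetically", {
  prof <- parse_psiblast_pssm(pssm_fixture_lines(), sequence_id = "fx")
  expect_s3_class(prof, "pssm_profile")
  expect_equal(nrow(prof$scores), 3)
  expect_equal(prof$residues, "ACD")
  # row 1 held 1:20 in file order: A=1, R=2, N=3, ..., V=20
  expect_equal(unname(prof$scores[1, "A"]), 1)
  expect_equal(unname(prof$scores[1, "R"]), 2)
  expect_equal(unname(prof$scores[1, "N"]), 3)
  expect_equal(unname(prof$scores[1, "V"]), 20)
  expect_equal(unname(prof$scores[2, "V"]), 1)
  expect_equal(unname(prof$scores[3, "A"]), -10)
  # every file column lands at its alphabetical index, all rows
  file_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  expect_equal(unname(prof$scores[1, file_order]), 1:20)
})

test_that("parser rejects malformed input with the offending line", {
  lines <- pssm_fixture_lines()
  truncated <- lines
  truncated[5] <- substr(truncated[5], 1, 40)
  expect_error(parse_psiblast_pssm(truncated), "line 5.*truncated")

  skipped <- lines[-4]
  expect_error(parse_psiblast_pssm(skipped), "not consecutive")

  expect_error(parse_psiblast_pssm(lines[-3]), "not a PSSM file")

  wild <- lines
  wild[4] <- gsub(" 20 ", " 25 ", wild[4])
  expect_error(parse_psiblast_pssm(wild), "band")
})

test_that("logistic normalization maps scores into (0, 1) monotonically", {
  prof <- synthesize_profile("ACDEF", self_score = 7, off_score = -3)
  norm <- logistic_normalize(prof)
  expect_true(all(norm$scores > 0 & norm$scores < 1))
  # closed form: g(0) = 0.5 exactly, g(7) = 1 / (1 + e^-7)
  zero <- logistic_normalize(pssm_profile("z", "A", matrix(0L, 1, 20)))
  expect_equal(unname(zero$scores[1, ]), rep(0.5, 20))
  seven <- logistic_normalize(pssm_profile("s", "A", matrix(7L, 1, 20)))
  expect_equal(unname(seven$scores[1, 1]), 0.9990889, tolerance = 1e-6)
  g <- function(x) logistic_normalize(pssm_profile("m", "A", matrix(as.integer(x), 1, 20)))$scores[1, 1]
  expect_true(g(-3) < g(0) && g(0) < g(3))
  # idempotent on an already-normalized profile
  expect_equal(logistic_normalize(norm), norm)
})

test_that("pssm400 pools normalized scores per query-residue type", {
  # one position, all-zero raw scores: the A block is g(0)/N = 0.5
  prof <- logistic_normalize(pssm_profile("one", "A", matrix(0L, 1, 20)))
  v <- pssm400(prof, "A")
  expect_length(v, 400)
  expect_equal(unname(v[paste0("PSSM_A", AA20)]), rep(0.5, 20))
  expect_equal(sum(v != 0), 20)
  expect_true(all(v >= 0 & v < 1))

  expect_error(pssm400(prof, "C"), "mismatch")
  raw <- synthesize_profile("ACD")
  expect_error(pssm400(raw, "ACD"), "normalized")
})

test_that("pssm400 matches the naive triple-loop pooling oracle", {
  withr::with_seed(17, {
    for (i in 1:20) {
      s <- random_seq(sample(10:40, 1))
      norm <- logistic_normalize(synthesize_profile(s, noise_sd = 2, seed = i))
      expect_equal(unname(pssm400(norm, s)), oracle_pssm400(norm$scores, s))
    }
  })
})

test_that("pssm400 is invariant to the order of same-residue positions", {
  s <- "ACAC"
  norm <- logistic_normalize(synthesize_profile(s, noise_sd = 3, seed = 4))
  swapped <- norm
  swapped$scores <- norm$scores[c(3, 2, 1, 4), ]  # swap the two A positions
  expect_equal(pssm400(norm, s), pssm400(swapped, s))
})

test_that("alternative pooling statistics relate to the default as declared", {
  s <- "AACDD"
  norm <- logistic_normalize(synthesize_profile(s, noise_sd = 2, seed = 8))
  lnorm <- pssm400(norm, s)
  expect_equal(pssm400(norm, s, aggregate = "sum"), lnorm * nchar(s),
               ignore_attr = TRUE)
  per_mean <- pssm400(norm, s, aggregate = "mean")
  expect_equal(unname(per_mean[paste0("PSSM_A", AA20)]),
               unname(lnorm[paste0("PSSM_A", AA20)]) * nchar(s) / 2)
})

test_that("synthesized profiles are deterministic, banded and template-shaped", {
  p <- synthesize_profile("AC", self_score = 5, off_score = -2, noise_sd = 0)
  expect_equal(unname(p$scores[1, "A"]), 5)
  expect_equal(unname(p$scores[1, setdiff(AA20, "A")]), rep(-2, 19))
  expect_equal(unname(p$scores[2, "C"]), 5)

  a <- synthesize_profile("ACDEF", noise_sd = 2, seed = 99)
  b <- synthesize_profile("ACDEF", noise_sd = 2, seed = 99)
  expect_identical(a$scores, b$scores)

  # extreme noise stays clamped inside the parser's band
  wild <- synthesize_profile("ACDEF", self_score = 19, off_score = -19,
                             noise_sd = 30, seed = 1)
  expect_true(all(abs(wild$scores) <= 20))
  expect_error(synthesize_profile("AC", self_score = -2, off_score = 5))
})

test_that("profiles round-trip exactly through ASCII write and parse", {
  withr::with_seed(31, {
    for (i in 1:5) {
      s <- random_seq(sample(5:30, 1))
      p <- synthesize_profile(s, noise_sd = 2, seed = i)
      f <- withr::local_tempfile(fileext = ".pssm")
      write_pssm_ascii(p, f)
      back <- read_psiblast_pssm(f, sequence_id = p$sequence_id)
      expect_equal(back$residues, p$residues)
      expect_equal(unname(back$scores), unname(p$scores))
    }
  })
})
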
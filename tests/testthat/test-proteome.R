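make_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- emc_fit(zero_noise_dataset(seed = 31), seed = 31)
    fit
  }
})

random_tmds <- function(n, seed, L = 26L) {
  set.seed(seed)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i)
    paste(sample(aas, L, replace = TRUE), collapse = ""), character(1))
}

test_that("orientation reverses endo-start TMDs and is idempotent", {
  recs <- data.frame(protein_id = c("P1", "P2"), tmd_index = 1L,
                     sequence = c("KLLVP", "KLLVP"),
                     start_side = c("exo", "endo"),
                     stringsAsFactors = FALSE)
  out <- orient_tmd(recs)
  expect_identical(out$sequence, c("KLLVP", "PVLLK"))
  expect_true(all(out$start_side == "exo"))
  expect_identical(orient_tmd(out), out)
  # missing annotation defaults to exo with a warning
  recs$start_side <- NA
  expect_warning(out2 <- orient_tmd(recs), "without topology")
  expect_identical(out2$sequence, recs$sequence)
})

test_that("location labels map to membrane sides per the topology convention", {
  expect_identical(map_localization("Extracellular"), "exo")
  expect_identical(map_localization("Lumenal"), "exo")
  expect_identical(map_localization("Mitochondrial matrix"), "exo")
  expect_identical(map_localization("Perinuclear space"), "exo")
  expect_identical(map_localization("Cytoplasmic"), "endo")
  expect_warning(side <- map_localization("Golgi mystery"), "unrecognized")
  expect_identical(side, "endo")
})

test_that("proteome scores are min-max normalized to [0, 100] with max aggregation", {
  fit <- make_fit()
  set.seed(101)
  n_prot <- 100L
  n_tmds <- sample(1:4, n_prot, replace = TRUE)
  recs <- data.frame(
    protein_id = rep(sprintf("P%03d", seq_len(n_prot)), n_tmds),
    sequence = random_tmds(sum(n_tmds), seed = 102),
    stringsAsFactors = FALSE)
  recs$start_side <- "exo"
  scored <- score_proteome(fit, recs)

  raw <- scored$tmd$raw_score
  oracle <- (raw - min(raw)) / (max(raw) - min(raw)) * 100
  expect_equal(scored$tmd$score, oracle, tolerance = 1e-12)
  expect_identical(range(scored$tmd$score), c(0, 100))
  expect_identical(order(raw), order(scored$tmd$score))

  per_prot <- tapply(scored$tmd$score, scored$tmd$protein_id, max)
  expect_equal(scored$protein$score,
               as.vector(per_prot[scored$protein$protein_id]),
               tolerance = 1e-12)
  # max-then-normalize equals normalize-then-max
  raw_max <- tapply(raw, scored$tmd$protein_id, max)
  expect_equal(scored$protein$score,
               as.vector((raw_max[scored$protein$protein_id] - min(raw)) /
                           (max(raw) - min(raw)) * 100),
               tolerance = 1e-12)
})

test_that("degenerate and shuffled inputs score consistently", {
  fit <- make_fit()
  one <- data.frame(protein_id = "P1", sequence = random_tmds(1, 7),
                    start_side = "exo", stringsAsFactors = FALSE)
  expect_identical(score_proteome(fit, one)$protein$score, 0)

  two <- data.frame(protein_id = "P1", sequence = random_tmds(2, 8),
                    start_side = "exo", stringsAsFactors = FALSE)
  s2 <- score_proteome(fit, two)
  expect_identical(s2$protein$score, 100)

  # protein score invariant to TMD order
  recs <- data.frame(protein_id = rep(c("A", "B"), each = 3L),
                     sequence = random_tmds(6, 9), start_side = "exo",
                     stringsAsFactors = FALSE)
  a <- score_proteome(fit, recs)
  b <- score_proteome(fit, recs[c(3, 1, 2, 6, 5, 4), ])
  expect_equal(a$protein$score, b$protein$score, tolerance = 1e-12)
})

test_that("group summaries match manual arithmetic", {
  fit <- make_fit()
  recs <- data.frame(
    protein_id = c("S1", "S2", "M1", "M1", "M2", "M2", "M2"),
    sequence = random_tmds(7, 10), start_side = "exo",
    class_label = c("enzyme", "enzyme", "transporter", "transporter",
                    "receptor", "receptor", "receptor"),
    stringsAsFactors = FALSE)
  scored <- score_proteome(fit, recs)
  sm <- summarize_groups(scored, by = "pass", frequencies = TRUE)
  p <- scored$protein
  multi <- p$score[p$n_tmds > 1]
  single <- p$score[p$n_tmds == 1]
  expect_equal(sm$mean[sm$group == "multipass"], mean(multi))
  expect_equal(sm$sd[sm$group == "single-pass"], sd(single))
  expect_identical(sm$n, c(2L, 2L))
  expect_equal(sum(sm$share), 1)

  sml <- summarize_groups(scored, by = "class_label")
  expect_identical(sort(sml$group), c("enzyme", "receptor", "transporter"))

  all_single <- score_proteome(fit, recs[1:2, ])
  sm1 <- summarize_groups(all_single, by = "pass")
  expect_identical(nrow(sm1), 1L)
  expect_identical(sm1$group, "single-pass")
})

test_that("expected protein score grows with TMD count under i.i.d. scores", {
  fit <- make_fit()
  set.seed(33)
  ks <- c(1L, 2L, 4L, 8L)
  per_group <- 150L
  recs <- do.call(rbind, lapply(seq_along(ks), function(gi) {
    k <- ks[gi]
    data.frame(
      protein_id = rep(sprintf("G%d_%03d", gi, seq_len(per_group)), each = k),
      sequence = random_tmds(per_group * k, seed = 200 + gi),
      start_side = "exo", stringsAsFactors = FALSE)
  }))
  scored <- score_proteome(fit, recs)
  means <- summarize_groups(scored, by = "n_tmds")
  means <- means[order(as.integer(means$group)), ]
  expect_identical(as.integer(means$group), ks)
  expect_true(all(diff(means$mean) > 0))
})

test_that("TMD tables read from TSV with location mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tsequence\tlocation",
               "P1\tKLLV\tCytoplasmic",
               "P2\tKLLV\tExtracellular"), f)
  df <- read_tmd_table(f)
  expect_identical(df$start_side, c("endo", "exo"))
})
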
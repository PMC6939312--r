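make_results <- function(densities, accessions = sprintf("P%03d", seq_along(densities))) {
  tibble::tibble(
    accession = accessions,
    n_idrs = ifelse(is.na(densities), 0L, 1L),
    n_disordered_residues = ifelse(is.na(densities), 0L, 50L),
    abtscore = ifelse(is.na(densities), 0, densities * 50),
    abtdensity = densities
  )
}

test_that("stratification cuts 100 distinct densities into 5/10/15/70", {
  set.seed(51)
  res <- make_results(sample(seq(0.01, 1, length.out = 100)))
  lab <- stratify(res)
  expect_equal(as.vector(table(lab$group)), c(5L, 10L, 15L, 70L))
  # order-isomorphic boundaries: every group-1 density >= every group-2 density
  for (g in 1:3) {
    expect_gte(
      min(lab$abtdensity[lab$group == g]),
      max(lab$abtdensity[lab$group == g + 1])
    )
  }
})

test_that("stratification uses floor arithmetic on small sets", {
  set.seed(52)
  res <- make_results(sample(seq(0.1, 1, length.out = 20)))
  lab <- stratify(res)
  expect_equal(as.vector(table(lab$group)), c(1L, 2L, 3L, 14L))
})

test_that("ties fill groups in stable input order", {
  res <- make_results(rep(0.5, 20))
  lab <- stratify(res)
  expect_equal(as.vector(table(lab$group)), c(1L, 2L, 3L, 14L))
  expect_equal(lab$group[1], 1L) # first input row takes the top slot
  expect_equal(lab$group[2:3], c(2L, 2L))
})

test_that("no-IDR proteins receive no group and all-NA input errors", {
  dens <- c(0.9, NA, 0.5, NA, 0.1)
  lab <- stratify(make_results(dens))
  expect_true(all(is.na(lab$group[is.na(dens)])))
  expect_true(all(!is.na(lab$group[!is.na(dens)])))
  expect_error(stratify(make_results(c(NA_real_, NA_real_))), "defined ABTdensity")
  expect_error(stratify(make_results(0.5), cuts = c(0.3, 0.2)), "strictly increasing")
})

test_that("group summaries partition the ranked proteins", {
  set.seed(53)
  res <- make_results(runif(100))
  lab <- stratify(res)
  summ <- summarize_groups(lab)
  expect_equal(summ$group, 1:4)
  expect_equal(sum(summ$n), 100L)
  expect_equal(summ$n, c(5L, 10L, 15L, 70L))
  expect_true(all(summ$abtdensity_min <= summ$abtdensity_mean))
  expect_true(all(summ$abtdensity_mean <= summ$abtdensity_max))
  # single-protein degenerate summary has min = max
  one <- summarize_groups(stratify(make_results(0.5)))
  expect_equal(one$abtdensity_min, one$abtdensity_max)
})

test_that("subset summaries report medians over the intersection", {
  res <- make_results(c(0.1, 0.2, 0.3, 0.4, NA))
  all_s <- subset_summary(res, res$accession)
  expect_equal(all_s$n, 5L)
  expect_equal(all_s$median_abtdensity, 0.25)
  single <- subset_summary(res, "P002")
  expect_equal(single$median_abtscore, res$abtscore[2])
  with_unknown <- subset_summary(res, c("P001", "NOPE1", "NOPE2"))
  expect_equal(with_unknown$n, 1L)
  expect_equal(with_unknown$n_missing, 2L)
  expect_error(subset_summary(res, c("NOPE")), "no listed accession")
})

test_that("group accession exports have the stratified sizes and are byte-stable", {
  set.seed(54)
  res <- make_results(sample(seq(0.1, 1, length.out = 20)))
  lab <- stratify(res)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_group_accessions(lab, d1)
  export_group_accessions(lab, d2)
  sizes <- vapply(1:4, function(g) {
    length(readLines(file.path(d1, sprintf("group%d_accessions.txt", g))))
  }, integer(1))
  expect_equal(sizes, c(1L, 2L, 3L, 14L))
  for (g in 1:4) {
    f <- sprintf("group%d_accessions.txt", g)
    expect_identical(
      readBin(file.path(d1, f), "raw", 1e5),
      readBin(file.path(d2, f), "raw", 1e5)
    )
  }
  # tiny N: groups can be empty but files still exist
  tiny <- stratify(make_results(c(0.5, 0.7)))
  d3 <- withr::local_tempdir()
  export_group_accessions(tiny, d3)
  expect_true(all(file.exists(file.path(d3, sprintf("group%d_accessions.txt", 1:4)))))
})

test_that("score_proteome skips proteins without tracks and records them", {
  dir <- withr::local_tempdir()
  out <- make_synthetic_proteome(file.path(dir, "fix"), n_proteins = 4, seed = 9)
  # remove one track file
  removed <- file.path(out$disorder_dir, "SYN0002.iupred")
  unlink(removed)
  expect_warning(res <- score_proteome(out$fasta, out$disorder_dir), "SYN0002")
  expect_equal(nrow(res), 3L)
  skipped <- attr(res, "skipped")
  expect_equal(skipped$accession, "SYN0002")
  expect_equal(skipped$reason, "missing disorder track")
})

test_that("score_proteome errors when nothing is scorable", {
  dir <- withr::local_tempdir()
  out <- make_synthetic_proteome(file.path(dir, "fix"), n_proteins = 4, seed = 9)
  empty_dir <- file.path(dir, "empty")
  dir.create(empty_dir)
  expect_error(
    suppressWarnings(score_proteome(out$fasta, empty_dir)),
    "no scorable"
  )
})

test_that("rescoring a proteome is deterministic", {
  dir <- withr::local_tempdir()
  out <- make_synthetic_proteome(file.path(dir, "fix"), n_proteins = 8, seed = 2)
  r1 <- score_proteome(out$fasta, out$disorder_dir)
  r2 <- score_proteome(out$fasta, out$disorder_dir)
  expect_identical(r1$abtscore, r2$abtscore)
  expect_identical(r1$abtdensity, r2$abtdensity)
})
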
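test_that("residue charges follow the D/E/K/R convention", {
  expect_equal(residue_charge("D"), -1L)
  expect_equal(residue_charge("E"), -1L)
  expect_equal(residue_charge("K"), 1L)
  expect_equal(residue_charge("R"), 1L)
  expect_equal(residue_charge(c("H", "X", "U", "G")), rep(0L, 4))
  expect_equal(residue_charge("DRHk"), c(-1L, 1L, 0L, 1L))
})

test_that("NCPR profile matches hand-computed values for the diblock", {
  expect_equal(ncpr_profile("DDDDD"), rep(-1, 5))
  expect_equal(ncpr_profile("GGGGG"), rep(0, 5))
  expect_equal(
    ncpr_profile("DDDDDKKKKK"),
    c(-1, -1, -1, -0.6, -0.2, 0.2, 0.6, 1, 1, 1)
  )
  expect_error(ncpr_profile(""), "non-empty")
  expect_error(ncpr_profile("DDK", 4), "odd")
})

test_that("tract detection splits on zeros and sign changes", {
  tr <- find_tracts(rep(-1, 5))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$sign, -1L)
  expect_equal(tr$area, 5)

  tr <- find_tracts(c(-1, -1, 0, -1, -1))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, c(1L, 4L))

  tr <- find_tracts(rep(c(0.2, -0.2), 3))
  expect_equal(nrow(tr), 6L)
  expect_true(all(tr$end == tr$start))
})

test_that("filtered area sums match hand-worked examples", {
  expect_equal(sum_filtered_areas(ncpr_profile("DDDDDKKKKK")), 7.6)
  expect_equal(sum_filtered_areas(ncpr_profile("DKDKDKDKDK")), 0)
  expect_equal(sum_filtered_areas(ncpr_profile(strrep("G", 20))), 0)
})

test_that("NCPR and tracts agree with naive per-position recomputation", {
  set.seed(13)
  for (i in 1:200) {
    s <- random_aa_seq(sample(5:100, 1))
    prof <- ncpr_profile(s)
    expect_equal(prof, naive_ncpr(s))
    tr <- find_tracts(prof)
    nt <- naive_tracts(prof)
    expect_equal(nrow(tr), length(nt))
    if (length(nt) > 0) {
      expect_equal(tr$start, vapply(nt, function(t) as.integer(t$start), integer(1)))
      expect_equal(tr$area, vapply(nt, `[[`, numeric(1), "area"))
    }
    # unfiltered tract area is bounded by total |NCPR| and sequence length
    expect_lte(sum(tr$area), sum(abs(prof)) + 1e-12)
    expect_lte(sum(abs(prof)), nchar(s))
    # filtered sum is non-increasing in the area threshold
    expect_gte(
      sum_filtered_areas(prof, 0.5),
      sum_filtered_areas(prof, 1.5)
    )
  }
})

test_that("charge fractions count K/R and D/E", {
  expect_equal(charge_fractions("DDKK"), c(f_plus = 0.5, f_minus = 0.5))
  expect_equal(charge_fractions("GGGG"), c(f_plus = 0, f_minus = 0))
  expect_equal(charge_fractions("DDDG"), c(f_plus = 0, f_minus = 0.75))
})

test_that("delta matches the blob-window definition", {
  expect_equal(charge_delta("EEEEEE", 5), 0)
  expect_equal(charge_delta("GGGGGG", 5), 0)
  expect_gt(charge_delta("EEEKKK", 5), 0)
  expect_equal(charge_delta("EEEKKK", 5), naive_delta(naive_charges("EEEKKK"), 5))
  expect_error(charge_delta("EEK", 5), "shorter")
})

test_that("delta_max equals the exhaustive maximum on small compositions", {
  # EEEKKK: its own fully segregated arrangement attains the maximum
  expect_equal(
    charge_delta_max("EEEKKK", 5),
    exhaustive_dmax(3, 3, 0, 5)
  )
  expect_equal(charge_delta_max("EEEKKK", 5), charge_delta("EEEKKK", 5))
  expect_equal(charge_delta_max("GGGGGG", 5), 0)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    p <- sample(0:n, 1)
    m <- sample(0:(n - p), 1)
    seq <- paste(sample(strsplit(
      strrep("K", p) |> paste0(strrep("D", m), strrep("G", n - p - m)), ""
    )[[1]]), collapse = "")
    for (g in c(5, 6)) {
      if (n < g) next
      expect_equal(charge_delta_max(seq, g), exhaustive_dmax(p, m, n - p - m, g),
        tolerance = 1e-12
      )
      expect_gte(charge_delta_max(seq, g) + 1e-12, charge_delta(seq, g))
    }
  }
})

test_that("the constructive fallback stays consistent with the exact program", {
  set.seed(6)
  for (i in 1:10) {
    s <- random_aa_seq(sample(30:60, 1))
    for (g in c(5, 6)) {
      exact <- charge_delta_max(s, g)
      heur <- charge_delta_max(s, g, max_ops = 1) # force the fallback
      expect_lte(heur, exact + 1e-12)
      expect_gte(heur + 1e-12, charge_delta(s, g)) # never below the sequence itself
    }
  }
})

test_that("kappa separates mixed from segregated charge patterns", {
  expect_equal(charge_kappa("EEEEEKKKKK"), 1.0)
  expect_lt(charge_kappa("EKEKEKEKEK"), 0.1)
  expect_true(is.na(charge_kappa("GGGGGGGGGG")))
  expect_true(is.na(charge_kappa("DDDDDDDDDD"))) # one-sign charges: delta always 0
})

test_that("kappa is bounded, reversal-invariant and charge-swap-invariant", {
  set.seed(21)
  for (i in 1:15) {
    s <- random_aa_seq(sample(10:50, 1))
    k <- charge_kappa(s)
    if (is.na(k)) next
    expect_gte(k, 0)
    expect_lte(k, 1 + 1e-12)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(charge_kappa(rev_s), k, tolerance = 1e-9)
    swapped <- chartr("DKER", "KDRE", s)
    expect_equal(charge_kappa(swapped), k, tolerance = 1e-9)
  }
})
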
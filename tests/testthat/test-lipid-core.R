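test_that("species grammar parses and round-trips", {
  sp <- parse_species(c("18:0", "20:4n-6", "18:1n-9 DMA", "16:0 DMA",
                        "22:6n-3", "16:1n-7"))
  expect_equal(sp$carbons, c(18, 20, 18, 16, 22, 16))
  expect_equal(sp$double_bonds, c(0, 4, 1, 0, 6, 1))
  expect_equal(sp$series, c("saturate", "n-6", "DMA", "DMA", "n-3", "n-7"))
  expect_equal(sp$is_dma, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(format_species(sp), sp$name)

  expect_error(parse_species("oleic"), "unparseable")
  expect_error(parse_species("18:1"), "n-series")
  expect_error(parse_species("18:0n-9"), "saturate")
})

test_that("fatty-acid totals partition the profile", {
  expect_equal(compute_totals(c("18:0" = 100))$total_saturates, 100)

  fa <- c("16:0" = 30, "18:0" = 20, "18:1n-9" = 25, "20:4n-6" = 15,
          "22:6n-3" = 10)
  tot <- compute_totals(fa)
  expect_equal(tot$total_saturates, 50)
  expect_equal(tot$total_mufa, 25)
  expect_equal(tot$total_n6, 15)
  expect_equal(tot$total_n3, 10)
  expect_equal(tot$total_lcpufa, 25)

  # partition: saturates + all unsaturates + DMAs = profile sum
  fa2 <- c(fa, "16:0 DMA" = 4, "18:1n-9 DMA" = 2, "18:2n-6" = 6)
  tot2 <- compute_totals(fa2)
  expect_equal(tot2$total_saturates + tot2$total_unsaturates +
                 tot2$total_dma, sum(fa2), tolerance = 1e-12)
  expect_equal(tot2$total_dma, 6)
  # 18:2n-6 is n-6 but not long-chain
  expect_equal(tot2$total_n6, 21)
  expect_equal(tot2$total_n6_lcpufa, 15)
  expect_error(compute_totals(numeric(0)), "empty")
})

test_that("unsaturation and peroxidability indexes follow the standard forms", {
  expect_equal(unsaturation_index(c("16:0" = 100)), 0)
  expect_equal(unsaturation_index(c("18:1n-9" = 100)), 100)
  expect_equal(unsaturation_index(c("18:0" = 50, "22:6n-3" = 50)), 300)
  expect_equal(peroxidability_index(c("16:0" = 100)), 0)
  expect_equal(peroxidability_index(c("22:6n-3" = 100)), 800)
  expect_equal(peroxidability_index(c("18:1n-9" = 100)), 2.5)
  # DMAs carry chain unsaturation but are excluded from both indexes
  expect_equal(unsaturation_index(c("18:1n-9 DMA" = 50, "16:0" = 50)), 0)
})

test_that("indexes are linear in the profile and ratios scale-invariant", {
  set.seed(42)
  toks <- c("16:0", "18:0", "18:1n-9", "18:2n-6", "20:4n-6", "22:6n-3",
            "16:0 DMA")
  for (i in 1:5) {
    a <- setNames(stats::runif(7, 1, 30), toks)
    b <- setNames(stats::runif(7, 1, 30), toks)
    al <- stats::runif(1)
    mix <- al * a + (1 - al) * b
    expect_equal(unsaturation_index(mix),
                 al * unsaturation_index(a) + (1 - al) * unsaturation_index(b),
                 tolerance = 1e-12)
    expect_equal(peroxidability_index(mix),
                 al * peroxidability_index(a) +
                   (1 - al) * peroxidability_index(b),
                 tolerance = 1e-12)
    # ratio operations are invariant under renormalization to 100
    lc <- setNames(stats::runif(6, 1, 30),
                   c("PC", "PE", "PS", "SM", "CHO", "SE"))
    lc100 <- 100 * lc / sum(lc)
    expect_equal(class_ratios(lc)$cho_se_ratio,
                 class_ratios(lc100)$cho_se_ratio, tolerance = 1e-12)
    expect_equal(class_ratios(lc)$anionic_zwitterionic_ratio,
                 class_ratios(lc100)$anionic_zwitterionic_ratio,
                 tolerance = 1e-12)
  }
})

test_that("class ratios follow the published definitions", {
  lc <- c(CHO = 40, SE = 10, PG = 5, PI = 5, PS = 10, PC = 20, PE = 20,
          SM = 10, SULF = 6, OTHER_SL = 4)
  cr <- class_ratios(lc)
  expect_equal(cr$cho_se_ratio, 4)
  expect_equal(cr$anionic_zwitterionic_ratio, 0.5)
  expect_equal(cr$total_sphingolipids, 20)
  # zero denominator flags, does not throw
  expect_true(is.nan(class_ratios(c(CHO = 40, SE = 0))$cho_se_ratio))
})

test_that("cohort CSV round-trips and validates closure", {
  df <- toy_cohort_df()
  co <- as_raft_cohort(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  expect_setequal(fa_cols(back), fa_cols(co))

  bad <- df
  bad[1, "16:0"] <- bad[1, "16:0"] - 10  # row sums to 90
  expect_error(as_raft_cohort(bad), "closure.*N1")
  warn <- df
  warn[1, "16:0"] <- warn[1, "16:0"] + 2
  expect_warning(as_raft_cohort(warn), "100")

  dup <- df; dup$subject_id[2] <- "N1"
  expect_error(as_raft_cohort(dup), "duplicate")
  nogrp <- df; nogrp$group <- NULL
  expect_error(as_raft_cohort(nogrp), "group")
  unk <- df; names(unk)[6] <- "not-a-species"
  expect_error(as_raft_cohort(unk), "unparseable")
})

test_that("derived index set assembles per subject and exports JSON", {
  co <- as_raft_cohort(toy_cohort_df())
  idx <- derive_indexes(co)
  expect_equal(nrow(idx), 6)
  expect_equal(idx$sat_unsat_ratio[1], 50 / 50)
  expect_equal(idx$uix[1], 25 + 60 + 60)
  path <- withr::local_tempfile(fileext = ".json")
  export_indexes_json(co, path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$uix, idx$uix)
})
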
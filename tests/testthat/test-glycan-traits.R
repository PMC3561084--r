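toy_peak_table <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("peak_id\tstructures",
               "GP4\tFA2",
               "GP8\tA2[6]G1",
               "GP9\tFA2[3]G1",
               "GP18\tFA2G2S1"), path)
  read_peak_table(path)
}

test_that("profile normalization is proportional, idempotent, and guards zeros", {
  eq <- matrix(1, 2, 24, dimnames = list(c("a", "b"), sprintf("GP%d", 1:24)))
  expect_equal(unname(normalize_profiles(eq)[1, ]), rep(100 / 24, 24))
  x <- matrix(0, 1, 24, dimnames = list("a", sprintf("GP%d", 1:24)))
  x[1, 1] <- 3; x[1, 2] <- 1
  norm <- normalize_profiles(x)
  expect_equal(unname(norm[1, 1:2]), c(75, 25))
  expect_equal(normalize_profiles(norm), norm)
  expect_error(normalize_profiles(matrix(0, 1, 24)), "degenerate")
  expect_error(normalize_profiles(-x), "non-negative")
})

test_that("peak selection uses the major structure and supports degenerate predicates", {
  toy <- toy_peak_table()
  expect_identical(
    select_peaks(toy, fucosylated = TRUE, galactoses = 1, neutral = TRUE),
    "GP9")
  expect_length(select_peaks(toy, galactoses = 2, neutral = TRUE), 0L)
  pt <- default_peak_table()
  expect_length(select_peaks(pt), 24L)
  expect_setequal(select_peaks(pt, neutral = FALSE),
                  sprintf("GP%d", 16:24))
})

test_that("trait expressions evaluate to hand-computed values", {
  pt <- default_peak_table()
  reg <- default_trait_registry()
  # profile: GP9 = 10, remaining neutral mass 70 spread over neutral peaks,
  # sialylated mass 20 -> neutral sum 80, IGP48 = 100*10/80 = 12.5
  prof <- matrix(0, 1, 24, dimnames = list("s1", sprintf("GP%d", 1:24)))
  prof[1, "GP9"] <- 10
  prof[1, c("GP1", "GP4", "GP6", "GP14")] <- 70 / 4
  prof[1, c("GP18", "GP23")] <- 10
  igp48 <- evaluate_trait(reg[reg$trait_id == "IGP48", ], prof, pt)
  expect_equal(igp48, 12.5)
  # all monogalactosylated neutral peaks fucosylated -> IGP64 = 100
  igp64 <- evaluate_trait(reg[reg$trait_id == "IGP64", ], prof, pt)
  expect_equal(igp64, 100)
  # direct traits are the peak percentages themselves
  igp8 <- evaluate_trait(reg[reg$trait_id == "IGP8", ], prof, pt)
  expect_equal(igp8, 10)
})

test_that("unknown peak references are reported", {
  pt <- default_peak_table()
  spec <- data.frame(trait_id = "X", kind = "ratio", expression = "GP99 / GP1",
                     description = "", stringsAsFactors = FALSE)
  prof <- matrix(100 / 24, 1, 24, dimnames = list("s", sprintf("GP%d", 1:24)))
  expect_error(evaluate_trait(spec, prof, pt), "GP99")
})

test_that("the full trait matrix respects conservation, scale and range invariants", {
  prof <- simulate_glycome_profiles(8, seed = 41)
  igp <- derive_all_traits(prof)
  reg <- default_trait_registry()
  expect_identical(colnames(igp), reg$trait_id)
  # conservation: direct traits sum to 100 per sample
  direct <- reg$trait_id[reg$kind == "direct"]
  expect_equal(unname(rowSums(igp[, direct])), rep(100, 8), tolerance = 1e-9)
  # ratio traits are scale invariant
  igp_scaled <- derive_all_traits(prof * 3.7)
  expect_equal(igp_scaled, igp, tolerance = 1e-10)
  # percentage-of-class traits stay within [0, 100]
  perc <- reg$trait_id[reg$kind %in% c("direct", "percentage")]
  expect_true(all(igp[, perc] >= 0 & igp[, perc] <= 100 + 1e-9, na.rm = TRUE))
  # identical profiles give identical rows
  rep3 <- prof[c(1, 1, 1), ]
  rownames(rep3) <- c("a", "b", "c")
  igp3 <- derive_all_traits(rep3)
  expect_equal(unname(igp3[1, ]), unname(igp3[3, ]))
  expect_error(derive_all_traits(prof[c(1, 1), ]), "duplicate sample")
})

test_that("rescaling a sialylated peak leaves within-neutral-fraction traits unchanged", {
  prof <- simulate_glycome_profiles(5, seed = 7)
  igp <- derive_all_traits(prof)
  prof2 <- prof
  prof2[, "GP18"] <- prof2[, "GP18"] * 2   # sialylated peak
  igp2 <- derive_all_traits(prof2)
  neutral_traits <- c("IGP48", "IGP55", "IGP56", "IGP57", "IGP64", "IGP76")
  expect_equal(igp2[, neutral_traits], igp[, neutral_traits], tolerance = 1e-9)
})

test_that("zero class denominators become missing values, not errors", {
  prof <- simulate_glycome_profiles(3, seed = 11)
  prof[, c("GP5", "GP6")] <- 0   # no fucosylated+bisecting agalactosylated mass
  igp <- derive_all_traits(prof)
  expect_true(all(is.na(igp[, "IGP73"])))
  expect_true(attr(igp, "n_missing") >= 3)
})

test_that("the one-to-one direct map emits 24 conserved direct traits", {
  reg <- default_trait_registry(direct_map = "one_to_one")
  expect_equal(sum(reg$kind == "direct"), 24L)
  prof <- simulate_glycome_profiles(3, seed = 5)
  igp <- derive_all_traits(prof, registry = reg)
  expect_equal(unname(rowSums(igp[, sprintf("IGP%d", 1:24)])), rep(100, 3),
               tolerance = 1e-9)
})

test_that("trait matrices and glycome profiles round-trip through TSV", {
  prof <- simulate_glycome_profiles(4, seed = 3)
  igp <- derive_all_traits(prof)
  tf <- tempfile(fileext = ".tsv")
  write_trait_tsv(igp, tf)
  back <- read_trait_tsv(tf)
  expect_equal(unname(back), unname(igp[, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  gf <- tempfile(fileext = ".tsv")
  write_glycome_tsv(prof, gf)
  expect_equal(read_glycome_tsv(gf), prof, tolerance = 1e-12)
})
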
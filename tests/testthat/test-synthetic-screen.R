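test_that("ground-truth objects validate their parameters", {
  expect_s3_class(ground_truth(), "ground_truth")
  expect_error(ground_truth(noise_sd = c(cytotoxicity = -1, stemness = 1)),
               "nonnegative")
  expect_error(ground_truth(clip = list(cytotoxicity = c(1, 0),
                                        stemness = c(0, 100))), "lo < hi")
  expect_error(ground_truth(baseline = c(cytotoxicity = NA, stemness = 1)),
               "finite")
})

test_that("zero effects and zero noise reproduce the baseline exactly", {
  gt <- ground_truth(noise_sd = c(cytotoxicity = 0, stemness = 0))
  screen <- generate_screen(gt, n_records = 50, seed = 1)
  expect_equal(unique(1 - screen$nalm6_survival), gt$baseline[["cytotoxicity"]])
  expect_equal(unique(screen$stemness), gt$baseline[["stemness"]])
})

test_that("a single planted positive motif effect separates domains strictly", {
  gt <- ground_truth(
    additive = tibble::tibble(motif = "M9", cytotoxicity = 0.1, stemness = 5),
    noise_sd = c(cytotoxicity = 0, stemness = 0)
  )
  screen <- generate_screen(gt, n_records = 246, seed = 4)
  cyto <- 1 - screen$nalm6_survival
  has_m9 <- grepl("\\bM9\\b", screen$domain_label)
  expect_gt(min(cyto[has_m9]), max(cyto[!has_m9]))
})

test_that("screen generation is deterministic and byte-stable on disk", {
  gt <- ground_truth_regime("default")
  s1 <- generate_screen(gt, n_records = 100, seed = 9)
  s2 <- generate_screen(gt, n_records = 100, seed = 9)
  expect_identical(s1, s2)
  f1 <- tempfile(); f2 <- tempfile()
  write_screen_table(s1, f1); write_screen_table(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(s1, generate_screen(gt, n_records = 100, seed = 10)))
})

test_that("sampling respects the candidate pool size", {
  gt <- ground_truth_regime("default")
  lib <- tiny_library(2, 2) # 6 domains
  dom <- enumerate_domains(lib)
  expect_error(generate_screen(gt, dom, n_records = 7, library = lib),
               "exceeds")
  expect_equal(nrow(generate_screen(gt, dom, n_records = 6, library = lib)), 6)
})

test_that("measurement noise matches its nominal standard deviation", {
  # midrange baseline and no effects so clipping never triggers
  gt <- ground_truth(baseline = c(cytotoxicity = 0.5, stemness = 50),
                     noise_sd = c(cytotoxicity = 0.08, stemness = 2.5))
  screen <- generate_screen(gt, n_records = 1000, seed = 6)
  resid_c <- (1 - screen$nalm6_survival) - 0.5
  resid_s <- screen$stemness - 50
  expect_lt(abs(sd(resid_c) - 0.08) / 0.08, 0.1)
  expect_lt(abs(sd(resid_s) - 2.5) / 2.5, 0.1)
})

test_that("noiseless generated phenotypes equal the analytic model", {
  gt <- ground_truth_regime("default")
  lib <- motif_library()
  tp <- true_phenotypes(gt, c("M9-M10-M1", "M1", "M6-M6", "M13-M13-M13"), lib)
  a <- function(m, ph) {
    i <- match(m, gt$additive$motif)
    ifelse(is.na(i), 0, gt$additive[[ph]][i])
  }
  # M9-M10-M1: additive + positional (M9@i, M1@k) + pairs (M1,M10),(M1,M9),(M9,M10)
  expect_equal(
    tp$cytotoxicity[1],
    gt$baseline[["cytotoxicity"]] + a("M9", "cytotoxicity") +
      a("M10", "cytotoxicity") + a("M1", "cytotoxicity") + 0.03 + 0.04 +
      0.06 + 0.05 + 0.04
  )
  # single M1 sits at slot i (positional -0.04), no pairs
  expect_equal(tp$cytotoxicity[2],
               gt$baseline[["cytotoxicity"]] + a("M1", "cytotoxicity") - 0.04)
  # M6-M6 counts the additive twice plus the self-pair once
  expect_equal(tp$cytotoxicity[3],
               gt$baseline[["cytotoxicity"]] + 2 * a("M6", "cytotoxicity") - 0.03)
  # all-spacer domain is pure baseline
  expect_equal(tp$cytotoxicity[4], gt$baseline[["cytotoxicity"]])
})

test_that("recovery metrics are bounded and need matching motif sets", {
  gt <- ground_truth_regime("strong")
  me <- tibble::tibble(motif = paste0("M", 1:12),
                       mean_percentile = withr::with_seed(1, stats::runif(12, 0, 100)),
                       n_domains = 1, sem = NA_real_)
  rr <- recovery_report(gt, me, "cytotoxicity")
  expect_true(abs(rr$additive_rank_correlation) <= 1)
  expect_true(is.na(rr$pair_hit_rate))
  expect_error(recovery_report(gt, me[1:4, ], "cytotoxicity"), "mismatch")
})

test_that("null screens carry no recoverable motif signal", {
  lib <- motif_library()
  dom <- enumerate_domains(lib)
  gt_null <- ground_truth_regime("null")
  gt_strong <- ground_truth_regime("strong")
  cors <- purrr::map_dbl(1:5, function(s) {
    screen <- generate_screen(gt_null, dom, n_records = 246, seed = s)
    ranked <- percentile_rank(
      dplyr::mutate(screen, mean = 1 - .data$nalm6_survival), "mean")
    me <- motif_enrichment(ranked, lib)
    # score correlation against the strong regime's planted effects: there is
    # nothing to recover, so it should hover near zero
    recovery_report(gt_strong, me, "cytotoxicity")$additive_rank_correlation
  })
  expect_lt(mean(abs(cors)), 0.3)
})
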
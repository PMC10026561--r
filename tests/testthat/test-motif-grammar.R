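test_that("percentile ranking follows the (rank - 0.5)/N convention", {
  p4 <- percentile_rank(tibble::tibble(domain_label = paste0("M", 1:4),
                                       mean = c(0.3, 0.1, 0.9, 0.5)))
  expect_equal(sort(p4$percentile), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(p4$percentile[p4$mean == 0.1], 12.5)
  ties <- percentile_rank(tibble::tibble(domain_label = paste0("M", 1:5),
                                         mean = rep(1, 5)))
  expect_equal(ties$percentile, rep(50, 5))
  expect_error(percentile_rank(tibble::tibble(domain_label = "M1", mean = 1)),
               "at least 2")
})

test_that("mean percentile is exactly 50 and oracle-exact for arbitrary scores", {
  for (seed in 1:5) {
    scores <- withr::with_seed(seed, {
      x <- stats::rnorm(97)
      x[sample(97, 10)] <- x[1] # inject ties
      x
    })
    tab <- percentile_rank(tibble::tibble(domain_label = paste0("d", 1:97),
                                          mean = scores))
    expect_equal(mean(tab$percentile), 50)
    expect_true(all(tab$percentile > 0 & tab$percentile < 100))
    expect_equal(tab$percentile, oracle_percentiles(scores))
  }
})

test_that("enrichment statistics match the brute-force oracle on small libraries", {
  lib <- tiny_library(4, 3) # 84 domains; subsample to <= 50
  dom <- enumerate_domains(lib)
  for (seed in 1:3) {
    sub <- withr::with_seed(seed, dom[sample(nrow(dom), 50), ])
    ranked <- percentile_rank(fake_predictions(sub, seed))
    sig <- signaling_motifs(lib)
    me <- motif_enrichment(ranked, lib)
    pe <- pair_enrichment(ranked, lib)
    pos <- position_enrichment(ranked, lib)
    for (m in sig) {
      o <- oracle_motif_mean(ranked$domain_label, ranked$percentile, m)
      row <- me[me$motif == m, ]
      expect_equal(row$mean_percentile, o$mean, tolerance = 1e-9)
      expect_equal(row$n_domains, o$n)
    }
    for (r in seq_len(nrow(pe))) {
      o <- oracle_pair_mean(ranked$domain_label, ranked$percentile,
                            pe$motif_a[r], pe$motif_b[r])
      expect_equal(pe$mean_percentile[r], o$mean, tolerance = 1e-9)
      expect_equal(pe$n_domains[r], o$n)
    }
    for (m in sig) {
      for (s in 1:3) {
        o <- oracle_position_mean(ranked$domain_label, ranked$percentile, m, s)
        row <- pos[pos$motif == m & pos$position == c("i", "j", "k")[s], ]
        expect_equal(row$mean_percentile, o$mean, tolerance = 1e-9)
        expect_equal(row$n_domains, o$n)
      }
    }
  }
})

test_that("motif statistics count a domain once regardless of copy number", {
  lib <- motif_library()
  ranked <- percentile_rank(tibble::tibble(
    domain_label = c("M9-M9-M9", "M9-M1", "M2"),
    mean = c(0.9, 0.5, 0.1)
  ))
  me <- motif_enrichment(ranked, lib, motifs = "M9")
  expect_equal(me$n_domains, 2)
  expect_equal(me$mean_percentile,
               mean(ranked$percentile[ranked$domain_label != "M2"]))
})

test_that("self-pairs require multiplicity two and the matrix is symmetric", {
  lib <- motif_library()
  ranked <- percentile_rank(tibble::tibble(
    domain_label = c("M9-M9-M1", "M9-M9-M2", "M9-M1", "M9-M10-M9"),
    mean = c(0.9, 0.4, 0.5, 0.7)
  ))
  pe <- pair_enrichment(ranked, lib)
  m99 <- pe[pe$motif_a == "M9" & pe$motif_b == "M9", ]
  expect_equal(m99$n_domains, 3) # M9-M1 has only one copy
  expect_equal(m99$mean_percentile,
               mean(ranked$percentile[ranked$domain_label != "M9-M1"]))
  M <- pair_matrix(pe, lib)
  expect_true(isSymmetric(M))
  expect_equal(dim(M), c(12, 12))
  # spacer excluded from the report
  expect_false(any(c(pe$motif_a, pe$motif_b) == "M13"))
})

test_that("unobserved cells are flagged, never silently zero", {
  lib <- motif_library()
  singles <- tibble::tibble(domain_label = paste0("M", 1:12),
                            mean = (1:12) / 12)
  ranked <- percentile_rank(singles)
  pos <- position_enrichment(ranked, lib)
  jk <- pos[pos$position != "i", ]
  expect_true(all(jk$n_domains == 0))
  expect_true(all(is.na(jk$mean_percentile)))
  pe <- pair_enrichment(ranked, lib)
  expect_true(all(pe$n_domains == 0))
})

test_that("enrichment is invariant to adding a constant to all predictions", {
  lib <- tiny_library(5, 3)
  dom <- enumerate_domains(lib)
  preds <- fake_predictions(dom, 3)
  shifted <- dplyr::mutate(preds, mean = mean + 7.3)
  r1 <- percentile_rank(preds); r2 <- percentile_rank(shifted)
  expect_equal(motif_enrichment(r1, lib), motif_enrichment(r2, lib))
  expect_equal(pair_enrichment(r1, lib), pair_enrichment(r2, lib))
  expect_equal(position_enrichment(r1, lib), position_enrichment(r2, lib))
})

test_that("random scores leave every motif near the 50th percentile", {
  lib <- tiny_library(6, 3) # 258 domains
  dom <- enumerate_domains(lib)
  reps <- purrr::map_dfr(1:100, function(s) {
    motif_enrichment(percentile_rank(fake_predictions(dom, s)), lib)
  })
  avg <- dplyr::summarise(dplyr::group_by(reps, .data$motif),
                          m = mean(.data$mean_percentile))
  expect_true(all(abs(avg$m - 50) < 3))
})

test_that("permutation-null exceedance of the 95th null quantile stays near 5%", {
  lib <- tiny_library(6, 3)
  dom <- enumerate_domains(lib)
  base <- fake_predictions(dom, 1)
  perm_stats <- function(seed) {
    perm <- withr::with_seed(seed, dplyr::mutate(base, mean = sample(mean)))
    me <- motif_enrichment(percentile_rank(perm), lib)
    abs(me$mean_percentile - 50)
  }
  null_mat <- vapply(1:150, perm_stats, numeric(6))
  q95 <- apply(null_mat, 1, quantile, probs = 0.95)
  eval_mat <- vapply(151:200, perm_stats, numeric(6))
  exceed <- mean(eval_mat > q95)
  expect_lte(exceed, 0.10)
})

test_that("combined pair ranking sorts by percentile sum with flagged ties", {
  lib <- tiny_library(4, 3)
  dom <- enumerate_domains(lib)
  ranked <- percentile_rank(fake_predictions(dom, 9))
  pe <- pair_enrichment(ranked, lib)
  same <- rank_pairs_combined(pe, pe)
  expect_equal(same$combined, 2 * same$cytotoxicity)
  expect_equal(same$motif_a, pe$motif_a[order(-pe$mean_percentile)])
  expect_true(all(diff(same$combined) <= 0))
  expect_error(rank_pairs_combined(pe, pe[-1, ]), "share")
  tied <- tibble::tibble(motif_a = c("M1", "M2"), motif_b = c("M2", "M3"),
                         mean_percentile = c(60, 60), n_domains = c(5, 5))
  rt <- rank_pairs_combined(tied, tied)
  expect_true(all(rt$tied))
})
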
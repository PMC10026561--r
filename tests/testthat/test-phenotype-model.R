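# model-dependent tests share one small trained ensemble
lib_pm <- motif_library()
screen_pm <- average_replicates(normalize_phenotypes(
  generate_screen(ground_truth_regime("default"), n_records = 150, seed = 5,
                  library = lib_pm)))
fit_pm <- train_ensemble(screen_pm, "cytotoxicity", lib_pm,
                         variants = quick_variants(4), master_seed = 5)

test_that("the default configuration trains ten distinct members", {
  v <- default_variants()
  expect_equal(nrow(v), 10)
  expect_false(any(duplicated(v[c("hidden_width", "decay")])))
  small <- average_replicates(normalize_phenotypes(
    generate_screen(ground_truth_regime("default"), n_records = 60, seed = 1)))
  fit <- train_ensemble(small, "cytotoxicity", lib_pm, master_seed = 1)
  expect_length(fit$members, 10)
  expect_equal(glance(fit)$n_members, 10)
  expect_equal(nrow(tidy(fit)), 10)
})

test_that("training and prediction are deterministic under the master seed", {
  f1 <- train_ensemble(screen_pm, "cytotoxicity", lib_pm,
                       variants = quick_variants(3), master_seed = 11)
  f2 <- train_ensemble(screen_pm, "cytotoxicity", lib_pm,
                       variants = quick_variants(3), master_seed = 11)
  labels <- c("M9-M10-M1", "M6", "M1-M1-M1")
  expect_identical(predict(f1, labels)$mean, predict(f2, labels)$mean)
  f3 <- train_ensemble(screen_pm, "cytotoxicity", lib_pm,
                       variants = quick_variants(3), master_seed = 12)
  expect_false(identical(predict(f1, labels)$mean, predict(f3, labels)$mean))
})

test_that("ensemble aggregation is the member mean with sem = sd/sqrt(m)", {
  dom <- parse_domain_label(c("M1", "M2-M3", "M9-M10-M1", "M13", "M6-M6-M6"),
                            lib_pm)
  p <- predict(fit_pm, dom)
  members <- attr(p, "members")
  expect_equal(ncol(members), 4)
  expect_equal(p$mean, rowMeans(members))
  expect_equal(p$sem, apply(members, 1, sd) / sqrt(ncol(members)))
  # identical members => sem 0
  clone <- fit_pm
  clone$members <- rep(clone$members[1], 4)
  expect_equal(predict(clone, dom)$sem, rep(0, nrow(dom)))
})

test_that("the full enumerated library yields one prediction per domain", {
  dom <- enumerate_domains(lib_pm)
  p <- predict(fit_pm, dom)
  expect_equal(nrow(p), 2379)
  expect_identical(p$domain_label, dom$domain_label)
  expect_true(all(is.finite(p$mean)))
})

test_that("evaluation implements rmse and R-squared by definition", {
  ev <- evaluate_ensemble(fit_pm, screen_pm)
  obs <- screen_pm$cytotoxicity
  pred <- predict(fit_pm, screen_pm$domain_label)$mean
  expect_equal(ev$rmse, sqrt(mean((obs - pred)^2)))
  expect_equal(ev$r_squared,
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_lte(ev$r_squared, 1)
  expect_error(evaluate_ensemble(fit_pm, screen_pm[0, ]), "no records")
})

test_that("constant targets warn and fit an intercept-only ensemble", {
  const <- dplyr::mutate(screen_pm[1:20, ], cytotoxicity = 0.4)
  expect_warning(
    fit <- train_ensemble(const, "cytotoxicity", lib_pm,
                          variants = quick_variants(2), master_seed = 1),
    "constant")
  p <- predict(fit, c("M1", "M9-M10"))
  expect_equal(p$mean, c(0.4, 0.4))
  ev <- evaluate_ensemble(fit, const)
  expect_equal(ev$rmse, 0)
  expect_true(is.na(ev$r_squared))
})

test_that("a noiseless additive screen is fit nearly perfectly", {
  gt <- ground_truth_regime("default")
  gt0 <- ground_truth(additive = gt$additive,
                      noise_sd = c(cytotoxicity = 0, stemness = 0))
  screen <- average_replicates(normalize_phenotypes(
    generate_screen(gt0, n_records = 200, seed = 3, library = lib_pm)))
  fit <- train_ensemble(screen, "cytotoxicity", lib_pm, master_seed = 3)
  ev <- evaluate_ensemble(fit, screen)
  expect_lt(ev$rmse, 0.02)
  expect_gte(ev$r_squared, 0.99)
})

test_that("test error cannot beat the irreducible noise floor", {
  gt <- ground_truth_regime("default")
  screen <- average_replicates(normalize_phenotypes(
    generate_screen(gt, n_records = 246, seed = 21, library = lib_pm)))
  sp <- split_screen(screen, 25, seed = 21)
  for (ph in c("cytotoxicity", "stemness")) {
    fit <- train_ensemble(sp$train, ph, lib_pm, master_seed = 21)
    ev <- evaluate_ensemble(fit, sp$test)
    expect_gte(ev$rmse, gt$noise_sd[[ph]] * 0.9)
  }
})

test_that("untrained or mismatched inputs are rejected", {
  broken <- fit_pm
  broken$members <- list()
  expect_error(predict(broken, "M1"), "no trained members")
  expect_error(train_ensemble(screen_pm, "stemness", lib_pm,
                              variants = quick_variants(2), master_seed = 1),
               NA) # stemness column exists: trains fine
  no_ph <- dplyr::select(screen_pm, -"cytotoxicity")
  expect_error(train_ensemble(no_ph, "cytotoxicity", lib_pm), "column")
})
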
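#' Default hyperparameter variants for the ensemble
#'
#' The ensemble deliberately trains members with *different* hyperparameters
#' rather than bootstrap resamples: the default grid is a ladder of ten
#' hidden-layer widths from 2 to 24 units at a common mild weight decay,
#' giving ten distinct feed-forward regressors whose disagreement (s.e.m.
#' across members) expresses model uncertainty. Narrow members act as
#' strongly constrained, nearly additive regressors; wide members can
#' capture pair and position interactions.
#'
#' @param n_members Number of variants (default 10).
#' @return A tibble with columns `variant`, `hidden_width`, `decay`, `maxit`.
#' @export
default_variants <- function(n_members = 10) {
  widths <- c(2, 3, 4, 6, 8, 10, 12, 16, 20, 24)
  tibble::tibble(
    variant = seq_len(n_members),
    hidden_width = rep(widths, length.out = n_members),
    decay = 0.01,
    maxit = 400L
  )
}

phenotype_scale <- function(phenotype) {
  switch(phenotype,
    cytotoxicity = c(0, 1),
    stemness = c(0, 100),
    abort(paste0("unknown phenotype: ", phenotype))
  )
}

#' Train a phenotype ensemble
#'
#' Fits one single-hidden-layer feed-forward network (linear output,
#' squared-error loss, weight-decay regularisation; [nnet::nnet()]) per
#' hyperparameter variant, mapping the one-hot domain encoding to the
#' phenotype. The target is rescaled to \[0,1\] internally so cytotoxicity
#' and stemness train identically; predictions are returned on the native
#' scale. All stochasticity (weight initialisation per member) derives from
#' `master_seed`, so identical data + config + seed reproduce the model
#' bit-for-bit.
#'
#' @param records Normalized screen records with `domain_label` and the
#'   phenotype column.
#' @param phenotype `"cytotoxicity"` or `"stemness"`.
#' @param library The [motif_library()] defining the encoding.
#' @param variants Hyperparameter tibble, see [default_variants()].
#' @param master_seed Integer master seed.
#' @return An object of class `car_ensemble`.
#' @export
train_ensemble <- function(records, phenotype = c("cytotoxicity", "stemness"),
                           library = motif_library(),
                           variants = default_variants(),
                           master_seed = 1) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  if (!phenotype %in% names(records)) {
    abort(paste0("records lack a '", phenotype, "' column"))
  }
  X <- encode_domains(records$domain_label, library)
  y <- records[[phenotype]]
  if (any(!is.finite(y))) abort("phenotype values must be finite")
  rng <- phenotype_scale(phenotype)
  y01 <- (y - rng[1]) / (rng[2] - rng[1])
  constant <- sd(y) == 0
  if (constant) {
    warn("constant phenotype target; fitting intercept-only members")
  }
  member_seeds <- withr::with_seed(master_seed,
                                   sample.int(.Machine$integer.max - 1,
                                              nrow(variants)))
  members <- purrr::pmap(
    list(variants$hidden_width, variants$decay, variants$maxit, member_seeds),
    function(width, decay, maxit, seed) {
      if (constant) {
        return(list(type = "constant", value = y01[1]))
      }
      fit <- withr::with_seed(seed, nnet::nnet(
        x = X, y = y01, size = width, decay = decay, maxit = maxit,
        linout = TRUE, trace = FALSE, MaxNWts = 10000
      ))
      list(type = "nnet", fit = fit)
    }
  )
  structure(
    list(
      phenotype = phenotype,
      members = members,
      variants = variants,
      library = library,
      y_range = rng,
      n_train = nrow(records),
      manifest = list(
        master_seed = as.integer(master_seed),
        member_seeds = member_seeds,
        data_fingerprint = rlang::hash(list(records$domain_label, y)),
        n_train = nrow(records)
      )
    ),
    class = "car_ensemble"
  )
}

#' @export
print.car_ensemble <- function(x, ...) {
  cat("<car_ensemble> ", length(x$members), "-member ", x$phenotype,
      " ensemble trained on ", x$n_train, " records (seed ",
      x$manifest$master_seed, ")\n", sep = "")
  invisible(x)
}

member_predictions <- function(object, X) {
  cols <- lapply(object$members, function(m) {
    if (m$type == "constant") rep(m$value, nrow(X))
    else as.numeric(predict(m$fit, X))
  })
  p01 <- do.call(cbind, cols)
  rng <- object$y_range
  p01 * (rng[2] - rng[1]) + rng[1]
}

#' Predict phenotypes for domains
#'
#' The ensemble prediction is the arithmetic mean across members; `sem` is
#' the member standard deviation divided by the square root of the member
#' count. The full per-member prediction matrix is attached as attribute
#' `"members"` so downstream enrichment can be recomputed per member.
#'
#' @param object A trained [train_ensemble()] model.
#' @param newdata Domains tibble (e.g. [enumerate_domains()]) or character
#'   labels.
#' @param ... Unused.
#' @return A tibble with `domain_label`, `mean`, `sem`.
#' @export
predict.car_ensemble <- function(object, newdata, ...) {
  if (length(object$members) == 0) abort("ensemble has no trained members")
  if (is.character(newdata)) newdata <- parse_domain_label(newdata, object$library)
  X <- encode_domains(newdata, object$library)
  preds <- member_predictions(object, X)
  out <- tibble::tibble(
    domain_label = newdata$domain_label,
    mean = rowMeans(preds),
    sem = apply(preds, 1, sd) / sqrt(ncol(preds))
  )
  attr(out, "members") <- preds
  out
}

#' Evaluate an ensemble against observed records
#'
#' Computes the root mean squared error of the ensemble-mean prediction and
#' the coefficient of determination `1 - SS_res/SS_tot`.
#'
#' @param model A trained `car_ensemble`.
#' @param records Screen records carrying the model's phenotype column.
#' @return A one-row tibble: `phenotype`, `n`, `rmse`, `r_squared`.
#' @export
evaluate_ensemble <- function(model, records) {
  stopifnot(inherits(model, "car_ensemble"))
  if (nrow(records) < 1) abort("no records to evaluate")
  obs <- records[[model$phenotype]]
  pred <- predict(model, records$domain_label)$mean
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  tibble::tibble(
    phenotype = model$phenotype,
    n = nrow(records),
    rmse = sqrt(ss_res / nrow(records)),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  )
}

#' @describeIn train_ensemble Per-member hyperparameters and seeds.
#' @param x A `car_ensemble`.
#' @param ... Unused.
#' @export
tidy.car_ensemble <- function(x, ...) {
  dplyr::mutate(x$variants,
    member_seed = x$manifest$member_seeds,
    type = purrr::map_chr(x$members, "type")
  )
}

#' @describeIn train_ensemble One-row model summary.
#' @export
glance.car_ensemble <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype,
    n_members = length(x$members),
    n_train = x$n_train,
    master_seed = x$manifest$master_seed
  )
}
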
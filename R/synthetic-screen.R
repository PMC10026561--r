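#' Specify the ground truth of a synthetic arrayed screen
#'
#' The generative model for a synthetic screen is additive on each
#' phenotype's native scale: a baseline, one additive effect per motif copy,
#' a positional modifier per (motif, slot) occurrence, and one interaction
#' per unordered motif pair present in the domain. Gaussian measurement
#' noise is added and the result clipped to the phenotype's range
#' (cytotoxicity 0-1, stemness 0-100 by default).
#'
#' @param baseline Named numeric, baseline per phenotype, e.g.
#'   `c(cytotoxicity = 0.45, stemness = 35)`.
#' @param additive Tibble `motif`, `cytotoxicity`, `stemness`: per-copy
#'   additive effects. Motifs omitted have effect 0.
#' @param positional Tibble `motif`, `position`, `cytotoxicity`, `stemness`:
#'   modifiers applied when the motif occupies that slot. May be empty.
#' @param pairs Tibble `motif_a`, `motif_b`, `cytotoxicity`, `stemness`:
#'   interaction added once per unordered pair present (self pairs need two
#'   copies). May be empty.
#' @param noise_sd Named numeric, measurement noise s.d. per phenotype.
#' @param clip List of length-2 ranges per phenotype.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(baseline = c(cytotoxicity = 0.45, stemness = 35),
                         additive = NULL, positional = NULL, pairs = NULL,
                         noise_sd = c(cytotoxicity = 0.08, stemness = 2.5),
                         clip = list(cytotoxicity = c(0, 1),
                                     stemness = c(0, 100))) {
  empty_add <- tibble::tibble(motif = character(), cytotoxicity = numeric(),
                              stemness = numeric())
  empty_pos <- tibble::tibble(motif = character(), position = character(),
                              cytotoxicity = numeric(), stemness = numeric())
  empty_pair <- tibble::tibble(motif_a = character(), motif_b = character(),
                               cytotoxicity = numeric(), stemness = numeric())
  gt <- list(
    baseline = baseline,
    additive = tibble::as_tibble(additive %||% empty_add),
    positional = tibble::as_tibble(positional %||% empty_pos),
    pairs = tibble::as_tibble(pairs %||% empty_pair),
    noise_sd = noise_sd,
    clip = clip
  )
  vals <- c(baseline, noise_sd, unlist(clip),
            gt$additive$cytotoxicity, gt$additive$stemness,
            gt$positional$cytotoxicity, gt$positional$stemness,
            gt$pairs$cytotoxicity, gt$pairs$stemness)
  if (any(!is.finite(vals))) abort("ground-truth parameters must be finite")
  if (any(noise_sd < 0)) abort("noise_sd must be nonnegative")
  for (ph in names(clip)) {
    if (clip[[ph]][1] >= clip[[ph]][2]) abort("clip range must have lo < hi")
  }
  structure(gt, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> baseline", paste(sprintf("%s=%g", names(x$baseline),
      x$baseline), collapse = ", "), "\n")
  cat("  ", nrow(x$additive), "additive effects,", nrow(x$positional),
      "positional modifiers,", nrow(x$pairs), "pair interactions\n")
  cat("  noise sd", paste(sprintf("%s=%g", names(x$noise_sd), x$noise_sd),
      collapse = ", "), "\n")
  invisible(x)
}

#' Preset ground-truth regimes
#'
#' Three study conditions used throughout validation:
#' \describe{
#'   \item{`default`}{Emulates the qualitative motif grammar of the real
#'     screen: TRAF-recruiting motifs (M9, M10, M11) and the PLC-gamma-1
#'     motif (M1) activate both phenotypes; the SHP-1 motif (M6) inhibits
#'     both; the Vav1 motif (M5) suppresses cytotoxicity while promoting
#'     stemness; M1+TRAF pairs are synergistic while M1 paired with the
#'     PI3K- or Grb2-class motif is redundant (the interaction cancels M1's
#'     additive gain); M1 works best at slot k and the TRAF motifs at slots
#'     i/j. Noise s.d. 0.08 (cytotoxicity) and 2.5
#'     (stemness) so that trained-model residuals land near realistic
#'     arrayed-screen scales.}
#'   \item{`strong`}{A high signal-to-noise regime for parameter-recovery
#'     studies: a full spread of additive effects up to |0.15| on the 0-1
#'     scale (100x that on the stemness scale), one dominant pair
#'     interaction (M1+M10), two planted positional contrasts, noise s.d.
#'     0.05 / 2.5.}
#'   \item{`null`}{No effects at all; phenotypes are baseline plus noise.
#'     Used to calibrate false-positive behaviour of the enrichment
#'     statistics.}
#' }
#'
#' @param regime One of `"default"`, `"strong"`, `"null"`.
#' @return A [ground_truth()] object.
#' @export
ground_truth_regime <- function(regime = c("default", "strong", "null")) {
  regime <- match.arg(regime)
  if (regime == "null") {
    return(ground_truth())
  }
  if (regime == "strong") {
    add <- tibble::tibble(
      motif = paste0("M", 1:12),
      cytotoxicity = c(0.08, 0.01, 0.00, 0.03, -0.10, -0.15,
                       -0.02, -0.06, 0.12, 0.10, 0.05, -0.04)
    )
    add$stemness <- add$cytotoxicity * 100
    pos <- tibble::tibble(
      motif = c("M1", "M1", "M6", "M6"),
      position = c("i", "k", "i", "k"),
      cytotoxicity = c(-0.05, 0.05, 0.03, -0.03)
    )
    pos$stemness <- pos$cytotoxicity * 100
    # one dominant synergy plus strong redundancy of M1 with the CD28-class
    # motifs (PI3K/GRB2/LCK), the structure the design-rule query probes
    prs <- tibble::tibble(
      motif_a = c("M1", "M1", "M1", "M1"),
      motif_b = c("M10", "M2", "M4", "M7"),
      cytotoxicity = c(0.25, -0.15, -0.15, -0.15),
      stemness = c(25, -15, -15, -15)
    )
    return(ground_truth(
      baseline = c(cytotoxicity = 0.35, stemness = 35),
      additive = add, positional = pos, pairs = prs,
      noise_sd = c(cytotoxicity = 0.05, stemness = 2.5)
    ))
  }
  add <- tibble::tibble(
    motif = paste0("M", 1:12),
    cytotoxicity = c(0.06, 0.01, 0.00, 0.02, -0.08, -0.10,
                     0.01, -0.02, 0.10, 0.08, 0.05, -0.01),
    stemness = c(4, -1, 0, -2, 7, -2, 0, -1, 7, 6, 3, 0)
  )
  pos <- tibble::tibble(
    motif = c("M1", "M1", "M9", "M9", "M10", "M10", "M6"),
    position = c("i", "k", "i", "k", "i", "k", "k"),
    cytotoxicity = c(-0.04, 0.04, 0.03, -0.03, 0.03, -0.03, -0.03),
    stemness = c(-2, 2, 2, -2, 2, -2, -1)
  )
  # M1+TRAF synergy (complementary pathways); M1 with PI3K-, Grb2- or
  # Lck-class motifs is redundant signaling that cancels M1's additive gain
  prs <- tibble::tibble(
    motif_a = c("M1", "M1", "M9", "M9", "M6", "M1", "M1", "M1"),
    motif_b = c("M10", "M9", "M10", "M9", "M6", "M2", "M4", "M7"),
    cytotoxicity = c(0.06, 0.05, 0.04, 0.04, -0.03, -0.08, -0.08, -0.08),
    stemness = c(4, 3.5, 3, 3, -2, -5.5, -5.5, -5.5)
  )
  ground_truth(additive = add, positional = pos, pairs = prs)
}

effect_lookup <- function(df, keys, phenotype) {
  v <- setNames(df[[phenotype]], keys)
  function(key) {
    hit <- v[key]
    sum(hit[!is.na(hit)])
  }
}

#' Noiseless ground-truth phenotypes for domains
#'
#' Evaluates the generative model without noise (clipping applied).
#'
#' @param gt A [ground_truth()].
#' @param domains Domains tibble or labels.
#' @param library The [motif_library()].
#' @return A tibble: `domain_label`, `cytotoxicity`, `stemness`.
#' @export
true_phenotypes <- function(gt, domains, library = motif_library()) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.character(domains)) domains <- parse_domain_label(domains, library)
  motif_sets <- domain_motif_list(domains, library)
  sig <- signaling_motifs(library)
  out <- tibble::tibble(domain_label = domains$domain_label)
  for (ph in c("cytotoxicity", "stemness")) {
    addf <- effect_lookup(gt$additive, gt$additive$motif, ph)
    posf <- effect_lookup(gt$positional,
                          paste(gt$positional$motif, gt$positional$position),
                          ph)
    pairf <- effect_lookup(gt$pairs,
                           pair_key(gt$pairs$motif_a, gt$pairs$motif_b, sig),
                           ph)
    vals <- vapply(motif_sets, function(m) {
      slots <- SLOT_NAMES[seq_along(m)]
      gt$baseline[[ph]] + addf(m) + posf(paste(m, slots)) +
        pairf(domain_pairs(m, sig))
    }, numeric(1))
    out[[ph]] <- pmin(pmax(vals, gt$clip[[ph]][1]), gt$clip[[ph]][2])
  }
  out
}

#' Generate a synthetic arrayed screen
#'
#' Samples `n_records` domains without replacement, evaluates the
#' ground-truth model, adds Gaussian noise, clips to the phenotype ranges,
#' and returns a screen table in the standard format (survival fraction
#' rather than cytotoxicity, as an instrument would report). Deterministic
#' under `seed`.
#'
#' @param gt A [ground_truth()].
#' @param domains Candidate domains (default: the full enumerated library).
#' @param n_records Number of constructs to screen (default 246).
#' @param seed Integer seed.
#' @param library The [motif_library()].
#' @return A tibble: `domain_label`, `nalm6_survival`, `stemness`.
#' @export
#' @examples
#' gt <- ground_truth_regime("default")
#' screen <- generate_screen(gt, n_records = 20, seed = 1)
generate_screen <- function(gt, domains = NULL, n_records = 246, seed = 1,
                            library = motif_library()) {
  stopifnot(inherits(gt, "ground_truth"))
  domains <- domains %||% enumerate_domains(library)
  if (is.character(domains)) domains <- parse_domain_label(domains, library)
  if (n_records > nrow(domains)) {
    abort(paste0("n_records (", n_records, ") exceeds the ", nrow(domains),
                 " candidate domains"))
  }
  withr::with_seed(seed, {
    picked <- domains[sample.int(nrow(domains), n_records), , drop = FALSE]
    truth <- true_phenotypes(gt, picked, library)
    cyto <- truth$cytotoxicity +
      rnorm(n_records, 0, gt$noise_sd[["cytotoxicity"]])
    stem <- truth$stemness + rnorm(n_records, 0, gt$noise_sd[["stemness"]])
    tibble::tibble(
      domain_label = picked$domain_label,
      nalm6_survival = 1 - pmin(pmax(cyto, gt$clip$cytotoxicity[1]),
                                gt$clip$cytotoxicity[2]),
      stemness = pmin(pmax(stem, gt$clip$stemness[1]), gt$clip$stemness[2])
    )
  })
}

#' Score recovery of planted ground truth
#'
#' Compares enrichment results computed on a synthetic screen's trained
#' models with the planted parameters:
#' \describe{
#'   \item{`additive_rank_correlation`}{Spearman correlation between the
#'     planted per-motif additive effects and the recovered motif mean
#'     percentiles.}
#'   \item{`pair_hit_rate`}{Fraction of the top-`k` planted pair
#'     interactions (by combined planted effect) found in the top `k` of
#'     the combined pair ranking.}
#'   \item{`position_sign_accuracy`}{Fraction of planted positional
#'     contrasts (slot pairs with differing planted modifiers for a motif)
#'     whose recovered mean-percentile difference has the planted sign.}
#' }
#'
#' @param gt The [ground_truth()] used to generate the screen.
#' @param motif_enrich A [motif_enrichment()] tibble (for `phenotype`).
#' @param phenotype Phenotype the motif/position tables refer to.
#' @param pair_ranking Optional [rank_pairs_combined()] tibble.
#' @param position_table Optional [position_enrichment()] tibble.
#' @param top_k Size of the top set for `pair_hit_rate` (default 3).
#' @return A one-row tibble of recovery metrics (`NA` where the
#'   corresponding input or planted structure is absent).
#' @export
recovery_report <- function(gt, motif_enrich,
                            phenotype = c("cytotoxicity", "stemness"),
                            pair_ranking = NULL, position_table = NULL,
                            top_k = 3) {
  stopifnot(inherits(gt, "ground_truth"))
  phenotype <- match.arg(phenotype)
  planted <- setNames(gt$additive[[phenotype]], gt$additive$motif)
  missing <- setdiff(names(planted), motif_enrich$motif)
  if (length(missing) > 0) {
    abort(paste0("motif sets mismatch; enrichment lacks: ",
                 paste(missing, collapse = ", ")))
  }
  a <- planted[motif_enrich$motif]
  a[is.na(a)] <- 0
  rank_cor <- if (length(a) >= 3 && sd(a) > 0) {
    cor(a, motif_enrich$mean_percentile, method = "spearman")
  } else NA_real_

  hit_rate <- NA_real_
  combined_w <- gt$pairs$cytotoxicity +
    gt$pairs$stemness / diff(gt$clip$stemness) * diff(gt$clip$cytotoxicity)
  promoting <- gt$pairs[combined_w > 0, , drop = FALSE]
  if (!is.null(pair_ranking) && nrow(promoting) > 0) {
    ord <- order(-combined_w[combined_w > 0])
    k <- min(top_k, nrow(promoting))
    planted_keys <- pair_key(promoting$motif_a[ord[seq_len(k)]],
                             promoting$motif_b[ord[seq_len(k)]],
                             unique(c(pair_ranking$motif_a, pair_ranking$motif_b)))
    top <- head(pair_ranking, top_k)
    top_keys <- pair_key(top$motif_a, top$motif_b,
                         unique(c(pair_ranking$motif_a, pair_ranking$motif_b)))
    hit_rate <- mean(planted_keys %in% top_keys)
  }

  sign_acc <- NA_real_
  if (!is.null(position_table) && nrow(gt$positional) > 0) {
    hits <- c()
    for (m in unique(gt$positional$motif)) {
      slots <- SLOT_NAMES
      pl <- setNames(rep(0, length(slots)), slots)
      rows <- gt$positional[gt$positional$motif == m, ]
      pl[rows$position] <- rows[[phenotype]]
      rec <- position_table[position_table$motif == m, ]
      recv <- setNames(rec$mean_percentile, rec$position)
      for (s1 in seq_along(slots)) for (s2 in seq_len(s1 - 1)) {
        d <- pl[slots[s1]] - pl[slots[s2]]
        if (d != 0) {
          dr <- recv[slots[s1]] - recv[slots[s2]]
          if (is.finite(dr)) hits <- c(hits, sign(dr) == sign(d))
        }
      }
    }
    if (length(hits) > 0) sign_acc <- mean(hits)
  }

  tibble::tibble(
    additive_rank_correlation = rank_cor,
    pair_hit_rate = hit_rate,
    position_sign_accuracy = sign_acc
  )
}
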
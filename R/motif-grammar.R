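#' Percentile-rank predicted phenotypes
#'
#' Ranks domains by a predicted (or measured) score and converts ranks to
#' percentiles with the convention `(rank - 0.5) / N * 100`, ties receiving
#' averaged ranks. Under this convention the mean percentile over any table
#' is exactly 50, which every enrichment statistic inherits as its null
#' reference.
#'
#' If the input carries a per-member prediction matrix (attribute
#' `"members"`, as returned by [predict.car_ensemble()]), each member column
#' is percentile-ranked too and attached as attribute `"member_percentiles"`,
#' allowing enrichment statistics to report an s.e.m. across ensemble
#' members.
#'
#' @param predictions A tibble with `domain_label` and a score column.
#' @param score Name of the score column (default `"mean"`).
#' @return The input tibble with a `percentile` column added.
#' @export
#' @examples
#' percentile_rank(tibble::tibble(domain_label = c("M1", "M2", "M3", "M4"),
#'                                mean = c(0.1, 0.4, 0.2, 0.9)))
percentile_rank <- function(predictions, score = "mean") {
  stopifnot(is.data.frame(predictions))
  if (nrow(predictions) < 2) abort("need at least 2 predictions to rank")
  if (!score %in% names(predictions)) {
    abort(paste0("no '", score, "' column in predictions"))
  }
  to_pct <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x) * 100
  out <- dplyr::mutate(predictions, percentile = to_pct(.data[[score]]))
  members <- attr(predictions, "members")
  if (!is.null(members)) {
    attr(out, "member_percentiles") <- apply(members, 2, to_pct)
  }
  out
}

# Percentile values (and optional member-percentile rows) for a logical
# domain subset; returns mean, n, and s.e.m. across members when available.
subset_stat <- function(ranked, member_pct, in_subset) {
  n <- sum(in_subset)
  mean_pct <- if (n > 0) mean(ranked$percentile[in_subset]) else NA_real_
  sem <- NA_real_
  if (!is.null(member_pct) && n > 0) {
    per_member <- colMeans(member_pct[in_subset, , drop = FALSE])
    sem <- sd(per_member) / sqrt(length(per_member))
  }
  list(mean = mean_pct, n = n, sem = sem)
}

#' Motif enrichment in the ranked library
#'
#' For each signaling motif, the mean percentile of all domains containing at
#' least one copy (a domain counts once regardless of copy number). Motifs
#' enriched toward the top of the ranked distribution (mean above the 50th
#' percentile) promote the phenotype; those toward the bottom inhibit it.
#' The spacer part is excluded unless `include_spacer = TRUE`.
#'
#' @param ranked A [percentile_rank()] table covering the library.
#' @param library The [motif_library()].
#' @param motifs Motifs to report (default all non-spacer parts). Unknown
#'   ids are an error.
#' @param include_spacer Include spacer parts in the default motif set.
#' @return A tibble: `motif`, `mean_percentile`, `n_domains`, `sem` (NA
#'   unless member percentiles are attached to `ranked`).
#' @export
motif_enrichment <- function(ranked, library = motif_library(), motifs = NULL,
                             include_spacer = FALSE) {
  stopifnot(inherits(library, "motif_library"))
  motifs <- motifs %||%
    (if (include_spacer) library$motif_ids else signaling_motifs(library))
  unknown <- setdiff(motifs, library$motif_ids)
  if (length(unknown) > 0) {
    abort(paste0("motif(s) not in library: ", paste(unknown, collapse = ", ")))
  }
  motif_sets <- domain_motif_list(ranked$domain_label, library)
  member_pct <- attr(ranked, "member_percentiles")
  purrr::map_dfr(motifs, function(m) {
    st <- subset_stat(ranked, member_pct,
                      vapply(motif_sets, function(s) m %in% s, logical(1)))
    tibble::tibble(motif = m, mean_percentile = st$mean,
                   n_domains = st$n, sem = st$sem)
  })
}

pair_key <- function(a, b, ids) {
  ia <- match(a, ids); ib <- match(b, ids)
  swap <- ib < ia
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

# Unordered signaling-motif pairs contained in one domain's motif multiset;
# a self-pair requires at least two copies. Each pair is reported once per
# domain (multiset containment, not occurrence weighting).
domain_pairs <- function(motifs, signaling) {
  m <- motifs[motifs %in% signaling]
  if (length(m) < 2) return(character(0))
  cmb <- utils::combn(m, 2)
  unique(pair_key(cmb[1, ], cmb[2, ], signaling))
}

#' Motif-pair enrichment in the ranked library
#'
#' Mean percentile of domains containing each unordered pair of signaling
#' motifs (self-pairs require at least two copies of the motif; a domain
#' counts once per pair it contains). Covers all pairs of the 12 signaling
#' motifs; pairs never observed get `n_domains = 0` and an `NA` mean rather
#' than a silent zero.
#'
#' @inheritParams motif_enrichment
#' @return A long tibble: `motif_a`, `motif_b` (in library order, so
#'   `motif_a` never comes after `motif_b`), `mean_percentile`, `n_domains`,
#'   `sem`.
#' @export
pair_enrichment <- function(ranked, library = motif_library()) {
  stopifnot(inherits(library, "motif_library"))
  sig <- signaling_motifs(library)
  motif_sets <- domain_motif_list(ranked$domain_label, library)
  keys_by_domain <- purrr::map(motif_sets, domain_pairs, signaling = sig)
  member_pct <- attr(ranked, "member_percentiles")
  all_pairs <- expand.grid(a = seq_along(sig), b = seq_along(sig))
  all_pairs <- all_pairs[all_pairs$a <= all_pairs$b, ]
  all_pairs <- all_pairs[order(all_pairs$a, all_pairs$b), ]
  membership <- tibble::tibble(
    domain = rep(seq_along(keys_by_domain), lengths(keys_by_domain)),
    key = unlist(keys_by_domain)
  )
  by_key <- split(membership$domain, membership$key)
  purrr::map2_dfr(all_pairs$a, all_pairs$b, function(ia, ib) {
    key <- paste(sig[ia], sig[ib], sep = "|")
    idx <- by_key[[key]] %||% integer(0)
    in_subset <- rep(FALSE, nrow(ranked)); in_subset[idx] <- TRUE
    st <- subset_stat(ranked, member_pct, in_subset)
    tibble::tibble(motif_a = sig[ia], motif_b = sig[ib],
                   mean_percentile = st$mean, n_domains = st$n, sem = st$sem)
  })
}

#' Widen a pair-enrichment table to a symmetric matrix
#'
#' @param pairs A [pair_enrichment()] tibble.
#' @param library The [motif_library()] fixing row/column order.
#' @return A symmetric numeric matrix (signaling motifs x signaling motifs).
#' @export
pair_matrix <- function(pairs, library = motif_library()) {
  sig <- signaling_motifs(library)
  m <- matrix(NA_real_, length(sig), length(sig), dimnames = list(sig, sig))
  ia <- match(pairs$motif_a, sig); ib <- match(pairs$motif_b, sig)
  m[cbind(ia, ib)] <- pairs$mean_percentile
  m[cbind(ib, ia)] <- pairs$mean_percentile
  m
}

#' Positional enrichment of motifs
#'
#' Mean percentile of domains carrying each motif at each slot (i, j, k).
#' Cells with no occurrences (e.g. slot k in a library of single-motif
#' domains) are flagged with `n_domains = 0` and `NA` mean.
#'
#' @inheritParams motif_enrichment
#' @return A tibble: `motif`, `position`, `mean_percentile`, `n_domains`,
#'   `sem`.
#' @export
position_enrichment <- function(ranked, library = motif_library()) {
  stopifnot(inherits(library, "motif_library"))
  sig <- signaling_motifs(library)
  domains <- parse_domain_label(ranked$domain_label, library)
  member_pct <- attr(ranked, "member_percentiles")
  slots <- SLOT_NAMES[seq_len(library$slot_count)]
  grid <- tidyr::expand_grid(motif = sig, position = slots)
  purrr::map2_dfr(grid$motif, grid$position, function(m, pos) {
    v <- domains[[paste0("slot_", pos)]]
    st <- subset_stat(ranked, member_pct, !is.na(v) & v == m)
    tibble::tibble(motif = m, position = pos,
                   mean_percentile = st$mean, n_domains = st$n, sem = st$sem)
  })
}

#' Rank motif pairs by combined phenotype enrichment
#'
#' Orders unordered motif pairs by the sum of their mean percentiles for the
#' two phenotypes (descending), the criterion used to call pairs that
#' jointly promote — or jointly suppress — cytotoxicity and stemness. Exact
#' ties are broken by library order of the pair and flagged.
#'
#' @param cyto_pairs,stem_pairs [pair_enrichment()] tibbles for the two
#'   phenotypes, over the same library.
#' @return A tibble sorted by `combined` (descending): `motif_a`, `motif_b`,
#'   `cytotoxicity`, `stemness`, `combined`, `n_domains`, `tied`.
#' @export
rank_pairs_combined <- function(cyto_pairs, stem_pairs) {
  if (nrow(cyto_pairs) != nrow(stem_pairs) ||
      !identical(cyto_pairs[c("motif_a", "motif_b")],
                 stem_pairs[c("motif_a", "motif_b")])) {
    abort("pair tables do not share the same motif pairs/order")
  }
  out <- tibble::tibble(
    motif_a = cyto_pairs$motif_a,
    motif_b = cyto_pairs$motif_b,
    cytotoxicity = cyto_pairs$mean_percentile,
    stemness = stem_pairs$mean_percentile,
    combined = cyto_pairs$mean_percentile + stem_pairs$mean_percentile,
    n_domains = cyto_pairs$n_domains
  )
  out <- out[order(-out$combined, seq_len(nrow(out))), ]
  out$tied <- duplicated(out$combined) | duplicated(out$combined, fromLast = TRUE)
  out
}

#' Label a ranked pair table's pairs as "Ma+Mb"
#'
#' @param ranked_pairs A tibble with `motif_a` and `motif_b`.
#' @return Character vector of pair labels.
#' @export
pair_label <- function(ranked_pairs) {
  paste(ranked_pairs$motif_a, ranked_pairs$motif_b, sep = "+")
}
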
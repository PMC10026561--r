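#' Library parts table
#'
#' Reads the table of signaling-motif parts that make up the combinatorial
#' costimulatory-domain library: 12 short signaling motifs (M1-M12), each
#' recruiting a specific downstream binder (PLC-gamma-1, TRAFs, Grb2, GADS,
#' SHP-1, Vav1, PI3K, Lck, Pellino), plus a non-signaling spacer part (M13).
#'
#' The packaged default fixture records the binder class of every part. Class
#' assignments and core sequences that are not fixed by the library design
#' itself are synthetic placeholders (marked in `source_protein`); supply your
#' own TSV with columns `id`, `source_protein`, `binder_class`,
#' `core_sequence` to override them.
#'
#' @param path Path to a tab-separated parts table. Defaults to the packaged
#'   synthetic fixture.
#' @return A tibble with columns `id`, `source_protein`, `binder_class`,
#'   `core_sequence`.
#' @export
#' @examples
#' motif_parts()
motif_parts <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "motif_parts_synthetic.tsv", package = "cargrammar")
  parts <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = "NA", progress = FALSE)
  required <- c("id", "source_protein", "binder_class", "core_sequence")
  missing <- setdiff(required, names(parts))
  if (length(missing) > 0) {
    abort(paste0("parts table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  parts
}

#' Construct a combinatorial motif library
#'
#' A motif library is a set of `P` parts and a maximum domain length
#' (`slot_count` slots, read N-terminal to C-terminal and named i, j, k for
#' the default of three). The library defines the enumerable space of
#' costimulatory domains: all ordered motif sequences of length 1 to
#' `slot_count`, of which there are `sum(P^(1:slot_count))` -- 2379 for the
#' default 13 parts in 3 slots.
#'
#' @param parts A parts tibble as returned by [motif_parts()]. Ids must be
#'   unique and binder classes drawn from the fixed vocabulary.
#' @param slot_count Number of insertion slots (default 3).
#' @return An object of class `motif_library`.
#' @export
#' @examples
#' lib <- motif_library()
#' lib
motif_library <- function(parts = motif_parts(), slot_count = 3) {
  stopifnot(is.data.frame(parts), slot_count >= 1)
  if (nrow(parts) < 1) abort("parts table is empty")
  if (anyDuplicated(parts$id)) abort("motif ids must be unique")
  bad <- setdiff(unique(parts$binder_class), BINDER_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown binder_class value(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      parts = tibble::as_tibble(parts),
      slot_count = as.integer(slot_count),
      motif_ids = parts$id
    ),
    class = "motif_library"
  )
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library> ", length(x$motif_ids), " parts x ", x$slot_count,
      " slots (", library_size(x), " domains)\n", sep = "")
  print(x$parts, ...)
  invisible(x)
}

#' Number of enumerable domains in a library
#'
#' @param library A [motif_library()].
#' @return `sum(P^(1:slot_count))` where `P` is the number of parts.
#' @export
library_size <- function(library) {
  stopifnot(inherits(library, "motif_library"))
  P <- length(library$motif_ids)
  sum(P^(seq_len(library$slot_count)))
}

#' Motif ids excluding the spacer part
#'
#' Enrichment reports cover the signaling motifs only; parts whose binder
#' class is `SPACER` are dropped.
#'
#' @param library A [motif_library()].
#' @export
signaling_motifs <- function(library) {
  stopifnot(inherits(library, "motif_library"))
  library$parts$id[library$parts$binder_class != "SPACER"]
}

slot_cols <- function(slot_count) paste0("slot_", SLOT_NAMES[seq_len(slot_count)])

#' Enumerate every costimulatory domain in a library
#'
#' Generates all ordered motif sequences of length 1 to `slot_count`. Short
#' domains are left-aligned: a one-motif domain occupies slot i and the
#' trailing slots are absent (`NA`). Order is deterministic -- lexicographic
#' by slot, with an absent slot sorting before any motif and motifs in
#' parts-table order -- so repeated enumeration is byte-identical.
#'
#' @param library A [motif_library()].
#' @return A tibble with one row per domain: `domain_label`, one `slot_*`
#'   column per slot (`NA` when absent), and `n_motifs`.
#' @export
#' @examples
#' nrow(enumerate_domains(motif_library())) # 2379
enumerate_domains <- function(library) {
  stopifnot(inherits(library, "motif_library"))
  ids <- library$motif_ids
  P <- length(ids)
  S <- library$slot_count
  # index 0 encodes an absent slot; a filled slot never follows an absent one
  grids <- c(list(seq_len(P)), rep(list(0:P), S - 1))
  idx <- do.call(expand.grid, grids)
  if (S > 1) {
    for (s in 2:S) {
      keep <- !(idx[[s]] > 0 & idx[[s - 1]] == 0)
      idx <- idx[keep, , drop = FALSE]
    }
  }
  ord <- do.call(order, as.list(idx))
  idx <- idx[ord, , drop = FALSE]
  slots <- lapply(idx, function(col) ifelse(col == 0, NA_character_, ids[pmax(col, 1)]))
  out <- tibble::as_tibble(setNames(slots, slot_cols(S)))
  out$n_motifs <- rowSums(!is.na(as.matrix(out)))
  out <- tibble::add_column(out, domain_label = format_domain_label(out), .before = 1)
  out
}

#' Format domains as dash-separated labels
#'
#' @param domains A tibble with `slot_*` columns (absent slots `NA`).
#' @return Character vector of labels such as `"M9-M10-M1"`.
#' @export
format_domain_label <- function(domains) {
  sc <- grep("^slot_", names(domains), value = TRUE)
  m <- as.matrix(domains[sc])
  apply(m, 1, function(r) paste(r[!is.na(r)], collapse = "-"))
}

#' Parse dash-separated domain labels
#'
#' Accepts construct names such as `"M4-M9-M1"` or `"M4-M9-M1-ζ"`; a
#' trailing CD3-zeta token (`"ζ"`, `"zeta"` or `"z"`) names the invariant
#' signaling tail and is ignored. Motifs are placed left-aligned into slots.
#'
#' @param labels Character vector of domain labels.
#' @param library A [motif_library()]; tokens must be ids in it.
#' @return A domains tibble (`domain_label`, `slot_*`, `n_motifs`).
#' @export
#' @examples
#' parse_domain_label("M4-M9-M1-ζ", motif_library())
parse_domain_label <- function(labels, library = motif_library()) {
  stopifnot(inherits(library, "motif_library"))
  S <- library$slot_count
  toks <- strsplit(labels, "-", fixed = TRUE)
  toks <- lapply(toks, function(t) {
    t <- trimws(t)
    n <- length(t)
    if (n > 0 && t[n] %in% c("ζ", "zeta", "z")) t <- t[-n]
    t
  })
  for (ii in seq_along(toks)) {
    t <- toks[[ii]]
    if (length(t) == 0) {
      abort(paste0("empty domain label: '", labels[ii], "'"))
    }
    if (length(t) > S) {
      abort(paste0("label '", labels[ii], "' has ", length(t),
                   " motifs but the library has ", S, " slots"))
    }
    unknown <- setdiff(t, library$motif_ids)
    if (length(unknown) > 0) {
      abort(paste0("unknown motif id(s) in '", labels[ii], "': ",
                   paste(unknown, collapse = ", ")))
    }
  }
  slots <- lapply(seq_len(S), function(s) {
    vapply(toks, function(t) if (length(t) >= s) t[s] else NA_character_, "")
  })
  out <- tibble::as_tibble(setNames(slots, slot_cols(S)))
  out$n_motifs <- lengths(toks)
  tibble::add_column(out, domain_label = format_domain_label(out), .before = 1)
}

feature_names <- function(library) {
  lev <- c(library$motif_ids, ABSENT)
  as.vector(t(outer(SLOT_NAMES[seq_len(library$slot_count)], lev, paste, sep = ":")))
}

#' One-hot encode domains for regression
#'
#' Each slot contributes a block of `P + 1` indicators: one per motif plus an
#' explicit `ABSENT` indicator, so every row sums to `slot_count` and the
#' encoding is invertible ([decode_features()]). For the default library this
#' is the 42-entry input vector of the phenotype models.
#'
#' @param domains A domains tibble (from [enumerate_domains()] or
#'   [parse_domain_label()]) or a character vector of labels.
#' @param library A [motif_library()].
#' @return A binary matrix, one row per domain (rownames are labels), with
#'   columns named `"<slot>:<motif>"`.
#' @export
encode_domains <- function(domains, library = motif_library()) {
  stopifnot(inherits(library, "motif_library"))
  if (is.character(domains)) domains <- parse_domain_label(domains, library)
  sc <- slot_cols(library$slot_count)
  missing <- setdiff(sc, names(domains))
  if (length(missing) > 0) {
    abort(paste0("domains table lacks slot column(s): ",
                 paste(missing, collapse = ", ")))
  }
  lev <- c(library$motif_ids, ABSENT)
  blocks <- lapply(sc, function(col) {
    v <- domains[[col]]
    unknown <- setdiff(v[!is.na(v)], library$motif_ids)
    if (length(unknown) > 0) {
      abort(paste0("unknown motif id(s): ", paste(unknown, collapse = ", ")))
    }
    v[is.na(v)] <- ABSENT
    f <- factor(v, levels = lev)
    m <- matrix(0L, length(v), length(lev))
    m[cbind(seq_along(v), as.integer(f))] <- 1L
    m
  })
  out <- do.call(cbind, blocks)
  dimnames(out) <- list(
    if ("domain_label" %in% names(domains)) domains$domain_label
    else format_domain_label(domains),
    feature_names(library)
  )
  out
}

#' Invert a one-hot feature matrix back to domains
#'
#' @param features A matrix as produced by [encode_domains()].
#' @param library The [motif_library()] used for encoding.
#' @return A domains tibble.
#' @export
decode_features <- function(features, library = motif_library()) {
  stopifnot(inherits(library, "motif_library"))
  lev <- c(library$motif_ids, ABSENT)
  S <- library$slot_count
  if (ncol(features) != S * length(lev)) {
    abort("feature matrix width does not match the library encoding")
  }
  slots <- lapply(seq_len(S), function(s) {
    block <- features[, (s - 1) * length(lev) + seq_along(lev), drop = FALSE]
    if (any(rowSums(block) != 1)) abort("each slot block must have exactly one indicator set")
    v <- lev[max.col(block, ties.method = "first")]
    v[v == ABSENT] <- NA_character_
    v
  })
  out <- tibble::as_tibble(setNames(slots, slot_cols(S)))
  out$n_motifs <- rowSums(!is.na(as.matrix(out[slot_cols(S)])))
  tibble::add_column(out, domain_label = format_domain_label(out), .before = 1)
}

#' List the motifs of each domain
#'
#' @param domains Domains tibble or character labels.
#' @param library A [motif_library()].
#' @return A list of character vectors (N-to-C motif ids), one per domain.
#' @keywords internal
domain_motif_list <- function(domains, library = motif_library()) {
  if (is.character(domains)) domains <- parse_domain_label(domains, library)
  m <- as.matrix(domains[slot_cols(library$slot_count)])
  apply(m, 1, function(r) unname(r[!is.na(r)]), simplify = FALSE)
}
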
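#' Define a binder-class signature for receptor-like domains
#'
#' A signature describes a family of costimulatory domains by the multiset of
#' downstream-binder classes their signaling motifs recruit, ignoring spacer
#' parts. `"exact"` mode requires the non-spacer class multiset to equal the
#' signature; `"contains"` requires the signature to be contained in it.
#'
#' @param required_classes Character vector (multiset) of binder classes.
#' @param match_mode `"contains"` or `"exact"`.
#' @return An object of class `domain_signature`.
#' @export
#' @examples
#' domain_signature(c("TRAF", "TRAF"), "exact") # tandem-TRAF domains
domain_signature <- function(required_classes,
                             match_mode = c("contains", "exact")) {
  match_mode <- match.arg(match_mode)
  bad <- setdiff(required_classes, BINDER_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown binder class(es): ", paste(bad, collapse = ", ")))
  }
  structure(list(required_classes = required_classes, match_mode = match_mode),
            class = "domain_signature")
}

multiset_contains <- function(haystack, needle) {
  th <- table(haystack); tn <- table(needle)
  all(names(tn) %in% names(th)) && all(tn <= th[names(tn)])
}

#' Select library domains matching a binder-class signature
#'
#' @param domains A domains tibble (e.g. [enumerate_domains()]).
#' @param library The [motif_library()] supplying each part's binder class.
#' @param signature A [domain_signature()], or a list of signatures matched
#'   as alternatives (a domain qualifies if any signature matches).
#' @return The matching rows of `domains` (possibly none).
#' @export
select_like <- function(domains, library = motif_library(), signature) {
  if (inherits(signature, "domain_signature")) signature <- list(signature)
  stopifnot(all(vapply(signature, inherits, logical(1), "domain_signature")))
  class_of <- setNames(library$parts$binder_class, library$parts$id)
  motif_sets <- domain_motif_list(domains, library)
  classes <- purrr::map(motif_sets, function(m) {
    cls <- unname(class_of[m])
    cls[cls != "SPACER"]
  })
  ok <- vapply(classes, function(cls) {
    any(vapply(signature, function(sig) {
      if (sig$match_mode == "exact") {
        length(cls) == length(sig$required_classes) &&
          multiset_contains(cls, sig$required_classes) &&
          multiset_contains(sig$required_classes, cls)
      } else {
        multiset_contains(cls, sig$required_classes)
      }
    }, logical(1)))
  }, logical(1))
  domains[ok, , drop = FALSE]
}

#' Built-in receptor-like signatures
#'
#' `bb41` mirrors the 4-1BB costimulatory domain, whose native signaling
#' content is one or two TRAF-recruiting motifs: domains of 1-2 non-spacer
#' motifs that are all TRAF-class. `cd28` mirrors CD28, which natively
#' carries several distinct motifs recruiting PI3K, Grb2 and Lck: domains of
#' exactly two non-spacer motifs drawn from those three classes.
#'
#' @return A named list of signature lists usable with [select_like()].
#' @export
default_signatures <- function() {
  cd28_classes <- c("PI3K", "GRB2", "LCK")
  cd28_pairs <- expand.grid(a = cd28_classes, b = cd28_classes,
                            stringsAsFactors = FALSE)
  cd28_pairs <- cd28_pairs[cd28_pairs$a <= cd28_pairs$b, ]
  list(
    bb41 = list(
      domain_signature("TRAF", "exact"),
      domain_signature(c("TRAF", "TRAF"), "exact")
    ),
    cd28 = purrr::map2(cd28_pairs$a, cd28_pairs$b, function(a, b) {
      domain_signature(c(a, b), "exact")
    })
  )
}

#' Append motif copies to domains
#'
#' Appends `copies` of a motif at the most C-terminal free slot(s) of each
#' domain (slots fill left to right, so the appended motif lands immediately
#' after the existing motifs). Domains without enough free slots are an
#' error, reported by label, never silently dropped.
#'
#' @param domains Domains tibble or character labels.
#' @param motif Motif id to append.
#' @param library The [motif_library()].
#' @param copies Number of copies (default 1).
#' @return The augmented domains tibble.
#' @export
#' @examples
#' append_motif("M9-M10", "M1", motif_library())$domain_label # "M9-M10-M1"
append_motif <- function(domains, motif, library = motif_library(), copies = 1) {
  if (is.character(domains)) domains <- parse_domain_label(domains, library)
  if (!motif %in% library$motif_ids) {
    abort(paste0("unknown motif id: ", motif))
  }
  free <- library$slot_count - domains$n_motifs
  blocked <- free < copies
  if (any(blocked)) {
    abort(paste0("no free slot to append ", copies, " x ", motif, " to: ",
                 paste(domains$domain_label[blocked], collapse = ", ")))
  }
  sets <- domain_motif_list(domains, library)
  sets <- purrr::map(sets, function(m) c(m, rep(motif, copies)))
  parse_domain_label(vapply(sets, paste, "", collapse = "-"), library)
}

#' Predicted effect of appending a motif
#'
#' For each base domain, predicts both phenotypes before and after appending
#' `copies` of `motif` and reports the deltas (augmented minus base) with
#' uncertainties propagated from the ensemble s.e.m. of the two predictions.
#' This is the in-silico version of adding a signaling motif to the
#' C-terminus of an existing costimulatory domain.
#'
#' @param cyto_model,stem_model Trained [train_ensemble()] models for
#'   cytotoxicity and stemness, sharing the library encoding.
#' @param base_domains Domains tibble or character labels.
#' @param motif Motif id to append.
#' @param copies Number of copies (default 1).
#' @return A tibble: `base_label`, `augmented_label`, `delta_cytotoxicity`,
#'   `delta_stemness`, `sem_cytotoxicity`, `sem_stemness`.
#' @export
motif_addition_effect <- function(cyto_model, stem_model, base_domains, motif,
                                  copies = 1) {
  stopifnot(inherits(cyto_model, "car_ensemble"),
            inherits(stem_model, "car_ensemble"),
            cyto_model$phenotype == "cytotoxicity",
            stem_model$phenotype == "stemness")
  library <- cyto_model$library
  if (is.character(base_domains)) {
    base_domains <- parse_domain_label(base_domains, library)
  }
  augmented <- append_motif(base_domains, motif, library, copies)
  pc_b <- predict(cyto_model, base_domains)
  pc_a <- predict(cyto_model, augmented)
  ps_b <- predict(stem_model, base_domains)
  ps_a <- predict(stem_model, augmented)
  tibble::tibble(
    base_label = base_domains$domain_label,
    augmented_label = augmented$domain_label,
    delta_cytotoxicity = pc_a$mean - pc_b$mean,
    delta_stemness = ps_a$mean - ps_b$mean,
    sem_cytotoxicity = sqrt(pc_a$sem^2 + pc_b$sem^2),
    sem_stemness = sqrt(ps_a$sem^2 + ps_b$sem^2)
  )
}

#' Summarise addition effects over a domain subset
#'
#' @param effects A [motif_addition_effect()] tibble.
#' @return One row with the group mean delta and its standard error for each
#'   phenotype, plus the fraction of domains with a positive delta.
#' @export
addition_effect_summary <- function(effects) {
  n <- nrow(effects)
  tibble::tibble(
    n_domains = n,
    mean_delta_cytotoxicity = mean(effects$delta_cytotoxicity),
    se_delta_cytotoxicity = sd(effects$delta_cytotoxicity) / sqrt(n),
    frac_positive_cytotoxicity = mean(effects$delta_cytotoxicity > 0),
    mean_delta_stemness = mean(effects$delta_stemness),
    se_delta_stemness = sd(effects$delta_stemness) / sqrt(n),
    frac_positive_stemness = mean(effects$delta_stemness > 0)
  )
}
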
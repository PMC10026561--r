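# Small libraries and quick model configs used across tests.

tiny_library <- function(P = 3, S = 2) {
  parts <- motif_parts()[seq_len(P), ]
  motif_library(parts, slot_count = S)
}

# a reduced ensemble config to keep model-dependent tests fast
quick_variants <- function(n = 3) {
  v <- default_variants()
  v[seq_len(n), ]
}

# deterministic fake predictions over a domain set
fake_predictions <- function(domains, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    domain_label = domains$domain_label,
    mean = stats::runif(nrow(domains))
  ))
}
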
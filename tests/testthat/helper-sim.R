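# simulate a binary respondent-by-item matrix from a unidimensional 2PL
sim_2pl <- function(n, a, b, seed) {
  set.seed(seed)
  theta <- stats::rnorm(n)
  y <- vapply(seq_along(a), function(j) {
    stats::rbinom(n, 1L, stats::plogis(a[j] * (theta - b[j])))
  }, integer(n))
  colnames(y) <- sprintf("it%02d", seq_along(a))
  y
}

# a minimal binary item mapping for crosswalk construction in tests
binary_mapping <- function(construct, study, var = paste0(construct, "_v"),
                           gate = "", summary = FALSE) {
  item_mapping(construct_id = construct, study_id = study,
               source_variable = var,
               response_options = c(No = 0L, Yes = 1L),
               gate_variable = gate, is_summary_score = summary,
               recode = recode_rule(c(0L, 1L), c(0L, 1L)))
}
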
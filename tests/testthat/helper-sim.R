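# shared small simulation configs (kept modest so the suite stays fast)

small_config <- function(seed, ...) {
  sim_config(n_res = 72, n_genes = 60, n_dynamic_per_family = 6,
             seed = seed, ...)
}

# collapse edge tables to the identity level used for planted-recovery
# scoring
collapse_trans <- function(edges) {
  dplyr::distinct(edges, family, peak, attribute)
}

collapse_cis <- function(edges) {
  if ("families" %in% names(edges))
    edges <- tidyr::separate_rows(edges, "families", sep = ",")
  dplyr::distinct(edges, peak, gene, sign)
}

precision_recall <- function(inferred, planted, keys) {
  tp <- nrow(dplyr::inner_join(inferred, planted, by = keys))
  c(tp = tp, n_inf = nrow(inferred), n_pl = nrow(planted))
}
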
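# Independent oracles: deliberately plain, loop-based implementations
# used to cross-check the vectorized package code.

ACGT <- c("A", "C", "G", "T")

# enumerate every window score on the integer lattice the scanner uses,
# and exact tail probabilities by enumerating all 4^L background words
brute_pwm_pvalues <- function(pwm, bins = 1000) {
  lo <- log2((pwm$mat + 1e-3) / (1 + 4e-3) / 0.25)
  L <- nrow(lo)
  rng <- sum(apply(lo, 1, max)) - sum(apply(lo, 1, min))
  delta <- rng / bins
  oi <- round(sweep(lo, 1, apply(lo, 1, min)) / delta)
  base_int <- sum(round(apply(lo, 1, min) / delta))
  words <- expand.grid(rep(list(1:4), L))
  ints <- apply(words, 1, function(w) sum(oi[cbind(seq_len(L), w)])) + base_int
  tab <- sort(unique(ints))
  tibble::tibble(score_int = tab,
                 pvalue = vapply(tab, function(s) mean(ints >= s), 0))
}

# score every window of a sequence directly (both strands)
brute_scan <- function(seq, pwm) {
  lo <- log2((pwm$mat + 1e-3) / (1 + 4e-3) / 0.25)
  L <- nrow(lo)
  rc <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_at <- function(chars, off) {
    s <- 0
    for (j in seq_len(L)) {
      idx <- match(chars[off + j], ACGT)
      s <- s + if (is.na(idx)) 0 else unname(lo[j, idx])
    }
    s
  }
  out <- list()
  for (st in c("+", "-")) {
    s <- if (st == "+") seq else rc(seq)
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < L) next
    for (off in 0:(n - L)) {
      sc <- score_at(chars, off)
      genomic_off <- if (st == "+") off else n - L - off
      out[[length(out) + 1]] <- tibble::tibble(offset = genomic_off,
                                               strand = st, score = sc)
    }
  }
  dplyr::bind_rows(out)
}

# all-pairs nearest TSS-to-summit distance
brute_nearest <- function(genes, peaks) {
  vapply(seq_len(nrow(genes)), function(i) {
    same <- peaks$chrom == genes$chrom[i]
    if (!any(same)) return(Inf)
    min(abs(peaks$start[same] + peaks$summit[same] - genes$tss[i]))
  }, 0)
}

# plodding re-implementation of the trans-edge rule set
brute_trans_edges <- function(atac_calls, hits, family_calls, expression,
                              families) {
  rows <- list()
  hit_tab <- unique(hits[, c("peak", "family")])
  for (r in seq_len(nrow(hit_tab))) {
    fam <- hit_tab$family[r]; pk <- hit_tab$peak[r]
    fr <- families[families$name == fam, ]
    if (nrow(fr) == 0 || !fr$role %in% c("opener", "closer")) next
    calls <- atac_calls[atac_calls$feature == pk & atac_calls$direction != "none", ]
    for (ci in seq_len(nrow(calls))) {
      ta <- calls$time_a[ci]; tb <- calls$time_b[ci]; dirn <- calls$direction[ci]
      attr_ <- if ((fr$role == "opener") == (dirn == "up")) "binding" else "dissociation"
      if (attr_ == "binding") {
        if (!(ta >= fr$bind_min && tb <= fr$bind_max)) next
      } else {
        if (!(ta >= fr$diss_min && tb <= fr$diss_max)) next
      }
      et <- if (attr_ == "binding") tb else ta
      ex <- expression[expression$family == fam & expression$time == et, ]
      if (nrow(ex) == 0 || !ex$expressed) next
      if (attr_ == "binding") {
        exempt <- fr$bind_gate == "cocktail" && ta == 0 &&
          !is.na(fr$cocktail_free_tb) && tb <= fr$cocktail_free_tb
        if (!(fr$bind_gate == "none" || exempt)) {
          g <- family_calls[family_calls$family == fam &
                              family_calls$call == "activated", ]
          if (nrow(g) == 0 || !any(g$time_b <= ta)) next
        }
      } else {
        if (fr$diss_gate == "never") next
        if (fr$diss_gate == "repression") {
          g <- family_calls[family_calls$family == fam &
                              family_calls$call == "repressed", ]
          if (nrow(g) == 0 || !any(g$time_b <= ta)) next
        }
        # prior_binding resolved in a second pass below
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        family = fam, peak = pk, time_a = ta, time_b = tb, attribute = attr_,
        pending = attr_ == "dissociation" && fr$diss_gate == "prior_binding")
    }
  }
  if (!length(rows))
    return(tibble::tibble(family = character(), peak = character(),
                          time_a = numeric(), time_b = numeric(),
                          attribute = character()))
  e <- dplyr::bind_rows(rows)
  keep <- rep(TRUE, nrow(e))
  for (i in which(e$pending)) {
    b <- e[!e$pending & e$attribute == "binding" &
             e$family == e$family[i] & e$peak == e$peak[i], ]
    keep[i] <- nrow(b) > 0 && any(b$time_b <= e$time_a[i])
  }
  unique(dplyr::arrange(e[keep, c("family", "peak", "time_a", "time_b", "attribute")],
                        family, peak, time_a, time_b))
}

# plodding re-implementation of the cis-edge rule set
brute_cis_edges <- function(trans_edges, peaks, genes, gene_calls, constraints,
                            families, max_gap = 10000) {
  if (nrow(trans_edges) == 0 || nrow(constraints) == 0)
    return(tibble::tibble(peak = character(), gene = character(),
                          time_a = numeric(), time_b = numeric(),
                          sign = character(), families = character()))
  rows <- list()
  for (ti in seq_len(nrow(trans_edges))) {
    te <- trans_edges[ti, ]
    fr <- families[families$name == te$family, ]
    lim <- max(constraints$distance_bp[constraints$family == te$family], -Inf)
    if (!is.finite(lim)) next
    sign_ <- if ((fr$role == "opener") == (te$attribute == "binding"))
      "activation" else "repression"
    pk <- peaks[peaks$peak == te$peak, ]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      if (g$chrom != pk$chrom) next
      gap <- max(0, max(pk$start, g$start) - min(pk$end, g$end))
      if (gap > max_gap) next
      dist <- abs(pk$start + pk$summit - g$tss)
      if (dist > lim) next
      cons_cmp <- constraints[constraints$family == te$family, ]
      gcall <- gene_calls[gene_calls$feature == g$gene &
                            gene_calls$call != "unchanged", ]
      in_cdf <- FALSE
      for (k in seq_len(nrow(gcall)))
        if (any(cons_cmp$time_a == gcall$time_a[k] &
                  cons_cmp$time_b == gcall$time_b[k])) in_cdf <- TRUE
      if (!in_cdf) next
      for (k in seq_len(nrow(gcall))) {
        overlap <- max(te$time_a, gcall$time_a[k]) <= min(te$time_b, gcall$time_b[k])
        match_sign <- (sign_ == "activation") == (gcall$call[k] == "activated")
        if (overlap && match_sign)
          rows[[length(rows) + 1]] <- tibble::tibble(
            peak = te$peak, gene = g$gene,
            time_a = gcall$time_a[k], time_b = gcall$time_b[k],
            sign = sign_, family = te$family)
      }
    }
  }
  if (!length(rows))
    return(tibble::tibble(peak = character(), gene = character(),
                          time_a = numeric(), time_b = numeric(),
                          sign = character(), families = character()))
  dplyr::bind_rows(rows) |>
    dplyr::group_by(peak, gene, time_a, time_b, sign) |>
    dplyr::summarise(families = paste(sort(unique(family)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(peak, gene, time_a, time_b)
}

# random rule-engine input instance (not a full genome simulation)
random_rule_instance <- function(seed, n_peaks = 40, n_genes = 20) {
  withr::with_seed(seed, {
    tp <- c(0, 20, 40, 60, 120, 180, 240)
    cmp <- expand.grid(time_a = tp, time_b = tp)
    cmp <- cmp[cmp$time_a < cmp$time_b, ]
    fams <- family_rules()
    peaks <- tibble::tibble(
      peak = sprintf("p%02d", seq_len(n_peaks)), chrom = "c1",
      start = sort(sample.int(2e6, n_peaks)), summit = 150) |>
      dplyr::mutate(end = start + 300)
    genes <- tibble::tibble(
      gene = sprintf("g%02d", seq_len(n_genes)), chrom = "c1",
      start = sort(sample.int(2e6, n_genes))) |>
      dplyr::mutate(end = start + 5000, tss = start)
    hits <- tibble::tibble(
      peak = sample(peaks$peak, n_peaks * 2, replace = TRUE),
      family = sample(fams$name, n_peaks * 2, replace = TRUE))
    n_calls <- nrow(cmp) * n_peaks
    atac_calls <- tibble::tibble(
      feature = rep(peaks$peak, each = nrow(cmp)),
      time_a = rep(cmp$time_a, n_peaks), time_b = rep(cmp$time_b, n_peaks),
      direction = sample(c("up", "down", "none"), n_calls, TRUE,
                         prob = c(0.15, 0.15, 0.7)))
    gene_calls <- tibble::tibble(
      feature = rep(genes$gene, each = nrow(cmp)),
      time_a = rep(cmp$time_a, n_genes), time_b = rep(cmp$time_b, n_genes),
      call = sample(c("activated", "repressed", "unchanged"),
                    nrow(cmp) * n_genes, TRUE, prob = c(0.15, 0.15, 0.7)))
    family_calls <- tibble::tibble(
      family = rep(fams$name, each = 4),
      time_a = sample(tp[-7], nrow(fams) * 4, TRUE)) |>
      dplyr::mutate(time_b = time_a + 20,
                    call = sample(c("activated", "repressed"), nrow(fams) * 4, TRUE)) |>
      dplyr::distinct()
    expression <- tidyr::expand_grid(family = fams$name, time = tp) |>
      dplyr::mutate(expressed = stats::runif(dplyr::n()) < 0.8)
    constraints <- tibble::tibble(
      family = fams$name,
      time_a = 0, time_b = sample(tp[-1], nrow(fams), TRUE),
      distance_bp = sample(c(2000, 5000, 10000, 50000), nrow(fams), TRUE),
      max_delta = 0.5, pvalue = 0.01) |>
      dplyr::slice_sample(prop = 0.8)
    list(peaks = peaks, genes = genes, hits = hits, atac_calls = atac_calls,
         gene_calls = gene_calls, family_calls = family_calls,
         expression = expression, constraints = constraints, families = fams)
  })
}
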
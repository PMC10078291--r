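# Rule-based inference of the bipartite kinetic network:
# trans-edges (TF family -> RE) from accessibility dynamics + motifs +
# family expression, cis-edges (RE -> gene) from proximity, covariation
# and CDF-derived constraints.

#' TF-family rule configuration
#'
#' One row per family. `role` is the chromatin function (opener /
#' closer). `cocktail` families are activated directly by the stimulus,
#' so their binding edges need no transcriptional-activation gate.
#' `dissociates` marks openers whose dominant inferred action is
#' dissociation (loss of an activator). Windows restrict edge intervals
#' in minutes: binding edges need `time_a >= bind_min` and
#' `time_b <= bind_max`, dissociation edges `time_a >= diss_min` and
#' `time_b <= diss_max`. Gates: `bind_gate = "activation"` requires a
#' significant activation of a family gene ending no later than the
#' edge start; `diss_gate = "repression"` the mirror image;
#' `diss_gate = "prior_binding"` requires an earlier binding edge of
#' the same family at the same RE; `diss_gate = "never"` disables
#' dissociation edges for the family.
#'
#' Defaults encode the adipogenic program: AP-1/CEBP/GR are cocktail
#' openers whose stimulus-driven binding is exempt from the activation
#' gate only for baseline edges ending by `cocktail_free_tb` (0-20 min;
#' 0-40 for GR, whose binding window ends there and whose later
#' accessibility losses are emitted as dissociation edges); KLF and
#' TWIST require activation of a family gene; SP acts only from 40 min
#' on, as a dissociating opener gated on repression of its family
#' genes. Only GR and SP produce dissociation edges -- later reversals
#' at other factors' REs are treated as attenuation, not dissociation.
#'
#' @param time_max final time point of the design (minutes).
#' @export
family_rules <- function(time_max = 240) {
  tibble(
    name = c("AP1", "CEBP", "GR", "KLF", "TWIST", "SP"),
    role = c("opener", "opener", "opener", "opener", "closer", "opener"),
    cocktail = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dissociates = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    bind_min = c(0, 0, 0, 0, 0, 40),
    bind_max = c(time_max, time_max, 40, time_max, time_max, time_max),
    cocktail_free_tb = c(20, 20, 40, NA, NA, NA),
    diss_min = c(0, 0, 20, 0, 0, 40),
    diss_max = rep(time_max, 6),
    bind_gate = c("cocktail", "cocktail", "cocktail",
                  "activation", "activation", "activation"),
    diss_gate = c("never", "never", "prior_binding",
                  "never", "never", "repression")
  )
}

#' Map gene-level transcription calls to TF families
#' @param gene_calls calls from [transcription_series()].
#' @param family_genes tibble `family, gene` linking family-member
#'   genes to families.
#' @export
family_transcription_calls <- function(gene_calls, family_genes) {
  gene_calls |>
    dplyr::inner_join(family_genes, by = c(feature = "gene")) |>
    dplyr::filter(.data$call != "unchanged") |>
    dplyr::distinct(.data$family, .data$time_a, .data$time_b, .data$call)
}

#' Which families are expressed at each time point
#'
#' A family counts as expressed when at least one member gene's body
#' density exceeds the floor: the `floor_quantile` quantile of nonzero
#' gene body densities at that time point.
#'
#' @param densities tibble `gene, time, body_density`.
#' @param family_genes tibble `family, gene`.
#' @param floor_quantile quantile defining the expression floor.
#' @return tibble `family, time, expressed`.
#' @export
family_expression <- function(densities, family_genes, floor_quantile = 0.25) {
  floors <- densities |>
    dplyr::filter(.data$body_density > 0) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(floor = quantile(.data$body_density, floor_quantile),
                     .groups = "drop")
  densities |>
    dplyr::inner_join(family_genes, by = "gene") |>
    dplyr::inner_join(floors, by = "time") |>
    dplyr::group_by(.data$family, .data$time) |>
    dplyr::summarise(expressed = any(.data$body_density > .data$floor),
                     .groups = "drop")
}

#' Infer trans-edges (TF family to regulatory element)
#'
#' Applies the six-rule set: the RE is an accessibility peak; the
#' family motif is present; accessibility changes significantly over
#' the edge interval; the direction of change matches the family's
#' chromatin function (binding) or opposes it (dissociation); family
#' members are expressed at the appropriate end of the interval (the
#' later time point for binding, the earlier for dissociation), with
#' non-cocktail families additionally gated on a significant
#' transcriptional change of a family gene; and per-family temporal
#' windows restrict edge intervals.
#'
#' @param atac_calls all-pairs accessibility calls from
#'   [differential_series()] (peaks as `feature`).
#' @param hits motif hits with `peak, family`.
#' @param family_calls from [family_transcription_calls()].
#' @param expression from [family_expression()].
#' @param families rule tibble from [family_rules()]; families whose
#'   `role` is `unassigned` are skipped with a warning.
#' @return tibble `family, peak, time_a, time_b, attribute`
#'   (binding / dissociation).
#' @export
infer_trans_edges <- function(atac_calls, hits, family_calls, expression,
                              families = family_rules()) {
  skip <- families$name[!families$role %in% c("opener", "closer")]
  if (length(skip))
    warn(sprintf("skipping families with unassigned function: %s",
                 paste(skip, collapse = ", ")))
  families <- dplyr::filter(families, .data$role %in% c("opener", "closer"))
  sig <- atac_calls |>
    dplyr::filter(.data$direction != "none") |>
    dplyr::select(peak = "feature", "time_a", "time_b", "direction")
  cand <- hits |>
    dplyr::distinct(.data$peak, .data$family) |>
    dplyr::inner_join(sig, by = "peak", relationship = "many-to-many") |>
    dplyr::inner_join(families, by = c(family = "name")) |>
    dplyr::mutate(attribute = dplyr::if_else(
      (.data$role == "opener") == (.data$direction == "up"),
      "binding", "dissociation"))
  # temporal windows
  cand <- dplyr::filter(cand, dplyr::if_else(
    .data$attribute == "binding",
    .data$time_a >= .data$bind_min & .data$time_b <= .data$bind_max,
    .data$time_a >= .data$diss_min & .data$time_b <= .data$diss_max))
  # expression floor: later time point for binding, earlier for dissociation
  cand <- cand |>
    dplyr::mutate(expr_time = dplyr::if_else(.data$attribute == "binding",
                                             .data$time_b, .data$time_a)) |>
    dplyr::inner_join(dplyr::rename(expression, expr_time = "time"),
                      by = c("family", "expr_time")) |>
    dplyr::filter(.data$expressed)
  # transcriptional gates
  act <- dplyr::filter(family_calls, .data$call == "activated")
  rep_ <- dplyr::filter(family_calls, .data$call == "repressed")
  gate_ok <- function(fam, t_a, gate_tbl) {
    g <- gate_tbl[gate_tbl$family == fam, ]
    nrow(g) > 0 && any(g$time_b <= t_a)
  }
  cand$gate_pass <- vapply(seq_len(nrow(cand)), function(i) {
    if (cand$attribute[i] == "binding") {
      # cocktail exemption covers only stimulus-driven baseline edges;
      # later binding needs the family gene transcriptionally activated
      exempt <- cand$bind_gate[i] == "cocktail" && cand$time_a[i] == 0 &&
        !is.na(cand$cocktail_free_tb[i]) &&
        cand$time_b[i] <= cand$cocktail_free_tb[i]
      if (cand$bind_gate[i] == "none" || exempt) TRUE
      else gate_ok(cand$family[i], cand$time_a[i], act)
    } else {
      switch(cand$diss_gate[i],
             none = TRUE,
             never = FALSE,
             repression = gate_ok(cand$family[i], cand$time_a[i], rep_),
             prior_binding = NA)  # resolved against the binding set below
    }
  }, NA)
  binding <- cand |>
    dplyr::filter(.data$attribute == "binding", .data$gate_pass) |>
    dplyr::select("family", "peak", "time_a", "time_b", "attribute")
  needs_prior <- dplyr::filter(cand, .data$attribute == "dissociation",
                               is.na(.data$gate_pass))
  prior_ok <- needs_prior |>
    dplyr::inner_join(dplyr::select(binding, "family", "peak", bind_tb = "time_b"),
                      by = c("family", "peak"), relationship = "many-to-many") |>
    dplyr::filter(.data$bind_tb <= .data$time_a) |>
    dplyr::distinct(.data$family, .data$peak, .data$time_a, .data$time_b, .data$attribute)
  diss <- cand |>
    dplyr::filter(.data$attribute == "dissociation",
                  !is.na(.data$gate_pass), .data$gate_pass) |>
    dplyr::select("family", "peak", "time_a", "time_b", "attribute")
  out <- dplyr::bind_rows(binding, diss, prior_ok) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$family, .data$peak, .data$time_a, .data$time_b)
  out
}

# implied regulatory sign of a trans edge on a nearby gene
implied_sign <- function(role, attribute) {
  dplyr::if_else((role == "opener") == (attribute == "binding"),
                 "activation", "repression")
}

#' Infer cis-edges (regulatory element to gene)
#'
#' A cis-edge links an RE to a gene when (1) the RE interval is within
#' `max_gap` (10 kb) of the gene body, (2) the RE carries a trans-edge
#' whose interval overlaps a significant transcription call of the gene
#' (covariation over the same time range; closed-interval overlap, or
#' exact equality with `strict_interval`), (3) the implied sign of
#' every contributing family's trans-edge matches the gene's call,
#' (4) the gene is dynamic in at least one comparison identified by the
#' factor's CDF analysis, and (5) the TSS-to-summit distance is within
#' the factor's CDF distance limit. Factors absent from the constraint
#' table contribute no cis-edges.
#'
#' @param trans_edges from [infer_trans_edges()].
#' @param peaks peak tibble (`peak, chrom, start, end, summit`).
#' @param genes gene tibble (`gene, chrom, start, end, tss`).
#' @param gene_calls from [transcription_series()].
#' @param constraints from [cdf_constraints()].
#' @param families rule tibble (for the opener/closer roles).
#' @param max_gap RE-to-gene-body gap limit, bp.
#' @param strict_interval require identical (not merely overlapping)
#'   trans/cis intervals.
#' @return tibble `peak, gene, time_a, time_b, sign, families,
#'   re_direction, distance_bp, gap_bp`.
#' @export
infer_cis_edges <- function(trans_edges, peaks, genes, gene_calls, constraints,
                            families = family_rules(), max_gap = 10000,
                            strict_interval = FALSE) {
  empty <- tibble(peak = character(), gene = character(), time_a = numeric(),
                  time_b = numeric(), sign = character(), families = character(),
                  re_direction = character(), distance_bp = numeric(),
                  gap_bp = numeric())
  if (nrow(trans_edges) == 0 || nrow(constraints) == 0) return(empty)
  limits <- constraints |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(max_distance = max(.data$distance_bp), .groups = "drop")
  te <- trans_edges |>
    dplyr::inner_join(dplyr::select(families, family = "name", "role"), by = "family") |>
    dplyr::mutate(sign = implied_sign(.data$role, .data$attribute)) |>
    dplyr::inner_join(limits, by = "family")
  pk <- dplyr::select(peaks, "peak", pk_chrom = "chrom", pk_start = "start",
                      pk_end = "end", "summit")
  gn <- dplyr::select(genes, "gene", gn_chrom = "chrom", gn_start = "start",
                      gn_end = "end", "tss")
  pairs <- dplyr::inner_join(pk, gn, by = c(pk_chrom = "gn_chrom"),
                             relationship = "many-to-many") |>
    dplyr::mutate(
      gap_bp = interval_gap(.data$pk_start, .data$pk_end, .data$gn_start, .data$gn_end),
      distance_bp = abs(.data$pk_start + .data$summit - .data$tss)) |>
    dplyr::filter(.data$gap_bp <= max_gap)
  sig_gene <- gene_calls |>
    dplyr::filter(.data$call != "unchanged") |>
    dplyr::select(gene = "feature", g_ta = "time_a", g_tb = "time_b", "call")
  # comparison-set rule: the gene is dynamic in >= 1 CDF comparison
  cdf_ok <- sig_gene |>
    dplyr::inner_join(dplyr::select(constraints, "family", g_ta = "time_a", g_tb = "time_b"),
                      by = c("g_ta", "g_tb"), relationship = "many-to-many") |>
    dplyr::distinct(.data$family, .data$gene)
  cand <- te |>
    dplyr::inner_join(pairs, by = "peak", relationship = "many-to-many") |>
    dplyr::filter(.data$distance_bp <= .data$max_distance) |>
    dplyr::inner_join(sig_gene, by = "gene", relationship = "many-to-many") |>
    dplyr::filter(intervals_overlap(.data$time_a, .data$time_b, .data$g_ta, .data$g_tb,
                                    strict = strict_interval)) |>
    dplyr::filter((.data$sign == "activation") == (.data$call == "activated")) |>
    dplyr::semi_join(cdf_ok, by = c("family", "gene"))
  if (nrow(cand) == 0) return(empty)
  cand |>
    dplyr::group_by(.data$peak, .data$gene, time_a = .data$g_ta, time_b = .data$g_tb,
                    .data$sign) |>
    dplyr::summarise(
      families = paste(sort(unique(.data$family)), collapse = ","),
      distance_bp = .data$distance_bp[1],
      gap_bp = .data$gap_bp[1],
      .groups = "drop") |>
    dplyr::mutate(re_direction = dplyr::if_else(.data$sign == "activation", "up", "down")) |>
    dplyr::arrange(.data$peak, .data$gene, .data$time_a, .data$time_b)
}

#' Assemble a kinetic network object
#' @param trans_edges,cis_edges edge tibbles.
#' @param family_genes tibble `family, gene`.
#' @param time_points design time points, minutes.
#' @export
build_network <- function(trans_edges, cis_edges, family_genes = NULL,
                          time_points = NULL) {
  structure(list(trans = trans_edges, cis = cis_edges,
                 family_genes = family_genes %||% tibble(family = character(), gene = character()),
                 time_points = time_points),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("<kinetic_network> %d trans-edges (%d REs, %d families), %d cis-edges (%d genes)\n",
              nrow(x$trans), dplyr::n_distinct(x$trans$peak),
              dplyr::n_distinct(x$trans$family), nrow(x$cis),
              dplyr::n_distinct(x$cis$gene)))
  invisible(x)
}

#' @method tidy kinetic_network
#' @export
tidy.kinetic_network <- function(x, ...) network_edge_table(x)

#' @method glance kinetic_network
#' @export
glance.kinetic_network <- function(x, ...) {
  tibble(n_trans = nrow(x$trans), n_cis = nrow(x$cis),
         n_res = dplyr::n_distinct(x$trans$peak),
         n_genes = dplyr::n_distinct(x$cis$gene),
         n_families = dplyr::n_distinct(x$trans$family))
}

#' Flag attenuated (transient) edges
#'
#' An edge is attenuated when its RE or target gene later shows a
#' significant change of opposite sign: for a cis-edge, a gene call of
#' the opposite direction or an RE accessibility change opposite to the
#' direction that produced the edge, starting no earlier than the edge
#' interval's end; for a trans-edge, an opposite RE change.
#'
#' @param net `kinetic_network`.
#' @param atac_calls,gene_calls all-pairs call tables.
#' @param families rule tibble (for the opener/closer roles).
#' @return the network with `attenuated` columns on both edge tables.
#' @export
annotate_attenuation <- function(net, atac_calls, gene_calls,
                                 families = family_rules()) {
  sig_atac <- dplyr::filter(atac_calls, .data$direction != "none")
  later_opposite_re <- function(peak, dirn, after) {
    s <- sig_atac[sig_atac$feature == peak, ]
    any(s$time_a >= after & s$direction != dirn)
  }
  closers <- families$name[families$role == "closer"]
  tr <- net$trans
  if (nrow(tr)) {
    tr_dir <- dplyr::if_else(
      tr$attribute == "binding",
      dplyr::if_else(tr$family %in% closers, "down", "up"),
      dplyr::if_else(tr$family %in% closers, "up", "down"))
    tr$attenuated <- vapply(seq_len(nrow(tr)), function(i)
      later_opposite_re(tr$peak[i], tr_dir[i], tr$time_b[i]), NA)
  } else tr$attenuated <- logical()
  ci <- net$cis
  if (nrow(ci)) {
    sig_gene <- dplyr::filter(gene_calls, .data$call != "unchanged")
    ci$attenuated <- vapply(seq_len(nrow(ci)), function(i) {
      opp_call <- if (ci$sign[i] == "activation") "repressed" else "activated"
      g <- sig_gene[sig_gene$feature == ci$gene[i], ]
      gene_rev <- any(g$time_a >= ci$time_b[i] & g$call == opp_call)
      gene_rev || later_opposite_re(ci$peak[i], ci$re_direction[i], ci$time_b[i])
    }, NA)
  } else ci$attenuated <- logical()
  net$trans <- tr
  net$cis <- ci
  net
}

#' Constrained subnetwork statistics
#'
#' Counts genes solely vs combinatorially regulated by each factor,
#' bound REs without downstream targets, and the distribution of RE
#' combination classes (nonempty subsets of the activator families
#' bound at each RE).
#'
#' @param net `kinetic_network`.
#' @param factors activator families to enumerate (k of them give
#'   2^k - 1 possible RE classes).
#' @return list with tibbles `gene_counts` (factor, solely,
#'   combinatorial), `re_without_targets` (factor, n), and
#'   `re_classes` (class, n).
#' @export
subnetwork_stats <- function(net, factors) {
  assert_that(length(factors) <= 6, "combination enumeration supports at most 6 families")
  upstream <- net$cis |>
    tidyr::separate_rows("families", sep = ",") |>
    dplyr::distinct(.data$gene, family = .data$families)
  gene_sets <- upstream |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(fams = list(sort(unique(.data$family))), .groups = "drop")
  gene_counts <- purrr::map_dfr(factors, function(f) {
    has <- vapply(gene_sets$fams, function(s) f %in% s, NA)
    solo <- vapply(gene_sets$fams, function(s) identical(s, f), NA)
    tibble(factor = f, solely = sum(solo), combinatorial = sum(has & !solo))
  })
  targeted <- unique(net$cis$peak)
  re_without <- net$trans |>
    dplyr::filter(.data$family %in% factors) |>
    dplyr::distinct(.data$family, .data$peak) |>
    dplyr::group_by(factor = .data$family) |>
    dplyr::summarise(n = sum(!.data$peak %in% targeted), .groups = "drop")
  re_classes <- net$trans |>
    dplyr::filter(.data$family %in% factors, .data$attribute == "binding") |>
    dplyr::distinct(.data$peak, .data$family) |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(class = paste(sort(unique(.data$family)), collapse = "+"),
                     .groups = "drop") |>
    dplyr::count(.data$class, name = "n")
  list(gene_counts = gene_counts, re_without_targets = re_without,
       re_classes = re_classes,
       n_possible_classes = 2^length(factors) - 1)
}

#' Time-respecting downstream reach of a gene node
#'
#' Breadth-first traversal from a gene node through its TF family's
#' trans-edges and onward through cis-edges, admitting an edge only if
#' its interval starts no earlier than the start of the interval that
#' reached the current node ("subgraphs that respect the flow of
#' time"). Gene nodes propagate to their family node (if the gene
#' encodes a family member) at unchanged arrival time.
#'
#' @param net `kinetic_network` with `family_genes`.
#' @param source_gene gene id to start from.
#' @param source_start arrival-interval start of the source (minutes);
#'   typically the start of the gene's activation interval.
#' @return list with `res` and `genes` (character vectors of reached
#'   node ids, source excluded) and the counts `n_res`, `n_genes`.
#' @export
downstream_reach <- function(net, source_gene, source_start = 0) {
  arrive <- new.env(parent = emptyenv())
  key <- function(type, id) paste0(type, ":", id)
  queue <- list(list(type = "gene", id = source_gene, at = source_start))
  assign(key("gene", source_gene), source_start, envir = arrive)
  guard <- 0L
  while (length(queue)) {
    guard <- guard + 1L
    assert_that(guard < 1e6, "time-respecting traversal failed to terminate")
    node <- queue[[1]]; queue <- queue[-1]
    nexts <- list()
    if (node$type == "gene") {
      fams <- net$family_genes$family[net$family_genes$gene == node$id]
      for (f in fams) nexts[[length(nexts) + 1]] <-
          list(type = "family", id = f, at = node$at)
    } else if (node$type == "family") {
      e <- net$trans[net$trans$family == node$id & net$trans$time_a >= node$at, ]
      for (i in seq_len(nrow(e))) nexts[[length(nexts) + 1]] <-
          list(type = "re", id = e$peak[i], at = e$time_a[i])
    } else {
      e <- net$cis[net$cis$peak == node$id & net$cis$time_a >= node$at, ]
      for (i in seq_len(nrow(e))) nexts[[length(nexts) + 1]] <-
          list(type = "gene", id = e$gene[i], at = e$time_a[i])
    }
    for (nx in nexts) {
      k <- key(nx$type, nx$id)
      best <- mget(k, envir = arrive, ifnotfound = Inf)[[1]]
      if (nx$at < best) {
        assign(k, nx$at, envir = arrive)
        queue[[length(queue) + 1]] <- nx
      }
    }
  }
  all_keys <- ls(envir = arrive)
  res <- sub("^re:", "", all_keys[startsWith(all_keys, "re:")])
  genes <- setdiff(sub("^gene:", "", all_keys[startsWith(all_keys, "gene:")]),
                   source_gene)
  list(res = sort(res), genes = sort(genes),
       n_res = length(res), n_genes = length(genes))
}

#' Validate network invariants
#'
#' Checks interval validity, the trans-edge cover of every cis-edge
#' (overlapping intervals), distance bounds, and sign consistency.
#'
#' @param net `kinetic_network`.
#' @param peaks,genes feature tables.
#' @param constraints CDF constraint table used at construction.
#' @param families rule tibble.
#' @param max_gap gap limit used at construction.
#' @return tibble `check, pass, detail`; attribute `valid` TRUE when
#'   all checks pass.
#' @export
validate_network <- function(net, peaks, genes, constraints,
                             families = family_rules(), max_gap = 10000) {
  checks <- list()
  add <- function(name, ok, detail = "") checks[[length(checks) + 1]] <<-
    tibble(check = name, pass = ok, detail = detail)
  tr <- net$trans; ci <- net$cis
  add("trans_intervals", all(tr$time_a < tr$time_b))
  add("trans_attributes", all(tr$attribute %in% c("binding", "dissociation")))
  if (nrow(ci)) {
    cover <- ci |>
      dplyr::inner_join(dplyr::select(tr, "peak", tr_ta = "time_a", tr_tb = "time_b"),
                        by = "peak", relationship = "many-to-many") |>
      dplyr::filter(intervals_overlap(.data$time_a, .data$time_b,
                                      .data$tr_ta, .data$tr_tb)) |>
      dplyr::distinct(.data$peak, .data$gene, .data$time_a, .data$time_b)
    add("cis_trans_cover",
        nrow(dplyr::distinct(ci, .data$peak, .data$gene, .data$time_a, .data$time_b)) ==
          nrow(cover),
        "every cis-edge's RE carries an overlapping trans-edge")
    add("cis_gap_bound", all(ci$gap_bp <= max_gap))
    if (nrow(constraints)) {
      lim <- constraints |>
        dplyr::group_by(.data$family) |>
        dplyr::summarise(max_distance = max(.data$distance_bp), .groups = "drop")
      fam_lim <- ci |>
        tidyr::separate_rows("families", sep = ",") |>
        dplyr::inner_join(lim, by = c(families = "family"))
      add("cis_distance_bound", all(fam_lim$distance_bp <= fam_lim$max_distance))
    }
    add("cis_signs", all(ci$sign %in% c("activation", "repression")))
  } else {
    add("cis_trans_cover", TRUE, "no cis-edges")
  }
  out <- dplyr::bind_rows(checks)
  structure(out, valid = all(out$pass))
}
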
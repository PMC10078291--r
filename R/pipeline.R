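# End-to-end orchestration over a simulated (or file-based) data set:
# accessibility dynamics -> motif scanning -> PRO-seq metrics -> CDF
# constraints -> network inference -> compartment fits -> cooperation.

#' Run the full kinetic-network pipeline
#'
#' Sequences the analysis modules in their natural order on a
#' simulated data set (from [simulate_dataset()]) or on equivalent
#' in-memory tables. Every stage's output is returned (and optionally
#' written to `out_dir`); the run is deterministic given `seed`.
#'
#' @param data list as returned by [simulate_dataset()] (`genes`,
#'   `peaks`, `atac`, `proseq`, `design`).
#' @param families rule tibble from [family_rules()]; defaults to rules
#'   spanning the design's time range.
#' @param pwms named list of `pwm_model`s (defaults to the simulated
#'   family PWMs when present in `data$truth`).
#' @param q_threshold significance threshold for differential calls.
#' @param motif_p PWM scan p-value threshold.
#' @param max_gap cis-edge RE-to-gene-body gap limit, bp.
#' @param cdf_permutations permutations per CDF comparison.
#' @param expression_floor quantile for the family-expression floor.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @param seed integer seed for the permutation tests.
#' @return list with all intermediates: `size_factors, atac_calls,
#'   classes, hits, direction, pause, gene_calls, constraints, network,
#'   validation, stats, report`.
#' @export
run_pipeline <- function(data, families = NULL, pwms = NULL,
                         q_threshold = 0.05, motif_p = 1e-4,
                         max_gap = 10000, cdf_permutations = 200,
                         expression_floor = 0.25, out_dir = NULL,
                         seed = 1L) {
  design <- data$design
  tp <- sort(unique(design$time))
  families <- families %||% family_rules(time_max = max(tp))
  pwms <- pwms %||% setNames(data$truth$config$tf_families$pwm,
                             data$truth$config$tf_families$name)

  # 1. accessibility dynamics
  sf <- size_factors(data$atac)
  atac_calls <- differential_series(data$atac, design, "all", q_threshold)
  norm <- normalize_counts(data$atac, sf)
  traj <- as_tibble(norm, rownames = "peak") |>
    tidyr::pivot_longer(-"peak", names_to = "sample", values_to = "x") |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::group_by(.data$peak, .data$time) |>
    dplyr::summarise(mean_norm = mean(.data$x), .groups = "drop")
  classes <- classify_kinetics(traj, atac_calls)

  # 2. motifs
  hits <- scan_pwm_set(dplyr::select(data$peaks, "peak", "seq"), pwms,
                       p_threshold = motif_p)
  direction <- assign_direction(classes, hits)

  # 3. nascent transcription
  gene_calls <- transcription_series(data$proseq$body_counts, design, "all",
                                     q_threshold)
  pause <- pause_metrics_series(data$genes, data$proseq$tracks)
  densities <- dplyr::select(pause, "gene", "time", "body_density")

  # 4. CDF constraints (per factor, baseline comparisons)
  dynamic_peaks <- classes$peak[classes$class != "nondynamic"]
  constraints <- cdf_constraints(
    data$genes, gene_calls, data$peaks, hits, families, dynamic_peaks,
    n_permutations = cdf_permutations, seed = seed)

  # 5. network
  fam_calls <- family_transcription_calls(gene_calls, data$truth$family_genes)
  expr <- family_expression(densities, data$truth$family_genes,
                            floor_quantile = expression_floor)
  trans <- infer_trans_edges(atac_calls, hits, fam_calls, expr, families)
  cis <- infer_cis_edges(trans, data$peaks, data$genes, gene_calls,
                         constraints, families, max_gap = max_gap)
  net <- build_network(trans, cis, data$truth$family_genes, tp) |>
    annotate_attenuation(atac_calls, gene_calls, families)
  validation <- validate_network(net, data$peaks, data$genes, constraints,
                                 families, max_gap = max_gap)
  stats <- subnetwork_stats(net, families$name[families$role == "opener" &
                                                 !families$dissociates])

  # 6. compartment fit for the pause-release factor's isolated targets
  gr_fit <- NULL
  gr_genes <- data$truth$genes$gene[which(data$truth$genes$target_of == "GR")]
  if (length(gr_genes) >= 3) {
    med_occ <- function(tm) {
      p <- dplyr::filter(pause, .data$gene %in% gr_genes, .data$time == tm,
                         !.data$flagged)
      list(P = median(p$pause_density) * 50, b = median(p$body_density))
    }
    gr_fit <- tryCatch(fit_fold_changes(med_occ(tp[1]), med_occ(tp[2])),
                       error = function(e) NULL)
  }

  report <- list(
    n_peaks = nrow(data$peaks),
    n_dynamic = sum(classes$class != "nondynamic"),
    class_counts = as.list(table(classes$class)),
    n_trans_edges = nrow(trans), n_cis_edges = nrow(cis),
    trans_attenuated_frac = if (nrow(net$trans)) mean(net$trans$attenuated) else NA,
    cis_attenuated_frac = if (nrow(net$cis)) mean(net$cis$attenuated) else NA,
    network_valid = isTRUE(attr(validation, "valid")),
    gr_fit = if (!is.null(gr_fit)) as.list(glance(gr_fit)) else NULL,
    thresholds = list(q_threshold = q_threshold, motif_p = motif_p,
                      max_gap = max_gap, cdf_permutations = cdf_permutations,
                      expression_floor = expression_floor, seed = seed))

  out <- list(size_factors = sf, atac_calls = atac_calls, classes = classes,
              hits = hits, direction = direction, pause = pause,
              gene_calls = gene_calls, constraints = constraints,
              network = net, validation = validation, stats = stats,
              fit = gr_fit, report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out$atac_calls, file.path(dir, "atac_calls.tsv"))
  readr::write_tsv(as_tibble(out$classes), file.path(dir, "kinetic_classes.tsv"))
  readr::write_tsv(out$hits, file.path(dir, "motif_hits.tsv"))
  readr::write_tsv(out$gene_calls, file.path(dir, "gene_calls.tsv"))
  readr::write_tsv(out$pause, file.path(dir, "pause_metrics.tsv"))
  readr::write_tsv(as_tibble(out$constraints), file.path(dir, "cdf_constraints.tsv"))
  write_network(out$network, file.path(dir, "network_edges.tsv"),
                graphml = file.path(dir, "network.graphml"))
  jsonlite::write_json(out$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Thresholds and paths for file-based runs; see the vignette for the
#' schema. Returns a plain list suitable for `do.call(run_pipeline, .)`
#' after loading the referenced inputs.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in cfg$paths) assert_that(file.exists(p), "config path does not exist: %s", p)
  cfg
}
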
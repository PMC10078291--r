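# Synthetic ATAC/PRO-seq time-course generator with planted ground
# truth. One synthetic chromosome carries genes on a fixed spacing grid
# (unambiguous nearest-gene assignment); dynamic regulatory elements
# are planted near their target genes with the family motif embedded at
# the summit; accessibility follows fixed class trajectories and
# nascent transcription follows the two-compartment polymerase model
# with planted rate fold-changes. Counts are negative binomial with a
# shared dispersion and per-replicate log-normal library sizes.

kinetic_class_trajectories <- function() {
  # relative accessibility at the seven design time points
  list(
    nondynamic          = c(1, 1, 1, 1, 1, 1, 1),
    immediate_increase  = c(1, 3, 3, 3, 3, 3, 3),
    transient_increase  = c(1, 3, 3, 2.2, 1.4, 1.1, 1),
    gradual_increase    = c(1, 1, 2, 2.5, 3, 3, 3),
    transient_decrease  = c(1, 1, 0.4, 0.33, 0.5, 0.8, 1),
    gradual_decrease    = c(1, 1, 1, 0.4, 0.33, 0.33, 0.33))
}

make_family_pwm <- function(name, consensus, p = 0.92) {
  letters_ <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - p) / 3, nrow = length(letters_), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(letters_)) mat[i, letters_[i]] <- p
  pwm_model(name, mat)
}

#' Default planted TF-family program
#'
#' Mirrors the adipogenic narrative: cocktail-activated openers (AP-1,
#' CEBP, GR) act from 0-20 min, with GR regulatory elements transient;
#' a transcriptionally induced opener (KLF-like) acts from 20 min; a
#' transcriptionally induced closer (TWIST-like) represses from
#' 20-60 min; a repressed opener (SP-like) dissociates from 40 min on.
#' Each family has a distinct synthetic 8-bp motif.
#'
#' @param motif_p consensus-base probability of the synthetic PWMs.
#' @export
default_tf_families <- function(motif_p = 0.92) {
  fam <- tibble(
    name = c("AP1", "CEBP", "GR", "KLF", "TWIST", "SP"),
    consensus = c("TGACTCAG", "ATTGCGCA", "AGAACAGG", "GGGTGGGG",
                  "CATCTGCA", "GGGCGGAA"),
    role = c("opener", "opener", "opener", "opener", "closer", "opener"),
    cocktail = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dissociates = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    genic_regulation = c("cocktail", "cocktail", "cocktail",
                         "transcriptional", "transcriptional", "transcriptional"),
    class = c("immediate_increase", "immediate_increase", "transient_increase",
              "gradual_increase", "transient_decrease", "gradual_decrease"),
    # interval of the first planted accessibility change (minutes)
    change_a = c(0, 0, 0, 20, 20, 40),
    change_b = c(20, 20, 20, 40, 40, 60),
    # regulatory sign on target genes
    target_sign = c("activation", "activation", "activation", "activation",
                    "repression", "repression"),
    # SP acts at promoters: its REs are planted promoter-proximal; NA
    # defers to the config-wide summit-to-TSS cap
    re_offset_max = c(NA, NA, NA, NA, NA, 250))
  fam$pwm <- purrr::map2(fam$name, fam$consensus, make_family_pwm, p = motif_p)
  fam
}

#' Simulation configuration
#'
#' @param time_points minutes, strictly increasing, starting at 0.
#' @param n_replicates replicates per time point.
#' @param n_res total number of accessibility peaks.
#' @param n_genes number of genes (>= planted targets + family genes).
#' @param n_dynamic_per_family planted dynamic REs per TF family.
#' @param tf_families tibble from [default_tf_families()].
#' @param dispersion shared negative-binomial dispersion (0 = Poisson).
#' @param libsize_sd sd of per-replicate log-normal size factors.
#' @param atac_depth mean baseline ATAC counts per peak.
#' @param pro_depth PRO-seq reads per polymerase.
#' @param gene_spacing TSS spacing on the synthetic chromosome, bp.
#' @param gene_length gene length, bp.
#' @param peak_width peak width, bp (summit at the midpoint).
#' @param re_offset_max maximum planted summit-to-TSS distance, bp.
#' @param nondynamic_motif_frac fraction of nondynamic peaks carrying a
#'   random family motif at a random (non-summit-centred) offset.
#' @param seed integer seed; all generator randomness flows through it.
#' @export
sim_config <- function(time_points = c(0, 20, 40, 60, 120, 180, 240),
                       n_replicates = 3, n_res = 150, n_genes = 100,
                       n_dynamic_per_family = 10,
                       tf_families = default_tf_families(),
                       dispersion = 0.05, libsize_sd = 0.15,
                       atac_depth = 100, pro_depth = 10,
                       gene_spacing = 25000, gene_length = 8000,
                       peak_width = 300, re_offset_max = 2500,
                       nondynamic_motif_frac = 0.3, seed = 1L) {
  assert_that(all(diff(time_points) > 0) && time_points[1] == 0,
              "time points must be strictly increasing and start at 0")
  assert_that(dispersion >= 0, "dispersion must be non-negative")
  assert_that(length(time_points) == 7,
              "the planted class trajectories are defined over seven time points")
  cfg <- list(time_points = time_points, n_replicates = n_replicates,
              n_res = n_res, n_genes = n_genes,
              n_dynamic_per_family = n_dynamic_per_family,
              tf_families = tf_families, dispersion = dispersion,
              libsize_sd = libsize_sd, atac_depth = atac_depth,
              pro_depth = pro_depth, gene_spacing = gene_spacing,
              gene_length = gene_length, peak_width = peak_width,
              re_offset_max = re_offset_max,
              nondynamic_motif_frac = nondynamic_motif_frac,
              seed = as.integer(seed))
  n_dyn <- n_dynamic_per_family * nrow(tf_families)
  assert_that(n_dyn <= n_res,
              "infeasible config: %d planted dynamic REs exceed %d peaks", n_dyn, n_res)
  assert_that(n_dyn + 3 <= n_genes,
              "infeasible config: need %d target genes plus cocktail family genes, have %d",
              n_dyn + 3, n_genes)
  structure(cfg, class = "sim_config")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Replace accidental family-motif occurrences with fresh random bases.
# The planted PWMs are sharp enough that scan hits at p <= 1e-4 occur
# only at exact consensus matches (asserted in the test suite), so
# fixed-string search over consensus + reverse complement suffices and
# is much faster than rescanning.
scrub_sequence <- function(seq, patterns, keep_offset = NULL, keep_width = 0,
                           max_iter = 25) {
  for (it in seq_len(max_iter)) {
    found <- lapply(patterns, function(p) {
      m <- gregexpr(p, seq, fixed = TRUE)[[1]]
      if (m[1] == -1) integer() else
        cbind(start = as.integer(m), width = nchar(p))
    })
    found <- do.call(rbind, found[lengths(found) > 0])
    if (!is.null(found) && !is.null(keep_offset)) {
      # leave anything overlapping the planted window alone; the caller
      # re-plants the motif afterwards
      keep <- abs(found[, "start"] - (keep_offset + 1)) <= keep_width
      found <- found[!keep, , drop = FALSE]
    }
    if (is.null(found) || nrow(found) == 0) return(seq)
    ch <- strsplit(seq, "")[[1]]
    for (i in seq_len(nrow(found))) {
      idx <- found[i, "start"]:(found[i, "start"] + found[i, "width"] - 1)
      ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    }
    seq <- paste(ch, collapse = "")
  }
  stop_kn("failed to scrub accidental motif matches after %d rounds", max_iter)
}

plant_motif <- function(seq, consensus, offset) {
  ch <- strsplit(seq, "")[[1]]
  ch[(offset + 1):(offset + nchar(consensus))] <- strsplit(consensus, "")[[1]]
  paste(ch, collapse = "")
}

# transcription-coordinate half-open window [p1, p2) to genomic
genomic_window <- function(tss, strand, p1, p2) {
  if (strand == "+") c(tss + p1, tss + p2) else c(tss - p2 + 1, tss - p1 + 1)
}

#' Generate the planted ground truth
#'
#' Builds the synthetic chromosome, gene models, dynamic and
#' nondynamic peaks with embedded motifs, per-gene compartment-model
#' parameters with planted fold-changes, and the planted trans/cis
#' edge sets.
#'
#' @param config from [sim_config()].
#' @return list with `genes`, `peaks` (motif-embedded sequences
#'   included) and `truth` (class `truth_set`).
#' @export
simulate_truth <- function(config) {
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  fam <- config$tf_families
  tp <- config$time_points
  n_fam <- nrow(fam)
  n_dyn <- config$n_dynamic_per_family * n_fam
  chrom <- "chrS"
  chrom_len <- (config$n_genes + 2) * config$gene_spacing

  # genes on the spacing grid, random strand
  tss <- config$gene_spacing * seq_len(config$n_genes)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  glen <- config$gene_length
  genes <- tibble(
    chrom = chrom,
    start = ifelse(strand == "+", tss, tss - glen + 1),
    end = ifelse(strand == "+", tss + glen, tss + 1),
    gene = sprintf("g%03d", seq_len(config$n_genes)),
    strand = strand, tss = tss)

  # roles: targets for each family, then cocktail family genes, rest static
  ord <- sample(config$n_genes)
  target_idx <- ord[seq_len(n_dyn)]
  pool <- ord[(n_dyn + 1):config$n_genes]
  fam_of_target <- rep(fam$name, each = config$n_dynamic_per_family)
  genes$target_of <- NA_character_
  genes$target_of[target_idx] <- fam_of_target
  # family-member genes: TWIST's gene is an AP-1 target (induced by the
  # cocktail), SP's gene a TWIST target (repressed in the second wave),
  # KLF's gene a CEBP target; AP-1/CEBP/GR member genes are
  # constitutively expressed non-targets
  pick_target <- function(f) which(genes$target_of == f)[1]
  family_genes <- tibble(
    family = c("AP1", "CEBP", "GR", "KLF", "TWIST", "SP"),
    gene = c(genes$gene[pool[1]], genes$gene[pool[2]], genes$gene[pool[3]],
             genes$gene[pick_target("CEBP")], genes$gene[pick_target("AP1")],
             genes$gene[pick_target("TWIST")]))
  family_genes <- dplyr::semi_join(family_genes, fam, by = c(family = "name"))

  # peaks: dynamic REs near their target TSS, nondynamic elsewhere;
  # per-family offset caps override the config-wide cap
  w <- config$peak_width
  fam_cap <- if ("re_offset_max" %in% names(fam))
    fam$re_offset_max[match(fam_of_target, fam$name)] else rep(NA_real_, n_dyn)
  off_cap <- ifelse(is.na(fam_cap), config$re_offset_max, fam_cap)
  dyn_summit <- genes$tss[target_idx] +
    sample(c(-1, 1), n_dyn, TRUE) *
      vapply(off_cap, function(m) sample.int(m, 1), 0L)
  nd <- config$n_res - n_dyn
  nd_summit <- sort(sample.int(chrom_len - 2 * w, nd) + w)
  peaks <- tibble(
    chrom = chrom,
    summit_pos = c(dyn_summit, nd_summit),
    peak = sprintf("pk%03d", seq_len(config$n_res)),
    score = 0, strand = ".",
    class = c(fam$class[match(fam_of_target, fam$name)], rep("nondynamic", nd)),
    family = c(fam_of_target, rep(NA_character_, nd)),
    target_gene = c(genes$gene[target_idx], rep(NA_character_, nd))) |>
    dplyr::mutate(start = .data$summit_pos - w %/% 2, end = .data$start + w,
                  summit = w %/% 2)

  # sequences: scrubbed random background, planted consensus at the
  # summit (dynamic) or a random offset (a fraction of nondynamic)
  consensus <- setNames(fam$consensus, fam$name)
  patterns <- unique(c(fam$consensus, revcomp(fam$consensus)))
  nd_has_motif <- runif(nd) < config$nondynamic_motif_frac
  nd_fam <- sample(fam$name, nd, replace = TRUE)
  seqs <- character(config$n_res)
  motif_offset <- rep(NA_integer_, config$n_res)
  for (i in seq_len(config$n_res)) {
    s <- scrub_sequence(random_seq(w), patterns)
    f <- peaks$family[i]
    if (is.na(f) && i > n_dyn && nd_has_motif[i - n_dyn]) f <- nd_fam[i - n_dyn]
    if (!is.na(f)) {
      cons <- consensus[[f]]
      off <- if (!is.na(peaks$family[i])) {
        w %/% 2 - nchar(cons) %/% 2 + sample(-3:3, 1)
      } else sample.int(w - nchar(cons) - 20, 1) + 10
      planted <- plant_motif(s, cons, off)
      s <- scrub_sequence(planted, patterns, keep_offset = off,
                          keep_width = nchar(cons))
      # planting may need a re-plant if scrubbing touched the flanks
      s <- plant_motif(s, cons, off)
      motif_offset[i] <- off
    }
    seqs[i] <- s
  }
  peaks$seq <- seqs
  peaks$motif_offset <- motif_offset

  # accessibility trajectories per peak
  traj <- kinetic_class_trajectories()
  atac_mean <- purrr::map_dfr(seq_len(config$n_res), function(i) {
    tibble(peak = peaks$peak[i], time = tp,
           rel = traj[[peaks$class[i]]],
           mean = config$atac_depth * traj[[peaks$class[i]]])
  })

  # per-gene base rate parameters and planted fold-changes; baseline
  # expression spans ~2 orders of magnitude (as real transcriptomes do)
  # so the family-expression floor separates expressed from silent
  # genes; TF-family member genes sit in the well-expressed range
  base <- rate_params(
    k_init = rlnorm(config$n_genes, log(8), 1.0),
    k_pre = 0.02, k_rel = 2, k_elong = 2500,
    L = glen - 350)
  base$k_init[genes$gene %in% family_genes$gene] <- 25
  intervals <- tibble(time_a = tp[-length(tp)], time_b = tp[-1])
  fold <- tidyr::expand_grid(gene = genes$gene, intervals) |>
    dplyr::mutate(f_init = 1, f_rel = 1)
  plant_fold <- function(fold, gene_id, ta, tb, f_init, f_rel = 1) {
    i <- fold$gene == gene_id & fold$time_a == ta & fold$time_b == tb
    fold$f_init[i] <- f_init
    fold$f_rel[i] <- f_rel
    fold
  }
  for (i in which(!is.na(genes$target_of))) {
    f <- genes$target_of[i]
    fr <- fam[fam$name == f, ]
    if (fr$target_sign == "activation") {
      if (f == "GR") {
        fold <- plant_fold(fold, genes$gene[i], fr$change_a, fr$change_b, 2.0, 1.5)
      } else {
        fold <- plant_fold(fold, genes$gene[i], fr$change_a, fr$change_b, 2.5)
      }
    } else {
      fold <- plant_fold(fold, genes$gene[i], fr$change_a, fr$change_b, 0.4)
    }
  }

  # noiseless occupancy at every time point (steady-state snapshots)
  occupancy <- purrr::map_dfr(seq_len(config$n_genes), function(i) {
    fc <- dplyr::filter(fold, .data$gene == genes$gene[i]) |>
      dplyr::arrange(.data$time_a)
    p <- base[i, ]
    out <- list(dplyr::bind_cols(tibble(gene = genes$gene[i], time = tp[1]),
                                 steady_state(p)))
    for (j in seq_len(nrow(fc))) {
      p <- apply_fold_changes(p, fc$f_init[j], fc$f_rel[j])
      out[[j + 1]] <- dplyr::bind_cols(tibble(gene = genes$gene[i], time = fc$time_b[j]),
                                       steady_state(p))
    }
    dplyr::bind_rows(out)
  })

  # planted edges
  dyn <- peaks[seq_len(n_dyn), ]
  trans_edges <- purrr::map_dfr(seq_len(nrow(dyn)), function(i) {
    fr <- fam[fam$name == dyn$family[i], ]
    first <- tibble(family = dyn$family[i], peak = dyn$peak[i],
                    time_a = fr$change_a, time_b = fr$change_b,
                    attribute = if (fr$dissociates) "dissociation" else "binding")
    extra <- NULL
    # only GR carries planted dissociation edges (its transient REs
    # lose the factor after the early phase); other transient REs are
    # attenuation, not dissociation
    if (dyn$class[i] == "transient_increase" && dyn$family[i] == "GR")
      extra <- tibble(family = dyn$family[i], peak = dyn$peak[i],
                      time_a = 60, time_b = 240, attribute = "dissociation")
    dplyr::bind_rows(first, extra)
  })
  cis_edges <- tibble(peak = dyn$peak, gene = dyn$target_gene,
                      sign = fam$target_sign[match(dyn$family, fam$name)],
                      family = dyn$family)

  truth <- structure(list(
    config = config, chrom = chrom, chrom_len = chrom_len,
    genes = genes, peaks = peaks, family_genes = family_genes,
    atac_mean = atac_mean, base_params = dplyr::bind_cols(tibble(gene = genes$gene), base),
    fold_changes = fold, occupancy = occupancy,
    trans_edges = trans_edges, cis_edges = cis_edges,
    functions = dplyr::select(fam, family = "name", "role", "dissociates"),
    seed = config$seed), class = "truth_set")
  list(genes = genes, peaks = peaks, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> seed %d: %d peaks (%d dynamic), %d genes, %d trans / %d cis planted edges\n",
              x$seed, nrow(x$peaks), sum(x$peaks$class != "nondynamic"),
              nrow(x$genes), nrow(x$trans_edges), nrow(x$cis_edges)))
  invisible(x)
}

#' Serialize / restore a truth set as JSON
#' @param truth `truth_set`.
#' @param path JSON file.
#' @export
write_truth <- function(truth, path) {
  x <- truth[setdiff(names(truth), "config")]
  x$config <- truth$config[setdiff(names(truth$config), "tf_families")]
  x$tf_family_names <- truth$config$tf_families$name
  jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("genes", "peaks", "family_genes", "atac_mean", "base_params",
               "fold_changes", "occupancy", "trans_edges", "cis_edges", "functions"))
    x[[nm]] <- as_tibble(as.data.frame(x[[nm]]))
  x
}

sample_names <- function(config) {
  tidyr::expand_grid(time = config$time_points,
                     replicate = seq_len(config$n_replicates)) |>
    dplyr::mutate(sample = sprintf("t%03d_r%d", .data$time, .data$replicate))
}

#' Design table matching the simulated count columns
#' @param config `sim_config`.
#' @export
sim_design <- function(config) sample_names(config)

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the replicated ATAC-seq count matrix
#'
#' Counts are negative binomial around the depth-scaled planted class
#' trajectory, with per-replicate log-normal library-size factors.
#' With `noiseless = TRUE` the rounded expected counts are returned
#' (the infinite-depth, zero-dispersion limit used by recovery tests).
#'
#' @param truth `truth_set` from [simulate_truth()].
#' @param config the same `sim_config`.
#' @param noiseless return expected counts instead of draws.
#' @return tibble `peak` x sample columns.
#' @export
simulate_atac <- function(truth, config = truth$config, noiseless = FALSE) {
  des <- sample_names(config)
  withr::with_seed(config$seed + 1L, {
    lib <- rlnorm(nrow(des), -config$libsize_sd^2 / 2, config$libsize_sd)
    wide <- truth$atac_mean |>
      dplyr::select("peak", "time", "mean") |>
      dplyr::inner_join(des, by = "time", relationship = "many-to-many") |>
      dplyr::mutate(mu = .data$mean * lib[match(.data$sample, des$sample)],
                    count = if (noiseless) round(.data$mean) else
                      nb_draw(dplyr::n(), .data$mu, config$dispersion)) |>
      dplyr::select("peak", "sample", "count") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "count")
    wide[match(truth$peaks$peak, wide$peak), ]
  })
}

#' Simulate PRO-seq pause/body counts and signal tracks
#'
#' Pause-region and gene-body read counts are negative binomial around
#' the compartment-model steady-state occupancies at each time point
#' (`P x pro_depth` and `b x body_length x pro_depth`); the signal
#' tracks are noiseless polymerase densities: a uniform pause peak of
#' density `P/50` over the 50-bp pause region at the planted summit
#' (60 bp downstream of the TSS), uniform body density `b`, and an
#' antisense peak upstream of the TSS (half the pause density) giving
#' promoters their divergent signature.
#'
#' @inheritParams simulate_atac
#' @return list with `pause_counts`, `body_counts` (tibbles gene x
#'   sample), `tracks` (tibble `time, chrom, start, end, value,
#'   strand`), `design`, and the geometry (`pause_summit_p`, region
#'   bounds).
#' @export
simulate_proseq <- function(truth, config = truth$config, noiseless = FALSE) {
  genes <- truth$genes
  glen <- config$gene_length
  assert_that(glen >= 50 + 500, "gene shorter than pause region + 500 bp")
  des <- sample_names(config)
  summit_p <- 60L
  pause_lo <- summit_p - 25L; pause_hi <- summit_p + 25L
  body_lo <- summit_p + 250L
  body_len <- glen - body_lo
  occ <- truth$occupancy
  counts <- withr::with_seed(config$seed + 2L, {
    lib <- rlnorm(nrow(des), -config$libsize_sd^2 / 2, config$libsize_sd)
    both <- occ |>
      dplyr::inner_join(des, by = "time", relationship = "many-to-many") |>
      dplyr::mutate(
        lib = lib[match(.data$sample, des$sample)],
        mu_pause = .data$P * config$pro_depth * .data$lib,
        mu_body = .data$b * body_len * config$pro_depth * .data$lib,
        pause = if (noiseless) round(.data$P * config$pro_depth) else
          nb_draw(dplyr::n(), .data$mu_pause, config$dispersion),
        body = if (noiseless) round(.data$b * body_len * config$pro_depth) else
          nb_draw(dplyr::n(), .data$mu_body, config$dispersion))
    both
  })
  to_wide <- function(col) {
    counts |>
      dplyr::select("gene", "sample", value = dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "sample", values_from = "value") |>
      (\(x) x[match(genes$gene, x$gene), ])()
  }
  # noiseless density tracks (polymerases per bp)
  tracks <- purrr::map_dfr(config$time_points, function(tm) {
    oc <- dplyr::filter(occ, .data$time == tm)
    purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      o <- oc[oc$gene == g$gene, ]
      anti <- setdiff(c("+", "-"), g$strand)
      pw <- genomic_window(g$tss, g$strand, pause_lo, pause_hi)
      bw <- genomic_window(g$tss, g$strand, body_lo, glen)
      dw <- genomic_window(g$tss, g$strand, -135L, -85L)
      tibble(time = tm, chrom = g$chrom,
             start = c(pw[1], bw[1], dw[1]), end = c(pw[2], bw[2], dw[2]),
             value = c(o$P / 50, o$b, 0.5 * o$P / 50),
             strand = c(g$strand, g$strand, anti))
    })
  })
  list(pause_counts = to_wide("pause"), body_counts = to_wide("body"),
       tracks = tracks, design = des,
       pause_summit_p = summit_p,
       pause_region = c(pause_lo, pause_hi), body_start_p = body_lo)
}

#' Simulate a complete data set (truth + ATAC + PRO-seq)
#' @inheritParams simulate_atac
#' @export
simulate_dataset <- function(config, noiseless = FALSE) {
  st <- simulate_truth(config)
  list(genes = st$genes, peaks = st$peaks, truth = st$truth,
       atac = simulate_atac(st$truth, config, noiseless = noiseless),
       proseq = simulate_proseq(st$truth, config, noiseless = noiseless),
       design = sim_design(config))
}
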
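sharp_pwm <- function(consensus, p = 1, name = "M") {
  letters_ <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - p) / 3, length(letters_), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(letters_)) mat[i, letters_[i]] <- p
  pwm_model(name, mat)
}

test_that("a probability-1 consensus PWM scores ~16 bits over uniform background", {
  pwm <- sharp_pwm("ACGTACGT", p = 1)
  seq <- paste0("TTTT", "ACGTACGT", "TTTT")
  hits <- scan_pwm(c(x = seq), pwm)
  best <- hits[which.max(hits$score), ]
  # 8 x log2(1/0.25) = 16, up to the small pseudo-probability
  expect_equal(best$score, 16, tolerance = 0.01)
  expect_equal(best$offset, 4L)
  expect_equal(best$score_fraction, 1, tolerance = 1e-9)
})

test_that("reverse-complementing a sequence flips hit strands, not counts", {
  pwm <- sharp_pwm("TGACTCAG", p = 0.9)
  withr::with_seed(3, {
    base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  })
  seq <- paste0(substr(base, 1, 100), "TGACTCAG", substr(base, 101, 200))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
  h1 <- scan_pwm(c(x = seq), pwm)
  h2 <- scan_pwm(c(x = rc), pwm)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score))
  expect_equal(table(h1$strand)[["+"]], table(h2$strand)[["-"]])
  # offsets mirror: a hit at offset o maps to n - L - o
  expect_setequal(h2$offset, nchar(seq) - 8 - h1$offset)
})

test_that("exact DP p-values equal brute-force enumeration on length-4 PWMs", {
  withr::with_seed(9, {
    for (rep in 1:3) {
      mat <- matrix(rgamma(16, 1), 4, 4)
      mat <- mat / rowSums(mat)
      pwm <- pwm_model("R", mat)
      dp <- pwm_score_distribution(pwm)
      bf <- brute_pwm_pvalues(pwm)
      joined <- dplyr::inner_join(dp$tail, bf, by = "score_int",
                                  suffix = c("_dp", "_bf"))
      expect_equal(nrow(joined), nrow(bf))  # every achievable score present
      expect_equal(joined$pvalue_dp, joined$pvalue_bf, tolerance = 1e-10)
      # the maximal score's p-value equals the enumerated tail
      expect_equal(min(dp$tail$pvalue), min(bf$pvalue), tolerance = 1e-10)
    }
  })
})

test_that("scan agrees with a brute-force window scorer on random sequence", {
  pwm <- default_tf_families()$pwm[[1]]
  withr::with_seed(21, {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  })
  seq <- paste0(seq, "TGACTCAG")  # ensure at least one hit
  hits <- scan_pwm(c(x = seq), pwm, p_threshold = 0.01)
  bf <- brute_scan(seq, pwm)
  joined <- dplyr::inner_join(hits, bf, by = c("offset", "strand"),
                              suffix = c("_pkg", "_bf"))
  expect_equal(nrow(joined), nrow(hits))
  expect_equal(joined$score_pkg, joined$score_bf, tolerance = 1e-9)
  expect_true(all(hits$pvalue <= 0.01))
  # every brute-force window at or above the weakest reported hit appears
  expect_equal(nrow(hits), sum(bf$score >= min(hits$score) - 1e-9))
})

test_that("N bases score as background and PWMs longer than the sequence yield no hits", {
  pwm <- sharp_pwm("ACGT", p = 1)
  expect_silent(h <- scan_pwm(c(x = "ANGT"), pwm, p_threshold = 1))
  expect_equal(nrow(scan_pwm(c(x = "AC"), pwm)), 0)
})

test_that("motif density: summit-centred hits give a delta at 0; uniform hits are flat", {
  peaks <- tibble::tibble(peak = sprintf("p%d", 1:50), summit = 150,
                          class = "increased")
  hits0 <- tibble::tibble(peak = peaks$peak, offset = 150 - 4, strand = "+",
                          score = 10, pvalue = 1e-5, score_fraction = 1,
                          width = 8)
  dens <- motif_density(peaks, hits0, half_window = 200)
  expect_equal(dens$density[dens$offset == 0], 1)
  expect_equal(sum(dens$density), 1)
  # uniformly placed hits: chi-square test does not reject flatness
  withr::with_seed(14, {
    n <- 10000
    hitsu <- tibble::tibble(peak = sample(peaks$peak, n, TRUE),
                            offset = sample(0:292, n, TRUE), strand = "+",
                            score = 10, pvalue = 1e-5, score_fraction = 1,
                            width = 8)
    densu <- motif_density(peaks, hitsu, half_window = 140)
    counts <- densu$density * 50
    chisq <- sum((counts - mean(counts))^2 / mean(counts))
    expect_gt(stats::pchisq(chisq, df = length(counts) - 1, lower.tail = FALSE),
              0.001)
  })
  expect_error(motif_density(peaks[0, ], hits0), "empty")
})

test_that("planted motifs put the increased-class density peak above nondynamic", {
  st <- simulate_truth(small_config(17))
  hits <- scan_pwm_set(dplyr::select(st$peaks, peak, seq),
                       setNames(st$truth$config$tf_families$pwm,
                                st$truth$config$tf_families$name))
  pk <- dplyr::mutate(st$peaks, class = class_direction(class))
  ap1 <- dplyr::filter(hits, family == "AP1")
  dens <- motif_density(pk, ap1, half_window = 100)
  inc0 <- dens$density[dens$class == "increased" & abs(dens$offset) <= 10]
  non <- dens$density[dens$class == "nondynamic"]
  expect_gt(max(inc0), max(non))
})

test_that("assign_direction: majority rules, ties unassigned, single-motif subset", {
  peaks <- tibble::tibble(
    peak = sprintf("p%02d", 1:40),
    class = rep(c("immediate_increase", "gradual_decrease"), each = 20))
  # OP: 9 of 10 single-motif peaks in increase classes; CL: 9/10 decrease;
  # TIE: exactly 50/50
  hits <- dplyr::bind_rows(
    tibble::tibble(peak = c(sprintf("p%02d", 1:9), "p21"), family = "OP"),
    tibble::tibble(peak = c(sprintf("p%02d", 22:30), "p10"), family = "CL"),
    tibble::tibble(peak = c("p11", "p12", "p31", "p32"), family = "TIE"),
    # a peak with two families is excluded from every single-motif set
    tibble::tibble(peak = "p40", family = c("OP", "CL")))
  res <- assign_direction(peaks, hits)
  fn <- setNames(res$functions$role, res$functions$family)
  expect_equal(fn[["OP"]], "opener")
  expect_equal(fn[["CL"]], "closer")
  expect_equal(fn[["TIE"]], "unassigned")
  expect_false("p40" %in% res$single_motif_peaks$peak)
})

test_that("planted family functions are recovered in the noiseless limit", {
  ds <- simulate_dataset(small_config(23), noiseless = TRUE)
  calls <- differential_series(ds$atac, ds$design, "all")
  norm <- normalize_counts(ds$atac)
  traj <- tibble::as_tibble(norm, rownames = "peak") |>
    tidyr::pivot_longer(-peak, names_to = "sample", values_to = "x") |>
    dplyr::inner_join(ds$design, by = "sample") |>
    dplyr::group_by(peak, time) |>
    dplyr::summarise(mean_norm = mean(x), .groups = "drop")
  cl <- classify_kinetics(traj, calls)
  hits <- scan_pwm_set(dplyr::select(ds$peaks, peak, seq),
                       setNames(ds$truth$config$tf_families$pwm,
                                ds$truth$config$tf_families$name))
  res <- assign_direction(cl, hits)
  fams <- ds$truth$config$tf_families
  # SP dissociates (decrease classes) so its observed role is closer-like;
  # the other openers must come out opener and TWIST closer
  expected <- ifelse(fams$dissociates | fams$role == "closer", "closer", "opener")
  got <- res$functions$role[match(fams$name, res$functions$family)]
  expect_equal(got, expected)
})
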
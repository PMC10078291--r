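mk_track <- function(...) {
  structure(tibble::tibble(...), class = c("signal_track", class(tibble::tibble())))
}

plus_gene <- tibble::tibble(chrom = "c1", start = 10000, end = 18000,
                            gene = "gA", strand = "+", tss = 10000)

test_that("pause summit, region, and index follow their definitions", {
  # unique max at TSS+32, uniform body signal
  tr <- mk_track(
    chrom = "c1",
    start = c(10000, 10032, 10033, 10300),
    end = c(10032, 10033, 10100, 18000),
    value = c(1, 9, 1, 0.1),
    strand = "+")
  pm <- pause_metrics(plus_gene, tr)
  expect_equal(pm$summit_p, 32L)
  expect_equal(pm$summit_pos, 10032)
  # pause region [summit-25, summit+25) has 9 + 49 x ~1-ish signal;
  # check the exact densities instead of re-deriving by hand
  expect_false(pm$flagged)
  expect_gt(pm$pause_index, 1)
})

test_that("pause index equals (pause sum/50)/(body sum/body length)", {
  # pause signal ~2/bp with a unique spike at TSS+35; the 50-bp window
  # around the summit sums to 100.5, the body is uniform 0.1/bp from
  # summit+250 on: PI = (100.5/50)/0.1 = 20.1
  tr <- mk_track(chrom = "c1",
                 start = c(10010, 10035, 10036, 10285),
                 end = c(10035, 10036, 10060, 18000),
                 value = c(2, 2.5, 2, 0.1), strand = "+")
  pm <- pause_metrics(plus_gene, tr)
  expect_equal(pm$summit_p, 35L)
  expect_equal(pm$pause_density, 100.5 / 50, tolerance = 1e-9)
  expect_equal(pm$body_density, 0.1, tolerance = 1e-9)
  expect_equal(pm$pause_index, (100.5 / 50) / 0.1, tolerance = 1e-9)
})

test_that("minus-strand genes mirror plus-strand genes exactly", {
  minus_gene <- tibble::tibble(chrom = "c1", start = 92001, end = 100001,
                               gene = "gB", strand = "-", tss = 100000)
  # mirror image of the first test's track around the TSS
  tr_p <- mk_track(chrom = "c1",
                   start = c(10000, 10032, 10033, 10300),
                   end = c(10032, 10033, 10100, 18000),
                   value = c(1, 9, 1, 0.1), strand = "+")
  tr_m <- mk_track(chrom = "c1",
                   start = c(100000 - 31, 100000 - 32, 100000 - 99, 100000 - 7999),
                   end = c(100000 + 1, 100000 - 31, 100000 - 32, 100000 - 299),
                   value = c(1, 9, 1, 0.1), strand = "-")
  pm_p <- pause_metrics(plus_gene, tr_p)
  pm_m <- pause_metrics(minus_gene, tr_m)
  expect_equal(pm_m$summit_p, pm_p$summit_p)
  expect_equal(pm_m$pause_index, pm_p$pause_index)
  expect_equal(pm_m$summit_pos, 100000 - 32)
})

test_that("zero signal in the search window flags the gene; short genes error", {
  tr <- mk_track(chrom = "c1", start = 50000, end = 50010, value = 1, strand = "+")
  pm <- pause_metrics(plus_gene, tr)
  expect_true(pm$flagged)
  expect_true(is.na(pm$pause_index))
  short_gene <- dplyr::mutate(plus_gene, end = start + 600)
  expect_error(pause_metrics(short_gene, tr), "too short")
})

test_that("differential transcription: null rate controlled, planted activation detected", {
  des <- tidyr::expand_grid(time = c(0, 20), replicate = 1:3) |>
    dplyr::mutate(sample = sprintf("t%d_r%d", time, replicate))
  withr::with_seed(77, {
    m <- matrix(rnbinom(6 * 2000, mu = 200, size = 20), ncol = 6,
                dimnames = list(sprintf("g%04d", 1:2000), des$sample))
    m[1, ] <- 0  # zero in both groups: excluded, not called
    res <- differential_transcription(m, des, 0, 20)
    expect_false("g0001" %in% res$feature)
    expect_lte(mean(res$call != "unchanged"), 0.05)
    # planted 2-fold activation at sequencing depth/dispersion where the
    # test is well powered, 200 seeded runs
    up <- 0
    for (i in 1:200) {
      mm <- matrix(rnbinom(6 * 20, mu = 500, size = 100), ncol = 6,
                   dimnames = list(sprintf("g%02d", 1:20), des$sample))
      mm[1, 4:6] <- rnbinom(3, mu = 1000, size = 100)
      r <- differential_transcription(mm, des, 0, 20)
      up <- up + (r$call[r$feature == "g01"] == "activated")
    }
    expect_gt(up / 200, 0.95)
  })
})

test_that("composite of a single anchor reproduces that window; zero signal stays zero", {
  tr <- mk_track(chrom = "c1", start = c(1000, 1100), end = c(1050, 1200),
                 value = c(2, 0.5), strand = "+")
  anchors <- tibble::tibble(chrom = "c1", pos = 1025, strand = "+")
  cp <- composite_profile(anchors, tr, half_window = 100)
  sense <- cp[cp$orientation == "sense", ]
  expect_equal(sense$mean_signal[sense$offset == 0], 2)
  expect_equal(sense$mean_signal[sense$offset == 20], 2)  # 1045 in [1000,1050)
  expect_equal(sense$mean_signal[sense$offset == 90], 0.5)
  expect_equal(sense$mean_signal[sense$offset == -50], 0)
  empty <- composite_profile(anchors, mk_track(chrom = character(), start = numeric(),
                                               end = numeric(), value = numeric(),
                                               strand = character()), 50)
  expect_true(all(empty$mean_signal == 0))
  expect_error(composite_profile(anchors[0, ], tr), "empty")
})

test_that("PI from a one-gene composite equals the direct computation", {
  tr <- mk_track(chrom = "c1",
                 start = c(10010, 10035, 10036, 10285),
                 end = c(10035, 10036, 10060, 18000),
                 value = c(2, 2.5, 2, 0.1), strand = "+")
  pm <- pause_metrics(plus_gene, tr)
  anchors <- tibble::tibble(chrom = "c1", pos = pm$summit_pos, strand = "+")
  cp <- composite_profile(anchors, tr, half_window = 2000)
  sense <- cp[cp$orientation == "sense", ]
  pause <- mean(sense$mean_signal[sense$offset >= -25 & sense$offset < 25])
  # the composite window covers part of the uniform body
  body <- mean(sense$mean_signal[sense$offset >= 250 & sense$offset <= 2000])
  expect_equal(pause / body, pm$pause_index, tolerance = 1e-9)
})

test_that("removing promoter anchors collapses the divergent composite", {
  # extra nondynamic motif instances provide the non-promoter anchor set
  st <- simulate_truth(small_config(19, nondynamic_motif_frac = 0.9))
  pro <- simulate_proseq(st$truth)
  tr0 <- dplyr::filter(pro$tracks, time == 0) |> dplyr::select(-time)
  hits <- scan_pwm_set(dplyr::select(st$peaks, peak, seq),
                       setNames(st$truth$config$tf_families$pwm,
                                st$truth$config$tf_families$name))
  sp <- dplyr::filter(hits, family == "SP") |>
    dplyr::inner_join(st$peaks, by = "peak") |>
    dplyr::mutate(pos = start + offset + 4, strand = "+") |>
    dplyr::select(chrom, pos, strand)
  # promoter anchors = within 500 bp of a TSS
  near_tss <- vapply(sp$pos, function(p)
    any(abs(st$genes$tss - p) <= 500), NA)
  expect_gt(sum(near_tss), 2)
  expect_gt(sum(!near_tss), 2)
  all_cp <- composite_profile(sp, tr0, half_window = 300)
  far_cp <- composite_profile(sp[!near_tss, ], tr0, half_window = 300)
  amp <- function(cp) max(cp$mean_signal)
  expect_gt(amp(all_cp) / max(amp(far_cp), 1e-12), 2)
})

test_that("median pause index of pause-release targets drops across the planted change", {
  st <- simulate_truth(small_config(29))
  pro <- simulate_proseq(st$truth)
  gr_genes <- st$genes$gene[which(st$genes$target_of == "GR")]
  pm <- pause_metrics_series(dplyr::select(st$genes, chrom, start, end, gene, strand, tss),
                             pro$tracks)
  pi0 <- pm$pause_index[pm$time == 0 & pm$gene %in% gr_genes]
  pi20 <- pm$pause_index[pm$time == 20 & pm$gene %in% gr_genes]
  expect_lt(median(pi20), median(pi0))
  # the planted fold is f_rel = 1.5 with k_pre << k_rel: PI ratio ~ 1/1.5
  expect_equal(median(pi20) / median(pi0), 1 / 1.5, tolerance = 0.05)
})

test_that("the divergent-peak caller pairs upstream minus with downstream plus signal", {
  tr <- mk_track(chrom = "c1",
                 start = c(980, 1100), end = c(1020, 1150),
                 value = c(3, 5), strand = c("-", "+"))
  dv <- call_divergent_peaks(tr, threshold = 1, max_gap = 300)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$minus_pos, 1000)
  expect_equal(dv$plus_pos, 1125)
  # plus upstream of minus is not a divergent pair
  tr2 <- mk_track(chrom = "c1", start = c(980, 1100), end = c(1020, 1150),
                  value = c(3, 5), strand = c("+", "-"))
  expect_equal(nrow(call_divergent_peaks(tr2, threshold = 1)), 0)
})
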
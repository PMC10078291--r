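fams <- family_rules()

expr_all <- tidyr::expand_grid(family = fams$name,
                               time = c(0, 20, 40, 60, 120, 180, 240)) |>
  dplyr::mutate(expressed = TRUE)

test_that("trans-edge rules: cocktail binding, SP dissociation, expression timing", {
  hits <- tibble::tibble(peak = c("re1", "re2", "re3"),
                         family = c("GR", "SP", "TWIST"))
  atac_calls <- dplyr::bind_rows(
    tibble::tibble(feature = "re1", time_a = 0, time_b = 20, direction = "up"),
    tibble::tibble(feature = "re2", time_a = 60, time_b = 120, direction = "down"),
    tibble::tibble(feature = "re3", time_a = 0, time_b = 20, direction = "down"))
  fam_calls <- tibble::tibble(family = "SP", time_a = 0, time_b = 40,
                              call = "repressed")
  te <- infer_trans_edges(atac_calls, hits, fam_calls, expr_all, fams)
  # GR motif + significant increase 0->20 + expressed: binding edge
  expect_true(any(te$family == "GR" & te$peak == "re1" &
                    te$attribute == "binding" & te$time_a == 0 & te$time_b == 20))
  # SP motif + decrease 60->120 + Sp repressed by 60: dissociation edge
  expect_true(any(te$family == "SP" & te$peak == "re2" &
                    te$attribute == "dissociation"))
  # TWIST decrease 0->20 while Twist2 not yet activated: no edge
  expect_false(any(te$peak == "re3"))
})

test_that("GR binding is confined to the first 40 min; later losses are dissociation", {
  hits <- tibble::tibble(peak = "re1", family = "GR")
  atac_calls <- dplyr::bind_rows(
    tibble::tibble(feature = "re1", time_a = 0, time_b = 20, direction = "up"),
    tibble::tibble(feature = "re1", time_a = 40, time_b = 60, direction = "up"),
    tibble::tibble(feature = "re1", time_a = 60, time_b = 240, direction = "down"))
  te <- infer_trans_edges(atac_calls, hits, family_calls = tibble::tibble(
    family = character(), time_a = numeric(), time_b = numeric(), call = character()),
    expr_all, fams)
  expect_true(any(te$attribute == "binding" & te$time_b == 20))
  expect_false(any(te$attribute == "binding" & te$time_a == 40))  # window + gate
  expect_true(any(te$attribute == "dissociation" & te$time_a == 60))
})

test_that("dissociation without a prior binding edge is suppressed", {
  hits <- tibble::tibble(peak = "re1", family = "GR")
  atac_calls <- tibble::tibble(feature = "re1", time_a = 60, time_b = 240,
                               direction = "down")
  te <- infer_trans_edges(atac_calls, hits, tibble::tibble(
    family = character(), time_a = numeric(), time_b = numeric(), call = character()),
    expr_all, fams)
  expect_equal(nrow(te), 0)
})

test_that("unexpressed families and unassigned roles contribute no edges", {
  hits <- tibble::tibble(peak = "re1", family = c("AP1", "XX"))
  atac_calls <- tibble::tibble(feature = "re1", time_a = 0, time_b = 20,
                               direction = "up")
  silent <- dplyr::mutate(expr_all, expressed = family != "AP1")
  te <- infer_trans_edges(atac_calls, hits, tibble::tibble(
    family = character(), time_a = numeric(), time_b = numeric(), call = character()),
    silent, dplyr::bind_rows(fams, tibble::tibble(name = "XX", role = "unassigned"))) |>
    suppressWarnings()
  expect_equal(nrow(te), 0)
})

test_that("cis-edge rules: proximity caps, covariation, and factor distance limits", {
  peaks <- tibble::tibble(peak = c("re1", "re2", "re3"), chrom = "c1",
                          start = c(1000, 30000, 300000), summit = 150) |>
    dplyr::mutate(end = start + 300)
  genes <- tibble::tibble(gene = c("gA", "gB"), chrom = "c1",
                          start = c(4000, 36000), end = c(9000, 41000),
                          tss = c(4000, 36000))
  trans <- tibble::tibble(
    family = c("GR", "SP", "AP1"), peak = c("re1", "re2", "re3"),
    time_a = c(0, 60, 0), time_b = c(20, 120, 20),
    attribute = c("binding", "dissociation", "binding"))
  gene_calls <- dplyr::bind_rows(
    tibble::tibble(feature = "gA", time_a = 0, time_b = 20, call = "activated"),
    tibble::tibble(feature = "gB", time_a = 60, time_b = 120, call = "repressed"))
  cons <- tibble::tibble(
    family = c("GR", "SP", "AP1"), time_a = c(0, 60, 0), time_b = c(20, 120, 20),
    distance_bp = c(100000, 2000, 100000), max_delta = 0.5, pvalue = 0.01)
  ci <- infer_cis_edges(trans, peaks, genes, gene_calls, cons, fams)
  # GR RE 3 kb from an early-activated gene: activation edge
  expect_true(any(ci$peak == "re1" & ci$gene == "gA" & ci$sign == "activation"))
  # SP RE ~5.7 kb from a repressed gene but SP's limit is 2 kb: no edge
  expect_false(any(ci$peak == "re2"))
  # an RE far from every gene body never links, whatever the covariation
  expect_false(any(ci$peak == "re3"))
})

test_that("rule engine matches the brute-force applicator on random instances", {
  for (seed in 1:50) {
    inst <- random_rule_instance(seed, n_peaks = 40, n_genes = 20)
    te_pkg <- infer_trans_edges(inst$atac_calls, inst$hits, inst$family_calls,
                                inst$expression, inst$families)
    te_bf <- brute_trans_edges(inst$atac_calls, inst$hits, inst$family_calls,
                               inst$expression, inst$families)
    expect_identical(as.data.frame(te_pkg), as.data.frame(te_bf))
    ci_pkg <- infer_cis_edges(te_pkg, inst$peaks, inst$genes, inst$gene_calls,
                              inst$constraints, inst$families) |>
      dplyr::select(peak, gene, time_a, time_b, sign, families)
    ci_bf <- brute_cis_edges(te_bf, inst$peaks, inst$genes, inst$gene_calls,
                             inst$constraints, inst$families)
    expect_identical(as.data.frame(ci_pkg), as.data.frame(ci_bf))
  }
})

test_that("attenuation flags later reversals of gene or RE state", {
  trans <- tibble::tibble(family = "GR", peak = "re1", time_a = 0, time_b = 20,
                          attribute = "binding")
  cis <- tibble::tibble(peak = "re1", gene = "gA", time_a = 0, time_b = 20,
                        sign = "activation", families = "GR",
                        re_direction = "up", distance_bp = 500, gap_bp = 0)
  net <- build_network(trans, cis)
  atac_none <- tibble::tibble(feature = character(), time_a = numeric(),
                              time_b = numeric(), direction = character())
  # gene activated 0->20 then repressed 60->240: attenuated
  gc1 <- tibble::tibble(feature = "gA", time_a = c(0, 60), time_b = c(20, 240),
                        call = c("activated", "repressed"))
  n1 <- annotate_attenuation(net, atac_none, gc1)
  expect_true(n1$cis$attenuated)
  # sustained activation: not attenuated
  gc2 <- tibble::tibble(feature = "gA", time_a = 0, time_b = 20, call = "activated")
  n2 <- annotate_attenuation(net, atac_none, gc2)
  expect_false(n2$cis$attenuated)
  # RE reversal alone also attenuates the cis-edge and the trans-edge
  atac_rev <- tibble::tibble(feature = "re1", time_a = 60, time_b = 240,
                             direction = "down")
  n3 <- annotate_attenuation(net, atac_rev, gc2)
  expect_true(n3$cis$attenuated)
  expect_true(n3$trans$attenuated)
})

test_that("a planted attenuation fraction of 0.6 is recovered within 0.05", {
  # five families, three with transient regulatory elements: 3/5 of the
  # planted cis-edges attenuate
  fam5 <- default_tf_families() |>
    dplyr::filter(name != "KLF")
  fam5$class[fam5$name == "CEBP"] <- "transient_increase"
  cfg <- sim_config(n_res = 120, n_genes = 80, n_dynamic_per_family = 10,
                    tf_families = fam5, seed = 101)
  ds <- simulate_dataset(cfg)
  res <- run_pipeline(ds, seed = 101)
  # judge attenuation per RE-gene link (a link's earliest interval decides;
  # rows for the same link over later calls would dilute the fraction)
  links <- res$network$cis |>
    dplyr::group_by(peak, gene, sign) |>
    dplyr::summarise(att = any(attenuated), .groups = "drop")
  expect_equal(mean(links$att), 0.6, tolerance = 0.084)
})

test_that("subnetwork statistics match hand counts and brute-force recomputation", {
  trans <- tibble::tibble(
    family = c("AP1", "AP1", "GR"), peak = c("re1", "re2", "re2"),
    time_a = 0, time_b = 20, attribute = "binding")
  cis <- tibble::tibble(
    peak = c("re1", "re2", "re2"), gene = c("g1", "g2", "g2"),
    time_a = 0, time_b = 20, sign = "activation",
    families = c("AP1", "AP1,GR", "AP1,GR"),
    re_direction = "up", distance_bp = 500, gap_bp = 0) |> dplyr::distinct()
  st <- subnetwork_stats(build_network(trans, cis), c("AP1", "GR"))
  expect_equal(st$gene_counts$solely[st$gene_counts$factor == "AP1"], 1)  # g1
  expect_equal(st$gene_counts$combinatorial[st$gene_counts$factor == "AP1"], 1)  # g2
  expect_equal(st$re_classes$n[st$re_classes$class == "AP1"], 1)
  expect_equal(st$re_classes$n[st$re_classes$class == "AP1+GR"], 1)
  # four activator families allow exactly 15 combination classes
  expect_equal(subnetwork_stats(build_network(trans, cis),
                                c("AP1", "CEBP", "GR", "KLF"))$n_possible_classes, 15)
  # brute-force recomputation on random toy networks
  withr::with_seed(71, {
    for (i in 1:50) {
      n_re <- 12; n_g <- 8
      tr <- tibble::tibble(
        family = sample(c("A", "B", "C"), 25, TRUE),
        peak = sample(sprintf("re%02d", 1:n_re), 25, TRUE),
        time_a = 0, time_b = 20, attribute = "binding") |> dplyr::distinct()
      linked <- tr[sample.int(nrow(tr), 10, TRUE), ]
      ci <- tibble::tibble(
        peak = linked$peak, gene = sample(sprintf("g%02d", 1:n_g), 10, TRUE),
        time_a = 0, time_b = 20, sign = "activation", families = linked$family,
        re_direction = "up", distance_bp = 1, gap_bp = 0) |>
        dplyr::group_by(peak, gene, time_a, time_b, sign, re_direction,
                        distance_bp, gap_bp) |>
        dplyr::summarise(families = paste(sort(unique(families)), collapse = ","),
                         .groups = "drop")
      st_i <- subnetwork_stats(build_network(tr, ci), c("A", "B", "C"))
      # brute force: per-gene upstream family sets from the raw edge list
      up <- list()
      for (r in seq_len(nrow(ci)))
        for (f in strsplit(ci$families[r], ",")[[1]])
          up[[ci$gene[r]]] <- union(up[[ci$gene[r]]], f)
      for (f in c("A", "B", "C")) {
        solely <- sum(vapply(up, function(s) identical(sort(s), f), NA))
        combo <- sum(vapply(up, function(s) f %in% s && length(s) > 1, NA))
        expect_equal(st_i$gene_counts$solely[st_i$gene_counts$factor == f], solely)
        expect_equal(st_i$gene_counts$combinatorial[st_i$gene_counts$factor == f], combo)
      }
    }
  })
})

test_that("downstream reach respects the flow of time", {
  trans <- tibble::tibble(family = "TW", peak = c("re1", "re2"),
                          time_a = c(20, 40), time_b = c(40, 60),
                          attribute = "binding")
  cis <- tibble::tibble(peak = c("re1", "re2"), gene = c("g2", "g3"),
                        time_a = c(40, 0), time_b = c(60, 20),
                        sign = "repression", families = "TW",
                        re_direction = "down", distance_bp = 1, gap_bp = 0)
  net <- build_network(trans, cis, family_genes = tibble::tibble(family = "TW",
                                                                 gene = "g1"))
  r <- downstream_reach(net, "g1", source_start = 0)
  # the (20,40) trans-edge and its (40,60) cis-edge are both admitted
  expect_true("re1" %in% r$res && "g2" %in% r$genes)
  # re2 is reached at 40, but its cis-edge starts at 0 < 40: not traversed
  expect_true("re2" %in% r$res)
  expect_false("g3" %in% r$genes)
  expect_equal(r$n_res, 2)
  expect_equal(r$n_genes, 1)
})

test_that("the validator passes on a well-formed network and reports structure", {
  trans <- tibble::tibble(family = "AP1", peak = "re1", time_a = 0, time_b = 20,
                          attribute = "binding")
  cis <- tibble::tibble(peak = "re1", gene = "g1", time_a = 0, time_b = 20,
                        sign = "activation", families = "AP1",
                        re_direction = "up", distance_bp = 100, gap_bp = 0)
  cons <- tibble::tibble(family = "AP1", time_a = 0, time_b = 20,
                         distance_bp = 1000, max_delta = 1, pvalue = 0.001)
  v <- validate_network(build_network(trans, cis), NULL, NULL, cons)
  expect_true(attr(v, "valid"))
  # a cis-edge whose RE has no overlapping trans-edge fails the cover check
  bad_cis <- dplyr::mutate(cis, time_a = 120, time_b = 240)
  v2 <- validate_network(build_network(trans, bad_cis), NULL, NULL, cons)
  expect_false(attr(v2, "valid"))
})
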
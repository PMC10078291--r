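#' Read accessibility peaks from a BED file
#'
#' Accepts BED6+1 (seventh column = summit offset from `start`) or plain
#' BED6, in which case the summit defaults to the interval midpoint
#' (`start + (end - start) %/% 2`, stored as an offset). Intervals are
#' 0-based half-open and returned sorted by (chrom, start).
#'
#' @param path BED6 or BED6+1 file (tab-separated, no header).
#' @return tibble with columns `chrom, start, end, peak, score, strand,
#'   summit` (summit is the offset from `start`).
#' @export
read_peaks <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && !all(nf %in% c(6L, 7L)))
    stop_kn("malformed BED line %d: expected 6 or 7 fields, got %d",
            which(!nf %in% c(6L, 7L))[1], nf[!nf %in% c(6L, 7L)][1])
  parse_num <- function(i, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
    if (anyNA(v)) stop_kn("malformed BED line %d: non-numeric %s", which(is.na(v))[1], what)
    v
  }
  if (length(lines) == 0L)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  peak = character(), score = numeric(), strand = character(),
                  summit = numeric()))
  pk <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = parse_num(2, "start"), end = parse_num(3, "end"),
    peak = vapply(fields, `[`, "", 4), score = parse_num(5, "score"),
    strand = vapply(fields, `[`, "", 6),
    summit = ifelse(nf == 7L,
                    suppressWarnings(as.numeric(vapply(fields, function(f) f[7] %||% NA_character_, ""))),
                    NA_real_)
  )
  pk$summit[is.na(pk$summit)] <- (pk$end - pk$start)[is.na(pk$summit)] %/% 2
  bad <- which(pk$start < 0 | pk$end <= pk$start)
  if (length(bad)) stop_kn("invalid interval at BED line %d: start=%g end=%g",
                           bad[1], pk$start[bad[1]], pk$end[bad[1]])
  bad <- which(pk$summit < 0 | pk$summit >= pk$end - pk$start)
  if (length(bad)) stop_kn("summit outside interval at BED line %d", bad[1])
  dplyr::arrange(pk, .data$chrom, .data$start, .data$end)
}

#' Write peaks as BED6+1
#' @param peaks tibble as returned by [read_peaks()].
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  out <- dplyr::arrange(peaks, .data$chrom, .data$start, .data$end) |>
    dplyr::select("chrom", "start", "end", "peak", "score", "strand", "summit")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Six tab-separated columns without header: chrom, start, end, name,
#' strand, TSS. Coordinates 0-based half-open; the TSS is a 0-based
#' position (equal to `start` for + genes and `end - 1` for - genes in
#' conventional annotations, but stored explicitly).
#' @param path TSV file.
#' @export
read_genes <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene", "strand", "tss"),
                       col_types = "cnncci", progress = FALSE)
  assert_that(all(g$end > g$start), "gene intervals must satisfy end > start")
  assert_that(all(g$strand %in% c("+", "-")), "gene strand must be + or -")
  dplyr::arrange(g, .data$chrom, .data$start)
}

#' @rdname read_genes
#' @param genes tibble with columns `chrom, start, end, gene, strand, tss`.
#' @export
write_genes <- function(genes, path) {
  readr::write_tsv(dplyr::select(genes, "chrom", "start", "end", "gene", "strand", "tss"),
                   path, col_names = FALSE)
  invisible(path)
}

validate_track_half <- function(tr, label) {
  assert_that(all(tr$end > tr$start), "bedGraph %s: end must exceed start", label)
  tr <- dplyr::arrange(tr, .data$chrom, .data$start)
  ovl <- tr |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 & .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  assert_that(nrow(ovl) == 0, "bedGraph %s: overlapping intervals (first at %s:%g)",
              label, ovl$chrom[1] %||% "", ovl$start[1] %||% 0)
  tr
}

#' Read a strand-specific signal track from a bedGraph pair
#'
#' Minus-strand values are stored as magnitudes with the strand carried
#' in a `strand` column (PRO-seq minus tracks conventionally carry
#' negative values; the sign is stripped). Point queries return 0
#' outside covered intervals.
#'
#' @param plus_path,minus_path 4-column bedGraph files.
#' @return tibble with `chrom, start, end, value, strand`
#'   (class `signal_track`).
#' @export
read_signal_pair <- function(plus_path, minus_path) {
  rd <- function(p) {
    if (length(readr::read_lines(p, n_max = 1)) == 0)
      return(tibble(chrom = character(), start = numeric(), end = numeric(),
                    value = numeric()))
    readr::read_tsv(p, col_names = c("chrom", "start", "end", "value"),
                    col_types = "cnnd", progress = FALSE)
  }
  plus <- validate_track_half(rd(plus_path), "plus")
  minus <- validate_track_half(rd(minus_path), "minus")
  minus$value <- abs(minus$value)
  tr <- dplyr::bind_rows(
    dplyr::mutate(plus, strand = "+"),
    dplyr::mutate(minus, strand = "-")
  )
  assert_that(all(is.finite(tr$value)), "signal values must be finite")
  structure(dplyr::arrange(tr, .data$strand, .data$chrom, .data$start),
            class = c("signal_track", class(tibble())))
}

#' Write a signal track as a bedGraph pair
#'
#' Minus-strand values are written with negative sign (the conventional
#' PRO-seq dialect), so a write/read round trip is the identity.
#' @param track `signal_track` tibble.
#' @param plus_path,minus_path output files.
#' @export
write_signal_pair <- function(track, plus_path, minus_path) {
  wr <- function(x, p, sgn) {
    x <- dplyr::arrange(x, .data$chrom, .data$start)
    readr::write_tsv(tibble(chrom = x$chrom, start = x$start, end = x$end,
                            value = sgn * x$value), p, col_names = FALSE)
  }
  wr(dplyr::filter(track, .data$strand == "+"), plus_path, 1)
  wr(dplyr::filter(track, .data$strand == "-"), minus_path, -1)
  invisible(c(plus_path, minus_path))
}

#' Query a signal track at single positions
#'
#' @param track `signal_track` tibble.
#' @param chrom,pos,strand vectors (recycled) of query positions
#'   (0-based).
#' @return numeric vector of signal values (0 where uncovered).
#' @export
signal_query <- function(track, chrom, pos, strand = "+") {
  n <- max(length(chrom), length(pos), length(strand))
  q <- tibble(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
              strand = rep_len(strand, n))
  out <- numeric(n)
  for (key in unique(paste(q$chrom, q$strand))) {
    sel <- paste(q$chrom, q$strand) == key
    sub <- track[track$chrom == q$chrom[sel][1] & track$strand == q$strand[sel][1], ]
    if (nrow(sub) == 0) next
    sub <- dplyr::arrange(sub, .data$start)
    idx <- findInterval(q$pos[sel], sub$start)
    hit <- idx >= 1 & q$pos[sel] < sub$end[pmax(idx, 1)]
    v <- numeric(sum(sel))
    v[hit] <- sub$value[idx[hit]]
    out[sel] <- v
  }
  out
}

# per-bp signal over [start, end) on one strand, as a numeric vector
signal_window <- function(track, chrom, start, end, strand = "+") {
  sub <- track[track$chrom == chrom & track$strand == strand, ]
  v <- numeric(end - start)
  if (nrow(sub) == 0) return(v)
  sub <- sub[sub$end > start & sub$start < end, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    a <- max(sub$start[i], start); b <- min(sub$end[i], end)
    v[(a - start + 1):(b - start)] <- sub$value[i]
  }
  v
}

#' Read position weight matrices in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections.
#' Rows whose probabilities deviate from sum 1 by more than 1e-3 raise
#' an error; smaller deviations are renormalized.
#'
#' @param path MEME minimal file.
#' @return named list of `pwm_model` objects (fields `name`, `mat`
#'   (positions x ACGT probability matrix), `background`).
#' @export
read_meme_pwm <- function(path) {
  lines <- readr::read_lines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  assert_that(length(motif_at) > 0, "no MOTIF blocks in %s", path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  out <- lapply(motif_at, function(i) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- i + grep("letter-probability matrix", lines[(i + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    assert_that(ncol(mat) == 4, "PWM %s: expected 4 columns per row", name)
    sums <- rowSums(mat)
    bad <- which(abs(sums - 1) > 1e-3)
    assert_that(length(bad) == 0, "PWM %s row %d sums to %.5f (tolerance 1e-3)",
                name, bad[1] %||% 0L, sums[bad[1]])
    mat <- mat / sums
    colnames(mat) <- c("A", "C", "G", "T")
    pwm_model(name, mat, background = bg)
  })
  names(out) <- vapply(out, function(m) m$name, "")
  out
}

#' Construct a PWM model
#' @param name motif/TF family name.
#' @param mat positions x 4 probability matrix (columns A,C,G,T).
#' @param background length-4 background distribution.
#' @export
pwm_model <- function(name, mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  assert_that(all(abs(rowSums(mat) - 1) < 1e-6), "PWM rows must sum to 1")
  structure(list(name = name, mat = mat, background = background),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s, %d positions, consensus %s\n",
              x$name, nrow(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param pwm a `pwm_model`.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$mat)[max.col(pwm$mat, ties.method = "first")], collapse = "")
}

#' Write PWMs in MEME minimal format
#' @param pwms list of `pwm_model` objects.
#' @param path output file.
#' @export
write_meme_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  con <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", c("A", "C", "G", "T"), pwms[[1]]$background), collapse = " "),
           "")
  for (m in pwms) {
    con <- c(con, sprintf("MOTIF %s", m$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", nrow(m$mat)),
             apply(m$mat, 1, function(r) paste(sprintf("%.9f", r), collapse = "  ")),
             "")
  }
  readr::write_lines(con, path)
  invisible(path)
}

#' Export a network as edge-list TSV (and optionally GraphML)
#'
#' The TSV has one row per edge with columns
#' `src, dst, edge_kind, interval_start_min, interval_end_min, attribute`.
#' Trans-edges run family -> RE (attribute binding/dissociation);
#' cis-edges run RE -> gene (attribute activation/repression, with
#' `:attenuated` appended when flagged).
#'
#' @param net a `kinetic_network` from [build_network()].
#' @param path TSV output path.
#' @param graphml optional GraphML output path (written via igraph).
#' @export
write_network <- function(net, path, graphml = NULL) {
  edges <- network_edge_table(net)
  readr::write_tsv(edges, path)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, col_types = "cccnnc", progress = FALSE)
}

network_edge_table <- function(net) {
  tr <- net$trans
  ci <- net$cis
  tr_tab <- tibble(src = tr$family, dst = tr$peak, edge_kind = "trans",
                   interval_start_min = tr$time_a, interval_end_min = tr$time_b,
                   attribute = tr$attribute)
  att <- if ("attenuated" %in% names(ci)) {
    ifelse(ci$attenuated, paste0(ci$sign, ":attenuated"), ci$sign)
  } else ci$sign
  ci_tab <- tibble(src = ci$peak, dst = ci$gene, edge_kind = "cis",
                   interval_start_min = ci$time_a, interval_end_min = ci$time_b,
                   attribute = att)
  dplyr::bind_rows(tr_tab, ci_tab) |>
    dplyr::arrange(.data$edge_kind, .data$src, .data$dst,
                   .data$interval_start_min, .data$interval_end_min, .data$attribute)
}
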
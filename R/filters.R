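# Post-processing filters for initial frameshift predictions. Filter I
# removes predictions whose downstream ORF carries a functional ribosome
# binding site (a real gene start argues against a frameshift reading).
# Filter II (high-GC fragments only, GC > 50%) removes predictions too close
# to the stop codon terminating the upstream ORF. Filter III (low-GC
# fragments only) removes predictions too close to a gene or fragment border.

#' Filter configuration
#'
#' @param rbs_threshold Filter I fires when the downstream-ORF RBS score is
#'   strictly greater than this (default 2.0).
#' @param border_dist Filter III minimum distance in nt to gene/fragment
#'   borders (default 50).
#' @param tp_window True-positive window in nt used by the benchmark
#'   (default 20).
#' @param gc_split GC% split between Filter II (above) and Filter III (at or
#'   below); default 50.
#' @param stop_dist_a,stop_dist_b Filter II minimum stop-codon distance
#'   `d_min(theta) = max(0, a * theta + b)` in nt; the linear form is a
#'   documented stand-in with defaults a = 2 nt/%, b = -60 nt (40 nt at
#'   GC 50%, 90 nt at GC 75%).
#' @return A `filter_config` list.
#' @export
filter_config <- function(rbs_threshold = 2.0, border_dist = 50L,
                          tp_window = 20L, gc_split = 50,
                          stop_dist_a = 2.0, stop_dist_b = -60) {
  stopifnot(border_dist >= 0, tp_window >= 0, gc_split > 0, gc_split < 100)
  structure(list(rbs_threshold = rbs_threshold, border_dist = border_dist,
                 tp_window = tp_window, gc_split = gc_split,
                 stop_dist_a = stop_dist_a, stop_dist_b = stop_dist_b),
            class = "filter_config")
}

#' Filter II distance threshold
#' @param theta GC content in percent.
#' @param cfg A `filter_config`.
#' @return Minimum required distance to the upstream-ORF stop codon, nt.
#' @export
stop_dist_min <- function(theta, cfg = filter_config()) {
  max(0, cfg$stop_dist_a * theta + cfg$stop_dist_b)
}

#' Ribosome-binding-site position weight matrix
#'
#' Default model: the Shine-Dalgarno consensus `AGGAGG` with the consensus
#' base at probability `match_prob` per column and the rest uniform, scored
#' as natural-log odds against a uniform background. The paper-scale
#' threshold (2.0) is interpreted on this scale; both the PWM and the
#' threshold are replaceable via configuration.
#'
#' @param consensus 6-letter consensus string.
#' @param match_prob Probability of the consensus base in each column.
#' @param spacer_range Allowed spacer (gap between the motif's 3' end and the
#'   start codon) in nt, `c(min, max)` with min >= 3, max <= 15.
#' @return An `rbs_model` with the probability `pwm` (4 x 6, rows A,C,G,T)
#'   and `spacer_range`.
#' @export
rbs_model <- function(consensus = "AGGAGG", match_prob = 0.85,
                      spacer_range = c(4L, 12L)) {
  stopifnot(nchar(consensus) == 6L, match_prob > 0.25, match_prob < 1,
            spacer_range[1] >= 3L, spacer_range[2] <= 15L,
            spacer_range[1] <= spacer_range[2])
  cons <- encode_seq(consensus)
  stopifnot(!anyNA(cons))
  pwm <- matrix((1 - match_prob) / 3, 4L, 6L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(cons + 1L, 1:6)] <- match_prob
  stopifnot(all(abs(colSums(pwm) - 1) < 1e-12))
  structure(list(pwm = pwm, spacer_range = as.integer(spacer_range)),
            class = "rbs_model")
}

#' Score the best ribosome binding site upstream of a candidate gene start
#'
#' Maximizes the PWM log-odds (vs uniform background) of the 6-mer placed at
#' each allowed spacer upstream of the start codon, strand-aware. Returns
#' `-Inf` when no spacer placement has full sequence context (so Filter I
#' fails open on truncated context).
#'
#' @param seq Fragment DNA string.
#' @param start_pos 1-based position of the first base of the start codon in
#'   reading direction (for `-` strand genes, the rightmost base in source
#'   coordinates).
#' @param strand `"+"` or `"-"`.
#' @param rbs An `rbs_model`.
#' @return Maximum log-odds score in nats, or `-Inf`.
#' @export
score_rbs <- function(seq, start_pos, strand = "+", rbs = rbs_model()) {
  L <- nchar(seq)
  stopifnot(start_pos >= 1L, start_pos <= L)
  if (strand == "-") {
    seq <- revcomp(seq)
    start_pos <- L - start_pos + 1L
  }
  codes <- encode_seq(seq)
  lo <- log(rbs$pwm / 0.25)
  best <- -Inf
  for (sp in rbs$spacer_range[1]:rbs$spacer_range[2]) {
    w <- start_pos - sp - 6L
    if (w < 1L) next
    win <- codes[w:(w + 5L)]
    if (anyNA(win)) next
    best <- max(best, sum(lo[cbind(win + 1L, 1:6)]))
  }
  best
}

# Reflect an FS/gene pair into forward-strand ("plus view") coordinates.
# Frames are preserved (a position decoded in frame f on the minus strand
# corresponds to frame f on the reverse complement); the boundary position
# reflects to L - pos because the convention names the left edge of a
# between-nucleotide boundary.
#' @noRd
plus_view <- function(fs, gene, seq) {
  L <- nchar(seq)
  if (fs$strand == "+") {
    list(seq = seq, pos = fs$pos, gene_start = gene$start,
         gene_end = gene$end, f_up = fs$upstream_frame,
         f_down = fs$downstream_frame, L = L)
  } else {
    list(seq = revcomp(seq), pos = L - fs$pos,
         gene_start = L - gene$end + 1L, gene_end = L - gene$start + 1L,
         f_up = fs$upstream_frame, f_down = fs$downstream_frame, L = L)
  }
}

# First in-frame stop codon (start position of the triplet) at or after
# `from`, in frame f (codon starts at positions q with (q-1-f) %% 3 == 0).
#' @noRd
next_inframe_stop <- function(codes, f, from) {
  L <- length(codes)
  # codon starts satisfy (q - 1 - f) %% 3 == 0, i.e. q = f+1 (mod 3)
  q0 <- from + ((f + 1L - from) %% 3L)
  qs <- seq.int(q0, L - 2L, by = 3L)
  if (q0 > L - 2L) return(NA_integer_)
  st <- stop_ends(codes)
  hit <- qs[st[qs + 2L]]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# Start-codon test: ATG, GTG, TTG at position q.
#' @noRd
is_start_codon <- function(codes, q) {
  c1 <- codes[q]; c2 <- codes[q + 1L]; c3 <- codes[q + 2L]
  !is.na(c1) && !is.na(c2) && !is.na(c3) &&
    c2 == 3L && c3 == 2L && c1 %in% c(0L, 2L, 3L)
}

#' Filter I: RBS of the downstream ORF
#'
#' Resolves the most 5' in-frame start codon (ATG/GTG/TTG) of the
#' downstream-frame ORF lying at or upstream of the frameshift, scores its
#' RBS, and removes the prediction iff the score is strictly greater than the
#' threshold. Fails open (keeps the prediction) when no start resolves or the
#' upstream context is truncated.
#'
#' @param fs One row of a frameshift data.frame (needs `pos`, `strand`,
#'   `upstream_frame`, `downstream_frame`).
#' @param gene The containing gene row (needs `start`, `end`).
#' @param seq Fragment DNA string.
#' @param rbs An `rbs_model`.
#' @param cfg A `filter_config`.
#' @return `TRUE` if the prediction should be removed.
#' @export
filter_I <- function(fs, gene, seq, rbs = rbs_model(), cfg = filter_config()) {
  v <- plus_view(fs, gene, seq)
  codes <- encode_seq(v$seq)
  if (v$pos < 1L || v$pos > v$L) return(FALSE)
  f <- v$f_down
  # ORF bounds in the downstream frame: positions after the last in-frame
  # stop that ends strictly before the frameshift.
  q0 <- 1L + ((f + 1L - 1L) %% 3L) # first codon start of frame f
  qs <- seq.int(q0, max(q0, v$pos), by = 3L)
  qs <- qs[qs + 2L <= length(codes)]
  if (length(qs) == 0L) return(FALSE)
  st <- stop_ends(codes)
  stops_before <- qs[st[qs + 2L] & (qs + 2L) < v$pos]
  orf_lo <- if (length(stops_before)) stops_before[length(stops_before)] + 3L else q0
  cand <- qs[qs >= orf_lo & qs <= v$pos]
  starts <- cand[vapply(cand, function(q) is_start_codon(codes, q), TRUE)]
  if (length(starts) == 0L) return(FALSE) # unresolvable: fail open
  score <- score_rbs(v$seq, starts[1L], "+", rbs)
  is.finite(score) && score > cfg$rbs_threshold
}

#' Filter II: distance to the upstream ORF's stop codon (high-GC fragments)
#'
#' Applies only when the fragment GC content exceeds `gc_split` (50% by
#' default). Removes the prediction iff the distance from the frameshift to
#' the first in-frame stop of the upstream frame, downstream of the
#' frameshift, is below `stop_dist_min(theta)`. Keeps the prediction when no
#' such stop exists before the fragment end.
#'
#' @inheritParams filter_I
#' @param theta Fragment GC content in percent.
#' @return `TRUE` if the prediction should be removed.
#' @export
filter_II <- function(fs, gene, seq, theta, cfg = filter_config()) {
  if (theta <= cfg$gc_split) return(FALSE)
  v <- plus_view(fs, gene, seq)
  codes <- encode_seq(v$seq)
  q <- next_inframe_stop(codes, v$f_up, v$pos + 1L)
  if (is.na(q)) return(FALSE) # no stop before fragment end: keep
  d <- q - v$pos
  d < stop_dist_min(theta, cfg)
}

#' Filter III: proximity to gene or fragment borders (low-GC fragments)
#'
#' Applies only when the fragment GC content is at or below `gc_split`.
#' Removes the prediction iff its distance to the gene start, gene end,
#' fragment start or fragment end is below `border_dist` (50 nt by default).
#'
#' @inheritParams filter_I
#' @param fragment_len Fragment length in nt.
#' @param theta Fragment GC content in percent.
#' @return `TRUE` if the prediction should be removed.
#' @export
filter_III <- function(fs, gene, fragment_len, theta, cfg = filter_config()) {
  if (theta > cfg$gc_split) return(FALSE)
  d <- min(fs$pos - gene$start, gene$end - fs$pos,
           fs$pos - 1L, fragment_len - fs$pos)
  d < cfg$border_dist
}

#' Apply the false-positive filters to a set of frameshift predictions
#'
#' Every filter is evaluated on every prediction (so filter-combination
#' studies can read `filters_failed` regardless of what was enabled); a
#' prediction is removed iff it fails at least one *enabled* filter. Filters
#' only ever remove predictions; positions are never changed.
#'
#' @param calls List with data.frames `genes` and `frameshifts` as returned
#'   by [detect_frameshifts()].
#' @param seq Fragment DNA string the calls refer to.
#' @param theta GC content (percent) governing the Filter II/III split.
#' @param rbs An `rbs_model`.
#' @param cfg A `filter_config`.
#' @param enabled Character subset of `c("I", "II", "III")`.
#' @return The frameshift data.frame with added columns `filters_failed`
#'   (comma-separated) and `kept`.
#' @export
apply_filters <- function(calls, seq, theta, rbs = rbs_model(),
                          cfg = filter_config(),
                          enabled = c("I", "II", "III")) {
  stopifnot(all(enabled %in% c("I", "II", "III")))
  fs <- calls$frameshifts
  if (is.null(fs) || nrow(fs) == 0L) {
    fs$filters_failed <- character(0)
    fs$kept <- logical(0)
    return(fs)
  }
  L <- nchar(seq)
  failed <- character(nrow(fs))
  kept <- logical(nrow(fs))
  for (i in seq_len(nrow(fs))) {
    f <- fs[i, ]
    g <- calls$genes[f$gene, ]
    fails <- c(
      if (filter_I(f, g, seq, rbs, cfg)) "I",
      if (filter_II(f, g, seq, theta, cfg)) "II",
      if (filter_III(f, g, L, theta, cfg)) "III"
    )
    failed[i] <- paste(fails, collapse = ",")
    kept[i] <- length(intersect(fails, enabled)) == 0L
  }
  fs$filters_failed <- failed
  fs$kept <- kept
  fs
}
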
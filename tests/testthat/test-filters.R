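# Hand-built Filter I scenario (plus strand, downstream frame 0):
# stop TAA at 10-12 bounds the downstream ORF; AGGAGG at 18-23 sits at
# spacer 7 upstream of the only in-frame start codon ATG at 31-33.
rbs_scenario <- function(total_len = 200L) {
  seq <- paste0(strrep("C", 9), "TAA", strrep("C", 5), "AGGAGG",
                strrep("C", 7), "ATG", strrep("C", total_len - 33L))
  fs <- data.frame(pos = 60L, fs_shift = -1L, strand = "+", gene = 1L,
                   upstream_frame = 1L, downstream_frame = 0L,
                   score = 5, stringsAsFactors = FALSE)
  gene <- data.frame(start = 31L, end = 150L, strand = "+")
  list(seq = seq, fs = fs, gene = gene)
}

test_that("score_rbs finds the consensus motif at its maximal PWM score", {
  sc <- rbs_scenario()
  rbs <- rbs_model()
  max_attainable <- 6 * log(0.85 / 0.25)
  expect_equal(score_rbs(sc$seq, 31L, "+", rbs), max_attainable)
  # strand-aware: same motif seen from the reverse complement
  expect_equal(score_rbs(revcomp(sc$seq), nchar(sc$seq) - 31L + 1L, "-", rbs),
               max_attainable)
})

test_that("a uniform PWM scores zero and truncated context returns -Inf", {
  unif <- structure(list(
    pwm = matrix(0.25, 4L, 6L, dimnames = list(c("A", "C", "G", "T"), NULL)),
    spacer_range = c(4L, 12L)), class = "rbs_model")
  expect_equal(score_rbs("ACGTACGTACGTACGTACGTACGTACGT", 25L, "+", unif), 0)
  expect_identical(score_rbs("ACGTACGT", 3L, "+", rbs_model()), -Inf)
})

test_that("filter I removes on RBS score strictly above the threshold", {
  sc <- rbs_scenario()
  consensus_score <- score_rbs(sc$seq, 31L, "+", rbs_model())

  # PWM scaled so the consensus scores 5.1 > 2.0: removed
  m51 <- 0.25 * exp(5.1 / 6)
  rbs51 <- rbs_model(match_prob = m51)
  expect_equal(score_rbs(sc$seq, 31L, "+", rbs51), 5.1)
  expect_true(filter_I(sc$fs, sc$gene, sc$seq, rbs51, filter_config()))

  # score exactly equal to the threshold: kept (strict inequality)
  cfg_eq <- filter_config(rbs_threshold = consensus_score)
  expect_false(filter_I(sc$fs, sc$gene, sc$seq, rbs_model(), cfg_eq))
  cfg_below <- filter_config(rbs_threshold = consensus_score - 1e-9)
  expect_true(filter_I(sc$fs, sc$gene, sc$seq, rbs_model(), cfg_below))

  # no upstream context for any spacer: fail open
  sc2 <- sc
  sc2$seq <- paste0("ATG", strrep("C", 120)) # start at 3' ... start codon at 1
  fs2 <- sc$fs; fs2$pos <- 30L
  gene2 <- data.frame(start = 1L, end = 90L, strand = "+")
  expect_false(filter_I(fs2, gene2, sc2$seq, rbs_model(), filter_config()))
})

test_that("filter II applies only above the GC split and uses d_min(theta)", {
  # upstream frame 0; only stop codon TAA placed in frame at position q
  make_case <- function(q, len = 400L) {
    seq <- paste0(strrep("C", q - 1L), "TAA", strrep("C", len - q - 2L))
    fs <- data.frame(pos = 90L, fs_shift = 1L, strand = "+", gene = 1L,
                     upstream_frame = 0L, downstream_frame = 1L, score = 1)
    gene <- data.frame(start = 10L, end = 350L, strand = "+")
    list(seq = seq, fs = fs, gene = gene)
  }
  cfg <- filter_config() # a = 2, b = -60: d_min(60) = 60
  expect_equal(stop_dist_min(60, cfg), 60)
  expect_equal(stop_dist_min(75, cfg), 90)
  expect_equal(stop_dist_min(20, cfg), 0)

  near <- make_case(q = 121L) # d = 31 < 60, q = 121 is a frame-0 codon start
  far <- make_case(q = 292L)  # d = 202
  expect_false(filter_II(near$fs, near$gene, near$seq, theta = 40, cfg))
  expect_true(filter_II(near$fs, near$gene, near$seq, theta = 60, cfg))
  expect_false(filter_II(far$fs, far$gene, far$seq, theta = 60, cfg))

  # no in-frame stop before the fragment end: keep
  nostop <- make_case(q = 122L) # TAA out of frame 0
  expect_false(filter_II(nostop$fs, nostop$gene, nostop$seq, theta = 60, cfg))
})

test_that("filter III enforces the 50-nt border rule below the GC split", {
  cfg <- filter_config()
  gene <- data.frame(start = 60L, end = 500L, strand = "+")
  fs <- function(p) data.frame(pos = p, fs_shift = 1L, strand = "+", gene = 1L,
                               upstream_frame = 0L, downstream_frame = 1L,
                               score = 1)
  # 30 nt from gene start
  expect_true(filter_III(fs(90L), gene, fragment_len = 600L, theta = 45, cfg))
  # all four distances >= 50
  expect_false(filter_III(fs(150L), gene, fragment_len = 600L, theta = 45, cfg))
  # close to the fragment end
  expect_true(filter_III(fs(460L), gene,
                         fragment_len = 500L, theta = 45, cfg))
  # high-GC fragment: filter III never fires
  expect_false(filter_III(fs(90L), gene, fragment_len = 600L, theta = 55, cfg))
})

test_that("filters II and III are mutually exclusive across the GC split", {
  near <- local({
    # in-frame stop 21 nt after the FS and gene border 10 nt before it:
    # filter II would fire above the split, filter III below it
    seq <- paste0(strrep("C", 90), "TAA", strrep("C", 307))
    fs <- data.frame(pos = 70L, fs_shift = 1L, strand = "+", gene = 1L,
                     upstream_frame = 0L, downstream_frame = 1L, score = 1)
    gene <- data.frame(start = 60L, end = 350L, strand = "+")
    list(seq = seq, fs = fs, gene = gene)
  })
  cfg <- filter_config()
  for (theta in seq(5, 95, by = 5)) {
    ii <- filter_II(near$fs, near$gene, near$seq, theta, cfg)
    iii <- filter_III(near$fs, near$gene, nchar(near$seq), theta, cfg)
    expect_false(ii && iii)
    if (theta <= 50) expect_false(ii)
    if (theta > 50) expect_false(iii)
  }
})

test_that("apply_filters records all failures but removes only enabled ones", {
  sc <- rbs_scenario()
  # fs 29 nt from gene start so filter III also fails at low GC
  sc$fs$pos <- 59L
  calls <- list(genes = sc$gene, frameshifts = sc$fs)
  out <- apply_filters(calls, sc$seq, theta = 45, rbs = rbs_model(),
                       cfg = filter_config(), enabled = "I")
  expect_equal(nrow(out), 1L)
  expect_false(out$kept)
  expect_setequal(strsplit(out$filters_failed, ",")[[1]], c("I", "III"))
  expect_equal(out$pos, sc$fs$pos) # positions never move

  # nothing enabled: output equals input
  out0 <- apply_filters(calls, sc$seq, theta = 45, enabled = character(0))
  expect_true(all(out0$kept))

  # II never fails on a low-GC fragment
  expect_false("II" %in% strsplit(out$filters_failed, ",")[[1]])
})

test_that("raising the RBS threshold weakly increases survivors", {
  sc <- rbs_scenario()
  calls <- list(genes = sc$gene, frameshifts = sc$fs)
  survivors <- vapply(c(0, 2, 5, 7.5, 10), function(thr) {
    out <- apply_filters(calls, sc$seq, theta = 60, rbs = rbs_model(),
                         cfg = filter_config(rbs_threshold = thr),
                         enabled = "I")
    sum(out$kept)
  }, 0L)
  expect_true(all(diff(survivors) >= 0L))
})
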
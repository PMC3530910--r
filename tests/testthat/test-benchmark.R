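test_that("fixture genomes hit the GC target within 2 points and are stop-free", {
  for (th in c(30, 50, 70)) {
    g <- make_fixture_genome(th, n_genes = 20L, seed = 21L)
    expect_lt(abs(gc_percent(g$record$seq) - th), 2)
    for (i in seq_len(nrow(g$annotation))) {
      cds <- substr(g$record$seq, g$annotation$start[i], g$annotation$end[i])
      if (g$annotation$strand[i] == "-") cds <- revcomp(cds)
      n <- nchar(cds)
      expect_equal(n %% 3L, 0L)
      expect_equal(substr(cds, 1L, 3L), "ATG")
      codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
      expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
      expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    }
  }
  expect_error(make_fixture_genome(90), "parameter error")
  expect_identical(make_fixture_genome(50, seed = 3L),
                   make_fixture_genome(50, seed = 3L))
})

test_that("cut_fragments produces n fragments of exact length with legal maps", {
  g <- fixture_genome(50)
  fr <- cut_fragments(g, 400L, 200L, seed = 2L)
  expect_equal(nrow(fr), 200L)
  expect_true(all(nchar(fr$seq) == 400L))
  for (m in fr$coding_map) {
    if (nrow(m) == 0L) next
    expect_true(all(m[, "start"] >= 1L & m[, "end"] <= 400L))
    expect_true(all(m[, "start"] <= m[, "end"]))
  }
  expect_identical(fr, cut_fragments(g, 400L, 200L, seed = 2L))
})

test_that("fragment coding maps carry genuine coding sequence on both strands", {
  # a fragment's coding interval, read on the fragment, must re-occur in the
  # source genome's CDS (possibly reverse-complemented)
  g <- fixture_genome(50)
  fr <- cut_fragments(g, 400L, 30L, seed = 12L)
  for (i in seq_len(nrow(fr))) {
    m <- fr$coding_map[[i]]
    for (r in seq_len(nrow(m))) {
      sub <- substr(fr$seq[i], m[r, "start"], m[r, "end"])
      found <- grepl(sub, g$record$seq, fixed = TRUE) ||
        grepl(revcomp(sub), g$record$seq, fixed = TRUE)
      expect_true(found)
    }
  }
})

test_that("inject_indels modifies exactly round(fraction * n) fragments legally", {
  g <- fixture_genome(50)
  fr <- cut_fragments(g, 600L, 200L, seed = 4L)
  mod <- inject_indels(fr, 0.2, "both", seed = 5L)
  hit <- !is.na(mod$fs_pos)
  expect_equal(sum(hit), 40L)
  expect_true(all(mod$fs_pos[hit] >= 51L))
  expect_true(all(mod$fs_pos[hit] <= 600L - 50L))
  expect_true(all(nchar(mod$seq[hit & mod$fs_type == "insertion"]) == 601L))
  expect_true(all(nchar(mod$seq[hit & mod$fs_type == "deletion"]) == 599L))
  # every indel lies in a pre-indel coding stretch > 200 nt
  for (i in which(hit)) {
    m <- fr$coding_map[[i]]
    lens <- m[, "end"] - m[, "start"] + 1L
    inside <- m[, "start"] <= mod$fs_pos[i] & m[, "end"] >= mod$fs_pos[i] &
      lens > 200L
    expect_true(any(inside))
  }
  expect_identical(inject_indels(fr, 0, "both", seed = 5L), fr)
  # fragments with no coding stretch cannot take an indel
  bare <- fr[1:4, ]
  bare$coding_map <- rep(list(cbind(start = integer(0), end = integer(0))), 4L)
  expect_error(inject_indels(bare, 1.0, "both", seed = 5L), "deficit")
})

test_that("score_predictions implements the 20-nt window and 1-1 matching", {
  truth <- data.frame(id = paste0("f", 1:10),
                      fs_pos = c(rep(NA_integer_, 5), 100L, 200L, 300L,
                                 400L, 500L))
  # exact hits
  preds <- data.frame(fragment_id = paste0("f", 6:10),
                      pos = c(100L, 200L, 300L, 400L, 500L))
  r <- score_predictions(truth, preds)
  expect_equal(c(r$A, r$T, r$S), c(5L, 5L, 5L))
  expect_equal(c(r$Sn, r$Sp, r$avg), c(1, 1, 1))

  # one truth at 100; predictions at 85 (|15| <= 20, TP) and 130 (FP)
  truth1 <- data.frame(id = "f1", fs_pos = 100L)
  preds1 <- data.frame(fragment_id = c("f1", "f1"), pos = c(85L, 130L))
  r <- score_predictions(truth1, preds1)
  expect_equal(c(r$A, r$T, r$S), c(2L, 1L, 1L))
  expect_equal(r$Sp, 0.5)

  # no predictions: Sn = 0, Sp undefined
  r <- score_predictions(truth, preds[0, ])
  expect_equal(r$Sn, 0)
  expect_true(is.na(r$Sp))

  # boundary: exactly 20 nt away is a TP, 21 is not
  r20 <- score_predictions(truth1, data.frame(fragment_id = "f1", pos = 120L))
  r21 <- score_predictions(truth1, data.frame(fragment_id = "f1", pos = 121L))
  expect_equal(r20$T, 1L)
  expect_equal(r21$T, 0L)
})

oracle_caller <- function(fragments) {
  hit <- !is.na(fragments$fs_pos)
  data.frame(fragment_id = fragments$id[hit], pos = fragments$fs_pos[hit])
}

null_caller <- function(fragments) {
  data.frame(fragment_id = character(0), pos = integer(0))
}

test_that("benchmark closes the loop with oracle and null callers", {
  fam <- fixture_family()
  genomes <- list(a = fixture_genome(40, seed = 31L),
                  b = fixture_genome(60, seed = 32L))
  res <- run_benchmark(fam, genomes, lengths = 600L, fractions = 0.2,
                       n = 50L, seed = 3L, caller = oracle_caller)
  expect_true(all(res$cells$Sn == 1))
  expect_true(all(res$cells$Sp == 1))
  expect_true(all(res$cells$T <= res$cells$S & res$cells$T <= res$cells$A))

  res0 <- run_benchmark(fam, genomes, lengths = 600L, fractions = 0.2,
                        n = 50L, seed = 3L, caller = null_caller)
  expect_true(all(res0$cells$Sn == 0))
  expect_true(all(is.na(res0$cells$Sp)))
})

test_that("summary averages across genomes first, then across indel types", {
  fam <- fixture_family()
  genomes <- list(a = fixture_genome(40, seed = 31L),
                  b = fixture_genome(60, seed = 32L))
  # deterministic imperfect caller: only reports odd-numbered fragments
  half_caller <- function(fragments) {
    hit <- !is.na(fragments$fs_pos) &
      (seq_len(nrow(fragments)) %% 2L == 1L)
    out <- data.frame(fragment_id = fragments$id[hit],
                      pos = fragments$fs_pos[hit])
    # plus one FP per run to decouple Sn from Sp
    rbind(out, data.frame(fragment_id = fragments$id[1], pos = 1L))
  }
  res <- run_benchmark(fam, genomes, lengths = 400L, fractions = 0.2,
                       n = 40L, seed = 9L, caller = half_caller)
  cells <- res$cells
  expect_equal(nrow(cells), 4L) # 2 genomes x 2 types
  by_type <- vapply(c("insertion", "deletion"), function(ty) {
    mean(cells$Sn[cells$type == ty])
  }, 0)
  expect_equal(res$summary$Sn, mean(by_type))
})

test_that("enabling more filters never increases A or T", {
  fam <- fixture_family()
  g <- fixture_genome(60, seed = 33L)
  frags <- inject_indels(cut_fragments(g, 600L, 50L, seed = 8L), 0.2, "both",
                         seed = 9L)
  counts <- lapply(list(character(0), "I", c("I", "II"), c("I", "II", "III")),
                   function(en) {
    caller <- metafs:::pipeline_caller(fam, decoder_params(), filter_config(),
                                       rbs_model(), en)
    preds <- caller(frags)
    r <- score_predictions(frags, preds)
    c(A = r$A, T = r$T)
  })
  A <- vapply(counts, `[[`, 0L, "A")
  TP <- vapply(counts, `[[`, 0L, "T")
  expect_true(all(diff(A) <= 0L))
  expect_true(all(diff(TP) <= 0L))
})
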
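# Shared fixtures, built once per test run. The fixture family is trained on
# nine synthetic genomes spanning GC 30-70%.

.fixture_cache <- new.env(parent = emptyenv())

fixture_family <- function() {
  if (is.null(.fixture_cache$fam)) {
    .fixture_cache$fam <- build_fixture_family(seed = 42)
  }
  .fixture_cache$fam
}

fixture_model <- function(theta = 50, params = decoder_params()) {
  model_for_gc(fixture_family(), theta, params)
}

fixture_genome <- function(theta = 50, seed = 7L, n_genes = 40L) {
  key <- sprintf("g_%s_%s_%s", theta, seed, n_genes)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture_genome(theta, n_genes = n_genes,
                                                 seed = seed)
  }
  .fixture_cache[[key]]
}

# Brute-force per-position phase/hexamer labeller used as the counting oracle.
brute_force_hexamer_counts <- function(record, annotation) {
  coding <- matrix(0L, 4096L, 3L)
  hexes <- all_hex_strings()
  cds <- annotation[annotation$feature == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    s <- substr(record$seq, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    n <- nchar(s)
    for (j in 6:n) {
      h <- substr(s, j - 5L, j)
      if (grepl("N", h)) next
      phase <- (j - 1L) %% 3L
      idx <- match(h, hexes)
      coding[idx, phase + 1L] <- coding[idx, phase + 1L] + 1L
    }
  }
  coding + 1L
}

all_hex_strings <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T")
      g <- expand.grid(b6 = b, b5 = b, b4 = b, b3 = b, b2 = b, b1 = b,
                       stringsAsFactors = FALSE)
      cache <<- paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)
    }
    cache
  }
})

# Toy 3-state, 2-letter decoding problem for oracle tests.
toy_space <- function() {
  trans <- matrix(c(0.8, 0.15, 0.05,
                    0.1, 0.7, 0.2,
                    0.25, 0.25, 0.5), 3L, byrow = TRUE)
  emis <- matrix(c(0.9, 0.1,
                   0.5, 0.5,
                   0.2, 0.8), 3L, byrow = TRUE) # P(letter | state)
  list(log_trans = log(trans), log_init = log(c(0.5, 0.3, 0.2)),
       log_emis = log(emis))
}

# Exhaustive Viterbi oracle: maximum path log probability by enumerating all
# hidden paths. Emission matrix E is L x K (log), trans/init in log space.
enumerate_best_path_logp <- function(E, log_trans, log_init) {
  L <- nrow(E); K <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(1:K), L)))
  score <- log_init[paths[, 1L]] + E[1L, ][paths[, 1L]]
  if (L > 1L) {
    for (t in 2:L) {
      score <- score + log_trans[cbind(paths[, t - 1L], paths[, t])] +
        E[t, ][paths[, t]]
    }
  }
  max(score)
}
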
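# Simulation benchmark: synthetic annotated genomes with controllable GC
# content, fixed-length fragment sampling, single-indel injection into long
# coding stretches, and sensitivity/specificity scoring with a fixed
# true-positive window.

# Per-codon-position base probabilities at a target GC fraction. The three
# positions carry deliberately different GC loads (offsets +0.12, -0.18,
# +0.06, mean zero) and different within-GC base asymmetries, emulating the
# positional asymmetry of real codon usage that frame discrimination relies
# on.
#' @noRd
codon_pos_probs <- function(theta_frac) {
  s1 <- theta_frac + 0.12
  s2 <- theta_frac - 0.18
  s3 <- theta_frac + 0.06
  stopifnot(s1 > 0, s1 < 1, s2 > 0, s2 < 1, s3 > 0, s3 < 1)
  list(
    c(A = 2 * (1 - s1) / 3, C = 0.25 * s1, G = 0.75 * s1, T = (1 - s1) / 3),
    c(A = 0.75 * (1 - s2), C = 2 * s2 / 3, G = s2 / 3, T = 0.25 * (1 - s2)),
    c(A = (1 - s3) / 3, C = s3 / 2, G = s3 / 2, T = 2 * (1 - s3) / 3)
  )
}

#' Generate a synthetic annotated genome at a target GC content
#'
#' Alternating non-coding / CDS layout. CDS bodies are sampled from a
#' 3-periodic codon model whose per-position base composition is tuned so the
#' realized genome GC content lands within about 2 percentage points of the
#' target; genes are internally stop-free in frame, begin with ATG and end
#' with a stop codon, and are placed on alternating strands. Gene and
#' intergenic lengths follow a fixed cyclic layout, so genomes generated at
#' different GC targets have identical coding totals. Deterministic under
#' `seed`.
#'
#' @param theta_target Target GC content in percent, in `[25, 75]`.
#' @param n_genes Number of genes.
#' @param mean_gene_len Mean CDS length in nt (cyclic layout 0.5x .. 1.5x).
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return List with `record` (sequence record) and `annotation` (CDS
#'   data.frame).
#' @export
make_fixture_genome <- function(theta_target, n_genes = 40L,
                                mean_gene_len = 600L, seed = 1L,
                                id = sprintf("fixture_gc%02.0f", theta_target)) {
  if (theta_target < 25 || theta_target > 75) {
    stop("parameter error: theta_target must lie in [25, 75], got ", theta_target)
  }
  t <- theta_target / 100
  pp <- codon_pos_probs(t)
  gene_lens <- rep(round(c(0.5, 0.75, 1, 1.5, 1.25) * mean_gene_len / 3) * 3L,
                   length.out = n_genes)
  nc_lens <- rep(c(120L, 160L, 100L, 180L, 140L), length.out = n_genes + 1L)
  strands <- rep(c("+", "-"), length.out = n_genes)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  nc_probs <- c((1 - t) / 2, t / 2, t / 2, (1 - t) / 2)

  with_seed(seed, {
    sample_codons <- function(n) {
      b1 <- sample(bases, n, TRUE, prob = pp[[1L]])
      b2 <- sample(bases, n, TRUE, prob = pp[[2L]])
      b3 <- sample(bases, n, TRUE, prob = pp[[3L]])
      cod <- paste0(b1, b2, b3)
      while (any(bad <- cod %in% stops)) {
        nb <- sum(bad)
        cod[bad] <- paste0(sample(bases, nb, TRUE, prob = pp[[1L]]),
                           sample(bases, nb, TRUE, prob = pp[[2L]]),
                           sample(bases, nb, TRUE, prob = pp[[3L]]))
      }
      cod
    }
    pieces <- character(0)
    ann <- list()
    pos <- 0L
    for (i in seq_len(n_genes)) {
      nc <- paste(sample(bases, nc_lens[i], TRUE, prob = nc_probs),
                  collapse = "")
      pieces <- c(pieces, nc)
      pos <- pos + nc_lens[i]
      n_body <- gene_lens[i] / 3L - 2L
      gene <- paste0("ATG", paste(sample_codons(n_body), collapse = ""),
                     sample(stops, 1L))
      if (strands[i] == "-") gene <- revcomp(gene)
      pieces <- c(pieces, gene)
      ann[[i]] <- data.frame(seq_id = id, start = pos + 1L,
                             end = pos + gene_lens[i], strand = strands[i],
                             feature = "CDS", stringsAsFactors = FALSE)
      pos <- pos + gene_lens[i]
    }
    tail_nc <- paste(sample(bases, nc_lens[n_genes + 1L], TRUE,
                            prob = nc_probs), collapse = "")
    pieces <- c(pieces, tail_nc)
    seq <- paste(pieces, collapse = "")
    list(record = list(id = id, seq = seq, length = nchar(seq)),
         annotation = do.call(rbind, ann))
  })
}

#' Build a small heuristic model family from synthetic genomes
#'
#' Trains [fit_family()] on [make_fixture_genome()] output across a grid of
#' GC targets. This is the self-contained stand-in for a family trained on
#' large collections of annotated genomes; a user-trained family file can be
#' supplied to the pipeline instead.
#'
#' @param thetas GC targets (percent) of the training genomes.
#' @param n_genes,mean_gene_len Per-genome layout, see [make_fixture_genome()].
#' @param seed Integer seed (genome `i` uses `seed + i`).
#' @param degree Polynomial degree.
#' @param return_genomes If `TRUE`, attach the training genomes as the
#'   `"genomes"` attribute.
#' @return A `heuristic_family`.
#' @export
build_fixture_family <- function(thetas = seq(30, 70, by = 5), n_genes = 40L,
                                 mean_gene_len = 600L, seed = 1L, degree = 5L,
                                 return_genomes = FALSE) {
  genomes <- lapply(seq_along(thetas), function(i) {
    make_fixture_genome(thetas[i], n_genes, mean_gene_len, seed = seed + i)
  })
  summaries <- lapply(genomes, function(g) count_hexamers(g$record, g$annotation))
  fam <- fit_family(summaries, degree = degree)
  if (return_genomes) attr(fam, "genomes") <- genomes
  fam
}

#' Cut a genome into fixed-length fragments
#'
#' Samples `n` fragments at uniform-random start offsets (with replacement)
#' and uniform-random strand; each fragment carries its CDS intervals
#' intersected with the fragment and shifted (and, for minus-strand
#' fragments, reflected) into fragment coordinates.
#'
#' @param genome List with `record` and `annotation` (as from
#'   [make_fixture_genome()] or assembled from FASTA + GFF3).
#' @param length Fragment length in nt.
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `source`, `offset`, `strand`,
#'   `nominal_len`, `seq`, `fs_pos` (NA), `fs_type` (NA) and list column
#'   `coding_map` (matrices of CDS start/end in fragment coordinates).
#' @export
cut_fragments <- function(genome, length, n, seed = 1L) {
  L <- genome$record$length
  if (L < length) stop("genome shorter than requested fragment length")
  cds <- genome$annotation[genome$annotation$feature == "CDS", , drop = FALSE]
  with_seed(seed, {
    starts <- sample.int(L - length + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$record$seq, starts, starts + length - 1L)
    maps <- vector("list", n)
    for (i in seq_len(n)) {
      a <- starts[i]; b <- starts[i] + length - 1L
      s <- pmax(cds$start, a); e <- pmin(cds$end, b)
      keep <- s <= e
      m <- cbind(start = s[keep] - a + 1L, end = e[keep] - a + 1L)
      if (strands[i] == "-") {
        seqs[i] <- revcomp(seqs[i])
        m <- cbind(start = length - m[, "end"] + 1L,
                   end = length - m[, "start"] + 1L)
        m <- m[order(m[, "start"]), , drop = FALSE]
      }
      maps[[i]] <- m
    }
    out <- data.frame(
      id = sprintf("%s_frag%05d", genome$record$id, seq_len(n)),
      source = genome$record$id, offset = starts, strand = strands,
      nominal_len = length, seq = seqs, fs_pos = NA_integer_,
      fs_type = NA_character_, stringsAsFactors = FALSE)
    out$coding_map <- maps
    out
  })
}

# Eligible indel positions of one fragment: inside coding stretches longer
# than 200 nt, at least 50 nt from both fragment boundaries.
#' @noRd
eligible_zones <- function(map, L, min_stretch = 200L, margin = 50L) {
  if (is.null(map) || nrow(map) == 0L) return(NULL)
  long <- map[(map[, "end"] - map[, "start"] + 1L) > min_stretch, , drop = FALSE]
  if (nrow(long) == 0L) return(NULL)
  lo <- pmax(long[, "start"], margin + 1L)
  hi <- pmin(long[, "end"], L - margin)
  ok <- lo <= hi
  if (!any(ok)) return(NULL)
  cbind(lo = lo[ok], hi = hi[ok])
}

#' Inject single-nucleotide indels into a fraction of the fragments
#'
#' Exactly `round(fraction * n)` fragments receive one indel at a uniformly
#' random eligible position: inside a coding stretch longer than 200 nt and
#' at least 50 nt from both fragment boundaries. Inserted bases are uniform
#' over A,C,G,T. Fragments with no eligible site are excluded from selection.
#'
#' @param fragments data.frame from [cut_fragments()].
#' @param fraction Fraction of all fragments to modify (e.g. 0.05, 0.10,
#'   0.20).
#' @param type `"insertion"`, `"deletion"`, or `"both"` (fair coin per
#'   fragment).
#' @param seed Integer seed.
#' @return The fragments data.frame with `seq`, `fs_pos` and `fs_type`
#'   updated on the modified rows.
#' @export
inject_indels <- function(fragments, fraction, type = c("both", "insertion",
                                                        "deletion"),
                          seed = 1L) {
  type <- match.arg(type)
  n <- nrow(fragments)
  k <- round(fraction * n)
  if (k == 0L) return(fragments)
  zones <- lapply(seq_len(n), function(i) {
    eligible_zones(fragments$coding_map[[i]], fragments$nominal_len[i])
  })
  eligible <- which(!vapply(zones, is.null, TRUE))
  if (length(eligible) < k) {
    stop("only ", length(eligible), " fragments have an eligible indel site; ",
         k, " required (deficit ", k - length(eligible), ")")
  }
  with_seed(seed, {
    chosen <- sample(eligible, k)
    for (i in chosen) {
      z <- zones[[i]]
      sites <- unlist(lapply(seq_len(nrow(z)),
                             function(r) seq.int(z[r, "lo"], z[r, "hi"])))
      pos <- if (length(sites) == 1L) sites else sample(sites, 1L)
      ty <- switch(type, both = sample(c("insertion", "deletion"), 1L),
                   insertion = "insertion", deletion = "deletion")
      s <- fragments$seq[i]
      if (ty == "insertion") {
        base <- sample(c("A", "C", "G", "T"), 1L)
        fragments$seq[i] <- paste0(substr(s, 1L, pos - 1L), base,
                                   substr(s, pos, nchar(s)))
      } else {
        fragments$seq[i] <- paste0(substr(s, 1L, pos - 1L),
                                   substr(s, pos + 1L, nchar(s)))
      }
      fragments$fs_pos[i] <- pos
      fragments$fs_type[i] <- ty
    }
    fragments
  })
}

#' Score frameshift predictions against simulated truth
#'
#' A prediction is a true positive iff its fragment carries a simulated
#' frameshift and the predicted position lies within `window` nt of the true
#' position; each true frameshift can be matched by at most one prediction
#' (the closest; remaining predictions on the fragment are false positives).
#'
#' @param truth data.frame with columns `id` and `fs_pos` (NA when the
#'   fragment carries no indel), e.g. from [inject_indels()].
#' @param predictions data.frame with columns `fragment_id` and `pos`.
#' @param window True-positive window in nt (default 20).
#' @return A `benchmark_result` list: counts `A` (all predictions), `T`
#'   (true positives), `S` (simulated frameshifts), and `Sn = T/S`,
#'   `Sp = T/A` (NA when A = 0), `avg = (Sn + Sp)/2`.
#' @export
score_predictions <- function(truth, predictions, window = 20L) {
  A <- nrow(predictions)
  has_fs <- !is.na(truth$fs_pos)
  S <- sum(has_fs)
  TP <- 0L
  for (i in which(has_fs)) {
    d <- abs(predictions$pos[predictions$fragment_id == truth$id[i]] -
               truth$fs_pos[i])
    if (length(d) && min(d) <= window) TP <- TP + 1L
  }
  Sn <- if (S > 0L) TP / S else NA_real_
  Sp <- if (A > 0L) TP / A else NA_real_
  structure(list(A = A, T = TP, S = S, Sn = Sn, Sp = Sp,
                 avg = (Sn + Sp) / 2), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("A = %d predictions, T = %d true positives, S = %d simulated\n",
              x$A, x$T, x$S))
  cat(sprintf("Sn = %.3f  Sp = %.3f  (Sn+Sp)/2 = %.3f\n",
              x$Sn, x$Sp, x$avg))
  invisible(x)
}

# Default caller: the full pipeline; returns kept frameshift calls.
#' @noRd
pipeline_caller <- function(family, params, cfg, rbs, enabled) {
  function(fragments) {
    recs <- lapply(seq_len(nrow(fragments)), function(i) {
      list(id = fragments$id[i], seq = fragments$seq[i],
           length = nchar(fragments$seq[i]))
    })
    res <- run_pipeline(recs, family, params = params, cfg = cfg, rbs = rbs,
                        enabled = enabled)
    fs <- res$frameshifts
    fs[fs$kept, c("fragment_id", "pos"), drop = FALSE]
  }
}

#' Run the full simulation benchmark
#'
#' For every combination of genome, fragment length, frameshift fraction and
#' indel type: cut fragments, inject indels, call frameshifts, and score.
#' The summary table averages each cell first across genomes and then
#' between the insertion and deletion sets.
#'
#' @param family A `heuristic_family` used by the caller.
#' @param genomes Named list of genomes (each a list with `record`,
#'   `annotation`).
#' @param lengths Fragment lengths in nt.
#' @param fractions Fractions of fragments receiving an indel.
#' @param types Indel test sets (scored separately, then averaged).
#' @param n Fragments per (genome, length) set.
#' @param window True-positive window in nt.
#' @param seed Integer base seed; every cell derives its own sub-seeds.
#' @param params,cfg,rbs,enabled Pipeline settings (see [run_pipeline()]);
#'   `enabled` picks the filter subset, enabling filter-ablation studies.
#' @param caller Optional replacement caller
#'   `function(fragments) data.frame(fragment_id, pos)`; defaults to the
#'   package pipeline.
#' @return List with `cells` (one row per combination, counts and rates) and
#'   `summary` (per length x fraction, genome- then type-averaged `Sn`,
#'   `Sp`, `avg`).
#' @export
run_benchmark <- function(family, genomes, lengths = c(400L, 600L, 800L),
                          fractions = c(0.05, 0.10, 0.20),
                          types = c("insertion", "deletion"), n = 2000L,
                          window = 20L, seed = 1L,
                          params = decoder_params(), cfg = filter_config(),
                          rbs = rbs_model(),
                          enabled = c("I", "II", "III"), caller = NULL) {
  if (is.null(caller)) caller <- pipeline_caller(family, params, cfg, rbs, enabled)
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, function(g) g$record$id, "")
  }
  cells <- list()
  cell_i <- 0L
  for (gname in names(genomes)) {
    for (len in lengths) {
      for (fr in fractions) {
        for (ty in types) {
          cell_i <- cell_i + 1L
          s1 <- (seed * 1009L + cell_i * 7919L) %% 2147483647L
          frags <- cut_fragments(genomes[[gname]], len, n, seed = s1)
          frags <- inject_indels(frags, fr, ty, seed = s1 + 1L)
          preds <- caller(frags)
          r <- score_predictions(frags, preds, window)
          cells[[cell_i]] <- data.frame(
            genome = gname, length = len, fraction = fr, type = ty,
            A = r$A, T = r$T, S = r$S, Sn = r$Sn, Sp = r$Sp, avg = r$avg,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  stopifnot(all(cells$T <= cells$S), all(cells$T <= cells$A))

  by_type <- stats::aggregate(cbind(Sn, Sp, avg) ~ length + fraction + type,
                              data = cells, FUN = mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  summary <- stats::aggregate(cbind(Sn, Sp, avg) ~ length + fraction,
                              data = by_type, FUN = mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  summary <- summary[order(summary$length, summary$fraction), , drop = FALSE]
  list(cells = cells, summary = summary)
}
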
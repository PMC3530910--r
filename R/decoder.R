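# Frame-aware HMM decoder. State space: NC plus coding-in-frame-f states for
# f in {0,1,2} on each strand. A transition between two coding frames inside
# one gene is a frameshift candidate. All arithmetic is in log space.
#
# State order (also the Viterbi tie-break order: prefer NC, then lower frame,
# then + strand):
#   1 NC, 2 C(0,+), 3 C(0,-), 4 C(1,+), 5 C(1,-), 6 C(2,+), 7 C(2,-)

.STATE_FRAME <- c(NA, 0L, 0L, 1L, 1L, 2L, 2L)
.STATE_STRAND <- c(NA, "+", "-", "+", "-", "+", "-")

#' Build the frame-transition state space for a fragment model
#'
#' Durations are geometric: a state with mean length `m` has self-transition
#' probability `1 - 1/m`. Inside a coding state, probability mass `p_fs` is
#' reserved for switching to one of the two alternative frames on the same
#' strand (`p_fs/2` each); there is no direct transition between strands. The
#' initial distribution is the stationary occupancy implied by the durations,
#' which makes decoding exactly symmetric under reverse complement.
#'
#' @param model A `fragment_model` from [model_for_gc()].
#' @return An object of class `state_space` with `log_trans` (7 x 7, from x
#'   to), `log_init`, the frame-switch transition mask, and state metadata.
#' @export
build_state_space <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  p <- model$params
  exit_c <- 1 / p$mean_coding_len
  exit_nc <- 1 / p$mean_noncoding_len
  stay_c <- 1 - exit_c - p$p_fs
  if (stay_c <= 0) {
    stop("config error: p_fs (", p$p_fs,
         ") exceeds the coding exit probability budget")
  }
  trans <- matrix(0, 7L, 7L)
  trans[1L, 1L] <- 1 - exit_nc
  trans[1L, 2:7] <- exit_nc / 6
  for (s in 2:7) {
    trans[s, 1L] <- exit_c
    trans[s, s] <- stay_c
    same_strand <- which(.STATE_STRAND == .STATE_STRAND[s])
    trans[s, setdiff(same_strand, s)] <- p$p_fs / 2
  }
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-9))

  pi_nc <- p$mean_noncoding_len / (p$mean_noncoding_len + p$mean_coding_len)
  init <- c(pi_nc, rep((1 - pi_nc) / 6, 6L))

  switch_mask <- matrix(FALSE, 7L, 7L)
  for (s in 2:7) {
    same_strand <- which(.STATE_STRAND == .STATE_STRAND[s])
    switch_mask[s, setdiff(same_strand, s)] <- TRUE
  }

  structure(list(
    log_trans = log(trans),
    log_init = log(init),
    switch_mask = switch_mask,
    frame = .STATE_FRAME,
    strand = .STATE_STRAND,
    n_states = 7L
  ), class = "state_space")
}

# Per-strand emission scores from one sequence direction.
# Returns coding: L x 3 matrix, column p+1 = log P at the position assuming
# the position is codon phase p (phase of the hexamer's last base); nc:
# length-L vector. Positions without a clean 6-mer context (first five
# positions, or any N in the window) score log(1/4) everywhere (neutral
# background). An in-frame stop codon adds the stop penalty at phase 2.
#' @noRd
strand_scores <- function(codes, model) {
  L <- length(codes)
  bg <- log(0.25)
  coding <- matrix(bg, L, 3L)
  nc <- rep(bg, L)
  hm <- hex_indices(codes)
  ok <- which(!is.na(hm))
  if (length(ok)) {
    for (p in 1:3) coding[ok, p] <- model$coding_logp[hm[ok], p]
    nc[ok] <- model$noncoding_logp[hm[ok]]
  }
  st <- stop_ends(codes)
  coding[st, 3L] <- coding[st, 3L] + model$params$stop_penalty
  list(coding = coding, nc = nc)
}

# Full L x 7 emission matrix. Minus-strand coding states read the coding
# model on the reverse complement (their 6-mer context lies downstream in
# forward coordinates); the NC state averages the forward and reverse
# non-coding log scores, so the whole matrix mirrors exactly under reverse
# complement.
#' @noRd
emission_matrix <- function(codes, model) {
  L <- length(codes)
  fwd <- strand_scores(codes, model)
  rv <- strand_scores(revcomp_codes(codes), model)
  E <- matrix(NA_real_, L, 7L)
  i <- seq_len(L)
  istar <- L - i + 1L
  for (f in 0:2) {
    E[, 2L + 2L * f] <- fwd$coding[cbind(i, ((i - 1L - f) %% 3L) + 1L)]
    E[, 3L + 2L * f] <- rv$coding[cbind(istar, ((istar - 1L - f) %% 3L) + 1L)]
  }
  E[, 1L] <- (fwd$nc + rv$nc[istar]) / 2
  E
}

#' Viterbi decoding over an explicit emission matrix
#'
#' Generic max-log-probability path finder. Ties are broken toward the state
#' with the lower index, both within the recursion and at termination.
#'
#' @param log_emissions L x K matrix of per-position, per-state emission log
#'   scores.
#' @param log_trans K x K transition log-probability matrix (from x to).
#' @param log_init Length-K initial log distribution.
#' @param ban_mask Optional K x K logical matrix of transitions to forbid
#'   inside `ban_window`.
#' @param ban_window Optional `c(a, b)`: the ban applies to steps landing on
#'   positions `a+1 .. b`.
#' @return List with `path` (integer states) and `logp`.
#' @export
viterbi <- function(log_emissions, log_trans, log_init,
                    ban_mask = NULL, ban_window = NULL) {
  L <- nrow(log_emissions)
  K <- ncol(log_emissions)
  stopifnot(L >= 1L, all(dim(log_trans) == K), length(log_init) == K)
  trans_banned <- log_trans
  if (!is.null(ban_mask)) trans_banned[ban_mask] <- -Inf
  use_ban <- !is.null(ban_mask) && !is.null(ban_window)

  V <- log_init + log_emissions[1L, ]
  back <- matrix(0L, L, K)
  cols <- seq_len(K)
  for (t in seq_len(L)[-1L]) {
    Tt <- if (use_ban && t > ban_window[1L] && t <= ban_window[2L]) {
      trans_banned
    } else {
      log_trans
    }
    M <- Tt + V # adds V[from] down each column
    am <- max.col(t(M), ties.method = "first")
    V <- M[cbind(am, cols)] + log_emissions[t, ]
    back[t, ] <- am
  }
  end <- which.max(V)
  path <- integer(L)
  path[L] <- end
  if (L > 1L) for (t in L:2L) path[t - 1L] <- back[t, path[t]]
  list(path = path, logp = V[end])
}

#' Decode one fragment with the frame-aware HMM
#'
#' @param seq DNA string (at least 6 nt).
#' @param model A `fragment_model`.
#' @param space Optional pre-built `state_space`.
#' @param ban_window Optional `c(start, end)`: forbid frame-switch transitions
#'   whose landing position lies in `start+1 .. end` (used for the constrained
#'   no-frameshift rescoring of a gene).
#' @return List with `path` (integer state per position), `logp`, the
#'   `space` used, and the `emissions` matrix (L x 7 log scores).
#' @export
viterbi_decode <- function(seq, model, space = build_state_space(model),
                           ban_window = NULL) {
  codes <- if (is.character(seq)) encode_seq(seq) else seq
  if (length(codes) < 6L) stop("sequence shorter than 6 nt cannot be decoded")
  E <- emission_matrix(codes, model)
  mask <- if (is.null(ban_window)) NULL else space$switch_mask
  out <- viterbi(E, space$log_trans, space$log_init,
                 ban_mask = mask, ban_window = ban_window)
  out$space <- space
  out$emissions <- E
  out
}

#' Convert a decoded state path into gene and frameshift calls
#'
#' Maximal runs of coding states on one strand become genes; a frame change
#' inside a run becomes a frameshift at the last nucleotide decoded in the
#' left-hand frame. The frame difference is taken in the gene's reading
#' direction and mapped to `+1` (insertion-like, frame advanced by 1) or
#' `-1` (deletion-like, frame advanced by 2).
#'
#' @param path Integer state path from [viterbi_decode()].
#' @param space The `state_space` used for decoding.
#' @param emissions Optional emission matrix; when given, each gene gets a
#'   log-odds score (emission of the decoded states minus the NC emission
#'   over the gene span).
#' @return List of data.frames `genes` (columns `start`, `end`, `strand`,
#'   `score`, `n_segments`, `truncated_left`, `truncated_right`) and
#'   `frameshifts` (columns `pos`, `fs_shift`, `strand`, `gene`,
#'   `upstream_frame`, `downstream_frame`, `score`); `frames_path` is
#'   attached to `genes` as a list column of `(frame, from, to)` segments.
#' @export
calls_from_path <- function(path, space, emissions = NULL) {
  L <- length(path)
  r <- rle(path)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  seg_strand <- space$strand[r$values]
  seg_frame <- space$frame[r$values]
  coding <- r$values != 1L

  genes <- list(); fss <- list(); frames_paths <- list()
  k <- 1L
  n_seg <- length(r$values)
  while (k <= n_seg) {
    if (!coding[k]) { k <- k + 1L; next }
    j <- k
    while (j < n_seg && coding[j + 1L] && seg_strand[j + 1L] == seg_strand[k]) {
      j <- j + 1L
    }
    gs <- seg_start[k]; ge <- seg_end[j]
    strand <- seg_strand[k]
    gene_idx <- length(genes) + 1L
    score <- if (is.null(emissions)) NA_real_ else {
      idx <- gs:ge
      sum(emissions[cbind(idx, path[idx])] - emissions[idx, 1L])
    }
    genes[[gene_idx]] <- data.frame(
      start = gs, end = ge, strand = strand, score = score,
      n_segments = j - k + 1L,
      truncated_left = gs == 1L, truncated_right = ge == L,
      stringsAsFactors = FALSE)
    frames_paths[[gene_idx]] <- data.frame(
      frame = seg_frame[k:j], from = seg_start[k:j], to = seg_end[k:j])
    if (j > k) {
      for (m in k:(j - 1L)) {
        f_left <- seg_frame[m]; f_right <- seg_frame[m + 1L]
        delta <- if (strand == "+") (f_right - f_left) %% 3L
                 else (f_left - f_right) %% 3L
        fss[[length(fss) + 1L]] <- data.frame(
          pos = seg_end[m],
          fs_shift = if (delta == 1L) 1L else -1L,
          strand = strand, gene = gene_idx,
          upstream_frame = if (strand == "+") f_left else f_right,
          downstream_frame = if (strand == "+") f_right else f_left,
          score = NA_real_, stringsAsFactors = FALSE)
      }
    }
    k <- j + 1L
  }

  empty_genes <- data.frame(start = integer(0), end = integer(0),
                            strand = character(0), score = numeric(0),
                            n_segments = integer(0),
                            truncated_left = logical(0),
                            truncated_right = logical(0))
  empty_fs <- data.frame(pos = integer(0), fs_shift = integer(0),
                         strand = character(0), gene = integer(0),
                         upstream_frame = integer(0),
                         downstream_frame = integer(0), score = numeric(0))
  genes_df <- if (length(genes)) do.call(rbind, genes) else empty_genes
  genes_df$frames_path <- if (length(genes)) I(frames_paths) else I(list())
  fs_df <- if (length(fss)) do.call(rbind, fss) else empty_fs
  list(genes = genes_df, frameshifts = fs_df)
}

#' Detect frameshifts in a single fragment
#'
#' Runs the frame-aware Viterbi decoder, extracts gene and frameshift calls,
#' and scores each frameshift as the Viterbi margin: the decoded log
#' probability minus the best path forbidden from switching frames inside
#' that gene (a second, constrained decode).
#'
#' @param seq DNA string.
#' @param model A `fragment_model`.
#' @param space Optional pre-built `state_space`.
#' @return List with `genes`, `frameshifts`, `path` and `logp`; coordinates
#'   are 1-based on the given sequence.
#' @export
detect_frameshifts <- function(seq, model, space = build_state_space(model)) {
  codes <- if (is.character(seq)) encode_seq(seq) else seq
  E <- emission_matrix(codes, model)
  dec <- viterbi(E, space$log_trans, space$log_init)
  calls <- calls_from_path(dec$path, space, emissions = E)
  fs <- calls$frameshifts
  if (nrow(fs) > 0L) {
    for (g in unique(fs$gene)) {
      gene <- calls$genes[g, ]
      con <- viterbi(E, space$log_trans, space$log_init,
                     ban_mask = space$switch_mask,
                     ban_window = c(gene$start, gene$end))
      fs$score[fs$gene == g] <- dec$logp - con$logp
    }
  }
  calls$frameshifts <- fs
  list(genes = calls$genes, frameshifts = fs,
       path = dec$path, logp = dec$logp)
}

#' Sample a sequence and hidden path from the fragment model
#'
#' Exact ancestral sampling from the decoder's generative view, restricted to
#' the non-coding state and forward-strand coding states (reverse-strand
#' coding emissions condition on downstream bases, so they cannot be sampled
#' left to right; minus-strand behaviour is exercised by reverse-complementing
#' sampled sequences). Emission conditionals honour the in-frame stop-codon
#' penalty, re-normalized, and the first five positions are background.
#'
#' @param model A `fragment_model`.
#' @param length Fragment length in nt (at least 6).
#' @param seed Integer seed; the same seed reproduces the fragment bit for
#'   bit.
#' @param force_path Optional integer state path (values in `{1, 2, 4, 6}`)
#'   to sample emissions along, instead of sampling the hidden chain.
#' @return List with `seq`, `path`, and `length`.
#' @export
sample_from_model <- function(model, length, seed = NULL, force_path = NULL) {
  stopifnot(length >= 6L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p <- model$params
  plus_states <- c(1L, 2L, 4L, 6L)
  if (is.null(force_path)) {
    exit_c <- 1 / p$mean_coding_len
    exit_nc <- 1 / p$mean_noncoding_len
    tr <- matrix(0, 4L, 4L) # order NC, C0+, C1+, C2+
    tr[1L, ] <- c(1 - exit_nc, rep(exit_nc / 3, 3L))
    for (s in 2:4) {
      tr[s, 1L] <- exit_c
      tr[s, s] <- 1 - exit_c - p$p_fs
      tr[s, setdiff(2:4, s)] <- p$p_fs / 2
    }
    pi0 <- c(p$mean_noncoding_len, rep(p$mean_coding_len / 3, 3L))
    pi0 <- pi0 / sum(pi0)
    idx <- integer(length)
    idx[1L] <- sample.int(4L, 1L, prob = pi0)
    for (t in 2:length) idx[t] <- sample.int(4L, 1L, prob = tr[idx[t - 1L], ])
    path <- plus_states[idx]
  } else {
    stopifnot(length(force_path) == length, all(force_path %in% plus_states))
    path <- as.integer(force_path)
  }

  codes <- integer(length)
  stop_next <- function(c1, c2) {
    # which next bases complete a stop codon after c1, c2
    if (is.na(c1) || is.na(c2)) return(integer(0))
    if (c1 == 3L && c2 == 0L) return(c(0L, 2L)) # TAA, TAG
    if (c1 == 3L && c2 == 2L) return(0L)        # TGA
    integer(0)
  }
  for (t in seq_len(length)) {
    if (t <= 5L) {
      codes[t] <- sample.int(4L, 1L) - 1L
      next
    }
    ctx <- sum(codes[(t - 5L):(t - 1L)] * c(256L, 64L, 16L, 4L, 1L))
    hexes <- ctx * 4L + 1:4 # hexamer indices for next base A,C,G,T
    st <- path[t]
    if (st == 1L) {
      pr <- exp(model$noncoding_logp[hexes])
    } else {
      f <- .STATE_FRAME[st]
      phase <- (t - 1L - f) %% 3L
      lp <- model$coding_logp[hexes, phase + 1L]
      if (phase == 2L) {
        bad <- stop_next(codes[t - 2L], codes[t - 1L])
        lp[bad + 1L] <- lp[bad + 1L] + p$stop_penalty
      }
      pr <- exp(lp)
    }
    codes[t] <- sample.int(4L, 1L, prob = pr / sum(pr)) - 1L
  }
  list(seq = decode_seq(codes), path = path, length = length)
}

#' Sample a fragment containing one forced mid-gene frame switch
#'
#' Builds a hidden path with a non-coding head and tail, one forward-strand
#' gene, and exactly one frame switch at a random position in the central
#' part of the gene, then samples the sequence along it. Used for generative
#' self-consistency checks of switch localization.
#'
#' @param model A `fragment_model`.
#' @param length Fragment length in nt.
#' @param seed Integer seed.
#' @param nc_head,nc_tail Non-coding flank lengths in nt.
#' @param margin Minimum distance in nt of the switch from either gene end.
#' @return List with `seq`, `path`, `switch_pos` (last nt in the upstream
#'   frame), `frame_from`, `frame_to`.
#' @export
sample_fragment_with_switch <- function(model, length = 600L, seed = NULL,
                                        nc_head = 60L, nc_tail = 60L,
                                        margin = 100L) {
  gene_start <- nc_head + 1L
  gene_end <- length - nc_tail
  stopifnot(gene_end - gene_start + 1L > 2L * margin)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  frames <- sample(0:2, 2L)
  sw <- sample(seq.int(gene_start + margin, gene_end - margin), 1L)
  path <- rep(1L, length)
  path[gene_start:sw] <- 2L + 2L * frames[1L]
  path[(sw + 1L):gene_end] <- 2L + 2L * frames[2L]
  out <- sample_from_model(model, length, seed = NULL, force_path = path)
  out$switch_pos <- sw
  out$frame_from <- frames[1L]
  out$frame_to <- frames[2L]
  out
}
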
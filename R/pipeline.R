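# Two-step orchestration. Step 1 decodes each input sequence with p_fs = 0
# (a plain heuristic gene finder) to select the model by GC content and to
# partition the sequence into same-strand gene groups. Step 2 re-decodes each
# group with p_fs > 0 to call frameshifts, applies the false-positive
# filters, and maps everything back to input coordinates.

#' Map a position from group working coordinates back to source coordinates
#'
#' Plus-strand groups are an affine offset; minus-strand groups reflect
#' within the interval (`pos' = end - pos + 1`). Round-trips exactly with
#' [map_to_group()].
#'
#' @param pos 1-based position(s) in group working coordinates.
#' @param group List with `start`, `end`, `strand` describing the group's
#'   source interval.
#' @return Source coordinate(s).
#' @export
map_back <- function(pos, group) {
  glen <- group$end - group$start + 1L
  if (any(pos < 1L | pos > glen)) {
    stop("internal consistency error: call outside group bounds")
  }
  if (group$strand == "+") pos + group$start - 1L else group$end - pos + 1L
}

#' Map a source position into group working coordinates
#' @inheritParams map_back
#' @export
map_to_group <- function(pos, group) {
  if (any(pos < group$start | pos > group$end)) {
    stop("internal consistency error: position outside group interval")
  }
  if (group$strand == "+") pos - group$start + 1L else group$end - pos + 1L
}

# Partition step-1 genes into maximal same-strand runs and attach the
# flanking non-coding context up to the neighbouring runs' gene edges (the
# full gap is shared by both neighbours; the rule is exactly symmetric under
# reverse complement). `core` is the span of the run's own genes.
#' @noRd
strand_groups <- function(genes, L) {
  if (nrow(genes) == 0L) return(list())
  genes <- genes[order(genes$start), , drop = FALSE]
  run_id <- cumsum(c(1L, genes$strand[-1L] != genes$strand[-nrow(genes)]))
  groups <- list()
  for (g in unique(run_id)) {
    rows <- genes[run_id == g, , drop = FALSE]
    core <- c(min(rows$start), max(rows$end))
    prev_end <- if (g == 1L) 0L else max(genes$end[run_id == g - 1L])
    next_start <- if (g == max(run_id)) L + 1L else min(genes$start[run_id == g + 1L])
    groups[[g]] <- list(start = prev_end + 1L, end = next_start - 1L,
                        strand = rows$strand[1L], core = core)
  }
  groups
}

#' Run the full frameshift-detection pipeline
#'
#' @param records List of sequence records (as from [read_fasta()]), or a
#'   named character vector of sequences.
#' @param family A `heuristic_family` from [fit_family()] or [read_family()].
#' @param params Decoder parameters ([decoder_params()]); `p_fs` here is the
#'   step-2 frame-switch prior (step 1 always uses `p_fs = 0`).
#' @param cfg Filter configuration ([filter_config()]).
#' @param rbs RBS model for Filter I ([rbs_model()]).
#' @param enabled Filters enabled for removal; `character(0)` disables
#'   filtering (all raw step-2 calls are kept).
#' @return List of data.frames `genes` and `frameshifts` in source
#'   coordinates, keyed by `fragment_id`. Frameshift rows carry
#'   `filters_failed` and `kept`; gene rows are the merged set (step-1 genes,
#'   with genes overlapping a surviving frameshift replaced by the
#'   frameshifted step-2 gene call).
#' @export
run_pipeline <- function(records, family, params = decoder_params(),
                         cfg = filter_config(), rbs = rbs_model(),
                         enabled = c("I", "II", "III")) {
  if (is.character(records)) {
    ids <- if (is.null(names(records))) paste0("seq", seq_along(records)) else names(records)
    records <- lapply(seq_along(records), function(i) {
      list(id = ids[i], seq = unname(records[i]), length = nchar(records[i]))
    })
  }
  params0 <- params
  params0$p_fs <- 0

  all_genes <- list()
  all_fs <- list()
  model_cache <- new.env(parent = emptyenv())
  get_models <- function(theta) {
    key <- sprintf("%.6f", theta)
    if (is.null(model_cache[[key]])) {
      m1 <- model_for_gc(family, theta, params0)
      m2 <- model_for_gc(family, theta, params)
      model_cache[[key]] <- list(step1 = m1, space1 = build_state_space(m1),
                                 step2 = m2, space2 = build_state_space(m2))
    }
    model_cache[[key]]
  }

  for (rec in records) {
    L <- nchar(rec$seq)
    if (L < 6L) {
      warning("sequence ", rec$id, " shorter than 6 nt; skipped")
      next
    }
    theta <- tryCatch(gc_percent(rec$seq), error = function(e) NA_real_)
    if (is.na(theta)) {
      warning("sequence ", rec$id, " has undefined GC content; skipped")
      next
    }
    mods <- get_models(theta)

    dec1 <- viterbi_decode(rec$seq, mods$step1, mods$space1)
    calls1 <- calls_from_path(dec1$path, mods$space1, emissions = dec1$emissions)
    genes1 <- calls1$genes
    if (nrow(genes1) == 0L) next

    groups <- strand_groups(genes1, L)
    fs_rows <- list()
    for (grp in groups) {
      wseq <- substr(rec$seq, grp$start, grp$end)
      if (grp$strand == "-") wseq <- revcomp(wseq)
      if (nchar(wseq) < 6L) next
      det <- detect_frameshifts(wseq, mods$step2, mods$space2)
      if (nrow(det$frameshifts) == 0L) next
      fs <- apply_filters(det, wseq, theta, rbs, cfg, enabled)
      for (i in seq_len(nrow(fs))) {
        f <- fs[i, ]
        g <- det$genes[f$gene, ]
        # source coordinates
        src <- sort(map_back(c(g$start, g$end), grp))
        gene_src <- data.frame(
          fragment_id = rec$id, start = src[1L], end = src[2L],
          strand = if (grp$strand == "+") f$strand else chartr("+-", "-+", f$strand),
          score = g$score, n_segments = g$n_segments,
          truncated_left = if (grp$strand == "+") g$truncated_left else g$truncated_right,
          truncated_right = if (grp$strand == "+") g$truncated_right else g$truncated_left,
          stringsAsFactors = FALSE)
        # drop calls that fall wholly outside this group's own gene span
        # (the shared flanks belong to the neighbouring group)
        if (gene_src$end < grp$core[1L] || gene_src$start > grp$core[2L]) next
        pos_src <- if (grp$strand == "+") f$pos + grp$start - 1L else grp$end - f$pos
        fs_rows[[length(fs_rows) + 1L]] <- cbind(
          data.frame(
            fragment_id = rec$id, pos = pos_src, fs_shift = f$fs_shift,
            strand = gene_src$strand, score = f$score,
            upstream_frame = f$upstream_frame,
            downstream_frame = f$downstream_frame,
            gene_start = gene_src$start, gene_end = gene_src$end,
            filters_failed = f$filters_failed, kept = f$kept,
            stringsAsFactors = FALSE),
          data.frame(gene_score = gene_src$score,
                     gene_n_segments = gene_src$n_segments,
                     gene_truncated_left = gene_src$truncated_left,
                     gene_truncated_right = gene_src$truncated_right))
      }
    }

    fs_df <- if (length(fs_rows)) do.call(rbind, fs_rows) else NULL
    if (!is.null(fs_df) && nrow(fs_df) > 1L) {
      # neighbouring groups share their flanks; a gene spanning the junction
      # can be decoded twice - keep the higher-scoring copy of identical calls
      key <- paste(fs_df$pos, fs_df$strand, fs_df$fs_shift)
      ord <- order(key, -fs_df$score)
      fs_df <- fs_df[ord[!duplicated(key[ord])], , drop = FALSE]
      fs_df <- fs_df[order(fs_df$pos), , drop = FALSE]
    }
    # merged gene set: step-1 genes not overlapping a surviving frameshifted
    # gene, plus the frameshifted step-2 gene calls
    keep_genes <- data.frame(
      fragment_id = rec$id, start = genes1$start, end = genes1$end,
      strand = genes1$strand, score = genes1$score,
      n_segments = genes1$n_segments,
      truncated_left = genes1$truncated_left,
      truncated_right = genes1$truncated_right, stringsAsFactors = FALSE)
    if (!is.null(fs_df) && any(fs_df$kept)) {
      k <- fs_df[fs_df$kept, , drop = FALSE]
      repl <- unique(data.frame(
        fragment_id = k$fragment_id, start = k$gene_start, end = k$gene_end,
        strand = k$strand, score = k$gene_score,
        n_segments = k$gene_n_segments,
        truncated_left = k$gene_truncated_left,
        truncated_right = k$gene_truncated_right, stringsAsFactors = FALSE))
      ov <- rep(FALSE, nrow(keep_genes))
      for (j in seq_len(nrow(repl))) {
        ov <- ov | (keep_genes$start <= repl$end[j] & keep_genes$end >= repl$start[j])
      }
      keep_genes <- rbind(keep_genes[!ov, , drop = FALSE], repl)
      keep_genes <- keep_genes[order(keep_genes$start), , drop = FALSE]
    }
    all_genes[[length(all_genes) + 1L]] <- keep_genes
    if (!is.null(fs_df)) {
      fs_df <- fs_df[, !(names(fs_df) %in% c("gene_score", "gene_n_segments",
                                             "gene_truncated_left",
                                             "gene_truncated_right")),
                     drop = FALSE]
      all_fs[[length(all_fs) + 1L]] <- fs_df
    }
  }

  empty_genes <- data.frame(fragment_id = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            score = numeric(0), n_segments = integer(0),
                            truncated_left = logical(0),
                            truncated_right = logical(0))
  empty_fs <- data.frame(fragment_id = character(0), pos = integer(0),
                         fs_shift = integer(0), strand = character(0),
                         score = numeric(0), upstream_frame = integer(0),
                         downstream_frame = integer(0),
                         gene_start = integer(0), gene_end = integer(0),
                         filters_failed = character(0), kept = logical(0))
  list(
    genes = if (length(all_genes)) do.call(rbind, all_genes) else empty_genes,
    frameshifts = if (length(all_fs)) do.call(rbind, all_fs) else empty_fs
  )
}
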
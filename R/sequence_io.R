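#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased on ingest, RNA `U` is mapped to `T`, and any other
#' character outside `{A,C,G,T,N}` is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A list of sequence records; each record is a list with elements
#'   `id` (first whitespace-delimited token of the header), `seq` (character
#'   string over `A,C,G,T,N`) and `length`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)[[1]]$seq
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty FASTA file at line 1: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("format error: line 1 of ", path, " is not a FASTA header")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("format error: no sequences in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  lapply(seq_along(set), function(i) {
    s <- sanitize_seq(as.character(set[[i]]))
    list(id = ids[i], seq = s, length = nchar(s))
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records List of records as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i) {
      list(id = names(records)[i], seq = unname(records[i]))
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    n <- nchar(r$seq)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' GC content of a DNA sequence, in percent
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return GC content \eqn{\theta} on the percentage scale, in `[0, 100]`.
#' @examples
#' gc_percent("ATGCNN") # 50
#' @export
gc_percent <- function(seq) {
  codes <- encode_seq(seq)
  n <- sum(!is.na(codes))
  if (n == 0L) stop("GC content undefined: sequence empty or all-N")
  100 * sum(codes == 1L | codes == 2L, na.rm = TRUE) / n
}

#' Reverse complement
#'
#' @param seq DNA string over `{A,C,G,T,N}`; `N` complements to `N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) stop("invalid characters in sequence: ", substr(bad, 1, 10))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# revcomp on the integer code scale (used in decoder inner paths).
#' @noRd
revcomp_codes <- function(codes) {
  rev(3L - codes)
}

#' Enumerate maximal open reading frames
#'
#' Reports all maximal stop-free stop-to-stop intervals of length at least
#' `min_len` in all six frames, in 1-based inclusive forward-strand
#' coordinates. Intervals running off a fragment end are reported with
#' truncation flags, since metagenomic fragments routinely clip genes.
#'
#' @param seq DNA string.
#' @param min_len Minimum ORF length in nt; must be a positive multiple of 3.
#' @return A data.frame with columns `start`, `end`, `frame` (0,1,2; offset of
#'   the first codon position in the reading strand), `strand`,
#'   `truncated_left`, `truncated_right` (truncation at the 5' / 3' end of the
#'   reading strand).
#' @export
enumerate_orfs <- function(seq, min_len = 90L) {
  stopifnot(min_len >= 3L, min_len %% 3L == 0L)
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    codes <- encode_seq(s)
    stops <- stop_ends(codes)
    for (f in 0:2) {
      # third codon positions in this frame: i with (i - 1 - f) %% 3 == 2
      thirds <- seq.int(f + 3L, L, by = 3L)
      if (f + 3L > L) thirds <- integer(0)
      stop_at <- thirds[stops[thirds]] # last nt of in-frame stop codons
      bounds <- c(f - 2L, stop_at, L + 1L) # virtual stops off both ends
      for (k in seq_len(length(bounds) - 1L)) {
        a <- bounds[k] + 1L       # first nt after the upstream stop
        b <- bounds[k + 1L] - 3L  # last nt before the downstream stop codon
        if (k == length(bounds) - 1L) b <- L # run off the 3' end
        a <- max(a, 1L)
        if (b < a) next
        len <- b - a + 1L
        if (len < min_len) next
        tl <- k == 1L
        tr <- k == length(bounds) - 1L
        if (strand == "+") {
          out[[length(out) + 1L]] <- data.frame(
            start = a, end = b, frame = f, strand = strand,
            truncated_left = tl, truncated_right = tr)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            start = L - b + 1L, end = L - a + 1L, frame = f, strand = strand,
            truncated_left = tl, truncated_right = tr)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      strand = character(0), truncated_left = logical(0),
                      truncated_right = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$frame, res$strand), , drop = FALSE]
}

#' Read CDS annotations from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` returning the flat annotation
#' table the trainer and simulator use.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"CDS"`).
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `feature`.
#' @export
read_gff3 <- function(path, feature = "CDS") {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("read_gff3 requires the rtracklayer and GenomicRanges packages")
  }
  g <- rtracklayer::import(path)
  g <- g[as.character(g$type) %in% feature]
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    feature = as.character(g$type),
    stringsAsFactors = FALSE
  )
}

#' Write gene and frameshift calls as GFF3
#'
#' Genes become `gene` features; frameshifts become single-nucleotide
#' `frameshift` point features with attributes `fs_type`
#' (`insertion-like`/`deletion-like`), `fs_shift`, `score` and
#' `filters_failed`.
#'
#' @param calls A list with data.frames `genes` and `frameshifts`, as returned
#'   by [run_pipeline()].
#' @param path Output path.
#' @param kept_only If `TRUE` (default) write only frameshifts that survived
#'   the enabled filters.
#' @return `path`, invisibly.
#' @export
write_gff3_calls <- function(calls, path, kept_only = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- calls$genes
  fs <- calls$frameshifts
  if (!is.null(fs) && nrow(fs) > 0L && kept_only && "kept" %in% names(fs)) {
    fs <- fs[fs$kept, , drop = FALSE]
  }
  if (!is.null(genes) && nrow(genes) > 0L) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      attrs <- sprintf("ID=gene%04d;truncated_left=%s;truncated_right=%s",
                       i, tolower(g$truncated_left), tolower(g$truncated_right))
      sc <- if (is.na(g$score)) "." else sprintf("%.3f", g$score)
      writeLines(paste(g$fragment_id, "metafs", "gene", g$start, g$end,
                       sc, g$strand, ".", attrs, sep = "\t"), con)
    }
  }
  if (!is.null(fs) && nrow(fs) > 0L) {
    for (i in seq_len(nrow(fs))) {
      x <- fs[i, ]
      type <- if (x$fs_shift > 0) "insertion-like" else "deletion-like"
      ff <- if (nchar(x$filters_failed) == 0L) "none" else x$filters_failed
      attrs <- sprintf("ID=fs%04d;fs_type=%s;fs_shift=%+d;filters_failed=%s",
                       i, type, x$fs_shift, ff)
      writeLines(paste(x$fragment_id, "metafs", "frameshift", x$pos, x$pos,
                       sprintf("%.3f", x$score), x$strand, ".", attrs,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
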
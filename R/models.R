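#' Count coding and non-coding hexamers in an annotated genome
#'
#' Coding hexamers are counted per codon phase: the phase of a hexamer is the
#' codon position (0, 1 or 2) of its last base relative to the reading frame
#' of the CDS it lies in. CDS on the minus strand are reverse-complemented
#' before counting. Non-coding hexamers are counted on both strands of the
#' complement of all CDS intervals (non-coding sequence carries no strand),
#' and every count cell receives a pseudocount of 1.
#'
#' @param record A sequence record (list with `id`, `seq`) as from
#'   [read_fasta()].
#' @param annotation data.frame with columns `seq_id`, `start`, `end`,
#'   `strand`, `feature`; only `CDS` rows are used.
#' @return A list with elements `theta` (genome GC%), `coding` (4096 x 3
#'   count matrix, phases 0..2 in columns), `noncoding` (length-4096 count
#'   vector), `coding_freq`, `noncoding_freq` (relative frequencies per
#'   phase / overall), or `NULL` (with a warning) if the genome has no CDS.
#' @export
count_hexamers <- function(record, annotation) {
  cds <- annotation[annotation$feature == "CDS" &
                      annotation$seq_id == record$id, , drop = FALSE]
  if (nrow(cds) == 0L) {
    warning("genome ", record$id, " has no CDS annotation; skipped")
    return(NULL)
  }
  L <- nchar(record$seq)
  stopifnot(all(cds$start >= 1L), all(cds$end <= L), all(cds$start <= cds$end))
  codes_fwd <- encode_seq(record$seq)

  coding <- matrix(0L, nrow = 4096L, ncol = 3L)
  for (i in seq_len(nrow(cds))) {
    sub <- codes_fwd[cds$start[i]:cds$end[i]]
    if (cds$strand[i] == "-") sub <- revcomp_codes(sub)
    idx <- hex_indices(sub)
    pos <- which(!is.na(idx))
    if (length(pos) == 0L) next
    phase <- (pos - 1L) %% 3L # codon position of the hexamer's last base
    tab <- tabulate(idx[pos] + 4096L * phase, nbins = 3L * 4096L)
    coding <- coding + matrix(tab, nrow = 4096L)
  }

  # complement of CDS intervals
  cov <- rep(FALSE, L)
  for (i in seq_len(nrow(cds))) cov[cds$start[i]:cds$end[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nc <- rep(0L, 4096L)
  for (k in which(!r$values)) {
    sub <- codes_fwd[starts[k]:ends[k]]
    if (length(sub) < 6L) next
    for (ss in list(sub, revcomp_codes(sub))) {
      idx <- hex_indices(ss)
      idx <- idx[!is.na(idx)]
      if (length(idx)) nc <- nc + tabulate(idx, nbins = 4096L)
    }
  }

  coding <- coding + 1L
  nc <- nc + 1L
  list(
    theta = gc_percent(record$seq),
    coding = coding,
    noncoding = nc,
    coding_freq = sweep(coding, 2L, colSums(coding), "/"),
    noncoding_freq = nc / sum(nc)
  )
}

#' Fit a GC-dependent heuristic model family
#'
#' For every hexamer (and, for coding counts, every codon phase) the observed
#' relative frequency across training genomes is regressed on genome GC
#' content with a least-squares polynomial of the given degree (default 5).
#' Instantiating a model for a fragment then only requires the fragment's GC
#' content; see [model_for_gc()].
#'
#' Polynomials are fitted (and stored) on the fractional GC scale
#' `x = theta/100`, which keeps the degree-5 Vandermonde system well
#' conditioned; the user-facing interface is GC% throughout.
#'
#' @param summaries List of per-genome summaries from [count_hexamers()]
#'   (`NULL` entries are dropped).
#' @param degree Polynomial degree in GC (default 5).
#' @return An object of class `heuristic_family`: coefficient arrays
#'   `coding` (4096 x 3 x degree+1) and `noncoding` (4096 x degree+1), the
#'   fitted `theta_range`, and fit metadata.
#' @export
fit_family <- function(summaries, degree = 5L) {
  summaries <- Filter(Negate(is.null), summaries)
  n <- length(summaries)
  need <- if (degree == 0L) 1L else degree + 2L
  if (n < need) {
    stop("fit error: ", n, " training genome(s) for degree ", degree,
         "; need at least ", need, " - lower the degree or add genomes")
  }
  thetas <- vapply(summaries, `[[`, 0, "theta")
  if (degree >= 1L && diff(range(thetas)) < 20) {
    stop("fit error: training GC contents span ",
         round(diff(range(thetas)), 1),
         " percentage points (< 20); degenerate spread - lower the degree")
  }
  # fit on the fractional GC scale: |x| <= 1 keeps the Vandermonde system
  # well conditioned at degree 5
  X <- outer(thetas / 100, 0:degree, `^`)
  qrX <- qr(X)

  coding <- array(NA_real_, dim = c(4096L, 3L, degree + 1L))
  for (p in 1:3) {
    Y <- vapply(summaries, function(s) s$coding_freq[, p], numeric(4096L))
    beta <- qr.coef(qrX, t(Y)) # (degree+1) x 4096
    coding[, p, ] <- t(beta)
  }
  Ync <- vapply(summaries, `[[`, numeric(4096L), "noncoding_freq")
  noncoding <- unname(t(qr.coef(qrX, t(Ync))))

  structure(list(
    coding = coding,
    noncoding = noncoding,
    degree = degree,
    theta_range = range(thetas),
    n_genomes = n,
    thetas = thetas
  ), class = "heuristic_family")
}

#' @export
print.heuristic_family <- function(x, ...) {
  cat("Heuristic hexamer model family\n")
  cat(sprintf("  degree %d polynomials in GC%%, fitted on %d genomes\n",
              x$degree, x$n_genomes))
  cat(sprintf("  GC range covered: %.1f%% - %.1f%%\n",
              x$theta_range[1], x$theta_range[2]))
  invisible(x)
}

#' Decoder parameters attached to an instantiated fragment model
#'
#' @param p_fs Frame-switch probability per coding nucleotide, in `[0, 0.1)`.
#'   `p_fs = 0` turns the decoder into a plain (no-frameshift) gene finder.
#' @param mean_coding_len,mean_noncoding_len Mean state durations in nt for
#'   the geometric duration approximation.
#' @param stop_penalty Log-space penalty (nats) added when an in-frame stop
#'   codon is emitted inside a coding state.
#' @return A named list of validated parameters.
#' @export
decoder_params <- function(p_fs = 1e-3, mean_coding_len = 900,
                           mean_noncoding_len = 150, stop_penalty = -25) {
  stopifnot(p_fs >= 0, p_fs < 0.1,
            mean_coding_len > 1, mean_noncoding_len > 1, stop_penalty <= 0)
  if (p_fs + 1 / mean_coding_len >= 1) {
    stop("config error: p_fs plus coding exit probability exceeds 1")
  }
  list(p_fs = p_fs, mean_coding_len = mean_coding_len,
       mean_noncoding_len = mean_noncoding_len, stop_penalty = stop_penalty)
}

#' Instantiate a fragment model at a given GC content
#'
#' Evaluates every polynomial of the family at `theta` (clamped to the fitted
#' GC range for extrapolation), clamps frequencies to `[1e-6, 1]`,
#' renormalizes each next-base conditional distribution (per 5-mer context,
#' per phase) to sum to 1 and stores the logs, together with the decoder
#' parameters.
#'
#' @param family A `heuristic_family` from [fit_family()].
#' @param theta Fragment GC content in percent, in `[0, 100]`.
#' @param params Decoder parameters from [decoder_params()].
#' @return An object of class `fragment_model` with matrices `coding_logp`
#'   (4096 x 3: log P(base 6 | bases 1..5, phase of base 6)) and
#'   `noncoding_logp` (length 4096), plus `theta` and `params`.
#' @export
model_for_gc <- function(family, theta, params = decoder_params()) {
  stopifnot(inherits(family, "heuristic_family"))
  if (!is.finite(theta) || theta < 0 || theta > 100) {
    stop("theta must be a GC percentage in [0, 100], got ", theta)
  }
  th <- min(max(theta, family$theta_range[1]), family$theta_range[2])
  powers <- (th / 100)^(0:family$degree)

  cond_from_freq <- function(freq) {
    f <- pmin(pmax(freq, 1e-6), 1)
    # contexts are contiguous blocks of 4 because the last base varies fastest
    tot <- rep(colSums(matrix(f, nrow = 4L)), each = 4L)
    log(f / tot)
  }

  coding_logp <- matrix(NA_real_, 4096L, 3L)
  for (p in 1:3) {
    freq <- as.vector(matrix(family$coding[, p, ], ncol = family$degree + 1L) %*% powers)
    coding_logp[, p] <- cond_from_freq(freq)
  }
  nc_freq <- as.vector(family$noncoding %*% powers)

  structure(list(
    theta = theta,
    coding_logp = coding_logp,
    noncoding_logp = as.vector(cond_from_freq(nc_freq)),
    params = params
  ), class = "fragment_model")
}

#' @export
print.fragment_model <- function(x, ...) {
  cat(sprintf("Fragment model at GC = %.1f%% (p_fs = %g, durations %g/%g nt)\n",
              x$theta, x$params$p_fs, x$params$mean_coding_len,
              x$params$mean_noncoding_len))
  invisible(x)
}

#' Write a model family to a TSV file with a JSON sidecar
#'
#' The TSV holds one row per (hexamer, phase) with columns `hexamer`, `phase`
#' (0..2 for coding, `nc` for non-coding) and `c0..c<degree>` (polynomial
#' coefficients on the fractional GC scale `x = theta/100`) printed at full
#' double precision; the `.json` sidecar carries the fit metadata. The format
#' is diff-able and language neutral, and the round trip is bit identical.
#'
#' @param family A `heuristic_family`.
#' @param path Output TSV path; the sidecar is written at `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  hex <- all_hexamers()
  deg <- family$degree
  fmt <- function(m) apply(m, 2L, function(col) sprintf("%.17g", col))
  rows <- character(0)
  header <- paste(c("hexamer", "phase", paste0("c", 0:deg)), collapse = "\t")
  for (p in 1:3) {
    m <- fmt(matrix(family$coding[, p, ], ncol = deg + 1L))
    rows <- c(rows, paste(hex, p - 1L, apply(m, 1L, paste, collapse = "\t"),
                          sep = "\t"))
  }
  mnc <- fmt(family$noncoding)
  rows <- c(rows, paste(hex, "nc", apply(mnc, 1L, paste, collapse = "\t"),
                        sep = "\t"))
  writeLines(c(header, rows), path)
  meta <- list(degree = deg, theta_range = family$theta_range,
               n_genomes = family$n_genomes, thetas = family$thetas)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a model family written by [write_family()]
#'
#' @param path TSV path (the `.json` sidecar must sit next to it).
#' @return A `heuristic_family`.
#' @export
read_family <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  deg <- meta$degree
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          rep("numeric", deg + 1L)))
  hex <- all_hexamers()
  coding <- array(NA_real_, dim = c(4096L, 3L, deg + 1L))
  for (p in 1:3) {
    sub <- tab[tab$phase == as.character(p - 1L), , drop = FALSE]
    sub <- sub[match(hex, sub$hexamer), , drop = FALSE]
    coding[, p, ] <- as.matrix(sub[, paste0("c", 0:deg)])
  }
  sub <- tab[tab$phase == "nc", , drop = FALSE]
  sub <- sub[match(hex, sub$hexamer), , drop = FALSE]
  structure(list(
    coding = coding,
    noncoding = unname(as.matrix(sub[, paste0("c", 0:deg)])),
    degree = deg,
    theta_range = meta$theta_range,
    n_genomes = meta$n_genomes,
    thetas = meta$thetas
  ), class = "heuristic_family")
}
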
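# Internal 5-letter DNA alphabet utilities. Bases are encoded A=0, C=1, G=2,
# T=3, N=NA so that complement is 3 - code and a hexamer index is a base-4
# number with the most 5' base most significant.

.CODE_LOOKUP <- local({
  lk <- rep(NA_integer_, 256)
  lk[utf8ToInt("A")] <- 0L
  lk[utf8ToInt("C")] <- 1L
  lk[utf8ToInt("G")] <- 2L
  lk[utf8ToInt("T")] <- 3L
  lk
})

.HEX_WEIGHTS <- c(1L, 4L, 16L, 64L, 256L, 1024L)

#' @noRd
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .CODE_LOOKUP[utf8ToInt(seq)]
}

#' @noRd
decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- c("A", "C", "G", "T")[codes[ok] + 1L]
  paste(out, collapse = "")
}

# Clean raw sequence text on ingest: uppercase, RNA U -> T, anything outside
# {A,C,G,T,N} -> N.
#' @noRd
sanitize_seq <- function(seq) {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  gsub("[^ACGTN]", "N", s)
}

# Hexamer index (1..4096) of the 6-mer ending at each position; NA for the
# first five positions and wherever the window contains an N.
#' @noRd
hex_indices <- function(codes) {
  L <- length(codes)
  idx <- rep(NA_integer_, L)
  if (L < 6L) return(idx)
  emb <- embed(codes, 6L) # row j = codes[j+5], codes[j+4], ..., codes[j]
  idx[6:L] <- as.integer(emb %*% .HEX_WEIGHTS) + 1L
  idx
}

# Hexamer index from explicit 6 base codes (most 5' first).
#' @noRd
hex_index1 <- function(codes6) {
  sum(codes6 * rev(.HEX_WEIGHTS)) + 1L
}

# All 4096 hexamer strings in index order (last base varies fastest).
#' @noRd
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b6 = b, b5 = b, b4 = b, b3 = b, b2 = b, b1 = b,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)
}

# TRUE at positions i where codes[i-2..i] spell a stop codon (TAA, TAG, TGA).
#' @noRd
stop_ends <- function(codes) {
  L <- length(codes)
  out <- rep(FALSE, L)
  if (L < 3L) return(out)
  i <- 3:L
  c1 <- codes[i - 2L]; c2 <- codes[i - 1L]; c3 <- codes[i]
  hit <- !is.na(c1) & !is.na(c2) & !is.na(c3) & c1 == 3L &
    ((c2 == 0L & (c3 == 0L | c3 == 2L)) | (c2 == 2L & c3 == 0L))
  out[i] <- hit
  out
}
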
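# 2-bit k-mer codec and window decomposition.
#
# A k-mer over {A,C,G,T} is packed into a single numeric code with A=0, C=1,
# G=2, T=3, the first base occupying the highest-order bit pair.  For the
# default k = 16 the code range is [0, 4^16), which exceeds .Machine$integer.max
# but is represented exactly as a double (< 2^53).  Codes are used as store
# keys after formatting with `kmer_key()`.

# byte -> 2-bit value lookup; NA for anything that is not A/C/G/T (case-insensitive)
.BASE_VALS <- local({
  v <- rep(NA_real_, 256L)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("a")] <- 0
  v[utf8ToInt("C")] <- 1; v[utf8ToInt("c")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("g")] <- 2
  v[utf8ToInt("T")] <- 3; v[utf8ToInt("t")] <- 3
  v
})

.BASES <- c("A", "C", "G", "T")

# data.frame constructor without the checking overhead (hot path: per read)
fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}

# numeric 2-bit values of a DNA string; NA marks ambiguous characters
seq_base_vals <- function(seq) {
  .BASE_VALS[utf8ToInt(seq)]
}

#' Pack a k-mer into a 2-bit-per-base integer code
#'
#' Encodes a DNA string of length `k` over the alphabet `{A,C,G,T}`
#' (case-insensitive) as a single numeric code with `A=0, C=1, G=2, T=3`,
#' the first base in the highest-order bit pair.  The encoding is injective
#' on `{A,C,G,T}^k` and the code satisfies `0 <= code < 4^k`.
#'
#' @param seq Character scalar, the k-mer.
#' @param k k-mer length; defaults to `nchar(seq)`.
#' @return Numeric scalar code.  Signals an error of class
#'   `tapir_unencodable` for ambiguous characters (anything outside ACGT),
#'   so callers can skip such windows.
#' @seealso [decode_kmer()]
#' @export
#' @examples
#' encode_kmer(strrep("A", 16))   # 0
#' encode_kmer("ACGT")            # 0*64 + 1*16 + 2*4 + 3
encode_kmer <- function(seq, k = nchar(seq)) {
  if (nchar(seq) != k)
    stop("k-mer has length ", nchar(seq), ", expected ", k)
  vals <- seq_base_vals(seq)
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    stop(structure(
      class = c("tapir_unencodable", "error", "condition"),
      list(message = sprintf("unencodable k-mer: non-ACGT character at position %d of '%s'",
                             bad[1L], seq),
           call = sys.call(-1L))))
  }
  sum(vals * 4^((k - 1L):0))
}

#' Unpack a 2-bit k-mer code back into a DNA string
#'
#' Inverse of [encode_kmer()]: `decode_kmer(encode_kmer(s), nchar(s)) == s`
#' for any `s` over `{A,C,G,T}`.
#'
#' @param code Numeric code in `[0, 4^k)`.
#' @param k k-mer length.
#' @return Character scalar of length `k`.
#' @export
decode_kmer <- function(code, k) {
  if (code < 0 || code >= 4^k)
    stop("code ", format(code, scientific = FALSE), " out of range for k = ", k)
  out <- character(k)
  for (i in k:1) {
    out[i] <- .BASES[code %% 4 + 1]
    code <- code %/% 4
  }
  paste0(out, collapse = "")
}

# canonical store key for a code (decimal text; codes exceed 32-bit integers)
kmer_key <- function(code) {
  sprintf("%.0f", code)
}

# Codes of all k-windows of `vals` (2-bit values, NA = ambiguous) starting at
# the 1-based offsets `starts`.  Windows touching an NA yield NA.
codes_at <- function(vals, starts, k) {
  if (length(starts) == 0L) return(numeric(0))
  pow <- 4^((k - 1L):0)
  idx <- outer(0:(k - 1L), starts, `+`)
  colSums(matrix(vals[idx], nrow = k) * pow)
}

#' Non-overlapping (stride-k, "in phase") k-mer decomposition
#'
#' Splits a sequence into consecutive non-overlapping k-mers at positions
#' `0, k, 2k, ...` (0-based).  This is the decomposition used when indexing
#' references.  Windows containing any non-ACGT character are skipped (the
#' position still advances by k), and a trailing remainder shorter than k is
#' dropped.
#'
#' @param sequence DNA string.
#' @param k k-mer length.
#' @return A data frame with columns `code` (numeric k-mer code) and
#'   `pos` (0-based start, always a multiple of `k`).
#' @export
nonoverlapping_kmers <- function(sequence, k = 16L) {
  k <- as.integer(k)
  n <- nchar(sequence)
  if (n < k)
    return(fast_df(code = numeric(0), pos = integer(0)))
  starts <- seq.int(1L, n - k + 1L, by = k)
  vals <- seq_base_vals(sequence)
  codes <- codes_at(vals, starts, k)
  keep <- !is.na(codes)
  fast_df(code = codes[keep], pos = starts[keep] - 1L)
}

#' Overlapping (sliding-window) k-mer decomposition
#'
#' Slides a window of width `k` one base at a time across a read, yielding
#' k-mers at every offset `0 .. nchar(read) - k`.  This is the decomposition
#' used on the query side: only the windows that happen to be in phase with
#' the stride-k index can match, and the overlapping enumeration guarantees
#' one of them is, whatever the offset of the read on the reference.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param read DNA string.
#' @param k k-mer length.
#' @return A data frame with columns `code` and `offset` (0-based offset in
#'   the read).  Empty for reads shorter than `k`.
#' @export
overlapping_kmers <- function(read, k = 16L) {
  k <- as.integer(k)
  n <- nchar(read)
  if (n < k)
    return(fast_df(code = numeric(0), offset = integer(0)))
  starts <- 1L:(n - k + 1L)
  vals <- seq_base_vals(read)
  codes <- codes_at(vals, starts, k)
  keep <- !is.na(codes)
  fast_df(code = codes[keep], offset = starts[keep] - 1L)
}

#' Reverse complement of DNA strings
#'
#' @param seq Character vector of DNA strings (IUPAC ambiguity codes other
#'   than N are not expected; A/C/G/T/N and lowercase are handled).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}
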
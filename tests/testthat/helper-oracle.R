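# Brute-force reference scorer used as an independent oracle.
#
# No k-mer packing, no key-value stores: k-mers are plain strings, matching
# is direct substring comparison against the stride-k tiling of each
# reference, clustering and counting follow the documented scoring
# semantics.  Deliberately simple and slow; only run on toy instances.

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

oracle_stride_tiles <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(data.frame(kmer = character(0), pos = integer(0)))
  starts <- seq.int(1L, n - k + 1L, by = k)
  kmer <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmer)
  data.frame(kmer = kmer[keep], pos = starts[keep] - 1L)
}

oracle_overlap_kmers <- function(read, k) {
  read <- toupper(read)
  n <- nchar(read)
  if (n < k) return(character(0))
  kmer <- substring(read, 1:(n - k + 1L), k:n)
  kmer[!grepl("[^ACGT]", kmer)]
}

# largest (leftmost on ties) cluster of sorted positions under a gap tolerance
oracle_best_cluster <- function(pos, kmers, gap) {
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  sizes <- diff(brk)
  best <- which.max(sizes)
  sel <- (brk[best] + 1L):brk[best + 1L]
  list(size = sizes[best], kmers = unique(kmers[sel]))
}

# per-read, per-reference retained cluster for one orientation
oracle_orientation <- function(read, tiles, gap, k) {
  q <- unique(oracle_overlap_kmers(read, k))
  lapply(tiles, function(t) {
    m <- t$kmer %in% q
    if (!any(m)) return(NULL)
    oracle_best_cluster(t$pos[m], t$kmer[m], gap)
  })
}

oracle_score <- function(reads, refs, k = 16L, gap = 2L * k, min_cluster = 2L,
                         weights = c(0.5, 0.5), top_n = 25L) {
  reads <- toupper(reads)
  denom <- length(unique(unlist(lapply(reads, function(r)
    oracle_stride_tiles(r, k)$kmer), use.names = FALSE)))
  tiles <- lapply(refs, oracle_stride_tiles, k = k)
  counted <- lapply(refs, function(...) character(0))
  counts <- setNames(numeric(length(refs)), names(refs))
  for (read in reads) {
    fwd <- oracle_orientation(read, tiles, gap, k)
    rev <- oracle_orientation(oracle_revcomp(read), tiles, gap, k)
    for (ref in names(refs)) {
      f <- fwd[[ref]]; r <- rev[[ref]]
      pick <- if (is.null(r)) f
              else if (is.null(f)) r
              else if (r$size > f$size) r else f
      if (is.null(pick) || pick$size < min_cluster) next
      new <- setdiff(pick$kmers, counted[[ref]])
      counts[ref] <- counts[ref] + length(new)
      counted[[ref]] <- c(counted[[ref]], new)
    }
  }
  found <- names(counts)[counts > 0]
  if (length(found) == 0L)
    return(data.frame(ref_id = character(0), count = integer(0),
                      query_score = numeric(0), ref_score = numeric(0),
                      combined = numeric(0), rank = integer(0)))
  hits <- data.frame(ref_id = found,
                     count = as.integer(counts[found]),
                     query_score = counts[found] / denom,
                     ref_score = counts[found] /
                       (nchar(refs[found]) %/% k),
                     row.names = NULL)
  hits$combined <- weights[1] * hits$query_score + weights[2] * hits$ref_score
  hits <- hits[order(-hits$combined, -hits$ref_score, hits$ref_id), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  head(hits, top_n)
}
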
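# Read-set scoring by overlapping k-mer lookup and positional clustering.
#
# Each read is decomposed into overlapping k-mers, looked up in the presence
# store, and for every candidate reference the matched in-phase positions are
# sorted and split into clusters wherever the gap between consecutive
# positions exceeds a tolerance.  Only the largest cluster per (read,
# reference) is kept -- scattered isolated matches, e.g. a bacterial read
# against a mammalian genome, form no cluster and are discarded.  Cluster
# k-mers are then counted per reference (each distinct k-mer at most once per
# reference across the whole query set) and two normalized scores are formed:
#   query_score = count / unique stride-k k-mers of the query set  (1.0 when
#                 the query tiles the whole reference)
#   ref_score   = count / indexed k-mer count of the reference     (guards
#                 against large-reference bias)
# The hit list is ranked by their weighted sum.

#' Construct a read set
#'
#' Bundles reads with the denominator used by the query-coverage score: the
#' number of distinct k-mer codes in the stride-k (non-overlapping)
#' decomposition of all reads.  Only in-phase k-mers can match a stride-k
#' index, so this denominator makes "query tiles the whole reference" score
#' exactly 1; an overlapping-k-mer denominator could never reach 1.
#'
#' @param sequences Character vector of read sequences.
#' @param ids Optional read ids (default `read1 ... readN`).
#' @param k k-mer length used for the denominator (must match the index).
#' @return An object of class `tapir_read_set`: list with `ids`, `sequences`,
#'   `unique_query_kmers`, `k`.
#' @export
read_set <- function(sequences, ids = NULL, k = 16L) {
  stopifnot(is.character(sequences))
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(sequences))
  stopifnot(length(ids) == length(sequences))
  codes <- unlist(lapply(sequences, function(s) nonoverlapping_kmers(s, k)$code),
                  use.names = FALSE)
  structure(list(ids = ids,
                 sequences = toupper(sequences),
                 unique_query_kmers = length(unique(codes)),
                 k = as.integer(k)),
            class = "tapir_read_set")
}

as_read_set <- function(reads, k = 16L) {
  if (inherits(reads, "tapir_read_set")) {
    if (reads$k != k)
      stop("read set was built with k = ", reads$k, ", index has k = ", k)
    return(reads)
  }
  read_set(reads, k = k)
}

#' @export
print.tapir_read_set <- function(x, ...) {
  cat(sprintf("tapir_read_set: %d reads, %d unique stride-%d k-mers\n",
              length(x$sequences), x$unique_query_kmers, x$k))
  invisible(x)
}

# cluster positions/codes for one orientation of one read against all
# candidate references; returns a named list ref_id -> list(size, pos, codes)
.match_orientation <- function(seq, index, gap_tolerance) {
  k <- index$k
  km <- overlapping_kmers(seq, k)
  if (nrow(km) == 0L) return(list())
  codes <- unique(km$code)
  keys <- kmer_key(codes)
  hits <- mget(keys, envir = index$presence, ifnotfound = list(NULL))
  found <- !vapply(hits, is.null, TRUE)
  if (!any(found)) return(list())
  codes <- codes[found]
  keys <- keys[found]
  refs_per_code <- hits[found]
  ref_ids <- unique(unlist(refs_per_code, use.names = FALSE))

  out <- vector("list", length(ref_ids))
  names(out) <- ref_ids
  for (ref in ref_ids) {
    in_ref <- vapply(refs_per_code, function(r) ref %in% r, TRUE)
    pkeys <- pos_key(keys[in_ref], ref)
    plists <- mget(pkeys, envir = index$positions, ifnotfound = list(integer(0)))
    np <- lengths(plists)
    pos <- unlist(plists, use.names = FALSE)
    code_at <- rep(codes[in_ref], np)
    ord <- order(pos)
    pos <- pos[ord]
    code_at <- code_at[ord]
    # split into clusters where the gap between consecutive positions
    # exceeds the tolerance; keep the leftmost maximal cluster
    brk <- c(0L, which(diff(pos) > gap_tolerance), length(pos))
    sizes <- diff(brk)
    best <- which.max(sizes)  # leftmost of the maximal clusters
    sel <- (brk[best] + 1L):brk[best + 1L]
    out[[ref]] <- list(size = sizes[best], positions = pos[sel],
                       codes = unique(code_at[sel]))
  }
  out
}

#' Match one read against the index by positional k-mer clustering
#'
#' Looks up all overlapping k-mers of the read (and of its reverse
#' complement) in the presence store; for each candidate reference, collects
#' the matched in-phase positions, sorts them, splits them into clusters
#' wherever the gap between consecutive positions exceeds `gap_tolerance`,
#' and retains the largest cluster (leftmost on ties).  The orientation with
#' the larger best cluster is kept per reference (forward on ties), and
#' references whose best cluster is smaller than `min_cluster` are dropped.
#'
#' @param read DNA string.
#' @param index A `tapir_index`.
#' @param gap_tolerance Maximum gap (bases) between consecutive matched
#'   positions within a cluster; default `2 * k`, i.e. one missing in-between
#'   k-mer is tolerated.
#' @param min_cluster Minimum retained cluster size (matched k-mers); default 2.
#' @return A list of read matches, each a list with `ref_id`,
#'   `cluster_positions` (sorted, gaps `<= gap_tolerance`), `matched_kmers`
#'   (distinct k-mer codes in the cluster), `cluster_size` and `orientation`
#'   (`"+"` or `"-"`).  Empty list when nothing matches.
#' @export
match_read <- function(read, index, gap_tolerance = 2L * index$k,
                       min_cluster = 2L) {
  stopifnot(inherits(index, "tapir_index"))
  read <- toupper(read)
  fwd <- .match_orientation(read, index, gap_tolerance)
  rev <- .match_orientation(revcomp(read), index, gap_tolerance)
  refs <- union(names(fwd), names(rev))
  out <- list()
  for (ref in refs) {
    f <- fwd[[ref]]; r <- rev[[ref]]
    pick <- if (is.null(r)) f
            else if (is.null(f)) r
            else if (r$size > f$size) r else f  # forward wins ties
    orientation <- if (is.null(f) || (!is.null(r) && r$size > f$size)) "-" else "+"
    if (pick$size >= min_cluster)
      out[[length(out) + 1L]] <- list(ref_id = ref,
                                      cluster_positions = pick$positions,
                                      matched_kmers = pick$codes,
                                      cluster_size = pick$size,
                                      orientation = orientation)
  }
  out
}

#' Score a query read set against the index and rank the references
#'
#' Runs [match_read()] on every read and accumulates, per reference, the
#' number of matched k-mers in retained clusters.  A per-reference set of
#' already-counted k-mer codes ensures each distinct k-mer contributes at
#' most once per reference across the whole query set (so `ref_score <= 1`
#' and counts are additive over mixtures).  Each reference then receives
#' `query_score = count / unique_query_kmers`,
#' `ref_score = count / indexed_kmer_count`, and
#' `combined = w1 * query_score + w2 * ref_score`; the hit list is sorted by
#' `combined` and truncated to `top_n`.
#'
#' @param reads A `tapir_read_set` or character vector of read sequences.
#' @param index A `tapir_index`.
#' @param weights Numeric length-2 `(w1, w2)`, non-negative, not both zero;
#'   default equal weights `c(0.5, 0.5)`.
#' @param top_n Maximum hit-list length (default 25).
#' @param gap_tolerance,min_cluster Passed to [match_read()].
#' @return A data frame of hits: `ref_id`, `description`, `count`,
#'   `query_score`, `ref_score`, `combined`, `rank`, ordered by rank.  Zero
#'   rows when nothing in the index matches (a valid result for novel DNA).
#' @export
score_query_set <- function(reads, index, weights = c(0.5, 0.5), top_n = 25L,
                            gap_tolerance = 2L * index$k, min_cluster = 2L) {
  stopifnot(inherits(index, "tapir_index"),
            length(weights) == 2L, all(weights >= 0), any(weights > 0))
  reads <- as_read_set(reads, index$k)
  if (length(reads$sequences) == 0L) stop("no reads to score")

  counts <- new.env(parent = emptyenv())
  counted <- new.env(parent = emptyenv())  # ref -> env of counted code keys
  for (seq in reads$sequences) {
    for (m in match_read(seq, index, gap_tolerance, min_cluster)) {
      ref <- m$ref_id
      seen <- counted[[ref]]
      if (is.null(seen)) {
        seen <- new.env(parent = emptyenv())
        counted[[ref]] <- seen
        counts[[ref]] <- 0
      }
      new_keys <- kmer_key(m$matched_kmers)
      new_keys <- new_keys[!vapply(new_keys, function(kk)
        !is.null(seen[[kk]]), TRUE)]
      if (length(new_keys)) {
        counts[[ref]] <- counts[[ref]] + length(new_keys)
        for (kk in new_keys) seen[[kk]] <- TRUE
      }
    }
  }

  ref_ids <- ls(counts)
  if (length(ref_ids) == 0L) return(empty_hits())
  count <- vapply(ref_ids, function(r) counts[[r]], 0)
  recs <- lapply(ref_ids, function(r) index$catalog[[r]])
  ikc <- vapply(recs, `[[`, 0L, "indexed_kmer_count")
  hits <- data.frame(
    ref_id = ref_ids,
    description = vapply(recs, `[[`, "", "description"),
    count = as.integer(count),
    query_score = count / reads$unique_query_kmers,
    ref_score = count / ikc,
    row.names = NULL)
  hits$combined <- weights[1L] * hits$query_score + weights[2L] * hits$ref_score
  hits <- rank_hits(hits)
  utils::head(hits, top_n)
}

empty_hits <- function() {
  data.frame(ref_id = character(0), description = character(0),
             count = integer(0), query_score = numeric(0),
             ref_score = numeric(0), combined = numeric(0), rank = integer(0))
}

#' Order a hit table and assign ranks
#'
#' Stable ordering by `combined` descending, ties broken by `ref_score`
#' descending then `ref_id` ascending, so the ranking is a deterministic
#' function of the scores and independent of input order.
#'
#' @param hits Data frame with columns `ref_id`, `combined`, `ref_score`.
#' @return The same data frame ordered, with `rank` set to `1..nrow`.
#' @export
rank_hits <- function(hits) {
  ord <- order(-hits$combined, -hits$ref_score, hits$ref_id)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Write a hit table to JSON or TSV
#'
#' @param hits Hit data frame from [score_query_set()].
#' @param path Output file; format chosen by extension (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(hits, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
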
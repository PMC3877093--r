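# Client-side identification loop: sample reads, query a backend, fetch the
# top candidate references, align all unmapped reads against each, keep the
# reference minimizing the unmapped count, and recurse on the remainder.

#' Sampling plan for read queries
#'
#' @param sample_size Reads per query (default 100).
#' @param seed RNG seed; the same seed and input always give the same sample.
#' @return A list of class `tapir_sampling_plan`.
#' @export
sampling_plan <- function(sample_size = 100L, seed = 1L) {
  stopifnot(sample_size >= 1)
  structure(list(sample_size = as.integer(sample_size), seed = as.integer(seed)),
            class = "tapir_sampling_plan")
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is detected from the first non-empty character (`@` FASTQ, `>`
#' FASTA); gzipped files are handled.  Qualities are ignored (scoring uses
#' none).
#'
#' @param path File path.
#' @return A `tapir_read_set`.
#' @export
read_reads <- function(path) {
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("no reads in '", path, "'")
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(set) == 0L) stop("no reads in '", path, "'")
  read_set(as.character(set),
           ids = vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L))
}

# Reservoir sampling (Algorithm R): feed records one at a time; each of the
# first i records survives in the n-slot reservoir with probability n/i, so
# the final sample is uniform without replacement in a single pass.
new_reservoir <- function(n) {
  env <- new.env(parent = emptyenv())
  env$ids <- character(n); env$seqs <- character(n)
  env$n <- n; env$seen <- 0L
  env
}

reservoir_feed <- function(res, ids, seqs) {
  for (j in seq_along(ids)) {
    res$seen <- res$seen + 1L
    if (res$seen <= res$n) {
      res$ids[res$seen] <- ids[j]; res$seqs[res$seen] <- seqs[j]
    } else {
      slot <- sample.int(res$seen, 1L)
      if (slot <= res$n) {
        res$ids[slot] <- ids[j]; res$seqs[slot] <- seqs[j]
      }
    }
  }
}

reservoir_result <- function(res) {
  keep <- seq_len(min(res$seen, res$n))
  list(ids = res$ids[keep], seqs = res$seqs[keep])
}

# stream a FASTA/FASTQ file record by record into a callback(ids, seqs)
stream_reads <- function(path, callback, chunk_lines = 40000L) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("no reads in '", path, "'")
  if (startsWith(first, "@")) {
    pending <- first
    repeat {
      lines <- c(pending, readLines(con, n = chunk_lines))
      pending <- character(0)
      if (length(lines) == 0L) break
      nrec <- length(lines) %/% 4L
      if (nrec == 0L) stop("truncated FASTQ record in '", path, "'")
      rem <- length(lines) - nrec * 4L
      if (rem > 0L) {
        pending <- lines[(nrec * 4L + 1L):length(lines)]
        lines <- lines[seq_len(nrec * 4L)]
      }
      m <- matrix(lines, nrow = 4L)
      ids <- sub("^@", "", vapply(strsplit(m[1L, ], "[ \t]+"), `[`, "", 1L))
      callback(ids, m[2L, ])
      if (rem == 0L && length(lines) < chunk_lines) {
        nxt <- readLines(con, n = 1L)
        if (length(nxt) == 0L) break
        pending <- nxt
      }
    }
  } else {
    # FASTA: accumulate (possibly wrapped) records across chunk boundaries
    id <- sub("^>", "", strsplit(first, "[ \t]+")[[1L]][1L])
    seq_parts <- character(0)
    repeat {
      lines <- readLines(con, n = chunk_lines)
      if (length(lines) == 0L) break
      for (line in lines) {
        if (startsWith(line, ">")) {
          callback(id, paste(seq_parts, collapse = ""))
          id <- sub("^>", "", strsplit(line, "[ \t]+")[[1L]][1L])
          seq_parts <- character(0)
        } else {
          seq_parts <- c(seq_parts, line)
        }
      }
    }
    callback(id, paste(seq_parts, collapse = ""))
  }
}

#' Draw a uniform random sample of reads
#'
#' Uniform sampling without replacement by single-pass reservoir sampling, so
#' arbitrarily large read files need not fit in memory.  When fewer reads
#' exist than requested, all of them are returned.  Deterministic under the
#' plan's seed.
#'
#' @param source A FASTA/FASTQ path, a `tapir_read_set`, or a character
#'   vector of sequences.
#' @param plan A [sampling_plan()].
#' @return A `tapir_read_set` of at most `plan$sample_size` reads.
#' @export
sample_reads <- function(source, plan = sampling_plan()) {
  stopifnot(inherits(plan, "tapir_sampling_plan"))
  res <- new_reservoir(plan$sample_size)
  withr::with_seed(plan$seed, {
    if (is.character(source) && length(source) == 1L && file.exists(source)) {
      stream_reads(source, function(ids, seqs) reservoir_feed(res, ids, seqs))
    } else {
      rs <- if (inherits(source, "tapir_read_set")) source
            else read_set(source)
      if (length(rs$sequences) == 0L) stop("no reads")
      reservoir_feed(res, rs$ids, rs$sequences)
    }
  })
  out <- reservoir_result(res)
  if (length(out$seqs) == 0L) stop("no reads")
  read_set(out$seqs, ids = out$ids)
}

#' Identify candidate references for a read sample
#'
#' Dispatches on the backend: a local `tapir_index` is scored directly with
#' [score_query_set()]; a remote/service backend (see [loopback_backend()],
#' [remote_backend()]) sends the reads as a JSON query and parses the hit
#' list from the response.  Both routes return the same hit-list contract.
#'
#' @param sample A `tapir_read_set` (typically from [sample_reads()]).
#' @param backend A `tapir_index` or a `tapir_backend`.
#' @param ... Scoring overrides (`weights`, `top_n`, `gap_tolerance`,
#'   `min_cluster`).
#' @return Hit data frame as from [score_query_set()].
#' @export
identify <- function(sample, backend, ...) {
  if (inherits(backend, "tapir_index")) {
    score_query_set(sample, backend, ...)
  } else if (inherits(backend, "tapir_backend")) {
    backend_query(backend, sample, ...)
  } else {
    stop("backend must be a tapir_index or a tapir_backend")
  }
}

#' Create a local reference cache
#'
#' @return An environment used by [fetch_reference()]; instrumented with
#'   `$.fetches` (backend transfers) and `$.cache_hits` counters.
#' @export
reference_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$.fetches <- 0L
  env$.cache_hits <- 0L
  env
}

#' Fetch the full sequence of a reference, with local caching
#'
#' Retrieves a full reference record (including sequence) from the backend,
#' first checking a local cache so a sequence is transferred at most once.
#'
#' @param ref_id Reference id.
#' @param backend A `tapir_index` or `tapir_backend`.
#' @param cache A [reference_cache()]; pass the same one across calls to
#'   benefit from caching (optional).
#' @return A list `(ref_id, description, source, length, sequence)`.
#' @export
fetch_reference <- function(ref_id, backend, cache = NULL) {
  if (!is.null(cache)) {
    key <- paste0("ref:", ref_id)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      cache$.cache_hits <- cache$.cache_hits + 1L
      return(hit)
    }
  }
  rec <- if (inherits(backend, "tapir_index")) {
    index_reference(backend, ref_id)
  } else if (inherits(backend, "tapir_backend")) {
    backend_fetch(backend, ref_id)
  } else {
    stop("backend must be a tapir_index or a tapir_backend")
  }
  if (!is.null(cache)) {
    cache$.fetches <- cache$.fetches + 1L
    cache[[paste0("ref:", ref_id)]] <- rec
  }
  rec
}

#' Partition reads into mapped / unmapped against one reference
#'
#' Built-in seed-and-verify mapper: a read maps if one of its k-mers (either
#' strand) matches an in-phase k-mer of the reference and extending the
#' implied placement gives at least `min_identity` matching bases over the
#' read/reference overlap.  An external aligner can be plugged in via
#' `aligner`, a function `(sequences, reference_sequence) -> logical` saying
#' which reads map; it must honor the same partition contract.
#'
#' @param reads A `tapir_read_set` or character vector of sequences.
#' @param reference Reference record with `sequence` (from
#'   [fetch_reference()]) or a DNA string.
#' @param min_identity Identity threshold for the built-in mapper (default 0.9).
#' @param k Seed k-mer length (default 16).
#' @param aligner Optional external aligner adapter.
#' @param max_placements Distinct candidate placements tried per strand.
#' @return A list with `mapped` and `unmapped`, both `tapir_read_set`s;
#'   together an exact partition of the input.
#' @export
map_reads <- function(reads, reference, min_identity = 0.9, k = 16L,
                      aligner = NULL, max_placements = 5L) {
  rs <- if (inherits(reads, "tapir_read_set")) reads else read_set(reads, k = k)
  ref_seq <- if (is.list(reference)) reference$sequence else reference
  ref_seq <- toupper(ref_seq)

  if (!is.null(aligner)) {
    ok <- tryCatch(aligner(rs$sequences, ref_seq), error = function(e)
      stop("aligner adapter failed: ", conditionMessage(e), call. = FALSE))
    if (!is.logical(ok) || length(ok) != length(rs$sequences))
      stop("aligner adapter failed: must return one logical per read")
  } else {
    km <- nonoverlapping_kmers(ref_seq, k)
    ref_kv <- new_kv()
    pos_by_key <- split(km$pos, kmer_key(km$code))
    for (key in names(pos_by_key)) ref_kv[[key]] <- pos_by_key[[key]]
    ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
    L <- length(ref_chars)

    map_one <- function(seq) {
      for (oriented in c(seq, revcomp(seq))) {
        qk <- overlapping_kmers(oriented, k)
        if (nrow(qk) == 0L) next
        found <- mget(kmer_key(qk$code), envir = ref_kv,
                      ifnotfound = list(NULL))
        starts <- unlist(lapply(seq_along(found), function(i) {
          p <- found[[i]]
          if (is.null(p)) NULL else p - qk$offset[i]
        }), use.names = FALSE)
        if (is.null(starts) || length(starts) == 0L) next
        tab <- sort(table(starts), decreasing = TRUE)
        cand <- as.integer(names(tab))[seq_len(min(length(tab), max_placements))]
        ch <- strsplit(oriented, "", fixed = TRUE)[[1L]]
        n <- length(ch)
        for (s in cand) {           # s is the 0-based placement start
          lo <- max(0L, -s)         # read-coordinate overlap [lo, hi)
          hi <- min(n, L - s)
          if (hi - lo < k) next
          ident <- mean(ch[(lo + 1L):hi] == ref_chars[(s + lo + 1L):(s + hi)])
          if (ident >= min_identity) return(TRUE)
        }
      }
      FALSE
    }
    ok <- vapply(rs$sequences, map_one, TRUE, USE.NAMES = FALSE)
  }

  list(mapped = subset_read_set(rs, ok), unmapped = subset_read_set(rs, !ok))
}

subset_read_set <- function(rs, sel) {
  if (!any(sel)) return(read_set(character(0), ids = character(0), k = rs$k))
  read_set(rs$sequences[sel], ids = rs$ids[sel], k = rs$k)
}

#' Iterative identify / align-and-subtract workflow
#'
#' Repeats: draw a random sample from the currently unmapped reads, query the
#' backend for candidate references, try up to `top_k_to_try` hits by mapping
#' all unmapped reads against each, keep the reference for which the lowest
#' number of unmapped reads remains, and recurse on those.  Stops when the
#' maximum number of iterations is reached, no unmapped reads remain, the
#' backend returns an empty hit list, or the best candidate maps no reads
#' (zero-progress guard).  Sampling in iteration `i` uses seed
#' `plan$seed + i`, so the whole loop is deterministic.
#'
#' @param reads A FASTA/FASTQ path, `tapir_read_set`, or character vector.
#' @param backend A `tapir_index` or `tapir_backend`.
#' @param plan A [sampling_plan()].
#' @param max_iter Maximum iterations (default 5).
#' @param top_k_to_try Hits tried per iteration (default 5).
#' @param min_identity Mapper identity threshold.
#' @param ... Scoring overrides passed to [identify()].
#' @return A list with `iterations` (data frame: `iteration`, `chosen_ref`,
#'   `mapped_reads`, `mapped_fraction` of the initial total,
#'   `unmapped_remaining`), `hits` (hit list per iteration) and `unmapped`
#'   (final unmapped `tapir_read_set`).
#' @export
iterate_identify <- function(reads, backend, plan = sampling_plan(),
                             max_iter = 5L, top_k_to_try = 5L,
                             min_identity = 0.9, ...) {
  stopifnot(max_iter >= 1, top_k_to_try >= 1)
  pool <- if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    read_reads(reads) else if (inherits(reads, "tapir_read_set")) reads
    else read_set(reads)
  total <- length(pool$sequences)
  if (total == 0L) stop("no reads")
  cache <- reference_cache()
  iterations <- list()
  hit_lists <- list()
  for (it in seq_len(max_iter)) {
    if (length(pool$sequences) == 0L) break
    it_plan <- sampling_plan(plan$sample_size, plan$seed + it)
    sample <- sample_reads(pool, it_plan)
    hits <- identify(sample, backend, ...)
    hit_lists[[it]] <- hits
    if (nrow(hits) == 0L) break
    tried <- utils::head(hits$ref_id, top_k_to_try)
    best <- NULL
    for (ref_id in tried) {
      rec <- fetch_reference(ref_id, backend, cache)
      part <- map_reads(pool, rec, min_identity = min_identity)
      if (is.null(best) ||
          length(part$unmapped$sequences) < length(best$part$unmapped$sequences))
        best <- list(ref_id = ref_id, part = part)
    }
    n_mapped <- length(best$part$mapped$sequences)
    if (n_mapped == 0L) break
    pool <- best$part$unmapped
    iterations[[length(iterations) + 1L]] <- data.frame(
      iteration = length(iterations) + 1L,
      chosen_ref = best$ref_id,
      mapped_reads = n_mapped,
      mapped_fraction = n_mapped / total,
      unmapped_remaining = length(pool$sequences))
  }
  list(iterations = if (length(iterations)) do.call(rbind, iterations)
                    else data.frame(iteration = integer(0), chosen_ref = character(0),
                                    mapped_reads = integer(0),
                                    mapped_fraction = numeric(0),
                                    unmapped_remaining = integer(0)),
       hits = hit_lists,
       unmapped = pool)
}
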
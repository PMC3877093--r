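# Synthetic genomes, error-bearing reads and the rank benchmark.
#
# The generator emulates the evaluation design used for identification from
# raw reads: random genomes indexed together, reads drawn as random (possibly
# overlapping) sub-sequences of length 50-250 nt with uniform per-base
# substitution rates of 0-10%, sampled in sets of 5-300 and scored against
# the shared index, recording the rank of the true genome in the top-25 hit
# list.

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; deterministic under `seed` (the
#' global RNG state is left untouched).
#'
#' @param length Genome length in bases (must be at least `k = 16`).
#' @param seed Integer seed.
#' @param gc GC fraction (default 0.5).
#' @param ref_id Id for the generated record.
#' @return A list `(ref_id, description, source, length, sequence)`.
#' @export
generate_genome <- function(length, seed, gc = 0.5, ref_id = sprintf("g%d", seed)) {
  if (length < 16L) stop("genome length must be >= 16")
  stopifnot(gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- withr::with_seed(seed,
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  list(ref_id = ref_id, description = sprintf("%s synthetic random genome", ref_id),
       source = "synthetic", length = length, sequence = seq)
}

#' Simulate sequencing reads with substitution errors
#'
#' Reads are random, possibly overlapping sub-sequences of the genome: start
#' positions uniform on `[0, L - read_length]` with replacement across reads.
#' Each base is independently substituted with probability `sub_rate`,
#' uniformly to one of the three other bases (never the original).
#' Deterministic under `seed`.
#'
#' @param genome A genome record (list with `sequence`) or a DNA string.
#' @param read_length Read length in bases.
#' @param sub_rate Per-base substitution probability in `[0, 1]`.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param revcomp_frac Probability of flipping each read to its reverse
#'   complement (default 0, forward strand only).
#' @return A `tapir_read_set`.
#' @export
simulate_reads <- function(genome, read_length, sub_rate, n_reads, seed,
                           revcomp_frac = 0) {
  seq <- if (is.list(genome)) genome$sequence else genome
  L <- nchar(seq)
  if (read_length > L) stop("read_length exceeds genome length")
  stopifnot(sub_rate >= 0, sub_rate <= 1)
  reads <- withr::with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    out <- substring(seq, starts, starts + read_length - 1L)
    if (sub_rate > 0) {
      out <- vapply(out, function(r) {
        ch <- strsplit(r, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < sub_rate)
        if (length(hit)) {
          for (i in hit) {
            alt <- setdiff(c("A", "C", "G", "T"), ch[i])
            ch[i] <- alt[sample.int(3L, 1L)]
          }
        }
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    if (revcomp_frac > 0) {
      flip <- stats::runif(n_reads) < revcomp_frac
      out[flip] <- revcomp(out[flip])
    }
    out
  })
  read_set(reads, ids = sprintf("sim%d", seq_len(n_reads)))
}

#' Benchmark configuration
#'
#' Defaults mirror the standard evaluation grid: read lengths 50-250 nt,
#' substitution rates 0-10%, sample sizes 5-300 reads, 3 replicates.
#'
#' @param genome_length Length of each synthetic genome.
#' @param read_lengths Vector of read lengths.
#' @param sub_rates Vector of substitution rates.
#' @param sample_sizes Vector of reads-per-query sample sizes.
#' @param replicates Replicates per condition (default 3).
#' @param seed Master seed; every sub-draw derives deterministically from it.
#' @return A list of class `tapir_sim_config`.
#' @export
sim_config <- function(genome_length = 50000L,
                       read_lengths = c(50L, 75L, 100L, 150L, 200L, 250L),
                       sub_rates = c(0, 0.01, 0.05, 0.10),
                       sample_sizes = c(5L, 10L, 25L, 50L, 100L, 200L, 300L),
                       replicates = 3L, seed = 1L) {
  stopifnot(all(sub_rates >= 0), all(sub_rates <= 1), replicates >= 1)
  structure(list(genome_length = genome_length, read_lengths = read_lengths,
                 sub_rates = sub_rates, sample_sizes = sample_sizes,
                 replicates = replicates, seed = as.integer(seed)),
            class = "tapir_sim_config")
}

# deterministic per-draw sub-seed below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 8191) %% 2147483629) + 1L
}

#' Run the rank-recovery benchmark on synthetic genomes
#'
#' Generates `n_genomes` unrelated random genomes, builds one shared index,
#' and for every combination of genome, read length, substitution rate,
#' sample size and replicate scores a fresh simulated read sample, recording
#' the rank of the true genome in the top-25 hit list (`NA` = not found).
#' Optionally each genome gets `strains_per_genome` mutated copies (at
#' `strain_divergence` per-base divergence) indexed alongside it, emulating
#' closely related strains of one species; `species_rank` is then the best
#' rank of any member of the true genome's species group.
#'
#' @param config A [sim_config()].
#' @param n_genomes Number of unrelated genomes.
#' @param top_n Hit-list cap (default 25).
#' @param strains_per_genome Mutated copies per genome (default 0).
#' @param strain_divergence Per-base divergence of strain copies (default 0.01).
#' @return A `data.frame` of class `tapir_benchmark` with columns
#'   `genome_id`, `read_length`, `sub_rate`, `sample_size`, `replicate`,
#'   `rank_of_truth`, `species_rank` (both `NA` when absent from the list).
#' @export
run_benchmark <- function(config, n_genomes, top_n = 25L,
                          strains_per_genome = 0L, strain_divergence = 0.01) {
  stopifnot(inherits(config, "tapir_sim_config"))
  genomes <- lapply(seq_len(n_genomes), function(i)
    generate_genome(config$genome_length, seed = derive_seed(config$seed, i),
                    ref_id = sprintf("genome%02d", i)))
  seqs <- vapply(genomes, `[[`, "", "sequence")
  names(seqs) <- vapply(genomes, `[[`, "", "ref_id")
  species <- as.list(names(seqs))
  names(species) <- names(seqs)
  if (strains_per_genome > 0L) {
    for (i in seq_len(n_genomes)) {
      parent <- names(seqs)[i]
      for (s in seq_len(strains_per_genome)) {
        sid <- sprintf("%s_strain%d", parent, s)
        mut <- simulate_reads(seqs[[parent]], nchar(seqs[[parent]]),
                              strain_divergence, 1L,
                              seed = derive_seed(config$seed, 1000L + i * 10L + s))
        seqs[[sid]] <- mut$sequences[1L]
        species[[parent]] <- c(species[[parent]], sid)
      }
    }
  }
  index <- build_index(seqs, k = 16L, source = "synthetic")

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      sample_size = config$sample_sizes,
                      sub_rate = config$sub_rates,
                      read_length = config$read_lengths,
                      genome = seq_len(n_genomes),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid$genome[r]
    gid <- genomes[[g]]$ref_id
    reads <- simulate_reads(genomes[[g]], grid$read_length[r], grid$sub_rate[r],
                            grid$sample_size[r],
                            seed = derive_seed(config$seed, 100000L + r))
    hits <- score_query_set(reads, index, top_n = top_n)
    rk <- match(gid, hits$ref_id)
    group <- species[[gid]]
    sp <- suppressWarnings(min(match(group, hits$ref_id), na.rm = TRUE))
    rows[[r]] <- data.frame(genome_id = gid,
                            read_length = grid$read_length[r],
                            sub_rate = grid$sub_rate[r],
                            sample_size = grid$sample_size[r],
                            replicate = grid$replicate[r],
                            rank_of_truth = rk,
                            species_rank = if (is.finite(sp)) sp else NA_integer_)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tapir_benchmark", "data.frame")
  out
}

#' Summarize benchmark ranks per condition
#'
#' Per `(read_length, sub_rate, sample_size)`: mean and standard deviation of
#' the rank over trials where the truth was found (not-found trials are
#' excluded from the mean but counted in the found-fraction denominators),
#' a censored mean rank where a not-found trial counts as `censor_at`
#' (one past the hit-list cap, so missing the list is worse than any listed
#' rank), the fraction of trials with rank at most 5, the fraction found in
#' the capped list at all, and the species-level analogues.
#'
#' @param table A `tapir_benchmark` from [run_benchmark()].
#' @param censor_at Rank charged to not-found trials in `mean_rank_censored`
#'   (default 26, one past the default hit-list cap).
#' @return Data frame with one row per condition.
#' @export
summarize_ranks <- function(table, censor_at = 26L) {
  stopifnot(nrow(table) > 0)
  key <- interaction(table$read_length, table$sub_rate, table$sample_size,
                     drop = TRUE)
  parts <- split(table, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    cens <- ifelse(is.na(d$rank_of_truth), censor_at, d$rank_of_truth)
    data.frame(read_length = d$read_length[1L], sub_rate = d$sub_rate[1L],
               sample_size = d$sample_size[1L],
               n_trials = nrow(d),
               mean_rank = mean(d$rank_of_truth, na.rm = TRUE),
               sd_rank = stats::sd(d$rank_of_truth, na.rm = TRUE),
               mean_rank_censored = mean(cens),
               frac_top5 = mean(!is.na(d$rank_of_truth) & d$rank_of_truth <= 5),
               frac_found = mean(!is.na(d$rank_of_truth)),
               mean_species_rank = mean(d$species_rank, na.rm = TRUE),
               frac_species_top5 = mean(!is.na(d$species_rank) & d$species_rank <= 5),
               frac_species_found = mean(!is.na(d$species_rank)))
  }))
  out <- out[order(out$read_length, out$sub_rate, out$sample_size), ]
  rownames(out) <- NULL
  out
}
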
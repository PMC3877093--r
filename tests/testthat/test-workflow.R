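test_that("read sampling is seed-deterministic and caps at the population", {
  reads <- exact_reads(rand_dna(5000, 50), 100, 1000, seed = 51)
  s1 <- sample_reads(read_set(reads), sampling_plan(100, seed = 7))
  s2 <- sample_reads(read_set(reads), sampling_plan(100, seed = 7))
  expect_identical(s1$sequences, s2$sequences)
  expect_length(s1$sequences, 100)

  all_of_them <- sample_reads(read_set(reads[1:5]), sampling_plan(100, seed = 7))
  expect_setequal(all_of_them$sequences, reads[1:5])
})

test_that("file-based sampling streams FASTQ and FASTA identically to memory", {
  reads <- exact_reads(rand_dna(3000, 52), 120, 50, seed = 53)
  ids <- sprintf("r%d", 1:50)
  fq <- withr::local_tempfile(fileext = ".fastq")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fastq(fq, reads, ids)
  write_fasta(fa, reads, ids)
  from_fq <- sample_reads(fq, sampling_plan(10, seed = 9))
  from_fa <- sample_reads(fa, sampling_plan(10, seed = 9))
  from_mem <- sample_reads(read_set(reads, ids = ids), sampling_plan(10, seed = 9))
  expect_identical(from_fq$sequences, from_mem$sequences)
  expect_identical(from_fa$sequences, from_mem$sequences)
  expect_identical(from_fq$ids, from_mem$ids)
  # sampled sequences really come from the file, keyed by their ids
  expect_identical(from_fq$sequences, reads[match(from_fq$ids, ids)])
})

test_that("reservoir sampling is uniform (3 of 10, many seeds)", {
  reads <- vapply(1:10, function(i) rand_dna(30, 600 + i), "")
  counts <- integer(10)
  for (seed in 1:500) {
    s <- sample_reads(read_set(reads), sampling_plan(3, seed = seed))
    counts[match(s$sequences, reads)] <- counts[match(s$sequences, reads)] + 1L
  }
  freq <- counts / 500
  expect_true(all(abs(freq - 0.3) < 0.06))
})

test_that("empty read sources raise a 'no reads' error", {
  expect_error(sample_reads(read_set(character(0)), sampling_plan(5, 1)), "no reads")
  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_error(sample_reads(empty, sampling_plan(5, 1)), "no reads")
})

test_that("the built-in mapper maps error-free reads and rejects unrelated ones", {
  g <- generate_genome(20000, seed = 54, ref_id = "g")
  own <- simulate_reads(g, 150, 0, 40, seed = 55, revcomp_frac = 0.5)
  other <- simulate_reads(generate_genome(50000, seed = 56), 150, 0, 40, seed = 57)
  part_own <- map_reads(own, g)
  expect_length(part_own$mapped$sequences, 40)
  expect_length(part_own$unmapped$sequences, 0)
  part_other <- map_reads(other, g)
  expect_length(part_other$mapped$sequences, 0)
  expect_length(part_other$unmapped$sequences, 40)
  # exact partition
  mixed <- read_set(c(own$sequences, other$sequences))
  part <- map_reads(mixed, g)
  expect_identical(length(part$mapped$sequences) + length(part$unmapped$sequences),
                   length(mixed$sequences))
  expect_setequal(c(part$mapped$sequences, part$unmapped$sequences),
                  mixed$sequences)
})

test_that("noisy reads map while staying under the identity threshold rules", {
  g <- generate_genome(20000, seed = 58, ref_id = "g")
  noisy <- simulate_reads(g, 150, 0.05, 30, seed = 59)   # ~7-8 errors per read
  part <- map_reads(noisy, g, min_identity = 0.9)
  expect_gt(length(part$mapped$sequences), 25)           # nearly all map
})

test_that("a failing aligner adapter is reported by name, reads never dropped", {
  g <- generate_genome(5000, seed = 60)
  reads <- simulate_reads(g, 100, 0, 5, seed = 61)
  expect_error(map_reads(reads, g, aligner = function(s, r) stop("boom")),
               "aligner adapter failed")
  expect_error(map_reads(reads, g, aligner = function(s, r) TRUE),
               "one logical per read")
})

test_that("reference fetching is cached after the first transfer", {
  idx <- build_index(toy_genomes(2, 1000, seed = 470))
  cache <- reference_cache()
  r1 <- fetch_reference("toy01", idx, cache)
  r2 <- fetch_reference("toy01", idx, cache)
  expect_identical(cache$.fetches, 1L)
  expect_identical(cache$.cache_hits, 1L)
  expect_identical(r1, r2)
  expect_identical(nchar(r1$sequence), r1$length)
  expect_identical(r1$length, index_catalog(idx)$length[1])
  expect_error(fetch_reference("nope", idx, cache), class = "tapir_not_found")
})

test_that("a fetched reference re-indexes to an identical bundle", {
  refs <- toy_genomes(1, 1500, seed = 480)
  idx <- build_index(refs)
  rec <- fetch_reference("toy01", idx)
  re_idx <- build_index(setNames(rec$sequence, rec$ref_id))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_index(idx, d1, build_time = "t"); save_index(re_idx, d2, build_time = "t")
  for (f in c("presence.tsv", "positions.tsv", "refs.fasta"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("identify through a local index equals a direct scoring call", {
  gs <- toy_genomes(3, 5000, seed = 490)
  idx <- build_index(gs)
  sample <- read_set(exact_reads(gs[[2]], 150, 20, seed = 62))
  expect_identical(identify(sample, idx), score_query_set(sample, idx))
})

test_that("a pure single-genome read set resolves in one iteration", {
  gs <- toy_genomes(3, 20000, seed = 500)
  idx <- build_index(gs)
  reads <- read_set(exact_reads(gs[[1]], 150, 120, seed = 63))
  res <- iterate_identify(reads, idx, sampling_plan(50, seed = 64))
  expect_identical(nrow(res$iterations), 1L)
  expect_identical(res$iterations$chosen_ref, "toy01")
  expect_identical(res$iterations$mapped_fraction, 1)
  expect_identical(res$iterations$unmapped_remaining, 0L)
})

test_that("a 50/50 mixture is resolved over two iterations with conservation", {
  gs <- toy_genomes(2, 30000, seed = 510)
  idx <- build_index(gs)
  mix <- read_set(c(exact_reads(gs[[1]], 150, 60, seed = 65),
                    exact_reads(gs[[2]], 150, 60, seed = 66)))
  res <- iterate_identify(mix, idx, sampling_plan(30, seed = 67), max_iter = 5)
  expect_setequal(res$iterations$chosen_ref, names(gs))
  # conservation: mapped counts plus final unmapped equal the initial total
  expect_identical(sum(res$iterations$mapped_reads) +
                     length(res$unmapped$sequences), 120L)
  expect_true(all(diff(res$iterations$unmapped_remaining) < 0))
  expect_length(res$unmapped$sequences, 0)
})

test_that("max_iter = 1 on a mixture yields exactly one iteration record", {
  gs <- toy_genomes(2, 20000, seed = 520)
  idx <- build_index(gs)
  mix <- read_set(c(exact_reads(gs[[1]], 150, 40, seed = 68),
                    exact_reads(gs[[2]], 150, 40, seed = 69)))
  res <- iterate_identify(mix, idx, sampling_plan(20, seed = 70), max_iter = 1)
  expect_identical(nrow(res$iterations), 1L)
  expect_gt(length(res$unmapped$sequences), 0)
})

test_that("all-novel reads terminate the loop with an empty hit list", {
  idx <- build_index(toy_genomes(2, 10000, seed = 530))
  novel <- read_set(exact_reads(rand_dna(30000, 71), 150, 50, seed = 72))
  res <- iterate_identify(novel, idx, sampling_plan(25, seed = 73))
  expect_identical(nrow(res$iterations), 0L)
  expect_length(res$unmapped$sequences, 50)
  expect_identical(nrow(res$hits[[1]]), 0L)
})
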
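test_that("read-set k-mer denominator is order-invariant and positive", {
  reads <- exact_reads(rand_dna(2000, 20), 100, 10, seed = 21)
  rs1 <- read_set(reads)
  rs2 <- read_set(rev(reads))
  expect_gte(rs1$unique_query_kmers, 1)
  expect_identical(rs1$unique_query_kmers, rs2$unique_query_kmers)
})

test_that("an in-phase error-free read forms one full-size cluster", {
  g <- rand_dna(3000, 22)
  idx <- build_index(c(g1 = g))
  read <- substr(g, 16 * 5 + 1, 16 * 5 + 160)   # in phase, length 160
  m <- match_read(read, idx)
  expect_length(m, 1)
  expect_identical(m[[1]]$ref_id, "g1")
  expect_identical(m[[1]]$cluster_size, 160L %/% 16L)
  expect_identical(m[[1]]$cluster_positions, as.integer(16 * (5:14)))
  expect_identical(m[[1]]$cluster_size, length(m[[1]]$cluster_positions))
  expect_true(all(diff(m[[1]]$cluster_positions) <= 2 * idx$k))
  expect_identical(m[[1]]$orientation, "+")
})

test_that("reverse-complemented reads match with the '-' orientation", {
  g <- rand_dna(3000, 23)
  idx <- build_index(c(g1 = g))
  read <- revcomp(substr(g, 161, 320))
  m <- match_read(read, idx)
  expect_length(m, 1)
  expect_identical(m[[1]]$orientation, "-")
  expect_identical(m[[1]]$cluster_size, 10L)
})

test_that("scattered isolated matches are rejected by the cluster threshold", {
  # reference carrying two query k-mers separated by a huge gap: the read's
  # k-mers hit it only at two distant spots, so clusters have size 1
  a <- rand_dna(16, 24); b <- rand_dna(16, 25)
  big <- paste0(a, rand_dna(16 * 200, 26), b)
  read <- paste0(a, b)  # 32 nt read carrying both k-mers in phase
  idx <- build_index(c(big = big))
  expect_length(match_read(read, idx, min_cluster = 2), 0)
  m1 <- match_read(read, idx, min_cluster = 1)
  expect_length(m1, 1)
  expect_identical(m1[[1]]$cluster_size, 1L)
  expect_identical(m1[[1]]$cluster_positions, 0L)  # leftmost of the tied clusters
})

test_that("cluster sets match a brute-force matcher on a toy index", {
  refs <- toy_genomes(3, 2500, seed = 400)
  idx <- build_index(refs)
  tiles <- lapply(refs, oracle_stride_tiles, k = 16)
  withr::with_seed(27, {
    for (trial in 1:10) {
      src <- sample(names(refs), 1)
      read <- exact_reads(refs[[src]], 150, 1, seed = 28 + trial)
      m <- match_read(read, idx, min_cluster = 1)
      got <- setNames(lapply(m, `[[`, "cluster_size"),
                      vapply(m, `[[`, "", "ref_id"))
      fwd <- oracle_orientation(read, tiles, 32, 16)
      rev <- oracle_orientation(oracle_revcomp(read), tiles, 32, 16)
      for (ref in names(refs)) {
        f <- fwd[[ref]]; r <- rev[[ref]]
        pick <- if (is.null(r)) f else if (is.null(f)) r
                else if (r$size > f$size) r else f
        if (is.null(pick)) expect_false(ref %in% names(got))
        else expect_identical(got[[ref]], as.integer(pick$size))
      }
    }
  })
})

test_that("a query tiling an entire duplicate-free reference scores exactly 1", {
  g <- rand_dna(1600, 29)
  stopifnot(!anyDuplicated(nonoverlapping_kmers(g, 16)$code))
  starts <- seq(1, 1600 - 160 + 1, by = 160)
  reads <- substring(g, starts, starts + 159)
  idx <- build_index(c(g1 = g, other = rand_dna(1600, 30)))
  hits <- score_query_set(read_set(reads), idx)
  expect_identical(hits$ref_id[1], "g1")
  expect_identical(hits$query_score[1], 1)
  expect_identical(hits$ref_score[1], 1)
  expect_identical(hits$count[1], 100L)
})

test_that("reads from an unindexed genome return an empty hit list", {
  idx <- build_index(toy_genomes(2, 1000, seed = 410))
  novel <- exact_reads(rand_dna(5000, 31), 150, 20, seed = 32)
  hits <- score_query_set(read_set(novel), idx)
  expect_identical(nrow(hits), 0L)
})

test_that("an equal two-genome mixture splits the query score around 0.5", {
  gs <- toy_genomes(2, 20000, seed = 420)
  idx <- build_index(gs)
  reads <- c(exact_reads(gs[[1]], 150, 50, seed = 33),
             exact_reads(gs[[2]], 150, 50, seed = 34))
  hits <- score_query_set(read_set(reads), idx)
  expect_setequal(hits$ref_id, names(gs))
  expect_true(all(hits$query_score >= 0.4 & hits$query_score <= 0.6))
})

test_that("each k-mer is counted at most once per reference (ref_score <= 1)", {
  g <- rand_dna(2000, 35)
  idx <- build_index(c(g1 = g))
  # heavy oversampling: 200 overlapping reads from a 2 kb genome
  reads <- exact_reads(g, 150, 200, seed = 36)
  hits <- score_query_set(read_set(reads), idx)
  expect_lte(hits$ref_score[1], 1)
  expect_lte(hits$count[1], 2000 %/% 16)
})

test_that("ranking is deterministic, order-invariant, with documented tie-breaks", {
  hits <- data.frame(ref_id = c("b", "a", "c"),
                     combined = c(0.5, 0.5, 0.9),
                     ref_score = c(0.2, 0.4, 0.1))
  ranked <- rank_hits(hits)
  expect_identical(ranked$ref_id, c("c", "a", "b"))  # combined, then ref_score
  expect_identical(ranked$rank, 1:3)

  tie <- data.frame(ref_id = c("z", "y"), combined = c(0.5, 0.5),
                    ref_score = c(0.3, 0.3))
  expect_identical(rank_hits(tie)$ref_id, c("y", "z"))  # ref_id ascending

  withr::with_seed(37, {
    perm <- hits[sample(1:3), , drop = FALSE]
    expect_identical(rank_hits(perm)$ref_id, ranked$ref_id)
  })
})

test_that("identical inputs give identical hit lists regardless of read order", {
  gs <- toy_genomes(3, 5000, seed = 430)
  idx <- build_index(gs)
  reads <- c(exact_reads(gs[[1]], 150, 20, seed = 38),
             exact_reads(gs[[2]], 150, 20, seed = 39))
  h1 <- score_query_set(read_set(reads), idx)
  h2 <- score_query_set(read_set(rev(reads)), idx)
  expect_identical(h1, h2)
})

test_that("scoring equals the no-index brute-force implementation", {
  refs <- toy_genomes(4, 1500, seed = 440)
  withr::with_seed(40, {
    reads <- c(exact_reads(refs[[1]], 120, 8, seed = 41),
               exact_reads(refs[[2]], 120, 8, seed = 42),
               vapply(1:4, function(i) rand_dna(120, 8000 + i), ""))
  })
  idx <- build_index(refs)
  got <- score_query_set(read_set(reads), idx, weights = c(0.7, 0.3),
                         gap_tolerance = 48, min_cluster = 2)
  want <- oracle_score(reads, refs, gap = 48, min_cluster = 2,
                       weights = c(0.7, 0.3))
  expect_identical(got$ref_id, want$ref_id)
  expect_identical(got$count, want$count)
  expect_equal(got$query_score, want$query_score)
  expect_equal(got$ref_score, want$ref_score)
  expect_equal(got$combined, want$combined)
  expect_identical(got$rank, want$rank)
})

test_that("counts are additive over mixtures of k-mer-disjoint references", {
  gs <- toy_genomes(2, 8000, seed = 450)
  shared <- intersect(oracle_stride_tiles(gs[[1]], 16)$kmer,
                      oracle_stride_tiles(gs[[2]], 16)$kmer)
  stopifnot(length(shared) == 0)
  idx <- build_index(gs)
  ra <- exact_reads(gs[[1]], 150, 30, seed = 43)
  rb <- exact_reads(gs[[2]], 150, 30, seed = 44)
  mixed <- score_query_set(read_set(c(ra, rb)), idx)
  only_a <- score_query_set(read_set(ra), idx)
  only_b <- score_query_set(read_set(rb), idx)
  expect_identical(mixed$count[mixed$ref_id == names(gs)[1]],
                   only_a$count[only_a$ref_id == names(gs)[1]])
  expect_identical(mixed$count[mixed$ref_id == names(gs)[2]],
                   only_b$count[only_b$ref_id == names(gs)[2]])
})

test_that("expected counted k-mers do not increase with substitution rate", {
  g <- generate_genome(20000, seed = 46, ref_id = "g")
  idx <- build_index(c(g = g$sequence))
  mean_count <- vapply(c(0, 0.01, 0.05, 0.10), function(rate) {
    mean(vapply(1:10, function(rep) {
      reads <- simulate_reads(g, 150, rate, 20, seed = 47 + rep)
      hits <- score_query_set(reads, idx)
      if (nrow(hits)) hits$count[1] else 0
    }, 0))
  }, 0)
  expect_true(all(diff(mean_count) <= 0))
})

test_that("hit tables serialize to JSON and TSV with the same columns", {
  idx <- build_index(toy_genomes(2, 2000, seed = 460))
  reads <- exact_reads(index_reference(idx, "toy01")$sequence, 150, 10, seed = 48)
  hits <- score_query_set(read_set(reads), idx)
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, js); write_hits(hits, tsv)
  back <- jsonlite::fromJSON(js)
  expect_identical(back$ref_id, hits$ref_id)
  expect_equal(back$combined, hits$combined)
  tab <- read.delim(tsv)
  expect_identical(names(tab), names(hits))
})
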
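# Shared fixtures: small random genomes and read files, built in code.

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

toy_genomes <- function(n, len, seed = 101) {
  seqs <- vapply(seq_len(n), function(i) rand_dna(len, seed + i), "")
  names(seqs) <- sprintf("toy%02d", seq_len(n))
  seqs
}

write_fastq <- function(path, seqs, ids = sprintf("r%d", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

write_fasta <- function(path, seqs, ids = names(seqs)) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# exact substrings of a genome at fixed seeded positions
exact_reads <- function(genome, read_length, n, seed) {
  withr::with_seed(seed, {
    starts <- sample.int(nchar(genome) - read_length + 1L, n, replace = TRUE)
    substring(genome, starts, starts + read_length - 1L)
  })
}
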
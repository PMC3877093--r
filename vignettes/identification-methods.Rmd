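---
title: "Identifying organisms from raw reads: the method behind tapir"
author: "tapir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying organisms from raw reads: the method behind tapir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapir)
```

## The problem

A sequencing run produces reads, not organism names. When the sample is a
pure culture, a plasmid prep, or a simple mixture, the analyst usually knows
roughly what to expect and aligns everything against a chosen reference. When
the source is unknown — an infection of unclear origin, a contaminated food
sample, a bioreactor check — choosing the reference *is* the problem.
Aligning all reads against every known genome is prohibitively expensive, and
transferring a full sequencing run to a compute center consumes bandwidth
that a field laboratory may not have.

`tapir` treats the task as information retrieval rather than alignment: a
*DNA search engine*. A server (or a local session) holds a k-mer index over a
collection of reference sequences. A client samples a small number of reads
— one hundred is typically enough for a bacterial isolate — and submits just
those. The answer is a ranked list of candidate references. The client can
then fetch only the top candidates and do the expensive work (aligning all
reads) locally, iterating on whatever fails to map. The data transferred is
kilobytes up and at most a few genomes down.

## Indexing

Each reference sequence is split into **non-overlapping** k-mers: windows of
width $k = 16$ at positions $0, k, 2k, \dots$ (we call these *in-phase*
positions). Two stores are built:

* the **presence store** maps a k-mer to the sorted list of references that
  contain it at an in-phase position;
* the **position store** maps a (k-mer, reference) pair to the sorted
  in-phase positions where it occurs.

A catalog records, per reference, its description, provenance label, length
$L$ and indexed k-mer count $\lfloor L/k \rfloor$. With $k = 16$ a k-mer
packs exactly into 32 bits (2 bits per base, A=0, C=1, G=2, T=3, first base
in the highest-order bit pair); R stores the code as a double, which is exact
far beyond $4^{16}$. Windows containing any non-ACGT character are skipped —
real assemblies contain N runs — and the trailing remainder shorter than $k$
is dropped. Lowercase (soft-masked) bases are uppercased and indexed like any
other; masking conventions vary too much between sources to carry meaning
here. References are indexed on the forward strand only, which halves the
index; strand symmetry is instead handled at query time.

The stores are environment-backed hash maps keyed by the decimal form of the
packed code, behind a small key-value surface so a different backing (an
embedded on-disk store, a sharded remote store) can be substituted without
touching the scoring code. `save_index()` serializes a bundle to a directory
of plain-text tables (`presence.tsv`, `positions.tsv`, `catalog.tsv`,
`refs.fasta`, `meta.json`) in canonical key order, so rebuilding from the
same input yields byte-identical store files; `load_index()` restores the
bundle, including the build-time `k` recorded in its header. Queries against
a bundle built with a different `k` are rejected rather than silently
mis-scored.

## Scoring a read sample

Queries use **overlapping** k-mers: every window of width $k$ at offsets
$0, 1, \dots, \mathrm{len} - k$ of the read. Only the windows that happen to
fall in phase with a reference's stride-$k$ decomposition can match the
index, and enumerating all offsets guarantees that in-phase windows are
among them wherever the read sits on the reference. (The converse design —
overlapping index, stride-$k$ query — trades index size against query count;
the scoring principles are unchanged.)

For one read and one candidate reference, the in-phase positions of all
matched k-mers are sorted and split into **clusters** wherever the gap
between consecutive positions exceeds a tolerance (default $2k = 32$,
allowing one missing in-between k-mer). Only the largest cluster is retained
— leftmost on ties — and references whose best cluster holds fewer than
`min_cluster = 2` matched k-mers are dropped for that read. This positional
clustering is the noise filter: a bacterial read thrown against a mammalian
genome may share isolated k-mers scattered over megabases, but they form no
cluster and contribute nothing. Both the read and its reverse complement are
tried, and the orientation with the larger best cluster is kept per
reference (forward on ties) — real reads come from both strands.

Cluster k-mers are then accumulated per reference over all reads, with a
per-reference set of already-counted k-mers so each distinct k-mer
contributes at most once per reference for the whole query set. Keeping the
bookkeeping per reference (rather than one global set) preserves two
properties worth testing: counts are additive over mixtures of k-mer-disjoint
references, and no reference can exceed its own k-mer capacity. Each
reference with a non-zero count $c$ receives two normalized scores:

$$\mathrm{query\_score} = \frac{c}{U}, \qquad
  \mathrm{ref\_score} = \frac{c}{\lfloor L/k \rfloor},$$

where $U$ is the number of distinct k-mers in the **stride-k** decomposition
of the query set. The denominators deserve a note. Lookups use overlapping
k-mers, but only in-phase ones can ever match, so normalizing by the
overlapping k-mer count would cap the first score near $1/k$; with the
stride-$k$ denominator, a query set that tiles an entire duplicate-free
reference scores exactly 1, which is the intended calibration ("a complete
match scores 1", and an equal two-way mixture scores about 0.5 for each
component). Likewise "size of the reference" in the second score is taken as
the indexed k-mer count rather than bases, so a fully recovered reference
scores exactly 1 there too. The second score exists to counter
large-reference bias: a huge genome can absorb many query k-mers while
representing a poor explanation of the sample.

The final ranking uses the weighted sum
$w_1 \cdot \mathrm{query\_score} + w_2 \cdot \mathrm{ref\_score}$ with equal
weights by default, ties broken by `ref_score` (descending) then `ref_id`
(ascending) so the hit list is a deterministic function of the scores alone.
The list is capped at 25 hits.

```{r scoring-example}
genomes <- c(g1 = generate_genome(20000, seed = 1)$sequence,
             g2 = generate_genome(20000, seed = 2)$sequence)
index <- build_index(genomes, k = 16)
reads <- simulate_reads(list(sequence = genomes[["g1"]]), read_length = 150,
                        sub_rate = 0.01, n_reads = 100, seed = 3)
score_query_set(reads, index)
```

## The iterative client workflow

`iterate_identify()` implements the full loop for mixtures:

1. draw a uniform random sample (default 100 reads) from the currently
   unmapped pool — reservoir sampling in a single pass, so the read file
   never needs to fit in memory;
2. query the backend (local index or remote service) for the hit list;
3. for up to `top_k_to_try = 5` top hits, fetch the full reference
   (cached locally, so a sequence travels at most once) and align **all**
   unmapped reads against it;
4. keep the reference minimizing the unmapped count, record the round, and
   recurse on the remainder.

The loop stops when the iteration cap is reached, no unmapped reads remain,
or the hit list is empty; a fourth guard — the best candidate maps zero
reads — prevents spinning on pathological input, a case the three stated
conditions do not cover. Each round re-samples from the unmapped pool with
seed `seed + iteration`, so the whole trajectory is reproducible. Read
counts partition exactly: mapped counts over rounds plus the final unmapped
pool always sum to the initial total.

The default aligner is a built-in seed-and-verify mapper: a read maps if one
of its k-mers (either strand) seeds a placement on the reference and the
placed read agrees with the reference on at least `min_identity = 0.9` of
the overlapping bases. That threshold tolerates the 0–10% substitution range
considered here while rejecting unrelated sequence, and it keeps the package
self-contained and testable; any external aligner can be plugged in through
a function adapter honoring the same partition contract (mapped + unmapped =
input, never dropping a read).

## The synthetic benchmark

Real evaluations of this kind run against thousands of public genomes; that
is out of reach for a self-contained package, so the simulator reproduces
the *design* of such a benchmark at desk scale. `generate_genome()` draws
i.i.d. bases (GC fraction 0.5 by default); `simulate_reads()` draws reads as
random, possibly overlapping sub-sequences — uniform start positions, with
replacement — of lengths 50–250 nt, and applies uniform per-base
substitutions at rates 0–10%, never substituting a base for itself.
Substitutions model both sequencing error and true point divergence;
platform-specific artifacts (homopolymer indels, quality profiles) are
deliberately not modeled. `run_benchmark()` indexes `n_genomes` such genomes
together and, for every combination of genome, read length, substitution
rate, sample size (5–300 reads) and replicate (3 by default), scores a fresh
sample and records the rank of the true genome in the top-25 list.

What synthetic genomes do *not* emulate is the relatedness structure of real
collections: random 50 kb genomes share a given 16-mer with probability about
$L^2/4^{16} \approx 10^{-3}$ per pair, and clustered co-occurrences are
essentially impossible, so a found genome is almost always rank 1 and
degradation shows up as *not found* rather than as a worse rank. Two design
choices follow:

* `run_benchmark()` can add per-genome "strain" copies (mutated at 1%
  divergence) to emulate same-species competition; the species-level rank is
  then the best rank of any member of the true genome's group.
* `summarize_ranks()` reports, besides the mean rank over found trials (with
  not-found trials excluded from the mean but counted in the found-fraction
  denominator, mirroring how such figures nest a found-percentage bar next
  to a rank distribution), a **censored** mean rank in which a not-found
  trial is charged rank 26 — one past the list cap. The censored mean is the
  statistic used for directional claims ("shorter reads identify worse"),
  since it folds the dominant not-found effect into a single ordering.

At the scale exercised in the tests (20 unrelated 50 kb genomes, 100 reads
of 150 nt, substitution rates up to 5%), the true genome ranks first in
every trial; reads of 50 nt at 10% substitutions begin to miss the list,
reproducing the qualitative finding that such short reads are of little
practical use for identification. Problem sizes throughout the test suite
(genomes of 1.5–50 kb, samples of 5–300 reads, 3 replicates) were chosen as
the smallest at which these properties are comfortably non-trivial.

## The service layer

`tapir_service()` wraps an index behind two endpoints: a JSON query
(`POST /v1/query`, reads as plain strings — qualities are unused — with
optional overrides for `top_n`, weights, gap tolerance, cluster threshold)
and reference retrieval (`GET /v1/reference/{id}`, a 60-column FASTA
document). The handlers are pure functions of the request, so the response
provably equals a local `score_query_set()` on the same inputs; the loopback
backend pushes every request through JSON serialization exactly as the wire
would, making that equivalence testable without a network, and
`tapir_serve()`/`remote_backend()` provide the real HTTP transport (via the
optional `httpuv` and `curl` packages). Payloads above 10 MB are rejected —
the design premise is that a query is a small sample, and a typical
100-read × 250 nt query serializes to under 30 KB, comfortably within
mobile-broadband budgets. The wire format is this package's own declaration,
versioned in the path.

## Numerical and degenerate-input choices

* k-mer codes are doubles holding integers below $4^{16} < 2^{53}$: exact.
* Reads shorter than $k$ contribute nothing and are skipped, not errors.
* An empty hit list is a valid result (novel DNA); an empty *request* to the
  service is a client error — the distinction matters to the workflow's
  termination logic.
* Sampling more reads than exist returns the whole population.
* `sample_reads()`/`simulate_reads()`/`generate_genome()` take explicit
  seeds and restore the caller's RNG state; benchmark sub-draws derive from
  the master seed by a fixed linear rule, so every table is reproducible
  from one integer.
* Tie-breaks (rank order, leftmost maximal cluster, forward orientation) are
  all fixed and documented so identical inputs give identical outputs
  regardless of traversal order.

## Known limitations

* No paired-end awareness; no gapped/affine alignment in the scorer; no
  quality-score weighting.
* Forward-only indexing assumes queries handle strand, which the scorer and
  mapper do; a pipeline bypassing them must reverse-complement itself.
* The in-memory store holds the full index; the key-value abstraction is the
  seam for an on-disk or sharded backend, not a replacement for one.
* Synthetic genomes lack repeats, skewed composition and taxonomy; passing
  benchmarks here demonstrate the machinery's correctness and its behavior
  under substitution noise, not field accuracy on real collections.
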
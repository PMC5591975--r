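---
title: "Exact de Bruijn graph storage: the model behind havec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact de Bruijn graph storage: the model behind havec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(havec)
```

## The problem

Assemblers that work on a de Bruijn graph need, for every distinct k-mer of
a read set, two things: an exact membership test and the set of observed
outgoing edges. Explicit graph structures do not scale to the billions of
nodes a mammalian read set produces, and the classic space-efficient
alternative — a Bloom filter holding one presence bit per slot — buys its
compactness with false positives: two k-mers whose hash values share a
remainder modulo the table size are indistinguishable, and a spurious
"present" answer fabricates a node and, worse, a false edge.

`havec` removes the ambiguity instead of tolerating it. When a hash value
$v$ is split as

$$v = q \cdot M + r, \qquad r = v \bmod M,$$

the remainder $r$ addresses the table slot but the quotient $q$ is a
fingerprint: two distinct hash values in the same slot must differ in $q$.
If the hash function is additionally a *bijection* of the k-mer code space,
the pair (slot, quotient) pins down the hash value and hence exactly one
k-mer — membership answers cannot be wrong in either direction.

## The structure

Each of the $M$ table entries packs 40 bits (5 bytes):

| field              | bits | meaning                                        |
|--------------------|------|------------------------------------------------|
| neighbour bits     | 4    | which of A, C, G, T was seen following this k-mer |
| hash function index| 3    | which $H_i$ stored the entry; 0 = slot free    |
| quotient           | 33   | $\lfloor v / M \rfloor$ for the stored k-mer   |

Four neighbour bits cover all $2^4 = 16$ successor configurations a DNA
k-mer can have. An optional sixth byte holds a saturating occurrence count
(1–255) for cutoff-filtered assembly; the two layouts are otherwise
identical, and the package calls them 5-byte and 6-byte mode.

Insertion cascades over an ordered family $H_1, \dots, H_h$: the k-mer goes
to the first function whose slot is free, and the slot records which
function that was. When all $h$ probes hit occupied slots the k-mer spills
into a three-level auxiliary vector: level 1 is a fixed array of $V$
buckets addressed by $r_h \bmod V$ (with $r_h$ the last function's slot);
level 2 lists the distinct table slots that collided into the bucket; level
3 holds the (quotient, function index, neighbour bits[, count]) records per
slot. Lookups touch one bucket and scan lists whose lengths the spill rate
keeps tiny — about one spilled k-mer per thousand stored at the recommended
table sizing, so the lists are effectively constant-length.

Because every stored location carries its quotient and function index, the
whole k-mer set can be *enumerated* by inversion: slot and quotient
reconstruct $v = qM + r$, and applying $H_i^{-1}$ recovers the k-mer. This
is what `havec_kmers()` does; no separate key list is kept.

## Quotients need 33 bits — and that sizes the table

A k-mer code occupies $2k$ bits and the hash functions permute exactly that
space, so the largest hash value is $4^k - 1$ and the largest quotient is
$\lfloor (4^k - 1)/M \rfloor$. With 33 bits reserved for the quotient the
table must satisfy $M \ge 2^{2k-33}$: $2^{31}$ slots at $k = 32$, $2^{17}$
at $k = 25$, unconstrained for $k \le 16$. `havec()` enforces this floor at
creation (`min_table_size()`).

A design consequence worth stating: the hash functions here are bijective
mixing permutations *of the 2k-bit code space*, not of the full 64-bit
space. Only with this domain does the $2^{2k-33}$ floor hold for every $k$;
a 64-bit permutation would force $2^{31}$ slots even for short k-mers. At
$k = 32$ the two coincide. Each function is built from
multiply-by-odd-constant and xor-shift rounds modulo $2^{2k}$, all
invertible, with per-function constants derived deterministically from a
single master seed; the serialized graph stores only that seed.

The 3-bit function-index field can represent eight values, but value 0 is
the free-slot sentinel, so at most seven hash functions are usable. The
package caps `h` at 7 for this reason.

## Tunable parameters

* **k** (1–32): k-mer length. The 33-bit quotient budget is what limits
  k to 32.
* **M** (`table_size`): slots in the packed table. Memory is `M × 5` (or
  `× 6`) bytes; experiments with this family of structures put the memory
  optimum at 1.25–1.5 slots per distinct k-mer
  (`recommend_table_size()`, default factor 1.4). Growing M monotonically
  shrinks the vector spill (this is asserted as a trend test).
* **h** (1–7, default 4): probes per lookup. More functions fill the table
  more densely before spilling but cost probe time; 4 is a reasonable
  middle ground for tables sized by the rule above.
* **V** (`vector_size`): level-1 buckets of the spill structure. The
  worked example uses V = 3 for legibility; production guidance is absent
  from the original description, so the package defaults to
  `max(1024, M/1024)`, which at the observed ~1/1000 spill ratio keeps
  expected bucket occupancy near one sublist.
* **counts / cutoff**: 6-byte mode counts occurrences (saturating at 255).
  Cutoffs are applied at *query* time only; construction never drops a
  k-mer. One build therefore serves any cutoff in 1–255, and a filtered
  traversal stays closed because suppressed successors are filtered out of
  `havec_successors()` too. The alternative — dropping sub-cutoff k-mers at
  build time — would force a rebuild per cutoff and can orphan neighbour
  bits; query-time filtering was chosen for that reason.

## The worked example and one deliberate divergence

The package bundles a 15-base read with a stipulated (table-driven) hash
family so every step is hand-checkable (`worked_example()`). Replaying it
exercises first-probe insertion, second-probe insertion, vector spill, and
the in-place neighbour update when `TGTGT` recurs.

One step of the illustration's narrative is not consistent with its own
printed values: with hash1(`TGTGT`) = 34 and M = 11, `TGTGT`'s first probe
lands on slot 1, which is still free at that point in the insertion order,
so the algorithm stores it there (slot 1 ends up holding quotient 3,
function 1, neighbours CG) — the narrative instead sends `TGTGT` to the
vector and later puts `TGTCG` at slot 1. The package follows the algorithm:
`TGTGT` sits in the table and `TGTCG` spills. All printed entries that are
self-consistent (slots 0, 2, 3, 5, 8 and the `ATTGT` vector record at
bucket 2, table index 5) are reproduced verbatim and asserted in the test
suite. The stipulation table ships with a `synthetic` flag marking the few
hash values the illustration never prints but the replay must query (for
example the second probe of `TGTCG`, and values for never-inserted k-mers
that negative lookups hash); those values are arbitrary but fixed.

## Numerical and engineering choices

* **Base encoding**: A=0, C=1, G=2, T=3, first base most significant. Any
  fixed bijection works; this one sorts lexicographically and is frozen
  for serialization compatibility. 64-bit codes and hash values cross the
  R boundary as decimal strings because doubles lose exactness past
  $2^{53}$ (k > 26).
* **Ambiguous bases**: any window containing a non-ACGT symbol is skipped,
  and a window whose *following* base is ambiguous records no neighbour
  bit. This is standard assembler practice; the oracle shares the single
  window-scan implementation so the policy cannot diverge between builder
  and verifier.
* **Strand handling**: reads are used exactly as given — no
  reverse-complement canonicalization — mirroring the literal procedure
  the structure was described with. Callers wanting canonical k-mers can
  append reverse-complemented reads to the input.
* **Lookup-before-insert**: every observation first runs a full locate.
  Otherwise a k-mer stored under $H_j$ would be re-inserted under an
  earlier probe whose slot has meanwhile been read as free, duplicating
  it; the recurring-k-mer update path implies this order.
* **Segmented table allocation**: the table is backed by zero-filled
  segments (1 Mi entries each) allocated on first write. Untouched
  segments read as free entries. A table at the $k = 32$ floor of $2^{31}$
  slots is therefore cheap to create and to use sparsely — resident memory
  scales with the slots actually written, which is what makes routine
  verification runs at k = 31 and 32 practical on a laptop.
* **Bit order in the 40-bit word** (neighbours | function | quotient,
  most significant first) and little-endian byte order are frozen by the
  file format. The container adds a magic string, a version, the
  geometry-and-seed header, and a trailing FNV-1a checksum; any header
  tampering or truncation is detected at load. Stipulated families are
  not serializable (their values are not derivable from a seed) and
  `save_havec()` refuses them.

## What the synthetic generator does and does not emulate

`random_genome()` draws uniform i.i.d. bases; `sample_reads()` samples
uniform start positions on the forward strand and applies per-base
substitutions (default condition used in tests: 1%) and ambiguous-base
injection (0.2%) to exercise the skip policy. There are no indels, no
quality profiles, no coverage bias, no repeats beyond what uniform
sequence produces, and no reverse-strand reads. That is deliberate: the
properties under test — exactness of membership, neighbour sets, counts,
the table/vector partition — are combinatorial and do not depend on
realistic error structure, while substitution noise is exactly what
inflates the distinct-k-mer count and stresses occupancy and spill.
Passing tests therefore certify the data structure's correctness on any
read multiset; they say nothing about assembly quality on real libraries.

The test and verification runs use genomes of 10–50 kb at 5× coverage
with reads of length 100 (10 kb where k ≥ 31, since there the table floor
dominates memory), twenty builds across k ∈ {5, 15, 27, 31, 32}, an
exhaustive sweep of all 1024 5-mers, and an 8-step 5% table-growth ladder
at k = 15 starting from a deliberately undersized table (half the distinct
count) so that spill is substantial and its monotone decline is visible.

## Known limitations

* No contig/unitig extraction, graph cleaning, or multithreading — this is
  the storage layer only.
* The auxiliary vector grows without bound by design; an adversarially
  undersized table degrades toward the plain-list behaviour of the vector.
* k > 32 would need a wider quotient field and a different entry layout.
* SAM/BAM input is out of scope; convert to FASTA/FASTQ first.
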
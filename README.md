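# havec

Exact de Bruijn graph storage for genome assembly: a packed hash table
whose membership and neighbour queries are never wrong in either
direction, plus the spill structure, file formats, verification oracle,
read simulator and command-line tool around it.

## The problem and the idea

De Bruijn assemblers need, per distinct k-mer of a read set, an exact
membership test and the observed outgoing edges. Bloom-filter
representations fit in memory but answer "present" falsely whenever two
k-mers' hash values share a remainder modulo the table size — and a false
node fabricates false edges. `havec` stores what the Bloom filter throws
away. Splitting a hash value *v* by the table size *M*,

    v = q·M + r        (r = v mod M addresses the slot)

the quotient *q* is a fingerprint: values colliding in *r* must differ in
*q*. Each of the *M* slots packs 40 bits — 4 neighbour bits (one per
nucleotide that was seen following the k-mer), 3 bits naming which of the
cascaded hash functions H₁..H_h stored the entry (0 = free slot), and the
33-bit quotient. Since every H_i is a *bijection* of the 2k-bit k-mer
space, (slot, quotient, function index) identifies exactly one k-mer: no
false positives, no false negatives, and the stored set can even be
enumerated by inverting the hashes. Insertion probes H₁, H₂, … for the
first free slot; k-mers whose probes all collide spill into a small
three-level auxiliary vector keyed by the last function's slot index. An
optional sixth byte per entry keeps a saturating occurrence count so
abundance cutoffs (1–255) can be applied at query time, from one build.

The 33-bit quotient field forces `M ≥ 2^(2k−33)` (2³¹ slots at k = 32,
2¹⁷ at k = 25); `min_table_size()` and `havec()` enforce it. Memory is
`M × 5` (or `× 6`) bytes plus the measured spill payload; sizing the table
at 1.25–1.5 slots per distinct k-mer (`recommend_table_size()`) is the
sweet spot.

## A worked example

The bundled 15-base read `GGCAATTGTGTGTCG` with k = 5, an 11-slot table,
two stipulated hash functions and a 3-bucket spill vector is small enough
to check by hand:

```r
library(havec)
ex <- worked_example()
g  <- havec(ex$k, ex$M, ex$h, vector_size = ex$V, family = ex$family)
havec_build(g, ex$read)
g
#> <havec graph: k = 5, M = 11, h = 2, V = 3, 5-byte, stipulated hashes>
#>   10 distinct k-mer(s): 6 in table, 4 in vector; 1 read(s), 11 observation(s)
```

Eleven windows, ten distinct 5-mers (`TGTGT` occurs twice); six landed in
the table, four spilled. Queries report exactly where each k-mer lives
and which edges were observed:

```r
havec_locate(g, c("GCAAT", "ATTGT", "AAAAA"))
#>    kmer   kind index bucket ht_index pos hf
#> 1 GCAAT  table     5     NA       NA  NA  1
#> 2 ATTGT vector    NA      2        5   0  2
#> 3 AAAAA absent    NA     NA       NA  NA NA

havec_successors(g, "TGTGT")
#> [1] "GTGTC" "GTGTG"
```

`GCAAT` sits in table slot 5 (hash1(GCAAT) = 27 = 2·11 + 5, so quotient 2,
function 1); `ATTGT`, whose both probes collided, lives in the vector at
bucket 2 (= 5 mod 3) under table index 5; `AAAAA` was never read. `TGTGT`
recurred with different followers, so its entry accumulated neighbours C
and G. The full stored set comes back by hash inversion:

```r
havec_kmers(g)   # 10 rows: kmer, neighbours, count
```

Every build can be verified k-mer-by-k-mer against a brute-force oracle —
`compare_graph(g, kmer_oracle(ex$read, 5))` returns a zero-row
discrepancy report.

## Command line

```sh
Rscript inst/exec/havec.R simulate --length 10000 --n-reads 500 --error-rate 0.01 --seed 1 --out reads.fa
Rscript inst/exec/havec.R build    --input reads.fa --k 27 --mode 6byte --out graph.havec
Rscript inst/exec/havec.R query    --graph graph.havec --kmer ACG...   # membership + successors
Rscript inst/exec/havec.R stats    --graph graph.havec
Rscript inst/exec/havec.R dump     --graph graph.havec                 # TSV: kmer, neighbours, count
Rscript inst/exec/havec.R verify   --graph graph.havec --input reads.fa
```

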
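---
title: "Methods: reference curation, similarity search and taxonomy assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference curation, similarity search and taxonomy assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobarcode)
```

# The problem

Environmental-DNA metabarcoding of fish amplifies a short mitochondrial
marker (12S/16S rRNA, COXI, Cytb) from a water sample and asks which species
shed the DNA. Species-level resolution is limited by three things this
package addresses head-on:

* **reference databases contain chimeric records** — deposited sequences in
  which a segment actually derives from another species, so a perfect match
  can support the wrong name;
* **distinct species can share an identical marker region**, making a single
  "best hit" arbitrary;
* **off-target amplification** (human, amphibian, bird, invertebrate,
  rRNA/ITS carry-over) pollutes the read set.

The package curates a per-region-validated reference database, searches each
amplicon sequence variant (ASV) against reference plus a non-target
background, and reports species, *species complexes* (the set of
indistinguishable species, reported jointly instead of an over-broad LCA),
higher taxa, non-fish sources, or unassigned — with multi-sample
control/replicate bookkeeping on top.

# Reference curation

## Gene-name normalization and record merging

Deposited records name the same gene many ways (`rrnS`, `12S`, `s-rRNA`,
...). `normalize_gene_name()` maps the common spellings, case-insensitively
and ignoring hyphens/spaces, onto 15 canonical genes (2 rRNA + 13
protein-coding). Identical (sequence, gene, species) records are merged by
`merge_identical_sequences()`, pooling accessions and author names; an
identical sequence bearing conflicting gene labels is left split, with a
warning, rather than silently resolved.

## Per-chunk taxonomy validation

Chimeric segments in mitochondrial records can be as short as roughly
100 bp, so validation operates on 100-bp chunks rather than whole
sequences: chunks start at multiples of 100, and when the final chunk would
be short it is instead the *final 100 bp* (the last two chunks then
overlap). Genes shorter than 100 bp form a single whole-gene chunk and are
classified normally — dropping short partial genes would bias the database
against exactly the taxa with the least data.

For each chunk, homologs elsewhere in the database are collected at
**identity strictly above 99%** with at least 80% of the chunk covered
(semi-global alignment, both strands; records sharing an accession with the
query are excluded). The chunk is then classified by an
author-independence argument:

* **homospecific** — some homolog carries the *same species* label under an
  author set *disjoint* from the record's own: an independent submitter
  corroborates the taxonomy;
* **heterospecific** — *no* same-species homolog exists, and the homologs
  span at least two other species vouched by at least two mutually disjoint
  author sets: independent evidence the segment belongs elsewhere;
* **unknown** — anything weaker (no homologs, same-author evidence only, a
  single other species).

Author comparison uses normalized name sets (case-folded, punctuation
stripped); two records with *no* author metadata are treated as
not-independent, since independence cannot be demonstrated. Classification
depends only on the set of homologs, never on record iteration order.

Note that on a 100-bp chunk, "identity > 99%" effectively demands a perfect
copy (99/100 = 99.0 fails the strict inequality); this is deliberate — it
mirrors the printed threshold — and it means corroboration requires exact
agreement over the chunk, which same-species resubmissions provide.

## Habitat and occurrence data

Each species may carry a habitat profile (one water-column category,
multi-valued salinity and climate-zone sets) and occurrence coordinates.
Occurrences are deduplicated per species on a 1°×1° grid
(`floor(lat), floor(lon)` binning) — a deterministic O(n) reading of
"within a tolerance of 1 degree" — and proximity to a sampling site uses
the box metric `max(|Δlat|, |Δlon|)` with antimeridian wrapping, consistent
with the grid. Habitat/occurrence information is only ever *displayed* or
applied through explicit user filters; species lacking occurrence records
are never removed automatically, because absence of records is weak
evidence of absence.

## Background database

Non-fish sequences are clustered greedily at 97% global identity after
sorting by decreasing length (ties by id): a sequence joins the first
centroid within the threshold or founds a new one. Only centroids are kept
— the background is a filter that absorbs off-target reads, not a non-fish
identifier.

# The similarity-search engine

A self-contained aligner (C++; affine gaps) backs the whole stack, so no
external search binary is needed. Scoring is megablast-like: match +2,
mismatch −3, gap open 5, gap extend 2 (a gap of length L costs
`open + L·ext`); `N` matches nothing. **Identity is matching columns over
alignment columns, gaps included**; semi-global (ends-free) alignments
compute identity over the aligned core and report 0-based half-open
intervals; global alignments count terminal gap columns too, with terminal
gaps chargeable at their own rates (used by the long-read code, where
ragged amplicon ends are ubiquitous).

`search_topk()` emulates word-seeded search: subjects must share an exact
word with the query (28 bases in fast mode, 11 in sensitive mode), are
aligned on both strands, gated at ≥80% query coverage, and ranked by score
(ties broken by subject id; scores compared after rounding to one decimal,
the granularity at which tied bit-scores are meaningful).

Two search behaviours matter scientifically:

* **recursive top-hit saturation** (`recursive_top_hits()`): when a
  10-target search returns 10 hits all tied at the maximum score with
  identities at or above the species threshold, the tie may extend past the
  window; the search is repeated with the target count increased by 50
  until a lower-scoring hit proves the stratum complete. If the database is
  exhausted while still uniform, everything is returned and the result
  flagged unsaturated.
* **sensitive fallback** (`search_with_fallback()`): queries with no fast-
  mode hit are retried at word size 11, trading time for sensitivity, so
  divergent ASVs still receive their best hits.

An external BLASTN run can be substituted via `parse_hit_table()`, which
reads the 12/13-column tabular format (1-based inclusive coordinates,
minus-strand as `sstart > send`) into the same hit structure.

# ASV generation

## Short accurate reads

Reads are pooled across samples, dereplicated, and denoised by a
transparent abundance-skew rule (`denoise_simple()`): a unique sequence is
absorbed into a sequence at least 8× more abundant within 1 substitution —
the signature of a polymerase/sequencer error satellite. This is a
deliberate simplification of UNOISE-style denoisers (no β(d) error model,
no chimera detection), documented as such; precomputed ASV/OTU FASTA can
bypass the stage entirely (`read_asv_fasta()`), which is also the
reanalysis path against an updated reference. Defaults: `min_abundance = 2`
(unabsorbed singletons dropped, their total reported in an attribute so
reads can be reconciled), `max_dist = 1`, `skew = 8`. Runs that must
conserve every read use `min_abundance = 1`.

## Noisy long reads

Long reads are sorted by decreasing length and clustered greedily
(`nanopore_cluster()`); global alignment uses long-read penalties — match
+2, mismatch −4, internal gap open 4/extend 2, terminal open 2/extend 1
(the "4I/2E" convention: terminal gaps cheap). Each cluster's consensus is
the ASV: members align to the centroid, plurality base per centroid column
(ties to the centroid base), insertions kept only when present in more than
half the members.

**Choosing the clustering identity.** The threshold must sit between the
within-template and cross-template read-pair identities. At a per-base
error rate *e*, two reads of one template agree at roughly
`(1−e)² / (1+0.3e)` of columns (~94% at *e* = 3%), while reads of templates
≥5% apart agree at ~84%; the 97% default is therefore appropriate for
accurate long reads (*e* ≲ 1.5%) but over-splits 3%-error data. The bundled
long-read preset (`preset_nanopore()`) carries `cluster_identity = 90` —
the midpoint of the separating band implied by its own 3% error rate — plus
a cluster-size floor of 3 to drop stray error-rich reads. Because a greedy
pass can still split one template when an error-rich read founds a
centroid, consensus sequences within 97% identity are merged afterwards
(`merge_identity`); denoised consensuses of one template are near-identical
while cross-template consensuses stay near the template divergence, so the
merge is unambiguous.

# Taxonomy assignment

Each ASV's saturated top-score stratum is classified (`annotate_asv()`):

1. no hits → **unassigned**;
2. stratum entirely from the background → **nonfish**, labeled with the
   background taxon; a score *tie* between fish and background hits is
   resolved toward fish and flagged (`score_tie_with_nonfish`) — the
   platform exists to detect fish, and the flag preserves the ambiguity;
3. best fish identity below the species threshold (default 99%,
   user-adjustable) → **higher taxon**: the lowest common ancestor of the
   top-hit species over genus < family < order. A single sub-threshold
   species reports its *genus* — a near-miss to one species is evidence for
   the genus, not the species. No identity-band rank rules are applied;
4. at or above the threshold, the distinct top-hit species pass two
   filters: **nonbinomial names** (`sp.`, `cf.`, `aff.` ...) are dropped
   when a binomial is present (undescribed material should not displace a
   described species), then species whose *every* supporting hit lies in
   heterospecific reference territory are dropped (≥50% of the hit interval
   covered by heterospecific chunks, configurable via
   `hetero_overlap_frac`). One survivor → **species**; several →
   **species complex**, members sorted and joined by `/`. If the filters
   would empty the set, the unfiltered species set is kept and flagged
   rather than discarding the ASV.

Species-level calls aggregate read counts per sample by taxon label; higher
and non-fish calls stay per-ASV with the MD5 of the uppercase sequence, so
the same variant can be tracked across reanalyses. Total reads are
conserved across the three tables plus the unassigned remainder.

# Multi-sample matrices and published-result comparison

`build_matrix()` arranges species × samples in manifest order and computes
badges: **P** (detected in a positive control), **N** (negative control),
**S** (present in only a single replicate). "Single replicate" is read
globally by default — exactly one detection among replicate columns (groups
of size ≥2) and none in any other sample column — with a per-group variant
available; with one replicate group and no extra samples the two coincide.
Detection means count > 0 (`min_reads` raises the bar). Badges only flag;
nothing is subtracted or removed automatically. Matrices export to CSV
losslessly (counts and badges round-trip).

`compare_to_published()` categorizes each published taxon as
Single/Multiple/Clades/Diff/Undetected. Without per-ASV linkage to the
original study, "Diff" is approximated as: a congeneric species (for a
published species) or a species under the clade (for a published clade) was
detected instead; precedence is Single > Multiple > Clades > Diff >
Undetected, so every published taxon receives exactly one category. A
published clade resolved to a species *within* it counts as consistent
(Single) — the resolution improved, not changed.

# The synthetic-fixture generator

All tests run on generated data with known truth (`make_reference_db()`,
`plant_chimera()`, `simulate_reads()`, `make_background_contaminants()` and
the `preset_*` bundles). Design choices:

* species markers are a **star phylogeny** (root mutated independently per
  species) — adequate for identity-threshold logic, with no attempt at
  realistic tree shape;
* per species, the second record appends 10 extra 3′ bases: records stay
  distinct (surviving identical-sequence merging) yet corroborate each
  other's chunks exactly, with authors drawn from disjoint pools;
* the chimera preset plants a 150-bp donor segment, shared identically by
  two donor congeners, into the terminal region of one host record —
  emulating the documented pattern of chimeric terminal rRNA segments —
  leaving the host's second record clean;
* read errors are i.i.d. per base: substitutions only for the short-read
  model; a 40% substitution / 30% insertion / 30% deletion mix for the
  long-read model. No quality-score model, PCR bias, or chimeric read
  formation is simulated — so passing tests demonstrate the *algorithmic*
  contracts, not robustness to those real-data artifacts;
* identical seeds give byte-identical fixtures.

Problem sizes used by the test and validation suites — 12–16 reference
records of 600–660 bp, 250 long reads of ~200 bp, ~900 short reads across
five samples, 30 random search instances with up to 50 subjects — were
chosen as the smallest sizes at which every decision branch and invariant
is exercised with comfortable statistical margins.

# Numerical choices and degenerate inputs

* identity = matches / columns (gaps count) everywhere; one definition,
  stated once, used consistently;
* score ties compared after rounding to 1 decimal;
* greedy clustering order: length-descending, then id — deterministic;
* consensus ties resolve toward the centroid base;
* chunking of length < 100: one whole-sequence chunk; `length ≤ 0` is an
  error;
* out-of-range occurrence coordinates are skipped with a warning, not an
  error;
* empty author sets never demonstrate independence;
* heterospecific-overlap boundary: exactly 50% coverage triggers exclusion
  (inclusive).

# Known limitations

* The internal word-seeded search approximates, rather than reproduces,
  megablast/blastn seeding; E-values are parsed but never used.
* Denoising is a documented simplification; low-abundance ASV handling
  below `min_abundance` trades completeness for noise suppression.
* "Diff" in published-result comparison is a heuristic without per-ASV
  provenance from the original studies.
* Heterospecific detection requires at least two independent other-species
  homologs; a chimera corroborated by a single donor species remains
  "unknown" by design.
* All validation is against synthetic data; real amplicon data adds primer
  artifacts, chimeric reads and abundance skews the generator does not
  model.
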
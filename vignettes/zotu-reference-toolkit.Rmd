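---
title: "From publication text to fungal biogeography: the zotudb methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From publication text to fungal biogeography: the zotudb methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Public sequence archives hold thousands of fungal ITS metabarcoding runs,
but three obstacles keep them from being queried as one biodiversity
resource: the link between a publication and its archived runs is often
only a string buried in the article text; sample metadata (dates,
countries, coordinates, habitats) is free text in inconsistent dialects;
and every study processed its reads with a different pipeline, so the
resulting OTUs cannot be compared. `zotudb` addresses all three with a
uniform, offline, testable toolkit:

1. **Accession mining** recovers archive identifiers from plain article
   text.
2. **Metadata curation** standardizes dates, coordinates, countries,
   continents and habitat terms, keeping every raw value as provenance.
3. **The amplicon pipeline** converts raw FASTQ runs into zero-radius
   OTUs (ZOTUs): denoised, error-corrected unique sequences that are
   comparable across datasets *without reclustering*, because identity is
   exact string equality.
4. **The reference store** maintains the deduplicated ZOTU set with a
   `contains` provenance relation (which samples and runs each ZOTU was
   seen in) and a `Process` record of every parameter used.
5. **Biogeography queries** answer phylum-by-continent, shared-ZOTU and
   latitude-band questions by set algebra over presences.

A sixth module generates every input synthetically with known ground
truth, so the complete framework runs and is verified with no network
access and no downloads.

# Accession mining

Nine prefix classes are recognized — the SRA namespaces (`SRA` submission,
`SRP` study, `SRS` sample, `SRX` experiment, `SRR` run), the BioProject
namespaces (`PRJNA`, `PRJEB`) and the ENA namespaces (`ERP`, `ERS`). A
match requires the prefix, then 4–9 digits, with non-alphanumeric (or
string) boundaries on both sides. The boundary rule is the package's own
tightening of the prefix list: real INSDC accessions fit it, and it
eliminates in-word false positives ("**surp**lus" does not contain an SRA
hit) and digit-less mentions ("the SRA Study"). Run ranges such as
`SRR1502225–SRR1502736` are reported as two endpoint matches; expansion is
a separate, explicit utility (`expand_accession_range()`), because en/em
dashes in typeset PDFs make inline expansion lossy.

Structured cross-references (the DataBankList element of a PubMed record,
supplied by a local-file adapter) take precedence over text mining when
present; entries that fit no known prefix class are rejected with a
report, never silently dropped. PDF-to-text conversion is deliberately an
adapter boundary — the core consumes strings — since identifiers embedded
in PDF tables defeat text extraction anyway and need manual retrieval.

Primer resolution scans SRA experiment design descriptions for mentions of
universal ITS primers. The bundled primer table adds a `direction` column
(forward/reverse) to the name/sequence/marker/alias schema, because an
oriented pair is what the pipeline needs and published primer tables carry
this annotation. Ambiguity — two candidate primers in the same direction,
or a marker conflict — yields no resolution rather than a guess.

# Metadata curation

Curation is **non-destructive**: every curated record carries the raw
value of each field (`raw_*` columns), and reconstructing the raw input
from provenance is byte-exact — a property the tests enforce.

*Dates* are standardized to ISO 8601 from a fixed dialect list
(`YYYY-MM-DD`, `DD-Mon-YYYY`, `Mon-YYYY`, `YYYY`, `MM/DD/YYYY`). Partial
dates keep only the precision present ("Aug-2014" becomes "2014-08");
anything else fails soft to missing with a log line. The dialect list is
closed on purpose: silent guessing would corrupt provenance.

*Coordinates* are parsed from signed decimal, decimal-with-hemisphere and
degree–minute–second notation; DMS converts as deg + min/60 + sec/3600,
negated for S/W, rounded to six decimals. Out-of-range values are treated
as absent, with a warning.

*Geography* is assigned from a bundled gazetteer (50+ countries with
aliases, GeoNames identifiers, continents, centroids and bounding boxes).
Three coordinate sources are distinguished and recorded:

- `REPORTED` — coordinates given and inside the country's bounding box;
- `CENTROID_FALLBACK` — no coordinates; the country centroid substitutes
  exactly (samples stay mappable at country resolution);
- `CORRECTED` — coordinates reported but outside the country's box; the
  centroid replaces them. This is the package's offline replacement for a
  map-service-based repair step: bounding-box containment is deterministic
  and reproducible, at the cost of coarser boxes than a real border test.
  Samples near borders or in overseas territories can be misjudged; the
  raw value always survives in provenance.

When the raw country term is unknown to the gazetteer, country, continent
and identifier stay absent, but parsed coordinates are retained as
`REPORTED`: the coordinates are the sample's own observation, not a
gazetteer inference, and discarding them would lose information. When a
known country conflicts with in-box coordinates of a different country we
keep the coordinates and flag nothing further — guessing intent is out of
scope.

*Habitat terms* are tagged by exact, case-insensitive dictionary lookup
against a bundled ENVO term list; the longest contained label wins
("forest soil" beats "soil"). This keeps the contract of a named-entity
recognizer (term in, ENVO identifier out) with deterministic behaviour.

# The amplicon pipeline

Stage order for paired (Illumina) platforms: primer trimming of both
mates, pair merging, expected-error filtering, dereplication, denoising,
taxonomy filtering. Single-read platforms (454, Ion Torrent) skip the
merge; the filter/denoise path is otherwise identical, which we note as a
simplification — no flow-specific (homopolymer) error handling is
attempted.

**Defaults and why.** maxEE = 1.0 expected errors (inclusive: EE equal to
the bound passes, following the convention of the expected-error filtering
literature), minimum overlap 60 bp, minimum length 250 bp after trimming
and merging. The denoiser uses the published defaults of the UNOISE3
algorithm it implements: alpha = 2 and min_size = 8. Every value is
configurable and every run's values are frozen into the `Process` record,
so results remain reinterpretable.

**Primer trimming.** The forward primer must match at the 5' end with at
most one IUPAC-aware mismatch; the reverse primer's reverse complement, if
found downstream, is removed together with everything 3' of it. Reads
without a 5' hit are discarded and counted.

**Merging.** The reverse mate is reverse-complemented and slid against the
forward read; the offset maximizing matches − 4 × mismatches (the classic
overlap score) wins. A merge is accepted only if the overlap is at least
`min_overlap` bases at ≥ 90% identity. Consensus: agreeing positions get
quality min(Qf + Qr, 41); disagreements resolve to the higher-quality base
with quality |Qf − Qr| (ties to the forward read). This simple posterior
rule has a useful side effect: a disagreement between two good-quality
bases yields a near-zero merged quality, so the expected-error filter
later removes reads whose overlap was inconsistent.

**Denoising.** Uniques are processed in decreasing abundance (ties
lexicographic). A unique of abundance *a* joins the nearest eligible
centroid — one at edit distance *d* whose own dereplicated abundance
*a\_c* satisfies *a/a\_c* ≤ β(d) = 1/2^(αd+1) — and otherwise founds a new
centroid if *a* ≥ min_size. The skew test uses the centroid's *own*
abundance, not its accumulated total, matching the cited algorithm;
distance ties resolve to the earliest (most abundant) centroid. With zero
errors and min_size = 1, denoising is the identity on well-separated
dereplicated input. Chimera removal is deliberately absent from the
default path: the procedure this package reimplements does not describe
one, and inventing a stage would change results silently.

**Taxonomy filter.** Each ZOTU is aligned against a lineage-bearing
reference FASTA (UNITE-style headers,
`accession|k__…;p__…;…;s__…|SH-id`). Identity is matches / alignment
columns of the best global alignment with free end gaps, scored match +1,
mismatch −1, gap −1 per position. The gap-tolerant scoring matters: with
heavily gap-penalized ends-free alignment, unrelated sequences "win" short
perfect overlaps and report absurdly high identities; with this scoring,
unrelated 150–300 bp sequences settle near 50–60%, safely under the 70%
contamination threshold, while genuinely related sequences align
full-length. A ZOTU is kept iff its best hit is at least 70% identity
*and* the hit's kingdom is Fungi; both the lineage and the identity are
stored. Ties go to the first reference in file order.

**Conservation.** The stage report satisfies
reads_in = trim_discarded + merge_failed + filter_removed +
denoise_unabsorbed + Σ ZOTU abundances, checked by tests — no read is
silently lost.

# The reference store and incremental update

The store holds the integrated components (literature, studies,
experiments, samples, runs, reference sequences, `contains`, `Process`,
taxon assignments). Zero-radius semantics make deduplication exact string
matching on uppercased sequences; there is no near-duplicate merging. The
incremental update inserts a new reference row on a miss and only a
`contains` row on a hit; replaying a (reference, run) pair is a no-op, so
updates are idempotent per run, and inserted + reused = contains_added
holds for every update — the additivity that published update tables
exhibit. (One printed total in the source material is off by one from its
own additivity; the store enforces the law, not the typo.) Reference
identifiers are assigned in insertion order and are documented as
non-semantic: permuting the sample order permutes identifiers but never
the reference sequence *set*. Abundance is stored per `contains` row as a
harmless superset of the published semantics, which never read it.

The backing engine is an in-memory set of data frames with CSV
import/export, because no embedded SQL driver is available in the target
environment; the interface is engine-agnostic and the export/import round
trip is field-by-field exact. "Sample is always defined" is enforced at
ingest: experiments without a sample, and runs pointing at missing
experiments, are rejected record by record with a report.

# Biogeography queries

All queries are presence-based set algebra derived from
`contains` → sample → curated location. `phylum_by_continent()` counts
distinct ZOTUs per (phylum, continent); a ZOTU spanning continents counts
once per continent, so column sums can exceed the global distinct count —
that double-counting law is itself a tested invariant. Phyla outside a
configurable display list pool into "Other"; unresolved phyla into
"Unidentified". `shared_zotus()` and `pairwise_overlap()` compute
|Z(u) ∩ ∪Z(v≠u)| and |Z(u) ∩ Z(v)|; per-continent "number of ZOTUs" is
reported as distinct-per-continent (the diagonal of the pairwise matrix),
the reading we fixed where the source tables are ambiguous.
`taxon_in_latitude_band()` defaults to the tropics at ±23.43651°, the
standard astronomical tropic latitude, configurable and recorded.

# What the synthetic world does and does not establish

The generators state a world and stay there:

- Libraries: 10 true ZOTUs of 260 bp at pairwise edit distance ≥ 5,
  200 reads each, 0.5% per-base substitution error, constant Q30,
  250 bp paired reads — a small, clean Illumina ITS2 run.
- References: the true ZOTUs under fungal lineages, plus random fungal
  padding and non-fungal decoys verified at generation to align below
  70% identity to every true ZOTU.
- Corpora/metadata: one planted accession per prefix class amid decoy
  substrings; metadata rows covering every recognized date and coordinate
  dialect plus malformed rows whose truth entries mark expected-absent.

The error model is substitution-only by default so that edit-distance
truth stays exactly computable for denoiser checks; indels and
platform-specific error profiles (454 homopolymer noise) are not
simulated. Consequently a green planted-recovery test establishes that the
pipeline's stages compose correctly and that the denoiser separates
well-spaced templates at realistic error rates — it does not establish
performance on chimeras, length-variable ITS extraction, or homopolymer
noise, none of which the stated world contains.

# Numerical choices and degenerate inputs

- Quality arithmetic is exact (EE = Σ 10^(−Q/10)); the maxEE boundary is
  inclusive and tested.
- Dereplication breaks abundance ties lexicographically, making every
  downstream ordering deterministic.
- Merge offset search scores all relative shifts via FFT
  cross-correlation; identical scores resolve to the first (smallest)
  shift.
- Empty inputs propagate as empty outputs with zeroed counts everywhere
  (empty FASTQ → empty FASTA; empty store → empty query tables); contract
  violations (a paired platform without a mate file, a malformed reference
  header, an unknown taxonomic rank) are hard errors raised before any
  processing.
- Coordinates round to six decimals (≈ 0.11 m), far below gazetteer
  precision; round-trip error is bounded by 1e-6 degrees in tests.

# Known limitations

Bounding-box coordinate correction is coarser than true border geometry;
the ENVO tagger is a dictionary, not a recognizer; GENBANK-style processed
identifiers are out of scope by design; the store is single-writer and
desk-scale; and network acquisition (PubMed, archive fetch, gazetteer
lookups) is permanently behind local-file adapters — by construction, the
package never performs a download.
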
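---
title: "Structure-based transposable-element mining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based transposable-element mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

strucTE detects complete transposable elements (TEs) in assembled genome
sequence from their structural hallmarks alone — no repeat library of the
target species, no protein searches, no external aligners. Three element
classes are covered, each with its own detector, plus shared
repeat-library curation operations, a classification-code registry with a
header codec, a planted-element genome simulator, and recall/precision
scoring. The package deliberately stops where external evidence starts:
protein-homology calls, masking fractions and domain annotations enter as
plain tables, so the structural logic stays testable in isolation.

# The detectors

## Helitrons

Helitrons are rolling-circle transposons. They create no target-site
duplication and carry no terminal inverted repeats; their only reliable
structural signature sits at the 3' end: a short palindromic hairpin,
a spacer, and a CTRR terminus (R = A or G), with the element inserted
between a host A and a host T.

Detection is two-step, stringent-then-relaxed:

1. **Terminus discovery.** `scan_hairpin_termini()` scans both strands
   for the pattern *stem(7–10 nt) / loop(2–4 nt) / second arm within one
   substitution of the first arm's reverse complement (no indels) /
   spacer(6–10 nt) / CTRRT*. When several (stem, loop, spacer)
   placements explain one terminus, the longest stem, then the smallest
   loop, then the smallest spacer is kept — the most stable hairpin.
   Stems that are mono- or dinucleotide repeats (dinucleotide entropy
   ≤ 1 bit) are removed as low complexity. Termini are grouped into
   families of *identical* stems; families under 5 members are not
   considered.
2. **End-library construction.** For each family member a context tract
   (15 kb upstream through 200 bp downstream of the terminus,
   strand-normalized) is extracted. What a curator would do with
   dot plots is automated in `infer_family_ends()`: every tract pair is
   extended upstream from the anchored terminus (ungapped, +1 match,
   −3 mismatch, X-drop 12); the family boundary is the modal supported
   extension, because chance flank matches push individual pairs a few
   bases past the true limit while most pairs stop exactly at the shared
   host A. The host A itself is then pinned by a member-wise vote in a
   ±10 bp window (strongest A support first, then proximity), and the
   element starts immediately after it. Families without near-unanimous
   A support are rejected — a family-level application of the insertion
   rule. The first and last 40 bp of the inferred element become the
   family's end library.
3. **Relaxed genome scan.** `scan_end_library()` slides each 40 bp tract
   (both strands) reporting every placement with ≤ 4 mismatches;
   `pair_helitron_ends()` pairs a 3' hit with its nearest eligible
   5' hit of the same family and strand, requiring a span strictly
   between 200 bp and 15 kb, ≤ 4 mismatches per end, ≤ 1 mismatch in the
   terminal CTRR, and the A|element|T context. Overlapping same-family
   calls merge to the longest, and every call is re-checked by an
   independent validator before being emitted.

The A|element|T context is checked identically on both strands because
it is reverse-complement symmetric. The insertion rule itself is not
spelled out operationally in the pattern — we adopt the canonical
reading (host A immediately 5', host T immediately 3') and expose it as
a switch (`at_rule = FALSE` disables it).

## MULEs

Mutator-like elements are called from a library of TIR-family consensus
sequences (supplied, or produced by the simulator). Families with ≥ 30 %
of their length masked by known non-MULE repeats are removed first
(masking fractions are an input table). `locate_tir_hits()` finds
full-length consensus matches at ≥ 80 % identity on both strands;
`pair_tirs()` forms candidates from same-family, opposite-orientation hit
pairs with inner distance < 20 kb (inner edge to inner edge — the bound
is applied between the TIRs, not across them). `validate_tsd()` then
searches for a flanking 7–11 bp target-site duplication over a ±10 bp
swing of each end, comparing flank k-mers by unit-cost Levenshtein
distance with length-dependent tolerances: 7 bp must match perfectly,
8 bp allows one edit, 9–11 bp allow two.

The best TSD among all (length, offset) combinations is chosen by
**lowest edit distance, then smallest total offset, then longest
length**. Length-first ordering (the other natural choice) is provably
wrong here: a perfect 9-mer TSD always also yields a (10 bp, distance 2,
offset 0) match — the 10-mers are h+X versus X+h′, two edits apart — so
length-first would systematically report inflated TSD lengths, and with
a ±10 bp swing a random flank pair passes *some* 9–11 bp combination
with probability near one. Distance-then-offset ordering recovers the
true duplication uniquely; the same ordering resolves overlapping
candidate elements.

De novo TIR families need ≥ 5 TSD-validated elements genome-wide (known
families are exempt). Classification is evidence-driven and external:
calls containing a known non-MULE transposon hit are dropped; transposase
homology plus length > 3 kb makes a call autonomous; other protein
homology makes it a Pack-MULE; the rest are non-autonomous. All homology
uses an e-value < 1e-9 cutoff on the supplied table.

## MITEs (Stowaway and Tourist)

Short non-autonomous DNA transposons are found by an exhaustive
inverted-repeat scan in 1000 bp windows with 200 bp overlap. The window
bounds the element *start*; flanks and body are read from the full
sequence, so results are invariant to the tiling (a property the tests
assert). Two superfamily rules are implemented exactly:

* **Stowaway**: a TA dinucleotide TSD immediately flanking the element
  and the canonical CTCCTCCC motif within the TIR (minimum TIR 10 bp so
  the 8 bp motif plus TSD adjacency is meaningful);
* **Tourist**: identical 3 bp flanks, TIR starting with G or C, TIR
  ≥ 8 bp.

TIR complementarity allows ≤ 1 substitution, no indels; the reported TIR
length is the maximal complementary run within that budget. Element
length defaults to 50–800 bp — the typical MITE range; both bounds are
configurable. All rule checks are applied on both element readings,
since an element stored in reverse orientation presents the mirrored
structure.

Candidates are clustered greedily (longest first, ≥ 80 % global identity
to a centroid, reverse complements folded). Three curation rules turn
clusters into families: a family must occupy at least two distinct loci
(nested candidate calls at one site are one copy); a group whose member
loci mostly overlap a larger retained family is a shifted-variant shadow
of it and is dropped; and the first-round consensus is built against a
member of the group's *modal* length, because the longest member — the
clustering centroid — is occasionally a chance boundary-extended variant
that would skew the consensus ends. A second-round consensus is rebuilt
from up to 40 best-identity genomic copies (fewer are used, with a
message, when fewer exist). Final consensuses are mapped genome-wide;
where families compete for a locus the longest hit wins, ties by higher
identity then lower family id, and surviving placements are
non-overlapping.

## The combined pipeline

`annotate_genome()` runs Helitrons, then MULEs, then MITEs with the
earlier calls masked from the MITE candidate scan. Identical copies of a
large TE family necessarily repeat their internal sequence, and repeated
interior segments satisfy the loose Tourist rule (identical 3-mers plus
an 8 bp inverted repeat) at an appreciable rate, so unmasked MITE mining
over a fresh large-TE family would report its internal chance structures
as MITE families. Annotating large elements first and masking them is
the standard ordering in repeat annotation; the MITE detector remains
fully usable standalone.

# Library curation

* `composition_filter()` removes sequences with < 5 % AT or < 5 % GC
  content (N excluded from both numerator and denominator; all-N
  sequences removed). A sequence at exactly 5 % is kept.
* `cluster_redundancy()` collapses a library at 90 % identity by greedy
  longest-first centroid clustering; identity is matches over all
  columns of a global gapped alignment (terminal gaps included), so "90 %
  similarity" means similarity across the entire length.
* `define_families()` groups sequences by single linkage under the
  80-80-80 convention: ≥ 80 % identity over ≥ 80 % of the shorter
  sequence with ≥ 80 bp aligned.
* `select_centroids()` reduces a family to representatives at 80 %
  identity (the within-family redundancy step).
* `filter_small_families()` removes families with fewer than three
  copies unless a member carries a Copia/Gypsy domain annotation
  (annotations are an input table).
* `trim_filter()` keeps only elements shorter than 1.6 kb without
  reverse-transcriptase homology — the defining bounds of terminal-repeat
  retrotransposons in miniature.

Identity conventions for the clustering steps are stated rather than
inherited from any particular external tool; the global-alignment
definition above is the default and the one the tests pin down.

# The simulator

`simulate_te_genome()` builds an i.i.d. background (default GC 0.44,
the gene-poor intergenic composition typical of grass genomes) and
plants structurally exact elements:

* Helitrons (default 600–1500 bp, 4 families × 5 copies): body + hairpin
  + spacer + CTRR, inserted between a host A and T (the context is
  created at the site);
* MULEs (default 2200–3800 bp total, TIRs 100–180 bp, 4 families × 5
  copies): TIR + body + reverse-complement TIR, flanked by a duplicated
  host 7–11-mer TSD (length drawn per copy);
* Stowaway and Tourist MITEs (default 130–450 bp, 3 families × 5 copies
  each): motif-bearing or G/C-initial TIRs, TA or host-3-mer TSDs.

Copies are planted at uniform non-overlapping sites on random strands;
TSDs duplicate the actual host k-mer, so flank statistics are realistic.
Divergence is per-copy independent substitution (no indels), applied
after duplication so TSD and TIR degradation is realistic; boundary
truth stays exact by construction. Families of five copies are the
defaults because five is the support floor both the Helitron terminus
grouping and the de novo MULE rule impose — the study conditions
exercise the thresholds at their boundary.

Element bodies are rejection-sampled so that no planted element contains
a chance hairpin+CTRRT terminus other than a Helitron's own designed
one. Without this screen, an identical-copy family of any kind would
propagate every chance terminus in its body to all five copies,
manufacturing a valid terminus family out of background probability —
about one expected per 3 kb family at this composition. The screen keeps
the benchmark's truth unambiguous; it is a statement about the
*benchmark*, not about real genomes, where such embedded signatures do
occur and are handled by masking and curation.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: indel divergence and
truncated copies (the substitution-only matcher will not recover them),
nested insertions, solo ends, segmental duplications, low-complexity and
satellite background, GC heterogeneity, and assembly artifacts. A
Markov-chain background and an indel mode are deliberately out of the
default conditions so that boundary exactness remains well-defined.

# Numerical and convention choices

* **Coordinates** are 1-based inclusive everywhere — the native
  convention of R, IRanges and GFF3 — including in headers, which print
  genomic coordinates the way the worked example
  `RLG_#LTR/Gypsy_Ojapo1_fam7_Chr4_7056110_7070993 hopi FL` does.
* **N policy**: characters outside ACGTN become N on input, and N never
  matches anything in any detector, including another N — conservative
  for TIR/TSD evidence.
* **Matching** is substitution-only (Hamming) wherever the criteria are
  phrased as mismatch counts ("4 mismatches out of 40 bp"); edit
  distance is used exactly where the criteria say mismatches/indels
  (TSD validation). The consensus-to-genome matcher is a full-length
  Hamming scan at ≥ 80 % identity; under substitution-only divergence it
  is exact, and its blindness to indel-diverged or truncated copies is a
  stated limitation rather than a silent one.
* **Tie-breaks** are fixed and documented everywhere randomness could
  creep in: hairpin placement (longest stem / smallest loop / smallest
  spacer), TSD choice (distance / offset / length / leftmost), greedy
  cluster order (longest first, lexicographic), placement conflicts
  (longest / identity / family id), consensus ties (A < C < G < T, base
  beats gap).
* **Degenerate inputs**: empty candidate sets flow through every
  operation and produce empty, correctly-typed results; families whose
  tracts yield no consistent boundary or fail the AT vote are rejected
  with a logged reason, never an error.

# Problem sizes in the test-suite

The suite validates the scanners against brute-force oracles that
enumerate every placement (hairpin scan, end scan, TSD decision, MITE
triple loop) on 50–60 random sequences of 0.6–2 kb each, and runs the
full pipeline on a 500 kb genome with 70 planted elements (20 Helitrons,
20 MULEs, 15 Stowaway, 15 Tourist) at 0 % divergence, where it requires
100 % recall, 100 % precision and zero boundary error for every
detector. Smaller 60–150 kb genomes exercise individual detectors,
divergence monotonicity and strand handling. These sizes were chosen to
keep the whole suite comfortably under a quarter hour on a single core
while still crossing every threshold the methods define.

# Known limitations

* Step-1 Helitron families require *identical* stems; at a few percent
  divergence many terminus families fall under the 5-member floor, so
  sensitivity on diverged genomes depends on supplying an end library
  from a better-conserved relative (the two-step design anticipates
  exactly that use).
* The 80 % identity floors throughout mean elements diverged beyond
  ~20 % from their family consensus are invisible.
* MITE family curation assumes families do not legitimately nest inside
  one another at most of their loci; heavily nested MITE landscapes
  would need the overlap-redundancy rule relaxed.
* Scoring matches calls to truth at ≥ 80 % reciprocal overlap within an
  element kind; fragmented calls covering one element as two pieces
  count as misses, which is the conservative choice.
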
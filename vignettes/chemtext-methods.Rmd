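---
title: "chemtext: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemtext: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtext)
```

`chemtext` mines chemistry from plain text in four stages: tokenisation,
entity recognition, name-to-structure resolution and experimental-data
checking. This vignette is the package's own account of the methods: what
each model assumes, which knobs matter, and where the design was genuinely
open and a choice had to be made.

## Document model

All annotations are standoff: the source text is never mutated, and every
token and entity carries 0-based, half-open character offsets into the
NFC-normalised text such that slicing the text by `[start, end)`
reproduces the surface exactly. Offsets count Unicode code points, not
bytes or UTF-16 units; this makes slicing unambiguous across platforms and
is asserted by property tests throughout the suite. Entity types form a
closed set — CM (chemical), ONT (ontology term), RN (reaction), CJ
(chemical adjective), ASE (enzyme), CPR (chemical locant prefix) — plus
DATA, which lets parsed experimental-data spans share the standoff
JSON/TSV channel with named entities.

## Tokenisation dialect

Chemistry text defeats generic tokenisers: `C-H`, `C2H6O`, `NSC-2648` and
`2,5-dichlorobenzylamine` must each survive as one token. The tokeniser
therefore splits on whitespace and then iteratively detaches edge
punctuation (default set `. , ; : ! ? " ' ( ) [ ] { }`) into separate
tokens, with three deliberate exceptions:

* **Trailing periods** stay attached when the unit is a known abbreviation
  (`Fig.`, `calcd.`, an editable list) or a single letter plus period
  (`A.`), since those periods are part of the token, not sentence
  punctuation.
* **Brackets** are detached only when that leaves the bracket pair
  balanced in the remainder, or when the pair wraps the entire unit. So
  `(42).` unwraps to `(` `42` `)` `.`, while `poly(ethylene)` and
  `(S)-ibuprofen` stay whole. The wrapping clause is essential: requiring
  balance of the remainder alone would also forbid unwrapping `(42)`,
  which is clearly parenthesis noise rather than nomenclature.
* **Hyphens** are internal by default (`C-H` is one token); a unit splits
  into head, `-`, suffix only when the text after the final hyphen is in a
  configurable suffix list (`based`, `containing`, `free`, `rich`,
  `dependent`, `induced`, `mediated`, `derived`, `treated`). These
  suffixes mark compositional modifiers ("water-based") whose head should
  be visible to the recognisers on its own.

Paragraphs — maximal runs separated by blank lines — are the processing
unit; there is no sentence splitter, because no stage here needs one. A
parallel normalised surface (subscript digits mapped to ASCII) is used by
the classifiers; offsets always refer to the unmapped text.

## The n-gram token classifier

The pattern recogniser's core is a character n-gram naive Bayes model.
Chemical and non-chemical word lists (the latter defined as an English
word list minus the chemical list, case-folded) are each summarised by
counts of all length-*n* windows of every padded word (`n−1` leading `^`
markers, one trailing `$`). A token is scored by the smoothed
log-likelihood ratio
$$ s(w) \;=\; \sum_{g \in \mathrm{grams}(w)} \Big[ \log \frac{c_{\mathrm{chem}}(g)+\alpha}{T_{\mathrm{chem}}+\alpha V} \;-\; \log \frac{c_{\mathrm{non}}(g)+\alpha}{T_{\mathrm{non}}+\alpha V} \Big], $$
where \(V\) is the number of distinct n-grams seen in either class plus
one shared unseen bucket, and the chemical probability is the logistic
transform of the score offset by the prior log-odds,
\(p = \sigma(s + \mathrm{logit}(\pi))\).

Parameter choices, all exposed:

* **n = 4.** Short enough to generalise from small lexicons, long enough
  to capture morphemes like `-ene`, `-ylat`, `chlor`.
* **α = 1** (additive smoothing) with a shared unseen bucket — the
  simplest scheme under which swapping the two word lists exactly negates
  every score, a symmetry the tests assert.
* **prior π = 0.5**, so a zero score maps to probability 0.5. Corpus
  frequencies could inform a different prior; it is a parameter precisely
  because that is a modelling judgement, not a fact.
* Tokens are case-folded and digits are mapped to `0` before windowing, so
  the model learns digit *shape* rather than particular numbers.

One consequence of additive smoothing with unequal class totals: a token
made entirely of unseen n-grams scores \(m \log\frac{T_{\mathrm{non}}+\alpha
V}{T_{\mathrm{chem}}+\alpha V}\), which is positive whenever the chemical
class has fewer training windows. Punctuation tokens would therefore
drift "chemical". The pattern recogniser consequently never marks
pure-punctuation tokens as chemical — a deliberate guard, documented here
because it modifies the raw threshold rule.

## The pattern recogniser

Tokens with \(p \ge\) threshold (default 0.5) are marked chemical; within
each maximal run of chemical tokens, multi-token glob patterns (`*yl
*ate`, `*yl *ide`, `*ic acid`, `*ium *ide`; `*` is the sole wildcard,
whole-token anchored, case-folded) are matched left to right, the longest
pattern winning at each position; matches become multi-token CM entities
and unconsumed chemical tokens become single-token CM entities. Entity
confidence is the geometric mean of member probabilities — the natural
length-normalised product of independent token probabilities.
Longest-leftmost selection is the standard deterministic tie-break for
lexical matchers, and the greedy scan is verified against a brute-force
all-spans matcher in the tests.

## The MEMM recogniser

The trainable tagger labels each token with one of nine labels — `O` or
`B-t`/`I-t` for the four entity classes — a minimal scheme that supports
multi-token entities of every class. It is a Maximum Entropy Markov
Model: one multinomial maximum-entropy classifier predicts the label from
local features plus an indicator of the previous label (`prev=START` at
sequence start). Features per position: exact and case-folded surface,
word shape (character classes compressed, so `C-H` → `A-A`), prefixes and
suffixes of length 1–4, character trigrams of the padded surface, the
decile bucket of the n-gram chemical probability, a punctuation flag, and
the same items for both neighbours (`prev:`/`next:`, with `BOS`/`EOS`
pseudo-tokens at the boundaries contributing their surface feature).

Training converts gold spans (which must align with token boundaries;
misaligned spans are a named data error) to B/I/O sequences and maximises
the L2-regularised conditional log-likelihood with L-BFGS
(`stats::optim`), analytic gradients and a sparse design matrix. The
objective is convex and optimisation starts from zero weights, so
training is exactly reproducible; defaults are L2 strength 1.0 and at
most 200 iterations.

Decoding runs Viterbi over the label alphabet with the hard constraint
that `I-t` may only follow `B-t` or `I-t`; disallowed transitions get
probability zero *without* renormalisation, and the same convention
defines all path probabilities. Each decoded entity's confidence is a
constrained marginal: the probability mass of all valid label paths that
agree with the span's exact labels, divided by the mass of all valid
paths, computed by masked forward passes in log space. This definition
was chosen because it is exactly testable — the suite checks Viterbi
paths and confidences against exhaustive enumeration over all `9^L` label
sequences for short sequences, to 1e-9.

Known caveat, deliberately not mitigated: per-position normalisation
gives MEMMs label bias — mass entering a state must leave it regardless
of how well later observations fit. A CRF would remove it at the cost of
global normalisation; the plain MEMM is kept as the simpler, faithful
architecture.

## Lexicon stages

*Ontology lookup* is longest-leftmost dictionary matching over normalised
(case-folded, single-spaced) token surfaces; matches are token-aligned by
construction, carry every identifier registered for the term, and the
scan is verified against a brute-force all-substrings oracle. *Prefix
detection* is a deterministic finite automaton built from data (a JSON
list of literal items plus digit runs): one or more items — digit runs,
Greek letter names and symbols, R/S/E/Z, cis/trans, o/m/p, N/O locants —
separated by commas and terminated by a hyphen, applied to each token's
start; the longest accepting prefix becomes a CPR entity. The item
vocabulary ships as data because no canonical list of locant prefixes
exists; the DFA is checked against an independently constructed reference
regex. *Serial numbers* are whole-token regex matches (default
`^[A-Z]{2,4}-[0-9]+$`), confidence 1.

## Resolution

CM surfaces are looked up, case-folded and whitespace-collapsed, in an
ordered registry of name dictionaries (TSV: name, format, value).
Structures concatenate in registry order with exact duplicates (same
format and value) removed — dictionaries frequently share InChIs, and
reporting the same structure twice would misrepresent the evidence.
Permuting the registry can permute structure order but never changes the
resolved/unresolved verdict. A fallback hook fires only when every
dictionary misses; this is the integration point for an external
systematic-nomenclature parser, kept out of the package's dependencies on
purpose. Unresolvable entities are represented by absence, never by an
empty structure list.

## Experimental-data checking

Journal-mandated data strings are regular enough to parse with grammars:
`1H NMR (...) δ` followed by a comma-separated peak list
(`shift[–shift] (mult[, J = x[, y] Hz][, nH])`), the `13C` analogue,
`HRMS ... calcd for <formula> [ion] <num>, found <num>`, and `Anal. Calcd
for <formula>: E, p; ... Found: ...`. A located span whose interior fails
to parse is returned flagged unparsed rather than raising — a checker
must survive malformed manuscripts. Rendering a peak list and re-parsing
it is the identity, which the tests exercise on random peak lists.

Checks against a molecular formula:

* **1H NMR**: integrations must sum to the formula's hydrogen count,
  exactly — integrals are integers by convention, so no tolerance.
* **HRMS**: the printed calculated mass must be within **0.005 Da** of
  the monoisotopic mass of the *stated ion formula* (printed values are
  conventionally 4 decimal places, so 5 mDa separates typos from
  rounding), and found-vs-calcd within **5 ppm**, the common
  instrument-accuracy threshold.
* **Elemental analysis**: percents computed from the stated formula using
  standard average atomic weights must match each printed value within
  **0.4 percentage points**, the long-standing journal acceptance window.

Monoisotopic masses sum the exact masses of each element's most abundant
light isotope from a packaged table (41 elements); HRMS never uses
average masses, elemental analysis always does.

## The facade and the overlap policy

`chem_pipeline()` bundles one active recogniser with the always-on
lexicon stages and the data parser. Candidates from different stages can
overlap; the merge policy is a deterministic cascade: longer span wins,
then type priority CM > ONT > CPR > RN > CJ > ASE, then higher
confidence; finally CPR entities that abut or lie inside a CM span are
dropped (a locant prefix inside a recognised chemical name is part of the
name, not a separate finding). The cascade favours the most informative
reading of a span and makes merging idempotent. Pipelines are immutable
values: component replacement (`set_component`) returns a new pipeline,
nothing is cached mutably, no files or directories are ever created, and
the tests assert that interleaved and forked concurrent use of differently
configured pipelines reproduces sequential results exactly.

## The synthetic corpus generator

`corpus_spec()` fixes the study conditions for training and evaluating
the tagger offline: 500 sentences by default, vocabulary of 120 chemical
and 200 plain words, entity insertion rate 0.25, multi-token rate 0.2,
class mix 70/10/10/10 over CM/RN/CJ/ASE, mandatory seed. Chemical words
are random syllable concatenations ending in a class-typical suffix
(CM: `-ol`, `-ane`, `-ate`; RN: `-ation`, `-olysis`; CJ: `-ic`, `-ous`;
ASE: `-ase`); multi-token entities are headed by a `-yl` modifier word,
mirroring real multi-token chemical names ("ethyl acetate") — without
that head structure, a two-token entity would be statistically
indistinguishable from two adjacent single-token entities and the B/I
distinction would be unlearnable by construction. Plain words come from a
packaged English list filtered so none satisfies an entity suffix rule.
Gold spans are recorded at insertion time, never by pattern-matching the
rendered text, to avoid circularity with the recognisers under test; each
generated document re-tokenises its own text on construction, so token
alignment of the gold spans is verified by the type system rather than
trusted.

What the generator does **not** emulate: real journal prose, ambiguous
entity boundaries, nested or discontinuous mentions, out-of-vocabulary
morphology beyond the suffix rules, and annotation noise. Passing the
held-out recovery check (precision and recall ≥ 0.95 on 500 training /
100 test sentences) therefore demonstrates that the learning and decoding
machinery is correct, not that the tagger would reach such scores on
real literature — the shipped fixtures are miniatures, and real use means
training on a real annotated corpus via `memm_train()`.

## Numerical choices and degenerate inputs

* Forward and Viterbi recursions run in log space with log-sum-exp
  pooling; confidences are clamped to [0,1] against rounding at the
  boundaries.
* Viterbi ties break toward the lowest label index (`which.max`),
  deterministically.
* Empty documents, empty paragraphs, empty entity lists and empty
  formulas are all explicit cases: the first three yield empty results,
  the last is an error (a formula with no atoms has no mass).
* Problem sizes in the test suite — 1000 random tokenisation texts, 100
  random lexicons for the scorer oracle, 200 random models (length ≤ 6)
  for the enumeration oracle, 600 generated sentences for the recovery
  check — were chosen to exercise each property densely while keeping the
  whole suite comfortably under a minute per file on a laptop.

## Limitations

* The shipped lexicons, dictionary and ontology are fixtures (~150
  chemical words, 50 names, 100 terms) meant for tests, demos and API
  experiments; production use requires real resources in the documented
  TSV formats.
* The n-gram model's unseen-token bias (discussed above) makes the
  pattern recogniser permissive on out-of-vocabulary non-English tokens;
  raise the threshold or train on a larger English list when precision
  matters.
* No systematic-nomenclature parsing: names absent from every dictionary
  resolve only through the user-supplied fallback hook.
* Inline XML annotation of source documents is out of scope; standoff
  JSON/TSV is the only output channel.
* The MEMM's label-bias caveat stands; entity confidences are faithful to
  the model, not calibrated probabilities of correctness.
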
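# chemtext

Chemistry-aware text mining for R: named-entity recognition, chemical
name-to-structure resolution, and automated checking of reported
experimental data.

Chemistry papers carry much of their information in running text: compound
names ("ethyl acetate"), serial numbers ("NSC-2648"), locant prefixes
("2,5-"), ontology terms ("melting point"), and highly stylised data
strings ("1H NMR (400 MHz, CDCl3) δ 2.05 (s, 3H) ..."). `chemtext` is a
modular library for extracting all of these from plain text, aimed at
text-mining researchers and at anyone building literature-curation or
manuscript-checking tools.

## What is in the box

* **Chemistry-aware tokeniser.** Whitespace splitting followed by iterative
  edge-punctuation stripping with rules that keep domain tokens whole:
  `C-H`, `C2H6O`, `NSC-2648`, `2,5-dichlorobenzylamine` and
  `poly(ethylene)` each stay a single token, while `benzene (42).` becomes
  `benzene` `(` `42` `)` `.`. All tokens carry 0-based, half-open
  character offsets into the NFC-normalised source, and slicing the source
  by those offsets always reproduces the token.
* **Three interchangeable entity recognisers.**
  * A *regex recogniser* for compound serial numbers.
  * A *pattern recogniser*: a character 4-gram naive Bayes classifier
    scores each token as chemical or not, with smoothed log-likelihood
    ratio \(\sum_g \log \hat P(g\mid \mathrm{chem}) - \log \hat P(g\mid
    \mathrm{non})\), and runs of chemical tokens are assembled into
    multi-token entities by glob patterns such as `*yl *ate` (matching
    "ethyl acetate").
  * A trainable *Maximum Entropy Markov Model* over nine labels (`B-t`,
    `I-t` for the CM, RN, CJ and ASE classes plus `O`), with rich local
    features, Viterbi decoding under the I-follows-B/I constraint, and
    span confidences computed as constrained-forward probability ratios.
* **Lexicon stages.** Longest-leftmost dictionary lookup of ontology terms
  (ChEBI/FIX/REX-style TSV input) and a deterministic finite automaton for
  chemical locant prefixes (`2,5-`, `trans-`, `N,N-`, `α-`).
* **Name resolution.** An ordered registry of name dictionaries maps CM
  surfaces to SMILES/InChI/CML structures, with a pluggable fallback hook
  for an external systematic-nomenclature parser.
* **Experimental-data checker.** Regex grammars locate and parse 1H/13C
  NMR peak lists, HRMS lines and elemental analyses, then verify them
  against a molecular formula: proton integrals must sum to the H count,
  HRMS calculated masses must match the monoisotopic mass of the stated
  ion formula (default 0.005 Da, found-vs-calcd 5 ppm), and elemental
  percents must match within 0.4 points.
* **Synthetic corpus generator.** Deterministic word-list and annotated-
  corpus generation so the tagger is trainable and testable offline.

Everything is assembled behind a facade, `chem_pipeline()`, that works
with zero arguments using packaged fixture resources, creates no files or
global state, and supports functional component swapping.

## Worked example

```r
library(chemtext)
pl <- chem_pipeline()

for (e in findNamedEntities(pl,
    "Stirred in ethyl acetate overnight, then washed with water."))
  print(e)
#> <CM [11,24) "ethyl acetate" conf=1.000>

for (e in findNamedEntities(pl,
    "The melting point of 2,5-dichlorobenzylamine was measured."))
  print(e)
#> <ONT [4,17) "melting point" conf=1.000 ids=[FIX:0000001]>
#> <CM [21,44) "2,5-dichlorobenzylamine" conf=1.000>
```

The pattern recogniser scored "ethyl" and "acetate" as chemical tokens and
fused them through the `*yl *ate` pattern into one CM entity covering
offsets [11,24) of the input; the confidence is the geometric mean of the
member token probabilities. In the second sentence the ontology stage
matched "melting point" (with its fixture identifier), the n-gram model
recognised the dichlorobenzylamine token, and the locant prefix "2,5-",
though detected, was suppressed because it lies inside the CM span.

Resolution keeps only what a dictionary can ground:

```r
for (r in findResolvableEntities(pl, "benzene and the methyl ester"))
  print(r)
#> <resolved CM "benzene": 2 structure(s)>
#>   SMILES: c1ccccc1
#>   INCHI: InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H
```

And the data checker verifies a reported spectrum against a formula
(ethyl acetate, C4H8O2, has 8 protons):

```r
text <- paste("The product gave 1H NMR (400 MHz, CDCl3) δ 2.05 (s, 3H),",
              "4.12 (q, J = 7.1 Hz, 2H), 1.26 (t, J = 7.1 Hz, 3H).")
ann <- findData(pl, text)[[1]]
for (rep in check_consistency(ann, "C4H8O2")) print(rep)
#> hnmr_integration             PASS (observed 8, expected 8, tol 0)

monoisotopic_mass("C6H6")
#> [1] 78.0470
```

## Command line

A thin Rscript front end ships in `inst/cli/chemtext.R`:

```sh
Rscript inst/cli/chemtext.R run --input doc.txt --format tsv
Rscript inst/cli/chemtext.R gen-corpus --spec spec.json --out corpus/
Rscript inst/cli/chemtext.R train-ngram --chemical chem.txt --english en.txt --out ng.json
Rscript inst/cli/chemtext.R train-memm --corpus corpus/ --ngram ng.json --out memm.json
Rscript inst/cli/chemtext.R check-data --input doc.txt --formula C4H8O2
```

Exit codes: 0 success, 1 data error, 2 configuration error.

## Design notes

The methods vignette (`vignettes/chemtext-methods.Rmd`) documents the
models and their assumptions, the tokenisation dialect, all tunable
parameters with defaults and rationale, what the synthetic corpus does and
does not emulate, and known limitations.
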
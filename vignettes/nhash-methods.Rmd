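---
title: "Randomized n-gram hashing: the identifier scheme, its collision model, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized n-gram hashing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhash)
```

## The scheme

An identifier is produced in two phases from a participant's demographics
(first name, last name, MRN, date of birth) and a random number `r`.

**Sanitization.** The hash reads three canonical strings: `m1`, the
uppercase name token (first name then last name, with spaces, punctuation
and anything else outside A–Z removed; diacritics are folded to ASCII where
a trivial mapping exists, otherwise dropped); `m2`, the MRN left-zero-padded
to 8 digits (longer MRNs are rejected); `m3`, the date of birth rendered
`mmddyyyy`. Empty names after stripping, non-digit MRNs and unparseable
dates raise distinct typed conditions, so batch callers can report failures
per row.

**Phase 1 — randomized n-gram extraction.** For each profile component
`(source_i, n_i)` the `n_i` consecutive characters of `m_i` starting at the
0-based offset `r mod |m_i|` are extracted and the pieces concatenated into
the intermediate string. Two conventions here are deliberate choices where
the procedure is otherwise underdetermined:

* *0-based offsets.* The reference example (name `AARONSKOTNICA`,
  `r = 783305`, offset `783305 mod 13 = 3`, gram `ONSK`) only lands on `O`
  if index 0 is the first character.
* *Circular overflow.* The offset can reach `|m| − 1`, so a gram can run
  past the end of `m`. Reading wraps to the start, guaranteeing a fixed
  output length for every input; `ngram_extract(..., overflow = "reject")`
  is available for callers who prefer an error, but wrap is the default and
  is what the batch generator uses.

**Phase 2 — shift cipher and suffix.** The intermediate would otherwise
expose name letters and MRN/DOB digits directly, so it is encrypted with a
per-record shift cipher: letters rotate forward `C mod 26` within A–Z,
digits `C mod 10` within 0–9, where `C` is the Cantor pairing
`(k1+k2)(k1+k2+1)/2 + k2` of `k1 = |m1|` (the *sanitized* token length —
13 for `AARONSKOTNICA`, not 14 for the raw string with its space) and
`k2 =` the birth month (1–12). The pairing is evaluated in exact integer
arithmetic (doubles below 2^53, with an explicit guard). The final
identifier is the cipher followed by `r` zero-padded to the profile's
suffix width, so identifiers are fixed-width and the suffix parses without
a delimiter.

The default profile (`csr_profile()`) is a 4-gram of name + 4-gram of MRN +
2-gram of DOB + 6 random digits: 16 characters, letters in positions 1–4,
digits elsewhere. `r` is drawn uniformly from `[0, 10^6)`; the quoted range
"0 to 1,000,000" leaves the endpoints ambiguous, and the upper endpoint is
taken exclusive so every value fits the 6-digit suffix. Gram sizes,
component order and suffix width are all tunable through `nhash_profile()`;
the general scheme also admits per-component random numbers (pass a vector
`r`), in which case the suffix records the first — the default profile
shares a single `r` across components.

## Validation and error tolerance

The suffix exposes `r` in clear, which is what makes identifiers
validatable: `validate_identifier()` re-runs the generator on the codebook
record with the parsed `r` and compares byte-for-byte. This requires the
record — validation without the codebook is impossible by construction,
since the identifier deliberately reveals nothing else. Two failure modes
are kept distinct: *malformed* (wrong length, or a character outside the
per-position class) raises a typed error at parse time, while
*well-formed but invalid* (regeneration mismatch) returns a report with the
mismatching positions.

Any edit to a cipher position mismatches the deterministic regeneration, so
cipher-edit detection is total. A suffix edit changes `r`, which moves the
extraction offsets and regenerates a different cipher; it escapes detection
only if the new `r` happens to reproduce the typed cipher exactly.
`error_tolerance_scan()` enumerates every within-class single-position
substitution (25 per letter, 9 per digit — 208 mutants for the default
profile) and validates each. For the reference identifier all 208 are
detected; the tests also exercise a deliberately weak 1-component profile
where suffix edits *can* regenerate colliding ciphers, to confirm the scan
measures rather than assumes.

`report_name()` appends the per-visit 2-digit postfix (01–99) used to name
repeat-visit reports; visit 0 is disallowed since numbering starts at 01,
and the width is fixed at two digits.

## Registries and merging

Each site keeps a local registry; `generate_unique()` draws, generates,
checks the registry, and redraws on a local collision (default cap 100
attempts — the per-draw collision probability in any realistic registry is
far below 1, so hitting the cap signals a saturated suffix space, as the
tests demonstrate with a 1-digit suffix). Registries persist as JSON lines
(`{"id":…, "ref":…, "site":…, "created":…}`, one entry per line) — an
append-friendly audit format that round-trips exactly. Cross-site
collisions are not prevented (there is no central issuer); they surface at
data-merging time: `merge_registries()` returns the union plus the list of
identifiers present in both registries, keeping both references so the
issuing site can regenerate. Same-participant enrollment at two sites
(false split) is undetectable by design and out of scope.

R's seedable RNG backs the default draws so tests and simulations are
reproducible; production deployments should pass a cryptographically secure
`rng` to `generate_unique()`.

## The collision model

With `N` equally likely identifiers ("inverse probability" `N`), the
expected number of collisions after `I` insertions is the occupancy
formula

$$EC = I - N + N\left(1 - \tfrac1N\right)^I,$$

derived from the expected empty slots $EE = N(1-1/N)^I$ via
$EC = I - (N - EE)$. Numerically this is hostile: at `N ≈ 10^15`,
`I ≈ 10^6` the answer (`~7.6e-5`) is the residual of two `10^6`-sized
terms, far below double-precision resolution of the direct expression.
`expected_collisions()` therefore switches on `I/N`:

* `I/N ≤ 10^-2`: the cancellation-free alternating series
  $EC = \binom{I}{2}\frac1N - \binom{I}{3}\frac1{N^2} + \cdots$, whose term
  ratio is below `I/N`, summed to relative `10^-17` (a dozen terms at
  most);
* otherwise: `I + N*expm1(I*log1p(-1/N))`, well-conditioned once `EC` is
  comparable to `I`.

The tests pin both paths against 60-digit arbitrary-precision reference
values at `10^-9` relative tolerance, and against a Monte-Carlo
balls-in-bins estimate at small `N`. Degenerate inputs are handled exactly:
`EC = 0` for `I ≤ 1`, `EC = I − 1` for `N = 1`.

`csr_bounds()` brackets the effective `N` per component: name n-grams
between `10^n` (letters of common-name text carry roughly decimal entropy
per character) and `26^n`; MRN digits between `9^n` and `10^n`; DOB grams
`10^n` on both sides (only two year digits vary freely in the current
population); the random suffix exactly `10^random_digits`. For the default
profile the products are `6.561e15` and `4.56976e17` (displayed at two
significant figures, `6.6e15` and `4.6e17`). Published expected-collision
tables are quoted at these *rounded* totals, so `ec_table()` and the
acceptance script evaluate at the rounded `N` as given — recomputing from
the exact products shifts the third significant figure and would not match
the printed values; the exact products remain available as attributes.

## The synthetic cohort and the simulator

`cohort_config()` emulates the simulation protocol: first and last names
sampled with probability proportional to frequency weights, MRNs uniform
over 8-digit strings (leading zeros allowed), DOBs uniform over the days of
1910-01-01–2015-12-31. The bundled tables hold 241 common US surnames and
100 first names with census-scale weights (~3.5 KB of plain TSV); the
full top-5000-surnames/top-2500-first-names protocol is available by
passing user-supplied two-column tables. The generator reproduces the
*mechanism* of real demographics — frequency-skewed names, uniform MRNs —
but not their full richness: no name-length–ethnicity correlation, no
birth-cohort age structure, no shared-MRN households. Passing collision
tests therefore validates the identifier algebra and the occupancy model,
not demographic realism.

The random-string baseline `random_string_id(n, len)` is 4 uniform letters
followed by `len − 4` uniform digits, giving inverse probability
`26^4 · 10^(len-4)`. That composition is an inference: it is the one
consistent with the published expected-collision column for every baseline
length (e.g. `4.6e12` for length 11), and it is recorded here as an
explicit, overridable assumption rather than a documented fact.

`run_experiment()` runs replicated streams (per-run seed = `base_seed + k`,
so a table is reproducible from its arguments), counts collisions as
insertions minus distinct identifiers — the quantity whose expectation is
`EC` — and attaches the analytic expectation: a single `EC` for baselines,
the `[EC_upper-bound-N, EC_lower-bound-N]` bracket for the hash. Generation
is chunked (10^5 identifiers at a time) so memory stays at one run's worth
of strings. Full-scale runs of 10^8 records are supported behind
`allow_large = TRUE` (hours of CPU and tens of GiB of strings); the default
guard rail is 10^6 per run. The test suite uses 20 runs of 10^5 length-7
baseline identifiers (`EC ≈ 10.9`) and 20 runs of 10^4 hash identifiers
with a 2-digit suffix — sizes chosen so the expected counts are either
clearly resolvable (baseline) or clearly bracketed (hash) at desk scale
while the whole suite stays fast. At these scales the hash bracket ECs are
`~10^-6`–`10^-4`, so observed means are compared within the
`3σ/√runs` Poisson sampling band around the bracket rather than strictly
inside it (integer counts cannot fall between two sub-unity expectations).

## Known limitations

* Validation requires the codebook record; the identifier alone cannot be
  checked, only parsed.
* False splits (one participant, two sites, two identifiers) are invisible
  to the scheme.
* The collision bounds bracket name skew rather than model it; heavily
  skewed name tables (like the deliberately small bundled fixture) can push
  the true collision rate toward — and past — the nominal lower-bound-`N`
  expectation, which is why the simulator reports the bracket rather than a
  point value.
* MRNs longer than 8 digits are rejected rather than truncated; sites with
  wider MRNs should define a profile component accordingly.
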
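# nhash

Decentralized, validatable study identifiers for multicenter clinical
research, by randomized n-gram hashing.

## The problem

Multicenter studies need a pseudonymous study identifier per participant so
that clinical data (reports, EEG, imaging) can be linked across sites without
carrying protected health information (PHI). Centrally issued identifiers
need coordination (non-overlapping code blocks per site) or a web service
that receives identifying data; and plain sequential or random codes are not
*validatable* — a one-character typo silently becomes another participant's
valid code.

`nhash` implements a scheme in which each site generates identifiers locally,
with negligible collision probability, and in which any identifier can later
be checked against the codebook record that issued it:

1. **Randomized n-gram hashing.** Sanitize the demographics into three
   strings — `m1` the uppercase letters-only name (first + last), `m2` the
   MRN zero-padded to 8 digits, `m3` the date of birth as `mmddyyyy`. Draw a
   random number `r` in `[0, 10^6)` and extract an n-gram from each `m_i`
   starting at position `r mod |m_i|` (reading circularly): by default a
   4-gram of name, a 4-gram of MRN, a 2-gram of DOB. Concatenating them
   gives the intermediate string.
2. **Shift cipher.** Encrypt the intermediate by rotating letters by
   `C mod 26` and digits by `C mod 10`, where `C = (k1+k2)(k1+k2+1)/2 + k2`
   is the Cantor pairing of `k1 = |m1|` and `k2 =` birth month. Append `r`
   zero-padded to 6 digits: a fixed-width 16-character identifier whose
   suffix is the random number in clear.

Because the suffix exposes `r`, anyone holding the codebook record can
regenerate the identifier deterministically and compare byte-for-byte —
editing mistakes are detected rather than silently re-linked.

The package also provides the closed-form collision model
`EC = I − N + N(1 − 1/N)^I` (expected collisions after `I` insertions into
an identifier space of inverse probability `N`), evaluated with a
cancellation-free path that stays accurate at `N ≈ 10^15` where naive
floating point fails, and a synthetic-cohort simulator (frequency-weighted
names, uniform 8-digit MRNs, DOBs over 1910–2015) for empirical collision
counting against random-string baselines.

## Worked example

```r
library(nhash)
rec <- demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
generate_identifier(rec, r = 783305)
#> NHash identifier: TSXP606170783305
#>   intermediate: ONSK717281 (offsets 3, 1, 1)
#>   cipher: TSXP606170 (letters +5, digits +9), suffix r = 783305
```

The name token `AARONSKOTNICA` has 13 letters and the birth month is 8, so
the cipher key is `C = Cantor(13, 8) = 239`: letters shift by `239 mod 26 =
5`, digits by `239 mod 10 = 9`. A suffix typo is caught because the altered
`r` regenerates a different cipher:

```r
validate_identifier("TSXP606170783306", rec)
#> Identifier:   TSXP606170783306
#> Regenerated:  SXPT061302783306  (r = 783306)
#> INVALID: mismatch at position(s) 1, 2, 3, 4, 5, 6, 7, 8, 9, 10
```

How unlikely are collisions? The per-component bounds on the number of
equally likely identifiers multiply to `6.6e15 – 4.6e17`:

```r
csr_bounds()
#>  component   lower   upper
#>       name 1.0e+04 4.6e+05
#>        mrn 6.6e+03 1.0e+04
#>        dob 1.0e+02 1.0e+02
#>     random 1.0e+06 1.0e+06
#>      Total 6.6e+15 4.6e+17
expected_collisions(6.6e15, 1e8)   # worst case after 100 million insertions
#> [1] 0.7575757
```

and a desk-scale simulation confirms the model (length-7 random-string
baseline, 5 runs of 100,000 identifiers):

```r
run_experiment("random:7", size = 1e5, runs = 5, base_seed = 42)
#>  run seed collisions
#>    1   43         16
#>    2   44         10
#>    3   45          9
#>    4   46         12
#>    5   47         12
#> mean collisions: 11.8
#> analytic EC:     ec = 10.9406
```

Batch workflows (CSV in, CSV + registry out), registry merging with
cross-site collision reporting, per-visit report naming, and the exhaustive
single-edit error-tolerance scan are covered in the methods vignette
(`vignettes/nhash-methods.Rmd`). A thin command-line front end ships at
`inst/cli/nhash` (`generate`, `validate`, `merge`, `ec`, `simulate`).

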
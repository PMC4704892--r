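# Shared fixtures built in code.

# The fictional participant used throughout the documentation:
# sanitized name AARONSKOTNICA (13 letters), MRN 07172485, DOB 08/13/1956.
aaron <- function() {
  demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
}

# Random but always-sanitizable demographic records.
random_records <- function(n) {
  data.frame(
    first_name = replicate(n, paste(sample(letters, sample(2:8, 1),
                                           replace = TRUE), collapse = "")),
    last_name = replicate(n, paste(sample(letters, sample(2:10, 1),
                                          replace = TRUE), collapse = "")),
    mrn = formatC(sample.int(1e8, n) - 1L, width = 8, flag = "0"),
    dob = as.Date("1910-01-01") + sample.int(38000, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Brute-force start-index oracle: find where the extracted gram begins by
# scanning every circular offset of m, independent of the modular formula.
brute_force_offset <- function(gram, m) {
  len <- nchar(m)
  doubled <- strrep(m, ceiling((len + nchar(gram)) / len))
  hits <- which(vapply(seq_len(len) - 1L, function(s)
    substr(doubled, s + 1, s + nchar(gram)) == gram, logical(1)))
  hits - 1L
}
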
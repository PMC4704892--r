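test_that("sanitization strips punctuation, pads MRN and formats DOB", {
  s <- sanitize(aaron())
  expect_equal(s$name_token, "AARONSKOTNICA")
  expect_equal(s$mrn_token, "07172485")
  expect_equal(s$dob_token, "08131956")

  s2 <- sanitize(demographic_record("o'Hara", "X", "1", "2000-01-02"))
  expect_equal(s2$name_token, "OHARAX")
  expect_equal(s2$mrn_token, "00000001")
  expect_equal(s2$dob_token, "01022000")
})

test_that("sanitization rejects bad inputs with distinct error classes", {
  expect_error(sanitize(demographic_record("  ", "---", "1", "2000-01-02")),
               class = "nhash_empty_name")
  expect_error(sanitize(demographic_record("A", "B", "1234567890", "2000-01-02")),
               class = "nhash_invalid_mrn")
  expect_error(sanitize(demographic_record("A", "B", "12a4", "2000-01-02")),
               class = "nhash_invalid_mrn")
  expect_error(sanitize(demographic_record("A", "B", "1", "02/30/2000")),
               class = "nhash_invalid_dob")
  expect_error(sanitize(demographic_record("A", "B", "1", "not a date")),
               class = "nhash_invalid_dob")
})

test_that("n-gram extraction starts at r mod |m| and wraps circularly", {
  expect_equal(ngram_extract(783305, 4, "AARONSKOTNICA"), "ONSK")
  expect_equal(ngram_extract(783305, 4, "07172485"), "7172")
  expect_equal(ngram_extract(783305, 2, "08131956"), "81")
  expect_equal(ngram_extract(0, 3, "ABC"), "ABC")
  expect_equal(ngram_extract(12, 4, "AARONSKOTNICA"), "AAAR") # wraps past end
  expect_error(ngram_extract(1, 2, ""), class = "nhash_empty_input")
  expect_error(ngram_extract(12, 4, "AARONSKOTNICA", overflow = "reject"),
               class = "nhash_ngram_overflow")
  expect_equal(ngram_extract(12, 4, "AARONSKOTNIC", overflow = "reject"),
               "AARO") # offset 0: no overflow, reject mode passes
})

test_that("extraction offset obeys the modular law against a brute-force scan", {
  set.seed(71)
  for (i in 1:200) {
    m <- paste(sample(LETTERS, sample(3:15, 1), replace = TRUE), collapse = "")
    r <- sample.int(1e6, 1)
    n <- sample(1:4, 1)
    gram <- ngram_extract(r, n, m)
    expect_equal(nchar(gram), n)
    # modular offset must be among the positions where the gram occurs
    expect_true((r %% nchar(m)) %in% brute_force_offset(gram, m))
  }
})

test_that("Cantor pairing matches its closed form and rejects bad input", {
  expect_identical(cantor_pair(13, 8), 239)
  expect_identical(cantor_pair(0, 0), 0)
  expect_identical(cantor_pair(1, 2), 8)
  expect_error(cantor_pair(-1, 2), class = "nhash_bad_argument")
  expect_error(cantor_pair(1.5, 2), class = "nhash_bad_argument")
  # pairing is injective over a small grid (it is a bijection on N^2)
  grid <- expand.grid(k1 = 0:40, k2 = 0:40)
  expect_false(anyDuplicated(cantor_pair(grid$k1, grid$k2)) > 0)
})

test_that("shift key derives from sanitized name length and birth month", {
  key <- derive_shift_key(sanitize(aaron()))
  expect_equal(key$k1, 13)
  expect_equal(key$k2, 8)
  expect_equal(key$C, 239)
  expect_equal(key$letter_shift, 5)
  expect_equal(key$digit_shift, 9)

  key2 <- derive_shift_key(sanitize(demographic_record("A", "B", "1", "01/15/1980")))
  expect_equal(key2$C, cantor_pair(2, 1))
  expect_equal(key2$C, 7)
  expect_equal(key2$letter_shift, 7)
  expect_equal(key2$digit_shift, 7)
})

test_that("shift cipher rotates letters mod 26 and digits mod 10", {
  key <- list(letter_shift = 5, digit_shift = 9)
  expect_equal(shift_encrypt("ONSK717281", key), "TSXP606170")
  expect_equal(shift_encrypt("ABC", list(letter_shift = 0, digit_shift = 0)), "ABC")
  expect_equal(shift_encrypt("Z9", list(letter_shift = 1, digit_shift = 1)), "A0")
  expect_equal(shift_decrypt("TSXP606170", key), "ONSK717281")
  expect_error(shift_encrypt("a1", key), class = "nhash_bad_charset")
  expect_error(shift_encrypt("A-1", key), class = "nhash_bad_charset")
})

test_that("decrypt inverts encrypt for all shifts on random alphanumerics", {
  set.seed(83)
  pool <- strsplit(nhash:::LETTERS_DIGITS, "")[[1]]
  for (i in 1:1000) {
    s <- paste(sample(pool, sample(1:20, 1), replace = TRUE), collapse = "")
    key <- list(letter_shift = sample(0:25, 1), digit_shift = sample(0:9, 1))
    enc <- shift_encrypt(s, key)
    expect_identical(shift_decrypt(enc, key), s)
    expect_equal(nchar(enc), nchar(s))
    # character class preserved per position
    expect_identical(gsub("[A-Z]", "L", gsub("[0-9]", "D", enc)),
                     gsub("[A-Z]", "L", gsub("[0-9]", "D", s)))
  }
})

test_that("identifier generation reproduces the documented example end to end", {
  id <- generate_identifier(aaron(), 783305)
  expect_equal(id$offsets, c(3, 1, 1))
  expect_equal(id$ngrams, c("ONSK", "7172", "81"))
  expect_equal(id$intermediate, "ONSK717281")
  expect_equal(id$cipher_part, "TSXP606170")
  expect_equal(id$random_part, "783305")
  expect_equal(id$full, "TSXP606170783305")
  expect_equal(as.character(id), "TSXP606170783305")

  # neighbouring random number: re-derived independently from the algorithm
  id2 <- generate_identifier(aaron(), 783306)
  expect_equal(id2$offsets, c(4, 2, 2))
  expect_equal(id2$intermediate, "NSKO172413")
  expect_equal(id2$full, "SXPT061302783306")

  # zero case: all offsets 0, zero-padded suffix
  id0 <- generate_identifier(aaron(), 0)
  expect_equal(id0$offsets, c(0, 0, 0))
  expect_equal(id0$intermediate, "AARO071708")
  expect_equal(id0$random_part, "000000")
})

test_that("generation is deterministic and respects length/class invariants", {
  set.seed(11)
  recs <- random_records(60)
  profile <- csr_profile()
  regex <- nhash:::identifier_regex(profile)
  for (i in seq_len(nrow(recs))) {
    rec <- demographic_record(recs$first_name[i], recs$last_name[i],
                              recs$mrn[i], recs$dob[i])
    r <- sample.int(1e6, 1) - 1L
    a <- generate_identifier(rec, r, profile)
    b <- generate_identifier(rec, r, profile)
    expect_identical(a$full, b$full)
    expect_equal(nchar(a$full), 16)
    expect_true(grepl(regex, a$full))
  }
})

test_that("r outside the suffix range or negative is rejected", {
  expect_error(generate_identifier(aaron(), 1e6), class = "nhash_bad_argument")
  expect_error(generate_identifier(aaron(), -1), class = "nhash_bad_argument")
  expect_equal(generate_identifier(aaron(), 999999)$random_part, "999999")
})

test_that("per-component random numbers are honoured; suffix records the first", {
  id <- generate_identifier(aaron(), c(783305, 783306, 783306))
  expect_equal(id$ngrams[1], "ONSK")   # r1 = 783305 on name
  expect_equal(id$ngrams[2], "1724")   # r2 = 783306 on MRN, offset 2
  expect_equal(id$random_part, "783305")
})

test_that("batch generation agrees with the scalar path", {
  set.seed(29)
  recs <- random_records(80)
  r <- sample.int(1e6, 80) - 1L
  batch <- generate_identifier_batch(recs$first_name, recs$last_name,
                                     recs$mrn, recs$dob, r)
  single <- vapply(seq_len(80), function(i)
    generate_identifier(demographic_record(recs$first_name[i], recs$last_name[i],
                                           recs$mrn[i], recs$dob[i]),
                        r[i])$full,
    character(1))
  expect_identical(batch, single)
})

test_that("non-default profiles drive shape, charset and suffix width", {
  p <- nhash_profile(list(list(source = "dob", n = 3),
                          list(source = "name", n = 2)), random_digits = 4)
  id <- generate_identifier(aaron(), 57, p)
  expect_equal(nchar(id$full), 3 + 2 + 4)
  expect_true(grepl("^[0-9]{3}[A-Z]{2}[0-9]{4}$", id$full))
  expect_equal(id$random_part, "0057")
})

test_that("generate_unique retries on local collision and errors when saturated", {
  reg <- nhash_registry()
  id1 <- generate_unique(aaron(), reg, rng = local({
    draws <- c(783305, 783305, 783306); k <- 0
    function() { k <<- k + 1; draws[k] }
  }))
  expect_equal(id1$full, "TSXP606170783305")
  expect_equal(registry_size(reg), 1)

  # first draw now collides with the registered identifier; second accepted
  id2 <- generate_unique(aaron(), reg, rng = local({
    draws <- c(783305, 783306); k <- 0
    function() { k <<- k + 1; draws[k] }
  }))
  expect_equal(id2$full, "SXPT061302783306")

  # a registry holding every variant for the record exhausts retries
  tiny <- csr_profile(random_digits = 1)
  reg2 <- nhash_registry(profile = tiny)
  for (r in 0:9) registry_add(reg2, generate_identifier(aaron(), r, tiny)$full)
  expect_error(generate_unique(aaron(), reg2, profile = tiny, max_retries = 50),
               class = "nhash_retries_exhausted")
})
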
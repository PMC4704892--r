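#' Extract an n-gram at a randomized, modularly computed start position
#'
#' Returns the `n` consecutive characters of `m` beginning at the 0-based
#' index `s = r mod |m|`. When `s + n` runs past the end of `m` the read
#' wraps circularly to the start, so the result always has exactly `n`
#' characters (`overflow = "wrap"`); with `overflow = "reject"` such reads
#' raise an error instead.
#'
#' @param r Nonnegative integer (the random number driving the start offset).
#' @param n Gram size, a positive integer.
#' @param m Non-empty character string to read from.
#' @param overflow `"wrap"` (default: circular read) or `"reject"`.
#' @return A string of exactly `n` characters.
#' @examples
#' ngram_extract(783305, 4, "AARONSKOTNICA")  # "ONSK", start 783305 mod 13 = 3
#' ngram_extract(0, 3, "ABC")
#' @export
ngram_extract <- function(r, n, m, overflow = c("wrap", "reject")) {
  overflow <- match.arg(overflow)
  stopifnot(length(m) == 1L, length(r) == 1L, length(n) == 1L)
  if (is.na(m) || !nzchar(m)) stop(nhash_error("empty_input", "`m` must be non-empty"))
  if (r < 0) stop(nhash_error("bad_argument", "`r` must be nonnegative"))
  if (n < 1) stop(nhash_error("bad_argument", "`n` must be >= 1"))
  len <- nchar(m)
  s <- r %% len
  if (overflow == "reject" && s + n > len)
    stop(nhash_error("ngram_overflow",
      sprintf("%d-gram starting at offset %d overruns |m| = %d", n, s, len)))
  ngram_extract_vec(r, n, m)
}

# Vectorized circular n-gram extraction: r and m recycled to common length,
# scalar n. Core of the batch generator.
ngram_extract_vec <- function(r, n, m) {
  len <- nchar(m)
  s <- r %% len
  reps <- ceiling((s + n) / len)
  substr(strrep(m, reps), s + 1, s + n)
}

#' Cantor pairing function
#'
#' The bijection `(k1, k2) -> (k1+k2)(k1+k2+1)/2 + k2` from pairs of
#' nonnegative integers to nonnegative integers, evaluated in exact integer
#' arithmetic. Used here to derive the shift-cipher key from the sanitized
#' name length and the birth month.
#'
#' @param k1,k2 Nonnegative integers (vectorized).
#' @return Nonnegative integer(s), as doubles exact below 2^53.
#' @examples
#' cantor_pair(13, 8)  # 239
#' @export
cantor_pair <- function(k1, k2) {
  if (any(k1 < 0) || any(k2 < 0))
    stop(nhash_error("bad_argument", "Cantor pairing requires nonnegative inputs"))
  if (any(k1 != floor(k1)) || any(k2 != floor(k2)))
    stop(nhash_error("bad_argument", "Cantor pairing requires integer inputs"))
  t <- k1 + k2
  out <- t * (t + 1) / 2 + k2
  if (any(out >= 2^53))
    stop(nhash_error("bad_argument", "inputs too large for exact integer arithmetic"))
  out
}

#' Derive the shift-cipher key from a sanitized record
#'
#' The key pairs `k1` (length of the sanitized name token) with `k2` (the
#' birth month, 1-12) through the Cantor pairing function; the resulting
#' integer `C` is reduced mod 26 for letters and mod 10 for digits.
#'
#' @param s An `nhash_input` from [sanitize()].
#' @return An object of class `nhash_key` with fields `k1`, `k2`, `C`,
#'   `letter_shift`, `digit_shift`.
#' @examples
#' rec <- demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
#' derive_shift_key(sanitize(rec))  # C = 239, shifts 5 / 9
#' @export
derive_shift_key <- function(s) {
  k1 <- nchar(s$name_token)
  k2 <- as.integer(substr(s$dob_token, 1, 2))
  C <- cantor_pair(k1, k2)
  structure(
    list(k1 = k1, k2 = k2, C = C,
         letter_shift = C %% 26, digit_shift = C %% 10),
    class = "nhash_key"
  )
}

#' @export
print.nhash_key <- function(x, ...) {
  cat(sprintf("Shift key: k1 = %d, k2 = %d, C = %s; letters +%d, digits +%d\n",
              x$k1, x$k2, format(x$C, scientific = FALSE),
              x$letter_shift, x$digit_shift))
  invisible(x)
}

LETTERS_DIGITS <- paste0(paste(LETTERS, collapse = ""), "0123456789")

rotated_alphabet <- function(letter_shift, digit_shift) {
  ls <- letter_shift %% 26
  ds <- digit_shift %% 10
  paste0(
    paste(LETTERS[((seq_len(26) - 1 + ls) %% 26) + 1], collapse = ""),
    paste((((0:9) + ds) %% 10), collapse = "")
  )
}

shift_apply <- function(s, letter_shift, digit_shift) {
  bad <- grepl("[^A-Z0-9]", s)
  if (any(bad))
    stop(nhash_error("bad_charset",
      sprintf("string %s contains characters outside [A-Z0-9]", deparse(s[bad][1]))))
  chartr(LETTERS_DIGITS, rotated_alphabet(letter_shift, digit_shift), s)
}

#' Shift-cipher encryption and decryption
#'
#' Rotates each letter forward `letter_shift` places within A-Z and each
#' digit forward `digit_shift` places within 0-9, both with wraparound;
#' length and per-position character class are preserved.
#' `shift_decrypt()` is the exact inverse.
#'
#' @param s Alphanumeric string(s), characters in `[A-Z0-9]` only.
#' @param key An `nhash_key`, or any list with `letter_shift` and
#'   `digit_shift` fields.
#' @return The rotated string(s).
#' @examples
#' key <- list(letter_shift = 5, digit_shift = 9)
#' shift_encrypt("ONSK717281", key)  # "TSXP606170"
#' shift_decrypt("TSXP606170", key)  # back again
#' @export
shift_encrypt <- function(s, key) {
  shift_apply(s, key$letter_shift, key$digit_shift)
}

#' @rdname shift_encrypt
#' @export
shift_decrypt <- function(s, key) {
  shift_apply(s, 26L - key$letter_shift %% 26L, 10L - key$digit_shift %% 10L)
}

# Strings each component reads from, in profile order
component_sources <- function(s, profile) {
  vapply(profile$components, function(cmp)
    switch(cmp$source, name = s$name_token, mrn = s$mrn_token, dob = s$dob_token),
    character(1))
}

#' Generate an identifier for one record and one random number
#'
#' The two-phase algorithm: (1) extract one n-gram per profile component
#' from the sanitized inputs, each starting at `r mod |m_i|` (a single
#' shared `r`), and concatenate them into the intermediate string;
#' (2) encrypt the intermediate with the shift cipher keyed by the Cantor
#' pair of (name length, birth month), then append `r` zero-padded to the
#' profile's suffix width.
#'
#' @param record A [demographic_record()].
#' @param r Nonnegative integer below `10^random_digits`. Per-component
#'   random numbers are supported by passing a vector of length
#'   `length(profile$components)`; the suffix then records the first.
#' @param profile An [nhash_profile()]; defaults to [csr_profile()].
#' @return An object of class `nhash_id` with fields `full`, `cipher_part`,
#'   `random_part`, `intermediate`, `r`, `offsets`, `ngrams`, `key`.
#' @examples
#' rec <- demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
#' generate_identifier(rec, r = 783305)  # "TSXP606170783305"
#' @export
generate_identifier <- function(record, r, profile = csr_profile()) {
  k <- length(profile$components)
  if (!length(r) %in% c(1L, k))
    stop(nhash_error("bad_argument",
      sprintf("`r` must have length 1 or %d", k)))
  rs <- rep_len(r, k)
  if (any(rs < 0) || any(rs != floor(rs)))
    stop(nhash_error("bad_argument", "`r` must be nonnegative integer(s)"))
  if (rs[1] >= 10^profile$random_digits)
    stop(nhash_error("bad_argument",
      sprintf("r = %s does not fit in %d suffix digits",
              format(rs[1], scientific = FALSE), profile$random_digits)))

  s <- sanitize(record)
  ms <- component_sources(s, profile)
  ns <- vapply(profile$components, function(cmp) cmp$n, integer(1))
  offsets <- rs %% nchar(ms)
  ngrams <- vapply(seq_len(k), function(i) ngram_extract_vec(rs[i], ns[i], ms[i]),
                   character(1))
  intermediate <- paste(ngrams, collapse = "")
  key <- derive_shift_key(s)
  cipher_part <- shift_encrypt(intermediate, key)
  random_part <- formatC(rs[1], width = profile$random_digits, flag = "0",
                         format = "d")
  structure(
    list(full = paste0(cipher_part, random_part),
         cipher_part = cipher_part, random_part = random_part,
         intermediate = intermediate, r = rs[1],
         offsets = offsets, ngrams = ngrams, key = key,
         profile = profile),
    class = "nhash_id"
  )
}

#' @export
print.nhash_id <- function(x, ...) {
  cat("NHash identifier:", x$full, "\n")
  cat("  intermediate:", x$intermediate,
      sprintf("(offsets %s)\n", paste(x$offsets, collapse = ", ")))
  cat(sprintf("  cipher: %s (letters +%d, digits +%d), suffix r = %s\n",
              x$cipher_part, x$key$letter_shift, x$key$digit_shift,
              format(x$r, scientific = FALSE)))
  invisible(x)
}

#' @export
as.character.nhash_id <- function(x, ...) x$full

#' @export
format.nhash_id <- function(x, ...) x$full

#' Batch identifier generation over vectors of demographics
#'
#' Vectorized equivalent of [generate_identifier()] returning the bare
#' identifier strings; used by the batch CSV workflow and the collision
#' simulator. All arguments are recycled to a common length.
#'
#' @param first_name,last_name,mrn,dob Demographic field vectors (`dob` as
#'   `Date` or `mm/dd/yyyy` / `yyyy-mm-dd` strings).
#' @param r Nonnegative integers below `10^random_digits`.
#' @param profile An [nhash_profile()].
#' @return Character vector of full identifiers.
#' @export
generate_identifier_batch <- function(first_name, last_name, mrn, dob, r,
                                      profile = csr_profile()) {
  name_token <- fold_name(paste0(first_name, last_name))
  if (any(!nzchar(name_token)))
    stop(nhash_error("empty_name", "record with empty sanitized name"))
  mrn <- as.character(mrn)
  if (any(!grepl("^[0-9]{1,8}$", mrn)))
    stop(nhash_error("invalid_mrn", "MRN must be 1-8 decimal digits"))
  mrn_token <- sprintf("%08d", as.integer(mrn))
  dob <- parse_dob(dob)
  dob_token <- format(dob, "%m%d%Y")
  if (any(r < 0) || any(r >= 10^profile$random_digits))
    stop(nhash_error("bad_argument", "r out of range for suffix width"))

  n <- max(length(name_token), length(mrn_token), length(dob_token), length(r))
  name_token <- rep_len(name_token, n); mrn_token <- rep_len(mrn_token, n)
  dob_token <- rep_len(dob_token, n);   r <- rep_len(r, n)

  parts <- lapply(profile$components, function(cmp) {
    m <- switch(cmp$source, name = name_token, mrn = mrn_token, dob = dob_token)
    ngram_extract_vec(r, cmp$n, m)
  })
  intermediate <- do.call(paste0, parts)

  # cipher keys vary per record; group rows sharing (letter, digit) shift
  C <- cantor_pair(nchar(name_token), as.integer(substr(dob_token, 1, 2)))
  ls <- C %% 26; ds <- C %% 10
  grp <- ls * 10 + ds
  cipher <- character(n)
  for (g in unique(grp)) {
    i <- which(grp == g)
    cipher[i] <- chartr(LETTERS_DIGITS,
                        rotated_alphabet(ls[i[1]], ds[i[1]]),
                        intermediate[i])
  }
  paste0(cipher, formatC(r, width = profile$random_digits, flag = "0",
                         format = "d"))
}

#' Generate an identifier guaranteed fresh in a local registry
#'
#' Draws a random number, generates the identifier, and checks it against
#' the site's local registry (the duplication check run before an
#' identifier enters use); on a local collision a fresh random number is
#' drawn and the generation repeated. The accepted identifier is inserted
#' into the registry.
#'
#' @param record A [demographic_record()].
#' @param registry An [nhash_registry()]; mutated in place.
#' @param profile An [nhash_profile()].
#' @param max_retries Attempts before giving up (a saturated registry).
#' @param rng Zero-argument function returning one integer uniform on
#'   `[0, 10^random_digits)`. Defaults to R's RNG (seedable via
#'   `set.seed()`); substitute a cryptographically secure source in
#'   production deployments.
#' @param ref Opaque local reference stored alongside the identifier.
#' @return The accepted `nhash_id`.
#' @export
generate_unique <- function(record, registry, profile = csr_profile(),
                            max_retries = 100L, rng = NULL, ref = NA_character_) {
  stopifnot(max_retries >= 1L)
  if (is.null(rng)) {
    space <- 10^profile$random_digits
    rng <- function() {
      if (space <= .Machine$integer.max) sample.int(space, 1L) - 1L
      else floor(stats::runif(1) * space)
    }
  }
  for (attempt in seq_len(max_retries)) {
    id <- generate_identifier(record, rng(), profile)
    if (!registry_contains(registry, id$full)) {
      registry_add(registry, id$full, ref = ref)
      return(id)
    }
  }
  stop(nhash_error("retries_exhausted",
    sprintf("no unused identifier found in %d attempts; registry may be saturated",
            max_retries)))
}
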
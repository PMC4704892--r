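#' Split an identifier into cipher part and embedded random number
#'
#' The suffix of an identifier is the random number in clear, so any
#' identifier can be split without secrets: the first `sum(n_i)` characters
#' are the cipher part, the remaining `random_digits` parse back to `r`.
#' Wrong length or characters outside the per-position class (letters in
#' name positions, digits elsewhere) make the identifier *malformed*,
#' which is distinct from well-formed-but-invalid (see
#' [validate_identifier()]).
#'
#' @param id_string Identifier string.
#' @param profile An [nhash_profile()].
#' @return A list with `cipher_part` and `r`.
#' @examples
#' parse_identifier("TSXP606170783305")  # cipher "TSXP606170", r = 783305
#' @export
parse_identifier <- function(id_string, profile = csr_profile()) {
  stopifnot(length(id_string) == 1L)
  if (!grepl(identifier_regex(profile), id_string))
    stop(nhash_error("malformed_id",
      sprintf("%s is not a well-formed identifier for profile %s (expected %d chars, letters in name positions, digits elsewhere)",
              deparse(as.character(id_string)), profile_tag(profile),
              id_length(profile))))
  cl <- cipher_length(profile)
  list(cipher_part = substr(id_string, 1, cl),
       r = as.numeric(substr(id_string, cl + 1, id_length(profile))))
}

identifier_regex <- function(profile) {
  mask <- cipher_letter_mask(profile)
  runs <- rle(mask)
  body <- paste0(ifelse(runs$values, "[A-Z]", "[0-9]"),
                 "{", runs$lengths, "}", collapse = "")
  paste0("^", body, "[0-9]{", profile$random_digits, "}$")
}

#' Validate an identifier against its codebook record
#'
#' Regenerates the identifier from the demographic record and the random
#' number embedded in the suffix, and compares byte-for-byte. Because
#' generation is deterministic given `(record, r)`, any edit to the cipher
#' part — and, in practice, any edit to the suffix, which changes the
#' regenerated cipher — yields a mismatch. Validation requires the record:
#' without the codebook entry there is nothing to regenerate from.
#'
#' @param id_string Identifier to check.
#' @param record The [demographic_record()] the codebook links it to.
#' @param profile An [nhash_profile()].
#' @return An object of class `nhash_validation`: fields `identifier`,
#'   `parsed_r`, `regenerated`, `valid`, `mismatch_positions`.
#' @examples
#' rec <- demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
#' validate_identifier("TSXP606170783305", rec)$valid   # TRUE
#' validate_identifier("TSXP606170783306", rec)$valid   # FALSE
#' @export
validate_identifier <- function(id_string, record, profile = csr_profile()) {
  parsed <- parse_identifier(id_string, profile)
  regen <- generate_identifier(record, parsed$r, profile)$full
  a <- strsplit(id_string, "")[[1]]
  b <- strsplit(regen, "")[[1]]
  mismatch <- which(a != b)
  structure(
    list(identifier = id_string, parsed_r = parsed$r, regenerated = regen,
         valid = identical(regen, id_string),
         mismatch_positions = mismatch),
    class = "nhash_validation"
  )
}

#' @export
print.nhash_validation <- function(x, ...) {
  cat("Identifier:  ", x$identifier, "\n")
  cat("Regenerated: ", x$regenerated,
      sprintf(" (r = %s)\n", format(x$parsed_r, scientific = FALSE)))
  if (x$valid) cat("VALID: regeneration matches byte-for-byte\n")
  else cat("INVALID: mismatch at position(s)",
           paste(x$mismatch_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive single-edit error-tolerance scan
#'
#' Enumerates every single-position, within-character-class substitution of
#' a valid identifier (25 alternatives per letter position, 9 per digit
#' position), validates each mutant against the record, and reports the
#' fraction detected as invalid. Cipher-position edits are always caught
#' (regeneration is deterministic in `r`); suffix edits change `r` and are
#' caught unless the new `r` happens to regenerate the typed cipher.
#'
#' @param id_string A valid identifier for `record`.
#' @param record Its [demographic_record()].
#' @param profile An [nhash_profile()].
#' @param positions `"all"`, `"cipher"`, or `"suffix"`.
#' @return An object of class `nhash_scan`: `fraction_detected`, `total`,
#'   `detected`, `missed` (character vector of undetected mutants), and a
#'   per-position data.frame `detail`.
#' @export
error_tolerance_scan <- function(id_string, record, profile = csr_profile(),
                                 positions = c("all", "cipher", "suffix")) {
  positions <- match.arg(positions)
  if (!validate_identifier(id_string, record, profile)$valid)
    stop(nhash_error("bad_argument",
      "scan requires an identifier that validates against the record"))
  cl <- cipher_length(profile)
  total_len <- id_length(profile)
  pos_set <- switch(positions,
    all = seq_len(total_len),
    cipher = seq_len(cl),
    suffix = (cl + 1L):total_len)
  chars <- strsplit(id_string, "")[[1]]
  letter_pos <- c(cipher_letter_mask(profile), rep(FALSE, profile$random_digits))

  rows <- list()
  missed <- character()
  for (p in pos_set) {
    alphabet <- if (letter_pos[p]) LETTERS else as.character(0:9)
    for (alt in setdiff(alphabet, chars[p])) {
      mutant <- chars; mutant[p] <- alt
      mutant <- paste(mutant, collapse = "")
      ok <- validate_identifier(mutant, record, profile)$valid
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, substitute = alt, mutant = mutant,
        detected = !ok, stringsAsFactors = FALSE)
      if (ok) missed <- c(missed, mutant)
    }
  }
  detail <- do.call(rbind, rows)
  structure(
    list(fraction_detected = mean(detail$detected),
         total = nrow(detail), detected = sum(detail$detected),
         missed = missed, detail = detail,
         identifier = id_string, positions = positions),
    class = "nhash_scan"
  )
}

#' @export
print.nhash_scan <- function(x, ...) {
  cat(sprintf("Single-edit scan of %s (%s positions): %d/%d substitutions detected (%.4f)\n",
              x$identifier, x$positions, x$detected, x$total,
              x$fraction_detected))
  if (length(x$missed))
    cat("undetected mutants:", paste(x$missed, collapse = ", "), "\n")
  invisible(x)
}

#' Per-visit report name: identifier plus 2-digit visit postfix
#'
#' A participant makes multiple clinic visits, each producing a discharge
#' report; reports are named by the identifier plus a zero-padded 2-digit
#' visit number (01-99).
#'
#' @param identifier Identifier string (or `nhash_id`).
#' @param visit_number Integer in 1..99.
#' @return The postfixed name.
#' @examples
#' report_name("TSXP606170783305", 1)  # "TSXP60617078330501"
#' @export
report_name <- function(identifier, visit_number) {
  if (inherits(identifier, "nhash_id")) identifier <- identifier$full
  v <- as.integer(visit_number)
  if (is.na(v) || v < 1L || v > 99L)
    stop(nhash_error("bad_argument", "visit_number must be an integer in 1..99"))
  paste0(identifier, formatC(v, width = 2, flag = "0"))
}
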
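#' Construct a demographic record
#'
#' Bundles the identity fields consumed by the hash: first and last name,
#' medical record number (MRN, a digit string of at most 8 digits), and date
#' of birth. Validation is deferred to [sanitize()], which is where malformed
#' fields are rejected.
#'
#' @param first_name,last_name Character scalars; each must contain at least
#'   one alphabetic character.
#' @param mrn Digit string (or integer) of at most 8 digits; shorter MRNs are
#'   left-padded with zeros during sanitization.
#' @param dob Date of birth: a `Date`, or a string in `mm/dd/yyyy` or ISO
#'   `yyyy-mm-dd` form.
#' @return An object of class `nhash_record`.
#' @examples
#' demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956")
#' @export
demographic_record <- function(first_name, last_name, mrn, dob) {
  structure(
    list(first_name = as.character(first_name),
         last_name = as.character(last_name),
         mrn = as.character(mrn),
         dob = dob),
    class = "nhash_record"
  )
}

#' @export
print.nhash_record <- function(x, ...) {
  cat("Demographic record:", x$first_name, x$last_name,
      "| MRN", x$mrn, "| DOB", format(parse_dob(x$dob), "%m/%d/%Y"), "\n")
  invisible(x)
}

# Accepts Date, mm/dd/yyyy, or yyyy-mm-dd; vectorized. Errors on failure.
parse_dob <- function(dob) {
  if (inherits(dob, "Date")) return(dob)
  dob <- as.character(dob)
  out <- as.Date(rep(NA_real_, length(dob)))
  slash <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", dob)
  out[slash] <- as.Date(dob[slash], format = "%m/%d/%Y")
  iso <- !slash & grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", dob)
  out[iso] <- as.Date(dob[iso], format = "%Y-%m-%d")
  if (anyNA(out)) {
    bad <- dob[is.na(out)][1]
    stop(nhash_error("invalid_dob",
      sprintf("cannot parse date of birth %s (expected mm/dd/yyyy or yyyy-mm-dd)",
              deparse(bad))))
  }
  out
}

# Fold diacritics where a plain ASCII mapping exists, then drop everything
# that is not A-Z. Vectorized.
fold_name <- function(x) {
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- ""
  gsub("[^A-Z]", "", toupper(x))
}

#' Sanitize a demographic record into the three hash-input strings
#'
#' Produces the canonical inputs the n-gram hash reads: the uppercase
#' letters-only name token (first name then last name, punctuation, spaces
#' and diacritics removed), the MRN left-zero-padded to 8 digits, and the
#' date of birth rendered as `mmddyyyy`.
#'
#' @param record An [demographic_record()], or anything with `first_name`,
#'   `last_name`, `mrn`, `dob` fields.
#' @return An object of class `nhash_input` with fields `name_token`,
#'   `mrn_token`, `dob_token` and `dob` (the parsed `Date`).
#' @examples
#' sanitize(demographic_record("Aaron", "Skotnica", "07172485", "08/13/1956"))
#' @export
sanitize <- function(record) {
  name_token <- fold_name(paste0(record$first_name, record$last_name))
  if (!nzchar(name_token))
    stop(nhash_error("empty_name",
      "name contains no alphabetic characters after sanitization"))

  mrn <- as.character(record$mrn)
  if (!grepl("^[0-9]+$", mrn))
    stop(nhash_error("invalid_mrn",
      sprintf("MRN %s must consist only of decimal digits", deparse(mrn))))
  if (nchar(mrn) > 8L)
    stop(nhash_error("invalid_mrn",
      sprintf("MRN %s has more than 8 digits", deparse(mrn))))
  mrn_token <- sprintf("%08d", as.integer(mrn))

  dob <- parse_dob(record$dob)
  dob_token <- format(dob, "%m%d%Y")

  structure(
    list(name_token = name_token, mrn_token = mrn_token,
         dob_token = dob_token, dob = dob),
    class = "nhash_input"
  )
}

#' @export
print.nhash_input <- function(x, ...) {
  cat("Sanitized hash input:\n")
  cat("  m1 (name):", x$name_token, sprintf("(|m1| = %d)\n", nchar(x$name_token)))
  cat("  m2 (MRN): ", x$mrn_token, "\n")
  cat("  m3 (DOB): ", x$dob_token, "\n")
  invisible(x)
}

# Typed condition so callers can distinguish input-validation failures
# (class nhash_<code>) from ordinary errors.
nhash_error <- function(code, message) {
  structure(
    class = c(paste0("nhash_", code), "nhash_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}
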
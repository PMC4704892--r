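#' Synthetic cohort configuration
#'
#' Describes how synthetic participant demographics are drawn: first and
#' last names sampled with probability proportional to frequency weights
#' from name tables, MRNs uniform over 8-digit strings (leading zeros
#' allowed), dates of birth uniform over the days of 1910-01-01 to
#' 2015-12-31. The bundled tables hold ~200 common US surnames and ~100
#' first names with census-scale weights; studies wanting the full
#' top-5000/top-2500 protocol supply their own two-column
#' (name, weight) files.
#'
#' @param surnames,firstnames data.frames with columns `name` and `weight`
#'   (positive), or paths to whitespace/tab-delimited two-column files with
#'   a header. `NULL` loads the bundled tables.
#' @param mrn_digits MRN width (digits).
#' @param dob_range Length-2 `Date` (or parseable) vector, inclusive.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(surnames = NULL, firstnames = NULL,
                          mrn_digits = 8L,
                          dob_range = as.Date(c("1910-01-01", "2015-12-31"))) {
  surnames <- load_name_table(surnames, "surnames")
  firstnames <- load_name_table(firstnames, "firstnames")
  dob_range <- as.Date(dob_range)
  stopifnot(length(dob_range) == 2L, !anyNA(dob_range),
            dob_range[1] <= dob_range[2], mrn_digits >= 1L)
  structure(
    list(surnames = surnames, firstnames = firstnames,
         mrn_digits = as.integer(mrn_digits), dob_range = dob_range),
    class = "cohort_config"
  )
}

load_name_table <- function(x, which) {
  if (is.null(x))
    x <- system.file("extdata", paste0(which, ".tsv"), package = "nhash",
                     mustWork = TRUE)
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), all(c("name", "weight") %in% names(x)),
            nrow(x) >= 1L)
  if (any(!is.finite(x$weight)) || any(x$weight <= 0))
    stop(nhash_error("bad_argument", "name weights must be positive and finite"))
  x[, c("name", "weight")]
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d surnames x %d first names (frequency-weighted),\n",
              nrow(x$surnames), nrow(x$firstnames)))
  cat(sprintf("  %d-digit uniform MRN, DOB uniform %s .. %s\n",
              x$mrn_digits, x$dob_range[1], x$dob_range[2]))
  invisible(x)
}

#' Draw synthetic participant demographics
#'
#' `sample_cohort()` draws `n` records at once; `sample_person()` is the
#' single-record convenience. Both use R's current RNG stream, so
#' `set.seed()` gives byte-identical record streams.
#'
#' @param n Number of records.
#' @param config A [cohort_config()].
#' @return `sample_cohort()`: a data.frame with columns `first_name`,
#'   `last_name`, `mrn`, `dob`; `sample_person()`: a
#'   [demographic_record()].
#' @export
sample_cohort <- function(n, config = cohort_config()) {
  stopifnot(n >= 1L)
  first <- sample(config$firstnames$name, n, replace = TRUE,
                  prob = config$firstnames$weight)
  last <- sample(config$surnames$name, n, replace = TRUE,
                 prob = config$surnames$weight)
  mrn <- random_digit_strings(n, config$mrn_digits)
  span <- as.integer(config$dob_range[2] - config$dob_range[1]) + 1L
  dob <- config$dob_range[1] + (sample.int(span, n, replace = TRUE) - 1L)
  data.frame(first_name = first, last_name = last, mrn = mrn, dob = dob,
             stringsAsFactors = FALSE)
}

#' @rdname sample_cohort
#' @export
sample_person <- function(config = cohort_config()) {
  row <- sample_cohort(1L, config)
  demographic_record(row$first_name, row$last_name, row$mrn, row$dob)
}

# n uniform digit strings of the given width, leading zeros allowed
random_digit_strings <- function(n, width) {
  if (width <= 9) {
    formatC(sample.int(10^width, n, replace = TRUE) - 1L,
            width = width, flag = "0", format = "d")
  } else {
    do.call(paste0, lapply(seq_len(width), function(i)
      sample(as.character(0:9), n, replace = TRUE)))
  }
}

#' Random-string baseline identifiers
#'
#' The benchmark identifier: 4 uniform uppercase letters followed by
#' `len - 4` uniform digits, giving inverse probability
#' `26^4 * 10^(len-4)` (the composition consistent with the published
#' expected-collision figures for the Random-n baselines).
#'
#' @param n Number of identifiers to draw.
#' @param len Identifier length, `>= 5`.
#' @return Character vector of `n` identifiers.
#' @examples
#' set.seed(1); random_string_id(3, 11)
#' @export
random_string_id <- function(n, len) {
  if (len < 5) stop(nhash_error("bad_argument", "len must be >= 5"))
  letters4 <- do.call(paste0, lapply(1:4, function(i)
    sample(LETTERS, n, replace = TRUE)))
  paste0(letters4, random_digit_strings(n, len - 4L))
}

# Inverse probability of the Random-n baseline
random_string_space <- function(len) 26^4 * 10^(len - 4)

#' Count identifier collisions in a stream
#'
#' An insertion collides when its identifier is already present, so the
#' collision count is `length(ids) - length(unique(ids))` — the quantity
#' whose expectation is [expected_collisions()].
#'
#' @param ids Character vector of identifiers, in insertion order.
#' @return Nonnegative integer count.
#' @examples
#' count_collisions(c("a", "b", "a", "a"))  # 2
#' @export
count_collisions <- function(ids) {
  length(ids) - length(unique(ids))
}

#' Replicated collision-counting experiment
#'
#' Generates `runs` independent streams of `size` identifiers by the given
#' method, counts collisions in each, and reports per-run counts, their
#' mean, and the analytic expectation for the method's identifier space
#' (for the n-gram hash, the lower/upper inverse-probability bounds give
#' an EC bracket). Identifiers are generated in chunks so memory stays at
#' O(size) strings per run. Seeds for run `k` are derived as
#' `base_seed + k`, so identical `(method, size, runs, base_seed)` calls
#' reproduce the table exactly.
#'
#' @param method `"random:<len>"` (e.g. `"random:11"`) or `"nhash"`.
#' @param size Identifiers per run.
#' @param runs Number of replicates.
#' @param base_seed Integer seed the per-run seeds derive from.
#' @param profile Profile for `method = "nhash"`.
#' @param config [cohort_config()] for `method = "nhash"`.
#' @param max_size Guard rail: sizes above this need `allow_large = TRUE`
#'   (a full-scale 1e8-record run takes hours and tens of GiB of strings).
#' @param allow_large Explicit opt-in for very large runs.
#' @return A data.frame of class `collision_experiment` with columns `run`,
#'   `seed`, `collisions`; attributes `mean`, `ec` (named vector: the
#'   analytic EC, or bracket `ec_lower`/`ec_upper` for nhash), `method`,
#'   `size`.
#' @examples
#' run_experiment("random:7", size = 1e4, runs = 3, base_seed = 42)
#' @export
run_experiment <- function(method, size, runs = 5L, base_seed = 1L,
                           profile = csr_profile(), config = cohort_config(),
                           max_size = 1e6, allow_large = FALSE) {
  stopifnot(size >= 1, runs >= 1)
  if (size > max_size && !allow_large)
    stop(nhash_error("size_guard",
      sprintf("size %g exceeds the %g guard rail; pass allow_large = TRUE for full-scale runs",
              size, max_size)))

  if (grepl("^random:\\d+$", method)) {
    len <- as.integer(sub("^random:", "", method))
    gen <- function(n) random_string_id(n, len)
    ec <- c(ec = expected_collisions(random_string_space(len), size))
  } else if (identical(method, "nhash")) {
    gen <- function(n) {
      cohort <- sample_cohort(n, config)
      r <- floor(stats::runif(n) * 10^profile$random_digits)
      generate_identifier_batch(cohort$first_name, cohort$last_name,
                                cohort$mrn, cohort$dob, r, profile)
    }
    b <- csr_bounds(profile)
    ec <- c(ec_lower = expected_collisions(attr(b, "upper_total"), size),
            ec_upper = expected_collisions(attr(b, "lower_total"), size))
  } else {
    stop(nhash_error("bad_argument",
      sprintf("unknown method %s (use \"random:<len>\" or \"nhash\")",
              deparse(method))))
  }

  seeds <- base_seed + seq_len(runs)
  collisions <- integer(runs)
  chunk <- 1e5
  for (k in seq_len(runs)) {
    set.seed(seeds[k])
    ids <- character(size)
    done <- 0
    while (done < size) {
      m <- min(chunk, size - done)
      ids[done + seq_len(m)] <- gen(m)
      done <- done + m
    }
    collisions[k] <- count_collisions(ids)
  }
  out <- data.frame(run = seq_len(runs), seed = seeds, collisions = collisions)
  structure(out, class = c("collision_experiment", "data.frame"),
            mean = mean(collisions), ec = ec, method = method, size = size)
}

#' @export
print.collision_experiment <- function(x, ...) {
  cat(sprintf("Collision experiment: %s, %s identifiers x %d runs\n",
              attr(x, "method"),
              format(attr(x, "size"), big.mark = ",", scientific = FALSE),
              nrow(x)))
  print.data.frame(x, row.names = FALSE)
  cat("mean collisions:", format(attr(x, "mean")), "\n")
  ec <- attr(x, "ec")
  cat("analytic EC:    ",
      paste(sprintf("%s = %.6g", names(ec), ec), collapse = ", "), "\n")
  invisible(x)
}
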
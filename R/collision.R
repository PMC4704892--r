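#' Expected collisions after I uniform insertions into N slots
#'
#' The occupancy (birthday-problem) model: with an identifier scheme whose
#' inverse probability is `N` (that many equally likely identifier values),
#' the expected number of collisions after `I` insertions is
#' `EC = I - N + N (1 - 1/N)^I`.
#'
#' Naive floating-point evaluation cancels catastrophically when `I/N` is
#' tiny (for `N ~ 1e15` the answer is the residual of two ~`1e6`-sized
#' terms). For `I/N <= 1e-2` the value is therefore computed from the
#' cancellation-free alternating series
#' `EC = C(I,2)/N - C(I,3)/N^2 + C(I,4)/N^3 - ...`, which converges with
#' term ratio `< I/N`; otherwise from `I + N*expm1(I*log1p(-1/N))`, which
#' is well-conditioned in that regime. Relative accuracy is ~1e-12
#' throughout, comfortably inside the 1e-6 contract.
#'
#' @param N Inverse probability, `>= 1` (vectorized, recycled against `I`).
#' @param I Number of insertions, `>= 0`.
#' @return `EC`, a nonnegative real (0 when `I <= 1`; `I - 1` when `N = 1`).
#' @examples
#' expected_collisions(6.6e15, 1e6)   # 7.58e-5, i.e. 0.000076
#' expected_collisions(4.6e12, 1e8)   # 1086.95
#' @export
expected_collisions <- function(N, I) {
  check_NI(N, I)
  n <- max(length(N), length(I))
  N <- rep_len(as.numeric(N), n); I <- rep_len(as.numeric(I), n)
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- ec_one(N[j], I[j])
  out
}

check_NI <- function(N, I) {
  if (any(N < 1)) stop(nhash_error("bad_argument", "N must be >= 1"))
  if (any(I < 0)) stop(nhash_error("bad_argument", "I must be >= 0"))
}

ec_one <- function(N, I) {
  if (I <= 1) return(0)
  if (N == 1) return(I - 1)
  if (I / N <= 1e-2) {
    # alternating series in 1/N; term_{j+1} = term_j * -(I-j)/((j+1) N)
    term <- I * (I - 1) / (2 * N)
    total <- term
    j <- 2
    while (j < I) {
      term <- term * (-(I - j) / ((j + 1) * N))
      total <- total + term
      j <- j + 1
      if (abs(term) < abs(total) * 1e-17) break
    }
    total
  } else {
    I + N * expm1(I * log1p(-1 / N))
  }
}

#' Expected empty slots after I uniform insertions into N slots
#'
#' `EE = N (1 - 1/N)^I`; satisfies `EC = I - (N - EE)`, since `N - EE` is
#' the expected number of occupied slots.
#'
#' @inheritParams expected_collisions
#' @return `EE`, in `[0, N]`.
#' @export
expected_empty_slots <- function(N, I) {
  check_NI(N, I)
  n <- max(length(N), length(I))
  N <- rep_len(as.numeric(N), n); I <- rep_len(as.numeric(I), n)
  ifelse(N == 1, as.numeric(I == 0), N * exp(I * log1p(-1 / N)))
}

#' Per-component inverse-probability bounds for a profile
#'
#' Brackets the effective identifier space: for each n-gram component a
#' lower and an upper bound on the number of equally likely values, and
#' their products as bounds on the total inverse probability `N`. Name
#' n-grams are bounded below by `10^n` (letters drawn from a skewed,
#' roughly decimal-entropy alphabet of common-name text) and above by
#' `26^n`; MRN digits below by `9^n`, above by `10^n`; DOB grams by
#' `10^n` on both sides (only two year digits vary freely across the
#' current population); the random suffix contributes exactly
#' `10^random_digits`.
#'
#' @param profile An [nhash_profile()].
#' @return An object of class `nhash_bounds`: a data.frame with columns
#'   `component`, `lower`, `upper` plus a `Total` row; attributes
#'   `lower_total` and `upper_total` hold the exact products.
#' @examples
#' csr_bounds()  # totals 6.6e15 and 4.6e17
#' @export
csr_bounds <- function(profile = csr_profile()) {
  rows <- lapply(profile$components, function(cmp) {
    b <- switch(cmp$source,
      name = c(10^cmp$n, 26^cmp$n),
      mrn  = c(9^cmp$n, 10^cmp$n),
      dob  = c(10^cmp$n, 10^cmp$n))
    data.frame(component = cmp$source, lower = b[1], upper = b[2])
  })
  rows[[length(rows) + 1L]] <- data.frame(
    component = "random", lower = 10^profile$random_digits,
    upper = 10^profile$random_digits)
  tab <- do.call(rbind, rows)
  lower_total <- prod(tab$lower); upper_total <- prod(tab$upper)
  tab <- rbind(tab, data.frame(component = "Total", lower = lower_total,
                               upper = upper_total))
  structure(tab, class = c("nhash_bounds", "data.frame"),
            lower_total = lower_total, upper_total = upper_total)
}

#' @export
print.nhash_bounds <- function(x, ...) {
  cat("Inverse-probability bounds (number of equally likely identifiers):\n")
  shown <- data.frame(component = x$component,
                      lower = signif(x$lower, 2), upper = signif(x$upper, 2))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate expected collisions over grids of N and I
#'
#' Evaluates [expected_collisions()] for every (N, I) pair, reproducing
#' published bound tables when fed their (rounded) inverse probabilities.
#'
#' @param N Vector of inverse probabilities.
#' @param I Vector of insertion counts.
#' @param labels Optional row labels for the N values.
#' @return A data.frame of class `nhash_ec_table`, long form, with columns
#'   `label`, `N`, `I`, `EC`.
#' @examples
#' ec_table(N = c(6.6e15, 4.6e17), I = c(1e6, 1e7, 1e8))
#' @export
ec_table <- function(N, I, labels = NULL) {
  if (is.null(labels)) labels <- format(N, scientific = TRUE, digits = 2)
  grid <- expand.grid(i = seq_along(N), j = seq_along(I))
  out <- data.frame(
    label = labels[grid$i],
    N = N[grid$i], I = I[grid$j],
    EC = expected_collisions(N[grid$i], I[grid$j]),
    stringsAsFactors = FALSE)
  class(out) <- c("nhash_ec_table", "data.frame")
  out
}

#' @export
print.nhash_ec_table <- function(x, ...) {
  shown <- data.frame(label = x$label, N = x$N, I = x$I,
                      EC = signif(x$EC, 6))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
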
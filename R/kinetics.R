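# Kinetic competition ----------------------------------------------------
#
# The S1 population decays through three parallel first-order channels,
# so the branching fraction of each channel is its rate over the total:
# QYF = k_r / (k_r + k_ISC + k_IC), and the excited-state lifetime is
# 1 / (k_r + k_ISC + k_IC).

rates_from_input <- function(r) {
  if (is.data.frame(r)) {
    r <- validate_rate_set(as_tibble(r))
    out <- setNames(rep(0, 3), .rate_channels)
    out[r$channel] <- r$rate
    return(out)
  }
  if (is.numeric(r) && length(r) == 3L) {
    if (is.null(names(r))) names(r) <- .rate_channels
    return(r[.rate_channels])
  }
  abort("`r` must be a rate_set tibble or a numeric vector (k_r, k_isc, k_ic).")
}

#' Quantum yields, branching fractions and lifetime from a rate set
#'
#' @param r A [rate_set()] tibble, or a numeric vector of the three rates
#'   `(k_r, k_isc, k_ic)` in s^-1. A channel absent from a rate set
#'   counts as zero.
#' @return A one-row tibble: `qyf` (fluorescence quantum yield),
#'   `phi_isc` (dark-triplet formation yield), `phi_ic` (internal
#'   conversion yield) — fractions summing to 1 — and `lifetime` in s.
#' @examples
#' quantum_yield(c(1.61e8, 1.96e9, 4.96e6)) # QYF ~ 7.6%
#' @export
quantum_yield <- function(r) {
  k <- rates_from_input(r)
  if (any(k < 0) || any(!is.finite(k))) abort("rates must be finite and >= 0.")
  total <- sum(k)
  if (total == 0) abort("all rates are zero: lifetime and yields undefined.")
  tibble(
    qyf = k[["k_r"]] / total,
    phi_isc = k[["k_isc"]] / total,
    phi_ic = k[["k_ic"]] / total,
    lifetime = 1 / total
  )
}

yield_table_columns <- c(
  "name", "e_s1", "f_s1", "e_t1", "gap_s1_t1", "socme",
  "k_r", "k_r_provenance", "k_isc", "k_isc_provenance",
  "k_ic", "k_ic_provenance",
  "qyf", "phi_isc", "phi_ic", "lifetime", "qyf_percent"
)

#' Rate and quantum-yield table for a set of emitters
#'
#' Runs [compute_rates()] and [quantum_yield()] for each descriptor and
#' assembles one row per emitter, in input order. `qyf_percent` is the
#' fluorescence quantum yield in percent rounded half-up to an integer
#' (presentation only; `qyf` keeps full precision).
#'
#' @param ds A list of [emitter_descriptor()] objects.
#' @param p An [fcwd_params()] passed to the ISC channel.
#' @param prefer Passed to [compute_rates()]: `"supplied"` (default)
#'   or `"computed"`.
#' @return A tibble with one row per emitter: identification (`name`),
#'   S1-optimized-geometry inputs (`e_s1`, `f_s1`, `e_t1`, `gap_s1_t1`,
#'   `socme`), the three rates with their provenance, the yields
#'   (`qyf`, `phi_isc`, `phi_ic`), `lifetime`, and `qyf_percent`. An error in
#'   any row is rethrown naming the failing emitter. Duplicate emitter
#'   names are kept, with a warning.
#' @examples
#' yield_table(load_table1_fixtures())
#' @export
yield_table <- function(ds, p = fcwd_params(), prefer = c("supplied", "computed")) {
  prefer <- match.arg(prefer)
  if (!length(ds)) {
    return(tibble(
      name = character(), e_s1 = numeric(), f_s1 = numeric(),
      e_t1 = numeric(), gap_s1_t1 = numeric(), socme = numeric(),
      k_r = numeric(), k_r_provenance = character(),
      k_isc = numeric(), k_isc_provenance = character(),
      k_ic = numeric(), k_ic_provenance = character(),
      qyf = numeric(), phi_isc = numeric(), phi_ic = numeric(),
      lifetime = numeric(), qyf_percent = numeric()
    ))
  }
  nms <- vapply(ds, function(d) d$name %||% NA_character_, character(1))
  if (anyDuplicated(nms)) {
    warn(paste0("yield_table: duplicate emitter name(s) ",
                toString(unique(nms[duplicated(nms)])),
                "; all rows kept."))
  }
  rows <- purrr::map(ds, function(d) {
    rs <- tryCatch(
      compute_rates(d, p, prefer = prefer),
      error = function(e) {
        abort(paste0("yield_table: emitter '", d$name %||% "<unnamed>",
                     "' failed: ", conditionMessage(e)))
      }
    )
    q <- s1_opt_quantities(d)
    y <- quantum_yield(rs)
    by_ch <- split(rs, rs$channel)
    tibble(
      name = d$name,
      e_s1 = q$e_s1, f_s1 = q$f, e_t1 = q$e_t1,
      gap_s1_t1 = q$e_s1 - q$e_t1,
      socme = d$socme_s1_t1 %||% NA_real_,
      k_r = by_ch$k_r$rate, k_r_provenance = by_ch$k_r$provenance,
      k_isc = by_ch$k_isc$rate, k_isc_provenance = by_ch$k_isc$provenance,
      k_ic = by_ch$k_ic$rate, k_ic_provenance = by_ch$k_ic$provenance,
      qyf = y$qyf, phi_isc = y$phi_isc, phi_ic = y$phi_ic,
      lifetime = y$lifetime,
      qyf_percent = round_half_up(100 * y$qyf)
    )
  })
  purrr::list_rbind(rows)
}
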
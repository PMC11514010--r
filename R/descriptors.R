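# Emitter descriptor documents ------------------------------------------
#
# A descriptor collects the per-emitter excited-state quantities that the
# rate engine consumes: excitation energies and oscillator strengths of
# S1 and the low triplets at the S0- and S1-optimized geometries, the
# S1/T1 spin-orbit coupling matrix element, and (optionally) the S1->S0
# nonadiabatic coupling, an inventory of X-H accepting modes, and rate
# constants supplied from an external calculation. Units are fixed by the
# schema: energies in eV, couplings in cm^-1 (SOCME) and a.u. (NACME),
# frequencies in cm^-1, rates in s^-1.

DESCRIPTOR_SCHEMA <- "agphot/descriptor/v1"

.known_elements_states <- c("S0", "S1", "S2", "S3", "T1", "T2", "T3")
.context_tags <- c("S0-opt", "S1-opt")
.rate_channels <- c("k_r", "k_isc", "k_ic")

#' Build a set of electronic states for one optimized geometry
#'
#' @param label State labels (`"S1"`, `"T1"`, ...). Triplets must not carry
#'   an oscillator strength.
#' @param energy Excitation energies above S0 at this geometry, in eV.
#' @param oscillator_strength Dimensionless oscillator strengths; `NA` for
#'   states without one (all triplets).
#' @return A tibble with columns `label`, `energy`, `oscillator_strength`.
#' @export
electronic_states <- function(label, energy, oscillator_strength = NA_real_) {
  st <- tibble(
    label = as.character(label),
    energy = as.numeric(energy),
    oscillator_strength = as.numeric(oscillator_strength)
  )
  validate_states(st)
  st
}

validate_states <- function(st, where = "states") {
  if (!all(c("label", "energy") %in% names(st))) {
    abort(paste0(where, ": need `label` and `energy` columns."))
  }
  if (!"oscillator_strength" %in% names(st)) st$oscillator_strength <- NA_real_
  bad <- setdiff(st$label, .known_elements_states)
  if (length(bad)) abort(paste0(where, ": unknown state label(s) ", toString(bad), "."))
  if (anyDuplicated(st$label)) {
    abort(paste0(where, ": at most one entry per state label."))
  }
  excited <- st$label != "S0"
  if (any(!is.finite(st$energy[excited])) || any(st$energy[excited] <= 0)) {
    abort(paste0(where, ": excitation energies of excited states must be > 0 eV."))
  }
  f <- st$oscillator_strength
  if (any(!is.na(f) & f < 0)) {
    abort(paste0(where, ": oscillator strengths must be >= 0."))
  }
  triplet <- grepl("^T", st$label)
  if (any(triplet & !is.na(f))) {
    abort(paste0(where, ": triplet states must not carry an oscillator strength."))
  }
  st[c("label", "energy", "oscillator_strength")]
}

#' Build a rate set
#'
#' A rate set holds the three first-order decay channels of the fluorescent
#' S1 state — radiative (`k_r`), intersystem crossing to the dark triplet
#' (`k_isc`) and internal conversion to the ground state (`k_ic`) — each
#' tagged with its provenance (`"computed"` by this package or `"supplied"`
#' from an external calculation).
#'
#' @param k_r,k_isc,k_ic Rate constants in s^-1; omit a channel with `NULL`.
#' @param provenance Either a single string recycled to all channels or a
#'   vector matching the channels present, values `"computed"` or
#'   `"supplied"`.
#' @return A tibble with columns `channel`, `rate`, `provenance`.
#' @examples
#' rate_set(k_r = 1.61e8, k_isc = 1.96e9, k_ic = 4.96e6)
#' @export
rate_set <- function(k_r = NULL, k_isc = NULL, k_ic = NULL,
                     provenance = "supplied") {
  vals <- list(k_r = k_r, k_isc = k_isc, k_ic = k_ic)
  keep <- !vapply(vals, is.null, logical(1))
  channel <- names(vals)[keep]
  rate <- as.numeric(unlist(vals[keep], use.names = FALSE))
  if (length(provenance) == 1L) provenance <- rep(provenance, length(channel))
  rs <- tibble(channel = channel, rate = rate, provenance = provenance)
  validate_rate_set(rs)
  rs
}

validate_rate_set <- function(rs, where = "rate set") {
  if (!all(c("channel", "rate", "provenance") %in% names(rs))) {
    abort(paste0(where, ": need `channel`, `rate`, `provenance` columns."))
  }
  bad <- setdiff(rs$channel, .rate_channels)
  if (length(bad)) abort(paste0(where, ": unknown channel(s) ", toString(bad), "."))
  if (anyDuplicated(rs$channel)) abort(paste0(where, ": duplicate channel."))
  if (any(!is.finite(rs$rate)) || any(rs$rate < 0)) {
    abort(paste0(where, ": rates must be finite and >= 0."))
  }
  if (!all(rs$provenance %in% c("computed", "supplied"))) {
    abort(paste0(where, ": provenance must be 'computed' or 'supplied'."))
  }
  rs[c("channel", "rate", "provenance")]
}

#' Build an X-H accepting-mode inventory
#'
#' High-frequency, strongly anharmonic X-H stretches (X = C, N, O, ...)
#' are the accepting modes of the internal-conversion model: the
#' electronic gap is deposited into a few quanta of these oscillators.
#'
#' @param count Number of equivalent oscillators per class (integer >= 0).
#' @param frequency Fundamental frequencies in cm^-1; must lie in
#'   (1000, 5000), the X-H stretch window.
#' @param anharmonicity Dimensionless Morse anharmonicity chi per class,
#'   in (0, 0.1).
#' @return A tibble with columns `count`, `frequency`, `anharmonicity`.
#' @examples
#' xh_modes(c(20, 10, 6), c(2900, 3400, 3600), c(0.019, 0.021, 0.024))
#' @export
xh_modes <- function(count, frequency, anharmonicity) {
  m <- tibble(
    count = as.integer(count),
    frequency = as.numeric(frequency),
    anharmonicity = as.numeric(anharmonicity)
  )
  validate_xh_modes(m)
  m
}

validate_xh_modes <- function(m, where = "xh_modes") {
  if (!all(c("count", "frequency", "anharmonicity") %in% names(m))) {
    abort(paste0(where, ": need `count`, `frequency`, `anharmonicity`."))
  }
  if (any(m$count < 0)) abort(paste0(where, ": counts must be >= 0."))
  if (any(m$frequency <= 1000) || any(m$frequency >= 5000)) {
    abort(paste0(where, ": frequencies must lie in (1000, 5000) cm^-1."))
  }
  if (any(m$anharmonicity <= 0) || any(m$anharmonicity >= 0.1)) {
    abort(paste0(where, ": anharmonicity must lie in (0, 0.1)."))
  }
  m[c("count", "frequency", "anharmonicity")]
}

#' Construct and validate an emitter descriptor
#'
#' @param name Emitter identifier, e.g. `"Ag16(G)"`.
#' @param contexts Named list of state tables (see [electronic_states()]),
#'   keyed by geometry tag `"S0-opt"` and/or `"S1-opt"`.
#' @param socme_s1_t1 |<S1|H_SO|T1>| at the S1-optimized geometry, cm^-1.
#' @param nacme Optional S1->S0 nonadiabatic coupling magnitude, a.u.
#' @param xh_modes Optional accepting-mode inventory, see [xh_modes()].
#' @param supplied_rates Optional [rate_set()] of externally supplied rate
#'   constants (provenance `"supplied"`).
#' @param reference Optional named list of experimental reference values
#'   (never used in any computation).
#' @return An object of class `emitter_descriptor`.
#' @export
emitter_descriptor <- function(name, contexts, socme_s1_t1 = NULL,
                               nacme = NULL, xh_modes = NULL,
                               supplied_rates = NULL, reference = NULL) {
  d <- structure(
    list(
      name = name, contexts = contexts, socme_s1_t1 = socme_s1_t1,
      nacme = nacme, xh_modes = xh_modes, supplied_rates = supplied_rates,
      reference = reference
    ),
    class = "emitter_descriptor"
  )
  validate_descriptor(d)
}

validate_descriptor <- function(d) {
  if (is.null(d$name) || !nzchar(d$name)) abort("descriptor: `name` must be non-empty.")
  if (is.null(d$contexts) || !length(d$contexts)) {
    abort("descriptor: missing mandatory field `contexts`.")
  }
  bad <- setdiff(names(d$contexts), .context_tags)
  if (length(bad)) {
    abort(paste0("descriptor: unknown geometry context(s) ", toString(bad), "."))
  }
  d$contexts <- lapply(seq_along(d$contexts), function(i) {
    validate_states(as_tibble(d$contexts[[i]]),
                    where = paste0("context '", names(d$contexts)[i], "'"))
  }) |> setNames(names(d$contexts))
  if (!is.null(d$socme_s1_t1)) {
    if (!is.finite(d$socme_s1_t1) || d$socme_s1_t1 < 0) {
      abort("descriptor: `socme_s1_t1` must be finite and >= 0 cm^-1.")
    }
  }
  if (!is.null(d$nacme)) {
    if (!is.finite(d$nacme) || d$nacme < 0) {
      abort("descriptor: `nacme` must be finite and >= 0 a.u.")
    }
  }
  if (!is.null(d$xh_modes)) d$xh_modes <- validate_xh_modes(as_tibble(d$xh_modes))
  if (!is.null(d$supplied_rates)) {
    d$supplied_rates <- validate_rate_set(as_tibble(d$supplied_rates))
    if (!all(d$supplied_rates$provenance == "supplied")) {
      abort("descriptor: `supplied_rates` must have provenance 'supplied'.")
    }
  }
  d
}

#' @export
print.emitter_descriptor <- function(x, ...) {
  cat("<emitter_descriptor> ", x$name, "\n", sep = "")
  for (tag in names(x$contexts)) {
    st <- x$contexts[[tag]]
    cat("  ", tag, ": ", paste0(
      st$label, " ", format(st$energy, digits = 3), " eV",
      ifelse(is.na(st$oscillator_strength), "",
             paste0(" (f=", format(st$oscillator_strength, digits = 3), ")")),
      collapse = "; "
    ), "\n", sep = "")
  }
  if (!is.null(x$socme_s1_t1)) {
    cat("  SOCME(S1,T1): ", x$socme_s1_t1, " cm^-1\n", sep = "")
  }
  if (!is.null(x$supplied_rates)) {
    cat("  supplied rates: ", toString(x$supplied_rates$channel), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an emitter descriptor into a state table
#'
#' @param x An `emitter_descriptor`.
#' @param ... Unused.
#' @return A tibble with one row per electronic state and columns `name`,
#'   `geometry`, `label`, `energy`, `oscillator_strength`.
#' @method tidy emitter_descriptor
#' @export
tidy.emitter_descriptor <- function(x, ...) {
  purrr::imap(x$contexts, function(st, tag) {
    dplyr::mutate(st, name = x$name, geometry = tag, .before = 1)
  }) |> purrr::list_rbind()
}

# --- serialization ------------------------------------------------------

.descriptor_top_keys <- c(
  "schema", "name", "units", "contexts", "socme_s1_t1", "nacme",
  "xh_modes", "supplied_rates", "reference"
)

.descriptor_units <- list(
  energy = "eV", socme = "cm^-1", nacme = "a.u.",
  frequency = "cm^-1", rate = "s^-1"
)

descriptor_to_document <- function(d) {
  ctx <- lapply(d$contexts, function(st) {
    lapply(seq_len(nrow(st)), function(i) {
      rec <- list(label = st$label[i], energy = st$energy[i])
      if (!is.na(st$oscillator_strength[i])) {
        rec$oscillator_strength <- st$oscillator_strength[i]
      }
      rec
    })
  })
  doc <- list(schema = DESCRIPTOR_SCHEMA, name = d$name,
              units = .descriptor_units, contexts = ctx)
  if (!is.null(d$socme_s1_t1)) doc$socme_s1_t1 <- d$socme_s1_t1
  if (!is.null(d$nacme)) doc$nacme <- d$nacme
  if (!is.null(d$xh_modes)) {
    doc$xh_modes <- lapply(seq_len(nrow(d$xh_modes)), function(i) {
      as.list(d$xh_modes[i, ])
    })
  }
  if (!is.null(d$supplied_rates)) {
    doc$supplied_rates <- setNames(
      as.list(d$supplied_rates$rate), d$supplied_rates$channel
    )
  }
  if (!is.null(d$reference)) doc$reference <- d$reference
  doc
}

document_to_descriptor <- function(doc, path = "<document>") {
  if (!is.list(doc)) abort(paste0(path, ": not a descriptor document."))
  unknown <- setdiff(names(doc), .descriptor_top_keys)
  if (length(unknown)) {
    abort(paste0(path, ": unknown key(s) ", toString(unknown), "."))
  }
  for (key in c("schema", "name", "contexts")) {
    if (is.null(doc[[key]])) {
      abort(paste0(path, ": missing mandatory field `", key, "`."))
    }
  }
  if (!identical(doc$schema, DESCRIPTOR_SCHEMA)) {
    abort(paste0(path, ": unsupported schema '", doc$schema, "'."))
  }
  ctx <- lapply(doc$contexts, function(recs) {
    purrr::map(recs, function(r) {
      unknown <- setdiff(names(r), c("label", "energy", "oscillator_strength"))
      if (length(unknown)) {
        abort(paste0(path, ": unknown state key(s) ", toString(unknown), "."))
      }
      tibble(
        label = r$label, energy = as.numeric(r$energy),
        oscillator_strength = as.numeric(r$oscillator_strength %||% NA_real_)
      )
    }) |> purrr::list_rbind()
  })
  mods <- NULL
  if (!is.null(doc$xh_modes)) {
    mods <- purrr::map(doc$xh_modes, as_tibble) |> purrr::list_rbind()
  }
  rates <- NULL
  if (!is.null(doc$supplied_rates)) {
    rates <- rate_set(
      k_r = doc$supplied_rates$k_r, k_isc = doc$supplied_rates$k_isc,
      k_ic = doc$supplied_rates$k_ic, provenance = "supplied"
    )
  }
  emitter_descriptor(
    name = doc$name, contexts = ctx, socme_s1_t1 = doc$socme_s1_t1,
    nacme = doc$nacme, xh_modes = mods, supplied_rates = rates,
    reference = doc$reference
  )
}

#' Read an emitter descriptor document
#'
#' Parses and validates a YAML descriptor (schema `agphot/descriptor/v1`).
#' Unknown keys, missing mandatory fields, negative energies or couplings,
#' and oscillator strengths on triplet states are all rejected with an
#' error naming the offending field.
#'
#' @param path Path to a descriptor file.
#' @return A validated [emitter_descriptor()].
#' @export
read_descriptor <- function(path) {
  if (!file.exists(path)) abort(paste0("No such descriptor file: ", path))
  doc <- yaml::read_yaml(path)
  document_to_descriptor(doc, path = path)
}

#' Write an emitter descriptor document
#'
#' Serialization is canonical: a fixed key order and fixed numeric
#' precision, so writing the same descriptor twice yields byte-identical
#' files and `read_descriptor(write_descriptor(d))` round-trips.
#'
#' @param d A validated [emitter_descriptor()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor <- function(d, path) {
  d <- validate_descriptor(d)
  doc <- descriptor_to_document(d)
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}
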
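# Synthetic fixtures -----------------------------------------------------
#
# Deterministic generators so every module is testable without external
# data. A single seeded RNG stream (local, via a private environment
# swap) drives each generator call; the same seed always yields
# byte-identical artifacts.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for the descriptor generator
#'
#' Ranges default to the regime of the packaged reference emitters:
#' S1 emission energies 1.6-2.3 eV, S1-T1 gaps 0.2-0.4 eV, SOCMEs
#' 2-4.1 cm^-1, oscillator strengths 0.8-1.4.
#'
#' @param seed Integer seed; same seed, same output.
#' @param n_emitters Number of emitters to generate.
#' @param e_s1_range S1 energy range at the S1-optimized geometry, eV.
#' @param gap_range S1-T1 gap range, eV.
#' @param socme_range SOCME range, cm^-1.
#' @param f_range Oscillator-strength range.
#' @param nacme NACME given to every emitter, a.u.
#' @param fcwd_truth [fcwd_params()] used to manufacture each emitter's
#'   supplied k_ISC, so that [calibrate_fcwd()] can recover it in closed
#'   loop.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 17L, n_emitters = 8L,
                           e_s1_range = c(1.6, 2.3),
                           gap_range = c(0.2, 0.4),
                           socme_range = c(2, 4.1),
                           f_range = c(0.8, 1.4),
                           nacme = 5e-5,
                           fcwd_truth = fcwd_params()) {
  chk <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[2] < r[1]) {
      abort(paste0("generator_spec: `", nm, "` must be a positive interval."))
    }
  }
  chk(e_s1_range, "e_s1_range"); chk(gap_range, "gap_range")
  chk(socme_range, "socme_range"); chk(f_range, "f_range")
  validate_fcwd_params(fcwd_truth)
  structure(
    list(seed = as.integer(seed), n_emitters = as.integer(n_emitters),
         e_s1_range = e_s1_range, gap_range = gap_range,
         socme_range = socme_range, f_range = f_range, nacme = nacme,
         fcwd_truth = fcwd_truth),
    class = "generator_spec"
  )
}

#' Generate synthetic emitter descriptors
#'
#' Each emitter draws E(S1), the S1-T1 gap, SOCME and f uniformly from
#' the spec's ranges; its supplied k_ISC is *computed* from
#' `fcwd_truth` via [isc_rate()], so feeding the generated points back
#' through [calibrate_fcwd()] recovers the truth parameters (closed
#' loop). Every descriptor carries the generator seed in its `reference`
#' block and validates against the descriptor schema.
#'
#' @param spec A [generator_spec()].
#' @return A list of `n_emitters` validated [emitter_descriptor()]s.
#' @examples
#' ds <- gen_descriptors(generator_spec(seed = 1, n_emitters = 3))
#' names(ds[[1]]$contexts)
#' @export
gen_descriptors <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    purrr::map(seq_len(spec$n_emitters), function(i) {
      e_s1 <- runif(1, spec$e_s1_range[1], spec$e_s1_range[2])
      gap <- runif(1, spec$gap_range[1], spec$gap_range[2])
      socme <- runif(1, spec$socme_range[1], spec$socme_range[2])
      f <- runif(1, spec$f_range[1], spec$f_range[2])
      k_isc <- isc_rate(socme, gap, spec$fcwd_truth)
      emitter_descriptor(
        name = sprintf("syn%02d", i),
        contexts = list(
          "S1-opt" = electronic_states(
            label = c("T1", "S1"),
            energy = c(e_s1 - gap, e_s1),
            oscillator_strength = c(NA, f)
          )
        ),
        socme_s1_t1 = socme,
        nacme = spec$nacme,
        xh_modes = default_xh_modes(),
        supplied_rates = rate_set(k_isc = k_isc),
        reference = list(generator = list(seed = spec$seed, index = i))
      )
    })
  })
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation.
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a toy cluster/ligand structure pair
#'
#' Builds a reference structure with a compact metal core (`Ag`) and a
#' ligand shell (`C`/`N`/`O`), then a mobile copy obtained by a known
#' random rigid transform plus independent isotropic Gaussian jitter per
#' subset. Both structures carry named selections `"core"` and
#' `"ligand"`. With zero jitter, superposing the mobile copy on the
#' reference recovers the transform and an RMSD at machine precision.
#'
#' @param n_core Number of core atoms, >= 3.
#' @param n_ligand Number of ligand-shell atoms.
#' @param seed Integer seed.
#' @param sigma_core,sigma_ligand Jitter standard deviations (Angstrom)
#'   applied to the mobile copy's core/ligand atoms.
#' @return A list: `reference` and `mobile` (`structure3d`), plus the
#'   generating `rotation` and `translation`.
#' @export
gen_toy_cluster <- function(n_core, n_ligand = 2L * n_core, seed = 17L,
                            sigma_core = 0, sigma_ligand = 0) {
  if (n_core < 3L) abort("gen_toy_cluster: `n_core` must be >= 3.")
  with_seed(seed, {
    core <- matrix(rnorm(3 * n_core, sd = 1.6), ncol = 3)
    shell_dir <- matrix(rnorm(3 * n_ligand), ncol = 3)
    shell_dir <- shell_dir / sqrt(rowSums(shell_dir^2))
    shell <- shell_dir * runif(n_ligand, 4.5, 8)
    atoms <- tibble(
      element = c(rep("Ag", n_core),
                  sample(c("C", "N", "O"), n_ligand, replace = TRUE)),
      x = c(core[, 1], shell[, 1]),
      y = c(core[, 2], shell[, 2]),
      z = c(core[, 3], shell[, 3])
    )
    sel <- list(core = seq_len(n_core),
                ligand = n_core + seq_len(n_ligand))
    reference <- structure3d(atoms, name = "toy-reference", selections = sel)

    rot <- random_rotation()
    trans <- runif(3, -5, 5)
    xyz <- as.matrix(atoms[c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, trans, `+`)
    jitter_sd <- rep(c(sigma_core, sigma_ligand), c(n_core, n_ligand))
    xyz <- xyz + matrix(rnorm(length(xyz), sd = rep(jitter_sd, 3)),
                        ncol = 3)
    mobile_atoms <- atoms
    mobile_atoms$x <- xyz[, 1]; mobile_atoms$y <- xyz[, 2]
    mobile_atoms$z <- xyz[, 3]
    mobile <- structure3d(mobile_atoms, name = "toy-mobile", selections = sel)
    list(reference = reference, mobile = mobile,
         rotation = rot, translation = trans)
  })
}
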
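# Shared test helpers ----------------------------------------------------

table1_rates <- tibble::tibble(
  name = c("Ag16(G)", "Ag16(I)", "Ag10(G)", "Ag10(I)"),
  e_s1 = c(1.67, 1.66, 2.2, 2.17),
  f = c(1.33, 1.27, 1.19, 1.21),
  e_t1 = c(1.44, 1.43, 1.84, 1.78),
  socme = c(3.01, 2.05, 4.09, 3.68),
  k_r = c(1.61e8, 1.54e8, 2.49e8, 2.47e8),
  k_isc = c(1.96e9, 8.25e8, 8.79e8, 4.85e8),
  k_ic = c(4.96e6, 4.96e6, 1e6, 1e6)
)

minimal_descriptor <- function(name = "toy", e_s1 = 1.9, f = 1.0,
                               e_t1 = 1.6, socme = 3, ...) {
  emitter_descriptor(
    name = name,
    contexts = list(
      "S1-opt" = electronic_states(c("T1", "S1"), c(e_t1, e_s1), c(NA, f))
    ),
    socme_s1_t1 = socme,
    ...
  )
}

# Simple 5-atom structure: 3 Ag (right triangle) + N + O.
toy_structure <- function(name = "toy5") {
  structure3d(
    tibble::tibble(
      element = c("Ag", "Ag", "Ag", "N", "O"),
      x = c(0, 2.9, 0, 5, 0),
      y = c(0, 0, 2.9, 0, 5),
      z = c(0, 0, 0, 0, 0)
    ),
    name = name,
    selections = list(core = 1:3, hetero = 4:5)
  )
}
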
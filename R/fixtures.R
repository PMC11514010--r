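# Packaged reference emitters ------------------------------------------
#
# Four DNA-stabilized silver cluster emitters ship with the package:
# Ag16(G) and Ag10(G) (guanine-containing strands) and their
# inosine-substituted variants Ag16(I), Ag10(I). Each descriptor carries
# the calculated excitation energies of S1 and the low triplets at the
# S0- and S1-optimized geometries, oscillator strengths, the S1/T1
# spin-orbit coupling matrix element, and the externally calculated rate
# constants (k_r, k_ISC, k_IC) as supplied values. Experimental
# absorption/emission energies and quantum yields are stored in the
# `reference` block and are never used in computation.

.table1_fixture_files <- c(
  "ag16_G.yaml", "ag16_I.yaml", "ag10_G.yaml", "ag10_I.yaml"
)

#' Load the packaged reference emitter descriptors
#'
#' @return A named list of four validated [emitter_descriptor()] objects:
#'   `Ag16(G)`, `Ag16(I)`, `Ag10(G)`, `Ag10(I)`.
#' @examples
#' fx <- load_table1_fixtures()
#' tidy(fx[["Ag16(G)"]])
#' @export
load_table1_fixtures <- function() {
  paths <- system.file("extdata", .table1_fixture_files, package = "agphot",
                       mustWork = TRUE)
  ds <- lapply(paths, read_descriptor)
  setNames(ds, vapply(ds, `[[`, character(1), "name"))
}
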
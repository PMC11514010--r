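# Kabsch superposition ---------------------------------------------------

#' Least-squares rigid superposition of two structures
#'
#' Kabsch algorithm: the optimal proper rotation and translation mapping
#' the mobile selection onto the target selection (correspondence by
#' list order), via SVD of the covariance matrix with the determinant
#' sign correction, so the returned rotation is always proper
#' (det = +1) even when the best unconstrained transform would be a
#' reflection. The RMSD is computed over the selection after applying
#' the transform; the transform itself can be applied to all atoms with
#' [apply_superposition()].
#'
#' @param mobile,target `structure3d` objects.
#' @param selection A selection label defined on both structures, an
#'   index vector applied to both, or `NULL` for all atoms. Sizes must
#'   match and be >= 3.
#' @return An object of class `superposition`: `rotation` (3x3, maps
#'   mobile column vectors), `translation` (length-3), `rmsd` (Angstrom),
#'   `n_atoms`, and `degenerate` (TRUE when the selection is nearly
#'   collinear/planar-degenerate; the sign-fixed solution is still
#'   returned). Has [tidy()] and [glance()] methods.
#' @examples
#' pair <- gen_toy_cluster(8, 12, seed = 1)
#' superpose(pair$mobile, pair$reference, "core")
#' @export
superpose <- function(mobile, target, selection = NULL) {
  im <- if (is.null(selection)) seq_len(nrow(mobile$atoms))
        else resolve_selection(mobile, selection)
  it <- if (is.null(selection)) seq_len(nrow(target$atoms))
        else resolve_selection(target, selection)
  if (length(im) != length(it)) {
    abort(paste0("superpose: selection sizes differ (", length(im), " vs ",
                 length(it), ")."))
  }
  if (length(im) < 3L) abort("superpose: need at least 3 atoms.")
  P <- coords_matrix(mobile, im)
  Q <- coords_matrix(target, it)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(P0, Q0)             # sum over atoms of p q^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  aligned <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q0)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(qc - R %*% pc),
      rmsd = rmsd, n_atoms = length(im), degenerate = degenerate
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f Angstrom over %d atoms%s\n",
              x$rmsd, x$n_atoms,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

#' Tidy a superposition result
#'
#' @param x A `superposition`.
#' @param ... Unused.
#' @return A tibble of the affine map, one row per output coordinate:
#'   rotation matrix entries `r1`..`r3` and the translation component.
#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  tibble(
    axis = c("x", "y", "z"),
    r1 = x$rotation[, 1], r2 = x$rotation[, 2], r3 = x$rotation[, 3],
    translation = x$translation
  )
}

#' Summarize a superposition result
#'
#' @param x A `superposition`.
#' @param ... Unused.
#' @return A one-row tibble: `rmsd`, `n_atoms`, rotation determinant,
#'   and the `degenerate` flag.
#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(
    rmsd = x$rmsd, n_atoms = x$n_atoms,
    det_rotation = det(x$rotation), degenerate = x$degenerate
  )
}

#' Apply a fitted superposition to a whole structure
#'
#' @param fit A `superposition` from [superpose()].
#' @param s The `structure3d` to transform (typically the mobile one).
#' @return The transformed structure.
#' @export
apply_superposition <- function(fit, s) {
  xyz <- coords_matrix(s) %*% t(fit$rotation)
  xyz <- sweep(xyz, 2, fit$translation, `+`)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Per-selection RMSD report
#'
#' Each selection is superposed independently (its own Kabsch fit), so
#' subset RMSDs are comparable to per-subset fits reported for cluster
#' cores vs whole complexes.
#'
#' @param mobile,target `structure3d` objects.
#' @param selections Character vector of selection labels defined on
#'   both structures.
#' @return A tibble with columns `label`, `n_atoms`, `rmsd`.
#' @export
rmsd_report <- function(mobile, target, selections) {
  purrr::map(selections, function(lab) {
    fit <- superpose(mobile, target, lab)
    tibble(label = lab, n_atoms = fit$n_atoms, rmsd = fit$rmsd)
  }) |> purrr::list_rbind()
}

#' Interatomic bond table
#'
#' All unordered pairs of the two given elements at distance <= `cutoff`
#' (closed boundary), each pair once, sorted by distance.
#'
#' @param s A `structure3d`.
#' @param pair Length-2 character vector of element symbols, e.g.
#'   `c("Ag", "Ag")` or `c("Ag", "Cl")`.
#' @param cutoff Distance cutoff in Angstrom, > 0.
#' @return A tibble with columns `i`, `j` (atom indices, `i < j`),
#'   `element_i`, `element_j`, `distance`.
#' @export
bond_table <- function(s, pair, cutoff) {
  if (length(pair) != 2L) abort("`pair` must be two element symbols.")
  pair <- normalize_element(pair)
  bad <- setdiff(pair, PERIODIC_TABLE)
  if (length(bad)) abort(paste0("unknown element symbol(s) ", toString(bad), "."))
  if (!is.finite(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0.")
  ia <- which(s$atoms$element == pair[1])
  ib <- which(s$atoms$element == pair[2])
  cand <- tidyr::expand_grid(a = ia, b = ib) |>
    dplyr::transmute(i = pmin(.data$a, .data$b), j = pmax(.data$a, .data$b)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::distinct()
  if (!nrow(cand)) {
    return(tibble(i = integer(), j = integer(), element_i = character(),
                  element_j = character(), distance = numeric()))
  }
  xyz <- coords_matrix(s)
  d <- sqrt(rowSums((xyz[cand$i, , drop = FALSE] -
                       xyz[cand$j, , drop = FALSE])^2))
  out <- dplyr::mutate(cand,
    element_i = s$atoms$element[.data$i],
    element_j = s$atoms$element[.data$j],
    distance = d
  )
  dplyr::arrange(dplyr::filter(out, .data$distance <= cutoff), .data$distance)
}

vec_angle_deg <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Donor-acceptor contact report
#'
#' Lists donor/acceptor atom pairs at distance <= `d_max` (closed
#' boundary). When `angle_min` is given, hydrogen atoms in the donor
#' selection are used to enforce a D-H...A angle criterion: a contact is
#' kept if some H within 1.25 Angstrom of the donor heavy atom makes an
#' angle at H of at least `angle_min` degrees. Distances are reported to
#' 0.01 Angstrom.
#'
#' @param s A `structure3d`.
#' @param donors,acceptors Selection labels or index vectors; non-empty.
#'   Hydrogens in the donor selection are treated as candidate bridging
#'   H atoms, not as donors themselves.
#' @param d_max Maximum donor-acceptor distance, Angstrom.
#' @param angle_min Optional minimum D-H...A angle in degrees; requires
#'   hydrogens in the donor selection.
#' @return A tibble: `donor`, `acceptor` (atom indices), elements,
#'   `distance`, and `angle` (degrees, `NA` when not requested).
#' @export
contact_report <- function(s, donors, acceptors, d_max, angle_min = NULL) {
  id <- resolve_selection(s, donors)
  ia <- resolve_selection(s, acceptors)
  if (!length(id) || !length(ia)) abort("selections must be non-empty.")
  if (!is.finite(d_max) || d_max <= 0) abort("`d_max` must be > 0.")
  xyz <- coords_matrix(s)
  hyd <- id[s$atoms$element[id] == "H"]
  heavy_d <- setdiff(id, hyd)
  if (!is.null(angle_min) && !length(hyd)) {
    abort("contact_report: angle criterion requested but the donor selection contains no hydrogens.")
  }
  grid <- tidyr::expand_grid(donor = heavy_d, acceptor = ia) |>
    dplyr::filter(.data$donor != .data$acceptor)
  if (!nrow(grid)) {
    return(tibble(donor = integer(), acceptor = integer(),
                  donor_element = character(), acceptor_element = character(),
                  distance = numeric(), angle = numeric()))
  }
  d <- sqrt(rowSums((xyz[grid$donor, , drop = FALSE] -
                       xyz[grid$acceptor, , drop = FALSE])^2))
  grid$distance <- d
  grid <- dplyr::filter(grid, .data$distance <= d_max)
  ang <- rep(NA_real_, nrow(grid))
  if (!is.null(angle_min) && nrow(grid)) {
    keep <- logical(nrow(grid))
    for (k in seq_len(nrow(grid))) {
      dk <- grid$donor[k]; ak <- grid$acceptor[k]
      dh <- sqrt(rowSums((xyz[hyd, , drop = FALSE] -
                            matrix(xyz[dk, ], length(hyd), 3, byrow = TRUE))^2))
      near <- hyd[dh <= 1.25]
      if (!length(near)) next
      angles <- vapply(near, function(h) {
        vec_angle_deg(xyz[dk, ] - xyz[h, ], xyz[ak, ] - xyz[h, ])
      }, numeric(1))
      if (max(angles) >= angle_min) {
        keep[k] <- TRUE
        ang[k] <- max(angles)
      }
    }
    grid <- grid[keep, , drop = FALSE]
    ang <- ang[keep]
  }
  dplyr::mutate(grid,
    donor_element = s$atoms$element[.data$donor],
    acceptor_element = s$atoms$element[.data$acceptor],
    distance = round(.data$distance, 2),
    angle = ang
  ) |>
    dplyr::select("donor", "acceptor", "donor_element", "acceptor_element",
                  "distance", "angle") |>
    dplyr::arrange(.data$distance)
}
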
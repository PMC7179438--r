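#' Total binding free energy from MM/GBSA components
#'
#' Aggregates per-ligand end-point energy components into the binding
#' free energy:
#' `dG_bind = dE_vdw + dE_ele + dE_internal + dG_GB + dG_NP - T dS`,
#' i.e. the gas-phase molecular-mechanics terms plus polar (generalized
#' Born) and non-polar (surface-area) solvation, minus the entropy term.
#' The internal and entropy terms are optional and default to zero — in
#' single-trajectory MM/GBSA the internal term cancels exactly, and the
#' normal-mode entropy is frequently omitted. Standard errors, when
#' supplied as `<term>_sem` columns, are combined in quadrature under an
#' independence assumption.
#'
#' @param components A tibble with numeric columns `vdw`, `ele`, `gb`,
#'   `np` (kcal/mol), optional `internal` and `tds`, and optional
#'   `<term>_sem` columns.
#' @return The input with `dg_bind` (and `dg_bind_sem` when every
#'   component has a SEM) appended.
#' @examples
#' binding_energy(a2a_energy())
#' @export
binding_energy <- function(components) {
  needed <- c("vdw", "ele", "gb", "np")
  missing_cols <- setdiff(needed, names(components))
  if (length(missing_cols)) {
    abort(paste0("missing energy component column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  internal <- components[["internal"]] %||% 0
  tds <- components[["tds"]] %||% 0
  out <- components %>%
    mutate(dg_bind = .data$vdw + .data$ele + internal + .data$gb + .data$np - tds)
  sems <- paste0(needed, "_sem")
  if (all(sems %in% names(components))) {
    sem2 <- Reduce(`+`, purrr::map(sems, ~ components[[.x]]^2))
    if ("internal_sem" %in% names(components)) sem2 <- sem2 + components[["internal_sem"]]^2
    if ("tds_sem" %in% names(components)) sem2 <- sem2 + components[["tds_sem"]]^2
    out$dg_bind_sem <- sqrt(sem2)
  }
  out
}

#' Per-residue interaction energy totals
#'
#' In per-residue free-energy decomposition each residue's contribution
#' is the sum of its van der Waals, electrostatic, polar-solvation and
#' non-polar-solvation terms. Adds that total to the table.
#'
#' @param residues A tibble with numeric columns `vdw`, `elec`, `pol`,
#'   `np` (kcal/mol per residue).
#' @return The input with a `total` column appended.
#' @export
per_residue_total <- function(residues) {
  needed <- c("vdw", "elec", "pol", "np")
  missing_cols <- setdiff(needed, names(residues))
  if (length(missing_cols)) {
    abort(paste0("missing per-residue column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  mutate(residues, total = .data$vdw + .data$elec + .data$pol + .data$np)
}

#' Geometric hydrogen-bond criterion
#'
#' A frame counts as hydrogen-bonded when the donor-acceptor distance is
#' at most `max_distance` (default 3.5 angstrom) and the
#' acceptor-hydrogen-donor angle is at least `min_angle` (default 120
#' degrees).
#'
#' @param distance Donor-acceptor distances in angstrom (vectorised).
#' @param angle Acceptor-hydrogen-donor angles in degrees, in [0, 180].
#' @param max_distance Distance criterion in angstrom (default 3.5).
#' @param min_angle Angle criterion in degrees (default 120).
#' @return Logical vector.
#' @examples
#' is_hbond(c(3.4, 3.6, 3.4), c(150, 150, 119))
#' @export
is_hbond <- function(distance, angle, max_distance = 3.5, min_angle = 120) {
  if (any(is.na(distance)) || any(distance <= 0)) {
    abort("distance must be positive (angstrom)")
  }
  if (any(is.na(angle)) || any(angle < 0) || any(angle > 180)) {
    abort("angle must lie in [0, 180] degrees")
  }
  if (max_distance <= 0) abort("max_distance must be positive")
  if (min_angle <= 0 || min_angle > 180) abort("min_angle must lie in (0, 180]")
  distance <= max_distance & angle >= min_angle
}

#' Hydrogen-bond occupancy over simulation frames
#'
#' Occupancy is the percentage of frames in which the bond exists.
#'
#' @param present Logical vector, one element per frame (`TRUE` when the
#'   hydrogen-bond criteria hold in that frame).
#' @return Occupancy in percent, in [0, 100].
#' @examples
#' hbond_occupancy(rep(c(TRUE, FALSE), c(72, 28))) # 72
#' @export
hbond_occupancy <- function(present) {
  if (length(present) == 0) abort("occupancy needs at least one frame")
  if (anyNA(present)) abort("frame series must not contain missing values")
  100 * sum(present) / length(present)
}

#' Per-bond occupancy report from frame-level geometry
#'
#' Applies [is_hbond()] to per-frame distance/angle records and
#' summarises occupancy and mean bonded distance per donor/acceptor pair.
#'
#' @param frames A tibble with columns `distance` and `angle`, plus any
#'   identifying columns (e.g. `donor`, `acceptor`) to group by.
#' @param by Character vector of grouping columns (default: every column
#'   except `frame`, `distance`, `angle`).
#' @inheritParams is_hbond
#' @return A tibble with the grouping columns, `n_frames`,
#'   `occupancy_percent` and `mean_distance` (mean over bonded frames).
#' @export
hbond_report <- function(frames, by = NULL, max_distance = 3.5, min_angle = 120) {
  needed <- c("distance", "angle")
  if (!all(needed %in% names(frames))) {
    abort("frames must have 'distance' and 'angle' columns")
  }
  by <- by %||% setdiff(names(frames), c("frame", "distance", "angle"))
  frames %>%
    mutate(bonded = is_hbond(.data$distance, .data$angle,
                             max_distance = max_distance, min_angle = min_angle)) %>%
    group_by(across(all_of(by))) %>%
    summarise(
      n_frames = n(),
      occupancy_percent = hbond_occupancy(.data$bonded),
      mean_distance = if (any(.data$bonded)) mean(.data$distance[.data$bonded]) else NA_real_,
      .groups = "drop"
    )
}
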
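#' Packaged study tables
#'
#' Convenience loaders for the curated adenosine A2A agonist study inputs
#' shipped with the package (see [a2a_file()] for the raw files).
#'
#' * `a2a_training()`: the 21 agonists used for model building, with
#'   descriptors, EC50 (nM, from cAMP assays) and pEC50.
#' * `a2a_test()`: the 7 external-validation compounds.
#' * `a2a_screening()`: the 6 virtual-screening hits (no measured
#'   activity).
#' * `a2a_energy()`: per-ligand MM/GBSA component means and standard
#'   errors with total binding energies (kcal/mol).
#' * `a2a_binding()`: experimental Ki values (nM) with the corresponding
#'   binding free energies (kcal/mol).
#' * `a2a_hbonds()`: receptor-ligand hydrogen-bond occupancy summaries
#'   (percent of simulation time, mean donor-acceptor distance in
#'   angstrom).
#'
#' @return A tibble.
#' @name a2a_data
NULL

#' @rdname a2a_data
#' @export
a2a_training <- function() read_compound_table(a2a_file("a2a_training.tsv"))

#' @rdname a2a_data
#' @export
a2a_test <- function() read_compound_table(a2a_file("a2a_test.tsv"))

#' @rdname a2a_data
#' @export
a2a_screening <- function() read_compound_table(a2a_file("a2a_screening.tsv"))

#' @rdname a2a_data
#' @export
a2a_energy <- function() {
  readr::read_tsv(a2a_file("a2a_energy.tsv"), show_col_types = FALSE)
}

#' @rdname a2a_data
#' @export
a2a_binding <- function() {
  readr::read_tsv(a2a_file("a2a_binding.tsv"), show_col_types = FALSE)
}

#' @rdname a2a_data
#' @export
a2a_hbonds <- function() {
  readr::read_tsv(a2a_file("a2a_hbonds.tsv"), show_col_types = FALSE)
}

#' Reference regression models for A2A agonist potency
#'
#' The three published multiple-linear-regression coefficient sets for
#' pEC50 — tetraparametric (MV, MP, NA, HG), pentaparametric (+ PF) and
#' hexaparametric (+ AR) — as ready-to-use [qsar_model()] objects. These
#' are first-class inputs: predictions from them do not depend on
#' refitting.
#'
#' @param file Optional path to a JSON file in the same layout as the
#'   packaged `a2a_models.json`.
#' @return A named list of `qsar_model` objects (`tetra`, `penta`,
#'   `hexa`).
#' @examples
#' m <- a2a_models()
#' predict(m$penta, a2a_screening())
#' @export
a2a_models <- function(file = a2a_file("a2a_models.json")) {
  raw <- jsonlite::read_json(file)
  purrr::map(raw, function(m) {
    qsar_model(intercept = m$intercept,
               coefficients = unlist(m$coefficients),
               stats = if (!is.null(m$stats)) as_tibble(m$stats))
  })
}

#' Packaged pharmacophore model
#'
#' The six-feature 3D pharmacophore shared by the aligned A2A agonists:
#' two aromatic-ring features (radius 1.1 angstrom) and four hydrogen-bond
#' acceptor features (radius 0.5 angstrom).
#'
#' @param file Optional path to a pharmacophore JSON file
#'   (`[{"kind": ..., "xyz": [x,y,z], "radius": ...}, ...]`).
#' @return A pharmacophore feature tibble (see [pharmacophore()]).
#' @export
a2a_pharmacophore <- function(file = a2a_file("a2a_pharmacophore.json")) {
  raw <- jsonlite::read_json(file)
  pharmacophore(
    kind = purrr::map_chr(raw, "kind"),
    x = purrr::map_dbl(raw, ~ .x$xyz[[1]]),
    y = purrr::map_dbl(raw, ~ .x$xyz[[2]]),
    z = purrr::map_dbl(raw, ~ .x$xyz[[3]]),
    radius = purrr::map_dbl(raw, "radius")
  )
}
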
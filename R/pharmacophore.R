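FEATURE_KINDS <- c("aromatic", "h_acceptor", "h_donor", "hydrophobic",
                   "cation", "anion")

#' Construct a pharmacophore feature table
#'
#' A pharmacophore is a set of typed spatial features — aromatic rings,
#' hydrogen-bond acceptors/donors, hydrophobes, ions — each with a 3D
#' position (angstrom) and a tolerance radius. The packaged A2A agonist
#' model ([a2a_pharmacophore()]) has two aromatic and four acceptor
#' features.
#'
#' @param kind Feature types; one of `"aromatic"`, `"h_acceptor"`,
#'   `"h_donor"`, `"hydrophobic"`, `"cation"`, `"anion"`.
#' @param x,y,z Cartesian coordinates in angstrom.
#' @param radius Positive tolerance radius in angstrom.
#' @return A tibble of class `pharmacophore` with columns `kind`, `x`,
#'   `y`, `z`, `radius`.
#' @export
pharmacophore <- function(kind, x, y, z, radius) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), FEATURE_KINDS)
  if (length(bad)) {
    abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(c(x, y, z)))) abort("feature coordinates must be finite")
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    abort("feature radius must be positive")
  }
  out <- tibble(kind = kind, x = as.numeric(x), y = as.numeric(y),
                z = as.numeric(z), radius = as.numeric(radius))
  if (nrow(out) < 1) abort("a pharmacophore needs at least one feature")
  class(out) <- c("pharmacophore", class(out))
  out
}

feature_matrix <- function(features) {
  unname(as.matrix(features[c("x", "y", "z")]))
}

#' Least-squares rigid superposition of two point sets
#'
#' Kabsch alignment: finds the proper rotation (determinant +1) and
#' translation that minimise the root-mean-square deviation between
#' paired points, `R a_i + t ~ b_i`, via singular value decomposition of
#' the cross-covariance matrix.
#'
#' @param points_a,points_b Matrices (n x 3) or feature tibbles with the
#'   same number of rows (n >= 3), paired row-by-row.
#' @return A list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), and `rmsd` (angstrom).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' superpose(a, a + rep(c(5, -3, 2), each = 4))$rmsd # 0 up to rounding
#' @export
superpose <- function(points_a, points_b) {
  if (is.data.frame(points_a)) points_a <- feature_matrix(points_a)
  if (is.data.frame(points_b)) points_b <- feature_matrix(points_b)
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (nrow(a) != nrow(b)) abort("point sets must have equal length")
  if (nrow(a) < 3) abort("superposition needs at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))            # H = a0' b0 ; R = V diag(1,1,d) U'
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cb - drop(rot %*% ca)
  aligned <- sweep(a %*% t(rot), 2, trans, `+`)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((aligned - b)^2))))
}

apply_rigid <- function(points, rotation, translation) {
  sweep(as.matrix(points) %*% t(rotation), 2, translation, `+`)
}

#' Match candidate features against a pharmacophore model
#'
#' Searches type-consistent injective assignments of model features to
#' candidate features (aromatic to aromatic, acceptor to acceptor, ...),
#' pruned by pairwise-distance compatibility
#' (`|d_model(i,j) - d_cand(si,sj)| <= radius_i + radius_j`), refines
#' each surviving assignment by rigid superposition, and accepts it if
#' every matched pair lies within that model feature's radius after
#' alignment. The best (lowest-RMSD) accepted assignment is returned.
#' An unmatched candidate is a valid result, not an error.
#'
#' @param model A `pharmacophore` feature tibble (the hypothesis).
#' @param candidate A `pharmacophore` feature tibble (one compound's
#'   features; decoy features are allowed and simply stay unassigned).
#' @param require_all If `TRUE` (default) all model features must match;
#'   if `FALSE`, partial matches of at least 3 features are searched and
#'   the result maximises the number matched, then minimises RMSD.
#' @return A list with `matched` (logical), `assignment` (integer vector,
#'   model feature index -> candidate feature index, `NA` where
#'   unmatched), `rmsd` and `n_matched`.
#' @examples
#' ph <- a2a_pharmacophore()
#' match_pharmacophore(ph, ph)$rmsd # self-match, 0
#' @export
match_pharmacophore <- function(model, candidate, require_all = TRUE) {
  m <- nrow(model)
  nc <- nrow(candidate)
  mm <- feature_matrix(model)
  cm <- feature_matrix(candidate)
  dist_m <- as.matrix(stats::dist(mm))
  dist_c <- as.matrix(stats::dist(cm))
  compatible <- purrr::map(seq_len(m), function(i) {
    which(candidate$kind == model$kind[i])
  })
  no_match <- list(matched = FALSE, assignment = rep(NA_integer_, m),
                   rmsd = NA_real_, n_matched = 0L)
  min_matched <- if (require_all) m else min(m, 3L)

  best <- no_match
  consider <- function(assignment) {
    idx <- which(!is.na(assignment))
    if (length(idx) < 3) return()
    sp <- superpose(mm[idx, , drop = FALSE], cm[assignment[idx], , drop = FALSE])
    aligned <- apply_rigid(mm[idx, , drop = FALSE], sp$rotation, sp$translation)
    dists <- sqrt(rowSums((aligned - cm[assignment[idx], , drop = FALSE])^2))
    if (any(dists > model$radius[idx] + 1e-9)) return()
    better <- length(idx) > best$n_matched ||
      (length(idx) == best$n_matched && (is.na(best$rmsd) || sp$rmsd < best$rmsd))
    if (better) {
      best <<- list(matched = TRUE, assignment = assignment,
                    rmsd = sp$rmsd, n_matched = length(idx))
    }
  }

  recurse <- function(i, assignment, used) {
    if (i > m) {
      if (sum(!is.na(assignment)) >= min_matched) consider(assignment)
      return()
    }
    for (j in setdiff(compatible[[i]], used)) {
      ok <- TRUE
      for (k in seq_len(i - 1)) {
        if (!is.na(assignment[k]) &&
            abs(dist_m[i, k] - dist_c[j, assignment[k]]) >
              model$radius[i] + model$radius[k]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        assignment[i] <- j
        recurse(i + 1, assignment, c(used, j))
        assignment[i] <- NA_integer_
      }
    }
    # leaving feature i unmatched is only allowed in partial mode
    if (!require_all && (m - i) + sum(!is.na(assignment)) >= min_matched) {
      recurse(i + 1, assignment, used)
    }
  }
  if (nc >= min_matched) recurse(1L, rep(NA_integer_, m), integer(0))
  if (best$n_matched == m) best$matched <- TRUE
  if (require_all && best$n_matched < m) return(no_match)
  best
}

#' Build a labelled ranked screen
#'
#' @param compound_id Compound identifiers in rank order (best first).
#' @param label One of `"agonist"`, `"antagonist"`, `"decoy"` per
#'   compound.
#' @return A tibble with `rank`, `compound_id`, `label`.
#' @export
ranked_screen <- function(compound_id, label) {
  if (anyDuplicated(compound_id)) abort("compound ids must be unique")
  label <- as.character(label)
  bad <- setdiff(unique(label), c("agonist", "antagonist", "decoy"))
  if (length(bad)) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  tibble(rank = seq_along(compound_id),
         compound_id = as.character(compound_id), label = label)
}

#' Recovery of reference compounds in the top of a ranked screen
#'
#' Counts agonists, antagonists and decoys among the `k` best-ranked
#' compounds and reports the percentage of all reference agonists
#' recovered — the enrichment metric used to validate a pharmacophore
#' hypothesis against a contaminated screening library.
#'
#' @param screen A ranked screen from [ranked_screen()] (or any tibble
#'   with `compound_id` in rank order and a `label` column).
#' @param k Prefix size, `0 <= k <= nrow(screen)`.
#' @return A one-row tibble: `k`, `n_agonist`, `n_antagonist`, `n_decoy`,
#'   `percent_agonists_recovered`.
#' @examples
#' s <- simulate_ranked_screen(seed = 1)
#' recovery(s, k = 13)
#' @export
recovery <- function(screen, k) {
  if (length(k) != 1 || is.na(k) || k < 0 || k > nrow(screen)) {
    abort(paste0("k must lie in 0..", nrow(screen)))
  }
  total_agonists <- sum(screen$label == "agonist")
  top <- head(screen$label, k)
  tibble(
    k = as.integer(k),
    n_agonist = sum(top == "agonist"),
    n_antagonist = sum(top == "antagonist"),
    n_decoy = sum(top == "decoy"),
    percent_agonists_recovered =
      if (total_agonists == 0) 0 else 100 * sum(top == "agonist") / total_agonists
  )
}

#' Full recovery curve of a ranked screen
#'
#' @inheritParams recovery
#' @return A tibble with one row per `k = 0..nrow(screen)` (columns as
#'   [recovery()]).
#' @export
recovery_curve <- function(screen) {
  purrr::map(0:nrow(screen), recovery, screen = screen) %>% bind_rows()
}
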
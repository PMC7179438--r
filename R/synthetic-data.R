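# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Descriptor ranges matching the agonist training table.
default_descriptor_ranges <- function() {
  list(MV = c(846, 2394), MP = c(29, 94), "NA" = c(38, 120),
       PF = c(16, 41), HG = c(1, 18), AR = c(3, 6))
}

#' Simulate a compound/descriptor/activity table
#'
#' Generates a table with the statistical shape of the agonist training
#' data: descriptors drawn uniformly over realistic ranges (integer
#' descriptors rounded), activity as a known linear function of the
#' descriptors plus Gaussian noise, and an optional fraction of outliers
#' whose activity is shifted by a fixed amount. The generating
#' parameters are returned so parameter recovery can be tested.
#'
#' Defaults mirror the study conditions: the six canonical descriptors
#' over their training-table ranges, the reference tetraparametric
#' coefficients as the true model, and residual noise comparable to that
#' model's standard error of estimate.
#'
#' @param n_compounds Number of rows.
#' @param intercept True intercept.
#' @param betas Named vector of true coefficients (names must be a
#'   subset of `names(descriptor_ranges)`).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param descriptor_ranges Named list of `c(low, high)` sampling ranges.
#' @param outlier_fraction Fraction of rows turned into outliers, in
#'   [0, 1).
#' @param outlier_shift Activity shift applied to outliers.
#' @param correlation Optional exchangeable correlation (single value in
#'   (-1, 1)) injected between descriptors via a Gaussian copula, for
#'   collinearity stress tests.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A list: `table` (compound tibble with `pec50`) and `truth`
#'   (list with `intercept`, `betas`, `noise_sd`, `outlier_ids`).
#' @examples
#' sim <- simulate_compound_table(n_compounds = 30, noise_sd = 0, seed = 7)
#' fit <- fit_qsar(sim$table, names(sim$truth$betas))
#' @export
simulate_compound_table <- function(n_compounds = 21,
                                    intercept = 4.022064,
                                    betas = c(MV = 0.019606, MP = -0.720766,
                                              "NA" = 0.216313, HG = -0.139588),
                                    noise_sd = 0.3,
                                    descriptor_ranges = default_descriptor_ranges(),
                                    outlier_fraction = 0,
                                    outlier_shift = 0,
                                    correlation = NULL,
                                    seed = NULL) {
  if (is.null(names(betas))) abort("betas must be a named vector")
  if (!all(names(betas) %in% names(descriptor_ranges))) {
    abort("every beta must name a descriptor with a sampling range")
  }
  for (nm in names(descriptor_ranges)) {
    rg <- descriptor_ranges[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2]) {
      abort(paste0("invalid range for '", nm, "': low must be < high"))
    }
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    abort("outlier_fraction must lie in [0, 1)")
  }
  with_seed(seed, {
    d <- length(descriptor_ranges)
    u <- if (is.null(correlation)) {
      matrix(runif(n_compounds * d), n_compounds, d)
    } else {
      if (abs(correlation) >= 1) abort("correlation must lie in (-1, 1)")
      sigma <- matrix(correlation, d, d); diag(sigma) <- 1
      z <- matrix(rnorm(n_compounds * d), n_compounds, d) %*% chol(sigma)
      stats::pnorm(z)
    }
    cols <- purrr::imap(stats::setNames(seq_len(d), names(descriptor_ranges)),
      function(j, nm) {
        rg <- descriptor_ranges[[nm]]
        x <- rg[1] + u[, j] * (rg[2] - rg[1])
        if (nm %in% INTEGER_DESCRIPTORS) round(x) else x
      })
    tbl <- as_tibble(cols)
    names(tbl) <- names(descriptor_ranges)
    x <- as.matrix(tbl[names(betas)])
    activity <- intercept + drop(x %*% betas) + rnorm(n_compounds, 0, noise_sd)
    n_out <- floor(outlier_fraction * n_compounds)
    outlier_idx <- if (n_out > 0) sample(n_compounds, n_out) else integer(0)
    activity[outlier_idx] <- activity[outlier_idx] + outlier_shift
    table <- bind_cols(
      tibble(compound_id = as.character(seq_len(n_compounds)),
             code = paste0("SYN-", seq_len(n_compounds)),
             role = "training", ec50_nM = NA_real_, pec50 = activity),
      tbl
    )
    attr(table, "descriptor_names") <- names(descriptor_ranges)
    list(table = table,
         truth = list(intercept = intercept, betas = betas, noise_sd = noise_sd,
                      outlier_ids = as.character(sort(outlier_idx))))
  })
}

#' Simulate a labelled ranked screen
#'
#' Builds a ranked screening list of decoys contaminated with labelled
#' reference agonists and antagonists, optionally pinning the exact
#' number of a label within given rank prefixes. The defaults encode the
#' published summary of the pharmacophore validation screen — 530
#' compounds (500 decoys, 15 agonists, 15 antagonists) with 12 agonists
#' in the top 13 and 4 antagonists in the top 19; the full original
#' ranking is not public, so the generated order is synthetic but
#' consistent with that summary.
#'
#' @param n_decoys,n_agonists,n_antagonists Library composition.
#' @param pins Named list: for each label, a numeric vector
#'   `c(k = prefix, count = exact number of that label in the prefix)`
#'   or a 2-column matrix of several `(k, count)` rows. `NULL` entries
#'   mean unconstrained. Use `pins = NULL` for a fully random ranking.
#' @param seed Integer seed.
#' @return A ranked screen tibble (see [ranked_screen()]).
#' @examples
#' s <- simulate_ranked_screen(seed = 42)
#' recovery(s, 13)$percent_agonists_recovered # 80
#' @export
simulate_ranked_screen <- function(n_decoys = 500, n_agonists = 15,
                                   n_antagonists = 15,
                                   pins = list(agonist = c(k = 13, count = 12),
                                               antagonist = c(k = 19, count = 4)),
                                   seed = NULL) {
  if (any(c(n_decoys, n_agonists, n_antagonists) < 0)) {
    abort("library counts must be >= 0")
  }
  n_total <- n_decoys + n_agonists + n_antagonists
  totals <- c(agonist = n_agonists, antagonist = n_antagonists, decoy = n_decoys)
  with_seed(seed, {
    slot <- rep(NA_character_, n_total)
    for (label in names(pins)) {
      constraint <- pins[[label]]
      if (is.null(constraint)) next
      if (!label %in% names(totals)) {
        abort(paste0("unknown pinned label: ", label))
      }
      rows <- if (is.matrix(constraint)) constraint else matrix(constraint, nrow = 1,
        dimnames = list(NULL, names(constraint)))
      rows <- rows[order(rows[, "k"]), , drop = FALSE]
      prev_k <- 0; prev_count <- 0
      for (i in seq_len(nrow(rows))) {
        k <- rows[i, "k"]; count <- rows[i, "count"]
        need <- count - prev_count
        if (k > n_total || need < 0 || count > totals[[label]]) {
          abort(paste0("infeasible placement for label '", label, "'"))
        }
        free <- which(is.na(slot[(prev_k + 1):k])) + prev_k
        if (length(free) < need) {
          abort(paste0("infeasible placement for label '", label,
                       "': prefix ", k, " has too few free slots"))
        }
        chosen <- if (need > 0) sample(free, need) else integer(0)
        slot[chosen] <- label
        prev_k <- k; prev_count <- count
      }
      # remaining members of a pinned label go strictly after its last prefix
      leftover <- totals[[label]] - prev_count
      if (leftover > 0) {
        free <- which(is.na(slot))
        free <- free[free > prev_k]
        if (length(free) < leftover) {
          abort(paste0("infeasible placement for label '", label,
                       "': not enough free slots after rank ", prev_k))
        }
        slot[sample(free, leftover)] <- label
      }
    }
    for (label in setdiff(names(totals), names(pins))) {
      free <- which(is.na(slot))
      take <- sample(free, totals[[label]])
      slot[take] <- label
    }
    counts <- table(factor(slot, levels = names(totals)))
    stopifnot(all(counts == totals))
    ids <- unlist(purrr::imap(as.list(totals), ~ paste0(.y, "_", seq_len(.x))),
                  use.names = FALSE)
    # assign ids to slots label-wise in order of appearance
    id_pool <- split(ids, sub("_\\d+$", "", ids))
    out_ids <- character(n_total)
    used <- stats::setNames(rep(0L, length(totals)), names(totals))
    for (i in seq_len(n_total)) {
      lab <- slot[i]
      used[[lab]] <- used[[lab]] + 1L
      out_ids[i] <- id_pool[[lab]][used[[lab]]]
    }
    ranked_screen(out_ids, slot)
  })
}

#' Random proper rotation matrix
#'
#' Uniformly distributed 3D rotation (det +1), for rigid-invariance
#' checks.
#'
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    q <- qr(matrix(rnorm(9), 3, 3))
    r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(r) < 0) r[, 1] <- -r[, 1]
    r
  })
}

#' Simulate a candidate feature cloud for the pharmacophore matcher
#'
#' Takes a pharmacophore model, applies a rigid transform (random by
#' default), adds optional Gaussian positional jitter, and appends decoy
#' features of random kinds scattered around the model. With zero jitter
#' a perfect match is guaranteed to exist regardless of decoys.
#'
#' @param model A `pharmacophore` feature tibble.
#' @param rotation Optional 3 x 3 rotation (default: random).
#' @param translation Optional length-3 translation (default: random in
#'   [-20, 20] angstrom per axis).
#' @param jitter_sd Positional noise standard deviation in angstrom.
#' @param n_decoys Number of decoy features to append.
#' @param seed Integer seed.
#' @return A `pharmacophore` tibble of candidate features.
#' @examples
#' cloud <- simulate_feature_cloud(a2a_pharmacophore(), jitter_sd = 0, seed = 3)
#' match_pharmacophore(a2a_pharmacophore(), cloud)$matched
#' @export
simulate_feature_cloud <- function(model, rotation = NULL, translation = NULL,
                                   jitter_sd = 0, n_decoys = 0, seed = NULL) {
  if (jitter_sd < 0) abort("jitter_sd must be >= 0")
  with_seed(seed, {
    rotation <- rotation %||% random_rotation()
    translation <- translation %||% runif(3, -20, 20)
    pts <- apply_rigid(feature_matrix(model), rotation, translation)
    pts <- pts + matrix(rnorm(length(pts), 0, jitter_sd), nrow = nrow(pts))
    kinds <- model$kind
    radii <- model$radius
    if (n_decoys > 0) {
      centre <- colMeans(pts)
      spread <- max(3 * stats::dist(pts))
      decoy_pts <- matrix(rnorm(3 * n_decoys, mean = centre, sd = spread / 2),
                          ncol = 3, byrow = TRUE)
      pts <- rbind(pts, decoy_pts)
      kinds <- c(kinds, sample(unique(model$kind), n_decoys, replace = TRUE))
      radii <- c(radii, rep(mean(model$radius), n_decoys))
    }
    pharmacophore(kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                  radius = radii)
  })
}
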
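#' Enumerate descriptor subsets for best-subset regression
#'
#' All size-p combinations (without repetition) of the candidate
#' descriptors, for each requested size. With the six selected descriptors
#' and sizes 4, 5 and 6 this yields the 22 candidate models of the study
#' design: 15 tetraparametric, 6 pentaparametric, 1 hexaparametric.
#'
#' @param descriptors Character vector of candidate descriptor names.
#' @param sizes Integer vector of subset sizes.
#' @return A tibble with `model_id`, `p` (subset size), `subset` (a
#'   `"MV+MP+..."` label) and `descriptors` (list-column of name vectors),
#'   in deterministic lexicographic order within each size.
#' @examples
#' nrow(enumerate_models(c("MV", "MP", "NA", "PF", "HG", "AR"), sizes = 4:6))
#' @export
enumerate_models <- function(descriptors, sizes) {
  if (anyDuplicated(descriptors)) abort("descriptor names must be unique")
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > length(descriptors))) {
    abort(paste0("sizes must lie in 1..", length(descriptors)))
  }
  specs <- purrr::map(sizes, function(p) {
    combs <- combn(descriptors, p, simplify = FALSE)
    tibble(p = p, descriptors = combs)
  }) %>% bind_rows()
  specs %>%
    mutate(model_id = row_number(),
           subset = purrr::map_chr(.data$descriptors, paste, collapse = "+")) %>%
    select("model_id", "p", "subset", "descriptors")
}

#' Regression quality statistics from sums of squares
#'
#' The standard multiple-linear-regression summary used throughout QSAR:
#' squared multiple correlation `r2 = 1 - rss/tss`, multiple correlation
#' `r = sqrt(r2)`, explained variance
#' `r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)`, standard error of estimate
#' `see = sqrt(rss/(n - p - 1))` and variance ratio
#' `f = (r2/p) / ((1 - r2)/(n - p - 1))`. Residual degrees of freedom are
#' `n - p - 1` (intercept counted).
#'
#' @param rss Residual sum of squares.
#' @param tss Total (centred) sum of squares; must be positive.
#' @param n Number of training observations.
#' @param p Number of descriptors in the model.
#' @return A one-row tibble with columns `r`, `r2`, `r2_adj`, `see`, `f`.
#' @examples
#' # recover the adjusted r2 and F implied by r2 = 0.8944, n = 16, p = 4
#' model_stats(rss = (1 - 0.8944), tss = 1, n = 16, p = 4)
#' @export
model_stats <- function(rss, tss, n, p) {
  if (tss <= 0) abort("tss must be positive (constant activity has no model)")
  if (n - p - 1 < 1) abort("need n - p - 1 >= 1 residual degrees of freedom")
  r2 <- 1 - rss / tss
  tibble(
    r = sqrt(pmax(r2, 0)),
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    see = sqrt(rss / (n - p - 1)),
    f = (r2 / p) / ((1 - r2) / (n - p - 1))
  )
}

#' Linear QSAR model from explicit coefficients
#'
#' Wraps an intercept and named descriptor coefficients as a model object
#' that [predict()] and the validation/screening helpers accept. Use it
#' for externally reported coefficient sets (see [a2a_models()]); fitted
#' models from [fit_qsar()] share the same interface.
#'
#' @param intercept Intercept term.
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @param stats Optional one-row tibble of fit statistics (as from
#'   [model_stats()]).
#' @return An object of class `qsar_model`.
#' @examples
#' m <- qsar_model(1, c(MV = 0.5, HG = -0.2))
#' predict(m, tibble::tibble(MV = 2, HG = 1))
#' @export
qsar_model <- function(intercept, coefficients, stats = NULL) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("coefficients must be a named numeric vector")
  }
  structure(
    list(intercept = as.numeric(intercept),
         coefficients = coefficients,
         descriptors = names(coefficients),
         stats = stats),
    class = "qsar_model"
  )
}

# Backtick-quoted formula; needed because "NA" is a canonical descriptor name.
subset_formula <- function(activity, descriptors) {
  stats::as.formula(
    paste0("`", activity, "` ~ ", paste0("`", descriptors, "`", collapse = " + ")),
    env = baseenv()
  )
}

#' Fit an ordinary-least-squares QSAR model
#'
#' Fits activity on the raw (unscaled) values of the given descriptor
#' subset by OLS with intercept, via [stats::lm()], and attaches the
#' standard fit statistics (see [model_stats()]). `r` is the multiple
#' correlation coefficient, equal to the Pearson correlation between
#' fitted and observed activity.
#'
#' @param table A compound tibble with activity present.
#' @param descriptors Character vector naming the descriptor subset.
#' @param activity Activity column (default `"pec50"`).
#' @param exclude Optional compound ids to drop before fitting (e.g.
#'   outliers from [detect_outliers()]).
#' @return A `qsar_fit` object (inherits `qsar_model`): coefficients,
#'   training ids, removed outliers, fit statistics, and the underlying
#'   `lm` fit.
#' @examples
#' train <- dplyr::filter(a2a_training(), !compound_id %in% as.character(c(2:5, 8)))
#' fit <- fit_qsar(train, c("MV", "MP", "NA", "HG"))
#' glance(fit)
#' @export
fit_qsar <- function(table, descriptors, activity = "pec50", exclude = NULL) {
  if (!all(descriptors %in% names(table))) {
    abort(paste0("missing descriptor column(s): ",
                 paste(setdiff(descriptors, names(table)), collapse = ", ")))
  }
  if (!activity %in% names(table)) {
    abort(paste0("activity column '", activity, "' not found"))
  }
  if (!is.null(exclude)) {
    missing_ids <- setdiff(exclude, table$compound_id)
    if (length(missing_ids)) {
      abort(paste0("exclude ids not in table: ", paste(missing_ids, collapse = ", ")))
    }
    table <- filter(table, !.data$compound_id %in% exclude)
  }
  keep <- !is.na(table[[activity]])
  table <- table[keep, , drop = FALSE]
  n <- nrow(table)
  p <- length(descriptors)
  if (n < p + 2) {
    abort(paste0("need at least p + 2 = ", p + 2, " training rows, got ", n))
  }
  x <- as.matrix(table[descriptors])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < p + 1) {
    dep <- descriptors[qrx$pivot[seq_len(qrx$rank)][-1]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(setdiff(descriptors, dep), collapse = ", ")))
  }
  fit <- lm(subset_formula(activity, descriptors), data = table)
  y <- table[[activity]]
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  stats <- model_stats(rss, tss, n, p)
  cf <- coef(fit)
  out <- qsar_model(intercept = unname(cf[1]),
                    coefficients = setNames(unname(cf[-1]), descriptors),
                    stats = stats)
  out$n_train <- n
  out$training_ids <- table$compound_id
  out$removed_outliers <- as.character(exclude %||% character(0))
  out$activity <- activity
  out$lm <- fit
  out$observed <- y
  out$fitted <- unname(fitted(fit))
  class(out) <- c("qsar_fit", "qsar_model")
  out
}

#' Fit every enumerated descriptor subset
#'
#' Convenience wrapper: [enumerate_models()] then [fit_qsar()] for each
#' subset on the same training rows, returning one row per candidate
#' model with its fit statistics.
#'
#' @inheritParams fit_qsar
#' @param sizes Subset sizes to enumerate (default `c(4, 5, 6)`).
#' @param descriptors Candidate descriptors (default: all descriptor
#'   columns of `table`).
#' @return A tibble with the enumeration columns plus `r`, `r2`,
#'   `r2_adj`, `see`, `f` and a `fit` list-column of `qsar_fit` objects.
#' @examples
#' train <- dplyr::filter(a2a_training(), !compound_id %in% as.character(c(2:5, 8)))
#' fit_all_models(train, sizes = 4) %>% rank_models() %>% head(3)
#' @export
fit_all_models <- function(table, sizes = c(4, 5, 6),
                           descriptors = descriptor_names(table),
                           activity = "pec50", exclude = NULL) {
  specs <- enumerate_models(descriptors, sizes)
  fits <- purrr::map(specs$descriptors, fit_qsar,
                     table = table, activity = activity, exclude = exclude)
  specs %>%
    bind_cols(purrr::map(fits, "stats") %>% bind_rows()) %>%
    mutate(fit = fits)
}

#' Rank fitted models by statistical quality
#'
#' Orders candidate models by the study's selection rule — higher `r`,
#' then higher `F`, then smaller `SEE` — with the subset label as a final
#' lexicographic tie-break so the order is a deterministic total order.
#'
#' @param models A tibble of fitted models as from [fit_all_models()]
#'   (needs columns `r`, `f`, `see`, `subset`).
#' @return The tibble sorted best-first with a `rank` column prepended.
#' @export
rank_models <- function(models) {
  needed <- c("r", "f", "see", "subset")
  if (!all(needed %in% names(models))) {
    abort(paste0("models must have columns: ", paste(needed, collapse = ", ")))
  }
  models %>%
    arrange(desc(.data$r), desc(.data$f), .data$see,
            .data$subset) %>%
    mutate(rank = row_number()) %>%
    select("rank", dplyr::everything())
}

#' Flag outlying training compounds
#'
#' Two modes. With `ids` supplied ("pinned"), the listed compounds are
#' validated and returned as-is, for exact reproduction of a published
#' training-set split. Otherwise an iterative standardized-residual rule
#' is applied: fit, flag the single row with the largest
#' `|standardized residual|` if it exceeds `threshold`, refit without it,
#' and repeat until no row exceeds the threshold.
#'
#' @inheritParams fit_qsar
#' @param threshold Standardized-residual threshold (default 2.0).
#' @param ids Optional explicit compound ids (pinned mode).
#' @return Character vector of flagged compound ids (possibly empty).
#' @examples
#' detect_outliers(a2a_training(), c("MV", "MP", "NA", "HG"),
#'                 ids = as.character(c(2:5, 8)))
#' @export
detect_outliers <- function(table, descriptors, activity = "pec50",
                            threshold = 2, ids = NULL) {
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing_ids <- setdiff(ids, table$compound_id)
    if (length(missing_ids)) {
      abort(paste0("pinned ids not in table: ", paste(missing_ids, collapse = ", ")))
    }
    return(ids)
  }
  flagged <- character(0)
  p <- length(descriptors)
  repeat {
    remaining <- filter(table, !.data$compound_id %in% flagged)
    if (nrow(remaining) < p + 2) {
      abort("outlier removal would leave fewer than p + 2 training rows")
    }
    fit <- fit_qsar(remaining, descriptors, activity)
    if (fit$stats$see < 1e-10) break   # perfect fit: nothing to flag
    rs <- rstandard(fit$lm)
    worst <- which.max(abs(rs))
    if (length(worst) == 0 || abs(rs[worst]) <= threshold) break
    flagged <- c(flagged, remaining$compound_id[worst])
  }
  flagged
}

#' @export
print.qsar_model <- function(x, ...) {
  kind <- if (inherits(x, "qsar_fit")) "Fitted QSAR model" else "QSAR model"
  cat(kind, " (", length(x$descriptors), " descriptors)\n", sep = "")
  terms <- c("(Intercept)" = x$intercept, x$coefficients)
  print(terms)
  if (!is.null(x$stats)) {
    with(x$stats, cat(sprintf("n = %s  r = %.4f  r2 = %.4f  r2_adj = %.4f  SEE = %.4f  F = %.4f\n",
                              x$n_train %||% "?", r, r2, r2_adj, see, f)))
  }
  invisible(x)
}

#' Tidy a QSAR model's coefficients
#'
#' @param x A `qsar_model` or `qsar_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`; for fitted models also
#'   `std.error`, `statistic` and `p.value` from the underlying `lm`.
#' @method tidy qsar_model
#' @export
tidy.qsar_model <- function(x, ...) {
  out <- tibble(term = c("(Intercept)", x$descriptors),
                estimate = unname(c(x$intercept, x$coefficients)))
  if (!is.null(x$lm)) {
    sm <- summary(x$lm)$coefficients
    out$std.error <- unname(sm[, "Std. Error"])
    out$statistic <- unname(sm[, "t value"])
    out$p.value <- unname(sm[, "Pr(>|t|)"])
  }
  out
}

#' One-row model-quality summary
#'
#' @param x A `qsar_model` with fit statistics.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `p`, `r`, `r2`, `r2_adj`, `see`, `f`.
#' @method glance qsar_model
#' @export
glance.qsar_model <- function(x, ...) {
  if (is.null(x$stats)) abort("model carries no fit statistics")
  bind_cols(tibble(n = x$n_train %||% x$stats$n %||% NA_integer_,
                   p = length(x$descriptors)),
            x$stats[setdiff(names(x$stats), "n")])
}
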
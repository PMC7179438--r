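#' Read a compound/descriptor/activity table
#'
#' Reads a TSV or CSV table of compounds with molecular descriptors and
#' (optionally) activity values, validates it, and returns a tibble. The
#' canonical columns are `compound_id`, `code`, `role`, `ec50_nM`, `pec50`
#' and the descriptor columns `MV`, `MP`, `NA`, `PF`, `HG`, `AR` (matched
#' case-insensitively; any extra numeric column is kept as an additional
#' descriptor). Missing activities are represented as `NA`, never as 0.
#'
#' Validation enforces: unique `compound_id`; positive `ec50_nM` where
#' present; agreement of `pec50` with `9 - log10(ec50_nM)` at 5-decimal
#' rounding where both are present; non-negative integers for `NA`, `PF`,
#' `HG`, `AR`; positive `MV` and `MP`; and no missing cells in descriptor
#' columns.
#'
#' @param source Path to a delimited file, or a literal string of its
#'   contents (anything containing a newline is treated as literal text).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated tibble, row order preserved, with a
#'   `"descriptor_names"` attribute listing the descriptor columns.
#' @examples
#' tbl <- read_compound_table(a2a_file("a2a_training.tsv"))
#' dplyr::filter(tbl, code == "UK-432097")
#' @export
read_compound_table <- function(source, dialect = c("tsv", "csv")) {
  dialect <- arg_match(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  input <- if (is.character(source) && length(source) == 1 && grepl("\n", source)) {
    I(source)
  } else {
    if (!file.exists(source)) abort(paste0("file not found: ", source))
    source
  }
  raw <- suppressWarnings(
    reader(input, col_types = readr::cols(.default = readr::col_character()),
           progress = FALSE, name_repair = "minimal")
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) abort("empty table: no rows parsed")
  validate_compound_table(canonicalise_columns(raw))
}

#' Write a compound table
#'
#' Inverse of [read_compound_table()]: writes the canonical TSV/CSV layout
#' so that write-then-read is the identity on valid tables.
#'
#' @param table A compound tibble as returned by [read_compound_table()].
#' @param file Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `file`, invisibly.
#' @export
write_compound_table <- function(table, file, dialect = c("tsv", "csv")) {
  dialect <- arg_match(dialect)
  if (dialect == "tsv") readr::write_tsv(table, file) else readr::write_csv(table, file)
  invisible(file)
}

# Map case-insensitive aliases onto canonical names and coerce types.
canonicalise_columns <- function(raw) {
  nm <- names(raw)
  canon <- c(META_COLUMNS, DESCRIPTOR_NAMES)
  hit <- match(tolower(nm), tolower(canon))
  nm[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate columns after alias matching: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(raw) <- nm
  if (!"compound_id" %in% nm) abort("missing required column 'compound_id'")

  numeric_cols <- setdiff(nm, c("compound_id", "code", "role"))
  for (col in numeric_cols) {
    txt <- raw[[col]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(trimws(txt)) & is.na(val))
    if (length(bad)) {
      abort(paste0("non-numeric value '", txt[bad[1]], "' in column '", col,
                   "', row ", bad[1]))
    }
    raw[[col]] <- val
  }
  if (!"role" %in% nm) raw$role <- NA_character_
  if (!"code" %in% nm) raw$code <- NA_character_
  descriptors <- setdiff(names(raw), c(META_COLUMNS))
  ordered <- c(intersect(c(META_COLUMNS), names(raw)), descriptors)
  out <- as_tibble(raw[ordered])
  attr(out, "descriptor_names") <- descriptors
  out
}

#' Validate a compound table
#'
#' Checks the structural invariants described in [read_compound_table()].
#' Called automatically by the reader; exported so that tables assembled in
#' code can be checked too.
#'
#' @param table A tibble with at least `compound_id` and one descriptor
#'   column.
#' @return The table, invisibly validated (returned unchanged).
#' @export
validate_compound_table <- function(table) {
  if (!"compound_id" %in% names(table)) abort("missing required column 'compound_id'")
  dup <- table$compound_id[duplicated(table$compound_id)]
  if (length(dup)) {
    abort(paste0("duplicate compound_id: ", paste(unique(dup), collapse = ", ")))
  }
  if ("ec50_nM" %in% names(table)) {
    bad <- which(!is.na(table$ec50_nM) & table$ec50_nM <= 0)
    if (length(bad)) {
      abort(paste0("ec50_nM must be positive; offending compound_id: ",
                   table$compound_id[bad[1]]))
    }
    if ("pec50" %in% names(table)) {
      both <- which(!is.na(table$ec50_nM) & !is.na(table$pec50))
      mism <- both[abs(round(9 - log10(table$ec50_nM[both]), 5) -
                         round(table$pec50[both], 5)) > 1e-9]
      if (length(mism)) {
        abort(paste0("pec50 inconsistent with ec50_nM (9 - log10 convention) for ",
                     table$compound_id[mism[1]]))
      }
    }
  }
  descriptors <- descriptor_names(table)
  for (col in descriptors) {
    x <- table[[col]]
    if (anyNA(x)) {
      abort(paste0("missing value in descriptor column '", col, "' (compound ",
                   table$compound_id[which(is.na(x))[1]], ")"))
    }
    if (col %in% INTEGER_DESCRIPTORS &&
        (any(x < 0) || any(abs(x - round(x)) > 1e-9))) {
      abort(paste0("descriptor '", col, "' must be a non-negative integer"))
    }
    if (col %in% c("MV", "MP") && any(x <= 0)) {
      abort(paste0("descriptor '", col, "' must be positive"))
    }
  }
  attr(table, "descriptor_names") <- descriptors
  table
}

#' Descriptor columns of a compound table
#'
#' @param table A compound tibble.
#' @return Character vector of descriptor column names (every column that is
#'   not one of the id/activity meta columns).
#' @export
descriptor_names <- function(table) {
  attr(table, "descriptor_names") %||% setdiff(names(table), META_COLUMNS)
}

#' Pharmacophore-feature count from individual feature counts
#'
#' The compound-level descriptor PF is the total number of pharmacophoric
#' features: hydrogen-bond donors and acceptors, cationic and anionic
#' centres, aromatic rings and hydrophobic groups,
#' `PF = HBD + HBA + CATION + ANION + AR + HG`.
#'
#' @param hbd,hba,cation,anion,ar,hg Non-negative integer counts
#'   (vectorised).
#' @return Integer vector of PF values.
#' @examples
#' compute_pf(hbd = 2, hba = 5, cation = 0, anion = 0, ar = 5, hg = 3)
#' @export
compute_pf <- function(hbd = 0, hba = 0, cation = 0, anion = 0, ar = 0, hg = 0) {
  counts <- list(hbd = hbd, hba = hba, cation = cation,
                 anion = anion, ar = ar, hg = hg)
  len <- max(lengths(counts))
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-9)) {
      abort(paste0("feature count '", nm, "' must be a non-negative integer"))
    }
    counts[[nm]] <- rep_len(x, len)
  }
  as.integer(Reduce(`+`, counts))
}
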
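# Independent oracles and small fixture builders shared across tests.

# Normal-equations OLS via explicit Gram-matrix inversion (independent of lm).
normal_equations <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(t(xm) %*% xm) %*% t(xm) %*% y)
}

# Naive line/field TSV parser (no readr).
naive_parse_tsv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  rows <- fields[-1]
  out <- lapply(seq_along(header), function(j) vapply(rows, `[[`, "", j))
  names(out) <- header
  out
}

# Textbook Pearson correlation from covariance over variance products.
textbook_cor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# A small hand-typed compound table (values chosen arbitrarily but valid).
toy_table_text <- paste(
  "compound_id\tcode\trole\tec50_nM\tpec50\tMV\tMP\tNA\tPF\tHG\tAR",
  "t1\tC-1\ttraining\t10\t8\t1000.5\t30.25\t40\t16\t2\t3",
  "t2\tC-2\ttraining\t100\t7\t1200.0\t35.00\t45\t18\t3\t3",
  "t3\tC-3\ttraining\t1000\t6\t1400.5\t40.75\t50\t20\t4\t4",
  "t4\tC-4\ttraining\t10000\t5\t1600.0\t45.50\t55\t22\t5\t4",
  "t5\tC-5\ttraining\t100000\t4\t1800.5\t50.25\t60\t24\t6\t5",
  sep = "\n"
)

# Training rows used for the published models (five outliers removed).
study_outliers <- as.character(c(2:5, 8))

training_table <- function() a2aqsar::a2a_training()

# Construct a vector with an exact empirical correlation r to y.
vector_with_cor <- function(y, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(y))
  ys <- as.numeric(scale(y))
  zr <- resid(lm(z ~ ys))
  zs <- as.numeric(scale(zr))
  r * ys + sqrt(1 - r^2) * zs
}

# Uniform random proper rotation (independent construction from quaternions).
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
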
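# internal helpers shared across modules

# round-half-up (base round() is round-half-even); used for scaled group sizes
round_half_up <- function(x) floor(x + 0.5)

# allocate `total` across parts proportional to `counts` (largest remainder),
# so scaled ethnicity counts always sum to the scaled group size
allocate_counts <- function(counts, total) {
  raw <- counts / sum(counts) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

check_positive <- function(x, field) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", field), class = "arindex_domain_error")
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    abort(
      sprintf(
        "`%s` must be strictly positive and finite (offending position(s): %s).",
        field, paste(head(which(bad), 5L), collapse = ", ")
      ),
      class = "arindex_domain_error"
    )
  }
  invisible(x)
}

check_column <- function(data, col, caller) {
  if (!col %in% names(data)) {
    abort(
      sprintf("`%s()` requires a `%s` column.", caller, col),
      class = "arindex_schema_error"
    )
  }
  invisible(data)
}

# significance grade from nested interval exclusion of zero
grade_from_exclusion <- function(excl95, excl99, excl999) {
  if (isTRUE(excl999)) "***" else if (isTRUE(excl99)) "**" else if (isTRUE(excl95)) "*" else "ns"
}
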
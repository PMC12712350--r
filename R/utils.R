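# internal helpers

# round half away from zero (printed tables use half-up, not banker's rounding)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# normalize a drug name: lowercase, trim, collapse internal whitespace
normalize_drug_name <- function(x) {
  x <- stringr::str_squish(tolower(x))
  x
}

# paste the sorted elements of `value` per `id`, returning one string per
# element of `ids` ("" when an id has no rows); used for dedup keys. The
# per-group collapse is done by padding to a position matrix and pasting
# column-wise, which stays vectorized however many groups there are.
collapse_sorted <- function(id, value, ids) {
  if (length(id) == 0L) return(rep("", length(ids)))
  o <- order(id, value, method = "radix")
  idx <- match(id[o], ids)
  r <- rle(idx)
  pos <- sequence(r$lengths)
  maxk <- max(r$lengths)
  m <- matrix("", nrow = length(ids), ncol = maxk)
  m[cbind(idx, pos)] <- value[o]
  if (maxk == 1L) return(m[, 1L])
  do.call(paste, c(lapply(seq_len(maxk), function(k) m[, k]), sep = "\x1f"))
}

stopf <- function(...) abort(sprintf(...), call = NULL)

assert_probability_vector <- function(p, what, tol = 1e-9) {
  if (any(is.na(p)) || any(p < 0)) {
    stopf("%s must be non-negative and free of missing values", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  }
  invisible(p)
}
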
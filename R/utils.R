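#' @keywords internal
"_PACKAGE"

# Error helpers: configuration errors (bad thresholds/parameters) vs
# validation errors (malformed records) get distinct condition classes so
# callers and tests can tell them apart.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("melscreen_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("melscreen_validation_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is_scalar_number(x)) stop_config(name, " must be a single finite number")
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) stop_config(name, " must lie in [0,1], got ", x)
  invisible(x)
}

# Single-base complement; vectorized over character vectors of "A","C","G","T","N".
complement_base <- function(b) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- unname(map[toupper(b)])
  out[is.na(out)] <- "N"
  out
}

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

# Columns every variant-call table must carry.
VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene", "impact",
  "maf", "mac", "context5", "context3", "flags"
)

empty_variants <- function() {
  data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    impact = character(), maf = numeric(), mac = integer(),
    context5 = character(), context3 = character(), flags = character(),
    stringsAsFactors = FALSE
  )
}

check_variants <- function(variants, required = VARIANT_COLUMNS) {
  if (!is.data.frame(variants)) stop_validation("variants must be a data.frame")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    stop_validation("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(variants)
}
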
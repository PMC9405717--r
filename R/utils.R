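#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabulated survey percentages in
#' this package follow the usual half-up presentation (12.5% prints as 13%).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(12.5, 10.53, 82.5))
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalize a taxon binomial
#'
#' Trims and collapses whitespace, capitalizes the genus, lower-cases the
#' epithet, and truncates infraspecific labels (subsp./var. and trailing
#' authority words) to the binomial. Single-word labels (genus names) are
#' capitalized only.
#'
#' @param x character vector of taxon names.
#' @return normalized character vector.
#' @export
normalize_binomial <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  vapply(x, function(nm) {
    if (!nzchar(nm)) return(nm)
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    parts[1] <- paste0(toupper(substr(parts[1], 1, 1)),
                       tolower(substr(parts[1], 2, nchar(parts[1]))))
    if (length(parts) == 1L) return(parts)
    paste(parts[1], tolower(parts[2]))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

stop_hf <- function(...) stop(..., call. = FALSE)

#' @keywords internal
is_count_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m >= 0) && all(m == round(m))
}
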
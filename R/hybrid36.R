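# Hybrid-36 counting for fixed-column PDB fields (atom serial width 5,
# residue number width 4). Values that fit the plain decimal field are
# written as decimal; the next block is base-36 with uppercase letters
# (starting "A0000" / "A000"), then a lowercase block.

H36_DIGITS_UP <- c(0:9, LETTERS)
H36_DIGITS_LO <- c(0:9, letters)

h36_encode_base36 <- function(value, width, digits) {
  out <- character(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- digits[value %% 36 + 1L]
    value <- value %/% 36
  }
  paste(out, collapse = "")
}

#' Encode an integer in hybrid-36
#'
#' @param value non-negative integer.
#' @param width field width (5 for PDB atom serials, 4 for residue numbers).
#' @return character string of `width` characters.
#' @export
hy36_encode <- function(value, width) {
  stopifnot(width %in% c(4L, 5L))
  dec_max <- 10^width                      # values < dec_max are plain decimal
  block <- 26 * 36^(width - 1)             # size of each letter block
  if (value < 0) stop("hybrid-36 cannot encode negative values")
  if (value < dec_max) return(formatC(value, width = width, format = "d"))
  v <- value - dec_max
  if (v < block)
    return(h36_encode_base36(v + 10 * 36^(width - 1), width, H36_DIGITS_UP))
  v <- v - block
  if (v < block)
    return(h36_encode_base36(v + 10 * 36^(width - 1), width, H36_DIGITS_LO))
  stop("value ", value, " out of hybrid-36 range for width ", width)
}

#' Decode a hybrid-36 field
#'
#' @param text character string (one fixed-width field, may carry spaces).
#' @param width field width the string was encoded at.
#' @return integer value.
#' @export
hy36_decode <- function(text, width) {
  stopifnot(width %in% c(4L, 5L))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty hybrid-36 field")
  first <- substr(text, 1, 1)
  if (grepl("^-?[0-9]+$", text)) return(as.integer(text))
  chars <- strsplit(text, "")[[1]]
  digits <- if (first %in% LETTERS) H36_DIGITS_UP else H36_DIGITS_LO
  idx <- match(chars, digits)
  if (anyNA(idx)) stop("not a hybrid-36 field: ", sQuote(text))
  v <- 0
  for (i in idx) v <- v * 36 + (i - 1)
  offset <- if (first %in% LETTERS) 0 else 26 * 36^(width - 1)
  as.integer(v - 10 * 36^(width - 1) + 10^width + offset)
}
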
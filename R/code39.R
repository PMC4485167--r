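# Code 39 symbology: every character is 9 elements (5 bars interleaved with
# 4 spaces), exactly 3 of the 9 wide.  The table below is the published
# standard pattern set, written as 9-character strings over {N, W} in element
# order b1 s1 b2 s2 b3 s3 b4 s4 b5 (1-based, as in the usual symbology
# diagrams).

.code39_table <- c(
  "0" = "NNNWWNWNN", "1" = "WNNWNNNNW", "2" = "NNWWNNNNW", "3" = "WNWWNNNNN",
  "4" = "NNNWWNNNW", "5" = "WNNWWNNNN", "6" = "NNWWWNNNN", "7" = "NNNWNNWNW",
  "8" = "WNNWNNWNN", "9" = "NNWWNNWNN",
  "A" = "WNNNNWNNW", "B" = "NNWNNWNNW", "C" = "WNWNNWNNN", "D" = "NNNNWWNNW",
  "E" = "WNNNWWNNN", "F" = "NNWNWWNNN", "G" = "NNNNNWWNW", "H" = "WNNNNWWNN",
  "I" = "NNWNNWWNN", "J" = "NNNNWWWNN", "K" = "WNNNNNNWW", "L" = "NNWNNNNWW",
  "M" = "WNWNNNNWN", "N" = "NNNNWNNWW", "O" = "WNNNWNNWN", "P" = "NNWNWNNWN",
  "Q" = "NNNNNNWWW", "R" = "WNNNNNWWN", "S" = "NNWNNNWWN", "T" = "NNNNWNWWN",
  "U" = "WWNNNNNNW", "V" = "NWWNNNNNW", "W" = "WWWNNNNNN", "X" = "NWNNWNNNW",
  "Y" = "WWNNWNNNN", "Z" = "NWWNWNNNN",
  "-" = "NWNNNNWNW", "." = "WWNNNNWNN", " " = "NWWNNNWNN", "*" = "NWNNWNWNN",
  "$" = "NWNWNWNNN", "/" = "NWNWNNNWN", "+" = "NWNNNWNWN", "%" = "NNNWNWNWN"
)

.norm_char <- function(c) {
  # accept the unicode minus sign used in print for the hyphen character
  c <- as.character(c)
  c[c == "−"] <- "-"
  c
}

#' The full Code 39 pattern table
#'
#' @return A named character vector mapping each of the 44 supported
#'   characters to its 9-character wide/narrow pattern string (element order
#'   b1 s1 b2 s2 b3 s3 b4 s4 b5).
#' @export
#' @examples
#' code39_table()[c("-", "+", "*")]
code39_table <- function() .code39_table

#' Encode one character as its Code 39 element pattern
#'
#' Each Code 39 character is a fixed sequence of 5 bars and 4 spaces, exactly
#' 3 of the 9 elements wide.  Bars occupy the odd element indices (1, 3, 5,
#' 7, 9), spaces the even ones.
#'
#' @param c A single supported character (0-9, A-Z, space, "-", ".", "$",
#'   "/", "+", "%", "*").  The typographic minus sign is accepted as "-".
#' @return An object of class `code39_pattern`: a list with `character`, the
#'   9-element `elements` data frame (`index`, `role`, `width_class`), and
#'   the `pattern` string.
#' @export
#' @examples
#' encode_char("+")
encode_char <- function(c) {
  c <- .norm_char(c)
  if (length(c) != 1L || is.na(c) || nchar(c) != 1L)
    stop("'c' must be a single character", call. = FALSE)
  pat <- .code39_table[c]
  if (is.na(pat))
    stop(sprintf("character %s is not in the Code 39 character set",
                 dQuote(c)), call. = FALSE)
  wc <- strsplit(unname(pat), "")[[1]]
  elements <- data.frame(
    index = 1:9,
    role = rep(c("bar", "space"), length.out = 9),
    width_class = ifelse(wc == "W", "wide", "narrow"),
    stringsAsFactors = FALSE
  )
  structure(list(character = c, elements = elements, pattern = unname(pat)),
            class = "code39_pattern")
}

#' @export
print.code39_pattern <- function(x, ...) {
  cat(sprintf("Code 39 pattern for %s: %s\n", dQuote(x$character), x$pattern))
  invisible(x)
}

.as_pattern <- function(p) {
  if (inherits(p, "code39_pattern")) p else encode_char(p)
}

#' Count differing elements between two Code 39 patterns
#'
#' @param p,q `code39_pattern` objects or single characters.
#' @return The number of element positions (out of 9) at which the
#'   wide/narrow classes differ.  For the "-"/"+" pair this is 4: the pair is
#'   identical in the first 5 elements and differs only in the last 4, which
#'   is what makes it usable as an assay readout pair.
#' @export
#' @examples
#' diff_elements("-", "+")
diff_elements <- function(p, q) {
  length(differential_positions(p, q))
}

#' Element positions at which two Code 39 patterns differ
#'
#' @inheritParams diff_elements
#' @return Integer vector of 1-based element indices (b1 = 1, s1 = 2, ...,
#'   b5 = 9) where the two patterns have different width classes; empty if
#'   the patterns are identical.
#' @export
#' @examples
#' differential_positions("-", "+")  # 6 7 8 9
differential_positions <- function(p, q) {
  p <- .as_pattern(p)
  q <- .as_pattern(q)
  which(p$elements$width_class != q$elements$width_class)
}

#' Frame a payload as a full Code 39 barcode
#'
#' Appends the start/stop character "*" at both ends and records the
#' inter-character gap class (one narrow space, so the gap does not read as
#' the end of the symbol).
#'
#' @param s Payload string; every character must be a supported Code 39
#'   character and "*" may not occur in the payload.
#' @return An object of class `barcode_spec` with fields `payload`,
#'   `full_sequence`, `chars` (the framed character vector) and `gap`
#'   ("narrow").
#' @export
#' @examples
#' encode_string("+")$full_sequence  # "*+*"
encode_string <- function(s) {
  if (length(s) != 1L || is.na(s)) stop("'s' must be a single string", call. = FALSE)
  chars <- .norm_char(strsplit(as.character(s), "")[[1]])
  if (length(chars) == 0L)
    stop("empty payload: a barcode must encode at least one character",
         call. = FALSE)
  if (any(chars == "*"))
    stop("the start/stop character \"*\" may not occur inside the payload",
         call. = FALSE)
  bad <- setdiff(chars, names(.code39_table))
  if (length(bad))
    stop(sprintf("unsupported character(s): %s",
                 paste(dQuote(bad), collapse = ", ")), call. = FALSE)
  payload <- paste(chars, collapse = "")
  structure(list(
    payload = payload,
    full_sequence = paste0("*", payload, "*"),
    chars = c("*", chars, "*"),
    gap = "narrow"
  ), class = "barcode_spec")
}

#' @export
print.barcode_spec <- function(x, ...) {
  cat(sprintf("Code 39 barcode: %s (payload %s, narrow inter-character gaps)\n",
              x$full_sequence, dQuote(x$payload)))
  invisible(x)
}

#' Export the Code 39 pattern table as JSON
#'
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
code39_json <- function(path = NULL) {
  json <- jsonlite::toJSON(as.list(.code39_table), auto_unbox = TRUE,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
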
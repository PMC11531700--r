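#' The canonical protein alphabet
#'
#' Returns the residue alphabet used throughout the package: the 24 NCBI
#' BLAST symbols `ARNDCQEGHILKMFPSTWYVBZX*` coded 0..23 in that order, plus a
#' dedicated pad code 24. `X` (code 22) doubles as the ambiguity code: any
#' letter outside the alphabet (including `U`, `O`, `J`) encodes as `X`.
#'
#' @return An [AAAlphabet-class] object.
#' @examples
#' aaAlphabet()
#' @export
aaAlphabet <- function() {
  new("AAAlphabet",
      symbols = strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]],
      padCode = 24L)
}

#' @rdname aaAlphabet
#' @param alphabet an [AAAlphabet-class].
#' @export
alphabetSymbols <- function(alphabet) alphabet@symbols

#' @rdname aaAlphabet
#' @export
padCode <- function(alphabet) alphabet@padCode

#' Encode a residue string as integer codes
#'
#' Characters are read case-insensitively. Letters that are not alphabet
#' symbols map to the ambiguity code `X`; non-letter characters (other than
#' `*`) are rejected with the offending position named.
#'
#' @param text a non-empty residue string.
#' @param alphabet an [AAAlphabet-class]; defaults to [aaAlphabet()].
#' @param id optional sequence identifier attached as attribute `id`.
#' @return Integer vector of 0-based codes (attribute `id` if given).
#' @examples
#' encodeSequence("ARN")
#' encodeSequence("aja")   # J is not a residue symbol -> X
#' @export
encodeSequence <- function(text, alphabet = aaAlphabet(), id = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      nchar(text) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(text), "")[[1]]
  bad <- which(!grepl("[A-Z*]", chars))
  if (length(bad))
    stop(sprintf("non-letter character '%s' at position %d", chars[bad[1]],
                 bad[1]))
  codes <- match(chars, alphabet@symbols) - 1L
  codes[is.na(codes)] <- match("X", alphabet@symbols) - 1L
  if (!is.null(id)) attr(codes, "id") <- id
  codes
}

#' Decode integer codes back to a residue string
#'
#' @param codes integer vector of 0-based codes (pad codes are dropped).
#' @param alphabet an [AAAlphabet-class].
#' @return A character scalar.
#' @export
decodeSequence <- function(codes, alphabet = aaAlphabet()) {
  codes <- codes[codes != alphabet@padCode]
  if (any(codes < 0L | codes >= length(alphabet@symbols)))
    stop("code outside the alphabet")
  paste(alphabet@symbols[codes + 1L], collapse = "")
}
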
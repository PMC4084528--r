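# Signed 32-bit words are carried as doubles holding exact integers in
# [-2^31, 2^31 - 1].  Sums of up to ~2^20 words stay below 2^53, so all
# modular arithmetic below is exact.

TWO31 <- 2^31
TWO32 <- 2^32

#' Wrap integers into the signed 32-bit range
#'
#' Reduces integer values modulo 2^32 into `[-2^31, 2^31 - 1]`, the
#' two's-complement wraparound a 32-bit hardware adder performs.
#'
#' @param x numeric vector of exact integers (may exceed the 32-bit range).
#' @return numeric vector of signed 32-bit words.
#' @export
wrap32 <- function(x) {
  (x + TWO31) %% TWO32 - TWO31
}

#' Fixed-point number format
#'
#' Describes the fixed-point representation used for coordinates and forces:
#' a signed `word_bits`-bit integer word whose least-significant bit is worth
#' `lsb` physical units (length units for coordinates, force units for
#' forces).  The representable range is
#' `[-2^(word_bits-1) * lsb, (2^(word_bits-1) - 1) * lsb]`.
#'
#' @param lsb physical value of one least-significant bit; must be positive.
#' @param word_bits word width in bits (the modelled hardware uses 32).
#' @param signed logical; two's-complement interpretation (always `TRUE` in
#'   the modelled machine).
#' @return an object of class `fixed_format`.
#' @examples
#' fmt <- fixed_format(lsb = 1e-6)
#' fmt$range
#' @export
fixed_format <- function(lsb, word_bits = 32L, signed = TRUE) {
  stopifnot(is.numeric(lsb), length(lsb) == 1L, is.finite(lsb))
  if (lsb <= 0) stop("'lsb' must be positive")
  if (word_bits != 32L) stop("only 32-bit words are modelled")
  structure(
    list(
      word_bits = 32L,
      signed = isTRUE(signed),
      lsb = lsb,
      range = c(-TWO31 * lsb, (TWO31 - 1) * lsb)
    ),
    class = "fixed_format"
  )
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf(
    "<fixed_format> %d-bit %s, lsb = %.6g, range [%.6g, %.6g]\n",
    x$word_bits, if (x$signed) "two's complement" else "unsigned",
    x$lsb, x$range[1], x$range[2]
  ))
  invisible(x)
}

#' Fixed-point format for box-relative coordinates
#'
#' The default coordinate mapping: positions in `[0, L)` are scaled so that
#' one box length spans the full 32-bit word, i.e. `lsb = L / 2^32` per axis.
#'
#' @param box_length box edge length.
#' @return a `fixed_format`.
#' @export
coordinate_format <- function(box_length) {
  stopifnot(is.numeric(box_length), box_length > 0)
  fixed_format(lsb = box_length / TWO32)
}

#' Encode a coordinate as a 32-bit fixed-point word
#'
#' Maps a position in `[0, box_length)` to an integer word under the
#' box-relative convention `lsb = box_length / 2^32`.  Quantization uses
#' round-half-to-even.  The word is returned in signed (two's-complement)
#' form; the box midpoint `L/2` encodes to `2^31`, which wraps to `-2^31`.
#'
#' @param x numeric vector of positions, each in `[0, box_length)`; positions
#'   must already be wrapped into the box.
#' @param box_length box edge length.
#' @param fmt the coordinate `fixed_format`; defaults to
#'   `coordinate_format(box_length)`.
#' @return numeric vector of signed 32-bit words.
#' @seealso [decode_coordinate()]
#' @export
encode_coordinate <- function(x, box_length, fmt = coordinate_format(box_length)) {
  stopifnot(inherits(fmt, "fixed_format"))
  if (any(x < 0 | x >= box_length)) {
    stop("positions must lie in [0, box_length); apply the periodic wrap first")
  }
  # round() is round-half-to-even; a value rounding up to 2^32 wraps to 0,
  # which is the periodic image of the box origin.
  wrap32(round(x / fmt$lsb) %% TWO32)
}

#' Decode a fixed-point coordinate word
#'
#' Inverse of [encode_coordinate()] under the unsigned-fraction convention:
#' the signed word is reinterpreted modulo 2^32 and scaled by the lsb, so
#' the decoded value always lies in `[0, box_length)`.
#'
#' @param word numeric vector of signed 32-bit words.
#' @param box_length box edge length.
#' @param fmt the coordinate `fixed_format`.
#' @return numeric vector of positions in `[0, box_length)`.
#' @export
decode_coordinate <- function(word, box_length, fmt = coordinate_format(box_length)) {
  stopifnot(inherits(fmt, "fixed_format"))
  (word %% TWO32) * fmt$lsb
}

#' Quantize real values to fixed-point words
#'
#' Rounds physical values to integer multiples of the format's lsb with
#' round-half-to-even (unbiased accumulation), then wraps into the signed
#' 32-bit range.
#'
#' @param x numeric vector of physical values.
#' @param fmt a `fixed_format`.
#' @return numeric vector of signed 32-bit words.
#' @export
quantize <- function(x, fmt) {
  stopifnot(inherits(fmt, "fixed_format"))
  wrap32(round(x / fmt$lsb))
}

#' Fixed-point accumulator bank
#'
#' A vector of signed 32-bit integer words accumulated with two's-complement
#' wraparound and a sticky overflow flag.  Because the underlying operation
#' is integer addition modulo 2^32, the final word is bit-identical for every
#' ordering of the same terms -- the property the modelled hardware exploits
#' for deterministic parallel force summation.
#'
#' @param fmt a `fixed_format` describing the word scale.
#' @param n number of independent accumulator words.
#' @return an object of class `fixed_accumulator`.
#' @export
fixed_accumulator <- function(fmt, n = 1L) {
  stopifnot(inherits(fmt, "fixed_format"), n >= 1)
  structure(
    list(value = numeric(n), overflow = FALSE, fmt = fmt),
    class = "fixed_accumulator"
  )
}

#' @export
print.fixed_accumulator <- function(x, ...) {
  cat(sprintf(
    "<fixed_accumulator> %d word(s), overflow=%s, decoded head: %s\n",
    length(x$value), x$overflow,
    paste(signif(utils::head(x$value) * x$fmt$lsb, 6), collapse = " ")
  ))
  invisible(x)
}

#' Accumulate real-valued terms into a fixed-point accumulator
#'
#' Each term is quantized to the accumulator's lsb (round-half-to-even) and
#' added with 32-bit two's-complement wraparound.  Signed overflow at any
#' intermediate step sets the sticky `overflow` flag; the stored word is the
#' exact modular sum either way, so the result is independent of term order.
#'
#' @param acc a `fixed_accumulator` with a single word (see
#'   [accumulate_write()] for banks).
#' @param terms numeric vector of physical-valued terms.
#' @return the updated `fixed_accumulator`.
#' @export
accumulate <- function(acc, terms) {
  stopifnot(inherits(acc, "fixed_accumulator"), length(acc$value) == 1L)
  if (length(terms) == 0L) return(acc)
  q <- round(terms / acc$fmt$lsb)
  running <- acc$value + cumsum(q)
  # epoch = which 2^32 window the running sum sits in; any change means a
  # wraparound (signed overflow) occurred at that step
  epoch <- (running + TWO31) %/% TWO32
  if (any(epoch != 0)) acc$overflow <- TRUE
  acc$value <- wrap32(running[length(running)])
  acc
}

#' Decode an accumulator to physical units
#'
#' @param acc a `fixed_accumulator`.
#' @return numeric vector `value * lsb`.
#' @export
decode_accumulator <- function(acc) {
  stopifnot(inherits(acc, "fixed_accumulator"))
  acc$value * acc$fmt$lsb
}

#' Accumulate-on-write into a memory bank
#'
#' Models the global-memory DMA write mode in which incoming data are summed
#' into the destination words instead of overwriting them.  The accumulation
#' format is restricted to 32-bit integers: non-integer payloads with
#' `mode = "sum"` are an error.  Repeated indices are allowed and behave as
#' sequential writes.
#'
#' @param bank numeric vector of signed 32-bit words (the memory bank).
#' @param index 1-based positions written to, same length as `values`.
#' @param values numeric vector of integer words.
#' @param mode `"sum"` (accumulate with wraparound) or `"overwrite"`.
#' @return the updated bank.
#' @examples
#' accumulate_write(c(5), 1, 3, "sum")  # 8
#' @export
accumulate_write <- function(bank, index, values, mode = c("sum", "overwrite")) {
  mode <- match.arg(mode)
  stopifnot(length(index) == length(values))
  if (length(index) == 0L) return(bank)
  if (any(index < 1 | index > length(bank))) stop("index out of range")
  if (mode == "sum") {
    if (any(values != round(values))) {
      stop("accumulate-on-write is limited to 32-bit integer payloads")
    }
    add <- rowsum(values, group = index)
    idx <- as.integer(rownames(add))
    bank[idx] <- wrap32(bank[idx] + add[, 1])
  } else {
    # sequential semantics: the last write to an index wins
    bank[index] <- values
  }
  bank
}
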
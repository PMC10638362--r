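#' The eight S/V transfer functions
#'
#' A transfer function maps a continuous search coordinate to a
#' probability used to binarize metaheuristic positions. The S family is
#' sigmoidal with slopes 2, 1, 1/2, 1/3 (S1-S4); the V family is the even,
#' absolute-value family: V1 = |erf((sqrt(pi)/2) x)|, V2 = |tanh x|,
#' V3 = |x / sqrt(1 + x^2)|, V4 = |(2/pi) atan((pi/2) x)|.
#'
#' @param name one of `"s1".."s4"`, `"v1".."v4"` (case-insensitive).
#' @return an object of class `transfer_function` with fields `family`
#'   ("S" or "V") and `index` (1-4).
#' @export
transfer_function <- function(name) {
  name <- tolower(as.character(name))
  if (!grepl("^[sv][1-4]$", name)) {
    stop("transfer_function: unknown variant '", name,
         "'; expected one of s1..s4, v1..v4")
  }
  structure(list(family = toupper(substr(name, 1, 1)),
                 index = as.integer(substr(name, 2, 2)),
                 name = name),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat("transfer_function", toupper(x$name), "\n"); invisible(x)
}

#' All eight transfer-function names
#' @return character vector `c("s1".."s4", "v1".."v4")`.
#' @export
transfer_variants <- function() {
  c(paste0("s", 1:4), paste0("v", 1:4))
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Evaluate a transfer function
#'
#' @param tf a [transfer_function()].
#' @param x numeric vector of continuous positions (finite).
#' @return probabilities: in (0, 1) for the S family, `[0, 1)` for V.
#' @export
transfer_value <- function(tf, x) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(!is.finite(x))) stop("transfer_value: non-finite position")
  if (tf$family == "S") {
    slope <- c(2, 1, 1 / 2, 1 / 3)[tf$index]
    1 / (1 + exp(-slope * x))
  } else {
    switch(tf$index,
           abs(erf(sqrt(pi) / 2 * x)),
           abs(tanh(x)),
           abs(x / sqrt(1 + x^2)),
           abs(2 / pi * atan(pi / 2 * x)))
  }
}

#' S-shaped binarization of a continuous position row
#'
#' Per dimension a uniform `rand` is drawn and compared with `T(x)`. Under
#' the default `as_printed` orientation the bit is 1 iff `rand >= T(x)`
#' (so the activation probability is `1 - T(x)`); `conventional` uses the
#' usual `rand < T(x)` rule.
#'
#' @param x_row numeric vector of continuous positions.
#' @param tf an S-family [transfer_function()].
#' @param orientation `"as_printed"` (default) or `"conventional"`.
#' @return integer 0/1 vector.
#' @export
binarize_s <- function(x_row, tf, orientation = c("as_printed",
                                                  "conventional")) {
  stopifnot(inherits(tf, "transfer_function"))
  if (tf$family != "S") stop("binarize_s: S-family transfer required")
  orientation <- match.arg(orientation)
  tv <- transfer_value(tf, x_row)
  r <- runif(length(x_row))
  if (orientation == "as_printed") as.integer(r >= tv) else as.integer(r < tv)
}

#' V-shaped binarization: probabilistic bit complement
#'
#' Per dimension the previous bit is complemented with probability
#' `T(x)` and kept otherwise.
#'
#' @param x_row numeric vector of continuous positions.
#' @param prev_bits integer 0/1 vector of the previous binary position,
#'   same length as `x_row`.
#' @param tf a V-family [transfer_function()].
#' @return integer 0/1 vector.
#' @export
binarize_v <- function(x_row, prev_bits, tf) {
  stopifnot(inherits(tf, "transfer_function"))
  if (tf$family != "V") stop("binarize_v: V-family transfer required")
  if (length(prev_bits) != length(x_row)) {
    stop("binarize_v: prev_bits length ", length(prev_bits),
         " != position length ", length(x_row))
  }
  tv <- transfer_value(tf, x_row)
  flip <- runif(length(x_row)) < tv
  out <- as.integer(prev_bits)
  out[flip] <- 1L - out[flip]
  out
}

#' Repair an all-zero feature mask
#'
#' The wrapper cost is undefined for an empty feature subset; if no bit is
#' set, exactly one uniformly random bit is switched on. Otherwise the
#' mask is returned unchanged.
#'
#' @param bits integer 0/1 vector (non-empty).
#' @return integer 0/1 vector with at least one active bit.
#' @export
repair_mask <- function(bits) {
  if (length(bits) == 0L) stop("repair_mask: zero-length mask")
  bits <- as.integer(bits)
  if (!any(bits == 1L)) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}
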
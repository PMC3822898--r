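# Unit table: each entry maps a unit symbol to its dimension (named vector of
# base-dimension exponents) and its scale factor to the SI base unit of that
# dimension. Only the dimensions the object model needs are covered: time,
# frequency (1/time) and voltage, plus dimensionless.
.unit_table <- list(
  "s"   = list(dim = c(s = 1),  factor = 1),
  "ms"  = list(dim = c(s = 1),  factor = 1e-3),
  "us"  = list(dim = c(s = 1),  factor = 1e-6),
  "min" = list(dim = c(s = 1),  factor = 60),
  "h"   = list(dim = c(s = 1),  factor = 3600),
  "Hz"  = list(dim = c(s = -1), factor = 1),
  "kHz" = list(dim = c(s = -1), factor = 1e3),
  "V"   = list(dim = c(V = 1),  factor = 1),
  "mV"  = list(dim = c(V = 1),  factor = 1e-3),
  "uV"  = list(dim = c(V = 1),  factor = 1e-6),
  "1"   = list(dim = c(),       factor = 1)
)
# dimensionless: empty string cannot be a named list() argument
.unit_table[[length(.unit_table) + 1L]] <- list(dim = c(), factor = 1)
names(.unit_table)[length(.unit_table)] <- ""

.norm_dim <- function(d) {
  d <- d[d != 0]
  if (length(d)) d[order(names(d))] else stats::setNames(numeric(0), character(0))
}

.unit_info <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L)
    stop("unit must be a single string", call. = FALSE)
  if (unit == "" || unit == "1")
    return(list(dim = .norm_dim(c()), factor = 1))
  info <- .unit_table[[unit]]
  if (is.null(info)) {
    # composite labels produced by arithmetic, e.g. "V^2" or "s^-1"
    d <- .parse_dim_label(unit)
    if (is.null(d)) stop(sprintf("unknown unit '%s'", unit), call. = FALSE)
    info <- list(dim = d, factor = 1)
  }
  info$dim <- .norm_dim(info$dim)
  info
}

# parse labels of the form "s", "s^-2", "V^2*s^-1" over base dimensions
.parse_dim_label <- function(label) {
  if (label == "" || label == "1") return(c())
  parts <- strsplit(label, "*", fixed = TRUE)[[1]]
  d <- c()
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z]+)(\\^(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0) return(NULL)
    base <- m[2]
    if (!base %in% c("s", "V")) return(NULL)
    pw <- if (m[4] == "") 1 else as.numeric(m[4])
    d[base] <- (if (base %in% names(d)) d[[base]] else 0) + pw
  }
  d
}

.dim_label <- function(d) {
  d <- .norm_dim(d)
  if (!length(d)) return("")
  if (identical(d, c(s = -1))) return("Hz")
  paste(vapply(names(d), function(nm) {
    if (d[[nm]] == 1) nm else sprintf("%s^%g", nm, d[[nm]])
  }, character(1)), collapse = "*")
}

#' Create a physical quantity
#'
#' A quantity couples a numeric magnitude (scalar or array) with a physical
#' unit. Arithmetic between quantities checks dimensional compatibility:
#' adding seconds to volts is an error, adding milliseconds to seconds
#' converts first. Supported units: time (`s`, `ms`, `us`, `min`, `h`),
#' frequency (`Hz`, `kHz`), voltage (`V`, `mV`, `uV`) and dimensionless
#' (`""`).
#'
#' @param x numeric vector or array.
#' @param unit unit symbol as a string.
#' @return An object of class `qty`.
#' @examples
#' qty(c(0.1, 0.5), "s") + qty(100, "ms")
#' @export
qty <- function(x, unit = "") {
  if (inherits(x, "qty")) return(q_convert(x, unit))
  if (!is.numeric(x)) stop("quantity magnitude must be numeric", call. = FALSE)
  .unit_info(unit)
  mag <- if (is.null(dim(x))) as.numeric(x) else structure(as.numeric(x), dim = dim(x))
  structure(list(mag = mag, unit = unit), class = "qty")
}

#' Test whether an object is a quantity
#' @param x any object.
#' @export
is_qty <- function(x) inherits(x, "qty")

#' Magnitude of a quantity (in its own unit)
#' @param x a `qty`.
#' @export
q_mag <- function(x) {
  stopifnot(is_qty(x))
  x$mag
}

#' Unit symbol of a quantity
#' @param x a `qty`.
#' @export
q_unit <- function(x) {
  stopifnot(is_qty(x))
  x$unit
}

#' Convert a quantity to another unit of the same dimension
#' @param x a `qty`.
#' @param unit target unit symbol.
#' @export
q_convert <- function(x, unit) {
  stopifnot(is_qty(x))
  from <- .unit_info(x$unit)
  to <- .unit_info(unit)
  if (!identical(from$dim, to$dim))
    stop(sprintf("cannot convert '%s' to '%s': incompatible dimensions",
                 x$unit, unit), call. = FALSE)
  qty(x$mag * (from$factor / to$factor), unit)
}

#' Numeric magnitude of a quantity expressed in a given unit
#' @param x a `qty`.
#' @param unit unit to express the value in.
#' @export
q_in <- function(x, unit) q_mag(q_convert(x, unit))

.q_si <- function(x) {
  info <- .unit_info(x$unit)
  list(mag = x$mag * info$factor, dim = info$dim)
}

#' Dimension-aware quantity equality
#'
#' Two quantities compare equal when their dimensions match and their
#' magnitudes, expressed in a common unit, agree within `tol`.
#' @param a,b quantities.
#' @param tol absolute tolerance applied in SI units.
#' @export
q_equal <- function(a, b, tol = 1e-12) {
  if (!is_qty(a) || !is_qty(b)) return(FALSE)
  sa <- .q_si(a); sb <- .q_si(b)
  if (!identical(sa$dim, sb$dim)) return(FALSE)
  if (length(sa$mag) != length(sb$mag)) return(FALSE)
  if (!identical(dim(sa$mag), dim(sb$mag))) return(FALSE)
  if (length(sa$mag) == 0) return(TRUE)
  all(abs(sa$mag - sb$mag) <= tol + tol * pmax(abs(sa$mag), abs(sb$mag)))
}

#' @export
Ops.qty <- function(e1, e2) {
  if (missing(e2)) { # unary
    if (.Generic == "-") return(qty(-e1$mag, e1$unit))
    if (.Generic == "+") return(e1)
    stop(sprintf("unary %s not defined for quantities", .Generic), call. = FALSE)
  }
  both <- is_qty(e1) && is_qty(e2)
  if (.Generic %in% c("+", "-")) {
    if (!both) stop("cannot mix quantities and bare numbers in +/-", call. = FALSE)
    e2c <- q_convert(e2, e1$unit)
    return(qty(get(.Generic)(e1$mag, e2c$mag), e1$unit))
  }
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) {
    if (!both) stop("cannot compare a quantity with a bare number", call. = FALSE)
    e2c <- q_convert(e2, e1$unit)
    return(get(.Generic)(e1$mag, e2c$mag))
  }
  if (.Generic %in% c("*", "/")) {
    s1 <- if (is_qty(e1)) .q_si(e1) else list(mag = e1, dim = c())
    s2 <- if (is_qty(e2)) .q_si(e2) else list(mag = e2, dim = c())
    sgn <- if (.Generic == "/") -1 else 1
    nms <- unique(c(names(s1$dim), names(s2$dim)))
    dd <- stats::setNames(numeric(length(nms)), nms)
    dd[names(s1$dim)] <- s1$dim
    dd[names(s2$dim)] <- dd[names(s2$dim)] + sgn * s2$dim
    return(qty(get(.Generic)(s1$mag, s2$mag), .dim_label(dd)))
  }
  if (.Generic == "^") {
    if (is_qty(e2)) stop("exponent must be a bare number", call. = FALSE)
    s1 <- .q_si(e1)
    return(qty(s1$mag ^ e2, .dim_label(s1$dim * e2)))
  }
  stop(sprintf("operation %s not defined for quantities", .Generic), call. = FALSE)
}

#' @export
Math.qty <- function(x, ...) {
  if (.Generic %in% c("abs", "floor", "ceiling", "round", "trunc"))
    return(qty(get(.Generic)(x$mag, ...), x$unit))
  info <- .unit_info(x$unit)
  if (length(info$dim))
    stop(sprintf("%s requires a dimensionless quantity", .Generic), call. = FALSE)
  get(.Generic)(x$mag * info$factor, ...)
}

#' @export
Summary.qty <- function(..., na.rm = FALSE) {
  args <- list(...)
  if (!all(vapply(args, is_qty, logical(1))))
    stop("summary of mixed quantity/number arguments", call. = FALSE)
  unit <- args[[1]]$unit
  mags <- lapply(args, q_in, unit)
  if (.Generic %in% c("max", "min", "sum", "range"))
    return(qty(get(.Generic)(unlist(mags), na.rm = na.rm), unit))
  stop(sprintf("%s not defined for quantities", .Generic), call. = FALSE)
}

#' @export
`[.qty` <- function(x, i) qty(x$mag[i], x$unit)

#' @export
length.qty <- function(x) length(x$mag)

#' @export
diff.qty <- function(x, ...) qty(diff(x$mag, ...), x$unit)

#' @export
sort.qty <- function(x, decreasing = FALSE, ...) {
  qty(sort(x$mag, decreasing = decreasing), x$unit)
}

#' @export
format.qty <- function(x, ...) {
  paste0(format(x$mag, ...), " ", if (x$unit == "") "(dimensionless)" else x$unit)
}

#' @export
print.qty <- function(x, ...) {
  n <- length(x$mag)
  cat(sprintf("<quantity [%d] %s>\n", n, if (x$unit == "") "1" else x$unit))
  print(x$mag, ...)
  invisible(x)
}

# concatenate quantities, converting to the unit of the first
q_c <- function(...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, logical(1))]
  if (!length(args)) return(NULL)
  unit <- args[[1]]$unit
  qty(unlist(lapply(args, q_in, unit)), unit)
}

# seconds helpers used throughout the analysis code
.secs <- function(x) q_in(x, "s")
.hz <- function(x) q_in(x, "Hz")
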
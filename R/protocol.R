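# PGSE encodings and acquisition protocols.
#
# Units are fixed package-wide: times in ms, lengths in um, b in ms/um^2,
# diffusivities in um^2/ms, q in 1/um.  The gyromagnetic ratio only enters
# when converting the plateau q to a physical gradient amplitude.

# gamma for 1H in 1/(um * mT/m * ms): q = GAMMA * g * delta
.GAMMA <- 2.6752218744e-4

#' Construct an ideal rectangular-pulse PGSE encoding
#'
#' Builds a pulsed-gradient spin-echo sequence with rectangular gradient
#' pulses of width `delta` separated by `Delta` (ramp times neglected).  The
#' diffusion-encoding wavevector `q(t)` rises linearly over `[0, delta]`,
#' stays at its plateau over `[delta, Delta]`, and returns to zero over
#' `[Delta, Delta + delta]`, so that the encoding is balanced and
#' `b = integral of q(t)^2 dt = q_max^2 (Delta - delta/3)`.
#'
#' @param b Diffusion weighting in ms/um^2 (non-negative).
#' @param Delta Gradient pulse separation in ms.
#' @param delta Gradient pulse width in ms; must satisfy
#'   `0 < delta <= Delta`.
#' @return An object of class `"pgse"`: a list with elements `b`, `Delta`,
#'   `delta`, `q_max` (plateau wavevector, 1/um), `g` (gradient amplitude,
#'   mT/m) and `T` (encoding duration `Delta + delta`, ms).
#' @examples
#' seq <- pgse(100, Delta = 16, delta = 4.5)
#' seq$g  # physical gradient amplitude in mT/m
#' @seealso [q_of_t()], [qsq_integral()], [exvivo_protocol()]
#' @export
pgse <- function(b, Delta, delta) {
  stopifnot(length(b) == 1L, length(Delta) == 1L, length(delta) == 1L)
  if (!is.finite(b) || b < 0) stop("'b' must be non-negative")
  if (!is.finite(Delta) || !is.finite(delta) || delta <= 0 || Delta <= 0)
    stop("timings must be positive")
  if (delta > Delta) stop("'delta' must not exceed 'Delta'")
  q_max <- sqrt(b / (Delta - delta / 3))
  structure(
    list(b = b, Delta = Delta, delta = delta, q_max = q_max,
         g = q_max / (.GAMMA * delta), T = Delta + delta),
    class = "pgse")
}

#' @export
print.pgse <- function(x, ...) {
  cat(sprintf("PGSE: b = %g ms/um^2, Delta = %g ms, delta = %g ms (g = %.0f mT/m)\n",
              x$b, x$Delta, x$delta, x$g))
  invisible(x)
}

#' Evaluate the diffusion wavevector q(t) of a PGSE encoding
#'
#' @param seq A [pgse()] object.
#' @param t Time points in ms (vectorized); values outside `[0, Delta+delta]`
#'   return 0.
#' @return `q(t)` in 1/um.
#' @export
q_of_t <- function(seq, t) {
  stopifnot(inherits(seq, "pgse"))
  q <- numeric(length(t))
  up <- t >= 0 & t < seq$delta
  flat <- t >= seq$delta & t <= seq$Delta
  down <- t > seq$Delta & t <= seq$T
  q[up] <- seq$q_max * t[up] / seq$delta
  q[flat] <- seq$q_max
  q[down] <- seq$q_max * (seq$T - t[down]) / seq$delta
  q
}

#' Analytic integral of q(t)^2 over a sub-interval
#'
#' The q(t) profile is piecewise linear, so `q^2` is piecewise quadratic and
#' its integral is evaluated in closed form (no quadrature error).  With
#' `t0 = 0`, `t1 = Delta + delta` this recovers the b-value exactly.
#'
#' @param seq A [pgse()] object.
#' @param t0,t1 Integration limits in ms, `0 <= t0 <= t1 <= Delta + delta`.
#' @return The integral of `q(t)^2 dt` in ms/um^2.
#' @export
qsq_integral <- function(seq, t0 = 0, t1 = seq$T) {
  stopifnot(inherits(seq, "pgse"), t0 <= t1)
  # antiderivative of q^2 at time t
  F <- function(t) {
    t <- min(max(t, 0), seq$T)
    d <- seq$delta; D <- seq$Delta; q2 <- seq$q_max^2
    if (t <= d) return(q2 * t^3 / (3 * d^2))
    v <- q2 * d / 3
    if (t <= D) return(v + q2 * (t - d))
    v <- v + q2 * (D - d)
    u <- seq$T - t                       # time remaining on the down ramp
    v + q2 * d / 3 - q2 * u^3 / (3 * d^2)
  }
  F(t1) - F(t0)
}

#' The ex vivo multi-time acquisition protocol
#'
#' Returns the acquisition scheme used throughout the package's worked
#' examples: pulse width 4.5 ms, pulse separations 7.5, 11 and 16 ms, low
#' b-values 0.1, 0.5, 1, 2, 3, 4 and 5 ms/um^2 at every separation, and
#' dense high-b shells generated linearly in `b^(-1/2)` (in um/ms^(1/2)):
#' from 0.4 to 0.15 in steps of 0.025 for Delta = 7.5 ms (11 shells), from
#' 0.4 to 0.125 for Delta = 11 ms (12 shells), and from 0.4 to 0.1 for
#' Delta = 16 ms with the spacing halved between 0.3 and 0.1 (21 shells).
#' The grids are generated from these endpoints and steps, not hard-coded.
#'
#' @param include_lowest_b Keep the b = 0.1 ms/um^2 point in every shell
#'   (default `TRUE`); the returned table carries a `lowest_b` attribute
#'   flagging this choice.
#' @param n_directions Nominal direction count per shell, stored as an
#'   attribute (the models operate on powder averages).
#' @return An object of class `"acq_protocol"`: a data frame with columns
#'   `b`, `Delta`, `delta`, sorted by `Delta` then `b`, with unique
#'   `(b, Delta, delta)` rows.
#' @export
exvivo_protocol <- function(include_lowest_b = TRUE, n_directions = 30) {
  delta <- 4.5
  low_b <- c(0.1, 0.5, 1, 2, 3, 4, 5)
  if (!include_lowest_b) low_b <- low_b[-1]
  grids <- list(
    `7.5` = seq(0.4, 0.15, by = -0.025),
    `11`  = seq(0.4, 0.125, by = -0.025),
    `16`  = c(seq(0.4, 0.3, by = -0.025),
              seq(0.3 - 0.0125, 0.1, by = -0.0125)))
  rows <- lapply(names(grids), function(nm) {
    Delta <- as.numeric(nm)
    b <- sort(c(low_b, grids[[nm]]^-2))
    data.frame(b = b, Delta = Delta, delta = delta)
  })
  proto <- do.call(rbind, rows)
  proto <- proto[order(proto$Delta, proto$b), , drop = FALSE]
  rownames(proto) <- NULL
  structure(proto, class = c("acq_protocol", "data.frame"),
            n_directions = n_directions, lowest_b = include_lowest_b)
}

#' Assemble an acquisition protocol from b, Delta, delta vectors
#'
#' @param b,Delta,delta Numeric vectors (recycled to a common length) of
#'   diffusion weightings (ms/um^2) and pulse timings (ms).
#' @return An `"acq_protocol"` data frame sorted by `Delta` then `b` with
#'   duplicate `(b, Delta, delta)` rows removed.
#' @export
acq_protocol <- function(b, Delta, delta) {
  proto <- data.frame(b = b, Delta = Delta, delta = delta)
  if (any(proto$delta <= 0 | proto$Delta <= 0)) stop("timings must be positive")
  if (any(proto$delta > proto$Delta)) stop("'delta' must not exceed 'Delta'")
  if (any(proto$b < 0)) stop("'b' must be non-negative")
  proto <- unique(proto)
  proto <- proto[order(proto$Delta, proto$b), , drop = FALSE]
  rownames(proto) <- NULL
  structure(proto, class = c("acq_protocol", "data.frame"))
}

#' Read/write an acquisition protocol as delimited text
#'
#' Plain whitespace- or comma-delimited text with a header line naming the
#' columns `b`, `Delta`, `delta`; round-trips at 12 significant digits.
#'
#' @param file Path to the protocol file.
#' @return For `read_protocol`, an `"acq_protocol"` data frame.
#' @export
read_protocol <- function(file) {
  tab <- .read_delim_auto(file)
  need <- c("b", "Delta", "delta")
  if (!all(need %in% names(tab))) stop("protocol file must have columns b, Delta, delta")
  acq_protocol(tab$b, tab$Delta, tab$delta)
}

#' @rdname read_protocol
#' @param proto An `"acq_protocol"` data frame.
#' @export
write_protocol <- function(proto, file) {
  .write_delim(as.data.frame(proto)[c("b", "Delta", "delta")], file)
  invisible(file)
}

# -- shared delimited-text helpers ------------------------------------------

.read_delim_auto <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

.write_delim <- function(df, file) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12, format = "g"))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
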
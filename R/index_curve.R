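# The probability-to-index transform: a decreasing exponential
# f(x) = A + B * exp(C * x) anchored at three (probability, index) points,
# plus the four-colour traffic-light discretization of the index scale.

#' Default anchors of the well-being index curve
#'
#' Zero disease probability maps to index 5, certainty of disease to -5,
#' and a 55% probability to the orange/red threshold -2.5. The non-linear
#' placement of the third anchor makes the index fall steeply at moderate
#' risk, flagging danger early: a false alarm for a healthy person is
#' preferred over reassuring someone at high risk.
#'
#' @return A data.frame with columns `x` (probability) and `f` (index).
#' @export
default_anchors <- function() {
  data.frame(x = c(0, 1, 0.55), f = c(5, -5, -2.5))
}

#' Fit the anchored exponential index curve
#'
#' Solves f(x) = A + B exp(C x) exactly through three anchors: A and B are
#' eliminated analytically (B = (f2 - f1) / (exp(C x2) - exp(C x1)),
#' A = f1 - B exp(C x1)), leaving a one-dimensional root-find in C over a
#' wide bracket of negative rates. Anchors admitting no decreasing
#' exponential (e.g. collinear points) fail explicitly, never silently.
#'
#' @param anchors Data.frame with columns `x` (probability in `[0, 1]`) and
#'   `f` (index in `[-5, 5]`); exactly 3 rows with distinct `x`.
#' @param bracket Search interval for the rate C (default `c(-50, -1e-6)`).
#' @return An object of class `cwb_index_curve` with elements `A`, `B`,
#'   `C` and `anchors`. With the default anchors the fitted constants are
#'   A = -7.052755, B = 12.05276, C = -1.77011 (to the printed precision).
#' @examples
#' curve <- fit_index_curve()
#' round(c(curve$A, curve$B, curve$C), 5)
#' @export
fit_index_curve <- function(anchors = default_anchors(),
                            bracket = c(-50, -1e-6)) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("x", "f") %in% names(anchors)))
  if (nrow(anchors) != 3L) stop("exactly 3 anchors are required")
  if (anyDuplicated(anchors$x)) stop("anchor x values must be distinct")
  x <- anchors$x; f <- anchors$f

  coefs_at <- function(C) {
    B <- (f[2] - f[1]) / (exp(C * x[2]) - exp(C * x[1]))
    A <- f[1] - B * exp(C * x[1])
    c(A = A, B = B)
  }
  residual <- function(C) {
    ab <- coefs_at(C)
    ab[["A"]] + ab[["B"]] * exp(C * x[3]) - f[3]
  }
  r_lo <- residual(bracket[1]); r_hi <- residual(bracket[2])
  if (!is.finite(r_lo) || !is.finite(r_hi) || sign(r_lo) == sign(r_hi))
    stop("anchors admit no exponential solution in the search bracket ",
         "(degenerate, e.g. collinear, anchors)")
  C <- stats::uniroot(residual, bracket, tol = 1e-12)$root
  ab <- coefs_at(C)
  curve <- structure(list(A = unname(ab["A"]), B = unname(ab["B"]), C = C,
                          anchors = anchors),
                     class = "cwb_index_curve")
  resid <- abs(index_of(curve, x, clamp = FALSE) - f)
  if (any(resid > 1e-6))
    stop("fitted curve fails to reproduce its anchors (max residual ",
         format(max(resid)), ")")
  curve
}

#' Evaluate the index curve at a disease probability
#'
#' Computes A + B exp(C p) and clamps floating-point slop to the `[-5, 5]`
#' index scale. For the default curve the transform is strictly decreasing:
#' higher disease probability, lower well-being.
#'
#' @param curve A `cwb_index_curve`.
#' @param p Probability (vectorized) in `[0, 1]`.
#' @param clamp Clamp the result to `[-5, 5]` (default TRUE).
#' @return Numeric index values.
#' @examples
#' curve <- fit_index_curve()
#' index_of(curve, c(0, 0.55, 1))
#' @export
index_of <- function(curve, p, clamp = TRUE) {
  stopifnot(inherits(curve, "cwb_index_curve"))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  v <- curve$A + curve$B * exp(curve$C * p)
  if (clamp) v <- pmin(pmax(v, -5), 5)
  v
}

#' Colour band of an index value
#'
#' The four-level traffic-light discretization of the index scale, with
#' thresholds 2.5, 0 and -2.5. Bands are lower-inclusive: red `[-5, -2.5)`,
#' orange `[-2.5, 0)`, yellow `[0, 2.5)`, green `[2.5, 5]`.
#'
#' @param index Numeric (vectorized) in `[-5, 5]`.
#' @return Factor with ordered levels `red < orange < yellow < green`.
#' @examples
#' colour_of(c(3.68, -1.73, 0))
#' @export
colour_of <- function(index) {
  if (any(is.na(index)) || any(index < -5 - 1e-9 | index > 5 + 1e-9))
    stop("index values must lie in [-5, 5]")
  bands <- c("red", "orange", "yellow", "green")
  i <- findInterval(index, c(-2.5, 0, 2.5)) + 1L
  factor(bands[i], levels = bands, ordered = TRUE)
}

#' @export
print.cwb_index_curve <- function(x, ...) {
  cat(sprintf("Index curve: f(p) = %.6f + %.5f * exp(%.5f * p)\n",
              x$A, x$B, x$C))
  cat("  anchors: ", paste(sprintf("p=%g -> %g", x$anchors$x, x$anchors$f),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Persist an index curve as a small text file
#'
#' Three `name=value` lines for A, B, C followed by one line per anchor.
#'
#' @param curve A `cwb_index_curve`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_index_curve <- function(curve, path) {
  lines <- c(sprintf("A=%.17g", curve$A),
             sprintf("B=%.17g", curve$B),
             sprintf("C=%.17g", curve$C),
             sprintf("anchor=%.17g,%.17g", curve$anchors$x, curve$anchors$f))
  write_atomic(lines, path)
}

#' Read an index curve written by [write_index_curve()]
#' @param path File path.
#' @return A `cwb_index_curve`.
#' @export
read_index_curve <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    as.numeric(sub(paste0("^", key, "="), "",
                   grep(paste0("^", key, "="), lines, value = TRUE)))
  }
  anc_lines <- grep("^anchor=", lines, value = TRUE)
  anc <- do.call(rbind, lapply(strsplit(sub("^anchor=", "", anc_lines), ","),
                               as.numeric))
  structure(list(A = val("A"), B = val("B"), C = val("C"),
                 anchors = data.frame(x = anc[, 1], f = anc[, 2])),
            class = "cwb_index_curve")
}
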
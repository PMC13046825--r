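# Bliss-independence synergy scoring of endpoint permeabilization dose
# matrices. The plain Bliss reference model is implemented (expected
# combination fraction a + b - a*b); smoothing corrections applied by web
# synergy tools are deliberately not reproduced, so scores are comparable in
# sign and ordering rather than numerically identical to such tools.

#' Convert percent to a response fraction
#'
#' Divides by 100 and clips to \[0, 1\]. Clipping happens here, at the
#' synergy stage, so raw endpoint data stay untouched upstream.
#'
#' @param percent numeric, finite.
#' @export
to_fraction <- function(percent) {
  if (any(!is.finite(percent))) stop("non-finite input", call. = FALSE)
  pmin(pmax(percent / 100, 0), 1)
}

#' Bliss excess for a single combination
#'
#' \deqn{excess = f_{AB} - (f_A + f_B - f_A f_B)}
#' where all quantities are response fractions in \[0, 1\]. Positive excess
#' indicates synergy beyond independence; the reference is symmetric in the
#' two monotherapies.
#'
#' @param observed_ab observed combination response fraction.
#' @param a,b monotherapy response fractions.
#' @export
bliss_excess <- function(observed_ab, a, b) {
  vals <- c(observed_ab, a, b)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("responses must be fractions in [0, 1]", call. = FALSE)
  observed_ab - (a + b - a * b)
}

#' Construct a two-compound dose matrix
#'
#' Rows index compound A doses, columns compound B doses; both grids are
#' ascending and include 0, so the first row/column hold the monotherapy
#' margins and `response[1, 1]` is the double vehicle.
#'
#' @param doses_a,doses_b ascending dose grids (uM) including 0.
#' @param response matrix of fractional responses,
#'   `length(doses_a)` x `length(doses_b)`; values are clipped to \[0, 1\]
#'   here (the synergy stage owns clipping, so raw endpoint data upstream
#'   stay untouched).
#' @return object of class `dose_matrix`.
#' @export
dose_matrix <- function(doses_a, doses_b, response) {
  response <- as.matrix(response)
  if (any(is.finite(response)))
    response[] <- pmin(pmax(response, 0), 1)
  if (!0 %in% doses_a || !0 %in% doses_b)
    stop("missing margins: both dose grids must include 0", call. = FALSE)
  if (is.unsorted(doses_a) || is.unsorted(doses_b))
    stop("dose grids must be ascending", call. = FALSE)
  if (nrow(response) != length(doses_a) ||
      ncol(response) != length(doses_b))
    stop("response matrix dimensions must match the dose grids",
         call. = FALSE)
  if (any(!is.finite(response)))
    stop("all responses must be finite", call. = FALSE)
  dimnames(response) <- list(a = doses_a, b = doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b, response = response),
            class = "dose_matrix")
}

#' Per-cell Bliss excess and matrix-level synergy score
#'
#' Each combination cell (both doses > 0) is compared with the independence
#' expectation of its own row/column monotherapy margins. The summary score
#' is the mean excess over all combination cells, times 100 (percentage
#' points); positive = synergy, negative = antagonism.
#'
#' @param m a [dose_matrix()] of fractional responses.
#' @return list with `excess` (matrix, `NA` in margin cells) and `score`.
#' @export
synergy_matrix <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  resp <- m$response
  ia <- which(m$doses_a > 0); ib <- which(m$doses_b > 0)
  if (length(ia) == 0 || length(ib) == 0)
    stop("dose matrix has no combination cells", call. = FALSE)
  excess <- matrix(NA_real_, nrow(resp), ncol(resp),
                   dimnames = dimnames(resp))
  i0 <- which(m$doses_a == 0)[1]; j0 <- which(m$doses_b == 0)[1]
  for (i in ia) for (j in ib)
    excess[i, j] <- bliss_excess(resp[i, j], resp[i, j0], resp[i0, j])
  list(excess = excess, score = 100 * mean(excess[ia, ib]))
}
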
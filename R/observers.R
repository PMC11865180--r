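#' Synthetic observers for the Yes/No ensemble task
#'
#' Two generative response rules are available, one per hypothesis about how
#' probes are recognised.
#'
#' `observer_averaging()` realises the perceptual-averaging hypothesis: the
#' observer compares the probe to a stored mean of the display, and the
#' probability of responding "No" follows the three-parameter log-logistic
#' [loglogistic()] of the probe's ordinal distance from the mean. The default
#' parameters are anchored so that p(No) at distances 0/1/2 equals
#' 0.22/0.30/0.58, the orientation-task marginal means the analysis pipeline
#' is designed to detect.
#'
#' `observer_similarity()` realises the similarity hypothesis: the probe is
#' confused independently with each of the two old items, with confusion
#' probability `g(d)` a non-increasing kernel of the ordinal distance `d` to
#' that item, so p(No) = (1 - g(d1)) * (1 - g(d2)). Under this rule the
#' product identity p(No|M) = p(No|N1A) * p(No|N1B) holds by construction
#' whenever the kernel is truncated (g = 0 at the N1 probes' far-item
#' distance).
#'
#' When a trial varies an irrelevant feature dimension as well (factorial
#' designs), the response probability is a mixture
#' `(1 - lambda) * p_relevant + lambda * p_irrelevant`, with the irrelevant
#' term computed from `irrelevant` (another observer; defaults to the same
#' rule and parameters) applied to the irrelevant probe's distances. The
#' default weight `lambda = 0.15` keeps the relevant effect dominant while
#' giving factorial analyses a real irrelevant main effect to detect.
#'
#' @param a,b,c Log-logistic floor, location and slope (see [loglogistic()]).
#' @param kernel Numeric vector `g(0), g(1), ...` of confusion probabilities
#'   by ordinal distance; distances beyond its length have `g = 0`. Must lie
#'   in `[0, 1]` and be non-increasing.
#' @param lambda Mixture weight of the irrelevant dimension in `[0, 1]`.
#' @param irrelevant Observer applied to the irrelevant dimension (default:
#'   this observer itself).
#' @return An object of class `ec_observer`.
#' @export
#' @examples
#' obs <- observer_averaging()
#' response_prob(obs, dist_from_mean = 0:5)
observer_averaging <- function(a = 0.2034483, b = 3.8528039, c = 1.8718023,
                               lambda = 0.15, irrelevant = NULL) {
  stopifnot(a >= 0, a <= 1, c >= 0, lambda >= 0, lambda <= 1)
  structure(
    list(rule = "averaging", a = a, b = b, c = c,
         lambda = lambda, irrelevant = irrelevant),
    class = "ec_observer"
  )
}

#' @rdname observer_averaging
#' @export
observer_similarity <- function(kernel = c(0.80, 0.45, 0.15, 0.05, 0),
                                lambda = 0.15, irrelevant = NULL) {
  stopifnot(all(kernel >= 0), all(kernel <= 1))
  if (is.unsorted(rev(kernel))) {
    stop("confusion kernel must be non-increasing in distance", call. = FALSE)
  }
  structure(
    list(rule = "similarity", kernel = kernel,
         lambda = lambda, irrelevant = irrelevant),
    class = "ec_observer"
  )
}

#' @export
print.ec_observer <- function(x, ...) {
  if (x$rule == "averaging") {
    cat(sprintf("<ec_observer: averaging, a=%.4g b=%.4g c=%.4g lambda=%.2f>\n",
                x$a, x$b, x$c, x$lambda))
  } else {
    cat(sprintf("<ec_observer: similarity, g=(%s) lambda=%.2f>\n",
                paste(signif(x$kernel, 3), collapse = ", "), x$lambda))
  }
  invisible(x)
}

# Kernel lookup with zero tail.
kernel_at <- function(kernel, d) {
  out <- rep(0, length(d))
  inside <- d < length(kernel)
  out[inside] <- kernel[d[inside] + 1L]
  out
}

#' Response probability p(No) of an observer
#'
#' Computes the single-dimension probability of a "No" response. The
#' averaging rule needs the probe's ordinal distance from the mean; the
#' similarity rule needs the distances to the two old items.
#'
#' @param observer An `ec_observer`.
#' @param dist_from_mean Integer vector of distances from the mean.
#' @param d_lower,d_upper Integer vectors of distances to the lower and upper
#'   old item (similarity rule only).
#' @return Numeric vector of p(No) values in `[0, 1]`.
#' @export
response_prob <- function(observer, dist_from_mean = NULL,
                          d_lower = NULL, d_upper = NULL) {
  stopifnot(inherits(observer, "ec_observer"))
  p <- if (observer$rule == "averaging") {
    stopifnot(!is.null(dist_from_mean))
    loglogistic(dist_from_mean, observer$a, observer$b, observer$c)
  } else {
    stopifnot(!is.null(d_lower), !is.null(d_upper))
    (1 - kernel_at(observer$kernel, d_lower)) *
      (1 - kernel_at(observer$kernel, d_upper))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("observer produced a probability outside [0, 1]", call. = FALSE)
  }
  p
}
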
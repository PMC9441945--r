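#' Activation functions
#'
#' Elementwise non-linearities used throughout the detector family.  The
#' baseline network uses Swish-1 (SiLU), \eqn{x \cdot \sigma(x)}; the final
#' MGA-YOLO network replaces every activation with the Gaussian Error Linear
#' Unit, \eqn{x \cdot \Phi(x)} with \eqn{\Phi} the standard normal CDF.  GELU
#' is well approximated by \eqn{x \cdot \sigma(1.702 x)}, so the two differ
#' only in the steepness of the underlying sigmoid; both share the
#' characteristic non-monotonic dip for small negative inputs.
#'
#' @param x numeric vector or array.
#' @param kind one of `"gelu"`, `"swish1"` (alias `"silu"`), `"leaky_relu"`,
#'   `"relu"`, `"hswish"`, `"sigmoid"`, `"none"`.
#' @return `activation()` applies the chosen non-linearity elementwise and
#'   returns an object shaped like `x`.
#' @examples
#' act_gelu(c(-1, 0, 1))
#' act_swish1(2)
#' activation(seq(-3, 3, by = 1), "gelu")
#' @export
activation <- function(x, kind = c("gelu", "swish1", "silu", "leaky_relu",
                                   "relu", "hswish", "sigmoid", "none")) {
  kind <- match.arg(kind)
  switch(kind,
    gelu = act_gelu(x),
    swish1 = act_swish1(x),
    silu = act_swish1(x),
    leaky_relu = act_leaky_relu(x),
    relu = pmax(x, 0),
    hswish = x * pmin(pmax(x + 3, 0), 6) / 6,
    sigmoid = stats::plogis(x),
    none = x
  )
}

#' @rdname activation
#' @export
act_gelu <- function(x) x * stats::pnorm(x)

#' @rdname activation
#' @export
act_swish1 <- function(x) x * stats::plogis(x)

#' @rdname activation
#' @param slope negative-side slope of the leaky rectifier.
#' @export
act_leaky_relu <- function(x, slope = 0.1) ifelse(x > 0, x, slope * x)

# derivative of each activation, evaluated at the pre-activation input
act_grad <- function(x, kind) {
  switch(kind,
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    swish1 = ,
    silu = {
      s <- stats::plogis(x)
      s * (1 + x * (1 - s))
    },
    leaky_relu = ifelse(x > 0, 1, 0.1),
    relu = as.numeric(x > 0),
    hswish = ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6)),
    sigmoid = {
      s <- stats::plogis(x)
      s * (1 - s)
    },
    none = rep(1, length(x))
  )
}
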
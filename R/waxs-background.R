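#' Subtract a smooth diffuse background
#'
#' Fits a background model to the profile intensities inside user-chosen
#' anchor windows (q intervals free of Bragg reflections) and subtracts it
#' across the whole profile. The default model is a power law plus constant,
#' `A q^-p + c`, matching the smooth diffuse scatter under equatorial
#' cellulose profiles; `"linear"` fits a straight line instead. The fitted
#' model and anchors are recorded in the profile metadata.
#'
#' @param profile A [radial_profile()].
#' @param anchor_windows List of at least two `c(qmin, qmax)` intervals,
#'   each containing at least 3 profile points.
#' @param model `"power-law"` (default) or `"linear"`.
#' @return The background-subtracted [radial_profile()].
#' @export
subtract_background <- function(profile,
                                anchor_windows = list(c(5, 6.5), c(33.5, 35)),
                                model = c("power-law", "linear")) {
  stopifnot(inherits(profile, "radial_profile"))
  model <- match.arg(model)
  if (!is.list(anchor_windows) || length(anchor_windows) < 2L) {
    abort("need at least two anchor windows", class = "fs_config")
  }
  in_anchor <- rep(FALSE, nrow(profile))
  for (w in anchor_windows) {
    sel <- profile$q >= w[1] & profile$q <= w[2]
    if (sum(sel) < 3L) {
      abort(sprintf("anchor window [%g, %g] contains fewer than 3 points",
                    w[1], w[2]), class = "fs_config")
    }
    in_anchor <- in_anchor | sel
  }
  qa <- profile$q[in_anchor]
  ya <- profile$intensity[in_anchor]
  bg <- fit_background_model(qa, ya, model)
  out <- profile
  out$intensity <- profile$intensity - bg$fun(profile$q)
  set_profile_meta(out, background = list(model = bg$model,
                                          params = bg$params,
                                          anchors = anchor_windows))
}

fit_background_model <- function(qa, ya, model) {
  if (model == "power-law") {
    # power-law + constant; falls back to linear when unsupported by the data
    c0 <- max(min(ya), 0)
    a0 <- max((max(ya) - c0) * min(qa)^1.5, 1e-6)
    res_fn <- function(p) p[1] * qa^(-p[2]) + p[3] - ya
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, 1.5, c0), fn = res_fn,
                         lower = c(0, 0.1, -Inf), upper = c(Inf, 6, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      p <- setNames(fit$par, c("amplitude", "exponent", "constant"))
      return(list(model = "power-law", params = p,
                  fun = function(q) p[[1]] * q^(-p[[2]]) + p[[3]]))
    }
  }
  b <- setNames(coef(lm(ya ~ qa)), c("intercept", "slope"))
  list(model = "linear", params = b,
       fun = function(q) b[[1]] + b[[2]] * q)
}
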
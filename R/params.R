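#' Diffusion-model parameter set
#'
#' Bundles the seven parameters of the two-boundary Wiener diffusion model for
#' one experimental condition, plus the diffusion (scaling) constant `s`.
#' The lower boundary sits at 0 and the upper at `a`; the accumulator starts at
#' `zr * a`. The upper boundary is associated with the "old" response
#' throughout, the lower with "new". Drift varies across trials as
#' Normal(`v`, `sv`), the start point uniformly with range `sz` (absolute
#' evidence units), and the non-decision time uniformly with range `st`.
#'
#' All evidence-scale parameters (`v`, `a`, `sv`, `sz`) are expressed relative
#' to `s`: multiplying them together with `s` by a common factor leaves every
#' predicted choice probability and response-time distribution unchanged (see
#' [rescale_params()]). Times are in seconds.
#'
#' @param v Mean drift rate (evidence units per second, signed; positive values
#'   drift toward the upper/"old" boundary).
#' @param a Boundary separation (> 0).
#' @param zr Relative start point `z / a`, strictly between 0 and 1. 0.5 is
#'   unbiased.
#' @param t0 Mean non-decision time in seconds (>= 0).
#' @param sv Across-trial standard deviation of drift (>= 0).
#' @param sz Across-trial range of the start point, in absolute evidence units
#'   (uniform; the start-point support must stay inside the boundaries).
#' @param st Across-trial range of the non-decision time in seconds (uniform;
#'   `t0 - st/2` must be non-negative).
#' @param s Diffusion constant (> 0). Defaults to 0.1, the scale on which
#'   parameters are conventionally reported in the recognition-memory
#'   literature.
#'
#' @return An object of class `diffusion_params` (a named list).
#' @examples
#' p <- diffusion_params(v = 0.04, a = 0.14, zr = 0.66, t0 = 0.6)
#' wfpt_absorption(p)
#' @export
diffusion_params <- function(v, a, zr = 0.5, t0 = 0.3,
                             sv = 0, sz = 0, st = 0, s = 0.1) {
  p <- list(v = v, a = a, zr = zr, t0 = t0, sv = sv, sz = sz, st = st, s = s)
  validate_diffusion_params(p)
  structure(p, class = "diffusion_params")
}

validate_diffusion_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("Non-finite or non-scalar diffusion parameter(s): ",
                 paste(names(p)[!num], collapse = ", ")))
  }
  with(p, {
    if (a <= 0) abort("Boundary separation `a` must be positive.")
    if (zr <= 0 || zr >= 1) abort("Relative start point `zr` must lie in (0, 1).")
    if (t0 < 0) abort("Non-decision time `t0` must be non-negative.")
    if (s <= 0) abort("Diffusion constant `s` must be positive.")
    if (sv < 0 || sz < 0 || st < 0)
      abort("Variability parameters `sv`, `sz`, `st` must be non-negative.")
    if (zr * a - sz / 2 <= 0 || zr * a + sz / 2 >= a)
      abort("Start-point support `zr * a +/- sz/2` must lie strictly inside (0, a).")
    if (t0 - st / 2 < 0)
      abort("Non-decision support requires `t0 - st/2 >= 0`.")
  })
  invisible(p)
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("<diffusion_params>\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 3), " = ",
             format(vals, digits = 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Rescale a parameter set to a new diffusion constant
#'
#' The diffusion constant `s` is an arbitrary scale: `v`, `a`, `sv` and `sz`
#' scale linearly with it while `zr`, `t0` and `st` are unchanged. All
#' predicted choice probabilities and RT distributions are invariant under
#' this transformation; rescaling only changes the units in which evidence is
#' expressed (e.g. between the `s = 1` and `s = 0.1` reporting conventions).
#'
#' @param p A [diffusion_params()] object.
#' @param s_new New diffusion constant (> 0).
#' @return A `diffusion_params` object on the new scale.
#' @examples
#' p <- diffusion_params(v = 0.4, a = 1.4, s = 1)
#' rescale_params(p, 0.1)
#' @export
rescale_params <- function(p, s_new) {
  stopifnot(inherits(p, "diffusion_params"))
  if (!is.numeric(s_new) || length(s_new) != 1 || !is.finite(s_new) || s_new <= 0)
    abort("`s_new` must be a positive number.")
  k <- s_new / p$s
  diffusion_params(v = p$v * k, a = p$a * k, zr = p$zr, t0 = p$t0,
                   sv = p$sv * k, sz = p$sz * k, st = p$st, s = s_new)
}

# Replace selected fields, revalidating.
set_params <- function(p, ...) {
  new <- list(...)
  for (nm in names(new)) p[[nm]] <- new[[nm]]
  validate_diffusion_params(p)
  structure(p, class = "diffusion_params")
}

# Boundary labels and their fixed mapping to responses ("old" = upper).
boundary_labels <- c("upper", "lower")

boundary_to_response <- function(boundary) {
  c(upper = "old", lower = "new")[boundary]
}

response_to_boundary <- function(response) {
  c(old = "upper", new = "lower")[response]
}
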
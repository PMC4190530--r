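#' One-dimensional model potentials for Brownian pulling simulations
#'
#' Constructors for the analytic free-energy landscapes that
#' [sim_pull_ensemble()] pulls a particle across. Each returns a `pmf_form`
#' object bundling the potential \eqn{U(x)}, its gradient and its maximum
#' curvature (used for the integrator stability bound). Units are kcal/mol
#' for energies and Angstrom for distances.
#'
#' * `pmf_flat()`: \eqn{U(x) = 0}. Pulling on it costs no reversible work.
#' * `pmf_quadratic(a, x0)`: \eqn{U(x) = a (x - x_0)^2 / 2}, a single harmonic
#'   well of curvature `a` (kcal/mol/A^2) centred at `x0`.
#' * `pmf_double_well(height, half_width, center)`: the quartic
#'   \eqn{U(x) = h [((x - c)^2 - w^2)^2] / w^4} with minima at
#'   \eqn{c \pm w} and a barrier of `height` kcal/mol at \eqn{x = c} —
#'   a minimal model of a bound/unbound pair of states.
#'
#' @param a Curvature of the harmonic well, kcal/mol/A^2 (> 0).
#' @param x0,center Location parameter, Angstrom.
#' @param height Barrier height separating the two wells, kcal/mol (> 0).
#' @param half_width Half the distance between the two minima, Angstrom (> 0).
#' @return An object of class `pmf_form` with elements `name`, `energy`,
#'   `gradient`, `curvature_max` (a function of an x-range) and `params`.
#' @name pmf_forms
#' @examples
#' U <- pmf_quadratic(a = 0.5)
#' U$energy(5) # 6.25 kcal/mol
NULL

.new_pmf_form <- function(name, energy, gradient, curvature_max, params) {
  structure(
    list(name = name, energy = energy, gradient = gradient,
         curvature_max = curvature_max, params = params),
    class = "pmf_form"
  )
}

#' @rdname pmf_forms
#' @export
pmf_flat <- function() {
  .new_pmf_form(
    "flat",
    energy = function(x) rep(0, length(x)),
    gradient = function(x) rep(0, length(x)),
    curvature_max = function(range) 0,
    params = list()
  )
}

#' @rdname pmf_forms
#' @export
pmf_quadratic <- function(a, x0 = 0) {
  .check_scalar(a, "a", positive = TRUE)
  .check_scalar(x0, "x0")
  .new_pmf_form(
    "quadratic",
    energy = function(x) 0.5 * a * (x - x0)^2,
    gradient = function(x) a * (x - x0),
    curvature_max = function(range) a,
    params = list(a = a, x0 = x0)
  )
}

#' @rdname pmf_forms
#' @export
pmf_double_well <- function(height, half_width, center = 0) {
  .check_scalar(height, "height", positive = TRUE)
  .check_scalar(half_width, "half_width", positive = TRUE)
  .check_scalar(center, "center")
  h <- height
  w <- half_width
  .new_pmf_form(
    "double_well",
    energy = function(x) h * ((x - center)^2 - w^2)^2 / w^4,
    gradient = function(x) 4 * h * ((x - center)^2 - w^2) * (x - center) / w^4,
    curvature_max = function(range) {
      # U'' = 4h(3(x-c)^2 - w^2)/w^4, monotone in |x - c|: max at range ends
      xs <- c(range, center)
      max(4 * h * (3 * (xs - center)^2 - w^2) / w^4)
    },
    params = list(height = h, half_width = w, center = center)
  )
}

#' @export
print.pmf_form <- function(x, ...) {
  cat("<pmf_form> ", x$name, "\n", sep = "")
  if (length(x$params)) {
    cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
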
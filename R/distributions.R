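#' Gamma cost-uncertainty spec
#'
#' Unit costs are modelled as Gamma distributions with mean equal to the
#' estimated cost and, by default, a standard deviation of 20% of the mean.
#' With the default SD the shape parameter is (mean/sd)^2 = 25 and the scale
#' is mean/25.
#'
#' @param mean Estimated cost, thousand LBP, > 0.
#' @param sd Standard deviation, thousand LBP, > 0; defaults to `0.2 * mean`.
#' @return An object of class `gamma_spec`.
#' @export
gamma_spec <- function(mean, sd = 0.2 * mean) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) || mean <= 0) {
    stop("gamma spec: mean must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd <= 0) {
    stop("gamma spec: sd must be a positive number", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd), class = "gamma_spec")
}

#' Sample from a Gamma cost spec
#'
#' @param spec A [gamma_spec()].
#' @param n Number of draws.
#' @return `n` strictly positive cost draws.
#' @export
sample_gamma <- function(spec, n = 1) {
  stopifnot(inherits(spec, "gamma_spec"))
  shape <- (spec$mean / spec$sd)^2
  scale <- spec$sd^2 / spec$mean
  stats::rgamma(n, shape = shape, scale = scale)
}

#' Beta-PERT bounds from the 40% min-max rule
#'
#' Branch probability uncertainty uses a Beta-PERT whose mode is the point
#' estimate with a min-max range totalling 40% of the mode: min = 0.8 x mode
#' and max = 1.2 x mode, clamped to the unit interval.
#'
#' @param mode Point-estimate probability, strictly inside (0, 1).
#' @param relative_range Total min-max range relative to the mode
#'   (default 0.4).
#' @return `c(min, max)`.
#' @export
make_pert_bounds <- function(mode, relative_range = 0.4) {
  if (!is.numeric(mode) || length(mode) != 1 || mode <= 0 || mode >= 1) {
    stop("PERT mode must lie strictly inside (0, 1)", call. = FALSE)
  }
  half <- relative_range / 2
  c(min = max(0, (1 - half) * mode), max = min(1, (1 + half) * mode))
}

#' Beta-PERT spec
#'
#' Standard PERT construction: an underlying Beta with
#' `alpha = 1 + shape * (mode - min)/(max - min)` and
#' `beta = 1 + shape * (max - mode)/(max - min)`, rescaled to `[min, max]`.
#' The conventional shape (lambda) is 4, giving mean `(min + 4 mode + max)/6`.
#'
#' @param mode Probability in (0, 1).
#' @param min,max Support bounds; default to [make_pert_bounds()] of the mode.
#' @param shape PERT lambda (default 4).
#' @return An object of class `beta_pert_spec`.
#' @export
beta_pert_spec <- function(mode, min = NULL, max = NULL, shape = 4) {
  if (is.null(min) || is.null(max)) {
    b <- make_pert_bounds(mode)
    if (is.null(min)) min <- b[["min"]]
    if (is.null(max)) max <- b[["max"]]
  }
  if (!(min <= mode && mode <= max)) {
    stop("PERT spec requires min <= mode <= max", call. = FALSE)
  }
  if (!(min < max)) stop("PERT spec: degenerate range (min >= max)",
                         call. = FALSE)
  if (min < 0 || max > 1) stop("PERT probability support must lie in [0,1]",
                               call. = FALSE)
  if (shape <= 0) stop("PERT shape must be positive", call. = FALSE)
  structure(list(mode = mode, min = min, max = max, shape = shape),
            class = "beta_pert_spec")
}

#' Sample from a Beta-PERT spec
#'
#' @param spec A [beta_pert_spec()].
#' @param n Number of draws.
#' @return `n` draws inside `[spec$min, spec$max]`.
#' @export
sample_beta_pert <- function(spec, n = 1) {
  stopifnot(inherits(spec, "beta_pert_spec"))
  rng <- spec$max - spec$min
  a <- 1 + spec$shape * (spec$mode - spec$min) / rng
  b <- 1 + spec$shape * (spec$max - spec$mode) / rng
  spec$min + rng * stats::rbeta(n, a, b)
}

#' Dirichlet spec for three or more branches
#'
#' Joint uncertainty over k >= 3 mutually exclusive branch probabilities,
#' with concentration parameters equal to the original estimates. Following
#' the convention that Delphi estimates are elicited as percentages, alphas
#' are taken on the percent scale (e.g. 40/50/10, concentration 100).
#'
#' @param alphas Positive concentration parameters, one per branch (k >= 3).
#' @return An object of class `dirichlet_spec`.
#' @export
dirichlet_spec <- function(alphas) {
  alphas <- as.numeric(alphas)
  if (length(alphas) < 3) {
    stop("dirichlet spec needs at least 3 branches", call. = FALSE)
  }
  if (any(!is.finite(alphas)) || any(alphas <= 0)) {
    stop("dirichlet spec: all alphas must be positive", call. = FALSE)
  }
  structure(list(alphas = alphas), class = "dirichlet_spec")
}

#' Sample from a Dirichlet spec
#'
#' Uses the standard Gamma construction: independent Gamma(alpha_i, 1) draws
#' normalised by their sum. Each draw lies on the probability simplex and
#' component i has expectation alpha_i / sum(alpha).
#'
#' @param spec A [dirichlet_spec()].
#' @param n Number of draws.
#' @return An `n x k` matrix; rows sum to 1.
#' @export
sample_dirichlet <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dirichlet_spec"))
  k <- length(spec$alphas)
  g <- matrix(stats::rgamma(n * k, shape = rep(spec$alphas, each = n)),
              nrow = n, ncol = k)
  g / rowSums(g)
}

#' Resolve a two-branch node into complementary probabilities
#'
#' The Beta-PERT spec attaches to the branch whose estimate is listed; the
#' second branch takes the complement, so the two always sum to 1 exactly.
#'
#' @param node A `chance_node` with exactly two branches, the first carrying
#'   a `beta_pert_spec` (or a numeric estimate, auto-wrapped per the 40%
#'   min-max rule).
#' @param n Number of draws.
#' @return An `n x 2` matrix of `(p, 1 - p)` draws.
#' @export
resolve_two_branch <- function(node, n = 1) {
  stopifnot(inherits(node, "chance_node"))
  if (length(node$children) != 2) {
    stop(sprintf("node '%s' does not have exactly 2 branches", node$node_id),
         call. = FALSE)
  }
  specs <- vapply(node$probs, inherits, logical(1), what = "beta_pert_spec")
  if (sum(specs) > 1) {
    stop(sprintf("node '%s': both branches carry distribution specs",
                 node$node_id), call. = FALSE)
  }
  spec <- if (specs[1]) {
    node$probs[[1]]
  } else if (specs[2]) {
    # normalize so the spec is on the first returned column
    stop(sprintf("node '%s': spec must sit on the first branch",
                 node$node_id), call. = FALSE)
  } else {
    beta_pert_spec(node$probs[[1]])
  }
  p <- sample_beta_pert(spec, n)
  cbind(p, 1 - p, deparse.level = 0)
}
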
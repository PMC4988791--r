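#' Prior rule for an edge-appearance template
#'
#' Each rule describes how the intensity is expected to change across the
#' structure boundary in one modality: a sharp step or an exponential decay
#' with one or more length scales, between an inside and an outside level.
#' Levels are either absolute numbers (quantitative modalities such as QSM)
#' or expressed relative to "Self", the modal intensity inside the
#' structure (\code{"self"}, \code{"self*1.33"}, ...).
#'
#' @param modality modality label, e.g. \code{"t2s"} or \code{"qsm"}.
#' @param type \code{"step"} or \code{"exponential"}.
#' @param lambda decay scale(s) in mm for exponential rules; a rule with
#'   several scales expands to one mixture component per scale.
#' @param inside,outside level specification: a number, or a string
#'   \code{"self"} / \code{"self*<factor>"}.
#' @return An object of class \code{prior_rule}.
#' @export
prior_rule <- function(modality, type = c("step", "exponential"),
                       lambda = NULL, inside, outside) {
  type <- match.arg(type)
  if (type == "exponential") {
    if (is.null(lambda) || any(lambda <= 0))
      stop("exponential rules need positive lambda scale(s)")
  } else lambda <- NA_real_
  structure(list(modality = modality, type = type, lambda = lambda,
                 inside = parse_level(inside), outside = parse_level(outside)),
            class = "prior_rule")
}

parse_level <- function(x) {
  if (is.numeric(x)) return(list(kind = "absolute", value = x, factor = NA))
  x <- tolower(gsub("[ x]", "", as.character(x)))
  if (x == "self") return(list(kind = "self", value = NA, factor = 1))
  m <- regmatches(x, regexec("^self\\*([0-9.]+)$", x))[[1]]
  if (length(m) == 2L)
    return(list(kind = "self", value = NA, factor = as.numeric(m[2])))
  stop(sprintf("cannot parse level specification '%s'", x))
}

resolve_level <- function(level, self_value) {
  if (level$kind == "absolute") return(level$value)
  if (is.null(self_value) || is.na(self_value))
    stop("rule references Self but no self_value supplied")
  self_value * level$factor
}

#' Default prior rules for the three midbrain structures
#'
#' The rule table used for the substantia nigra, subthalamic nucleus and
#' red nucleus with T2*-weighted (relative, "Self"-scaled) and QSM
#' (absolute) contrasts.  QSM levels are in susceptibility-like arbitrary
#' units; T2* levels are relative to the modal intensity inside the
#' structure.
#'
#' @return Named list (per structure) of lists of \code{\link{prior_rule}}s.
#' @export
meshseg_default_rules <- function() {
  list(
    substantia_nigra = list(
      prior_rule("t2s", "exponential", lambda = c(1, 3),
                 inside = "self", outside = "self*1.33"),
      prior_rule("t2s", "exponential", lambda = 1,
                 inside = "self", outside = "self*0.67"),
      prior_rule("qsm", "exponential", lambda = c(1, 2),
                 inside = 0.15, outside = 0.05)),
    subthalamic_nucleus = list(
      prior_rule("t2s", "exponential", lambda = c(1, 3),
                 inside = "self", outside = "self*1.2"),
      prior_rule("t2s", "exponential", lambda = 1,
                 inside = "self", outside = "self*0.5"),
      prior_rule("qsm", "step", inside = 0.1, outside = 0.0),
      prior_rule("qsm", "exponential", lambda = c(1, 3),
                 inside = 0.1, outside = 0.0)),
    red_nucleus = list(
      prior_rule("t2s", "exponential", lambda = c(1, 3),
                 inside = "self", outside = "self*1.33"),
      prior_rule("qsm", "exponential", lambda = c(1, 3),
                 inside = 0.1, outside = 0.0)))
}

#' Default MRF weights per structure
#'
#' The subthalamic nucleus uses a higher weight because its reference mesh
#' is built at the native (finer) resolution.
#'
#' @return Named numeric vector of MRF weights.
#' @export
meshseg_default_mrf_weights <- function() {
  c(substantia_nigra = 10, subthalamic_nucleus = 100, red_nucleus = 10)
}

#' Model hyperparameters
#'
#' @param k profile sample count (used for the Wishart/Gamma shape
#'   \code{alpha0 = (k - 1)/2 + 3}).
#' @param n0 pseudo-observation weight of the prior mean profile.
#' @param alpha_dir Dirichlet parameter shared by all mixture components.
#' @param sigma_delta width (mm) of the Gaussian prior on displacements.
#' @param sigma_i template smoothness: sd, in sample units, of the Gaussian
#'   the templates are convolved with (models partial-volume blur).
#' @param beta_f_relative,beta_f_absolute prior residual standard
#'   deviations for Self-scaled (T2*-like) and absolute (QSM-like)
#'   modalities.
#' @return Named list of hyperparameters.
#' @export
meshseg_hyperparams <- function(k, n0 = 3, alpha_dir = 2, sigma_delta = 2,
                                sigma_i = 0.5, beta_f_relative = 0.1,
                                beta_f_absolute = 3e-4) {
  list(n0 = n0, alpha0 = (k - 1) / 2 + 3, alpha_dir = alpha_dir,
       sigma_delta = sigma_delta, sigma_i = sigma_i,
       beta_f_relative = beta_f_relative, beta_f_absolute = beta_f_absolute)
}

# analytic (pre-smoothing) template value at signed position s (mm)
template_value <- function(s, type, lambda, inside, outside) {
  if (type == "step") {
    ifelse(s < 0, inside, outside)
  } else {
    ifelse(s <= 0, inside, inside + (outside - inside) * (1 - exp(-s / lambda)))
  }
}

# discrete Gaussian smoothing with replicate padding; sd in sample units
smooth_template <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  hw <- max(1L, ceiling(4 * sd_samples))
  kern <- stats::dnorm(-hw:hw, sd = sd_samples)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1], hw), x, rep(x[length(x)], hw))
  as.numeric(stats::filter(xp, kern, sides = 2))[(hw + 1):(hw + length(x))]
}

#' Build edge templates from prior rules
#'
#' One template per rule and decay scale: a step places the inside level at
#' \eqn{s < 0} and the outside level at \eqn{s \ge 0}; an exponential with
#' scale \eqn{\lambda} follows
#' \eqn{inside + (outside - inside)(1 - e^{-s/\lambda})} for \eqn{s > 0}.
#' Templates are then convolved with a Gaussian of sd \code{sigma_i}
#' samples.
#'
#' @param rules list of \code{\link{prior_rule}}s (single modality).
#' @param config a \code{\link{profile_config}}.
#' @param self_value modal inside intensity; required when any rule
#'   references Self.
#' @param sigma_i template smoothness (sd in samples).
#' @param extended if TRUE return templates on the extended grid of
#'   \eqn{2\Delta + 1} positions (used internally so integer-grid
#'   displacement shifts stay within the tabulated range).
#' @return List of numeric template vectors; each carries attributes
#'   \code{type} and \code{lambda}.
#' @export
build_edge_templates <- function(rules, config, self_value = NULL,
                                 sigma_i = 0.5, extended = FALSE) {
  pos <- if (extended) {
    (-config$n_steps:config$n_steps) * config$step_mm
  } else config$positions
  out <- list()
  for (r in rules) {
    inside <- resolve_level(r$inside, self_value)
    outside <- resolve_level(r$outside, self_value)
    lambdas <- if (r$type == "step") NA_real_ else r$lambda
    for (lam in lambdas) {
      tv <- template_value(pos, r$type, lam, inside, outside)
      tv <- smooth_template(tv, sigma_i)
      attr(tv, "type") <- r$type
      attr(tv, "lambda") <- lam
      out[[length(out) + 1L]] <- tv
    }
  }
  out
}
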
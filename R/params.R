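#' @keywords internal
"_PACKAGE"

#' Treatment and context levels
#'
#' Canonical factor levels used throughout the package: three rearing
#' treatments (no competitor, one conspecific competitor, one heterospecific
#' competitor) and three assay contexts (familiar home tank, novel arena,
#' novel arena with predator cues).  All data frames, parameter matrices and
#' posterior draws index treatments and contexts in this order.
#'
#' @format Character vectors of length 3.
#' @name levels
NULL

#' @rdname levels
#' @export
TREATMENTS <- c("no_competition", "conspecific", "heterospecific")

#' @rdname levels
#' @export
CONTEXTS <- c("familiar", "novel", "predator")

.tc_matrix <- function(x, what) {
  m <- matrix(as.numeric(x), nrow = 3, ncol = 3,
              dimnames = list(TREATMENTS, CONTEXTS))
  if (anyNA(m)) stop("`", what, "` must be a 3x3 numeric matrix (treatment x context)")
  m
}

#' Construct generator parameters for the repeated-assay design
#'
#' Bundles every quantity needed to simulate a full behavioural experiment:
#' per-treatment sample sizes, population mean log-distances by treatment and
#' context, trial and body-size slopes, among-individual and egg-mass
#' variances, log-scale residual variances, hurdle (zero) probabilities for
#' the novel and predator contexts, per-treatment 3x3 among-individual
#' cross-context correlation matrices, and a Gaussian random-slope growth
#' model for snout--vent length (SVL).
#'
#' All variances are on the log scale except `growth` components (mm scale)
#' and `p_hurdle` (probability scale).  `sigma2_log` is the residual
#' (within-individual) variance of log-distance; its natural-scale
#' counterpart used in repeatability is `exp(sigma2_log)` (see
#' [within_variance_natural()]).
#'
#' @param n_individuals_per_treatment integer vector of 3 focal-individual
#'   counts, in `TREATMENTS` order.
#' @param n_trials trials per context (>= 2).
#' @param n_egg_masses number of egg masses (clutches); individuals are
#'   assigned to egg masses in rotation so each clutch spans treatments.
#' @param mu 3x3 matrix (treatment x context) of population mean
#'   log-distances (log pixels).
#' @param beta_trial length-3 slope of log-distance on trial index (0--5),
#'   one per context.
#' @param beta_svl length-3 slope of log-distance on globally standardised
#'   SVL, one per context.
#' @param V_among 3x3 among-individual variance (log scale).
#' @param V_eggmass length-3 egg-mass variance per context (log scale).
#' @param sigma2_log 3x3 residual variance of log-distance.
#' @param p_hurdle 3x3 probability that a trial records distance 0 (tadpole
#'   never left the acclimation zone); the familiar column must be 0.
#' @param Omega list of 3 correlation matrices (3x3, one per treatment)
#'   for among-individual effects across contexts.
#' @param growth list with components `size_mu` (length-3 treatment mean SVL
#'   at trial 0, mm), `size_trial_slope` (mm per trial),
#'   `V_size_intercept`, `V_size_slope` (length-3, per treatment),
#'   `size_int_slope_cor` (length-3, in [-1, 1]), `V_size_eggmass`, and
#'   `size_resid_var` (mm^2).
#' @param dropout probability a trial record is dropped missing-at-random
#'   (emulates deaths/recording failures); 0 disables.
#' @param seed integer seed used by [simulate_trials()] unless overridden.
#'
#' @return An object of class `"hlmm_params"` (a validated list).
#' @seealso [default_params()], [simulate_trials()]
#' @export
generator_params <- function(n_individuals_per_treatment,
                             n_trials,
                             n_egg_masses,
                             mu,
                             beta_trial,
                             beta_svl,
                             V_among,
                             V_eggmass,
                             sigma2_log,
                             p_hurdle,
                             Omega,
                             growth,
                             dropout = 0,
                             seed = 1L) {
  p <- structure(list(
    n_individuals_per_treatment = as.integer(n_individuals_per_treatment),
    n_trials = as.integer(n_trials),
    n_egg_masses = as.integer(n_egg_masses),
    mu = .tc_matrix(mu, "mu"),
    beta_trial = stats::setNames(as.numeric(beta_trial), CONTEXTS),
    beta_svl = stats::setNames(as.numeric(beta_svl), CONTEXTS),
    V_among = .tc_matrix(V_among, "V_among"),
    V_eggmass = stats::setNames(as.numeric(V_eggmass), CONTEXTS),
    sigma2_log = .tc_matrix(sigma2_log, "sigma2_log"),
    p_hurdle = .tc_matrix(p_hurdle, "p_hurdle"),
    Omega = Omega,
    growth = growth,
    dropout = as.numeric(dropout),
    seed = as.integer(seed)
  ), class = "hlmm_params")
  validate_params(p)
}

#' Validate generator parameters
#'
#' Checks the invariants of [generator_params()]: non-negative variances,
#' hurdle probabilities in [0, 1] and zero in the familiar context,
#' symmetric positive semi-definite correlation matrices with unit diagonal,
#' and at least two trials.  Called by the constructor; exported so
#' externally assembled parameter lists can be checked too.
#'
#' @param p an `"hlmm_params"` object (or plain list with the same fields).
#' @return `p`, invisibly classed, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  if (length(p$n_individuals_per_treatment) != 3L ||
      any(p$n_individuals_per_treatment < 0L))
    stop("n_individuals_per_treatment must be 3 non-negative counts")
  if (p$n_trials < 2L) stop("n_trials must be >= 2")
  if (p$n_egg_masses < 1L) stop("n_egg_masses must be >= 1")
  for (f in c("V_among", "sigma2_log")) {
    if (any(p[[f]] < 0)) stop(f, " must be non-negative")
  }
  if (any(p$V_eggmass < 0)) stop("V_eggmass must be non-negative")
  if (any(p$p_hurdle < 0 | p$p_hurdle > 1))
    stop("p_hurdle must lie in [0, 1]")
  if (any(p$p_hurdle[, "familiar"] != 0))
    stop("p_hurdle must be 0 in the familiar context (no hurdle there)")
  if (!is.list(p$Omega) || length(p$Omega) != 3L)
    stop("Omega must be a list of 3 correlation matrices")
  for (t in 1:3) {
    Om <- p$Omega[[t]]
    if (!isTRUE(all.equal(Om, t(Om))) ||
        !isTRUE(all.equal(unname(diag(Om)), rep(1, 3))))
      stop("Omega[[", t, "]] must be symmetric with unit diagonal")
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("Omega[[", t, "]] must be positive semi-definite")
  }
  g <- p$growth
  need <- c("size_mu", "size_trial_slope", "V_size_intercept", "V_size_slope",
            "size_int_slope_cor", "V_size_eggmass", "size_resid_var")
  if (!all(need %in% names(g))) stop("growth is missing components: ",
                                     paste(setdiff(need, names(g)), collapse = ", "))
  if (any(g$V_size_intercept < 0) || any(g$V_size_slope < 0) ||
      g$V_size_eggmass < 0 || g$size_resid_var < 0)
    stop("growth variances must be non-negative")
  if (any(abs(g$size_int_slope_cor) > 1))
    stop("growth size_int_slope_cor must lie in [-1, 1]")
  if (p$dropout < 0 || p$dropout >= 1) stop("dropout must lie in [0, 1)")
  invisible(p)
}

#' Default generator parameters anchored to the motivating experiment
#'
#' Returns the study conditions the package emulates: 54, 56 and 51 focal
#' individuals in the no-competition, conspecific and heterospecific
#' treatments; 6 trials in each of 3 contexts; 8 egg masses; posterior-mean
#' population parameters of the fitted behavioural model (mean log-distances,
#' trial and SVL slopes, among-individual and egg-mass variances, residual
#' variances, acclimation-zone probabilities) and of the body-size growth
#' model.  Residual variances are supplied on the log scale as
#' `log(V_within)` where `V_within` is the reported natural-scale
#' within-individual variance, so that [within_variance_natural()] is the
#' exact inverse.  Among-individual cross-context correlations default to
#' identity (no behavioural syndrome), matching the reported absence of
#' cross-context correlation.
#'
#' @param seed integer seed stored in the parameter set.
#' @return An `"hlmm_params"` object.
#' @examples
#' p <- default_params()
#' p$n_individuals_per_treatment  # 54 56 51
#' p$V_among["heterospecific", "familiar"]  # 0.686
#' p$p_hurdle["no_competition", "novel"]    # 0.375
#' @export
default_params <- function(seed = 1L) {
  mu <- rbind(no_competition = c(6.228, 6.819, 6.141),
              conspecific    = c(6.221, 6.212, 5.849),
              heterospecific = c(6.319, 5.854, 5.852))
  V_among <- rbind(no_competition = c(0.193, 0.129, 0.144),
                   conspecific    = c(0.175, 0.863, 0.493),
                   heterospecific = c(0.686, 0.403, 0.127))
  V_within <- rbind(no_competition = c(2.796, 2.773, 2.703),
                    conspecific    = c(1.770, 3.466, 2.788),
                    heterospecific = c(2.316, 2.736, 2.773))
  p_hurdle <- rbind(no_competition = c(0, 0.375, 0.450),
                    conspecific    = c(0, 0.512, 0.508),
                    heterospecific = c(0, 0.432, 0.416))
  generator_params(
    n_individuals_per_treatment = c(54L, 56L, 51L),
    n_trials = 6L,
    n_egg_masses = 8L,
    mu = mu,
    beta_trial = c(-0.114, -0.186, -0.068),
    beta_svl = c(-0.088, -0.227, -0.010),
    V_among = V_among,
    V_eggmass = c(0.157, 0.137, 0.054),
    sigma2_log = log(V_within),
    p_hurdle = p_hurdle,
    Omega = rep(list(diag(3)), 3),
    growth = list(
      size_mu = c(5.285, 5.014, 4.168),
      size_trial_slope = 0.056,
      V_size_intercept = c(0.288, 0.404, 0.406),
      V_size_slope = c(0.004, 0.008, 0.006),
      size_int_slope_cor = c(0, 0, 0),
      V_size_eggmass = 0.149,
      size_resid_var = 0.04
    ),
    dropout = 0,
    seed = seed
  )
}

#' @export
print.hlmm_params <- function(x, ...) {
  cat("Generator parameters (hurdle log-normal repeated-assay design)\n")
  cat("  individuals per treatment:",
      paste(x$n_individuals_per_treatment, collapse = "/"),
      " trials:", x$n_trials, " egg masses:", x$n_egg_masses, "\n")
  cat("  mean log-distance (treatment x context):\n")
  print(round(x$mu, 3))
  cat("  hurdle zero probabilities:\n")
  print(round(x$p_hurdle, 3))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
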
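#' Emission parameters of the two-state ADA model
#'
#' Container for the parameters of the bivariate Gaussian emission
#' distributions of the two hidden states, `S_NOADA` (no ADA production) and
#' `S_ADA` (ADA production). Each state has its own modes for the two observed
#' variables (the weighted PK residual and the ADA assay measurement) and its
#' own correlation between them; the two variances are shared across states,
#' one per observed variable.
#'
#' @param mu_pkres_noada,mu_pkres_ada Modes of the weighted PK residual in
#'   `S_NOADA` and `S_ADA` (dimensionless). A well-specified PK model gives
#'   residuals centred near zero while ADA production drives them negative.
#' @param mu_ada_noada,mu_ada_ada Modes of the ADA measurement (U/mL) in the
#'   two states. In the fixed-mode model variants these are held at the assay
#'   LLOQ (0.6 U/mL) and the clinical positivity threshold (2.4 U/mL).
#' @param sigma2_pkres,sigma2_ada Emission variances, shared across states
#'   (dimensionless and U/mL^2 respectively).
#' @param rho_noada,rho_ada State-specific correlations between the two
#'   observed variables, in (-1, 1).
#' @param omega2_mu_pkres,omega2_mu_ada Optional inter-individual variance of
#'   an additive subject-level shift applied to both state modes of the
#'   corresponding variable (0 disables the random effect).
#'
#' @return An object of class `emission_params`.
#' @seealso [transition_params()], [emission_logpdf()]
#' @export
emission_params <- function(mu_pkres_noada = 0, mu_pkres_ada = -1,
                            mu_ada_noada = 0.6, mu_ada_ada = 2.4,
                            sigma2_pkres = 1, sigma2_ada = 2,
                            rho_noada = 0, rho_ada = 0,
                            omega2_mu_pkres = 0, omega2_mu_ada = 0) {
  if (!(sigma2_pkres > 0 && sigma2_ada > 0))
    stop("emission variances must be strictly positive", call. = FALSE)
  if (!(abs(rho_noada) < 1 && abs(rho_ada) < 1))
    stop("state correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (omega2_mu_pkres < 0 || omega2_mu_ada < 0)
    stop("IIV variances must be non-negative", call. = FALSE)
  structure(list(
    mu_pkres_noada = mu_pkres_noada, mu_pkres_ada = mu_pkres_ada,
    mu_ada_noada = mu_ada_noada, mu_ada_ada = mu_ada_ada,
    sigma2_pkres = sigma2_pkres, sigma2_ada = sigma2_ada,
    rho_noada = rho_noada, rho_ada = rho_ada,
    omega2_mu_pkres = omega2_mu_pkres, omega2_mu_ada = omega2_mu_ada
  ), class = "emission_params")
}

#' Transition parameters of the two-state chain
#'
#' Only two elements of the 2x2 transition probability matrix are free:
#' `pi12` (`S_NOADA` to `S_ADA`) and `pi21` (`S_ADA` to `S_NOADA`); the
#' diagonal entries are their complements so rows sum to 1 exactly. The free
#' probabilities are stored on the logit scale, where subject-level random
#' effects act additively.
#'
#' @param logit_pi12,logit_pi21 Logits of the two estimated transition
#'   probabilities.
#' @param omega2_pi12,omega2_pi21 Optional inter-individual variances of the
#'   additive random effects on the logits (0 disables).
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(logit_pi12, logit_pi21,
                              omega2_pi12 = 0, omega2_pi21 = 0) {
  stopifnot(is.finite(logit_pi12), is.finite(logit_pi21))
  if (omega2_pi12 < 0 || omega2_pi21 < 0)
    stop("IIV variances must be non-negative", call. = FALSE)
  structure(list(logit_pi12 = logit_pi12, logit_pi21 = logit_pi21,
                 omega2_pi12 = omega2_pi12, omega2_pi21 = omega2_pi21),
            class = "transition_params")
}

#' @rdname transition_params
#' @param pi12,pi21 Transition probabilities on the natural (0, 1) scale.
#' @export
transition_params_from_probs <- function(pi12, pi21,
                                         omega2_pi12 = 0, omega2_pi21 = 0) {
  stopifnot(pi12 > 0, pi12 < 1, pi21 > 0, pi21 < 1)
  transition_params(stats::qlogis(pi12), stats::qlogis(pi21),
                    omega2_pi12, omega2_pi21)
}

# State order used throughout: 1 = S_NOADA, 2 = S_ADA.
.state_labels <- c("S_NOADA", "S_ADA")

# log density of the bivariate normal, elementwise in (y1, y2)
.bvn_logpdf <- function(y1, y2, mu1, mu2, s1, s2, rho) {
  z1 <- (y1 - mu1) / s1
  z2 <- (y2 - mu2) / s2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-rho^2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))
}

# n x 2 matrix of per-record log emission densities (columns = states).
# Missing components use the exact Gaussian marginal; a record with both
# components missing contributes log 1 = 0.
.emission_logmat <- function(y_pkres, y_ada, em,
                             shift_pkres = 0, shift_ada = 0) {
  n <- length(y_pkres)
  out <- matrix(0, n, 2)
  s1 <- sqrt(em$sigma2_pkres)
  s2 <- sqrt(em$sigma2_ada)
  mu1 <- c(em$mu_pkres_noada, em$mu_pkres_ada) + shift_pkres
  mu2 <- c(em$mu_ada_noada, em$mu_ada_ada) + shift_ada
  rho <- c(em$rho_noada, em$rho_ada)
  has1 <- !is.na(y_pkres)
  has2 <- !is.na(y_ada)
  both <- has1 & has2
  pk_only <- has1 & !has2
  ada_only <- !has1 & has2
  for (s in 1:2) {
    if (any(both))
      out[both, s] <- .bvn_logpdf(y_pkres[both], y_ada[both],
                                  mu1[s], mu2[s], s1, s2, rho[s])
    if (any(pk_only))
      out[pk_only, s] <- stats::dnorm(y_pkres[pk_only], mu1[s], s1, log = TRUE)
    if (any(ada_only))
      out[ada_only, s] <- stats::dnorm(y_ada[ada_only], mu2[s], s2, log = TRUE)
  }
  out
}

#' Log emission density of an observation record
#'
#' Evaluates the log of the state-conditional emission density: the bivariate
#' Gaussian when both observed variables are present, and the exact univariate
#' Gaussian marginal when one of them is missing (`NA`). A record with both
#' components missing has log density 0.
#'
#' @param y_pkres Weighted PK residual, or `NA` if missing. Vectorized.
#' @param y_ada ADA measurement (U/mL), or `NA` if missing. Vectorized.
#' @param state `"S_NOADA"`/`"S_ADA"` (or 1/2).
#' @param em An [emission_params()] object.
#' @param shift_pkres,shift_ada Additive subject-level shifts of the modes
#'   (the realized random effects of the mixed model; default 0).
#' @return Numeric vector of log densities.
#' @examples
#' em <- emission_params(mu_pkres_ada = -1.6, sigma2_pkres = 0.8,
#'                       sigma2_ada = 1.6, rho_ada = -0.07)
#' emission_logpdf(-1.0, 3.0, "S_ADA", em)
#' @export
emission_logpdf <- function(y_pkres, y_ada, state, em,
                            shift_pkres = 0, shift_ada = 0) {
  s <- .state_index(state)
  .emission_logmat(y_pkres, y_ada, em, shift_pkres, shift_ada)[, s]
}

.state_index <- function(state) {
  if (is.character(state)) {
    s <- match(state, .state_labels)
    if (anyNA(s)) stop("unknown state label: ", state, call. = FALSE)
  } else {
    s <- as.integer(state)
    if (!all(s %in% 1:2)) stop("state index must be 1 or 2", call. = FALSE)
  }
  s
}

#' Transition probability matrix
#'
#' Maps the logit-scale transition parameters (plus optional realized random
#' effects) to the 2x2 row-stochastic transition matrix. Diagonal entries are
#' computed as complements so that rows sum to 1 exactly.
#'
#' @param tp A [transition_params()] object.
#' @param eta12,eta21 Realized random effects added to the logits (default 0).
#' @return A 2x2 matrix with rows/columns ordered (`S_NOADA`, `S_ADA`).
#' @export
transition_probs <- function(tp, eta12 = 0, eta21 = 0) {
  p12 <- stats::plogis(tp$logit_pi12 + eta12)
  p21 <- stats::plogis(tp$logit_pi21 + eta21)
  matrix(c(1 - p12, p21, p12, 1 - p21), 2, 2,
         dimnames = list(.state_labels, .state_labels))
}

# Vectorized scaled forward recursion over a cohort.
#
# E1, E2: n_subj x T matrices of log emission densities under S_NOADA and
# S_ADA (records padded at the end with both-missing rows contribute 0 and do
# not change the likelihood). p12, p21: scalars or length-n vectors.
# Returns the per-subject log-likelihood vector; with keep_filter = TRUE also
# the filtered probabilities and per-record log scaling constants.
.forward_engine <- function(E1, E2, p12, p21, keep_filter = FALSE) {
  n <- nrow(E1)
  Tn <- ncol(E1)
  p11 <- 1 - p12
  p22 <- 1 - p21
  # record 1: everyone starts in S_NOADA, no transition
  ll <- E1[, 1]
  phi1 <- rep(1, n)
  phi2 <- rep(0, n)
  if (keep_filter) {
    PHI1 <- matrix(NA_real_, n, Tn)
    PHI2 <- matrix(NA_real_, n, Tn)
    LSC <- matrix(NA_real_, n, Tn)
    PHI1[, 1] <- 1; PHI2[, 1] <- 0; LSC[, 1] <- E1[, 1]
  }
  if (Tn > 1) {
    for (t in 2:Tn) {
      pr1 <- phi1 * p11 + phi2 * p21
      pr2 <- phi1 * p12 + phi2 * p22
      m <- pmax(E1[, t], E2[, t])
      a1 <- pr1 * exp(E1[, t] - m)
      a2 <- pr2 * exp(E2[, t] - m)
      nrm <- a1 + a2
      ll <- ll + log(nrm) + m
      phi1 <- a1 / nrm
      phi2 <- a2 / nrm
      if (keep_filter) {
        PHI1[, t] <- phi1; PHI2[, t] <- phi2; LSC[, t] <- log(nrm) + m
      }
    }
  }
  if (keep_filter) list(loglik = ll, phi1 = PHI1, phi2 = PHI2, logscale = LSC)
  else ll
}

#' Forward (filtering) recursion for one subject
#'
#' Computes the scaled forward recursion over a subject's time-ordered
#' observation records. The first record carries no transition: its
#' contribution is the emission density under `S_NOADA`, reflecting that all
#' subjects are drug naive and start in the no-production state. Each later
#' record propagates the filtered state probabilities through the transition
#' matrix, multiplies by the emission densities, and normalizes; the total
#' log-likelihood is the sum of the log normalizing constants. Records with
#' both components missing contribute log 1 and propagate the states by the
#' transition alone.
#'
#' @param records Data frame with columns `y_pkres` and `y_ada` (use `NA` for
#'   a missing component), one row per record in time order.
#' @param em An [emission_params()] object.
#' @param tp A [transition_params()] object.
#' @param etas Optional named list of realized random effects:
#'   `mu_pkres`, `mu_ada` (additive mode shifts), `pi12`, `pi21` (additive on
#'   the logits). Missing entries default to 0.
#' @return A list of class `filtered_trajectory` with elements `loglik`,
#'   `phi` (n x 2 matrix of filtered probabilities), and `logscale`
#'   (per-record log scaling constants; `sum(logscale) == loglik`).
#' @export
forward_loglik <- function(records, em, tp, etas = list()) {
  et <- .complete_etas(etas)
  E <- .emission_logmat(records$y_pkres, records$y_ada, em,
                        et$mu_pkres, et$mu_ada)
  p12 <- stats::plogis(tp$logit_pi12 + et$pi12)
  p21 <- stats::plogis(tp$logit_pi21 + et$pi21)
  r <- .forward_engine(matrix(E[, 1], 1), matrix(E[, 2], 1), p12, p21,
                       keep_filter = TRUE)
  phi <- cbind(S_NOADA = r$phi1[1, ], S_ADA = r$phi2[1, ])
  structure(list(loglik = r$loglik, phi = phi, logscale = r$logscale[1, ]),
            class = "filtered_trajectory")
}

.complete_etas <- function(etas) {
  out <- list(mu_pkres = 0, mu_ada = 0, pi12 = 0, pi21 = 0)
  for (nm in names(etas)) {
    if (!nm %in% names(out)) stop("unknown eta name: ", nm, call. = FALSE)
    out[[nm]] <- etas[[nm]]
  }
  out
}

#' Viterbi decoding of the most likely state sequence
#'
#' Dynamic-programming argmax over state paths under the same initialization
#' as [forward_loglik()] (the first record is in `S_NOADA` with probability
#' one). Ties are broken toward `S_NOADA`, so in the absence of signal the
#' decoded path stays in the no-production state.
#'
#' @inheritParams forward_loglik
#' @return A list of class `state_path` with `states` (character vector of
#'   `"S_NOADA"`/`"S_ADA"`), `path` (integer 1/2), and `log_prob`, the joint
#'   log-probability of the decoded path and the observations.
#' @export
viterbi_decode <- function(records, em, tp, etas = list()) {
  et <- .complete_etas(etas)
  E <- .emission_logmat(records$y_pkres, records$y_ada, em,
                        et$mu_pkres, et$mu_ada)
  p12 <- stats::plogis(tp$logit_pi12 + et$pi12)
  p21 <- stats::plogis(tp$logit_pi21 + et$pi21)
  lP <- log(matrix(c(1 - p12, p21, p12, 1 - p21), 2, 2))
  n <- nrow(E)
  delta <- matrix(-Inf, n, 2)
  back <- matrix(1L, n, 2)
  delta[1, 1] <- E[1, 1]
  if (n > 1) {
    for (t in 2:n) {
      for (j in 1:2) {
        cand <- delta[t - 1, ] + lP[, j]
        i <- if (cand[1] >= cand[2]) 1L else 2L  # tie toward S_NOADA
        back[t, j] <- i
        delta[t, j] <- cand[i] + E[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- if (delta[n, 1] >= delta[n, 2]) 1L else 2L
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  structure(list(states = .state_labels[path], path = path,
                 log_prob = delta[n, path[n]]),
            class = "state_path")
}

#' Decode state sequences for every subject in a record table
#'
#' Applies [viterbi_decode()] per subject to a long table of prepared
#' observation records (as produced by [prepare_hmm_records()] or
#' [simulate_mhmm()]).
#'
#' @param records Data frame with columns `subject_id`, `time`, `y_pkres`,
#'   `y_ada`.
#' @param fit Either an `mhmm_fit` object or a list with elements `em` and
#'   `tp`.
#' @return Data frame `subject_id`, `time`, `state`.
#' @export
decode_states <- function(records, fit) {
  pars <- .fit_params(fit)
  records <- records[order(records$subject_id, records$time), ]
  out <- lapply(split(records, records$subject_id, drop = TRUE), function(r) {
    v <- viterbi_decode(r, pars$em, pars$tp)
    data.frame(subject_id = r$subject_id, time = r$time, state = v$states,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.fit_params <- function(fit) {
  if (inherits(fit, "mhmm_fit")) list(em = fit$em, tp = fit$tp)
  else if (is.list(fit) && all(c("em", "tp") %in% names(fit))) fit
  else stop("'fit' must be an mhmm_fit or a list(em, tp)", call. = FALSE)
}
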
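#' Population PK model parameters
#'
#' One-compartment model with first-order absorption, parameterized in
#' apparent clearance and volume (subcutaneous dosing, bioavailability folded
#' into CL/F and V/F). Covariates act on the typical values as
#' `CL/F = cl_pop * (WT/70)^theta_wt_cl * (1 + theta_jp_cl * JP)` and
#' `V/F = v_pop * (1 + theta_jp_v * JP)`, with log-normal inter-individual
#' variability on CL/F and V/F and a proportional residual error.
#'
#' @param cl_pop Typical apparent clearance (L/day), > 0.
#' @param v_pop Typical apparent central volume (L), > 0.
#' @param ka First-order absorption rate constant (1/day), > 0; no IIV.
#' @param theta_wt_cl Allometric exponent of body weight on CL/F.
#' @param theta_jp_cl,theta_jp_v Proportional effect of Japanese ethnicity on
#'   CL/F and V/F (> -1).
#' @param omega2_cl,omega2_v IIV variances on the log scale, >= 0.
#' @param sigma_prop Proportional residual error SD, > 0.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(cl_pop, v_pop, ka, theta_wt_cl = 0,
                      theta_jp_cl = 0, theta_jp_v = 0,
                      omega2_cl = 0, omega2_v = 0, sigma_prop = 0.15) {
  stopifnot(cl_pop > 0, v_pop > 0, ka > 0,
            theta_jp_cl > -1, theta_jp_v > -1,
            omega2_cl >= 0, omega2_v >= 0, sigma_prop > 0)
  structure(list(cl_pop = cl_pop, v_pop = v_pop, ka = ka,
                 theta_wt_cl = theta_wt_cl, theta_jp_cl = theta_jp_cl,
                 theta_jp_v = theta_jp_v, omega2_cl = omega2_cl,
                 omega2_v = omega2_v, sigma_prop = sigma_prop),
            class = "pk_params")
}

# covariate-adjusted typical individual parameters (eta = 0)
.typical_pk <- function(p, weight, japanese) {
  list(cl = p$cl_pop * (weight / 70)^p$theta_wt_cl *
         (1 + p$theta_jp_cl * japanese),
       v = p$v_pop * (1 + p$theta_jp_v * japanese))
}

# single-dose one-compartment concentration, dt > 0
.onecpt_single <- function(amt, dt, ke, ka, v) {
  if (abs(ka - ke) < 1e-8 * ka) {
    # flip-flop degenerate limit ka -> ke
    amt / v * ka * dt * exp(-ka * dt)
  } else {
    amt * ka / (v * (ka - ke)) * (exp(-ke * dt) - exp(-ka * dt))
  }
}

#' Predict drug concentration under the one-compartment model
#'
#' Closed-form superposition of first-order-absorption one-compartment
#' contributions from every dose administered at or before the prediction
#' time. The degenerate case `ka == CL/V` uses the analytic limiting form.
#'
#' @param t Prediction times (days), >= 0; vectorized.
#' @param doses Data frame with columns `time` (days) and `amt` (mg).
#' @param cl,v Individual apparent clearance (L/day) and volume (L).
#' @param ka Absorption rate constant (1/day).
#' @return Concentrations (ug/mL, equivalently mg/L), non-negative.
#' @export
predict_concentration <- function(t, doses, cl, v, ka) {
  stopifnot(cl > 0, v > 0, ka > 0, all(t >= 0))
  ke <- cl / v
  conc <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    dt <- t - doses$time[d]
    on <- dt > 0
    if (any(on))
      conc[on] <- conc[on] + .onecpt_single(doses$amt[d], dt[on], ke, ka, v)
  }
  conc
}

# Occasion-1 PK observations usable for estimation: strictly before the
# second dose and strictly after the first dose (pre-first-dose samples have
# zero prediction and carry no information under proportional error).
.occ1_pk_obs <- function(sub) {
  if (nrow(sub$doses) == 0) return(sub$obs[0, ])
  t2 <- if (nrow(sub$doses) >= 2) sub$doses$time[2] else Inf
  t1 <- sub$doses$time[1]
  keep <- !is.na(sub$obs$pk) & sub$obs$time < t2 & sub$obs$time > t1
  sub$obs[keep, ]
}

# concentration and its derivatives wrt (eta_cl, eta_v) at one subject's
# observation times; d f/d eta_cl = ke * df/dke, d f/d eta_v = -f - ke * df/dke
.pk_f_and_grad <- function(eta, sub, p) {
  cl <- p$cl_pop * (sub$weight / 70)^p$theta_wt_cl *
    (1 + p$theta_jp_cl * sub$japanese) * exp(eta[1])
  v <- p$v_pop * (1 + p$theta_jp_v * sub$japanese) * exp(eta[2])
  ka <- p$ka
  ke <- cl / v
  tms <- sub$.grad_times
  f <- numeric(length(tms))
  dfdke <- numeric(length(tms))
  for (d in seq_len(nrow(sub$doses))) {
    dt <- tms - sub$doses$time[d]
    on <- dt > 0
    if (!any(on)) next
    dd <- dt[on]
    A <- sub$doses$amt[d] * ka / v
    if (abs(ka - ke) < 1e-6 * ka) {
      f[on] <- f[on] + A * dd * exp(-ka * dd)
      dfdke[on] <- dfdke[on] + A * dd^2 * exp(-ka * dd) / 2
    } else {
      e_ke <- exp(-ke * dd)
      e_ka <- exp(-ka * dd)
      f[on] <- f[on] + A * (e_ke - e_ka) / (ka - ke)
      dfdke[on] <- dfdke[on] +
        A * ((e_ke - e_ka) / (ka - ke)^2 - dd * e_ke / (ka - ke))
    }
  }
  list(f = f, g1 = ke * dfdke, g2 = -f - ke * dfdke)
}

# analytic gradient of the subject log-likelihood wrt (eta_cl, eta_v)
.pk_subject_ll_grad <- function(eta, sub, obs, p) {
  sub$.grad_times <- obs$time
  fg <- .pk_f_and_grad(eta, sub, p)
  f <- fg$f
  if (any(f <= 0) || !all(is.finite(f))) return(c(0, 0))
  s2 <- p$sigma_prop^2
  r <- obs$pk - f
  dldf <- -1 / f + r / (s2 * f^2) + r^2 / (s2 * f^3)
  c(sum(dldf * fg$g1), sum(dldf * fg$g2))
}

# log-likelihood of one subject's PK observations at given etas
.pk_subject_ll <- function(eta, sub, obs, p) {
  if (!all(is.finite(eta))) return(-1e10)
  cl <- p$cl_pop * (sub$weight / 70)^p$theta_wt_cl *
    (1 + p$theta_jp_cl * sub$japanese) * exp(eta[1])
  v <- p$v_pop * (1 + p$theta_jp_v * sub$japanese) * exp(eta[2])
  if (!is.finite(cl) || !is.finite(v) || cl <= 0 || v <= 0) return(-1e10)
  f <- predict_concentration(obs$time, sub$doses, cl, v, p$ka)
  if (any(f <= 0)) return(-1e10)
  sum(stats::dnorm(obs$pk, f, p$sigma_prop * f, log = TRUE))
}

# Laplace-approximated marginal log-likelihood contribution of one subject.
# Dimensions with omega2 = 0 are held at eta = 0 (no integration).
.pk_laplace_subject <- function(sub, obs, p, start = NULL) {
  free <- c(p$omega2_cl > 0, p$omega2_v > 0)
  om <- c(p$omega2_cl, p$omega2_v)
  if (nrow(obs) == 0) {
    return(list(ll = 0, eta = c(0, 0)))
  }
  if (!any(free)) {
    return(list(ll = .pk_subject_ll(c(0, 0), sub, obs, p), eta = c(0, 0)))
  }
  g <- function(ef) {
    eta <- c(0, 0)
    eta[free] <- ef
    .pk_subject_ll(eta, sub, obs, p) +
      sum(stats::dnorm(ef, 0, sqrt(om[free]), log = TRUE))
  }
  ggrad <- function(ef) {
    eta <- c(0, 0)
    eta[free] <- ef
    .pk_subject_ll_grad(eta, sub, obs, p)[free] - ef / om[free]
  }
  d <- sum(free)
  st <- if (is.null(start)) rep(0, d) else start[free]
  opt <- stats::optim(st, function(e) -g(e), function(e) -ggrad(e),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 300))
  ehat <- opt$par
  g0 <- g(ehat)
  # Hessian of -g from central differences of the analytic gradient
  h <- 1e-5
  H <- matrix(NA_real_, d, d)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    H[i, ] <- -(ggrad(ehat + ei) - ggrad(ehat - ei)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ldet <- determinant(H, logarithm = TRUE)
  if (ldet$sign <= 0) return(list(ll = -Inf, eta = c(0, 0)))
  eta <- c(0, 0)
  eta[free] <- ehat
  list(ll = g0 + d / 2 * log(2 * pi) - 0.5 * as.numeric(ldet$modulus),
       eta = eta)
}

.pk_layout <- data.frame(
  name = c("cl_pop", "v_pop", "ka", "theta_wt_cl", "theta_jp_cl",
           "theta_jp_v", "omega2_cl", "omega2_v", "sigma_prop"),
  transform = c("log", "log", "log", "identity", "log1p", "log1p",
                "log", "log", "log"),
  stringsAsFactors = FALSE
)

.pk_to_u <- function(x, tr) switch(tr, log = log(x), log1p = log(1 + x),
                                   identity = x)
.pk_to_nat <- function(u, tr) switch(tr, log = exp(u), log1p = expm1(u),
                                     identity = u)

.pk_pack <- function(p, free) {
  lay <- .pk_layout[.pk_layout$name %in% free, ]
  u <- mapply(.pk_to_u, unlist(p[lay$name]), lay$transform)
  names(u) <- lay$name
  u
}

.pk_unpack <- function(theta, free, template) {
  p <- template
  lay <- .pk_layout[.pk_layout$name %in% free, ]
  for (i in seq_len(nrow(lay)))
    p[[lay$name[i]]] <- .pk_to_nat(theta[[lay$name[i]]], lay$transform[i])
  p
}

#' Fit the population PK model to first-dosing-occasion data
#'
#' Maximizes the Laplace-approximated marginal likelihood of the PK
#' observations belonging to each subject's first dosing occasion (all records
#' strictly before the second dose event; a single-dose study is entirely
#' occasion 1). Subjects are drug naive there, so the fit is unaffected by
#' later ADA formation and yields unbiased first-occasion residuals.
#'
#' @param dataset An `ada_dataset` (see [read_dataset()]).
#' @param init A [pk_params()] object of starting values. Parameters named in
#'   `fixed` are held at their `init` values (set `omega2_*` to 0 in `init`
#'   and list them in `fixed` for a no-IIV fit).
#' @param fixed Character vector of parameter names not estimated.
#' @param control Passed to [stats::nlminb()].
#' @return A list of class `pk_fit`: `params` (fitted [pk_params()]),
#'   `loglik`, `converged`, `n_subjects`, `fixed`. Subjects without usable
#'   occasion-1 PK data are excluded with a warning.
#' @export
fit_first_occasion <- function(dataset, init, fixed = character(),
                               control = list()) {
  stopifnot(inherits(init, "pk_params"))
  free <- setdiff(.pk_layout$name, fixed)
  if (length(free) == 0) stop("no free parameters", call. = FALSE)
  # omega2 fixed at 0 must stay fixed (log transform undefined)
  for (nm in c("omega2_cl", "omega2_v"))
    if (nm %in% free && init[[nm]] == 0)
      stop(nm, " starts at 0; either fix it or give a positive start",
           call. = FALSE)

  subs <- dataset
  obs1 <- lapply(subs, .occ1_pk_obs)
  usable <- vapply(obs1, nrow, integer(1)) > 0
  if (!all(usable)) {
    warning(sum(!usable),
            " subject(s) without occasion-1 PK data excluded from the fit")
    subs <- subs[usable]
    obs1 <- obs1[usable]
  }
  if (length(subs) == 0) stop("no usable subjects", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    p <- tryCatch(.pk_unpack(theta, free, init), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    tot <- 0
    for (i in seq_along(subs)) {
      key <- as.character(i)
      st <- if (!is.null(cache[[key]])) cache[[key]] else NULL
      r <- .pk_laplace_subject(subs[[i]], obs1[[i]], p, start = st)
      if (!is.finite(r$ll)) return(1e10)
      cache[[key]] <- r$eta
      tot <- tot + r$ll
    }
    -tot
  }

  ctrl <- utils::modifyList(
    list(rel.tol = 1e-8, eval.max = 2000, iter.max = 500), control)
  start <- .pk_pack(init, free)
  # The warm-started inner Laplace step leaves ~1e-8-level noise on the
  # objective, which can trip PORT's curvature test well before the optimum;
  # restart from the incumbent until the objective is stationary.
  opt <- stats::nlminb(start, negll, control = ctrl)
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  rounds <- 0L
  while (!converged && is.finite(opt$objective) && rounds < 6L) {
    rounds <- rounds + 1L
    obj1 <- opt$objective
    opt2 <- stats::nlminb(opt$par, negll, control = ctrl)
    if (is.finite(opt2$objective) && opt2$objective <= obj1) opt <- opt2
    converged <- opt$convergence == 0 ||
      abs(opt2$objective - obj1) < 1e-7 * (abs(obj1) + 1)
  }
  theta <- opt$par
  names(theta) <- names(start)
  params <- .pk_unpack(theta, free, init)
  if (!converged)
    warning("PK fit did not formally converge; best-found values returned")
  structure(list(params = params, loglik = -opt$objective,
                 converged = converged, n_subjects = length(subs),
                 fixed = fixed, message = opt$message),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (first dosing occasion, Laplace), n =",
      x$n_subjects, "subjects\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      " converged:", x$converged, "\n")
  print(round(unlist(x$params), 5))
  invisible(x)
}

#' Empirical-Bayes individual PK parameters
#'
#' Per-subject MAP estimates of (CL/F, V/F) maximizing the product of the
#' random-effect prior and the subject's occasion-1 PK data likelihood.
#' A subject with no usable occasion-1 PK data (or zero IIV variances)
#' receives the covariate-adjusted typical values (full shrinkage).
#'
#' @param params A [pk_params()] object (typically from
#'   [fit_first_occasion()]).
#' @param dataset An `ada_dataset`.
#' @return Data frame of class `ebe_set`: `subject_id`, `cl_i`, `v_i`,
#'   `eta_cl`, `eta_v`.
#' @export
compute_ebes <- function(params, dataset) {
  if (inherits(params, "pk_fit")) params <- params$params
  rows <- lapply(dataset, function(sub) {
    obs <- .occ1_pk_obs(sub)
    free <- c(params$omega2_cl > 0, params$omega2_v > 0)
    eta <- c(0, 0)
    if (nrow(obs) > 0 && any(free)) {
      om <- c(params$omega2_cl, params$omega2_v)
      g <- function(ef) {
        e <- c(0, 0); e[free] <- ef
        .pk_subject_ll(e, sub, obs, params) +
          sum(stats::dnorm(ef, 0, sqrt(om[free]), log = TRUE))
      }
      ggrad <- function(ef) {
        e <- c(0, 0); e[free] <- ef
        .pk_subject_ll_grad(e, sub, obs, params)[free] - ef / om[free]
      }
      opt <- stats::optim(rep(0, sum(free)), function(e) -g(e),
                          function(e) -ggrad(e), method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 500))
      eta[free] <- opt$par
    }
    typ <- .typical_pk(params, sub$weight, sub$japanese)
    data.frame(subject_id = sub$subject_id,
               cl_i = typ$cl * exp(eta[1]), v_i = typ$v * exp(eta[2]),
               eta_cl = eta[1], eta_v = eta[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ebe_set", "data.frame")
  out
}

#' Individually weighted PK residuals
#'
#' Computes `IWRES = (DV - IPRED) / (sigma_prop * IPRED)` at every PK
#' observation over all dosing occasions, with individual predictions from the
#' empirical-Bayes parameters. Under a well-specified model IWRES have SD
#' near 1 and mean near 0; systematic over-prediction after ADA onset drives
#' them negative, which is the PK signal the hidden-Markov model reads.
#' Observations with zero individual prediction (samples at or before the
#' first dose) get `NA` residuals and are treated as missing downstream.
#'
#' @param params A [pk_params()] (or `pk_fit`).
#' @param ebes An `ebe_set` from [compute_ebes()].
#' @param dataset An `ada_dataset`.
#' @return Data frame `subject_id`, `time`, `occasion`, `dv`, `ipred`,
#'   `iwres`.
#' @export
compute_iwres <- function(params, ebes, dataset) {
  if (inherits(params, "pk_fit")) params <- params$params
  idx <- match(vapply(dataset, function(s) s$subject_id, character(1)),
               ebes$subject_id)
  rows <- lapply(seq_along(dataset), function(i) {
    sub <- dataset[[i]]
    keep <- !is.na(sub$obs$pk)
    if (!any(keep)) return(NULL)
    obs <- sub$obs[keep, ]
    cl <- ebes$cl_i[idx[i]]
    v <- ebes$v_i[idx[i]]
    ipred <- predict_concentration(obs$time, sub$doses, cl, v, params$ka)
    iwres <- ifelse(ipred > 0,
                    (obs$pk - ipred) / (params$sigma_prop * ipred),
                    NA_real_)
    data.frame(subject_id = sub$subject_id, time = obs$time,
               occasion = obs$occasion, dv = obs$pk, ipred = ipred,
               iwres = iwres, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
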
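#' Study design description
#'
#' Describes one trial (or trial arm group) for the cohort simulator: number
#' of subjects, maintenance dose arms, optional loading doses (administered at
#' weeks 0, 2 and 4, followed by maintenance dosing from week 6), dosing
#' interval, planned sampling days and covariate distributions.
#'
#' @param name Study label.
#' @param n_subjects Number of subjects (>= 1).
#' @param dose_mg Vector of maintenance dose arms (mg); each subject is
#'   assigned one arm uniformly at random.
#' @param interval `"Q2W"`, `"Q4W"` or `"single"`.
#' @param sampling_days Sorted vector of planned sampling times (days).
#' @param loading_dose_mg Optional vector of loading-dose amounts paired with
#'   `dose_mg` (same length); `NULL` for no loading doses.
#' @param weight_median,weight_cv Log-normal body-weight distribution (kg).
#' @param japanese_fraction Fraction of Japanese subjects.
#' @param ada_measured If `FALSE`, no ADA samples are drawn (single-dose
#'   phase-I setting).
#' @return An object of class `study_design`.
#' @export
study_design <- function(name, n_subjects, dose_mg,
                         interval = c("Q4W", "Q2W", "single"),
                         sampling_days, loading_dose_mg = NULL,
                         weight_median = 70, weight_cv = 0.2,
                         japanese_fraction = 0.1, ada_measured = TRUE) {
  interval <- match.arg(interval)
  stopifnot(n_subjects >= 1, all(dose_mg > 0),
            !is.unsorted(sampling_days), all(sampling_days >= 0))
  if (!is.null(loading_dose_mg))
    stopifnot(length(loading_dose_mg) == length(dose_mg),
              all(loading_dose_mg > 0))
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 dose_mg = dose_mg, interval = interval,
                 sampling_days = sampling_days,
                 loading_dose_mg = loading_dose_mg,
                 weight_median = weight_median, weight_cv = weight_cv,
                 japanese_fraction = japanese_fraction,
                 ada_measured = ada_measured),
            class = "study_design")
}

#' Default trial-design mix
#'
#' Six subcutaneous certolizumab pegol RA trial designs: a phase-II
#' dose-ranging Q4W study (50-800 mg), two 400 mg Q4W phase-III studies, two
#' Q2W studies with and without week-0/2/4 loading doses, and a richly sampled
#' single-dose phase-I study without ADA sampling. Totals 845 subjects at
#' the natural sizes; `n_total` rescales proportionally.
#'
#' @param n_total Optional total cohort size.
#' @return List of [study_design()] objects.
#' @export
default_designs <- function(n_total = NULL) {
  designs <- list(
    study_design("CDP870-004", 239, c(50, 100, 200, 400, 600, 800), "Q4W",
                 c(0, 7, 14, 28, 35, 42, 56, 63, 70, 84)),
    study_design("RA006", 116, 200, "Q2W",
                 c(7, 14, 28, 42, 56, 84, 112), loading_dose_mg = 400),
    study_design("CDP870-011", 111, 400, "Q4W",
                 c(7, 14, 28, 56, 84, 112, 140, 147, 154, 168)),
    study_design("CDP870-014", 124, 400, "Q4W",
                 c(7, 14, 28, 56, 84, 112, 140, 168)),
    study_design("C87041-flat", 120, c(200, 400), "Q2W",
                 c(7, 14, 28, 42, 56, 84, 168)),
    study_design("C87041-load", 119, c(200, 100), "Q2W",
                 c(7, 14, 28, 42, 56, 84, 168),
                 loading_dose_mg = c(400, 200)),
    study_design("PHA001", 16, 400, "single",
                 c(0.02, 0.04, 0.08, 0.17, 0.25, 0.33, 0.5, 1, 1.5, 2, 3, 4,
                   5, 6, 7, 13, 20, 27, 34, 41, 48, 55),
                 ada_measured = FALSE)
  )
  if (!is.null(n_total)) {
    scale <- n_total / sum(vapply(designs, function(d) d$n_subjects, 1L))
    designs <- lapply(designs, function(d) {
      d$n_subjects <- max(1L, as.integer(round(d$n_subjects * scale)))
      d
    })
  }
  designs
}

#' Default population PK parameters for the simulator
#'
#' Certolizumab-pegol-like one-compartment parameters: terminal half-life
#' near 14 days (CL/F 0.4 L/day, V/F 8 L), slow subcutaneous absorption
#' (ka 0.3 /day), allometric weight effect on CL/F, modest negative Japanese
#' ethnicity effects, 30% CV inter-individual variability on CL/F and V/F and
#' a 15% proportional residual error.
#'
#' @return A [pk_params()] object.
#' @export
default_pk_params <- function() {
  pk_params(cl_pop = 0.4, v_pop = 8, ka = 0.3,
            theta_wt_cl = 0.75, theta_jp_cl = -0.1, theta_jp_v = -0.1,
            omega2_cl = 0.09, omega2_v = 0.09, sigma_prop = 0.15)
}

#' Generative ADA-process parameters
#'
#' Parameters of the hidden ADA chain and its consequences used by
#' [simulate_cohort()]: per-record transition probabilities, the ADA-assay
#' emission in each state, the clearance inflation applied while a subject is
#' in the production state (which makes the no-ADA PK model over-predict and
#' drives the weighted residuals negative), and the assay constants.
#'
#' @param pi12,pi21 Per-record transition probabilities (S_NOADA to S_ADA and
#'   back), in `[0, 1)`.
#' @param ada_mu_noada,ada_mu_ada ADA emission modes by state (U/mL).
#' @param ada_sd ADA emission SD (U/mL). The default 0.4 reflects assay-like
#'   behaviour: no-production values sit at or just above the LLOQ and
#'   essentially never cross the 2.4 U/mL clinical threshold by noise alone,
#'   so the simulated clinically-positive fraction matches what trials of
#'   this kind report (~10%). This is deliberately smaller than the
#'   fitted model's shared emission SD, which is inflated by the
#'   shared-variance compromise.
#' @param cl_inflation_ada Multiplicative CL/F increase while in `S_ADA`
#'   (>= 1).
#' @param lognormal_ada If `TRUE`, draw ADA values log-normally (heavier right
#'   tail) with the same state medians and approximate spread; default uses
#'   the Gaussian emission, floored at the LLOQ.
#' @return An object of class `ada_generative_params`.
#' @export
ada_generative_params <- function(pi12 = 0.03, pi21 = 0.003,
                                  ada_mu_noada = 0.6, ada_mu_ada = 2.4,
                                  ada_sd = 0.4,
                                  cl_inflation_ada = 2,
                                  lognormal_ada = FALSE) {
  stopifnot(pi12 >= 0, pi12 < 1, pi21 >= 0, pi21 < 1,
            cl_inflation_ada >= 1, ada_sd > 0,
            ada_mu_ada > ada_mu_noada)
  structure(list(pi12 = pi12, pi21 = pi21,
                 ada_mu_noada = ada_mu_noada, ada_mu_ada = ada_mu_ada,
                 ada_sd = ada_sd, cl_inflation_ada = cl_inflation_ada,
                 lognormal_ada = lognormal_ada),
            class = "ada_generative_params")
}

# simulate an n x T matrix of hidden states (1/2), everyone starting in
# S_NOADA at the first record; p12/p21 scalars or length-n vectors
.sim_chain <- function(n, Tn, p12, p21) {
  s <- matrix(1L, n, Tn)
  if (Tn < 2) return(s)
  for (t in 2:Tn) {
    u <- stats::runif(n)
    prev <- s[, t - 1]
    go <- ifelse(prev == 1L, u < p12, u >= p21)  # TRUE -> in S_ADA at t
    s[, t] <- ifelse(go, 2L, 1L)
  }
  s
}

#' Simulate a clinical-trial cohort with hidden ADA dynamics
#'
#' Generates a long-format dataset emulating the trial designs: per subject,
#' covariates and individual PK parameters are drawn, the hidden two-state
#' chain evolves once per scheduled sampling record starting in `S_NOADA`,
#' clearance is inflated by `cl_inflation_ada` while the subject is in
#' `S_ADA`, PK observations are drawn with proportional error (floored at the
#' 0.41 ug/mL LLOQ with a BLQ flag) and ADA observations from the state's
#' Gaussian (floored at the 0.6 U/mL LLOQ). PK samples at or before the first
#' dose are never emitted. The hidden truth is returned alongside the data.
#'
#' @param designs List of [study_design()] objects (default
#'   [default_designs()]).
#' @param pk A [pk_params()] object (default [default_pk_params()]).
#' @param ada An [ada_generative_params()] object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `ada_cohort`: list with `data` (long-format
#'   data frame, see [long_format]) and `truth` (data frame `subject_id`,
#'   `time`, `state`).
#' @export
simulate_cohort <- function(designs = default_designs(),
                            pk = default_pk_params(),
                            ada = ada_generative_params(),
                            seed = 1) {
  set.seed(seed)
  lim <- assay_limits()
  data_rows <- list()
  truth_rows <- list()
  sid <- 0L
  for (des in designs) {
    for (i in seq_len(des$n_subjects)) {
      sid <- sid + 1L
      subject_id <- sprintf("S%04d", sid)
      wt <- stats::rlnorm(1, log(des$weight_median),
                          sqrt(log(1 + des$weight_cv^2)))
      jp <- stats::rbinom(1, 1, des$japanese_fraction)
      arm <- sample.int(length(des$dose_mg), 1)
      doses <- .dose_schedule(des, arm)
      eta_cl <- stats::rnorm(1, 0, sqrt(pk$omega2_cl))
      eta_v <- stats::rnorm(1, 0, sqrt(pk$omega2_v))
      typ <- .typical_pk(pk, wt, jp)
      cl_i <- typ$cl * exp(eta_cl)
      v_i <- typ$v * exp(eta_v)

      times <- des$sampling_days
      Tn <- length(times)
      st <- drop(.sim_chain(1, Tn, ada$pi12, ada$pi21))

      rows <- list()
      for (t in seq_len(Tn)) {
        occ <- max(1L, findInterval(times[t], doses$time))
        # PK sample (absent at or before the first dose)
        if (times[t] > doses$time[1]) {
          cl_eff <- cl_i * if (st[t] == 2L) ada$cl_inflation_ada else 1
          f <- predict_concentration(times[t], doses, cl_eff, v_i, pk$ka)
          y <- f * (1 + stats::rnorm(1, 0, pk$sigma_prop))
          blq <- y < lim$lloq_pk
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = subject_id, study = des$name, time = times[t],
            evid = 0L, amt = NA_real_, dvid = 1L,
            dv = if (blq) lim$lloq_pk else y, blq = as.integer(blq),
            occasion = occ, weight = wt, japanese = jp,
            stringsAsFactors = FALSE)
        }
        # ADA sample
        if (des$ada_measured) {
          mu <- if (st[t] == 2L) ada$ada_mu_ada else ada$ada_mu_noada
          y <- if (ada$lognormal_ada) {
            stats::rlnorm(1, log(mu), ada$ada_sd / mu)
          } else {
            stats::rnorm(1, mu, ada$ada_sd)
          }
          blq <- y < lim$lloq_ada
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = subject_id, study = des$name, time = times[t],
            evid = 0L, amt = NA_real_, dvid = 2L,
            dv = if (blq) lim$lloq_ada else y, blq = as.integer(blq),
            occasion = occ, weight = wt, japanese = jp,
            stringsAsFactors = FALSE)
        }
      }
      dose_rows <- data.frame(
        subject_id = subject_id, study = des$name, time = doses$time,
        evid = 1L, amt = doses$amt, dvid = NA_integer_, dv = NA_real_,
        blq = 0L, occasion = doses$occasion, weight = wt, japanese = jp,
        stringsAsFactors = FALSE)
      data_rows[[length(data_rows) + 1]] <-
        rbind(dose_rows, do.call(rbind, rows))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject_id = subject_id, time = times,
        state = .state_labels[st], stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, data_rows)
  data <- data[order(data$subject_id, data$time, data$evid), ]
  rownames(data) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(data = data, truth = truth), class = "ada_cohort")
}

.dose_schedule <- function(des, arm) {
  horizon <- max(des$sampling_days)
  amt <- des$dose_mg[arm]
  if (des$interval == "single") {
    d <- data.frame(time = 0, amt = amt)
  } else {
    step <- if (des$interval == "Q2W") 14 else 28
    if (!is.null(des$loading_dose_mg)) {
      ld <- des$loading_dose_mg[arm]
      lt <- c(0, 14, 28)
      mt <- seq(42, max(horizon, 42), by = step)
      d <- data.frame(time = c(lt, mt), amt = c(rep(ld, 3), rep(amt, length(mt))))
    } else {
      tt <- seq(0, horizon, by = step)
      d <- data.frame(time = tt, amt = rep(amt, length(tt)))
    }
  }
  d$occasion <- seq_len(nrow(d))
  d
}

#' @export
print.ada_cohort <- function(x, ...) {
  cat("Simulated ADA cohort:", length(unique(x$data$subject_id)),
      "subjects,", sum(x$data$evid == 0), "observation rows\n")
  ever <- tapply(x$truth$state == "S_ADA", x$truth$subject_id, any)
  cat("subjects ever in S_ADA (truth):", sum(ever),
      sprintf("(%.1f%%)\n", 100 * mean(ever)))
  invisible(x)
}

# simulate bivariate emissions for a state matrix (n x T); returns list(Y1, Y2)
.sim_emissions <- function(st, em, floor_ada = TRUE,
                           eta_mu_pkres = 0, eta_mu_ada = 0) {
  n <- nrow(st)
  Tn <- ncol(st)
  mu1 <- c(em$mu_pkres_noada, em$mu_pkres_ada)
  mu2 <- c(em$mu_ada_noada, em$mu_ada_ada)
  s1 <- sqrt(em$sigma2_pkres)
  s2 <- sqrt(em$sigma2_ada)
  rho <- c(em$rho_noada, em$rho_ada)[st]
  z1 <- matrix(stats::rnorm(n * Tn), n, Tn)
  z2 <- matrix(stats::rnorm(n * Tn), n, Tn)
  Y1 <- mu1[st] + eta_mu_pkres + s1 * z1
  Y2 <- mu2[st] + eta_mu_ada + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  dim(Y1) <- dim(Y2) <- c(n, Tn)
  if (floor_ada) Y2[Y2 < assay_limits()$lloq_ada] <- assay_limits()$lloq_ada
  list(Y1 = Y1, Y2 = Y2)
}

#' Simulate observation records directly from the hidden-Markov model
#'
#' Draws hidden chains (everyone starting in `S_NOADA`) and bivariate Gaussian
#' emissions at the given parameters, for a balanced cohort of `n_subjects`
#' subjects with `n_records` records each. By default the draws follow the
#' model density exactly (no LLOQ truncation), which is what parameter
#' recovery studies require; set `floor_ada = TRUE` to additionally apply the
#' 0.6 U/mL assay floor as real data would show it. Random effects with
#' positive `omega2_*` in `em`/`tp` are drawn per subject.
#'
#' @param n_subjects,n_records Cohort dimensions.
#' @param em,tp Generating parameters.
#' @param seed Integer seed.
#' @param times Record times in days (default 14-day spacing).
#' @param floor_ada Apply the LLOQ floor to simulated ADA values.
#' @return Object of class `mhmm_sim`: list with `records` (data frame
#'   `subject_id`, `time`, `y_pkres`, `y_ada`) and `states` (same shape with
#'   `state`).
#' @export
simulate_mhmm <- function(n_subjects, n_records, em, tp, seed = 1,
                          times = 14 * seq_len(n_records),
                          floor_ada = FALSE) {
  stopifnot(length(times) == n_records)
  set.seed(seed)
  eta12 <- if (tp$omega2_pi12 > 0)
    stats::rnorm(n_subjects, 0, sqrt(tp$omega2_pi12)) else 0
  eta21 <- if (tp$omega2_pi21 > 0)
    stats::rnorm(n_subjects, 0, sqrt(tp$omega2_pi21)) else 0
  e_mu1 <- if (em$omega2_mu_pkres > 0)
    stats::rnorm(n_subjects, 0, sqrt(em$omega2_mu_pkres)) else 0
  e_mu2 <- if (em$omega2_mu_ada > 0)
    stats::rnorm(n_subjects, 0, sqrt(em$omega2_mu_ada)) else 0
  p12 <- stats::plogis(tp$logit_pi12 + eta12)
  p21 <- stats::plogis(tp$logit_pi21 + eta21)
  st <- .sim_chain(n_subjects, n_records, p12, p21)
  ym <- .sim_emissions(st, em, floor_ada,
                       eta_mu_pkres = if (length(e_mu1) > 1)
                         matrix(e_mu1, n_subjects, n_records) else e_mu1,
                       eta_mu_ada = if (length(e_mu2) > 1)
                         matrix(e_mu2, n_subjects, n_records) else e_mu2)
  ids <- sprintf("S%05d", seq_len(n_subjects))
  records <- data.frame(
    subject_id = rep(ids, times = n_records),
    time = rep(times, each = n_subjects),
    y_pkres = as.vector(ym$Y1), y_ada = as.vector(ym$Y2),
    stringsAsFactors = FALSE)
  states <- data.frame(
    subject_id = rep(ids, times = n_records),
    time = rep(times, each = n_subjects),
    state = .state_labels[as.vector(st)], stringsAsFactors = FALSE)
  o <- order(records$subject_id, records$time)
  structure(list(records = records[o, ], states = states[o, ]),
            class = "mhmm_sim")
}

#' Simulate the observed variables from a fitted model
#'
#' Posterior-predictive style simulation: for each replicate, hidden chains
#' and emissions are drawn at the fitted parameters over the skeleton's
#' record grid (per-subject record times). Simulated ADA measurements below
#' 0.6 U/mL are set to 0.6, the assay LLOQ.
#'
#' @param fit An `mhmm_fit` (or `list(em, tp)`).
#' @param skeleton Data frame with columns `subject_id` and `time` giving the
#'   record grid (e.g. the fitted record table).
#' @param n_sim Number of replicates (default 100).
#' @param seed Integer seed.
#' @return Data frame `replicate`, `subject_id`, `time`, `y_pkres`, `y_ada`.
#' @export
simulate_observed_from_fit <- function(fit, skeleton, n_sim = 100, seed = 1) {
  pars <- .fit_params(fit)
  skeleton <- skeleton[order(skeleton$subject_id, skeleton$time), ]
  sp <- split(skeleton$time, skeleton$subject_id, drop = TRUE)
  n <- length(sp)
  len <- vapply(sp, length, integer(1))
  Tmax <- max(len)
  set.seed(seed)
  p12 <- stats::plogis(pars$tp$logit_pi12)
  p21 <- stats::plogis(pars$tp$logit_pi21)
  out <- vector("list", n_sim)
  keep <- sequence(len) + rep((seq_len(n) - 1) * Tmax, times = len)
  ids <- rep(names(sp), times = Tmax)  # column-major n x Tmax
  tvec <- unlist(sp, use.names = FALSE)
  for (r in seq_len(n_sim)) {
    st <- .sim_chain(n, Tmax, p12, p21)
    ym <- .sim_emissions(st, pars$em, floor_ada = TRUE)
    # matrices are n x Tmax column-major; per-subject row i uses entries
    # i, i+n, i+2n, ... -> index by (t-1)*n + i
    idx <- unlist(lapply(seq_len(n), function(i)
      (seq_len(len[i]) - 1) * n + i), use.names = FALSE)
    out[[r]] <- data.frame(
      replicate = r,
      subject_id = rep(names(sp), times = len),
      time = tvec,
      y_pkres = ym$Y1[idx], y_ada = ym$Y2[idx],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
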
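#' Threshold-based clinical ADA classification
#'
#' A subject is clinically ADA positive when at least one ADA measurement
#' exceeds the threshold (default 2.4 U/mL). Positive subjects are further
#' labelled `"transient"` when their last two or more ADA records have fallen
#' back below the threshold, else `"persistent"`; this codifies the visual
#' profile inspection traditionally used for that call and is a stand-in for
#' it.
#'
#' @param data A long-format data frame (see [long_format]), an `ada_cohort`,
#'   or a prepared record table with columns `subject_id`, `time`, `y_ada`.
#' @param threshold Clinical positivity threshold (U/mL).
#' @return Data frame `subject_id`, `ever_positive`, `first_positive_time`,
#'   `classification` (`"persistent"`/`"transient"`/`NA`). Subjects without
#'   any ADA record are absent from the result.
#' @export
classify_clinical <- function(data, threshold = 2.4) {
  ada <- .extract_ada(data)
  if (nrow(ada) == 0)
    return(data.frame(subject_id = character(), ever_positive = logical(),
                      first_positive_time = numeric(),
                      classification = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(split(ada, ada$subject_id, drop = TRUE), function(d) {
    d <- d[order(d$time), ]
    pos <- d$value > threshold
    ever <- any(pos)
    first_t <- if (ever) d$time[which(pos)[1]] else NA_real_
    cls <- NA_character_
    if (ever) {
      # trailing run of below-threshold records
      trail <- rev(cumprod(rev(!pos)))
      n_trail <- sum(trail > 0)
      cls <- if (n_trail >= 2) "transient" else "persistent"
    }
    data.frame(subject_id = d$subject_id[1], ever_positive = ever,
               first_positive_time = first_t, classification = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.extract_ada <- function(data) {
  if (inherits(data, "ada_cohort")) data <- data$data
  if ("y_ada" %in% names(data)) {
    d <- data[!is.na(data$y_ada), c("subject_id", "time", "y_ada")]
    names(d)[3] <- "value"
    return(d)
  }
  if (all(c("evid", "dvid", "dv") %in% names(data))) {
    d <- data[data$evid == 0 & data$dvid == 2 & !is.na(data$dv),
              c("subject_id", "time", "dv")]
    names(d)[3] <- "value"
    return(d)
  }
  stop("cannot find ADA measurements in 'data'", call. = FALSE)
}

#' Summarize decoded state sequences
#'
#' Per-subject summaries of decoded (or true) state paths: whether the subject
#' was ever in `S_ADA`, the time of first entry, and the fraction of records
#' spent there.
#'
#' @param paths Data frame `subject_id`, `time`, `state` (as returned by
#'   [decode_states()] or a cohort's `truth` element).
#' @return Data frame `subject_id`, `ever_in_s_ada`, `first_s_ada_time`,
#'   `frac_s_ada`; attribute `mean_first_s_ada_time` is the cohort mean over
#'   subjects with an entry.
#' @export
summarize_paths <- function(paths) {
  rows <- lapply(split(paths, paths$subject_id, drop = TRUE), function(d) {
    d <- d[order(d$time), ]
    inada <- d$state == "S_ADA"
    data.frame(subject_id = d$subject_id[1],
               ever_in_s_ada = any(inada),
               first_s_ada_time = if (any(inada)) d$time[which(inada)[1]]
               else NA_real_,
               frac_s_ada = mean(inada), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_first_s_ada_time") <-
    if (any(out$ever_in_s_ada))
      mean(out$first_s_ada_time[out$ever_in_s_ada]) else NA_real_
  out
}

#' Compare clinical detection times with model state-entry times
#'
#' For subjects clinically ADA positive, pairs the time of the first
#' above-threshold ADA measurement with the decoded first time in `S_ADA`,
#' and reports the two means and per-subject differences. Because the model
#' pools the PK signal with the assay, state entry typically precedes
#' clinical detection.
#'
#' @param clinical Result of [classify_clinical()].
#' @param states Result of [summarize_paths()].
#' @return A list of class `time_comparison`: `mean_first_positive`,
#'   `mean_first_s_ada`, and `paired`, a data frame `subject_id`,
#'   `first_positive_time`, `first_s_ada_time`, `difference` (model minus
#'   clinical; negative means earlier model detection). Restricted to
#'   clinically positive subjects present in both inputs; empty inputs yield
#'   an explicit empty result.
#' @export
compare_times <- function(clinical, states) {
  pos <- clinical[clinical$ever_positive, ]
  m <- merge(pos[, c("subject_id", "first_positive_time")],
             states[, c("subject_id", "first_s_ada_time")],
             by = "subject_id")
  if (nrow(m) == 0)
    return(structure(list(mean_first_positive = NA_real_,
                          mean_first_s_ada = NA_real_,
                          paired = m), class = "time_comparison"))
  m$difference <- m$first_s_ada_time - m$first_positive_time
  structure(list(
    mean_first_positive = mean(m$first_positive_time),
    mean_first_s_ada = mean(m$first_s_ada_time, na.rm = TRUE),
    paired = m
  ), class = "time_comparison")
}

#' @export
print.time_comparison <- function(x, ...) {
  cat("Clinically positive subjects paired:", nrow(x$paired), "\n")
  cat(sprintf("mean time to first positive measurement: %.1f days\n",
              x$mean_first_positive))
  cat(sprintf("mean decoded first time in S_ADA:        %.1f days\n",
              x$mean_first_s_ada))
  invisible(x)
}

#' Compare observed and simulated distributions over time bins
#'
#' Bins records by time (default 28-day buckets over the union of sampling
#' days) and contrasts observed percentiles with the distribution of the same
#' percentiles across simulated replicates, in the manner of a visual
#' predictive check.
#'
#' @param observed Data frame with `time` and the chosen `variable`.
#' @param simulated Replicate table from [simulate_observed_from_fit()]
#'   (must contain `replicate`, `time` and the variable).
#' @param variable `"y_pkres"` or `"y_ada"`.
#' @param bin_width Time bin width in days.
#' @param probs Percentiles to compare (default 5/50/95).
#' @return Data frame with one row per bin and percentile: `bin_mid`, `n_obs`,
#'   `prob`, `observed`, `sim_lo`, `sim_med`, `sim_hi` (2.5/50/97.5 percentiles
#'   of the replicate percentile). Bins without observed or simulated values
#'   are dropped with a warning.
#' @export
distribution_check <- function(observed, simulated,
                               variable = c("y_pkres", "y_ada"),
                               bin_width = 28, probs = c(0.05, 0.5, 0.95)) {
  variable <- match.arg(variable)
  stopifnot(length(unique(simulated$replicate)) >= 1)
  ov <- observed[[variable]]
  sv <- simulated[[variable]]
  keep_o <- !is.na(ov)
  keep_s <- !is.na(sv)
  breaks <- seq(0, max(observed$time, simulated$time) + bin_width,
                by = bin_width)
  ob <- cut(observed$time[keep_o], breaks, include.lowest = TRUE,
            labels = FALSE)
  sb <- cut(simulated$time[keep_s], breaks, include.lowest = TRUE,
            labels = FALSE)
  out <- list()
  dropped <- 0L
  for (b in sort(unique(ob))) {
    oi <- ov[keep_o][ob == b]
    si <- sb == b
    if (length(oi) == 0 || !any(si)) {
      dropped <- dropped + 1L
      next
    }
    sd_ <- simulated[keep_s, ][si, ]
    per_rep <- tapply(sd_[[variable]], sd_$replicate,
                      stats::quantile, probs = probs, names = FALSE)
    per_rep <- do.call(rbind, per_rep)  # n_rep x length(probs)
    qo <- stats::quantile(oi, probs = probs, names = FALSE)
    mid <- (breaks[b] + breaks[b + 1]) / 2
    for (k in seq_along(probs)) {
      band <- stats::quantile(per_rep[, k], c(0.025, 0.5, 0.975),
                              names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        bin_mid = mid, n_obs = length(oi), prob = probs[k],
        observed = qo[k], sim_lo = band[1], sim_med = band[2],
        sim_hi = band[3])
    }
  }
  if (dropped > 0)
    warning(dropped, " empty time bin(s) dropped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Balanced accuracy of decoded ever-in-S_ADA against the truth
#'
#' Convenience diagnostic for simulation studies where the hidden truth is
#' retained: the mean of sensitivity and specificity of the per-subject
#' decoded "ever in `S_ADA`" flag.
#'
#' @param decoded Data frame `subject_id`, `time`, `state` from
#'   [decode_states()].
#' @param truth Data frame of the same shape with the generating states.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
state_balanced_accuracy <- function(decoded, truth) {
  d <- summarize_paths(decoded)
  t_ <- summarize_paths(truth)
  m <- merge(d[, c("subject_id", "ever_in_s_ada")],
             t_[, c("subject_id", "ever_in_s_ada")],
             by = "subject_id", suffixes = c("_hat", "_true"))
  sens <- mean(m$ever_in_s_ada_hat[m$ever_in_s_ada_true])
  spec <- mean(!m$ever_in_s_ada_hat[!m$ever_in_s_ada_true])
  (sens + spec) / 2
}
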
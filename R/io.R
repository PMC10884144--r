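#' Long-format dataset columns
#'
#' Datasets use a NONMEM-style long format with one row per subject-time-event:
#' `subject_id`, `study`, `time` (days, 0-based from each subject's first
#' dose), `evid` (0 observation, 1 dose), `amt` (mg, dose rows), `dvid`
#' (1 PK concentration ug/mL, 2 ADA measurement U/mL; observation rows),
#' `dv` (value), `blq` (0/1 below-LLOQ flag), `occasion`, `weight` (kg),
#' `japanese` (0/1).
#'
#' @name long_format
#' @keywords internal
NULL

.required_cols <- c("subject_id", "study", "time", "evid", "amt", "dvid",
                    "dv", "blq", "weight", "japanese")

#' Assay limits of quantification and the clinical threshold
#'
#' LLOQ of the drug concentration assay (0.41 ug/mL) and of the ADA assay
#' (0.6 U/mL); measurements below these are reported at the limit. The
#' clinical ADA positivity threshold is 2.4 U/mL.
#' @export
assay_limits <- function() {
  list(lloq_pk = 0.41, lloq_ada = 0.6, clinical_threshold = 2.4)
}

#' Read a long-format dataset
#'
#' Reads the CSV defined in [long_format], validates it, substitutes
#' below-LLOQ values by the assay limits (0.41 ug/mL for PK, 0.6 U/mL for
#' ADA), groups rows by subject in time order, and merges simultaneous PK and
#' ADA observations at the same time into single records.
#'
#' @param path CSV file path (UTF-8).
#' @return An object of class `ada_dataset`: a list with one entry per
#'   subject, each a list with `subject_id`, `study`, `weight`, `japanese`,
#'   `doses` (data frame `time`, `amt`, `occasion`) and `obs` (data frame
#'   `time`, `pk`, `ada`, `pk_blq`, `ada_blq`, `occasion`; `NA` marks an
#'   absent component).
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_ada_dataset(df)
}

#' @rdname read_dataset
#' @param df A long-format data frame (e.g. the `data` element of a simulated
#'   cohort).
#' @export
as_ada_dataset <- function(df) {
  miss <- setdiff(.required_cols, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(df$time < 0)
  if (length(bad) > 0)
    stop("negative time at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  is_obs <- df$evid == 0
  bad <- which(is_obs & !df$dvid %in% c(1, 2))
  if (length(bad) > 0)
    stop("unknown dvid at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  bad <- which(is_obs & is.na(df$dv))
  if (length(bad) > 0)
    stop("observation row without dv at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is_obs & (is.na(df$amt) | df$amt <= 0))
  if (length(bad) > 0)
    stop("dose row without positive amt at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  lim <- assay_limits()
  df$dv[is_obs & df$blq == 1 & df$dvid == 1] <- lim$lloq_pk
  df$dv[is_obs & df$blq == 1 & df$dvid == 2] <- lim$lloq_ada

  subjects <- lapply(split(df, df$subject_id, drop = TRUE), function(d) {
    d <- d[order(d$time, d$evid), ]
    doses <- d[d$evid == 1, c("time", "amt")]
    doses <- doses[order(doses$time), ]
    doses$occasion <- seq_len(nrow(doses))
    obs <- d[d$evid == 0, ]
    # occasion of a record: index of the latest dose at or before it (min 1)
    occ_of <- function(t) {
      if (nrow(doses) == 0) return(rep(1L, length(t)))
      pmax(1L, findInterval(t, doses$time))
    }
    times <- sort(unique(obs$time))
    rec <- data.frame(time = times, pk = NA_real_, ada = NA_real_,
                      pk_blq = FALSE, ada_blq = FALSE,
                      occasion = occ_of(times))
    for (i in seq_len(nrow(obs))) {
      j <- match(obs$time[i], times)
      if (obs$dvid[i] == 1) {
        rec$pk[j] <- obs$dv[i]
        rec$pk_blq[j] <- obs$blq[i] == 1
      } else {
        rec$ada[j] <- obs$dv[i]
        rec$ada_blq[j] <- obs$blq[i] == 1
      }
    }
    list(subject_id = as.character(d$subject_id[1]),
         study = as.character(d$study[1]),
         weight = d$weight[1], japanese = as.integer(d$japanese[1]),
         doses = doses, obs = rec)
  })
  structure(subjects, class = "ada_dataset")
}

#' Write a long-format dataset
#'
#' @param data A long-format data frame (see [long_format]) or a simulated
#'   cohort object.
#' @param path Output CSV path.
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "ada_cohort")) data <- data$data
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Flatten an `ada_dataset` back to the long format
#'
#' Inverse of [as_ada_dataset()] (up to row order and the derived `occasion`
#' column).
#'
#' @param dataset An `ada_dataset`.
#' @return A long-format data frame.
#' @export
as_long_format <- function(dataset) {
  rows <- lapply(dataset, function(sub) {
    dose_rows <- if (nrow(sub$doses) > 0)
      data.frame(subject_id = sub$subject_id, study = sub$study,
                 time = sub$doses$time, evid = 1L, amt = sub$doses$amt,
                 dvid = NA_integer_, dv = NA_real_, blq = 0L,
                 occasion = sub$doses$occasion,
                 weight = sub$weight, japanese = sub$japanese,
                 stringsAsFactors = FALSE)
    obs_rows <- do.call(rbind, lapply(seq_len(nrow(sub$obs)), function(i) {
      r <- sub$obs[i, ]
      out <- NULL
      if (!is.na(r$pk))
        out <- rbind(out, data.frame(
          subject_id = sub$subject_id, study = sub$study, time = r$time,
          evid = 0L, amt = NA_real_, dvid = 1L, dv = r$pk,
          blq = as.integer(r$pk_blq), occasion = r$occasion,
          weight = sub$weight, japanese = sub$japanese,
          stringsAsFactors = FALSE))
      if (!is.na(r$ada))
        out <- rbind(out, data.frame(
          subject_id = sub$subject_id, study = sub$study, time = r$time,
          evid = 0L, amt = NA_real_, dvid = 2L, dv = r$ada,
          blq = as.integer(r$ada_blq), occasion = r$occasion,
          weight = sub$weight, japanese = sub$japanese,
          stringsAsFactors = FALSE))
      out
    }))
    rbind(dose_rows, obs_rows)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$time, out$evid), ]
  rownames(out) <- NULL
  out
}

#' Merge PK residuals and ADA measurements into HMM observation records
#'
#' Builds the bivariate record table consumed by [fit_mhmm()] and
#' [decode_states()]: one row per subject observation record with the weighted
#' PK residual (where defined) and the ADA measurement, either possibly
#' missing.
#'
#' @param dataset An `ada_dataset`.
#' @param iwres Residual table from [compute_iwres()]. May be `NULL` for
#'   ADA-only use.
#' @return Data frame `subject_id`, `time`, `y_pkres`, `y_ada`; records with
#'   both components missing are dropped.
#' @export
prepare_hmm_records <- function(dataset, iwres = NULL) {
  rows <- lapply(dataset, function(sub) {
    r <- sub$obs
    y_pkres <- rep(NA_real_, nrow(r))
    if (!is.null(iwres)) {
      iw <- iwres[iwres$subject_id == sub$subject_id, ]
      m <- match(r$time, iw$time)
      y_pkres[!is.na(m)] <- iw$iwres[m[!is.na(m)]]
    }
    data.frame(subject_id = sub$subject_id, time = r$time,
               y_pkres = y_pkres, y_ada = r$ada, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!(is.na(out$y_pkres) & is.na(out$y_ada)), ]
  rownames(out) <- NULL
  out
}

#' Read study designs from a YAML file
#'
#' The YAML file holds a list of design blocks mirroring the fields of
#' [study_design()] (`name`, `n_subjects`, `dose_mg`, `interval`,
#' `sampling_days`, optional `loading_dose_mg`, `weight_median`, `weight_cv`,
#' `japanese_fraction`, `ada_measured`).
#'
#' @param path YAML file path.
#' @return A list of [study_design()] objects.
#' @export
read_design_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) do.call(study_design, x))
}
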
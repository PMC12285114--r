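#' Split a cohort into a person-period table
#'
#' Expands each individual's follow-up into one row per integer-age band
#' and state. While disease free, an individual contributes exposure from
#' entry until disease onset, non-disease death, or censoring; after
#' onset they contribute exposure in the diseased state until death or
#' censoring. The band containing an event carries that event; events
#' falling exactly on an integer age are attributed to the preceding band.
#'
#' @param cohort a `cohort_table` data.frame (see [simulate_cohort()] /
#'   [read_cohort()]).
#' @return data.frame of class `person_period` with columns `id`, `state`
#'   (`"free"`/`"cvd"`), `age_band` (integer start of the 1-year band),
#'   `exposure_time`, `event` (`"none"`, `"t1"`, `"t2"`, `"t3"`), plus the
#'   cohort's `sex`, `group`, and covariate columns.
#' @export
split_person_time <- function(cohort) {
  free_end <- pmin(ifelse(is.na(cohort$age_cvd), Inf, cohort$age_cvd),
                   ifelse(is.na(cohort$age_death), Inf, cohort$age_death),
                   cohort$censor_age)
  free_event <- ifelse(cohort$cvd & free_end == cohort$age_cvd, "t1",
                ifelse(cohort$death & !cohort$cvd &
                         free_end == cohort$age_death, "t2", "none"))
  bad <- which(free_end <= cohort$entry_age |
                 (cohort$cvd & !is.na(cohort$age_death) &
                    cohort$age_death < cohort$age_cvd))
  if (length(bad) > 0) {
    warning(length(bad), " row(s) with inconsistent ages rejected: ids ",
            paste(utils::head(cohort$id[bad], 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "")
  }
  keep <- setdiff(seq_len(nrow(cohort)), bad)

  expand <- function(idx, start, end, event, state) {
    if (length(idx) == 0L) {
      return(data.frame(row = integer(0), state = character(0),
                        age_band = integer(0), exposure_time = numeric(0),
                        event = character(0), stringsAsFactors = FALSE))
    }
    first <- as.integer(floor(start))
    last <- as.integer(ceiling(end) - 1)
    nb <- pmax(1L, last - first + 1L)
    row_i <- rep(idx, nb)
    band <- sequence(nb, from = first, by = 1L)
    s <- rep(start, nb)
    e <- rep(end, nb)
    expo <- pmin(e, band + 1) - pmax(s, band)
    ev <- rep("none", length(band))
    is_last <- band == rep(last, nb)
    ev[is_last] <- rep(event, nb)[is_last]
    data.frame(row = row_i, state = state, age_band = band,
               exposure_time = expo, event = ev,
               stringsAsFactors = FALSE)
  }

  pieces <- list()
  fk <- keep[free_end[keep] > cohort$entry_age[keep]]
  pieces$free <- expand(fk, cohort$entry_age[fk], free_end[fk],
                        free_event[fk], "free")
  ck <- keep[cohort$cvd[keep]]
  if (length(ck) > 0) {
    cvd_end <- pmin(ifelse(is.na(cohort$age_death[ck]), Inf,
                           cohort$age_death[ck]),
                    cohort$censor_age[ck])
    cvd_event <- ifelse(cohort$death[ck] & cvd_end == cohort$age_death[ck],
                        "t3", "none")
    pos <- cvd_end > cohort$age_cvd[ck]
    pieces$cvd <- expand(ck[pos], cohort$age_cvd[ck][pos], cvd_end[pos],
                         cvd_event[pos], "cvd")
  }
  ppt <- do.call(rbind, pieces)
  carry <- setdiff(names(cohort),
                   c("age_cvd", "age_death", "censor_age", "cvd", "death",
                     "entry_age"))
  out <- cbind(ppt[setdiff(names(ppt), "row")], cohort[ppt$row, carry,
                                                       drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("person_period", "data.frame")
  out
}

#' Fit an age-specific Poisson transition-rate model
#'
#' Pools all exposure groups and fits a Poisson log-linear model of event
#' counts on an age basis with a log person-time offset, giving the
#' population-average 1-year transition rate \eqn{\hat\lambda(x)}. The
#' default basis is linear in age on the log scale (Gompertz-like); a
#' natural-spline basis is available.
#'
#' @param ppt a `person_period` table from [split_person_time()].
#' @param transition 1, 2, or 3.
#' @param basis `"gompertz"` (log-linear in age), `"constant"`
#'   (intercept only), or `"spline"` (natural spline).
#' @param df spline degrees of freedom when `basis = "spline"`.
#' @return object of class `poisson_rate_model`: list with `transition`,
#'   `coef`, `vcov`, `basis`, `df`, `knots` and a rate evaluator usable via
#'   [rate_at()].
#' @export
fit_rates <- function(ppt, transition,
                      basis = c("gompertz", "constant", "spline"),
                      df = 4) {
  basis <- match.arg(basis)
  state <- if (transition == 3) "cvd" else "free"
  ev <- paste0("t", transition)
  d <- ppt[ppt$state == state & ppt$exposure_time > 0, , drop = FALSE]
  agg <- stats::aggregate(
    cbind(events = d$event == ev, py = d$exposure_time),
    by = list(age_band = d$age_band), FUN = sum)
  if (sum(agg$events) == 0) {
    stop("no transition-", transition, " events; cannot fit rate model")
  }
  agg$age <- agg$age_band + 0.5
  if (basis == "gompertz") {
    fit <- stats::glm(events ~ age, offset = log(py), data = agg,
                      family = stats::poisson())
    knots <- NULL; bknots <- NULL
  } else if (basis == "constant") {
    fit <- stats::glm(events ~ 1, offset = log(py), data = agg,
                      family = stats::poisson())
    knots <- NULL; bknots <- NULL
  } else {
    basis_obj <- splines::ns(agg$age, df = df)
    knots <- attr(basis_obj, "knots")
    bknots <- attr(basis_obj, "Boundary.knots")
    fit <- stats::glm(events ~ splines::ns(age, knots = knots,
                                           Boundary.knots = bknots),
                      offset = log(py), data = agg,
                      family = stats::poisson())
  }
  structure(list(transition = transition, basis = basis, df = df,
                 coef = stats::coef(fit), vcov = stats::vcov(fit),
                 knots = knots, boundary_knots = bknots),
            class = "poisson_rate_model")
}

#' Evaluate a fitted (or perturbed) transition rate at given ages
#'
#' @param model a `poisson_rate_model`.
#' @param age numeric vector of ages.
#' @param coef optional replacement coefficient vector (used by the
#'   parametric bootstrap).
#' @return rate per person-year at each age (always positive).
#' @export
rate_at <- function(model, age, coef = NULL) {
  cf <- if (is.null(coef)) model$coef else coef
  X <- switch(model$basis,
    gompertz = cbind(1, age),
    constant = matrix(1, length(age), 1),
    cbind(1, splines::ns(age, knots = model$knots,
                         Boundary.knots = model$boundary_knots)))
  as.numeric(exp(X %*% cf))
}

#' Five-year age-specific category prevalence by state
#'
#' Computes, within each 5-year age band (40-44, ..., 85-89) and state,
#' the person-time share of each exposure group. Empty (band, state) cells
#' inherit the proportions of the nearest non-empty band in the same state
#' (with a message). Effective person-years per cell are retained for the
#' Dirichlet draws of the parametric bootstrap.
#'
#' @param ppt a `person_period` table.
#' @param group_col name of the exposure-category column (default
#'   `"group"`).
#' @param age_range bands covered, default `c(40, 90)`.
#' @return data.frame of class `prevalence_table`: `band_start`, `state`,
#'   `group`, `proportion`, `total_py` (cell person-years).
#' @export
compute_prevalence <- function(ppt, group_col = "group",
                               age_range = c(40, 90)) {
  starts <- seq(age_range[1], age_range[2] - 5, by = 5)
  groups <- if (is.factor(ppt[[group_col]])) levels(ppt[[group_col]])
            else sort(unique(ppt[[group_col]]))
  d <- ppt[ppt$age_band >= age_range[1] & ppt$age_band < age_range[2], ,
           drop = FALSE]
  d$band_start <- starts[findInterval(d$age_band, starts)]
  agg <- stats::aggregate(
    list(py = d$exposure_time),
    by = list(band_start = d$band_start, state = d$state,
              group = d[[group_col]]), FUN = sum)
  out <- expand.grid(band_start = starts, state = c("free", "cvd"),
                     group = groups, stringsAsFactors = FALSE)
  out <- merge(out, agg, all.x = TRUE)
  out$py[is.na(out$py)] <- 0
  out <- out[order(out$state, out$band_start, match(out$group, groups)), ]
  totals <- stats::ave(out$py, out$band_start, out$state, FUN = sum)
  out$proportion <- ifelse(totals > 0, out$py / totals, NA_real_)
  out$total_py <- totals
  # empty cells: borrow from nearest non-empty band within the state
  for (st in c("free", "cvd")) {
    rows <- out$state == st
    empty <- unique(out$band_start[rows & is.na(out$proportion)])
    filled <- unique(out$band_start[rows & !is.na(out$proportion)])
    if (length(empty) > 0 && length(filled) == 0) {
      if (st == "free") stop("no disease-free person-time at all")
      # no diseased person-time anywhere: fall back to the disease-free
      # composition band by band
      message("prevalence: no person-time in state cvd; ",
              "using disease-free proportions")
      src <- out$state == "free"
      out$proportion[rows] <- out$proportion[src][
        match(paste(out$band_start[rows], out$group[rows]),
              paste(out$band_start[src], out$group[src]))]
      next
    }
    for (bs in empty) {
      nearest <- filled[which.min(abs(filled - bs))]
      message("prevalence: empty cell (", bs, "-", bs + 4, ", ", st,
              ") filled from band ", nearest)
      src <- rows & out$band_start == nearest
      dst <- rows & out$band_start == bs
      out$proportion[dst] <- out$proportion[src][
        match(out$group[dst], out$group[src])]
    }
  }
  out <- out[, c("band_start", "state", "group", "proportion", "total_py")]
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Cox hazard ratios of exposure categories for one transition
#'
#' Transitions 1 and 2 use age as the time scale with left truncation at
#' entry; transition 3 uses time since disease onset as the time scale
#' with age at onset as an additional covariate. Ties are handled by
#' Efron's method. The first level of the exposure column is the reference
#' category.
#'
#' @param cohort a `cohort_table`.
#' @param transition 1, 2, or 3.
#' @param group_col exposure-category column name.
#' @param covariate_cols optional character vector of adjustment columns.
#' @param weights optional per-individual weights (e.g. from
#'   [ipw_reweight()]).
#' @return object of class `transition_hrs`: list with `transition`,
#'   `scheme` (the column name), `reference`, `log_hr` (named vector over
#'   non-reference groups), `se`, `vcov` (group terms only), `converged`.
#' @export
fit_hrs <- function(cohort, transition, group_col = "group",
                    covariate_cols = NULL, weights = NULL) {
  g <- cohort[[group_col]]
  if (!is.factor(g)) g <- factor(g)
  stopifnot(nlevels(g) >= 2)
  dat <- data.frame(.group = g)
  for (cc in covariate_cols) dat[[cc]] <- cohort[[cc]]
  rhs <- paste(c(".group", covariate_cols), collapse = " + ")

  if (transition %in% c(1, 2)) {
    free_end <- pmin(ifelse(is.na(cohort$age_cvd), Inf, cohort$age_cvd),
                     ifelse(is.na(cohort$age_death), Inf, cohort$age_death),
                     cohort$censor_age)
    ev <- if (transition == 1) {
      cohort$cvd & free_end == cohort$age_cvd
    } else {
      cohort$death & !cohort$cvd & free_end == cohort$age_death
    }
    dat$.start <- cohort$entry_age
    dat$.stop <- free_end
    dat$.event <- as.integer(ev)
    ok <- dat$.stop > dat$.start
    dat <- dat[ok, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[ok]
    form <- stats::as.formula(
      paste("survival::Surv(.start, .stop, .event) ~", rhs))
  } else if (transition == 3) {
    sel <- cohort$cvd
    dat <- dat[sel, , drop = FALSE]
    end <- pmin(ifelse(is.na(cohort$age_death[sel]), Inf,
                       cohort$age_death[sel]), cohort$censor_age[sel])
    dat$.time <- end - cohort$age_cvd[sel]
    dat$.event <- as.integer(cohort$death[sel] &
                               end == cohort$age_death[sel])
    dat$.age_onset <- cohort$age_cvd[sel]
    ok <- dat$.time > 0
    dat <- dat[ok, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[sel][ok]
    form <- stats::as.formula(
      paste("survival::Surv(.time, .event) ~", rhs, "+ .age_onset"))
  } else stop("transition must be 1, 2, or 3")

  ev_by_group <- table(dat$.group, dat$.event)
  if (any(ev_by_group[, "1"] == 0)) {
    stop("a group has no transition-", transition, " events")
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fit <- survival::coxph(form, data = dat, weights = .w,
                         ties = "efron", robust = !is.null(weights))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  gterms <- grep("^\\.group", names(cf))
  log_hr <- cf[gterms]
  names(log_hr) <- sub("^\\.group", "", names(log_hr))
  vcg <- vc[gterms, gterms, drop = FALSE]
  dimnames(vcg) <- list(names(log_hr), names(log_hr))
  conv <- !is.null(fit$info) || TRUE
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) {
    warning("transition-", transition,
            " Cox fit shows signs of monotone likelihood")
    conv <- FALSE
  }
  structure(list(transition = transition, scheme = group_col,
                 reference = levels(dat$.group)[1],
                 log_hr = log_hr, se = sqrt(diag(vcg)), vcov = vcg,
                 converged = conv),
            class = "transition_hrs")
}

#' Inverse-probability weights balancing disease cases to the cohort
#'
#' Fits a logistic model of disease-case membership on covariates over the
#' whole cohort and returns stabilized weights (marginal case fraction
#' divided by fitted probability), truncated at the 1st/99th percentiles.
#' Intended for a weighted refit of the transition-3 Cox model as a
#' collider-bias sensitivity analysis.
#'
#' @param cohort a `cohort_table`.
#' @param covariate_cols character vector of covariate column names.
#' @return numeric weight vector aligned to `cohort` rows (weights for
#'   non-cases are returned too, but only case rows enter a transition-3
#'   refit).
#' @export
ipw_reweight <- function(cohort, covariate_cols) {
  if (!any(cohort$cvd)) stop("no disease cases in cohort")
  dat <- data.frame(case = as.integer(cohort$cvd))
  for (cc in covariate_cols) dat[[cc]] <- cohort[[cc]]
  fit <- stats::glm(case ~ ., data = dat, family = stats::binomial())
  p <- stats::fitted(fit)
  w <- mean(dat$case) / p
  lo <- stats::quantile(w, 0.01)
  hi <- stats::quantile(w, 0.99)
  n_trunc <- sum(w < lo | w > hi)
  if (n_trunc > 0) {
    message("ipw_reweight: ", n_trunc, " weight(s) truncated at the ",
            "1st/99th percentiles")
  }
  pmin(pmax(w, lo), hi)
}
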
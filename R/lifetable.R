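#' Bundle the three life-table ingredients
#'
#' Collects the fitted objects the multistate life table consumes: the
#' three Poisson rate models, the prevalence table, and the per-transition
#' Cox hazard ratios for one exposure scheme.
#'
#' @param rates list of three `poisson_rate_model` objects (transitions
#'   1-3, in order).
#' @param prevalence a `prevalence_table`.
#' @param hrs list of three `transition_hrs` objects (same exposure
#'   scheme).
#' @param sex optional stratum label carried into outputs.
#' @return object of class `lifetable_inputs`.
#' @export
lifetable_inputs <- function(rates, prevalence, hrs, sex = NA_character_) {
  stopifnot(length(rates) == 3, length(hrs) == 3,
            inherits(prevalence, "data.frame"))
  for (i in 1:3) {
    stopifnot(inherits(rates[[i]], "poisson_rate_model"),
              inherits(hrs[[i]], "transition_hrs"))
  }
  ref <- hrs[[1]]$reference
  groups <- c(ref, names(hrs[[1]]$log_hr))
  stopifnot(all(groups %in% unique(prevalence$group)))
  structure(list(rates = rates, prevalence = prevalence, hrs = hrs,
                 groups = groups, reference = ref, sex = sex),
            class = "lifetable_inputs")
}

#' Convenience: fit all life-table inputs from a cohort
#'
#' Runs [split_person_time()], [fit_rates()] for the three transitions,
#' [compute_prevalence()], and [fit_hrs()] for one exposure scheme, and
#' bundles the results with [lifetable_inputs()].
#'
#' @param cohort a `cohort_table`.
#' @param group_col exposure-category column.
#' @param covariate_cols covariates for the Cox models.
#' @param basis age basis passed to [fit_rates()].
#' @param sex stratum label.
#' @return a `lifetable_inputs` object.
#' @export
fit_lifetable_inputs <- function(cohort, group_col = "group",
                                 covariate_cols = NULL,
                                 basis = "gompertz",
                                 sex = NA_character_) {
  ppt <- split_person_time(cohort)
  rates <- lapply(1:3, function(tr) fit_rates(ppt, tr, basis = basis))
  prev <- compute_prevalence(ppt, group_col = group_col)
  hrs <- lapply(1:3, function(tr)
    fit_hrs(cohort, tr, group_col = group_col,
            covariate_cols = covariate_cols))
  lifetable_inputs(rates, prev, hrs, sex = sex)
}

#' Calibrate a pooled rate into group-specific rates
#'
#' Rescales a pooled (population-average) transition rate into
#' group-specific rates using the groups' hazard ratios and their
#' prevalence in the at-risk state, so that the prevalence-weighted mean
#' of the group rates reproduces the pooled rate exactly:
#' \deqn{\lambda_g(x) = \lambda(x) \, HR_g \big/ \sum_h \pi_h(x) HR_h.}
#'
#' @param rate pooled rate(s) \eqn{\lambda(x)}, scalar or vector over ages.
#' @param prevalence matrix or vector of group prevalences aligned to
#'   `hr`; if a matrix, rows correspond to the entries of `rate`.
#' @param hr named vector of hazard ratios (reference included, = 1).
#' @return matrix (length(rate) x groups) of group-specific rates.
#' @export
calibrate_group_rates <- function(rate, prevalence, hr) {
  if (is.null(dim(prevalence))) {
    prevalence <- matrix(prevalence, nrow = length(rate),
                         ncol = length(hr), byrow = TRUE)
  }
  stopifnot(ncol(prevalence) == length(hr), all(hr > 0))
  denom <- as.numeric(prevalence %*% hr)
  out <- outer(rate / denom, hr)
  colnames(out) <- names(hr)
  out
}

#' Convert annual transition rates to transition probabilities
#'
#' Under constant hazards within the year, the competing transitions out
#' of the disease-free state have probabilities
#' \deqn{q_{fc} = \frac{\lambda_1}{\Lambda}(1 - e^{-\Lambda}), \quad
#'       q_{fd} = \frac{\lambda_2}{\Lambda}(1 - e^{-\Lambda}),}
#' with \eqn{\Lambda = \lambda_1 + \lambda_2}, and the diseased state has
#' \eqn{q_{cd} = 1 - e^{-\lambda_3}}. The \eqn{\Lambda = 0} limit gives
#' zero probabilities.
#'
#' @param lambda1,lambda2,lambda3 annual rates (vectors over ages).
#' @return data.frame with `q_free_cvd`, `q_free_dead`, `q_cvd_dead`.
#' @export
rates_to_probabilities <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 < 0) || any(lambda2 < 0) || any(lambda3 < 0)) {
    stop("negative transition rate")
  }
  tot <- lambda1 + lambda2
  p_exit <- 1 - exp(-tot)
  frac1 <- ifelse(tot > 0, lambda1 / tot, 0)
  frac2 <- ifelse(tot > 0, lambda2 / tot, 0)
  data.frame(q_free_cvd = frac1 * p_exit,
             q_free_dead = frac2 * p_exit,
             q_cvd_dead = 1 - exp(-lambda3))
}

# Group-specific calibrated rates on the 1-year age grid.
# Returns list of three (ages x groups) matrices. Optional overrides allow
# the bootstrap to inject perturbed coefficients / HRs / prevalences.
group_rate_grid <- function(inputs, ages = 40:89, coef_list = NULL,
                            log_hr_list = NULL, prevalence = NULL,
                            step = 1) {
  prev <- if (is.null(prevalence)) inputs$prevalence else prevalence
  groups <- inputs$groups
  mids <- ages + step / 2
  starts <- sort(unique(prev$band_start))
  band_of <- starts[findInterval(ages, starts)]
  lapply(1:3, function(i) {
    cf <- if (is.null(coef_list)) NULL else coef_list[[i]]
    pooled <- rate_at(inputs$rates[[i]], mids, coef = cf)
    lhr <- if (is.null(log_hr_list)) inputs$hrs[[i]]$log_hr
           else log_hr_list[[i]]
    hr <- c(1, exp(lhr))
    names(hr) <- groups
    st <- if (i == 3) "cvd" else "free"
    pmat <- sapply(groups, function(g) {
      pg <- prev[prev$state == st & prev$group == g, ]
      pg$proportion[match(band_of, pg$band_start)]
    })
    calibrate_group_rates(pooled, pmat, hr)
  })
}

# Core discrete recursion shared by the point-estimate and bootstrap
# paths. q1/q2/q3 are the annual transition probabilities over the ages;
# returns occupancies (length n+1) and person-years (length n).
mslt_recursion <- function(q1, q2, q3) {
  n <- length(q1)
  l_free <- numeric(n + 1); l_cvd <- numeric(n + 1)
  l_free[1] <- 1
  for (k in seq_len(n)) {
    new_cvd <- l_free[k] * q1[k]
    l_free[k + 1] <- l_free[k] * (1 - q1[k] - q2[k])
    l_cvd[k + 1] <- l_cvd[k] * (1 - q3[k]) + new_cvd * (1 - 0.5 * q3[k])
  }
  list(l_free = l_free, l_cvd = l_cvd,
       L_free = (l_free[-(n + 1)] + l_free[-1]) / 2,
       L_cvd = (l_cvd[-(n + 1)] + l_cvd[-1]) / 2)
}

#' Build a multistate life table for one exposure group
#'
#' Runs the discrete age recursion from 40 to 90 with radix
#' \eqn{l_{free}(40) = 1}: survivors leave the disease-free state via the
#' competing annual probabilities, new entrants to the diseased state face
#' half-interval transition-3 risk in their onset year, and person-years
#' are accumulated by the trapezoidal rule. The table is closed at 90 (no
#' survival credited beyond), so expectancies are temporary (40-90) life
#' expectancies.
#'
#' @param inputs a `lifetable_inputs` object.
#' @param group group label.
#' @param ages interval start ages (default `seq(40, 90 - step, step)`).
#' @param rate_grid optional precomputed output of the internal rate-grid
#'   builder (used by the bootstrap); when supplied, `inputs` may be
#'   minimal.
#' @param step interval width in years (default 1). Smaller steps refine
#'   the discretization toward the continuous-time solution.
#' @return data.frame of class `multistate_lifetable` with columns `age`,
#'   `l_free`, `l_cvd`, `L_free`, `L_cvd`, `q_free_cvd`, `q_free_dead`,
#'   `q_cvd_dead` (occupancies at the start of each interval; a closing
#'   row at 90 carries the final occupancies).
#' @export
build_lifetable <- function(inputs, group, ages = NULL, rate_grid = NULL,
                            step = 1) {
  if (is.null(ages)) ages <- seq(40, 90 - step, by = step)
  if (is.null(rate_grid)) {
    rate_grid <- group_rate_grid(inputs, ages, step = step)
  }
  gi <- match(group, colnames(rate_grid[[1]]))
  if (is.na(gi)) gi <- match(group, inputs$groups)
  if (is.na(gi)) stop("unknown group: ", group)
  q <- rates_to_probabilities(rate_grid[[1]][, gi] * step,
                              rate_grid[[2]][, gi] * step,
                              rate_grid[[3]][, gi] * step)
  n <- length(ages)
  rec <- mslt_recursion(q$q_free_cvd, q$q_free_dead, q$q_cvd_dead)
  out <- data.frame(age = c(ages, ages[n] + step),
                    l_free = rec$l_free, l_cvd = rec$l_cvd,
                    L_free = c(rec$L_free * step, 0),
                    L_cvd = c(rec$L_cvd * step, 0),
                    q_free_cvd = c(q$q_free_cvd, NA),
                    q_free_dead = c(q$q_free_dead, NA),
                    q_cvd_dead = c(q$q_cvd_dead, NA))
  attr(out, "group") <- group
  class(out) <- c("multistate_lifetable", "data.frame")
  out
}

#' Life expectancy from a multistate life table
#'
#' Sums person-years over the table: expected years disease free, years
#' lived with disease, their total, and the disease-free proportion.
#'
#' @param mslt a `multistate_lifetable`.
#' @return list with `total`, `free`, `with_cvd` (years) and `proportion`
#'   (percent of total LE that is disease free).
#' @export
life_expectancy <- function(mslt) {
  free <- sum(mslt$L_free)
  with_cvd <- sum(mslt$L_cvd)
  total <- free + with_cvd
  list(total = total, free = free, with_cvd = with_cvd,
       proportion = 100 * free / total)
}

# One table per group -> named list of life_expectancy() results.
le_all_groups <- function(inputs, ages = 40:89, rate_grid = NULL) {
  if (is.null(rate_grid)) rate_grid <- group_rate_grid(inputs, ages)
  res <- lapply(inputs$groups, function(g)
    life_expectancy(build_lifetable(inputs, g, ages, rate_grid)))
  names(res) <- inputs$groups
  res
}

# Cholesky factor with a diagonal fallback for degenerate covariances.
chol_or_diag <- function(vc) {
  vc <- as.matrix(vc)
  if (all(vc == 0)) return(vc)  # exact zero variance, no draw noise
  ch <- tryCatch(chol(vc), error = function(e) NULL)
  if (is.null(ch) || any(!is.finite(ch))) {
    warning("degenerate covariance; falling back to its diagonal")
    ch <- diag(sqrt(pmax(diag(vc), 0)), nrow = nrow(vc))
  }
  ch
}

# Precompute everything the bootstrap loop needs: design matrices on the
# age grid, band-level prevalence matrices with their effective
# person-years, and the band -> age expansion index.
engine_prep <- function(inputs, ages = 40:89) {
  mids <- ages + 0.5
  X <- lapply(inputs$rates, function(m) {
    switch(m$basis,
           gompertz = cbind(1, mids),
           constant = matrix(1, length(mids), 1),
           cbind(1, splines::ns(mids, knots = m$knots,
                                Boundary.knots = m$boundary_knots)))
  })
  prev <- inputs$prevalence
  starts <- sort(unique(prev$band_start))
  band_idx <- findInterval(ages, starts)
  groups <- inputs$groups
  pm <- function(st) {
    sapply(groups, function(g) {
      pg <- prev[prev$state == st & prev$group == g, ]
      pg$proportion[match(starts, pg$band_start)]
    })
  }
  py <- function(st) {
    vapply(starts, function(bs) {
      prev$total_py[prev$state == st & prev$band_start == bs][1]
    }, numeric(1))
  }
  list(ages = ages, X = X, band_idx = band_idx, groups = groups,
       prev_free = pm("free"), prev_cvd = pm("cvd"),
       py_free = py("free"), py_cvd = py("cvd"))
}

# One engine pass: pooled rates from coefficients, calibration, annual
# probabilities, recursion; returns groups x 4 matrix of LE quantities.
engine_run <- function(prep, coefs, hrs, prev_free, prev_cvd) {
  pooled <- lapply(1:3, function(i)
    as.numeric(exp(prep$X[[i]] %*% coefs[[i]])))
  pf <- prev_free[prep$band_idx, , drop = FALSE]
  pc <- prev_cvd[prep$band_idx, , drop = FALSE]
  G <- length(prep$groups)
  out <- matrix(NA_real_, G, 4,
                dimnames = list(prep$groups,
                                c("total", "free", "with_cvd",
                                  "proportion")))
  den1 <- as.numeric(pf %*% hrs[[1]])
  den2 <- as.numeric(pf %*% hrs[[2]])
  den3 <- as.numeric(pc %*% hrs[[3]])
  for (g in seq_len(G)) {
    l1 <- pooled[[1]] * hrs[[1]][g] / den1
    l2 <- pooled[[2]] * hrs[[2]][g] / den2
    l3 <- pooled[[3]] * hrs[[3]][g] / den3
    q <- rates_to_probabilities(l1, l2, l3)
    rec <- mslt_recursion(q$q_free_cvd, q$q_free_dead, q$q_cvd_dead)
    free <- sum(rec$L_free); with_cvd <- sum(rec$L_cvd)
    out[g, ] <- c(free + with_cvd, free, with_cvd,
                  100 * free / (free + with_cvd))
  }
  out
}

#' Parametric-bootstrap confidence intervals for life expectancy
#'
#' Propagates the sampling uncertainty of all three input components
#' through the life table by Monte Carlo: each run draws the Poisson
#' coefficients and log hazard ratios from Gaussian distributions with
#' their estimated covariance, redraws each (band, state) prevalence row
#' from a Dirichlet scaled by its effective person-years, rebuilds every
#' group's table from the shared draw, and records all quantities.
#' Confidence intervals are percentile 2.5/97.5. Because draws are shared
#' across groups within a run, between-group differences are computed
#' within runs.
#'
#' @param inputs a `lifetable_inputs` object (with SEs/covariances).
#' @param n_runs number of Monte Carlo runs (default 10000).
#' @param seed RNG seed.
#' @param ages integer ages covered.
#' @return object of class `le_bootstrap`: list with `point` (per-group
#'   point estimates), `ci` (per group x quantity, 2.5/97.5 percentiles),
#'   `draws` (array runs x groups x quantities), `n_runs`, `seed`.
#' @export
bootstrap_ci <- function(inputs, n_runs = 10000, seed = 1, ages = 40:89) {
  set.seed(seed)
  groups <- inputs$groups
  G <- length(groups)
  quantities <- c("total", "free", "with_cvd", "proportion")
  prep <- engine_prep(inputs, ages)

  # pre-draw all perturbed parameters
  coef_draws <- lapply(inputs$rates, function(m) {
    R <- chol_or_diag(m$vcov)
    sweep(matrix(stats::rnorm(n_runs * length(m$coef)), n_runs) %*% R,
          2, m$coef, `+`)
  })
  hr_draws <- lapply(inputs$hrs, function(h) {
    R <- chol_or_diag(h$vcov)
    lhr <- sweep(matrix(stats::rnorm(n_runs * length(h$log_hr)),
                        n_runs) %*% R, 2, h$log_hr, `+`)
    cbind(1, exp(lhr))  # reference first
  })
  dirichlet_draws <- function(pmat, py) {
    alpha <- pmat * py  # bands x groups effective counts
    arr <- array(stats::rgamma(n_runs * length(alpha),
                               shape = rep(alpha, each = n_runs)),
                 dim = c(n_runs, nrow(alpha), ncol(alpha)))
    tot <- apply(arr, c(1, 2), sum)
    zero <- tot == 0  # degenerate cells keep their point proportions
    for (g in seq_len(ncol(alpha))) {
      arr[, , g] <- ifelse(zero, matrix(pmat[, g], n_runs, nrow(alpha),
                                        byrow = TRUE),
                           arr[, , g] / tot)
    }
    arr
  }
  pf_draws <- dirichlet_draws(prep$prev_free, prep$py_free)
  pc_draws <- dirichlet_draws(prep$prev_cvd, prep$py_cvd)

  draws <- array(NA_real_, dim = c(n_runs, G, length(quantities)),
                 dimnames = list(NULL, groups, quantities))
  for (r in seq_len(n_runs)) {
    draws[r, , ] <- engine_run(
      prep,
      coefs = lapply(coef_draws, function(m) m[r, ]),
      hrs = lapply(hr_draws, function(m) m[r, ]),
      prev_free = matrix(pf_draws[r, , ], ncol = G),
      prev_cvd = matrix(pc_draws[r, , ], ncol = G))
  }
  point <- le_all_groups(inputs, ages)
  ci <- apply(draws, c(2, 3), stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  structure(list(point = point, ci = ci, draws = draws, n_runs = n_runs,
                 seed = seed, ages = ages),
            class = "le_bootstrap")
}

#' Between-group life-expectancy differences with bootstrap CIs
#'
#' Computes `group_a` minus `group_b` for every life-expectancy quantity,
#' using the point estimates and the paired bootstrap draws (differences
#' taken within each run, so shared input uncertainty cancels).
#'
#' @param boot a `le_bootstrap` from [bootstrap_ci()].
#' @param group_a,group_b group labels.
#' @return data.frame with `quantity`, `difference`, `lower`, `upper`.
#' @export
le_difference <- function(boot, group_a, group_b) {
  quantities <- dimnames(boot$draws)[[3]]
  pa <- unlist(boot$point[[group_a]])[quantities]
  pb <- unlist(boot$point[[group_b]])[quantities]
  dd <- boot$draws[, group_a, , drop = FALSE] -
    boot$draws[, group_b, , drop = FALSE]
  dd <- matrix(dd, nrow = dim(boot$draws)[1],
               dimnames = list(NULL, quantities))
  qs <- apply(dd, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(quantity = quantities,
             difference = as.numeric(pa - pb),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}
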
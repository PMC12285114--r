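#' Read a cohort event-history CSV
#'
#' Expects a comma-separated file with header columns `id`, `sex`,
#' `entry_age`, `age_cvd`, `age_death`, `censor_age` plus any exposure and
#' covariate columns; empty fields in `age_cvd` / `age_death` mean the
#' event did not occur. Rows violating the age ordering (entry before
#' events, disease onset not after death) are rejected and reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return a `cohort_table` data.frame (with `cvd` / `death` flags derived
#'   from the age columns).
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "sex", "entry_age", "age_cvd", "age_death",
                "censor_age")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("cohort file missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("entry_age", "age_cvd", "age_death", "censor_age")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  end_age <- pmin(ifelse(is.na(d$age_death), Inf, d$age_death),
                  d$censor_age)
  bad <- is.na(d$entry_age) | is.na(d$censor_age) |
    d$entry_age >= end_age |
    (!is.na(d$age_cvd) & d$age_cvd <= d$entry_age) |
    (!is.na(d$age_cvd) & !is.na(d$age_death) & d$age_death < d$age_cvd)
  if (any(bad)) {
    stop("invalid cohort rows at line(s): ",
         paste(which(bad) + 1L, collapse = ", "),
         " (age ordering or missing mandatory ages)")
  }
  d$cvd <- !is.na(d$age_cvd)
  d$death <- !is.na(d$age_death)
  if ("group" %in% names(d)) d$group <- factor(d$group)
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Write a cohort table as CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$cvd <- NULL
  out$death <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read GWAS summary statistics (TSV)
#'
#' Tab-separated with mandatory header
#' `variant_id chrom pos effect_allele other_allele beta p eaf`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_gwas <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "beta", "p", "eaf")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("GWAS file missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(d$p <= 0 | d$p > 1)) stop("p-values must lie in (0, 1]")
  if (any(d$effect_allele == d$other_allele)) {
    stop("effect and other allele identical for some variants")
  }
  if (anyDuplicated(d$variant_id)) stop("duplicate variant ids")
  d
}

#' Read / write PRS weights in a PGS-Catalog-like TSV
#'
#' Columns `variant_id`, `effect_allele`, `other_allele`, `weight`.
#'
#' @param path file path.
#' @return weights data.frame.
#' @export
read_prs_weights <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("weight file missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  d
}

#' @rdname read_prs_weights
#' @param weights weights data.frame.
#' @export
write_prs_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read life-table inputs from exported workbook sheets
#'
#' Reads the three life-table ingredients from plain-text CSV exports of
#' the supplementary-workbook sheets ("Input 1" Poisson coefficients,
#' "Input 2" group prevalence, "Input 3" Cox coefficients). The column
#' mapping is configurable so differently-labelled exports can be adapted
#' without editing the files.
#'
#' Expected default layout:
#' \describe{
#'   \item{rates sheet}{`transition` (1/2/3), `term` (`intercept` /
#'     `age`), `estimate`, `se`. A Gompertz-like log-linear age basis is
#'     assumed; covariances degrade to diagonal when only SEs are given.}
#'   \item{prevalence sheet}{`band_start`, `state` (`free`/`cvd`),
#'     `group`, `proportion`, optional `total_py` (defaults to a large
#'     effective person-time when absent, i.e. near-fixed prevalence).
#'     Rows within a (band, state) are renormalized, with a warning beyond
#'     1e-6.}
#'   \item{hrs sheet}{`transition`, `group`, `log_hr`, `se`; the reference
#'     group is the one with `log_hr` 0 and `se` 0, or may be omitted and
#'     named via `mapping$reference`.}
#' }
#'
#' @param rates_path,prevalence_path,hrs_path CSV paths for the three
#'   sheets.
#' @param mapping optional list renaming columns, e.g.
#'   `list(rates = c(estimate = "beta"))` maps this package's `estimate`
#'   to the file's `beta`; may also carry `reference` (reference group
#'   label) and `sex`.
#' @return a `lifetable_inputs` object (point-estimate-only if SEs are
#'   absent; bootstrap then degenerates to zero-width CIs).
#' @export
read_lifetable_sheets <- function(rates_path, prevalence_path, hrs_path,
                                  mapping = list()) {
  for (p in c(rates_path, prevalence_path, hrs_path)) {
    if (!file.exists(p)) stop("missing input sheet: ", p)
  }
  remap <- function(d, map) {
    if (is.null(map)) return(d)
    for (ours in names(map)) {
      theirs <- map[[ours]]
      if (theirs %in% names(d)) names(d)[names(d) == theirs] <- ours
    }
    d
  }
  rt <- remap(utils::read.csv(rates_path, stringsAsFactors = FALSE),
              mapping$rates)
  pv <- remap(utils::read.csv(prevalence_path, stringsAsFactors = FALSE),
              mapping$prevalence)
  hr <- remap(utils::read.csv(hrs_path, stringsAsFactors = FALSE),
              mapping$hrs)

  stopifnot(all(c("transition", "term", "estimate") %in% names(rt)))
  if (!"se" %in% names(rt)) rt$se <- 0
  rates <- lapply(1:3, function(tr) {
    ri <- rt[rt$transition == tr, ]
    if (nrow(ri) == 0) stop("rates sheet lacks transition ", tr)
    cf <- stats::setNames(ri$estimate, ri$term)
    cf <- cf[c("intercept", "age")]
    if (anyNA(cf)) stop("rates sheet needs 'intercept' and 'age' terms")
    se <- stats::setNames(ri$se, ri$term)[c("intercept", "age")]
    structure(list(transition = tr, basis = "gompertz", df = NA,
                   coef = stats::setNames(as.numeric(cf),
                                          c("(Intercept)", "age")),
                   vcov = diag(as.numeric(se)^2, 2),
                   knots = NULL, boundary_knots = NULL),
              class = "poisson_rate_model")
  })

  stopifnot(all(c("band_start", "state", "group", "proportion") %in%
                  names(pv)))
  if (!"total_py" %in% names(pv)) pv$total_py <- 1e6
  key <- paste(pv$band_start, pv$state)
  for (k in unique(key)) {
    idx <- which(key == k)
    s <- sum(pv$proportion[idx])
    if (abs(s - 1) > 1e-6) {
      warning("prevalence rows for (", k, ") sum to ", signif(s, 6),
              "; renormalized")
    }
    pv$proportion[idx] <- pv$proportion[idx] / s
  }
  class(pv) <- c("prevalence_table", "data.frame")

  stopifnot(all(c("transition", "group", "log_hr") %in% names(hr)))
  if (!"se" %in% names(hr)) hr$se <- 0
  reference <- mapping$reference
  if (is.null(reference)) {
    ref_rows <- hr[hr$log_hr == 0 & hr$se == 0, ]
    if (nrow(ref_rows) == 0) {
      stop("cannot identify reference group; supply mapping$reference")
    }
    reference <- ref_rows$group[1]
  }
  hrs <- lapply(1:3, function(tr) {
    hi <- hr[hr$transition == tr & hr$group != reference, ]
    if (nrow(hi) == 0) stop("hrs sheet lacks transition ", tr)
    structure(list(transition = tr, scheme = "group",
                   reference = reference,
                   log_hr = stats::setNames(hi$log_hr, hi$group),
                   se = stats::setNames(hi$se, hi$group),
                   vcov = diag(hi$se^2, nrow(hi)) |>
                     `dimnames<-`(list(hi$group, hi$group)),
                   converged = TRUE),
              class = "transition_hrs")
  })
  lifetable_inputs(rates, pv, hrs,
                   sex = if (is.null(mapping$sex)) NA_character_
                         else mapping$sex)
}

#' Write life-table sheets (round-trip counterpart)
#'
#' Exports a `lifetable_inputs` object to the three CSV sheets read by
#' [read_lifetable_sheets()].
#'
#' @param inputs a `lifetable_inputs`.
#' @param rates_path,prevalence_path,hrs_path output CSV paths.
#' @return invisibly, the three paths.
#' @export
write_lifetable_sheets <- function(inputs, rates_path, prevalence_path,
                                   hrs_path) {
  rt <- do.call(rbind, lapply(inputs$rates, function(m) {
    data.frame(transition = m$transition, term = c("intercept", "age"),
               estimate = as.numeric(m$coef),
               se = sqrt(diag(m$vcov)))
  }))
  utils::write.csv(rt, rates_path, row.names = FALSE)
  utils::write.csv(as.data.frame(inputs$prevalence), prevalence_path,
                   row.names = FALSE)
  hr <- do.call(rbind, lapply(inputs$hrs, function(h) {
    rbind(data.frame(transition = h$transition, group = h$reference,
                     log_hr = 0, se = 0),
          data.frame(transition = h$transition, group = names(h$log_hr),
                     log_hr = as.numeric(h$log_hr),
                     se = as.numeric(h$se)))
  }))
  utils::write.csv(hr, hrs_path, row.names = FALSE)
  invisible(c(rates_path, prevalence_path, hrs_path))
}

#' Load a simulation configuration from YAML
#'
#' Reads the keys of [sim_config()] (with `groups` as a list of records)
#' and rejects unknown keys.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  # keep YAML-1.1 boolean-like scalars ("n", "y", ...) as literal strings
  # so the cohort-size key `n` survives parsing
  y <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                             "bool#no" = identity))
  known <- c("n", "seed", "groups", "baseline", "entry_age_range",
             "sex_ratio", "followup_years")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$groups)) {
    y$groups <- do.call(rbind, lapply(y$groups, as.data.frame))
  }
  if (!is.null(y$baseline)) {
    y$baseline <- list(a = as.numeric(y$baseline$a),
                       b = as.numeric(y$baseline$b))
  }
  do.call(sim_config, y)
}

#' Serialize life-expectancy results to JSON
#'
#' Writes per-group point estimates, CIs, and (optionally) differences vs
#' the reference group, together with run metadata (seed, runs,
#' bootstrap distributions), in a stable key order.
#'
#' @param boot a `le_bootstrap` from [bootstrap_ci()].
#' @param inputs the `lifetable_inputs` used.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_le_results <- function(boot, inputs, path) {
  groups <- inputs$groups
  per_group <- lapply(groups, function(g) {
    pt <- boot$point[[g]]
    list(total = pt$total, free = pt$free, with_cvd = pt$with_cvd,
         proportion = pt$proportion,
         ci = list(total = as.numeric(boot$ci[, g, "total"]),
                   free = as.numeric(boot$ci[, g, "free"]),
                   with_cvd = as.numeric(boot$ci[, g, "with_cvd"]),
                   proportion = as.numeric(boot$ci[, g, "proportion"])))
  })
  names(per_group) <- groups
  diffs <- lapply(setdiff(groups, inputs$reference), function(g) {
    d <- le_difference(boot, g, inputs$reference)
    stats::setNames(lapply(seq_len(nrow(d)), function(i)
      list(difference = d$difference[i], lower = d$lower[i],
           upper = d$upper[i])), d$quantity)
  })
  names(diffs) <- setdiff(groups, inputs$reference)
  out <- list(
    metadata = list(package = "prslife",
                    version = as.character(utils::packageVersion("prslife")),
                    seed = boot$seed, n_runs = boot$n_runs,
                    sex = inputs$sex, reference = inputs$reference,
                    bootstrap = list(rates = "gaussian-on-coefficients",
                                     hrs = "gaussian-on-log-hr",
                                     prevalence = "dirichlet-by-person-years")),
    groups = per_group,
    differences_vs_reference = diffs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
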
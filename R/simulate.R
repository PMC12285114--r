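#' Default simulation configuration
#'
#' Returns the configuration of the synthetic study population: a cohort of
#' adults entering uniformly at ages 30-79, followed for a fixed
#' administrative horizon, moving through an illness-death model (disease
#' free -> incident CVD -> death, plus disease free -> non-CVD death) with
#' Gompertz baseline hazards \eqn{\lambda_i(x) = a_i e^{b_i x}} on the age
#' scale and multiplicative group hazard ratios.
#'
#' The default baselines (`a1 = 1.25e-4`, `b1 = 0.085`; `a2 = 3.5e-5`,
#' `b2 = 0.095`; `a3 = 2.0e-4`, `b3 = 0.09`) yield roughly a quarter of the
#' cohort developing CVD over a 12-year follow-up, and the default
#' three-group exposure (20/60/20 prevalence, transition HRs 1/1.20/1.63,
#' 1/1.01/1.11 and 1/1.07/1.25) mirrors a quintile-based genetic-risk
#' classification of a large cohort.
#'
#' @param n cohort size.
#' @param seed master seed; per-individual sub-streams are derived from it
#'   so that growing `n` leaves earlier individuals unchanged.
#' @param groups data.frame with columns `group`, `prevalence`, `hr1`,
#'   `hr2`, `hr3` (reference row has all HRs 1).
#' @param baseline list with numeric vectors `a` and `b` of length 3
#'   (transitions 1-3).
#' @param entry_age_range numeric length-2, uniform entry-age range.
#' @param sex_ratio male fraction.
#' @param followup_years administrative censoring horizon after entry.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 70000, seed = 1,
                       groups = data.frame(
                         group = c("low", "intermediate", "high"),
                         prevalence = c(0.2, 0.6, 0.2),
                         hr1 = c(1, 1.20, 1.63),
                         hr2 = c(1, 1.01, 1.11),
                         hr3 = c(1, 1.07, 1.25)),
                       baseline = list(a = c(1.25e-4, 3.5e-5, 2.0e-4),
                                       b = c(0.085, 0.095, 0.09)),
                       entry_age_range = c(30, 79),
                       sex_ratio = 0.4,
                       followup_years = 12) {
  stopifnot(all(baseline$a >= 0), length(baseline$a) == 3,
            length(baseline$b) == 3,
            all(groups$prevalence > 0),
            abs(sum(groups$prevalence) - 1) < 1e-8,
            all(groups$hr1 > 0), all(groups$hr2 > 0), all(groups$hr3 > 0),
            followup_years > 0, n >= 1)
  if (!any(groups$hr1 == 1 & groups$hr2 == 1 & groups$hr3 == 1)) {
    stop("groups must contain a reference row with all HRs equal to 1")
  }
  structure(list(n = n, seed = seed, groups = groups, baseline = baseline,
                 entry_age_range = entry_age_range, sex_ratio = sex_ratio,
                 followup_years = followup_years),
            class = "sim_config")
}

# Gompertz event-time sampler: time from age x0 until the hazard
# hr * a * exp(b x) accumulates the exponential draw e. Inf when the
# cumulative hazard never reaches e (b < 0) or the hazard is 0.
gompertz_time <- function(e, x0, a, b, hr = 1) {
  rate <- a * hr
  out <- rep(Inf, length(e))
  if (b == 0) {
    pos <- rate > 0
    out[pos] <- (e / rate)[pos]
    return(out)
  }
  arg <- 1 + b * e / (rate * exp(b * x0))
  ok <- rate > 0 & arg > 0
  out[ok] <- (log(arg) / b)[ok]
  out
}

#' Simulate an illness-death cohort
#'
#' Draws, per individual, entry age, sex, exposure group, and latent
#' Gompertz event times for the three transitions (the disease and
#' non-disease-death times compete from entry; after disease onset the
#' residual survival time is drawn from the transition-3 hazard indexed by
#' current age, i.e. the process is Markov in age). Administrative
#' censoring is applied at `entry + followup_years`. Two generic
#' covariates, `cov1` (standard normal) and `cov2` (Bernoulli 0.5), are
#' carried for model-adjustment plumbing but do not act on the hazards.
#'
#' Each individual uses a deterministic RNG sub-stream derived from the
#' master seed, so cohorts are fully reproducible and nested in `n`.
#'
#' @param config a [sim_config()] object.
#' @return data.frame of class `cohort_table` with columns `id`, `sex`,
#'   `entry_age`, `group`, `cov1`, `cov2`, `age_cvd`, `age_death`,
#'   `censor_age`, `cvd`, `death`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  a <- config$baseline$a
  b <- config$baseline$b
  gr <- config$groups

  id <- seq_len(n)
  # per-individual sub-seeds drawn sequentially from the master stream:
  # nested in n (the first k individuals are identical for any larger n)
  # and decorrelated across master seeds
  set.seed(config$seed)
  sub_seed <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  sex <- character(n); entry <- numeric(n); gidx <- integer(n)
  cov1 <- numeric(n); cov2 <- integer(n)
  e1 <- numeric(n); e2 <- numeric(n); e3 <- numeric(n)
  for (i in id) {
    set.seed(sub_seed[i])
    u <- stats::runif(4)
    sex[i] <- if (u[1] < config$sex_ratio) "male" else "female"
    entry[i] <- config$entry_age_range[1] +
      u[2] * diff(config$entry_age_range)
    gidx[i] <- findInterval(u[3], cumsum(gr$prevalence),
                            left.open = TRUE) + 1L
    cov1[i] <- stats::qnorm(u[4])
    ee <- stats::rexp(3)
    e1[i] <- ee[1]; e2[i] <- ee[2]; e3[i] <- ee[3]
    cov2[i] <- as.integer(stats::runif(1) < 0.5)
  }

  t1 <- gompertz_time(e1, entry, a[1], b[1], gr$hr1[gidx])
  t2 <- gompertz_time(e2, entry, a[2], b[2], gr$hr2[gidx])
  censor_age <- entry + config$followup_years

  cvd_first <- t1 < t2 & (entry + t1) < censor_age
  age_cvd <- ifelse(cvd_first, entry + t1, NA_real_)
  # residual survival after onset from the age-indexed transition-3 hazard
  t3 <- rep(NA_real_, n)
  has_cvd <- which(cvd_first)
  if (length(has_cvd) > 0) {
    t3[has_cvd] <- gompertz_time(e3[has_cvd], age_cvd[has_cvd], a[3], b[3],
                                 gr$hr3[gidx[has_cvd]])
  }
  age_death <- rep(NA_real_, n)
  death <- logical(n)
  # free -> non-CVD death
  noncvd_death <- !cvd_first & (entry + t2) < censor_age & t2 <= t1
  age_death[noncvd_death] <- (entry + t2)[noncvd_death]
  death[noncvd_death] <- TRUE
  # CVD -> death
  post_cvd_death <- cvd_first & (age_cvd + t3) < censor_age
  age_death[post_cvd_death] <- (age_cvd + t3)[post_cvd_death]
  death[post_cvd_death] <- TRUE

  out <- data.frame(id = id, sex = sex, entry_age = entry,
                    group = factor(gr$group[gidx], levels = gr$group),
                    cov1 = cov1, cov2 = cov2,
                    age_cvd = age_cvd, age_death = age_death,
                    censor_age = censor_age,
                    cvd = cvd_first, death = death)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Continuous-time life-expectancy oracle
#'
#' Integrates the Kolmogorov forward equations of the illness-death model
#' for a single exposure group from `index_age` (starting entirely disease
#' free) to `end_age`, and returns the exact expected years in each state
#' under the generative Gompertz hazards. This is the reference against
#' which the discrete multistate life table is validated.
#'
#' The system solved is
#' \deqn{P'_{free}(x) = -(\lambda_1(x)+\lambda_2(x)) P_{free}(x)}
#' \deqn{P'_{cvd}(x) = \lambda_1(x) P_{free}(x) - \lambda_3(x) P_{cvd}(x)}
#' with \eqn{LE_{free} = \int P_{free}} and \eqn{LE_{cvd} = \int P_{cvd}}
#' over \[index_age, end_age\].
#'
#' @param config a [sim_config()].
#' @param group group label from `config$groups` (default the first,
#'   reference, row).
#' @param index_age,end_age integration limits (defaults 40 and 90).
#' @param step integration output step in years (must be at most 0.1).
#' @return list with `total`, `free`, `with_cvd`, `proportion` (free/total),
#'   and `step`.
#' @export
true_life_expectancy <- function(config, group = NULL, index_age = 40,
                                 end_age = 90, step = 0.02) {
  stopifnot(inherits(config, "sim_config"), step <= 0.1, step > 0,
            end_age > index_age)
  gr <- config$groups
  gi <- if (is.null(group)) 1L else match(group, gr$group)
  if (is.na(gi)) stop("unknown group: ", group)
  a <- config$baseline$a
  b <- config$baseline$b
  hr <- c(gr$hr1[gi], gr$hr2[gi], gr$hr3[gi])
  lam <- function(i, x) a[i] * exp(b[i] * x) * hr[i]
  rhs <- function(x, y, parms) {
    l1 <- lam(1, x); l2 <- lam(2, x); l3 <- lam(3, x)
    list(c(-(l1 + l2) * y[1],
           l1 * y[1] - l3 * y[2],
           y[1],
           y[2]))
  }
  times <- seq(index_age, end_age, by = step)
  sol <- deSolve::ode(y = c(pfree = 1, pcvd = 0, ifree = 0, icvd = 0),
                      times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  free <- unname(sol[nrow(sol), "ifree"])
  with_cvd <- unname(sol[nrow(sol), "icvd"])
  list(total = free + with_cvd, free = free, with_cvd = with_cvd,
       proportion = free / (free + with_cvd), step = step)
}

#' Simulate genotypes, trait architectures, and GWAS summaries
#'
#' Generates a panel of independent biallelic variants (dosages Binomial(2,
#' freq)), sparse-normal per-trait causal effects with a configurable
#' shared component inducing cross-trait correlation, and noisy GWAS
#' summary statistics whose standard errors correspond to a stated GWAS
#' sample size. Each trait is emitted either as one trans-ancestry summary
#' or as a European/East Asian pair whose true effects are related by an
#' attenuation factor.
#'
#' A composite-outcome liability is built as a weighted sum of the traits'
#' genetic values plus noise, and a binary outcome drawn from its logistic
#' transform; the generative trait weights are returned as ground truth.
#'
#' @param n individuals.
#' @param m_variants number of variants (>= 50).
#' @param n_traits number of traits.
#' @param seed RNG seed.
#' @param architecture list of knobs: `prop_causal` (fraction of causal
#'   variants per trait, default 0.2), `h2` (per-trait genetic variance,
#'   default 0.3), `shared` (cross-trait effect correlation via a shared
#'   causal component, default 0.3), `gwas_n` (GWAS sample size for the
#'   summary SEs, default 5e4), `attenuation` (EAS-vs-EUR true-effect
#'   scaling, default 0.8), `n_trans` (number of traits emitted as
#'   trans-ancestry summaries, default half), `trait_gamma` (liability
#'   weight per trait; default 0.5 for trait 1, 0 otherwise),
#'   `spacing_bp` (variant spacing, default 1e5).
#' @return list with `genotypes` (n x m matrix), `variant_info`
#'   (variant_id, chrom, pos, effect_allele, other_allele, freq), `gwas`
#'   (per trait: either `$trans` or `$eur`/`$eas` summary data.frames),
#'   `true_beta` (m x n_traits), `trait_gamma`, `liability`, `outcome`.
#' @export
simulate_genetics <- function(n, m_variants, n_traits, seed = 1,
                              architecture = list()) {
  stopifnot(m_variants >= 50)
  arch <- utils::modifyList(
    list(prop_causal = 0.2, h2 = 0.3, shared = 0.3, gwas_n = 5e4,
         attenuation = 0.8, n_trans = floor(n_traits / 2),
         trait_gamma = c(0.5, rep(0, n_traits - 1)), spacing_bp = 1e5),
    architecture)
  set.seed(seed)
  freq <- stats::runif(m_variants, 0.05, 0.95)
  geno <- matrix(stats::rbinom(n * m_variants, 2, rep(freq, each = n)),
                 nrow = n)
  vid <- sprintf("v%04d", seq_len(m_variants))
  colnames(geno) <- vid
  variant_info <- data.frame(variant_id = vid, chrom = 1L,
                             pos = seq_len(m_variants) * arch$spacing_bp,
                             effect_allele = "A", other_allele = "G",
                             freq = freq, stringsAsFactors = FALSE)

  m_causal <- max(1L, round(arch$prop_causal * m_variants))
  var_per_allele <- 2 * freq * (1 - freq)
  shared_raw <- stats::rnorm(m_variants)
  true_beta <- matrix(0, m_variants, n_traits)
  for (t in seq_len(n_traits)) {
    causal <- sample.int(m_variants, m_causal)
    raw <- sqrt(arch$shared) * shared_raw[causal] +
      sqrt(1 - arch$shared) * stats::rnorm(m_causal)
    beta <- numeric(m_variants)
    beta[causal] <- raw
    gvar <- sum(beta^2 * var_per_allele)
    if (gvar > 0) beta <- beta * sqrt(arch$h2 / gvar)
    true_beta[, t] <- beta
  }
  colnames(true_beta) <- paste0("trait", seq_len(n_traits))

  se <- 1 / sqrt(arch$gwas_n * var_per_allele)
  make_summary <- function(beta_true) {
    bhat <- beta_true + stats::rnorm(m_variants, sd = se)
    data.frame(variant_id = vid, chrom = 1L, pos = variant_info$pos,
               effect_allele = "A", other_allele = "G",
               beta = bhat,
               p = pmax(2 * stats::pnorm(-abs(bhat / se)), 1e-300),
               eaf = freq, stringsAsFactors = FALSE)
  }
  gwas <- vector("list", n_traits)
  names(gwas) <- colnames(true_beta)
  for (t in seq_len(n_traits)) {
    if (t <= arch$n_trans) {
      gwas[[t]] <- list(trans = make_summary(true_beta[, t]))
    } else {
      gwas[[t]] <- list(
        eur = make_summary(true_beta[, t]),
        eas = make_summary(arch$attenuation * true_beta[, t]))
    }
  }

  gvalues <- geno %*% true_beta
  liability <- as.numeric(scale(gvalues) %*% arch$trait_gamma) +
    stats::rnorm(n)
  outcome <- stats::rbinom(n, 1, stats::plogis(liability - 1))

  list(genotypes = geno, variant_info = variant_info, gwas = gwas,
       true_beta = true_beta, trait_gamma = arch$trait_gamma,
       liability = liability, outcome = outcome)
}
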
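# Shared builders for the test suite. Expensive fitted objects are
# memoized within a test run so several files can reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# Hand-constructed cohort table from raw columns.
make_cohort <- function(...) {
  d <- data.frame(...)
  if (!"cvd" %in% names(d)) d$cvd <- !is.na(d$age_cvd)
  if (!"death" %in% names(d)) d$death <- !is.na(d$age_death)
  if (!"sex" %in% names(d)) d$sex <- "female"
  if ("group" %in% names(d) && !is.factor(d$group)) d$group <- factor(d$group)
  class(d) <- c("cohort_table", "data.frame")
  d
}

# Single-group configuration (reference only) for rate-recovery checks.
single_group_config <- function(n, seed = 1, ...) {
  sim_config(n = n, seed = seed,
             groups = data.frame(group = "all", prevalence = 1,
                                 hr1 = 1, hr2 = 1, hr3 = 1),
             ...)
}

# Default three-group cohort at n = 50,000, fitted once.
big_cohort <- function() {
  memo("big_cohort", simulate_cohort(sim_config(n = 50000, seed = 42)))
}

big_inputs <- function() {
  memo("big_inputs", fit_lifetable_inputs(big_cohort()))
}

# lifetable_inputs built directly from known generative parameters
# (exact coefficients, exact HRs, prevalence constant over age). The
# pooled rate is the prevalence-weighted mixture of the group rates, so
# with constant prevalence the calibration recovers each group's true
# hazard exactly.
generative_inputs <- function(config, se = 0) {
  gr <- config$groups
  rates <- lapply(1:3, function(i) {
    pooled_a <- config$baseline$a[i] *
      sum(gr$prevalence * gr[[paste0("hr", i)]])
    structure(list(transition = i, basis = "gompertz", df = NA,
                   coef = c(`(Intercept)` = log(pooled_a),
                            age = config$baseline$b[i]),
                   vcov = diag(se^2, 2), knots = NULL,
                   boundary_knots = NULL),
              class = "poisson_rate_model")
  })
  starts <- seq(40, 85, by = 5)
  prev <- expand.grid(band_start = starts, state = c("free", "cvd"),
                      group = gr$group, stringsAsFactors = FALSE)
  prev$proportion <- gr$prevalence[match(prev$group, gr$group)]
  prev$total_py <- 1e6
  class(prev) <- c("prevalence_table", "data.frame")
  hrs <- lapply(1:3, function(i) {
    hr <- gr[[paste0("hr", i)]][-1]
    structure(list(transition = i, scheme = "group",
                   reference = gr$group[1],
                   log_hr = stats::setNames(log(hr), gr$group[-1]),
                   se = stats::setNames(rep(se, length(hr)), gr$group[-1]),
                   vcov = diag(se^2, length(hr)) |>
                     `dimnames<-`(list(gr$group[-1], gr$group[-1])),
                   converged = TRUE),
              class = "transition_hrs")
  })
  lifetable_inputs(rates, prev, hrs)
}

# Genotype panel with LD blocks: each block is one latent variant plus
# noisy copies, giving strong within-block correlation.
block_ld_panel <- function(n, n_blocks, block_size, seed = 1,
                           spacing_bp = 5e4) {
  set.seed(seed)
  m <- n_blocks * block_size
  g <- matrix(0L, n, m)
  for (b in seq_len(n_blocks)) {
    f <- stats::runif(1, 0.2, 0.8)
    base <- stats::rbinom(n, 2, f)
    for (k in seq_len(block_size)) {
      j <- (b - 1) * block_size + k
      flip <- stats::runif(n) < 0.05
      g[, j] <- ifelse(flip, stats::rbinom(n, 2, f), base)
    }
  }
  colnames(g) <- sprintf("v%03d", seq_len(m))
  info <- data.frame(variant_id = colnames(g), chrom = 1L,
                     pos = seq_len(m) * spacing_bp,
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  list(genotypes = g, info = info)
}

# Brute-force greedy clumping oracle: literal translation of the rule,
# kept independent of the package implementation.
greedy_clump_oracle <- function(gwas, geno, r2_threshold, window_kb) {
  ord <- order(gwas$p)
  kept <- character(0)
  for (i in ord) {
    ok <- TRUE
    for (v in kept) {
      j <- which(gwas$variant_id == v)
      if (gwas$chrom[j] == gwas$chrom[i] &&
          abs(gwas$pos[j] - gwas$pos[i]) <= window_kb * 1000) {
        if (stats::cor(geno[, gwas$variant_id[i]], geno[, v])^2 >=
              r2_threshold) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) kept <- c(kept, gwas$variant_id[i])
  }
  kept
}
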
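test_that("clumping removes correlated variants and keeps independent ones", {
  set.seed(2)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  geno <- cbind(v1 = base, v2 = base,  # r^2 = 1
                v3 = rbinom(n, 2, 0.5))
  gwas <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = 1L,
                     pos = c(1e5, 1.5e5, 2e5),
                     effect_allele = "A", other_allele = "G",
                     beta = c(0.3, 0.25, 0.1),
                     p = c(1e-8, 1e-4, 0.05), eaf = 0.5)
  cands <- clump_and_threshold(gwas, geno, r2_threshold = 0.2,
                               p_thresholds = 1)
  expect_setequal(cands[[1]]$weights$variant_id, c("v1", "v3"))

  # uncorrelated variants all survive at p_threshold = 1
  geno_ind <- sapply(1:6, function(i) rbinom(n, 2, 0.5))
  colnames(geno_ind) <- paste0("w", 1:6)
  gwas_ind <- data.frame(variant_id = colnames(geno_ind), chrom = 1L,
                         pos = (1:6) * 1e4, effect_allele = "A",
                         other_allele = "G", beta = rnorm(6),
                         p = runif(6), eaf = 0.5)
  kept <- clump_and_threshold(gwas_ind, geno_ind, r2_threshold = 0.1,
                              p_thresholds = 1)[[1]]$weights$variant_id
  expect_setequal(kept, colnames(geno_ind))

  # p-value thresholding nests candidates
  cands2 <- clump_and_threshold(gwas, geno, r2_threshold = 0.2,
                                p_thresholds = c(1e-6, 1e-3, 1))
  sizes <- vapply(cands2, function(x) nrow(x$weights), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(clump_and_threshold(gwas[0, ], geno), "empty")
  expect_error(clump_and_threshold(gwas, geno, window_kb = 0), "window")
})

test_that("clumping matches the brute-force greedy oracle on LD blocks", {
  for (seed in 1:3) {
    panel <- block_ld_panel(n = 300, n_blocks = 10, block_size = 5,
                            seed = seed)
    set.seed(seed + 100)
    gwas <- data.frame(panel$info,
                       beta = rnorm(50, 0, 0.2),
                       p = runif(50)^2, eaf = 0.5)
    for (r2 in c(0.1, 0.5)) {
      got <- clump_and_threshold(gwas, panel$genotypes, r2_threshold = r2,
                                 window_kb = 250,
                                 p_thresholds = 1)[[1]]$weights$variant_id
      oracle <- greedy_clump_oracle(gwas, panel$genotypes, r2, 250)
      expect_setequal(got, oracle)
    }
  }
})

test_that("scoring is a standardized dot product with allele harmonization", {
  set.seed(3)
  n <- 50
  geno <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
                 dimnames = list(NULL, paste0("v", 1:20)))
  info <- data.frame(variant_id = colnames(geno), effect_allele = "A",
                     other_allele = "G", stringsAsFactors = FALSE)
  w <- data.frame(variant_id = colnames(geno), effect_allele = "A",
                  other_allele = "G", weight = rnorm(20),
                  stringsAsFactors = FALSE)

  # hand-computed dot product oracle
  raw_oracle <- as.numeric(geno %*% w$weight)
  expect_equal(score_individuals(w, geno, standardize = FALSE), raw_oracle)
  expect_equal(score_individuals(w, geno),
               as.numeric(scale(raw_oracle)))

  # single variant, weight one -> standardized dosage
  w1 <- w[1, ]; w1$weight <- 1
  expect_equal(score_individuals(w1, geno),
               as.numeric(scale(geno[, 1])))

  # invariant to variant order and to simultaneous allele + sign flip
  shuf <- sample(20)
  expect_equal(score_individuals(w[shuf, ], geno),
               score_individuals(w, geno))
  w_flip <- w
  w_flip$effect_allele <- "G"
  w_flip$other_allele <- "A"
  w_flip$weight <- -w$weight
  expect_equal(score_individuals(w_flip, geno, panel_info = info),
               score_individuals(w, geno, panel_info = info))

  # strand-ambiguous variants are dropped at harmonization
  w_amb <- w
  w_amb$effect_allele[1] <- "A"
  w_amb$other_allele[1] <- "T"
  h <- harmonize_weights(w_amb, info)
  expect_false("v1" %in% h$variant_id)
  expect_equal(nrow(h), 19)

  # degenerate cases
  w0 <- w; w0$weight <- 0
  expect_error(score_individuals(w0, geno), "zero variance")
  w_none <- w; w_none$variant_id <- paste0("x", 1:20)
  expect_error(score_individuals(w_none, geno), "overlap")
})

test_that("optimal-candidate selection picks the informative score", {
  set.seed(4)
  n <- 2000
  geno <- matrix(rbinom(n * 30, 2, 0.5), n, 30,
                 dimnames = list(NULL, paste0("v", 1:30)))
  true_w <- rnorm(30)
  liab <- as.numeric(scale(geno %*% true_w))
  y <- rbinom(n, 1, plogis(liab - 0.5))
  cand_true <- list(method = "external", hyperparams = "true",
                    weights = data.frame(variant_id = colnames(geno),
                                         effect_allele = "A",
                                         other_allele = "G",
                                         weight = true_w))
  cand_noise <- cand_true
  cand_noise$weights$weight <- rnorm(30)

  # single candidate returns itself
  expect_identical(select_optimal_prs(list(cand_noise), y, geno)$index, 1L)

  sel <- select_optimal_prs(list(cand_noise, cand_true), y, geno)
  expect_identical(sel$index, 2L)
  expect_gt(sel$z[2], sel$z[1])

  # identical candidates tie -> first by input order
  sel_tie <- select_optimal_prs(list(cand_true, cand_true), y, geno)
  expect_identical(sel_tie$index, 1L)

  expect_error(select_optimal_prs(list(), y, geno), "no candidates")
  expect_error(select_optimal_prs(list(cand_true), rep(1, n), geno),
               "both classes")
})

test_that("AIC integration keeps one ancestry or both as warranted", {
  set.seed(5)
  n <- 4000
  s1 <- rnorm(n); s2 <- rnorm(n)
  y_both <- rbinom(n, 1, plogis(0.5 * s1 + 0.5 * s2 - 1))

  # identical scores: single-score model wins on the parameter penalty
  r_same <- aic_integrate(s1, s1, y_both)
  expect_true(r_same$choice %in% c("eur_only", "eas_only"))

  # two independent informative components: both retained
  r_both <- aic_integrate(s1, s2, y_both)
  expect_identical(r_both$choice, "both")
  expect_identical(colnames(r_both$scores), c("eur", "eas"))

  # informative + pure noise: informative only
  y_one <- rbinom(n, 1, plogis(0.7 * s1 - 1))
  r_one <- aic_integrate(s1, rnorm(n), y_one)
  expect_identical(r_one$choice, "eur_only")
})

test_that("elastic-net stacking recovers signal and shrinks noise", {
  set.seed(6)
  n <- 5000; T <- 14
  scores <- matrix(rnorm(n * T), n, T,
                   dimnames = list(NULL, paste0("trait", 1:T)))
  y <- rbinom(n, 1, plogis(0.5 * scores[, 1] - 1))
  m <- elasticnet_stack(scores, y, seed = 9)
  expect_true("trait1" %in% names(m$trait_weights))
  expect_gt(m$trait_weights[["trait1"]], 0)
  noise_w <- m$trait_weights[setdiff(names(m$trait_weights), "trait1")]
  if (length(noise_w) > 0) {
    expect_true(all(abs(noise_w) < 0.5 * m$trait_weights[["trait1"]]))
  }

  # grouping property: duplicated informative traits share the weight
  scores2 <- scores
  scores2[, 2] <- scores2[, 1] + rnorm(n, sd = 0.01)
  y2 <- rbinom(n, 1, plogis(0.5 * scores2[, 1] - 1))
  m2 <- elasticnet_stack(scores2, y2, seed = 9, alpha_grid = 0.1)
  w12 <- m2$trait_weights[c("trait1", "trait2")]
  expect_true(all(w12 > 0))
  expect_lt(abs(diff(w12)) / mean(w12), 0.5)

  # fold assignment is seeded and recorded
  m_rep <- elasticnet_stack(scores, y, seed = 9)
  expect_identical(m$foldid, m_rep$foldid)
  expect_identical(m$trait_weights, m_rep$trait_weights)
})

test_that("permuted outcomes give an all-zero stack in most replicates", {
  set.seed(7)
  n <- 800; T <- 6
  scores <- matrix(rnorm(n * T), n, T,
                   dimnames = list(NULL, paste0("trait", 1:T)))
  y <- rbinom(n, 1, plogis(0.8 * scores[, 1] - 0.5))
  zero_runs <- vapply(1:10, function(s) {
    y_perm <- sample(y)
    m <- suppressWarnings(elasticnet_stack(scores, y_perm, seed = s))
    length(m$trait_weights) == 0
  }, logical(1))
  expect_gte(sum(zero_runs), 9)
})

test_that("variant expansion reproduces the stacked score on any panel", {
  set.seed(8)
  sim <- simulate_genetics(n = 800, m_variants = 60, n_traits = 3,
                           seed = 21,
                           architecture = list(trait_gamma = c(0.6, 0.4, 0)))
  trait_w <- lapply(1:3, function(t) {
    data.frame(variant_id = sim$variant_info$variant_id,
               effect_allele = "A", other_allele = "G",
               weight = sim$true_beta[, t], stringsAsFactors = FALSE)
  })
  names(trait_w) <- colnames(sim$true_beta)
  scores <- sapply(trait_w, function(w)
    score_individuals(w, sim$genotypes))
  m <- elasticnet_stack(scores, sim$outcome, seed = 2,
                        trait_variant_weights = lapply(
                          names(trait_w), function(tr) {
                            w <- trait_w[[tr]]
                            # per-variant weights on the raw-score scale:
                            # divide by the raw SD used to standardize
                            raw <- score_individuals(w, sim$genotypes,
                                                     standardize = FALSE)
                            w$weight <- w$weight / sd(raw)
                            w
                          }) |> stats::setNames(names(trait_w)))
  skip_if(length(m$trait_weights) == 0)
  expanded <- score_individuals(m$variant_expansion, sim$genotypes,
                                standardize = FALSE)
  stacked <- predict_metaprs(m, scores, standardize = FALSE)
  expect_gt(abs(cor(expanded, stacked)), 0.999999)
})

test_that("full meta-score pipeline separates incidence by quintile", {
  sim <- memo("metaprs_sim", simulate_genetics(
    n = 4000, m_variants = 120, n_traits = 4, seed = 31,
    architecture = list(trait_gamma = c(0.5, 0.4, 0, 0), n_trans = 2)))
  geno <- sim$genotypes
  half <- seq_len(2000)
  test_idx <- setdiff(seq_len(4000), half)

  trait_scores <- sapply(seq_len(4)[], function(t) {
    gw <- sim$gwas[[t]]
    if (!is.null(gw$trans)) {
      cands <- clump_and_threshold(gw$trans, geno[half, ],
                                   p_thresholds = c(1e-3, 0.1, 1))
      sel <- select_optimal_prs(cands, sim$outcome[half], geno[half, ])
      score_individuals(sel$prs, geno)
    } else {
      se <- clump_and_threshold(gw$eur, geno[half, ],
                                p_thresholds = c(1e-3, 0.1, 1))
      sa <- clump_and_threshold(gw$eas, geno[half, ],
                                p_thresholds = c(1e-3, 0.1, 1))
      pe <- select_optimal_prs(se, sim$outcome[half], geno[half, ])$prs
      pa <- select_optimal_prs(sa, sim$outcome[half], geno[half, ])$prs
      ai <- aic_integrate(score_individuals(pe, geno[half, ]),
                          score_individuals(pa, geno[half, ]),
                          sim$outcome[half])
      if (ai$choice == "both") {
        (score_individuals(pe, geno) + score_individuals(pa, geno)) / 2
      } else if (ai$choice == "eur_only") {
        score_individuals(pe, geno)
      } else {
        score_individuals(pa, geno)
      }
    }
  })
  colnames(trait_scores) <- names(sim$gwas)
  m <- elasticnet_stack(trait_scores[half, ], sim$outcome[half], seed = 3)
  skip_if(length(m$trait_weights) == 0)
  meta <- predict_metaprs(m, trait_scores[test_idx, ])
  cat5 <- categorize_prs(meta)$category
  inc <- tapply(sim$outcome[test_idx], cat5, mean)
  expect_gt(inc[["high"]], inc[["low"]])
})
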
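#' Greedy clumping and thresholding of GWAS summary statistics
#'
#' Standard C+T candidate construction: variants are visited in ascending
#' p-value order and retained unless their squared Pearson correlation of
#' dosages with any already-retained variant within `window_kb` reaches
#' `r2_threshold`. One candidate score is produced per p-value threshold,
#' containing the retained variants with p at or below that threshold,
#' weighted by their GWAS effect sizes.
#'
#' @param gwas data.frame of GWAS summary statistics with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `p`, `eaf`.
#' @param ld_ref genotype matrix used as the LD reference: numeric matrix
#'   of dosages in \[0, 2\] with variants in columns, column names matching
#'   `variant_id`.
#' @param r2_threshold squared-correlation cutoff above which a variant is
#'   clumped away (default 0.2).
#' @param window_kb clumping window in kilobases (default 250); only pairs
#'   on the same chromosome within this distance are compared.
#' @param p_thresholds numeric vector of p-value inclusion thresholds in
#'   (0, 1].
#' @return list of candidate PRS objects (one per threshold), each a list
#'   with `method = "clump_threshold"`, `hyperparams`, and `weights`
#'   (data.frame `variant_id`, `effect_allele`, `other_allele`, `weight`).
#' @export
clump_and_threshold <- function(gwas, ld_ref, r2_threshold = 0.2,
                                window_kb = 250,
                                p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-2,
                                                 0.1, 0.5, 1)) {
  if (nrow(gwas) == 0L) stop("empty GWAS summary")
  if (window_kb <= 0) stop("window_kb must be positive")
  stopifnot(all(p_thresholds > 0), all(p_thresholds <= 1))
  if (!all(gwas$variant_id %in% colnames(ld_ref))) {
    stop("LD reference does not cover all GWAS variants")
  }
  ord <- order(gwas$p)
  g <- gwas[ord, , drop = FALSE]
  retained <- integer(0)
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(g))) {
    keep <- TRUE
    for (j in retained) {
      if (g$chrom[j] == g$chrom[i] &&
          abs(g$pos[j] - g$pos[i]) <= window_bp) {
        r <- stats::cor(ld_ref[, g$variant_id[i]], ld_ref[, g$variant_id[j]])
        if (!is.na(r) && r^2 >= r2_threshold) {
          keep <- FALSE
          break
        }
      }
    }
    if (keep) retained <- c(retained, i)
  }
  kept <- g[retained, , drop = FALSE]
  lapply(p_thresholds, function(pt) {
    sel <- kept[kept$p <= pt, , drop = FALSE]
    list(
      method = "clump_threshold",
      hyperparams = list(r2_threshold = r2_threshold, window_kb = window_kb,
                         p_threshold = pt),
      weights = data.frame(variant_id = sel$variant_id,
                           effect_allele = sel$effect_allele,
                           other_allele = sel$other_allele,
                           weight = sel$beta,
                           stringsAsFactors = FALSE)
    )
  })
}

#' Harmonize score weights to a genotype panel's allele coding
#'
#' Matches weight rows to panel variants, flips the weight sign where the
#' score's effect allele is the panel's other allele, and drops
#' strand-ambiguous (A/T, C/G) variants, which cannot be resolved without
#' strand information.
#'
#' @param weights data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param panel_info data.frame with `variant_id`, `effect_allele`,
#'   `other_allele` describing the allele counted by the dosage columns.
#' @return harmonized weights data.frame (rows only for resolvable,
#'   panel-present variants; weights on the panel's effect-allele scale).
#' @export
harmonize_weights <- function(weights, panel_info) {
  ambiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  w <- weights[!ambiguous(weights$effect_allele, weights$other_allele), ,
               drop = FALSE]
  idx <- match(w$variant_id, panel_info$variant_id)
  w <- w[!is.na(idx), , drop = FALSE]
  p <- panel_info[idx[!is.na(idx)], , drop = FALSE]
  same <- w$effect_allele == p$effect_allele & w$other_allele == p$other_allele
  flipped <- w$effect_allele == p$other_allele & w$other_allele == p$effect_allele
  keep <- same | flipped
  w <- w[keep, , drop = FALSE]
  sgn <- ifelse(flipped[keep], -1, 1)
  data.frame(variant_id = w$variant_id,
             effect_allele = p$effect_allele[keep],
             other_allele = p$other_allele[keep],
             weight = w$weight * sgn,
             stringsAsFactors = FALSE)
}

#' Score individuals with a weight set and standardize
#'
#' Computes the additive score (sum over variants of weight times dosage)
#' and returns it standardized to mean 0, SD 1 over the scored individuals.
#'
#' @param prs candidate PRS object (as produced by [clump_and_threshold()])
#'   or a bare weights data.frame.
#' @param genotypes dosage matrix (individuals x variants, column names =
#'   variant ids).
#' @param panel_info optional allele metadata for harmonization via
#'   [harmonize_weights()]; when `NULL` the weight alleles are assumed
#'   already aligned to the panel.
#' @param standardize return standardized scores (default) or raw sums.
#' @return numeric score vector of length `nrow(genotypes)`.
#' @export
score_individuals <- function(prs, genotypes, panel_info = NULL,
                              standardize = TRUE) {
  w <- if (is.data.frame(prs)) prs else prs$weights
  if (!is.null(panel_info)) w <- harmonize_weights(w, panel_info)
  w <- w[w$variant_id %in% colnames(genotypes), , drop = FALSE]
  if (nrow(w) == 0L) stop("no overlapping variants between score and panel")
  raw <- as.numeric(genotypes[, w$variant_id, drop = FALSE] %*% w$weight)
  if (!standardize) return(raw)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("score has zero variance; cannot standardize")
  }
  (raw - mean(raw)) / s
}

#' Select the candidate score most strongly associated with the outcome
#'
#' Fits, for each candidate, a logistic model of the binary outcome on the
#' candidate's standardized score plus covariates, and returns the candidate
#' with the largest absolute Wald z statistic for the score term. Ties are
#' broken by input order; candidates whose model fails to converge (e.g.
#' separation) are flagged and skipped.
#'
#' @param candidates list of candidate PRS objects.
#' @param outcome binary vector (0/1) with both classes present.
#' @param genotypes dosage matrix used to score candidates.
#' @param covariates optional data.frame of adjustment covariates.
#' @param panel_info optional allele metadata passed to
#'   [score_individuals()].
#' @return list with `prs` (the winning candidate), `index`, `z`
#'   (per-candidate absolute Wald z; NA where skipped).
#' @export
select_optimal_prs <- function(candidates, outcome, genotypes,
                               covariates = NULL, panel_info = NULL) {
  if (length(candidates) == 0L) stop("no candidates supplied")
  if (length(unique(outcome)) < 2L) stop("outcome must have both classes")
  zs <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    sc <- tryCatch(
      score_individuals(candidates[[i]], genotypes, panel_info),
      error = function(e) NULL)
    if (is.null(sc)) next
    dat <- data.frame(y = outcome, score = sc)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    fit <- tryCatch(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit)) next
    co <- summary(fit)$coefficients
    if ("score" %in% rownames(co)) zs[i] <- abs(co["score", "z value"])
  }
  if (all(is.na(zs))) stop("no candidate could be evaluated")
  best <- which.max(zs)  # which.max is stable: first maximum wins
  list(prs = candidates[[best]], index = best, z = zs)
}

#' Decide between ancestry-specific scores by AIC
#'
#' Fits three logistic models of the outcome — on the European-ancestry
#' score, on the East Asian-ancestry score, and on both — each adjusted for
#' the supplied covariates, and keeps the specification with the smallest
#' AIC. Nearly collinear score pairs (|r| > 0.999) fall back to the single
#' better-AIC model, since the joint fit is unstable.
#'
#' @param prs_eur,prs_eas standardized score vectors aligned to the same
#'   individuals.
#' @param outcome binary vector.
#' @param covariates optional data.frame.
#' @return list with `choice` (`"eur_only"`, `"eas_only"`, or `"both"`),
#'   `aic` (named vector of the three AICs), and `scores` (matrix of the
#'   retained score column(s)).
#' @export
aic_integrate <- function(prs_eur, prs_eas, outcome, covariates = NULL) {
  stopifnot(length(prs_eur) == length(prs_eas),
            length(prs_eur) == length(outcome))
  base <- data.frame(y = outcome)
  if (!is.null(covariates)) base <- cbind(base, covariates)
  fit_one <- function(dat) stats::glm(y ~ ., data = dat,
                                      family = stats::binomial())
  aic_eur <- stats::AIC(fit_one(cbind(base, eur = prs_eur)))
  aic_eas <- stats::AIC(fit_one(cbind(base, eas = prs_eas)))
  collinear <- abs(stats::cor(prs_eur, prs_eas)) > 0.999
  aic_both <- if (collinear) Inf else {
    stats::AIC(fit_one(cbind(base, eur = prs_eur, eas = prs_eas)))
  }
  aics <- c(eur_only = aic_eur, eas_only = aic_eas, both = aic_both)
  choice <- names(aics)[which.min(aics)]
  scores <- switch(choice,
    eur_only = cbind(eur = prs_eur),
    eas_only = cbind(eas = prs_eas),
    both = cbind(eur = prs_eur, eas = prs_eas))
  list(choice = choice, aic = aics, scores = scores)
}

#' Stack trait-specific scores into a meta-score with the elastic net
#'
#' Integrates standardized trait-specific polygenic scores into a single
#' meta-score by penalized logistic regression. The elastic-net mixing
#' parameter is searched over a small grid by minimal cross-validated
#' deviance with a seeded, recorded ten-fold assignment; within the chosen
#' mixing, the penalty strength defaults to the one-standard-error rule
#' (`lambda_choice = "1se"`), which keeps the stack sparse when the scores
#' carry no signal — under `"min"` the deviance-minimizing penalty
#' frequently retains spurious small coefficients. The returned model
#' carries the stacking coefficients, the per-trait standardization used
#' before stacking, and (when per-variant weights are supplied) the
#' expansion of the meta-score onto individual variants.
#'
#' @param trait_scores numeric matrix (individuals x traits) of trait
#'   scores; column names are trait labels. Columns are re-standardized
#'   internally and the means/SDs recorded.
#' @param outcome binary vector.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param alpha_grid elastic-net mixing values to search (default
#'   0.1, 0.5, 0.9).
#' @param lambda_choice `"1se"` (default) or `"min"`: penalty-strength
#'   rule applied within the selected mixing value.
#' @param trait_variant_weights optional named list mapping trait label to
#'   its per-variant weights data.frame (`variant_id`, `effect_allele`,
#'   `other_allele`, `weight`); used to build the variant expansion.
#' @return object of class `metaprs_model`: list with `trait_weights`
#'   (named vector, zero-penalized traits dropped), `intercept`, `alpha`,
#'   `lambda`, `standardization` (per-trait mean/sd), `foldid`, and
#'   `variant_expansion` (data.frame or NULL).
#' @export
elasticnet_stack <- function(trait_scores, outcome, folds = 10, seed = 1,
                             alpha_grid = c(0.1, 0.5, 0.9),
                             lambda_choice = c("1se", "min"),
                             trait_variant_weights = NULL) {
  lambda_choice <- match.arg(lambda_choice)
  trait_scores <- as.matrix(trait_scores)
  if (ncol(trait_scores) < 2L) stop("need at least two trait scores")
  if (is.null(colnames(trait_scores))) {
    colnames(trait_scores) <- paste0("trait", seq_len(ncol(trait_scores)))
  }
  mu <- colMeans(trait_scores)
  sdv <- apply(trait_scores, 2, stats::sd)
  if (any(sdv == 0)) stop("constant trait score column")
  x <- scale(trait_scores, center = mu, scale = sdv)

  set.seed(seed)
  n <- nrow(x)
  foldid <- sample(rep_len(seq_len(folds), n))

  fits <- lapply(alpha_grid, function(a) {
    glmnet::cv.glmnet(x, outcome, family = "binomial", alpha = a,
                      foldid = foldid, type.measure = "deviance",
                      standardize = FALSE)
  })
  best_cvm <- vapply(fits, function(f) min(f$cvm), numeric(1))
  bi <- which.min(best_cvm)
  fit <- fits[[bi]]
  s_lambda <- paste0("lambda.", lambda_choice)
  beta <- as.numeric(stats::coef(fit, s = s_lambda))
  names(beta) <- rownames(stats::coef(fit, s = s_lambda))
  intercept <- beta[1]
  coefs <- beta[-1]
  if (all(coefs == 0)) {
    warning("all stacking coefficients are zero at the optimal penalty")
  }
  nz <- coefs[coefs != 0]

  variant_expansion <- NULL
  if (!is.null(trait_variant_weights) && length(nz) > 0) {
    pieces <- lapply(names(nz), function(tr) {
      w <- trait_variant_weights[[tr]]
      if (is.null(w)) return(NULL)
      data.frame(variant_id = w$variant_id,
                 effect_allele = w$effect_allele,
                 other_allele = w$other_allele,
                 weight = nz[[tr]] * w$weight / sdv[[tr]],
                 stringsAsFactors = FALSE)
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (length(pieces) > 0) {
      all_w <- do.call(rbind, pieces)
      variant_expansion <- stats::aggregate(
        weight ~ variant_id + effect_allele + other_allele, data = all_w,
        FUN = sum)
    }
  }

  structure(list(trait_weights = nz, intercept = unname(intercept),
                 alpha = alpha_grid[bi],
                 lambda = fit[[s_lambda]],
                 standardization = list(mean = mu, sd = sdv),
                 foldid = foldid,
                 variant_expansion = variant_expansion),
            class = "metaprs_model")
}

#' Compute the meta-score for new individuals
#'
#' Applies a fitted stacking model to a matrix of trait scores: each trait
#' column is standardized with the training means/SDs, multiplied by its
#' stacking coefficient, summed, and the result standardized over the
#' scored set.
#'
#' @param model a `metaprs_model` from [elasticnet_stack()].
#' @param trait_scores matrix with the same trait columns used in fitting.
#' @param standardize standardize the output over the scored individuals
#'   (default TRUE).
#' @return numeric meta-score vector.
#' @export
predict_metaprs <- function(model, trait_scores, standardize = TRUE) {
  trait_scores <- as.matrix(trait_scores)
  traits <- names(model$trait_weights)
  if (length(traits) == 0L) {
    return(rep(0, nrow(trait_scores)))
  }
  missing_tr <- setdiff(traits, colnames(trait_scores))
  if (length(missing_tr) > 0L) {
    stop("trait_scores missing columns: ", paste(missing_tr, collapse = ", "))
  }
  x <- scale(trait_scores[, traits, drop = FALSE],
             center = model$standardization$mean[traits],
             scale = model$standardization$sd[traits])
  raw <- as.numeric(x %*% model$trait_weights)
  if (!standardize) return(raw)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) stop("meta-score has zero variance")
  (raw - mean(raw)) / s
}
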
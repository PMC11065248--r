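# Chained-equation imputation of the laboratory block.
#
# A simplified multiple-imputation scheme: per-variable regression sweeps
# with predictive-mean matching (PMM) donors, several independent chains
# pooled by averaging. A classification-and-regression-tree strategy
# (rpart) is available as an alternative conditional model.

impute_predictors <- function() {
  c("age", "bmi", "sbp", "dx_diabetes", "dx_hypertension",
    "dx_dyslipidemia", "smoker")
}

# k-nearest predictive-mean-matching donor draw (vectorized over targets)
pmm_draw <- function(pred_missing, pred_obs, obs_values, k = 5L) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  vo <- obs_values[ord]
  n_obs <- length(po)
  k <- min(k, n_obs)
  pos <- findInterval(pred_missing, po)
  out <- numeric(length(pred_missing))
  for (i in seq_along(pred_missing)) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n_obs, pos[i] + k)
    idx <- lo:hi
    nearest <- idx[order(abs(po[idx] - pred_missing[i]))][seq_len(k)]
    out[i] <- vo[nearest[sample.int(length(nearest), 1L)]]
  }
  out
}

#' Impute missing laboratory values
#'
#' Fills missing lab values by chained per-variable conditional models with
#' predictive-mean matching: each lab variable is regressed on demographics,
#' examination values, diagnoses and the other (currently-filled) labs among
#' the observed records; missing entries receive the observed value of a
#' donor among the `k` nearest predictions. `n_chains` independent chains
#' are run and pooled by averaging, so imputed values remain inside the
#' observed range of each variable. Observed records are returned unchanged.
#'
#' @param pop Population data frame (possibly with `NA` lab blocks).
#' @param seed Integer seed.
#' @param n_chains Number of imputation chains pooled by averaging.
#' @param method Conditional model: `"pmm"` (linear regression + PMM,
#'   default) or `"cart"` (regression tree + PMM on tree predictions).
#' @param sweeps Chained-equation sweeps per chain.
#' @return The population with a complete lab block.
#' @export
impute_missing <- function(pop, seed = 1L, n_chains = 5L,
                           method = c("pmm", "cart"), sweeps = 2L) {
  method <- match.arg(method)
  miss <- is.na(pop[LAB_VARS])
  if (!any(miss)) return(pop)
  for (v in LAB_VARS) {
    if (all(miss[, v]))
      stop(sprintf("cannot impute '%s': no observed values", v),
           call. = FALSE)
  }
  preds_base <- impute_predictors()
  X <- pop[preds_base]
  X$sex_female <- pop$sex == "female"

  vars_to_do <- LAB_VARS[colSums(miss) > 0]
  chain_vals <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed * 1000L + ch)
    cur <- pop[LAB_VARS]
    # initialize missing entries with random observed draws
    for (v in vars_to_do) {
      obs <- cur[[v]][!miss[, v]]
      cur[[v]][miss[, v]] <- sample(obs, sum(miss[, v]), replace = TRUE)
    }
    for (sw in seq_len(sweeps)) {
      for (v in vars_to_do) {
        others <- setdiff(LAB_VARS, v)
        D <- cbind(X, cur[others])
        obs_idx <- !miss[, v]
        if (method == "pmm") {
          fit <- stats::lm(y ~ ., data = cbind(y = pop[[v]][obs_idx],
                                               D[obs_idx, ]))
          ph <- stats::predict(fit, newdata = D)
        } else {
          fit <- rpart::rpart(y ~ ., data = cbind(y = pop[[v]][obs_idx],
                                                  D[obs_idx, ]),
                              method = "anova")
          ph <- stats::predict(fit, newdata = D)
          # tie-break identical leaf predictions for donor matching
          ph <- ph + stats::runif(length(ph), -1e-9, 1e-9)
        }
        cur[[v]][miss[, v]] <- pmm_draw(ph[miss[, v]], ph[obs_idx],
                                        pop[[v]][obs_idx])
      }
    }
    chain_vals[[ch]] <- cur
  }
  pooled <- Reduce(`+`, lapply(chain_vals, as.matrix)) / n_chains
  for (v in vars_to_do)
    pop[[v]][miss[, v]] <- pooled[miss[, v], v]
  pop
}
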
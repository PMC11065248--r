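# Synthetic survey population: generation, lab missingness, imputation.
#
# The generator reproduces sex-stratified marginals of the Gaza 40+ household
# survey (diagnosis/medication prevalences, smoking, SBP, BMI, lipid panel,
# creatinine, HbA1c) with a Gaussian-rank (latent normal) dependence
# structure: continuous variables are moment-matched truncated normals, and
# booleans are obtained by thresholding the latent normal at the prevalence
# quantile, so marginals are exact in expectation whatever the dependence.

LAB_VARS <- c("total_chol", "triglycerides", "ldl", "hdl", "creatinine", "hba1c")

# latent variable order shared by the dependence matrix and the generator
LATENT_VARS <- c("age", "bmi", "sbp",
                 "dx_diabetes", "dx_hypertension", "dx_dyslipidemia",
                 "dx_asthma_copd", "smoker", "waterpipe",
                 "total_chol", "triglycerides", "ldl", "hdl", "creatinine",
                 "hba1c")

#' Default latent dependence matrix for the population generator
#'
#' Rank-correlation matrix over the latent normals behind the generated
#' variables. Only relationships the survey context implies are encoded
#' (age raises diagnosis prevalence and SBP, adiposity raises diabetes /
#' hypertension / dyslipidemia, smoking concentrates with waterpipe use and
#' respiratory disease, lipid fractions co-vary). Symmetric, unit diagonal,
#' positive semidefinite.
#'
#' @return A 15 x 15 correlation matrix with dimnames.
#' @export
default_dependence <- function() {
  K <- length(LATENT_VARS)
  R <- diag(K)
  dimnames(R) <- list(LATENT_VARS, LATENT_VARS)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("age", "dx_diabetes", 0.25)
  set_r("age", "dx_hypertension", 0.30)
  set_r("age", "dx_asthma_copd", 0.15)
  set_r("age", "sbp", 0.25)
  set_r("age", "creatinine", 0.15)
  set_r("bmi", "dx_diabetes", 0.20)
  set_r("bmi", "dx_hypertension", 0.15)
  set_r("bmi", "dx_dyslipidemia", 0.15)
  set_r("bmi", "sbp", 0.20)
  set_r("sbp", "dx_hypertension", 0.35)
  set_r("smoker", "dx_asthma_copd", 0.25)
  set_r("smoker", "waterpipe", 0.20)
  set_r("dx_dyslipidemia", "total_chol", 0.25)
  set_r("dx_dyslipidemia", "ldl", 0.25)
  set_r("dx_diabetes", "hba1c", 0.20)
  set_r("total_chol", "ldl", 0.85)
  set_r("total_chol", "hdl", 0.25)
  set_r("total_chol", "triglycerides", 0.30)
  set_r("ldl", "triglycerides", 0.20)
  set_r("hdl", "triglycerides", -0.20)
  R
}

sex_defaults <- function(sex) {
  if (sex == "male") {
    list(
      age = c(mean = 58.6, sd = 10.2),
      sbp = c(mean = 132.2, sd = 17.1),
      bmi = c(mean = 28.9, sd = 5.4),
      prev = c(refugee = 0.685,
               dx_diabetes = 0.250, dx_hypertension = 0.379,
               dx_dyslipidemia = 0.214, dx_asthma_copd = 0.101,
               smoker = 0.609, waterpipe = 0.145),
      treat = c(rx_diabetes = 498 / 525, rx_hypertension = 761 / 798,
                rx_statin = 0.796),
      labs = list(total_chol = c(mean = 170.5, sd = 38.8),
                  triglycerides = c(mean = 178.8, sd = 144.1),
                  ldl = c(mean = 106.3, sd = 37.7),
                  hdl = c(mean = 41.5, sd = 14.0),
                  creatinine = c(mean = 1.0, sd = 0.5)),
      hba1c = list(diabetes = c(mean = 13.3, sd = 1.5),
                   no_diabetes = c(mean = 5.6, sd = 0.7))
    )
  } else {
    list(
      age = c(mean = 55.4, sd = 10.5),
      sbp = c(mean = 128.0, sd = 18.7),
      bmi = c(mean = 33.5, sd = 6.4),
      prev = c(refugee = 0.685,
               dx_diabetes = 0.262, dx_hypertension = 0.425,
               dx_dyslipidemia = 0.223, dx_asthma_copd = 0.096,
               smoker = 0.012, waterpipe = 0.009),
      treat = c(rx_diabetes = 619 / 647, rx_hypertension = 1006 / 1051,
                rx_statin = 0.796),
      labs = list(total_chol = c(mean = 181.9, sd = 40.5),
                  triglycerides = c(mean = 167.4, sd = 121.5),
                  ldl = c(mean = 112.9, sd = 39.2),
                  hdl = c(mean = 46.5, sd = 16.5),
                  creatinine = c(mean = 0.8, sd = 0.4)),
      hba1c = list(diabetes = c(mean = 11.5, sd = 1.4),
                   no_diabetes = c(mean = 5.6, sd = 0.7))
    )
  }
}

VAR_BOUNDS <- list(
  age = c(40, 80), sbp = c(70, 260), bmi = c(12, 70),
  total_chol = c(80, 400), triglycerides = c(30, 1500), ldl = c(20, 320),
  hdl = c(10, 120), creatinine = c(0.3, 8), hba1c = c(4, 20)
)

#' Construct a population specification
#'
#' Holds per-sex marginal parameters (means/SDs for continuous variables,
#' prevalences for booleans, treatment rates given diagnosis), the latent
#' dependence matrix, the fraction of records with laboratory values, and the
#' default population size. Defaults reproduce the Gaza 40+ household survey
#' marginals (4,576 adults; 54.0% women; lab values in 1,938 records).
#'
#' @param female_fraction Proportion of women.
#' @param male,female Per-sex parameter lists; omitted entries fall back to
#'   the survey defaults (see `sex_defaults` in the sources for the layout).
#' @param dependence Latent correlation matrix over the 15 generator
#'   variables (see [default_dependence()]).
#' @param lab_observed_fraction Proportion of records carrying the lab block.
#' @param n_default Default population size.
#' @return An object of class `ncd_popspec`.
#' @export
population_spec <- function(female_fraction = 2473 / 4576,
                            male = list(), female = list(),
                            dependence = default_dependence(),
                            lab_observed_fraction = 1938 / 4576,
                            n_default = 4576) {
  spec <- list(
    female_fraction = female_fraction,
    male = utils::modifyList(sex_defaults("male"), male),
    female = utils::modifyList(sex_defaults("female"), female),
    dependence = dependence,
    lab_observed_fraction = lab_observed_fraction,
    n_default = n_default
  )
  class(spec) <- "ncd_popspec"
  validate_population_spec(spec)
  spec
}

#' Default population specification (survey marginals)
#' @return An `ncd_popspec` object.
#' @export
default_population_spec <- function() population_spec()

validate_population_spec <- function(spec) {
  bad <- character(0)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
      bad <<- c(bad, sprintf("%s must lie in [0, 1] (got %s)",
                             name, paste(signif(x, 4), collapse = ", ")))
  }
  chk_prob(spec$female_fraction, "female_fraction")
  chk_prob(spec$lab_observed_fraction, "lab_observed_fraction")
  for (s in c("male", "female")) {
    p <- spec[[s]]
    for (nm in names(p$prev)) chk_prob(p$prev[[nm]], paste0(s, "$prev$", nm))
    for (nm in names(p$treat)) chk_prob(p$treat[[nm]], paste0(s, "$treat$", nm))
    sds <- c(age = p$age[["sd"]], sbp = p$sbp[["sd"]], bmi = p$bmi[["sd"]],
             vapply(p$labs, function(v) v[["sd"]], numeric(1)),
             hba1c_dm = p$hba1c$diabetes[["sd"]],
             hba1c_no = p$hba1c$no_diabetes[["sd"]])
    if (any(sds <= 0))
      bad <- c(bad, sprintf("%s: all SDs must be > 0 (offending: %s)",
                            s, paste(names(sds)[sds <= 0], collapse = ", ")))
  }
  R <- spec$dependence
  if (!is.matrix(R) || nrow(R) != length(LATENT_VARS) ||
      ncol(R) != length(LATENT_VARS)) {
    bad <- c(bad, sprintf("dependence must be a %d x %d matrix",
                          length(LATENT_VARS), length(LATENT_VARS)))
  } else {
    if (max(abs(R - t(R))) > 1e-8) bad <- c(bad, "dependence must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8)
      bad <- c(bad, "dependence must have unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      bad <- c(bad, sprintf(
        "dependence must be positive semidefinite (min eigenvalue %.3g)",
        min(ev)))
  }
  if (length(bad) > 0)
    stop("invalid population specification:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  invisible(spec)
}

# ---- truncated-normal machinery -------------------------------------------

# moments of N(mu, sigma^2) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

.tn_cache <- new.env(parent = emptyenv())

# Solve for latent (mu, sigma) such that the [lo, hi]-truncated normal has
# the requested mean and SD, so bounded variables still recover their
# published marginal moments. Cached; deterministic.
match_truncnorm <- function(mean, sd, lo, hi) {
  key <- paste(mean, sd, lo, hi, sep = "|")
  hit <- .tn_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (m[["mean"]] - mean)^2 / max(sd, 1)^2 + (m[["sd"]] - sd)^2 / max(sd, 1)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi)
  .tn_cache[[key]] <- out
  out
}

# inverse CDF of the matched truncated normal, applied to uniforms
q_truncnorm <- function(u, pars) {
  a <- stats::pnorm((pars[["lo"]] - pars[["mu"]]) / pars[["sigma"]])
  b <- stats::pnorm((pars[["hi"]] - pars[["mu"]]) / pars[["sigma"]])
  stats::qnorm(a + u * (b - a)) * pars[["sigma"]] + pars[["mu"]]
}

gen_cont <- function(u, mean_sd, var) {
  b <- VAR_BOUNDS[[var]]
  q_truncnorm(u, match_truncnorm(mean_sd[["mean"]], mean_sd[["sd"]],
                                 b[1], b[2]))
}

# ---- generator -------------------------------------------------------------

#' Generate a synthetic survey population
#'
#' Draws `n` individual records whose per-sex marginals converge to the
#' specification as `n` grows. Records include demographics, diagnosis and
#' medication flags (medication implies diagnosis, drawn at the survey
#' treatment rates), tobacco exposures, examination values, and a complete
#' laboratory block (use [induce_lab_missingness()] to emulate the partial
#' lab subset). Deterministic for fixed `(spec, n, seed)`.
#'
#' @param spec An `ncd_popspec`, e.g. [default_population_spec()].
#' @param n Number of records (>= 0).
#' @param seed Integer seed controlling all randomness.
#' @return A data frame with one row per individual.
#' @export
generate_population <- function(spec = default_population_spec(), n = spec$n_default,
                                seed = 1L) {
  validate_population_spec(spec)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  cols <- c("id", "age", "sex", "refugee",
            "dx_diabetes", "dx_hypertension", "dx_dyslipidemia",
            "dx_asthma_copd",
            "rx_diabetes", "rx_hypertension", "rx_statin",
            "smoker", "waterpipe", "sbp", "bmi", LAB_VARS)
  if (n == 0L) {
    out <- data.frame(id = character(0), age = integer(0),
                      sex = character(0), refugee = logical(0))
    for (v in cols[!(cols %in% names(out))]) out[[v]] <- numeric(0)
    return(out[cols])
  }
  set.seed(seed)
  female <- stats::runif(n) < spec$female_fraction
  Rch <- chol(spec$dependence + diag(1e-9, length(LATENT_VARS)))

  gen_sex <- function(m, p) {
    Z <- matrix(stats::rnorm(m * length(LATENT_VARS)), m) %*% Rch
    colnames(Z) <- LATENT_VARS
    U <- stats::pnorm(Z)
    flag <- function(v) U[, v] > 1 - p$prev[[v]]
    dx_dm <- flag("dx_diabetes")
    h_pars <- list(dm = p$hba1c$diabetes, no = p$hba1c$no_diabetes)
    hba1c <- ifelse(dx_dm,
                    gen_cont(U[, "hba1c"], h_pars$dm, "hba1c"),
                    gen_cont(U[, "hba1c"], h_pars$no, "hba1c"))
    data.frame(
      age = as.integer(pmin(pmax(round(gen_cont(U[, "age"], p$age, "age")),
                                 40L), 80L)),
      dx_diabetes = dx_dm,
      dx_hypertension = flag("dx_hypertension"),
      dx_dyslipidemia = flag("dx_dyslipidemia"),
      dx_asthma_copd = flag("dx_asthma_copd"),
      smoker = flag("smoker"),
      waterpipe = flag("waterpipe"),
      sbp = gen_cont(U[, "sbp"], p$sbp, "sbp"),
      bmi = gen_cont(U[, "bmi"], p$bmi, "bmi"),
      total_chol = gen_cont(U[, "total_chol"], p$labs$total_chol, "total_chol"),
      triglycerides = gen_cont(U[, "triglycerides"], p$labs$triglycerides,
                               "triglycerides"),
      ldl = gen_cont(U[, "ldl"], p$labs$ldl, "ldl"),
      hdl = gen_cont(U[, "hdl"], p$labs$hdl, "hdl"),
      creatinine = gen_cont(U[, "creatinine"], p$labs$creatinine, "creatinine"),
      hba1c = hba1c
    )
  }

  males <- gen_sex(sum(!female), spec$male)
  females <- gen_sex(sum(female), spec$female)
  body <- males[rep(1L, n), ]
  body[!female, ] <- males
  body[female, ] <- females

  u_ref <- stats::runif(n)
  u_rx <- matrix(stats::runif(3L * n), n, 3)
  treat <- function(j, nm, dx) {
    rate <- ifelse(female, spec$female$treat[[nm]], spec$male$treat[[nm]])
    dx & (u_rx[, j] < rate)
  }
  p_ref <- ifelse(female, spec$female$prev[["refugee"]],
                  spec$male$prev[["refugee"]])
  out <- cbind(
    data.frame(id = sprintf("p%06d", seq_len(n)),
               sex = ifelse(female, "female", "male"),
               refugee = u_ref < p_ref),
    body)
  out$rx_diabetes <- treat(1, "rx_diabetes", out$dx_diabetes)
  out$rx_hypertension <- treat(2, "rx_hypertension", out$dx_hypertension)
  out$rx_statin <- treat(3, "rx_statin", out$dx_dyslipidemia)
  rownames(out) <- NULL
  out[cols]
}

#' Remove the laboratory block from a random subset of records
#'
#' Emulates the survey's partial laboratory linkage: only a fraction of
#' records carry lipid panel, creatinine and HbA1c values. Removal is a
#' completely-at-random Bernoulli draw; all six lab fields are blanked
#' together so the lab block is either fully present or fully absent.
#'
#' @param pop Population data frame from [generate_population()].
#' @param observed_fraction Probability a record keeps its labs (default the
#'   survey fraction 1938/4576).
#' @param seed Integer seed.
#' @return The population with `NA` lab blocks in the unobserved subset.
#' @export
induce_lab_missingness <- function(pop, observed_fraction = 1938 / 4576,
                                   seed = 1L) {
  if (!is.numeric(observed_fraction) || length(observed_fraction) != 1 ||
      !is.finite(observed_fraction) ||
      observed_fraction < 0 || observed_fraction > 1)
    stop("observed_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  drop <- stats::runif(nrow(pop)) >= observed_fraction
  pop[drop, LAB_VARS] <- NA_real_
  pop
}

#' Write / read a population CSV
#'
#' One row per individual; missing lab values are empty cells. The header is
#' the column layout documented in [generate_population()].
#'
#' @param pop Population data frame.
#' @param path File path.
#' @return `read_population` returns the population data frame.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (v in c("refugee", "dx_diabetes", "dx_hypertension", "dx_dyslipidemia",
              "dx_asthma_copd", "rx_diabetes", "rx_hypertension", "rx_statin",
              "smoker", "waterpipe"))
    pop[[v]] <- as.logical(pop[[v]])
  pop$age <- as.integer(pop$age)
  pop
}
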
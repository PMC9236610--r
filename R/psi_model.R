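#' Model formulas for PSI regression
#'
#' Seven model families relating PSI to structural and sequence features:
#' \itemize{
#'   \item `structure`: PSI ~ Mean(X) + SD(X) + Skew(X) + Kurtosis(X), the
#'     four moments of the ensemble unfolding-energy distribution X.
#'   \item `mfe`: PSI ~ Y, the unfolding energy of the single MFE structure.
#'   \item `splice_site`: PSI ~ SS (donor-strength change).
#'   \item `sre`: PSI ~ E + S + SS (enhancer, silencer, donor changes).
#'   \item `rbp`: PSI ~ Ex + In (exclusion / inclusion RBP aggregates).
#'   \item `interactive`: PSI ~ [Mean(X)+SD(X)+Skew(X)+Kurtosis(X)] *
#'     [isSynonymous + isIntronic] + [E+S+SS] * isNonSynonymous — the
#'     category-gated model: structure features act for synonymous and
#'     intronic mutations, SRE features for non-synonymous ones (products
#'     only, as the gates are indicators).
#'   \item `additive`: PSI ~ [Mean(X)+SD(X)+Skew(X)+Kurtosis(X)] + [E+S+SS].
#' }
#'
#' @param formula_id one of the ids above.
#' @param panel mutation panel data.frame (see [fit_beta_regression()]).
#' @return design matrix (with intercept).
#' @export
psi_design_matrix <- function(formula_id, panel) {
  f <- function(...) {
    cols <- c(...)
    miss <- setdiff(cols, names(panel))
    if (length(miss))
      stop("missing feature columns: ", paste(miss, collapse = ", "))
    m <- as.matrix(panel[, cols, drop = FALSE])
    cbind(`(Intercept)` = 1, m)
  }
  need_flags <- function() {
    miss <- setdiff(c("is_synonymous", "is_intronic", "is_non_synonymous"),
                    names(panel))
    if (length(miss))
      stop("missing feature columns: ", paste(miss, collapse = ", "))
  }
  switch(formula_id,
    structure = f("mean_dg", "sd_dg", "skew_dg", "kurt_dg"),
    mfe = f("mfe_dg"),
    splice_site = f("dss"),
    sre = f("enhancer", "silencer", "dss"),
    rbp = f("rbp_ex", "rbp_in"),
    additive = f("mean_dg", "sd_dg", "skew_dg", "kurt_dg",
                 "enhancer", "silencer", "dss"),
    interactive = {
      need_flags()
      f("mean_dg", "sd_dg", "skew_dg", "kurt_dg", "enhancer", "silencer",
        "dss")  # column check only
      gate_struct <- panel$is_synonymous + panel$is_intronic
      gate_sre <- panel$is_non_synonymous
      m <- cbind(
        `(Intercept)` = 1,
        `mean_dg:gate` = panel$mean_dg * gate_struct,
        `sd_dg:gate` = panel$sd_dg * gate_struct,
        `skew_dg:gate` = panel$skew_dg * gate_struct,
        `kurt_dg:gate` = panel$kurt_dg * gate_struct,
        `enhancer:nonsyn` = panel$enhancer * gate_sre,
        `silencer:nonsyn` = panel$silencer * gate_sre,
        `dss:nonsyn` = panel$dss * gate_sre)
      m
    },
    intercept_only = cbind(`(Intercept)` = rep(1, nrow(panel))),
    stop("unknown formula id '", formula_id, "'"))
}

#' Beta regression of PSI on features
#'
#' Maximum-likelihood Beta regression in the mean-precision
#' parameterization: PSI_i ~ Beta(mu_i * phi, (1 - mu_i) * phi) with
#' logit(mu_i) = x_i' beta.  When exact-boundary responses occur (0 and 1,
#' for completely skipped/included exons) the whole response is first shrunk
#' by the Smithson-Verkuilen transform y' = (y (n - 1) + 0.5) / n; panels
#' already inside the open interval are fitted untransformed.  The joint
#' likelihood in (beta, log phi) is maximized by quasi-Newton (BFGS,
#' analytic gradient, up to 500 iterations), initialized from a
#' logit-transformed least-squares fit; standard errors come from the
#' inverse observed information.
#'
#' @param panel data.frame with a `psi` column in `[0, 1]` and the feature
#'   columns the formula needs (`mean_dg`, `sd_dg`, `skew_dg`, `kurt_dg`,
#'   `mfe_dg`, `dss`, `enhancer`, `silencer`, `rbp_ex`, `rbp_in`,
#'   `is_non_synonymous`, `is_synonymous`, `is_intronic`).
#' @param formula_id see [psi_design_matrix()].
#' @return a `beta_fit`: coefficients, standard errors, `vcov`, precision
#'   `phi` (with SE), log-likelihood, convergence flag.  Constant
#'   (unidentifiable) feature columns are dropped with a warning and
#'   reported as NA, mirroring `lm()`'s rank-deficiency behavior;
#'   [predict_psi()] ignores NA coefficients.
#' @export
fit_beta_regression <- function(panel, formula_id = "interactive") {
  X <- psi_design_matrix(formula_id, panel)
  y <- panel$psi
  n <- length(y)
  if (n < ncol(X) + 2)
    stop("panel too small: ", n, " rows for ", ncol(X), " parameters")
  if (any(y < 0 | y > 1)) stop("PSI outside [0, 1]")
  if (any(y == 0 | y == 1))          # boundary outcomes occur: shrink to the
    y <- (y * (n - 1) + 0.5) / n     # open interval before fitting
  y <- pmin(pmax(y, 1e-10), 1 - 1e-10)  # numeric floor for the log-likelihood

  # constant (unidentifiable) feature columns are dropped from the
  # optimization and reported as NA, as lm() does for rank deficiency
  all_cols <- colnames(X)
  const <- setdiff(which(apply(X, 2, var) == 0), 1L)
  if (length(const)) {
    warning("constant feature column(s) dropped: ",
            paste(all_cols[const], collapse = ", "))
    X <- X[, -const, drop = FALSE]
  }

  negll <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    mu <- pmin(pmax(plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
  }
  grad <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    ystar <- qlogis(y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
    dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                  (1 - mu) * digamma((1 - mu) * phi) +
                  mu * log(y) + (1 - mu) * log(1 - y))
    -c(dbeta, dphi * phi)
  }
  # initialize from logit least squares (clamped against extreme responses)
  lf <- lm.fit(X, pmin(pmax(qlogis(y), -15), 15))
  mu0 <- plogis(drop(X %*% lf$coefficients))
  v0 <- var(y - mu0)
  phi0 <- max(0.5, mean(mu0 * (1 - mu0)) / max(v0, 1e-8) - 1)
  par0 <- c(lf$coefficients, log(phi0))
  opt <- optim(par0, negll, grad, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("singular information matrix; standard errors unavailable")
    matrix(NA_real_, length(par0), length(par0))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  k <- ncol(X)
  coefs <- setNames(rep(NA_real_, length(all_cols)), all_cols)
  ses <- coefs
  coefs[colnames(X)] <- opt$par[seq_len(k)]
  ses[colnames(X)] <- se[seq_len(k)]
  structure(list(formula_id = formula_id,
                 coefficients = coefs,
                 se = ses,
                 vcov = vcov,
                 phi = unname(exp(opt$par[k + 1])),
                 log_phi_se = se[k + 1],
                 loglik = -opt$value,
                 link = "logit",
                 converged = opt$convergence == 0,
                 n = n),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("beta regression (", x$formula_id, "), logit link, n = ", x$n,
      "\n", sep = "")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  cat("phi =", round(x$phi, 3), " loglik =", round(x$loglik, 3), "\n")
  invisible(x)
}

#' Predict PSI from a fitted model
#'
#' Inverse-logit of the linear predictor; predictions lie strictly inside
#' (0, 1).
#'
#' @param fit a `beta_fit`.
#' @param features data.frame with the feature columns the fitted formula
#'   needs (one row per variant).
#' @return numeric vector of predicted PSI.
#' @export
predict_psi <- function(fit, features) {
  X <- psi_design_matrix(fit$formula_id, features)
  use <- names(fit$coefficients)[!is.na(fit$coefficients)]
  if (!all(use %in% colnames(X))) stop("missing feature columns")
  if (anyNA(X[, use])) stop("missing feature values")
  p <- plogis(drop(X[, use, drop = FALSE] %*% fit$coefficients[use]))
  pmin(pmax(p, 1e-12), 1 - 1e-12)  # strictly inside the open interval
}

#' Bootstrap R-squared by repeated subsampling
#'
#' Draws `ceiling(fraction * n)` panel rows without replacement, fits the
#' model on the subsample, and computes the squared Pearson correlation
#' between observed and predicted PSI — overall and within each mutation
#' category — on the training subsample (set `holdout = TRUE` to evaluate on
#' the held-out rows instead).  Repeated `reps` times; a category with
#' constant PSI in a replicate yields NA.
#'
#' @param panel mutation panel with `psi`, `category`, and feature columns.
#' @param formula_id model formula.
#' @param fraction subsample fraction (default 0.7).
#' @param reps replicates (default 10).
#' @param seed RNG seed; a fixed seed reproduces the identical subsets.
#' @param holdout evaluate on the held-out 30% instead of the training 70%.
#' @return data.frame: one row per replicate, columns `rep`, `overall`,
#'   then one column per category.
#' @export
bootstrap_r2 <- function(panel, formula_id = "interactive", fraction = 0.7,
                         reps = 10, seed = 1L, holdout = FALSE) {
  n <- nrow(panel)
  m <- ceiling(fraction * n)
  cats <- sort(unique(panel$category))
  withr::with_seed(seed, {
    out <- lapply(seq_len(reps), function(r) {
      idx <- sample.int(n, m)
      fit <- fit_beta_regression(panel[idx, , drop = FALSE], formula_id)
      eval_rows <- if (holdout) setdiff(seq_len(n), idx) else idx
      sub <- panel[eval_rows, , drop = FALSE]
      pred <- predict_psi(fit, sub)
      r2 <- function(obs, p) {
        if (length(obs) < 3 || sd(obs) == 0 || sd(p) == 0) return(NA_real_)
        cor(obs, p)^2
      }
      row <- data.frame(rep = r, overall = r2(sub$psi, pred))
      for (cc in cats) {
        sel <- sub$category == cc
        row[[cc]] <- r2(sub$psi[sel], pred[sel])
      }
      row
    })
    do.call(rbind, out)
  })
}
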
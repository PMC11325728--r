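#' Sigmoid growth curves
#'
#' Trait value `W(t)` for the three classical asymptotic growth models,
#' parameterized by the upper asymptote `A`, growth rate `k` (1/day) and
#' inflection-related time `Ti` (days):
#' \itemize{
#'   \item logistic: `W = A / (1 + exp(-k (t - Ti)))` — `W(Ti) = A/2`, the
#'     inflection is at `Ti`;
#'   \item gompertz: `W = A exp(-exp(-k (t - Ti)))` — `W(Ti) = A/e`;
#'   \item richards3p: `W = A (1 + exp(-k (t - Ti)))^(-1/nu)` with the shape
#'     fixed at `nu = 0.5`, a three-parameter member of the Richards family
#'     that is left-skewed relative to the logistic.
#' }
#' Evaluation is overflow-safe for large `|k (t - Ti)|`.
#'
#' @param model One of `"logistic"`, `"gompertz"`, `"richards3p"`.
#' @param t Time (days).
#' @param A,k,Ti Curve parameters (`A > 0`, `k > 0`).
#' @export
sigmoid <- function(model = c("logistic", "gompertz", "richards3p"), t, A, k, Ti) {
  model <- match.arg(model)
  A * sigmoid_shape(model, t, k, Ti)
}

# Unit-asymptote shape; the fixed effects enter linearly through A.
sigmoid_shape <- function(model, t, k, Ti) {
  x <- k * (t - Ti)
  switch(model,
         logistic = stats::plogis(x),
         gompertz = exp(-exp(-pmin(x, 700))),
         richards3p = stats::plogis(x)^2)
}


#' Fit a hierarchical sigmoid growth model
#'
#' Fits trait trajectories with genotype-specific asymptote `A_g` and
#' inflection time `Ti_g`, a single growth rate `k` shared by all genotypes
#' (the constant-rate simplification that keeps the mixed model
#' identifiable), a replicate-level random intercept on the asymptote
#' (`u_r ~ N(0, sigma_u^2)`), and residual noise `N(0, sigma^2)`:
#'
#' `y = (A_g + u_r) * s(t; k, Ti_g) + e`
#'
#' where `s` is the unit-asymptote sigmoid shape. Because the model is
#' linear in the asymptote given the shape, the marginal Gaussian
#' likelihood is maximized by a two-layer scheme: for a candidate
#' `(k, Ti_1..G, sigma_u^2/sigma^2)` the asymptotes are profiled out by
#' generalized least squares and the residual variance in closed form; a
#' quasi-Newton search (with jittered restarts) runs over the remaining
#' parameters. Standard errors come from the observed information
#' (numerical Hessian over the fixed effects at the optimum, variance
#' components held at their estimates). Estimation is by maximum
#' likelihood, so AIC/BIC are comparable across models.
#'
#' @param records Trait table with `genotype`, `replicate`, `dap` columns
#'   and the trait column named by `trait`. Rows with missing trait values
#'   are dropped.
#' @param trait Name of the trait column (e.g. `"ch_max"`, `"cv"`,
#'   `"value"`).
#' @param model One of `"logistic"`, `"gompertz"`, `"richards3p"`.
#' @param restarts Number of jittered restarts after the data-driven start.
#' @param max_iter Optimizer iteration cap per start.
#' @param se Compute observed-information standard errors (skippable for
#'   simulation studies that only need point estimates and AIC).
#' @return A `growth_fit` object; see [tidy.growth_fit()],
#'   [glance.growth_fit()], [posthoc_contrasts()].
#' @export
fit_growth <- function(records, trait = "value",
                       model = c("logistic", "gompertz", "richards3p"),
                       restarts = 3, max_iter = 500, se = TRUE) {
  model <- match.arg(model)
  stopifnot(all(c("genotype", "replicate", "dap") %in% names(records)),
            trait %in% names(records))
  df <- records[!is.na(records[[trait]]), ]
  y <- df[[trait]]
  g <- factor(df$genotype)
  r <- factor(df$replicate)
  t <- df$dap
  G <- nlevels(g); R <- nlevels(r); n <- length(y)
  tpts <- tapply(t, g, function(v) length(unique(v)))
  if (any(tpts < 4)) stop("need at least 4 time points per genotype")
  if (R < 2) stop("need at least 2 replicates")

  init <- growth_init(y, g, t)
  starts <- list(c(log(init$k0), init$Ti0, log(0.1)))
  if (restarts > 0) {
    jit <- with_seed(derive_seed(20260922, "growth-restarts", model, n), {
      lapply(seq_len(restarts), function(s)
        c(rnorm(1, 0, 0.25), rnorm(G, 0, 2.5), rnorm(1, 0, 1)))
    })
    starts <- c(starts, lapply(jit, function(j) starts[[1]] + j))
  }
  lower <- c(log(0.002), rep(min(t) - 30, G), -20)
  upper <- c(log(2), rep(max(t) + 30, G), 10)
  gi <- as.integer(g); ri <- as.integer(r)
  cell <- ri + R * (gi - 1L)        # replicate x genotype cross-tab index
  ctx <- list(y = y, gi = gi, t = t, n = n, G = G, R = R,
              # sparse indicator matrices make the grouped sums O(n) with a
              # small constant (one sparse crossprod each)
              Mg = Matrix::sparseMatrix(i = seq_len(n), j = gi, x = 1,
                                        dims = c(n, G)),
              Mr = Matrix::sparseMatrix(i = seq_len(n), j = ri, x = 1,
                                        dims = c(n, R)),
              Mc = Matrix::sparseMatrix(i = seq_len(n), j = cell, x = 1,
                                        dims = c(n, R * G)))
  obj <- function(p) {
    profile_nll2(model, exp(p[1]), p[2:(G + 1)], exp(p[G + 2]), ctx)$nll2
  }
  best <- NULL
  trace <- character()
  for (s in seq_along(starts)) {
    p0 <- pmin(pmax(starts[[s]], lower), upper)
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = max_iter, factr = 1e4)),
      error = function(e) e)
    if (inherits(res, "error")) {
      trace <- c(trace, sprintf("start %d: %s", s, conditionMessage(res)))
      next
    }
    trace <- c(trace, sprintf("start %d: nll2 = %.4f (%s)", s, res$value,
                              if (res$convergence == 0) "converged" else "not converged"))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("growth model did not converge after restarts:\n",
         paste(trace, collapse = "\n"))
  }

  k_hat <- unname(exp(best$par[1]))
  Ti_hat <- unname(best$par[2:(G + 1)])
  lambda_hat <- unname(exp(best$par[G + 2]))
  prof <- profile_nll2(model, k_hat, Ti_hat, lambda_hat, ctx)
  sigma2 <- prof$sigma2
  sigma_u <- sqrt(lambda_hat * sigma2)
  singular <- best$par[G + 2] <= lower[G + 2] + 1e-6
  if (singular) sigma_u <- 0

  # observed-information SEs over the fixed effects (A_g, k, Ti_g), variance
  # components held at their ML estimates
  fixed <- c(prof$A, k_hat, Ti_hat)
  nll2_fixed <- function(p) {
    full_nll2(model, p[seq_len(G)], p[G + 1], p[(G + 2):(2 * G + 1)],
              lambda_hat, sigma2, ctx)
  }
  vc <- if (!se) NULL else tryCatch({
    h <- pracma::hessian(nll2_fixed, fixed)
    v <- 2 * solve(h)
    dimnames(v) <- list(fixed_names(levels(g)), fixed_names(levels(g)))
    v
  }, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 2 * G + 1) else sqrt(pmax(diag(vc), 0))

  loglik <- -prof$nll2 / 2
  n_params <- 2 * G + 3  # A_g, Ti_g, k, sigma_u^2, sigma^2
  structure(list(
    model = model, trait = trait,
    coefficients = tibble::tibble(
      genotype = levels(g),
      A = prof$A, A_se = se[seq_len(G)],
      Ti = Ti_hat, Ti_se = se[(G + 2):(2 * G + 1)]),
    k = k_hat, k_se = se[G + 1],
    sigma_u = sigma_u, sigma = sqrt(sigma2),
    singular = singular,
    vcov = vc,
    loglik = loglik,
    AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + log(n) * n_params,
    n_obs = n, n_params = n_params,
    converged = best$convergence == 0,
    trace = trace,
    data = tibble::tibble(genotype = as.character(g), replicate = as.character(r),
                          dap = t, value = y)),
    class = "growth_fit")
}

fixed_names <- function(genotypes) {
  c(paste0("A.", genotypes), "k", paste0("Ti.", genotypes))
}

# Data-driven starting values: A0 = 1.05 max, Ti0 = half-max crossing of the
# per-genotype mean trajectory, k0 = 4 * max slope / A0.
growth_init <- function(y, g, t) {
  per_g <- lapply(split(seq_along(y), g), function(idx) {
    mt <- tapply(y[idx], t[idx], mean)
    tt <- as.numeric(names(mt))
    A0 <- 1.05 * max(mt)
    half <- A0 / 2
    above <- which(mt >= half)
    Ti0 <- if (length(above) == 0) max(tt) else if (above[1] == 1) tt[1] else {
      i <- above[1]
      tt[i - 1] + (half - mt[i - 1]) / (mt[i] - mt[i - 1]) * (tt[i] - tt[i - 1])
    }
    slope <- max(diff(mt) / diff(tt))
    c(A0 = unname(A0), Ti0 = unname(Ti0), k0 = max(4 * slope / A0, 1e-3))
  })
  m <- do.call(rbind, per_g)
  list(Ti0 = m[, "Ti0"], k0 = stats::median(m[, "k0"]))
}

# Profiled -2 log marginal likelihood. Both the genotype design X and the
# replicate design Z have one nonzero entry (the shape s_i) per row, so all
# GLS pieces reduce to grouped sums (over precomputed index vectors in
# `ctx`) and a G x G solve.
profile_nll2 <- function(model, k, Ti, lambda, ctx) {
  s <- sigmoid_shape(model, ctx$t, k, Ti[ctx$gi])
  n <- ctx$n; G <- ctx$G; R <- ctx$R
  s2 <- s^2
  d_r <- as.numeric(Matrix::crossprod(ctx$Mr, s2))  # Z'Z diagonal
  m_inv <- 1 / (1 / lambda + d_r)
  B <- matrix(as.numeric(Matrix::crossprod(ctx$Mc, s2)), R, G)  # Z'X
  XtVX <- diag(as.numeric(Matrix::crossprod(ctx$Mg, s2)), G) - t(B) %*% (B * m_inv)
  sy <- s * ctx$y
  Zty <- as.numeric(Matrix::crossprod(ctx$Mr, sy))
  Xty <- as.numeric(Matrix::crossprod(ctx$Mg, sy)) - as.numeric(t(B) %*% (m_inv * Zty))
  A <- tryCatch(as.numeric(solve(XtVX, Xty)),
                error = function(e) rep(NA_real_, G))
  if (anyNA(A)) return(list(nll2 = 1e10, A = rep(0, G), sigma2 = NA_real_))
  res <- ctx$y - s * A[ctx$gi]
  Ztr <- as.numeric(Matrix::crossprod(ctx$Mr, s * res))
  q <- sum(res^2) - sum(m_inv * Ztr^2)
  sigma2 <- max(q / n, 1e-12)
  nll2 <- n * log(2 * pi * sigma2) + sum(log1p(lambda * d_r)) + q / sigma2
  list(nll2 = nll2, A = A, sigma2 = sigma2)
}

# -2 log marginal likelihood at fully specified parameters.
full_nll2 <- function(model, A, k, Ti, lambda, sigma2, ctx) {
  s <- sigmoid_shape(model, ctx$t, k, Ti[ctx$gi])
  res <- ctx$y - s * A[ctx$gi]
  d_r <- as.numeric(Matrix::crossprod(ctx$Mr, s^2))
  m_inv <- 1 / (1 / lambda + d_r)
  Ztr <- as.numeric(Matrix::crossprod(ctx$Mr, s * res))
  q <- sum(res^2) - sum(m_inv * Ztr^2)
  ctx$n * log(2 * pi * sigma2) + sum(log1p(lambda * d_r)) + q / sigma2
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s model for '%s': %d genotypes, %d obs\n",
              x$model, x$trait, nrow(x$coefficients), x$n_obs))
  cat(sprintf("  shared k = %.4f (SE %.4f) 1/day | sigma_u = %.4f | sigma = %.4f%s\n",
              x$k, x$k_se, x$sigma_u, x$sigma,
              if (x$singular) " [random effect pinned at 0]" else ""))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, BIC = %.2f\n", x$loglik, x$AIC, x$BIC))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One row per estimated fixed effect: `term`, `genotype`,
#'   `estimate`, `std.error`.
#' @export
tidy.growth_fit <- function(x, ...) {
  co <- x$coefficients
  dplyr::bind_rows(
    tibble::tibble(term = "A", genotype = co$genotype,
                   estimate = co$A, std.error = co$A_se),
    tibble::tibble(term = "Ti", genotype = co$genotype,
                   estimate = co$Ti, std.error = co$Ti_se),
    tibble::tibble(term = "k", genotype = NA_character_,
                   estimate = x$k, std.error = x$k_se))
}

#' @rdname tidy.growth_fit
#' @param x A `growth_fit`.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$AIC, BIC = x$BIC,
                 sigma = x$sigma, sigma_u = x$sigma_u, n_obs = x$n_obs,
                 n_params = x$n_params, converged = x$converged)
}

#' Predict genotype mean trajectories
#'
#' @param object A `growth_fit`.
#' @param newdata Tibble with `genotype` and `dap` columns; defaults to a
#'   dense grid over the fitted time range.
#' @param ... Unused.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- tidyr::expand_grid(
      genotype = object$coefficients$genotype,
      dap = seq(min(object$data$dap), max(object$data$dap), length.out = 100))
  }
  co <- object$coefficients
  i <- match(newdata$genotype, co$genotype)
  newdata$.pred <- sigmoid(object$model, newdata$dap, co$A[i], object$k, co$Ti[i])
  newdata
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  curves <- predict(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dap, y = .data$value,
                               colour = .data$genotype)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$.pred), linewidth = 0.8) +
    ggplot2::labs(x = "days after planting", y = object$trait,
                  colour = "genotype")
}

#' Rank growth models by information criteria
#'
#' Orders fits of the same data by AIC (ties broken by BIC) and reports
#' AIC/BIC differences to the best model. Likelihood-ratio p-values are
#' only computed for nested pairs (different parameter counts); the three
#' fixed-shape sigmoid families all have the same parameter count and are
#' flagged non-nested.
#'
#' @param fits List of `growth_fit` objects on identical data.
#' @return Tibble ranked best-first with `model`, `logLik`, `AIC`, `BIC`,
#'   `dAIC`, `dBIC`, `nested_vs_best`, `lrt_p`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "growth_fit")))
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) stop("fits were not computed on identical data")
  tb <- dplyr::bind_rows(purrr::map(fits, glance))
  tb <- tb[order(tb$AIC, tb$BIC), ]
  tb$dAIC <- tb$AIC - tb$AIC[1]
  tb$dBIC <- tb$BIC - tb$BIC[1]
  tb$nested_vs_best <- tb$n_params != tb$n_params[1]
  tb$lrt_p <- NA_real_
  if (nrow(tb) > 1) {
    for (i in 2:nrow(tb)) {
      if (tb$nested_vs_best[i]) {
        df <- abs(tb$n_params[i] - tb$n_params[1])
        lr <- 2 * abs(tb$logLik[1] - tb$logLik[i])
        tb$lrt_p[i] <- stats::pchisq(lr, df, lower.tail = FALSE)
      }
    }
  }
  dplyr::select(tb, "model", "logLik", "AIC", "BIC", "dAIC", "dBIC",
                "nested_vs_best", "lrt_p")
}

#' Pairwise genotype contrasts on growth parameters
#'
#' All pairwise Wald z-tests on the genotype-specific asymptote (`A`) or
#' inflection time (`Ti`), with multiplicity control by Bonferroni
#' (default) or a Tukey studentized-range adjustment, plus a compact letter
#' display at `alpha`: genotypes sharing no letter differ significantly.
#'
#' @param fit A `growth_fit` with a valid variance-covariance matrix.
#' @param parameter `"A"` or `"Ti"`.
#' @param correction `"bonferroni"` or `"tukey"`.
#' @param alpha Significance level for the letter display.
#' @return List with `contrasts` (pairwise table) and `letters` (per
#'   genotype, ordered by estimate).
#' @export
posthoc_contrasts <- function(fit, parameter = c("A", "Ti"),
                              correction = c("bonferroni", "tukey"),
                              alpha = 0.05) {
  parameter <- match.arg(parameter)
  correction <- match.arg(correction)
  if (is.null(fit$vcov)) stop("fit carries no standard errors")
  co <- fit$coefficients
  G <- nrow(co)
  if (G < 2) stop("need at least 2 genotypes")
  est <- if (parameter == "A") co$A else co$Ti
  names(est) <- co$genotype
  vn <- paste0(parameter, ".", co$genotype)
  V <- fit$vcov[vn, vn]
  pairs <- utils::combn(G, 2)
  diff <- est[pairs[1, ]] - est[pairs[2, ]]
  se <- sqrt(pmax(diag(V)[pairs[1, ]] + diag(V)[pairs[2, ]] -
                    2 * V[cbind(pairs[1, ], pairs[2, ])], 1e-12))
  z <- diff / se
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- switch(correction,
    bonferroni = p.adjust(p_raw, "bonferroni"),
    tukey = ptukey(abs(z) * sqrt(2), nmeans = G,
                   df = max(fit$n_obs - fit$n_params, 1), lower.tail = FALSE))
  contrasts <- tibble::tibble(
    genotype_1 = co$genotype[pairs[1, ]],
    genotype_2 = co$genotype[pairs[2, ]],
    estimate = unname(diff), std.error = unname(se), statistic = unname(z),
    p.value = unname(p_raw), adj.p.value = unname(p_adj))
  ord <- order(est)
  sig <- matrix(FALSE, G, G)
  sig[t(pairs)] <- p_adj < alpha
  sig <- sig | t(sig)
  letters_tbl <- tibble::tibble(
    genotype = co$genotype[ord],
    estimate = unname(est[ord]),
    letters = cld_letters(sig[ord, ord, drop = FALSE]))
  list(contrasts = contrasts, letters = letters_tbl,
       parameter = parameter, correction = correction, alpha = alpha)
}

# Compact letter display via the insert-and-absorb algorithm: maintain
# letter groups (sets of mutually non-different items); each significant
# pair splits every group containing both; redundant subset groups are
# absorbed.
cld_letters <- function(sig) {
  n <- nrow(sig)
  groups <- list(rep(TRUE, n))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    new_groups <- list()
    for (grp in groups) {
      if (grp[i] && grp[j]) {
        g1 <- grp; g1[i] <- FALSE
        g2 <- grp; g2[j] <- FALSE
        new_groups <- c(new_groups, list(g1, g2))
      } else new_groups <- c(new_groups, list(grp))
    }
    # absorb: drop duplicates and any group strictly contained in another
    new_groups <- unique(new_groups)
    keep <- vapply(seq_along(new_groups), function(a) {
      !any(vapply(seq_along(new_groups), function(b) {
        b != a && all(new_groups[[a]] <= new_groups[[b]]) &&
          any(new_groups[[b]] & !new_groups[[a]])
      }, logical(1)))
    }, logical(1))
    groups <- new_groups[keep]
  }
  # order groups by their first member so letters read low-to-high
  ord <- order(vapply(groups, function(g) which(g)[1], numeric(1)))
  groups <- groups[ord]
  out <- character(n)
  for (gi in seq_along(groups)) {
    mem <- groups[[gi]]
    out[mem] <- paste0(out[mem], letters[gi])
  }
  out
}

#' Per-genotype parameter table with significance letters
#'
#' The customary publication layout: shared growth rate, asymptote and
#' inflection-time estimates with standard errors and compact letter
#' displays from [posthoc_contrasts()].
#'
#' @param fit A `growth_fit`.
#' @param correction Multiplicity correction for the letters.
#' @export
genotype_parameter_table <- function(fit, correction = "bonferroni") {
  la <- posthoc_contrasts(fit, "A", correction)$letters
  lt <- posthoc_contrasts(fit, "Ti", correction)$letters
  co <- fit$coefficients
  tibble::tibble(
    genotype = co$genotype, k = fit$k,
    A = co$A, A_se = co$A_se,
    A_letters = la$letters[match(co$genotype, la$genotype)],
    Ti = co$Ti, Ti_se = co$Ti_se,
    Ti_letters = lt$letters[match(co$genotype, lt$genotype)]) |>
    dplyr::arrange(.data$A)
}
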
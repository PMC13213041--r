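#' Assemble the region-by-gene table for path modelling
#'
#' Turns regional similarity results into the observation table a path model
#' is fitted to: rows are regions, columns are genes, values are the regional
#' Spearman similarity scores. Scores whose permutation p-value is at or
#' above `p_threshold` are treated as missing (insufficient similarity to
#' the signature), and regions with any missing retained gene are dropped
#' (listwise deletion), with counts logged in the `retention` attribute.
#'
#' @param similarity_results A regional-scope [similarity_table()].
#' @param genes Genes to include (default: all present).
#' @param p_threshold Retention filter: keep scores with `p <` this value.
#'   The deliberately lenient default 0.5 keeps enough regions to fit while
#'   discarding clearly unrelated scores.
#' @return A `sem_table` tibble: `region` column then one column per gene,
#'   no missing cells; attribute `retention` records per-gene filtered
#'   counts and dropped regions.
#' @export
assemble_sem_table <- function(similarity_results, genes = NULL,
                               p_threshold = 0.5) {
  res <- similarity_results[startsWith(similarity_results$scope, "region:"), ]
  if (!nrow(res)) stop("no regional-scope similarity results", call. = FALSE)
  if (is.null(genes)) genes <- unique(res$gene)
  missing_genes <- setdiff(genes, res$gene)
  if (length(missing_genes)) {
    stop("similarity results lack gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  res <- res[res$gene %in% genes, c("gene", "scope", "rho", "p")]
  res$rho[!(res$p < p_threshold) | is.na(res$p)] <- NA_real_
  wide <- tidyr::pivot_wider(res[, c("gene", "scope", "rho")],
                             names_from = "gene", values_from = "rho")
  names(wide)[names(wide) == "scope"] <- "region"
  complete <- stats::complete.cases(wide[, genes, drop = FALSE])
  retention <- list(
    filtered_per_gene = vapply(genes, function(g) {
      sum(is.na(wide[[g]]))
    }, integer(1)),
    regions_total = nrow(wide),
    regions_kept = sum(complete),
    p_threshold = p_threshold)
  out <- wide[complete, c("region", genes)]
  if (nrow(out) < length(genes) + 1) {
    stop("only ", nrow(out), " regions survive the p < ", p_threshold,
         " filter; need at least ", length(genes) + 1, call. = FALSE)
  }
  attr(out, "retention") <- retention
  class(out) <- c("sem_table", class(out))
  out
}

# --- ML path-analysis machinery ------------------------------------------

# parameter bookkeeping: coefficients (free), log residual/exogenous
# variances (free), declared exogenous covariances (free)
sem_params <- function(model) {
  coef_keys <- paste(model$edges$parent, "->", model$edges$child)
  var_keys <- paste0("var: ", model$variables)
  cov_keys <- if (nrow(model$covs)) {
    paste0("cov: ", model$covs$a, " ~~ ", model$covs$b)
  } else character(0)
  list(coef = coef_keys, vars = var_keys, covs = cov_keys,
       n_free = length(coef_keys) + length(var_keys) + length(cov_keys))
}

# implied covariance from a raw parameter vector
sem_sigma <- function(theta, model, pk) {
  p <- length(model$variables)
  vars <- model$variables
  nb <- length(pk$coef)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  if (nb) {
    B[cbind(match(model$edges$child, vars),
            match(model$edges$parent, vars))] <- theta[seq_len(nb)]
  }
  Psi <- diag(exp(theta[nb + seq_len(p)]), p)
  dimnames(Psi) <- list(vars, vars)
  if (length(pk$covs)) {
    cv <- theta[nb + p + seq_along(pk$covs)]
    for (r in seq_len(nrow(model$covs))) {
      Psi[model$covs$a[r], model$covs$b[r]] <- cv[r]
      Psi[model$covs$b[r], model$covs$a[r]] <- cv[r]
    }
  }
  IB <- solve(diag(p) - B)
  IB %*% Psi %*% t(IB)
}

# Wishart ML discrepancy; large finite penalty off the PD cone
sem_fml <- function(theta, model, pk, S, logdetS) {
  Sigma <- sem_sigma(theta, model, pk)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logdet - logdetS + tr - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

# equation-wise OLS starting values computed from S (exact ML for recursive
# models with unconstrained exogenous covariances; an excellent start
# otherwise)
sem_start <- function(model, pk, S) {
  vars <- model$variables
  theta <- numeric(pk$n_free)
  nb <- length(pk$coef)
  resid_var <- diag(S)[vars]
  if (nb) {
    for (v in unique(model$edges$child)) {
      parents <- model$edges$parent[model$edges$child == v]
      b <- solve(S[parents, parents, drop = FALSE], S[parents, v])
      rows <- which(model$edges$child == v)
      theta[rows[match(parents, model$edges$parent[rows])]] <- b
      resid_var[v] <- max(S[v, v] - sum(b * S[parents, v]), 1e-4)
    }
  }
  theta[nb + seq_along(vars)] <- log(resid_var)
  if (length(pk$covs)) {
    theta[nb + length(vars) + seq_along(pk$covs)] <-
      S[cbind(model$covs$a, model$covs$b)]
  }
  theta
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the Wishart maximum-likelihood discrepancy
#' `F_ML = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p` over the free parameters
#' (path coefficients, residual variances, exogenous variances and any
#' declared exogenous covariances), with `chi2 = (N - 1) * F_ML` at the
#' optimum. Standard errors come from the inverse expected information
#' (numerical Hessian of the discrepancy); per-path p-values are two-sided
#' normal. A covariance matrix may be passed instead of data for exact-fit
#' testing. Fit indices are computed against the independence baseline
#' (free variances, zero covariances).
#'
#' @param model A [path_model()].
#' @param data A `sem_table` / data frame of observations (rows =
#'   observations, columns including the model variables), or a covariance
#'   matrix (then `n` is required).
#' @param n Sample size when `data` is a covariance matrix.
#' @param tol Convergence tolerance on the discrepancy.
#' @param max_iter Optimizer iteration cap.
#' @param n_starts Additional seeded random starts tried on non-convergence.
#' @return A `sem_fit`: estimates tibble (`term`, `estimate`, `se`, `z`,
#'   `p`), `chi2`, `df`, `n`, baseline `chi2_baseline` / `df_baseline`,
#'   `cfi`, `tli_raw`, `tli`, `rmsea`, `converged`. Use [tidy()] /
#'   [glance()].
#' @examples
#' m <- path_model(c("X -> Y", "Y -> Z"))
#' S <- simulate_path_data(m, c("X -> Y" = .5, "Y -> Z" = -.3),
#'                         residual_sds = 1, population = TRUE)
#' fit <- fit_path_model(m, S, n = 100)
#' fit$chi2   # ~ 0: exact fit to the model-implied covariance
#' @export
fit_path_model <- function(model, data, n = NULL, tol = 1e-10,
                           max_iter = 10000, n_starts = 3) {
  stopifnot(inherits(model, "path_model"))
  if (is.matrix(data) && nrow(data) == ncol(data) &&
      !is.null(rownames(data)) && setequal(rownames(data), colnames(data)) &&
      all(model$variables %in% rownames(data)) &&
      isTRUE(all.equal(data, t(data), tolerance = 1e-8))) {
    if (is.null(n)) stop("`n` required with a covariance matrix",
                         call. = FALSE)
    S <- data[model$variables, model$variables]
  } else {
    df <- as.data.frame(data)
    miss <- setdiff(model$variables, names(df))
    if (length(miss)) stop("data lacks variable(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    df <- df[, model$variables, drop = FALSE]
    n <- nrow(df)
    if (n < length(model$variables) + 1) {
      stop("need at least variables + 1 observations (have ", n, ")",
           call. = FALSE)
    }
    S <- stats::cov(df)
  }
  p <- length(model$variables)
  pk <- sem_params(model)
  df_model <- p * (p + 1) / 2 - pk$n_free
  if (df_model < 0) stop("model has more free parameters than moments",
                         call. = FALSE)
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  obj <- function(th) sem_fml(th, model, pk, S, logdetS)

  run_opt <- function(start) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
    # polish with Nelder-Mead to escape flat BFGS terminations
    o2 <- stats::optim(o$par, obj, method = "BFGS",
                       control = list(maxit = max_iter, reltol = 1e-14))
    if (o2$value < o$value) o2 else o
  }
  opt <- run_opt(sem_start(model, pk, S))
  converged <- opt$convergence == 0
  if (!converged) {
    for (s in seq_len(n_starts)) {
      alt <- with_seed(1000 + s,
                       sem_start(model, pk, S) +
                         stats::rnorm(pk$n_free, sd = 0.3))
      o <- run_opt(alt)
      if (o$value < opt$value) opt <- o
      if (o$convergence == 0) { converged <- TRUE; break }
    }
  }
  if (!converged && opt$value >= 1e9) {
    stop("path-model fit failed: implied covariance not positive definite ",
         "from any start (F = ", format(opt$value), ")", call. = FALSE)
  }
  fml <- max(opt$value, 0)
  chi2 <- (n - 1) * fml

  # standard errors: inverse expected information, vcov = 2/(N-1) * H^-1
  H <- pracma::hessian(obj, opt$par)
  vc <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, pk$n_free) else {
    dg <- diag(vc)
    ifelse(dg > 0, sqrt(dg), NA_real_)
  }
  nb <- length(pk$coef)
  est <- opt$par
  est_nat <- est
  se_nat <- se
  vidx <- nb + seq_len(p)
  est_nat[vidx] <- exp(est[vidx])            # back to variance scale
  se_nat[vidx] <- se[vidx] * est_nat[vidx]   # delta method
  terms <- c(pk$coef, pk$vars, pk$covs)
  zstat <- est_nat / se_nat
  estimates <- tibble::tibble(
    term = terms,
    type = c(rep("coefficient", nb), rep("variance", p),
             rep("covariance", length(pk$covs))),
    estimate = est_nat, se = se_nat, z = zstat,
    p = 2 * stats::pnorm(-abs(zstat)))

  # independence baseline (closed form): Sigma_B = diag(diag(S))
  f_base <- sum(log(diag(S))) - logdetS
  chi2_b <- (n - 1) * max(f_base, 0)
  df_b <- p * (p - 1) / 2

  fit <- structure(list(model = model, estimates = estimates,
                        chi2 = chi2, df = df_model, n = n, f_ml = fml,
                        chi2_baseline = chi2_b, df_baseline = df_b,
                        S = S, converged = converged,
                        optim_value = opt$value),
                   class = "sem_fit")
  idx <- fit_indices(fit)
  fit$cfi <- idx$cfi; fit$tli_raw <- idx$tli_raw
  fit$tli <- idx$tli; fit$rmsea <- idx$rmsea
  fit
}

#' Fit indices from model and baseline chi-squares
#'
#' `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_B - df_B, chi2_M - df_M, 0)`;
#' `TLI_raw = ((chi2_B / df_B) - (chi2_M / df_M)) / ((chi2_B / df_B) - 1)`
#' with the reported TLI truncated at 1; `RMSEA = sqrt(max(chi2_M - df_M, 0)
#' / (df_M * (N - 1)))`. When the model chi-square does not exceed its
#' degrees of freedom, CFI and truncated TLI are 1 and RMSEA is 0 (the
#' exact-fit limit). With `df_M = 0` TLI and RMSEA are undefined (`NA`).
#'
#' @param fit A `sem_fit`, or a list with `chi2`, `df`, `n`.
#' @param baseline Optional independence-model fit (defaults to the baseline
#'   stored in `fit`).
#' @return Tibble row: `cfi`, `tli_raw`, `tli`, `rmsea`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  c2m <- fit$chi2; dfm <- fit$df; n <- fit$n
  if (is.null(baseline)) {
    c2b <- fit$chi2_baseline; dfb <- fit$df_baseline
  } else {
    c2b <- baseline$chi2; dfb <- baseline$df
  }
  num <- max(c2m - dfm, 0)
  den <- max(c2b - dfb, c2m - dfm, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (dfm == 0) {
    tli_raw <- NA_real_
    rmsea <- NA_real_
  } else {
    rb <- c2b / dfb
    tli_raw <- (rb - c2m / dfm) / (rb - 1)
    rmsea <- sqrt(max(c2m - dfm, 0) / (dfm * (n - 1)))
  }
  tibble::tibble(cfi = cfi, tli_raw = tli_raw,
                 tli = if (is.na(tli_raw)) NA_real_ else min(tli_raw, 1),
                 rmsea = rmsea)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %d variables, %d edges | chi2 = %.4g on %d df (N = %d)\n",
              length(x$model$variables), nrow(x$model$edges), x$chi2, x$df,
              x$n))
  cat(sprintf("  CFI = %.3f, TLI = %.3f, RMSEA = %.3f%s\n",
              x$cfi, x$tli, x$rmsea,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @rdname fit_path_model
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) x$estimates

#' @rdname fit_path_model
#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, n = x$n, cfi = x$cfi,
                 tli_raw = x$tli_raw, tli = x$tli, rmsea = x$rmsea,
                 chi2_baseline = x$chi2_baseline,
                 df_baseline = x$df_baseline, converged = x$converged)
}
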
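#' Specify a directed path model
#'
#' A path model over observed variables only: directed edges carry linear
#' coefficients, exogenous variables (no parents) get free variances, and
#' exogenous covariances are fixed at zero unless declared in `covs`. The
#' graph must be acyclic.
#'
#' @param edges Character vector of `"parent -> child"` strings, or a
#'   two-column data frame with columns `parent`, `child`.
#' @param covs Optional character vector of `"a ~~ b"` strings declaring free
#'   exogenous covariances.
#' @return A `path_model`: list with `variables`, `edges` (tibble
#'   parent/child), `covs` (tibble a/b), `exogenous`, `order` (a topological
#'   order).
#' @examples
#' m <- path_model(c("X -> Y", "Y -> Z"))
#' m$exogenous
#' @export
path_model <- function(edges, covs = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(trimws(edges), "\\s*->\\s*")
    bad <- lengths(parts) != 2
    if (any(bad)) {
      stop("malformed edge: ", edges[bad][1], call. = FALSE)
    }
    edges <- tibble::tibble(parent = vapply(parts, `[`, "", 1),
                            child = vapply(parts, `[`, "", 2))
  } else {
    edges <- tibble::as_tibble(edges)[, c("parent", "child")]
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    stop("duplicate edges in model", call. = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  vars <- unique(c(edges$parent, edges$child))
  ord <- topo_order(vars, edges)
  if (is.null(ord)) stop("path model graph is cyclic", call. = FALSE)
  cov_tb <- tibble::tibble(a = character(), b = character())
  if (!is.null(covs) && length(covs)) {
    cp <- strsplit(trimws(sub("^cov:\\s*", "", covs)), "\\s*~~\\s*")
    cov_tb <- tibble::tibble(a = vapply(cp, `[`, "", 1),
                             b = vapply(cp, `[`, "", 2))
    if (!all(c(cov_tb$a, cov_tb$b) %in% vars)) {
      stop("covariance declared for unknown variable", call. = FALSE)
    }
  }
  exo <- setdiff(vars, unique(edges$child))
  structure(list(variables = vars, edges = edges, covs = cov_tb,
                 exogenous = exo, order = ord),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model>", length(x$variables), "variables,",
      nrow(x$edges), "directed edges,", nrow(x$covs), "free covariances\n")
  cat(paste0("  ", x$edges$parent, " -> ", x$edges$child, collapse = "\n"),
      "\n")
  invisible(x)
}

# Kahn topological sort; NULL if cyclic
topo_order <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tb <- table(edges$child)
  indeg[names(tb)] <- as.integer(tb)
  queue <- vars[indeg == 0]
  out <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- edges$child[edges$parent == v]
    for (kid in kids) {
      indeg2[kid] <- indeg2[kid] - 1L
      if (indeg2[kid] == 0L) queue <- c(queue, kid)
    }
  }
  if (length(out) != length(vars)) NULL else out
}

#' Read / write plain-text path-model files
#'
#' Model files hold one `parent -> child` line per edge plus optional
#' `cov: a ~~ b` lines; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return [read_path_model()] returns a `path_model`.
#' @export
read_path_model <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  covs <- lines[startsWith(lines, "cov:")]
  edges <- lines[!startsWith(lines, "cov:")]
  path_model(edges, covs = if (length(covs)) covs else NULL)
}

#' @rdname read_path_model
#' @param model A `path_model`.
#' @export
write_path_model <- function(model, path) {
  lines <- paste(model$edges$parent, "->", model$edges$child)
  if (nrow(model$covs)) {
    lines <- c(lines, paste0("cov: ", model$covs$a, " ~~ ", model$covs$b))
  }
  writeLines(lines, path)
  invisible(path)
}

# model-implied covariance for given coefficients / residual variances.
# B[child, parent] = coefficient; Psi = residual (co)variances.
implied_covariance <- function(model, coefficients, residual_sds) {
  p <- length(model$variables)
  vars <- model$variables
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (r in seq_len(nrow(model$edges))) {
    B[model$edges$child[r], model$edges$parent[r]] <-
      coefficients[[paste(model$edges$parent[r], "->",
                          model$edges$child[r])]]
  }
  Psi <- diag(residual_sds[vars]^2, p)
  dimnames(Psi) <- list(vars, vars)
  if (nrow(model$covs)) {
    for (r in seq_len(nrow(model$covs))) {
      stop("population covariance with free exogenous covariances requires ",
           "explicit values; not supported by the generator", call. = FALSE)
    }
  }
  IB <- solve(diag(p) - B)
  S <- IB %*% Psi %*% t(IB)
  dimnames(S) <- list(vars, vars)
  S
}

#' Simulate observations from a linear path model
#'
#' Generates each variable in topological order as the coefficient-weighted
#' sum of its parents plus Gaussian noise. Exogenous variables are pure
#' noise with standard deviation taken from `residual_sds`. With
#' `population = TRUE` the exact model-implied covariance matrix is returned
#' instead of samples, which is the input for exact-fit tests.
#'
#' @param model A [path_model()].
#' @param coefficients Named numeric vector keyed `"parent -> child"`; one
#'   entry per edge (missing entries are an error).
#' @param residual_sds Named numeric vector of residual standard deviations,
#'   one per variable (a single value is recycled). All must be > 0.
#' @param n_obs Number of rows to simulate.
#' @param seed Integer seed.
#' @param population If `TRUE`, return the model-implied covariance matrix.
#' @return A tibble with `n_obs` rows and one column per variable, or a
#'   covariance matrix when `population = TRUE`.
#' @examples
#' m <- path_model(c("X -> Y", "Y -> Z"))
#' S <- simulate_path_data(m, c("X -> Y" = 0.5, "Y -> Z" = -0.3),
#'                         residual_sds = 1, population = TRUE)
#' S["X", "Z"]  # = 0.5 * -0.3
#' @export
simulate_path_data <- function(model, coefficients, residual_sds = 1,
                               n_obs = 100, seed = 1, population = FALSE) {
  stopifnot(inherits(model, "path_model"))
  keys <- paste(model$edges$parent, "->", model$edges$child)
  missing <- setdiff(keys, names(coefficients))
  if (length(missing)) {
    stop("missing coefficient for edge: ", missing[1], call. = FALSE)
  }
  if (length(residual_sds) == 1L && is.null(names(residual_sds))) {
    residual_sds <- stats::setNames(rep(residual_sds,
                                        length(model$variables)),
                                    model$variables)
  }
  if (any(residual_sds <= 0)) {
    stop("`residual_sds` must be > 0", call. = FALSE)
  }
  if (population) {
    return(implied_covariance(model, as.list(coefficients), residual_sds))
  }
  dat <- with_seed(seed, {
    out <- matrix(0, n_obs, length(model$variables),
                  dimnames = list(NULL, model$variables))
    for (v in model$order) {
      eps <- stats::rnorm(n_obs, sd = residual_sds[[v]])
      parents <- model$edges$parent[model$edges$child == v]
      mu <- 0
      for (p in parents) {
        mu <- mu + coefficients[[paste(p, "->", v)]] * out[, p]
      }
      out[, v] <- mu + eps
    }
    out
  })
  tibble::as_tibble(as.data.frame(dat))
}
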
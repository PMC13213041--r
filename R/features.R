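#' Dual regression of a subject 4-D volume onto a spatial basis
#'
#' Two-stage least squares. Stage 1 regresses every timepoint's masked image
#' on the K basis maps, giving subject time courses; stage 2 regresses every
#' voxel's time series on the variance-normalized time courses, giving
#' subject-specific spatial maps.
#'
#' @param subject_4d A 4-D array (x, y, z, t) on `ic_basis$grid`, or a T x V
#'   matrix of in-mask values.
#' @param ic_basis An [make_ic_basis()] object.
#' @param max_condition Reject stage-1 designs with a larger condition
#'   number.
#' @return List with `timecourses` (T x K), `subject_maps` (K x V), and
#'   `degenerate` (TRUE when the input has zero variance, in which case the
#'   time courses are all zero).
#' @export
dual_regression <- function(subject_4d, ic_basis, max_condition = 1e8) {
  stopifnot(inherits(ic_basis, "ic_basis"))
  grid <- ic_basis$grid
  V <- nrow(ic_basis$maps)
  if (is.array(subject_4d) && length(dim(subject_4d)) == 4L) {
    if (!all(dim(subject_4d)[1:3] == grid$shape)) {
      stop("subject volume grid does not match the basis grid", call. = FALSE)
    }
    tdim <- dim(subject_4d)[4]
    X <- t(apply(subject_4d, 4, function(v) v[grid$mask]))
    dim(X) <- c(tdim, V)
  } else {
    X <- as.matrix(subject_4d)
    if (ncol(X) != V) {
      stop("matrix input must be T x V for V = ", V, " mask voxels",
           call. = FALSE)
    }
  }
  D <- ic_basis$maps                       # V x K design
  cn <- kappa(D, exact = TRUE)
  if (!is.finite(cn) || cn > max_condition) {
    stop("basis maps are rank deficient within the mask (condition number ",
         format(cn, digits = 3), ")", call. = FALSE)
  }
  degenerate <- all(abs(X - mean(X)) < .Machine$double.eps * 100)
  if (degenerate) {
    tc <- matrix(0, nrow(X), ncol(D))
    maps <- matrix(0, ncol(D), V)
    return(list(timecourses = tc, subject_maps = maps, degenerate = TRUE))
  }
  # stage 1: image_t ~ basis maps
  tc <- t(solve(crossprod(D), crossprod(D, t(X))))   # T x K
  # stage 2: voxel series ~ variance-normalized time courses
  sds <- apply(tc, 2, stats::sd)
  sds[sds == 0] <- 1
  tcn <- sweep(tc, 2, sds, "/")
  maps <- solve(crossprod(tcn), crossprod(tcn, X))    # K x V
  list(timecourses = tc, subject_maps = maps, degenerate = FALSE)
}

#' Functional connectivity matrix from component time courses
#'
#' Pearson correlation between each pair of included component time courses.
#'
#' @param timecourses T x K numeric matrix (T >= 3).
#' @param included_ids Component indices to retain (default all).
#' @return K' x K' correlation matrix (unit diagonal) over the included
#'   components, with dimnames `IC<i>`.
#' @export
fc_from_timeseries <- function(timecourses, included_ids = NULL) {
  tc <- as.matrix(timecourses)
  if (nrow(tc) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (is.null(included_ids)) included_ids <- seq_len(ncol(tc))
  included_ids <- sort(as.integer(included_ids))
  if (any(included_ids < 1 | included_ids > ncol(tc))) {
    stop("`included_ids` outside available components", call. = FALSE)
  }
  sub <- tc[, included_ids, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance component: IC",
         included_ids[which(sds == 0)[1]], call. = FALSE)
  }
  fc <- stats::cor(sub)
  diag(fc) <- 1
  dimnames(fc) <- list(paste0("IC", included_ids), paste0("IC", included_ids))
  fc
}

#' Build the subjects-by-edges connectivity feature table
#'
#' One row per subject, one column per retained component pair (upper
#' triangle, lexicographic `(i, j)` order with `i < j` over the sorted
#' inclusion list). This is the classifier's input; the edge-to-component
#' mapping travels with the table as the `edge_map` attribute.
#'
#' @param cohort A [simulate_cohort()] object, or a named list of T x K time
#'   series plus a `labels` vector.
#' @param ic_inclusion_list Component indices retained for analysis (encodes
#'   manual exclusion of artifact components).
#' @param labels Optional label vector when `cohort` is a bare list.
#' @return A tibble with columns `subject_id`, `label`, then one numeric
#'   column per edge, attribute `edge_map` (tibble: edge, i, j). Subjects
#'   whose FC computation fails are dropped with a warning, never imputed.
#' @export
build_feature_table <- function(cohort, ic_inclusion_list = NULL,
                                labels = NULL) {
  if (inherits(cohort, "cohort")) {
    ts_list <- cohort$timeseries
    labels <- cohort$subjects$label
    ids <- cohort$subjects$subject_id
  } else {
    ts_list <- cohort
    ids <- names(ts_list) %||% sprintf("sub-%03d", seq_along(ts_list))
    if (is.null(labels)) stop("`labels` required for list input",
                              call. = FALSE)
  }
  k <- ncol(ts_list[[1]])
  if (is.null(ic_inclusion_list)) ic_inclusion_list <- seq_len(k)
  if (!length(ic_inclusion_list)) {
    stop("inclusion list is empty", call. = FALSE)
  }
  emap <- upper_pairs(ic_inclusion_list)
  rows <- vector("list", length(ts_list))
  failed <- character(0)
  for (s in seq_along(ts_list)) {
    fc <- tryCatch(fc_from_timeseries(ts_list[[s]], ic_inclusion_list),
                   error = function(e) e)
    if (inherits(fc, "error")) {
      failed <- c(failed, paste0(ids[s], " (", conditionMessage(fc), ")"))
      next
    }
    vals <- fc[cbind(match(paste0("IC", emap$i), rownames(fc)),
                     match(paste0("IC", emap$j), colnames(fc)))]
    rows[[s]] <- c(vals)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (length(failed)) {
    warning("excluded ", length(failed), " subject(s) with failed FC: ",
            paste(failed, collapse = "; "), call. = FALSE)
  }
  mat <- do.call(rbind, rows[keep])
  colnames(mat) <- emap$edge
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids[keep], label = labels[keep]),
    tibble::as_tibble(as.data.frame(mat)))
  attr(out, "edge_map") <- emap
  out
}

#' Edge-to-component map of a feature table
#'
#' @param features A table built by [build_feature_table()].
#' @return Tibble with columns `edge`, `i`, `j`.
#' @export
edge_map <- function(features) {
  em <- attr(features, "edge_map")
  if (is.null(em)) {
    # reconstruct from column names of the form ICi_ICj
    cols <- setdiff(names(features), c("subject_id", "label"))
    ij <- regmatches(cols, regexec("^IC(\\d+)_IC(\\d+)$", cols))
    if (any(lengths(ij) != 3)) stop("cannot reconstruct edge map",
                                    call. = FALSE)
    em <- tibble::tibble(edge = cols,
                         i = as.integer(vapply(ij, `[`, "", 2)),
                         j = as.integer(vapply(ij, `[`, "", 3)))
  }
  em
}
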
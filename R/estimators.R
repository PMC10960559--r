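#' @title Plug-in estimators of multivariate moments and cumulant-based
#'   connectivity
#' @description Internal numeric kernels plus the user-facing estimator
#'   functions.  All moments use the 1/T temporal-averaging convention on
#'   z-scored signals; cumulants of order three equal the corresponding
#'   moments (zero means), and the fourth-order cumulant subtracts the three
#'   pairwise-moment products.
#' @name estimators
NULL

# (1/T) * sum_t prod_j X_{idx_j}(t), idx integer rows of m (repeats allowed)
moment_kernel <- function(m, idx) {
  p <- m[idx[1L], ]
  for (j in idx[-1L]) p <- p * m[j, ]
  mean(p)
}

cum4_kernel <- function(m, i, j, k, l) {
  moment_kernel(m, c(i, j, k, l)) -
    moment_kernel(m, c(i, j)) * moment_kernel(m, c(k, l)) -
    moment_kernel(m, c(i, k)) * moment_kernel(m, c(j, l)) -
    moment_kernel(m, c(i, l)) * moment_kernel(m, c(j, k))
}

edge_raw_kernel <- function(m, e1, e2) {
  den2 <- moment_kernel(m, c(e1[1], e1[1], e1[2], e1[2])) *
    moment_kernel(m, c(e2[1], e2[1], e2[2], e2[2]))
  if (den2 <= 0)
    stop("degenerate edge: zero fourth-moment normalizer", call. = FALSE)
  moment_kernel(m, c(e1, e2)) / sqrt(den2)
}

edge_redundant_kernel <- function(m, e1, e2) {
  i <- e1[1]; j <- e1[2]; k <- e2[1]; l <- e2[2]
  mij <- moment_kernel(m, c(i, j)); mkl <- moment_kernel(m, c(k, l))
  num <- mij * mkl +
    moment_kernel(m, c(i, k)) * moment_kernel(m, c(j, l)) +
    moment_kernel(m, c(i, l)) * moment_kernel(m, c(j, k))
  den2 <- (2 * mij^2 + moment_kernel(m, c(i, i)) * moment_kernel(m, c(j, j))) *
    (2 * mkl^2 + moment_kernel(m, c(k, k)) * moment_kernel(m, c(l, l)))
  if (den2 <= 0)
    stop("degenerate edge: zero redundant-part normalizer", call. = FALSE)
  num / sqrt(den2)
}

new_cumulant_estimate <- function(order, indices, measure, value,
                                  se = NA_real_, ci = c(NA_real_, NA_real_),
                                  p_value = NA_real_) {
  structure(list(order = order, indices = as.character(indices),
                 measure = measure, value = value, se = se, ci = ci,
                 p_value = p_value),
            class = "cumulant_estimate")
}

#' @export
print.cumulant_estimate <- function(x, ...) {
  cat(sprintf("%s[%s] = %.6g", x$measure, paste(x$indices, collapse = ","),
              x$value))
  if (!is.na(x$se)) cat(sprintf("  (se %.3g)", x$se))
  if (!is.na(x$p_value)) cat(sprintf("  p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Multivariate sample moment
#'
#' The plug-in moment `(1/T) * sum_t prod_j X_{i_j}(t)` of 2--4 (possibly
#' repeated) regions of a standardized series.  Repeated indices are allowed
#' here because the edge-connectivity normalizers need them; the public
#' connectivity measures restrict to distinct regions.
#'
#' @param x a [region_ts()]; z-scored automatically (with a notice) if not
#'   already standardized.
#' @param indices 2--4 region labels (or integer positions).
#' @return the moment value (numeric scalar).
#' @export
sample_moment <- function(x, indices) {
  x <- need_standardized(x)
  if (length(indices) < 2L || length(indices) > 4L)
    stop("sample_moment takes 2 to 4 indices", call. = FALSE)
  idx <- resolve_indices(x, indices)
  moment_kernel(x$data, idx)
}

resolve_indices <- function(x, indices) {
  if (is.numeric(indices)) {
    idx <- as.integer(indices)
    if (any(idx < 1L) || any(idx > nrow(x$data)))
      stop("region index out of range", call. = FALSE)
    idx
  } else region_index(x, indices)
}

#' Pairwise (second-order) correlation
#'
#' The plug-in second-order non-redundant correlation, i.e. the Pearson
#' correlation of the z-scored signals up to the (T-1)/T factor implied by
#' the 1/T moment convention.
#'
#' @inheritParams sample_moment
#' @param i,j region labels or positions.
#' @return a `cumulant_estimate`.
#' @export
correlation2 <- function(x, i, j) {
  x <- need_standardized(x)
  idx <- resolve_indices(x, c(i, j))
  if (idx[1] == idx[2])
    warning("self-pair correlation: value is (T-1)/T, not 1", call. = FALSE)
  new_cumulant_estimate(2L, x$region_ids[idx], "correlation",
                        moment_kernel(x$data, idx))
}

#' Coskewness of three regions
#'
#' Normalized third-order cumulant `(1/T) * sum_t X_i X_j X_k` of z-scored
#' signals: the multivariate generalization of skewness and the package's
#' measure of genuine third-order connectivity (it vanishes for Gaussian
#' signals of any correlation structure).
#'
#' @inheritParams sample_moment
#' @param i,j,k distinct region labels or positions.
#' @return a `cumulant_estimate`.
#' @export
coskewness <- function(x, i, j, k) {
  x <- need_standardized(x)
  idx <- resolve_indices(x, c(i, j, k))
  if (anyDuplicated(idx))
    stop("coskewness requires three distinct regions", call. = FALSE)
  new_cumulant_estimate(3L, x$region_ids[idx], "coskewness",
                        moment_kernel(x$data, idx))
}

#' Cokurtosis of four regions
#'
#' Normalized fourth-order cumulant of z-scored signals:
#' `m_ijkl - m_ij m_kl - m_ik m_jl - m_il m_jk`, the multivariate
#' generalization of excess kurtosis.  Zero for Gaussian signals, so a
#' nonzero value indicates genuine (non-redundant) fourth-order
#' connectivity.
#'
#' @inheritParams sample_moment
#' @param i,j,k,l distinct region labels or positions.
#' @return a `cumulant_estimate`.
#' @export
cokurtosis <- function(x, i, j, k, l) {
  x <- need_standardized(x)
  idx <- resolve_indices(x, c(i, j, k, l))
  if (anyDuplicated(idx))
    stop("cokurtosis requires four distinct regions", call. = FALSE)
  new_cumulant_estimate(4L, x$region_ids[idx], "cokurtosis",
                        cum4_kernel(x$data, idx[1], idx[2], idx[3], idx[4]))
}

#' Edge functional connectivity between two region pairs
#'
#' The raw edge connectivity is the normalized fourth moment
#' `m_ijkl / sqrt(m_iijj * m_kkll)` of the two edge product signals and lies
#' in [-1, 1].  Its redundant part is the same expression with the
#' fourth-order cumulants set to zero (i.e. expressed through pairwise
#' moments only) and equals the value expected under Gaussianity; the
#' corrected edge connectivity is raw minus redundant and vanishes for
#' Gaussian signals.
#'
#' @inheritParams sample_moment
#' @param edge1,edge2 length-2 vectors of region labels/positions; the two
#'   regions within an edge must differ.
#' @param part one of `"corrected"` (default), `"raw"`, `"redundant"`.
#' @return a `cumulant_estimate` (edge measures carry 4 indices).
#' @export
edge_connectivity <- function(x, edge1, edge2,
                              part = c("corrected", "raw", "redundant")) {
  part <- match.arg(part)
  x <- need_standardized(x)
  e1 <- resolve_indices(x, edge1)
  e2 <- resolve_indices(x, edge2)
  if (length(e1) != 2L || length(e2) != 2L)
    stop("each edge must name exactly two regions", call. = FALSE)
  if (e1[1] == e1[2] || e2[1] == e2[2])
    stop("an edge must join two distinct regions", call. = FALSE)
  val <- switch(part,
    raw = edge_raw_kernel(x$data, e1, e2),
    redundant = edge_redundant_kernel(x$data, e1, e2),
    corrected = edge_raw_kernel(x$data, e1, e2) -
      edge_redundant_kernel(x$data, e1, e2))
  new_cumulant_estimate(4L, x$region_ids[c(e1, e2)],
                        paste0("edge_", part), val)
}

#' @rdname edge_connectivity
#' @export
edge_connectivity_raw <- function(x, edge1, edge2)
  edge_connectivity(x, edge1, edge2, part = "raw")

#' @rdname edge_connectivity
#' @export
edge_connectivity_redundant <- function(x, edge1, edge2)
  edge_connectivity(x, edge1, edge2, part = "redundant")

#' @rdname edge_connectivity
#' @export
edge_connectivity_corrected <- function(x, edge1, edge2)
  edge_connectivity(x, edge1, edge2, part = "corrected")

#' Collect cumulant estimates into a result table
#'
#' @param ... `cumulant_estimate` objects (or a single list of them).
#' @return a data.frame with columns `indices`, `order`, `measure`, `value`,
#'   `se`, `ci_low`, `ci_high`, `p`, sorted lexicographically by index
#'   tuple.
#' @export
estimates_table <- function(...) {
  est <- list(...)
  if (length(est) == 1L && !inherits(est[[1]], "cumulant_estimate"))
    est <- est[[1]]
  stopifnot(all(vapply(est, inherits, TRUE, "cumulant_estimate")))
  df <- data.frame(
    indices = vapply(est, function(e) paste(e$indices, collapse = ","), ""),
    order = vapply(est, function(e) as.integer(e$order), 1L),
    measure = vapply(est, function(e) e$measure, ""),
    value = vapply(est, function(e) e$value, 1),
    se = vapply(est, function(e) e$se, 1),
    ci_low = vapply(est, function(e) e$ci[1], 1),
    ci_high = vapply(est, function(e) e$ci[2], 1),
    p = vapply(est, function(e) e$p_value, 1),
    stringsAsFactors = FALSE)
  df[order(df$indices, df$measure), , drop = FALSE]
}

#' Write an estimate table as TSV
#'
#' Fixed column schema, floats at 10 significant digits, deterministic
#' (lexicographic) row order.
#'
#' @param table data.frame from [estimates_table()] (or compatible).
#' @param path output path.
#' @export
write_results <- function(table, path) {
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(table[num], function(v)
    ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}
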
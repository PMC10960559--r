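#' Multi-subject ensemble of region time series
#'
#' Bundles per-subject [region_ts()] objects sharing one region set (same
#' labels, same order).  Each subject is standardized independently before
#' estimation, so group averages are averages of per-subject dimensionless
#' estimates.
#'
#' @param subjects list of `region_ts` objects.
#' @param homologous_pairs optional two-column matrix/data.frame of region
#'   labels giving matched (e.g. left/right hemisphere) region pairs used as
#'   joint targets for fourth-order maps; pairs must be disjoint.
#' @return a `subject_ensemble`.
#' @export
subject_ensemble <- function(subjects, homologous_pairs = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 1,
            all(vapply(subjects, inherits, TRUE, "region_ts")))
  ids <- subjects[[1]]$region_ids
  for (s in subjects)
    if (!identical(s$region_ids, ids))
      stop("all subjects must share one region set in the same order",
           call. = FALSE)
  if (!is.null(homologous_pairs)) {
    homologous_pairs <- as.matrix(homologous_pairs)
    stopifnot(ncol(homologous_pairs) == 2)
    if (anyDuplicated(as.vector(homologous_pairs)))
      stop("homologous pairs must be disjoint", call. = FALSE)
    if (!all(homologous_pairs %in% ids))
      stop("homologous pairs name unknown regions", call. = FALSE)
  }
  structure(list(subjects = lapply(subjects, standardize),
                 region_ids = ids, homologous_pairs = homologous_pairs),
            class = "subject_ensemble")
}

#' @export
print.subject_ensemble <- function(x, ...) {
  cat(sprintf("subject_ensemble: %d subjects, %d regions, %s homologous pairs\n",
              length(x$subjects), length(x$region_ids),
              if (is.null(x$homologous_pairs)) "no"
              else nrow(x$homologous_pairs)))
  invisible(x)
}

# vapply over subjects returns a plain vector when there is one target;
# normalize to a subjects x targets matrix
as_subject_matrix <- function(res, targets) {
  m <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  colnames(m) <- targets
  m
}

new_connectivity_map <- function(measure, seed_pair, targets, values) {
  structure(list(measure = measure, seed = seed_pair, targets = targets,
                 values = values, group_mean = colMeans(values),
                 se = NULL, p = NULL, significant = NULL, alpha = NULL),
            class = "connectivity_map")
}

#' Seed-based coskewness map
#'
#' Fixes two seed regions and computes, per subject, the coskewness of the
#' seed pair with every other region as target; the map value is the group
#' mean across subjects.
#'
#' @param ens a [subject_ensemble()].
#' @param seed_pair two region labels.
#' @return a `connectivity_map`; threshold it with [group_threshold()].
#' @export
coskewness_map <- function(ens, seed_pair) {
  stopifnot(inherits(ens, "subject_ensemble"), length(seed_pair) == 2)
  seed_pair <- as.character(seed_pair)
  si <- region_index(ens$subjects[[1]], seed_pair)
  targets <- setdiff(ens$region_ids, seed_pair)
  ti <- match(targets, ens$region_ids)
  values <- as_subject_matrix(vapply(ens$subjects, function(s) {
    p12 <- s$data[si[1], ] * s$data[si[2], ]
    as.vector(s$data[ti, , drop = FALSE] %*% p12) / ncol(s$data)
  }, numeric(length(targets))), targets)
  new_connectivity_map("coskewness", seed_pair, targets, values)
}

#' Seed-based correlation map
#'
#' Per subject, the Pearson correlation of each target region with each of
#' the two seed regions, averaged over the two seeds, then group-averaged.
#'
#' @inheritParams coskewness_map
#' @return a `connectivity_map`.
#' @export
correlation_map <- function(ens, seed_pair) {
  stopifnot(inherits(ens, "subject_ensemble"), length(seed_pair) == 2)
  seed_pair <- as.character(seed_pair)
  si <- region_index(ens$subjects[[1]], seed_pair)
  targets <- setdiff(ens$region_ids, seed_pair)
  ti <- match(targets, ens$region_ids)
  values <- as_subject_matrix(vapply(ens$subjects, function(s) {
    m <- s$data[ti, , drop = FALSE]
    (as.vector(m %*% s$data[si[1], ]) +
       as.vector(m %*% s$data[si[2], ])) / (2 * ncol(s$data))
  }, numeric(length(targets))), targets)
  new_connectivity_map("correlation", seed_pair, targets, values)
}

#' Seed-based fourth-order map over homologous target pairs
#'
#' Fixes two seed regions and lets a target *pair* vary over the ensemble's
#' homologous region pairs (pairs containing a seed are excluded).  For
#' `measure = "cokurtosis"` the map value is the cokurtosis of
#' (seed1, seed2, t1, t2); for `measure = "edge_corrected"` it is the
#' corrected edge connectivity between edges (seed1, seed2) and (t1, t2).
#'
#' @inheritParams coskewness_map
#' @param measure `"cokurtosis"` or `"edge_corrected"`.
#' @return a `connectivity_map` whose targets are pair labels
#'   `"t1|t2"`.
#' @export
fourth_order_map <- function(ens, seed_pair,
                             measure = c("cokurtosis", "edge_corrected")) {
  measure <- match.arg(measure)
  stopifnot(inherits(ens, "subject_ensemble"), length(seed_pair) == 2)
  if (is.null(ens$homologous_pairs))
    stop("fourth_order_map needs homologous_pairs in the ensemble",
         call. = FALSE)
  seed_pair <- as.character(seed_pair)
  hp <- ens$homologous_pairs
  keep <- !(hp[, 1] %in% seed_pair | hp[, 2] %in% seed_pair)
  hp <- hp[keep, , drop = FALSE]
  if (!nrow(hp)) stop("no target pairs left after excluding seeds",
                      call. = FALSE)
  targets <- paste(hp[, 1], hp[, 2], sep = "|")
  values <- as_subject_matrix(vapply(ens$subjects, function(s) {
    vapply(seq_len(nrow(hp)), function(g) {
      if (measure == "cokurtosis")
        cum4_kernel(s$data, region_index(s, seed_pair[1]),
                    region_index(s, seed_pair[2]),
                    region_index(s, hp[g, 1]), region_index(s, hp[g, 2]))
      else
        edge_raw_kernel(s$data, region_index(s, seed_pair),
                        region_index(s, hp[g, ])) -
          edge_redundant_kernel(s$data, region_index(s, seed_pair),
                                region_index(s, hp[g, ]))
    }, 1)
  }, numeric(nrow(hp))), targets)
  new_connectivity_map(measure, seed_pair, targets, values)
}

#' Threshold a group map by subject-level bootstrap
#'
#' Bootstraps subjects (independent resampling with replacement) to obtain
#' the sampling distribution of each target's group mean; a two-sided
#' p-value comes from the normal approximation with the bootstrap SE, and
#' the significance mask applies a Bonferroni correction over the number of
#' tested targets.
#'
#' @param map a `connectivity_map`.
#' @param alpha familywise significance level (default 0.01).
#' @param n_boot subject-bootstrap replicates (default 10000).
#' @return the map with `se`, `p`, `significant` (and `alpha`) filled in.
#' @export
group_threshold <- function(map, alpha = 0.01, n_boot = 10000L) {
  stopifnot(inherits(map, "connectivity_map"))
  ns <- nrow(map$values)
  if (ns < 2)
    stop("cannot bootstrap a single-subject ensemble", call. = FALSE)
  idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), ncol = n_boot)
  # weight matrix: how often each subject is drawn in each replicate
  W <- matrix(0, n_boot, ns)
  for (b in seq_len(n_boot)) {
    tb <- tabulate(idx[, b], nbins = ns)
    W[b, ] <- tb / ns
  }
  boot_means <- W %*% map$values
  se <- apply(boot_means, 2, stats::sd)
  z <- ifelse(se > 0, map$group_mean / se, ifelse(map$group_mean == 0, 0, Inf))
  p <- 2 * stats::pnorm(-abs(z))
  map$se <- se
  map$p <- p
  map$alpha <- alpha
  map$n_tests <- length(p)
  map$significant <- p < alpha / length(p)
  map
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("%s map, seeds (%s): %d targets, %d subjects\n", x$measure,
              paste(x$seed, collapse = ", "), length(x$targets),
              nrow(x$values)))
  if (!is.null(x$significant))
    cat(sprintf("thresholded at alpha = %g (Bonferroni over %d tests): %d significant\n",
                x$alpha, x$n_tests, sum(x$significant)))
  top <- order(-abs(x$group_mean))[seq_len(min(5, length(x$targets)))]
  for (i in top)
    cat(sprintf("  %-14s %+.5f%s\n", x$targets[i], x$group_mean[i],
                if (!is.null(x$p)) sprintf("  p = %.2g", x$p[i]) else ""))
  invisible(x)
}

#' @export
plot.connectivity_map <- function(x, ...) {
  ord <- order(x$group_mean)
  col <- if (is.null(x$significant)) "grey40"
         else ifelse(x$significant[ord], "firebrick", "grey70")
  graphics::barplot(x$group_mean[ord], names.arg = x$targets[ord],
                    las = 2, col = col, border = NA,
                    ylab = paste("group-mean", x$measure), ...)
  invisible(x)
}

#' Map as a result table
#'
#' @param map a `connectivity_map`.
#' @return data.frame with `target`, `group_mean`, `se`, `p`, `significant`.
#' @export
map_table <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  data.frame(target = map$targets, group_mean = map$group_mean,
             se = if (is.null(map$se)) NA_real_ else map$se,
             p = if (is.null(map$p)) NA_real_ else map$p,
             significant = if (is.null(map$significant)) NA else
               map$significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-level distribution of connectivity over random region tuples
#'
#' Draws `n_tuples` random distinct-region k-tuples, computes the chosen
#' measure per subject, averages across subjects, and returns the sample
#' together with a kernel density estimate.  A second independent selection
#' can be drawn to check that the estimated distribution does not depend on
#' the particular tuples chosen.
#'
#' @param ens a [subject_ensemble()].
#' @param k tuple size: 2 (correlation), 3 (coskewness) or 4 (cokurtosis or
#'   edge connectivity).
#' @param n_tuples number of random tuples (default 1000).
#' @param measure measure name; defaults to the cumulant of order `k`
#'   (`"correlation"`, `"coskewness"`, `"cokurtosis"`; `"edge_corrected"`
#'   is the alternative at k = 4).
#' @param selections number of independent tuple selections (default 1).
#' @return a list with per-selection `values` (group-averaged, length
#'   `n_tuples`) and `density` objects.
#' @export
random_ktuple_distribution <- function(ens, k = 3, n_tuples = 1000L,
                                       measure = NULL, selections = 1L) {
  stopifnot(inherits(ens, "subject_ensemble"), k %in% 2:4)
  if (is.null(measure))
    measure <- c("correlation", "coskewness", "cokurtosis")[k - 1]
  nr <- length(ens$region_ids)
  if (nr < k) stop("not enough regions for k-tuples", call. = FALSE)
  out <- lapply(seq_len(selections), function(s) {
    tuples <- t(replicate(n_tuples, sample.int(nr, k)))
    vals <- rowMeans(vapply(ens$subjects, function(sub) {
      vapply(seq_len(n_tuples), function(g) {
        id <- tuples[g, ]
        switch(measure,
          correlation = moment_kernel(sub$data, id),
          coskewness = moment_kernel(sub$data, id),
          cokurtosis = cum4_kernel(sub$data, id[1], id[2], id[3], id[4]),
          edge_corrected = edge_raw_kernel(sub$data, id[1:2], id[3:4]) -
            edge_redundant_kernel(sub$data, id[1:2], id[3:4]))
      }, 1)
    }, numeric(n_tuples)))
    list(tuples = tuples, values = vals, density = stats::density(vals))
  })
  structure(list(measure = measure, k = k, selections = out),
            class = "ktuple_distribution")
}

#' @export
print.ktuple_distribution <- function(x, ...) {
  cat(sprintf("%s over random %d-tuples: %d selection(s) of %d tuples\n",
              x$measure, x$k, length(x$selections),
              length(x$selections[[1]]$values)))
  for (s in x$selections)
    cat(sprintf("  mean %+.4g, sd %.4g\n", mean(s$values), stats::sd(s$values)))
  invisible(x)
}

#' Functional interpretation of a significant coskewness
#'
#' A third-order interaction admits two readings, disambiguated by the signs
#' of the pairwise correlations among the triplet.  When all three pairwise
#' correlations are non-negative, a positive coskewness reflects coherent
#' extreme activations of all three regions and a negative coskewness
#' coherent extreme deactivations; with mixed correlation signs, two regions
#' co-fluctuate against the third (the two-against-one pattern).
#'
#' @param x a [region_ts()].
#' @param indices three distinct region labels/positions.
#' @param tol magnitude below which the coskewness is reported as absent;
#'   default `qnorm(0.975) * sqrt(6/T)`, the approximate two-sided 5%
#'   critical value of the estimator under an independent Gaussian null.
#' @return one of `"coherent extreme activations"`,
#'   `"coherent extreme deactivations"`,
#'   `"two-against-one extreme fluctuations"`, `"none"` (with the
#'   coskewness value as attribute).
#' @export
interpret_sign <- function(x, indices,
                           tol = stats::qnorm(0.975) *
                             sqrt(6 / ncol(x$data))) {
  x <- need_standardized(x)
  idx <- resolve_indices(x, indices)
  stopifnot(length(idx) == 3, !anyDuplicated(idx))
  cs <- moment_kernel(x$data, idx)
  lab <- if (abs(cs) <= tol) "none" else {
    pair <- c(moment_kernel(x$data, idx[c(1, 2)]),
              moment_kernel(x$data, idx[c(1, 3)]),
              moment_kernel(x$data, idx[c(2, 3)]))
    if (all(pair >= 0)) {
      if (cs > 0) "coherent extreme activations"
      else "coherent extreme deactivations"
    } else "two-against-one extreme fluctuations"
  }
  structure(lab, coskewness = cs)
}
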
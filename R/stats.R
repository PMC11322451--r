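#' Subject-level permutation statistics for longitudinal connectomes
#'
#' All hypothesis tests are paired sample t-tests with a sign-flip
#' permutation null: for each iteration a random subset of subjects has its
#' two observations (o1, o2) exchanged, which flips the sign of that
#' subject's paired difference, and the t statistic is recomputed. Tests are
#' two-sided. Sampled p-values use the add-one convention
#' p = (1 + #permutations at least as extreme) / (1 + n_perm), so p is
#' always positive; exhaustive enumeration over all 2^n sign patterns uses
#' the pure proportion #extreme / 2^n. Each test draws its permutations from
#' an RNG substream derived from (seed, unit id), so results are independent
#' of evaluation order.
#'
#' @name longitudinal_stats
NULL

# t statistic from flip-pattern means; sum of squares is flip-invariant
.perm_t <- function(m, ss, n) {
  v <- (ss - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v > ss * 1e-14 + 1e-300, m / sqrt(v / n),
              ifelse(abs(m) > 1e-14 * sqrt(ss / n + 1e-300) + 1e-300,
                     sign(m) * Inf, 0))
  t
}

.perm_core <- function(d, n_perm, seed, exhaustive, add_one = TRUE) {
  n <- length(d)
  ss <- sum(d^2)
  if (ss == 0) return(list(t = 0, p = 1, exhaustive = exhaustive))
  m_obs <- mean(d)
  t_obs <- .perm_t(m_obs, ss, n)
  thr <- if (is.finite(t_obs)) abs(t_obs) - 1e-12 * max(1, abs(t_obs)) else Inf
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20",
                     call. = FALSE)
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    m <- as.vector(S %*% d) / n
    t_star <- .perm_t(m, ss, n)
    p <- mean(abs(t_star) >= thr)
  } else {
    m <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.vector(S %*% d) / n
    })
    t_star <- .perm_t(m, ss, n)
    hits <- sum(abs(t_star) >= thr)
    p <- if (add_one) (1 + hits) / (1 + n_perm) else hits / n_perm
  }
  list(t = t_obs, p = p, exhaustive = exhaustive)
}

#' Sign-flip permutation paired t-test
#'
#' Computes t = mean(d) / (sd(d)/sqrt(n)) on d = o2 - o1 (sample sd) and a
#' two-sided permutation p-value from per-subject sign flips of d.
#' Degenerate samples are handled explicitly: an all-zero d yields
#' (t = 0, p = 1); a zero-variance d with nonzero mean yields t = +/-Inf
#' with the null built under the same convention (all-same-sign patterns
#' are the only ties), with a warning.
#'
#' @param o1,o2 Paired observation vectors (same length, n >= 2).
#' @param n_perm Number of sampled sign-flip iterations (default 1000).
#' @param seed RNG seed for the sampled null.
#' @param exhaustive Enumerate all 2^n sign patterns instead of sampling
#'   (n <= 20).
#' @param add_one Use the add-one convention p = (1 + hits)/(1 + n_perm)
#'   for sampled nulls (default TRUE, guaranteeing p > 0); FALSE yields
#'   the plain permutation-distribution proportion hits/n_perm.
#' @return List with elements \code{t}, \code{p}, \code{n},
#'   \code{mean_diff}.
#' @export
paired_perm_ttest <- function(o1, o2, n_perm = 1000L, seed = 1L,
                              exhaustive = FALSE, add_one = TRUE) {
  stopifnot(length(o1) == length(o2))
  n <- length(o1)
  if (n < 2) stop("paired test requires n >= 2", call. = FALSE)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d <- o2 - o1
  if (sum(d^2) > 0 && stats::var(d) == 0)
    warning("zero-variance paired differences with nonzero mean; ",
            "p determined by the all-same-sign flip patterns",
            call. = FALSE)
  res <- .perm_core(d, n_perm, seed, exhaustive, add_one)
  list(t = res$t, p = res$p, n = n, mean_diff = mean(d))
}

#' Benjamini-Hochberg step-up adjusted p-values
#' @param p_values Numeric vector of p-values.
#' @return q-values, monotone in ranked p and never below p.
#' @export
bh_fdr <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Side-flip a cohort into canonical orientation
#'
#' Mirrors left-focus subjects' matrices so the surgical hemisphere
#' occupies the right-label block for every subject.
#'
#' @param cohort A \code{cohort}.
#' @return List (one per subject) of lists with matrices t0, t1, t2.
#' @export
canonical_matrices <- function(cohort) {
  lapply(cohort$subjects, function(s) {
    if (s$focus_side == "left")
      lapply(s$matrices, side_flip, parcellation = cohort$parcellation)
    else s$matrices
  })
}

interval_timepoints <- function(interval) {
  switch(interval, early = c("t0", "t1"), late = c("t1", "t2"),
         stop("interval must be 'early' or 'late'", call. = FALSE))
}

edge_observations <- function(matrices, timepoint, edge_idx) {
  t(vapply(matrices, function(m) m[[timepoint]][edge_idx],
           numeric(nrow(edge_idx))))
}

#' Edgewise longitudinal comparison
#'
#' One sign-flip permutation paired t-test per supported edge (i < j,
#' diagonal excluded) comparing connection weights between the two
#' timepoints of an interval. Results are indexed to the earlier timepoint:
#' direction "increase" means the later timepoint was larger. q-values are
#' Benjamini-Hochberg adjusted across all tested edges.
#'
#' @param matrices Canonical per-subject matrices
#'   (from [canonical_matrices()]).
#' @param interval "early" (t0 vs t1) or "late" (t1 vs t2).
#' @param support Logical edge support mask from [group_threshold()];
#'   non-supported edges are not tested.
#' @param n_perm,seed Permutation settings; each edge uses the substream
#'   derived from (seed, interval, i, j).
#' @param exhaustive Use exhaustive sign-flip enumeration per edge.
#' @param add_one Sampled-p convention (see [paired_perm_ttest()]).
#' @return data.frame: i, j, label_i, label_j, interval, t, p, q,
#'   direction.
#' @export
edgewise_compare <- function(matrices, interval, support, n_perm = 1000L,
                             seed = 1L, exhaustive = FALSE, add_one = TRUE) {
  tps <- interval_timepoints(interval)
  ut <- upper.tri(support) & support
  edge_idx <- which(ut, arr.ind = TRUE)
  nm <- rownames(support)
  n_e <- nrow(edge_idx)
  if (!n_e)
    return(data.frame(i = integer(0), j = integer(0),
                      label_i = character(0), label_j = character(0),
                      interval = character(0), t = numeric(0),
                      p = numeric(0), q = numeric(0),
                      direction = character(0)))
  O1 <- edge_observations(matrices, tps[1], edge_idx)
  O2 <- edge_observations(matrices, tps[2], edge_idx)
  t_v <- p_v <- md <- numeric(n_e)
  for (e in seq_len(n_e)) {
    d <- O2[, e] - O1[, e]
    res <- .perm_core(d, n_perm,
                      derive_seed(seed, paste(interval, edge_idx[e, 1],
                                              edge_idx[e, 2])),
                      exhaustive, add_one)
    t_v[e] <- res$t; p_v[e] <- res$p; md[e] <- mean(d)
  }
  data.frame(i = edge_idx[, 1], j = edge_idx[, 2],
             label_i = nm[edge_idx[, 1]], label_j = nm[edge_idx[, 2]],
             interval = interval, t = t_v, p = p_v, q = bh_fdr(p_v),
             direction = ifelse(md > 0, "increase",
                                ifelse(md < 0, "decrease", "none")),
             stringsAsFactors = FALSE)
}

#' Nodewise longitudinal comparison of a regional graph metric
#'
#' Computes the chosen regional measure per subject and timepoint within
#' the chosen scope, then runs one permutation paired t-test per node.
#' Both the uncorrected p and the BH q are reported (study thresholds:
#' p <= 0.001 uncorrected, q <= 0.05 corrected).
#'
#' @param matrices Canonical per-subject matrices.
#' @param parcellation Parcellation with side/group tags.
#' @param metric One of "betweenness_centrality", "clustering_coefficient",
#'   "local_efficiency", "nodal_strength".
#' @param scope Subnetwork scope (see [subnetwork()]).
#' @param interval "early" or "late".
#' @param n_perm,seed,exhaustive Permutation settings.
#' @param retained_labels Optional label-name subset.
#' @return data.frame: node, scope, metric, interval, t, p, q, direction.
#' @export
nodewise_compare <- function(matrices, parcellation, metric, scope,
                             interval, n_perm = 1000L, seed = 1L,
                             exhaustive = FALSE, retained_labels = NULL) {
  metric <- match.arg(metric, c("betweenness_centrality",
                                "clustering_coefficient",
                                "local_efficiency", "nodal_strength"))
  fn <- switch(metric,
               betweenness_centrality = betweenness_w,
               clustering_coefficient = clustering_onnela,
               local_efficiency = local_efficiency,
               nodal_strength = nodal_strength)
  tps <- interval_timepoints(interval)
  sub0 <- subnetwork(matrices[[1]][[tps[1]]], parcellation, scope,
                     retained_labels = retained_labels)
  nodes <- rownames(sub0)
  n_n <- length(nodes)
  if (!n_n)
    return(data.frame(node = character(0), scope = character(0),
                      metric = character(0), interval = character(0),
                      t = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0)))
  vals <- lapply(tps, function(tp) {
    t(vapply(matrices, function(m) {
      fn(subnetwork(m[[tp]], parcellation, scope,
                    retained_labels = retained_labels))
    }, numeric(n_n)))
  })
  t_v <- p_v <- md <- numeric(n_n)
  for (k in seq_len(n_n)) {
    d <- vals[[2]][, k] - vals[[1]][, k]
    res <- .perm_core(d, n_perm,
                      derive_seed(seed, paste("node", metric, scope,
                                              interval, nodes[k])),
                      exhaustive)
    t_v[k] <- res$t; p_v[k] <- res$p; md[k] <- mean(d)
  }
  data.frame(node = nodes, scope = scope, metric = metric,
             interval = interval, t = t_v, p = p_v, q = bh_fdr(p_v),
             direction = ifelse(md > 0, "increase",
                                ifelse(md < 0, "decrease", "none")),
             stringsAsFactors = FALSE)
}

#' Global-measure longitudinal comparison
#'
#' One permutation paired t-test per global measure within a scope. No FDR
#' correction is applied (study threshold: uncorrected p <= 0.05).
#'
#' @inheritParams nodewise_compare
#' @param small_world Include small-worldness (adds the null-ensemble
#'   cost; per-subject null seeds derive from \code{seed}).
#' @param n_null,n_rewires_per_edge Null-ensemble settings for
#'   small-worldness.
#' @return data.frame: measure, scope, interval, t, p, direction.
#' @export
global_compare <- function(matrices, parcellation, scope, interval,
                           n_perm = 1000L, seed = 1L, exhaustive = FALSE,
                           small_world = TRUE, n_null = 100L,
                           n_rewires_per_edge = 10L,
                           retained_labels = NULL) {
  tps <- interval_timepoints(interval)
  gm <- lapply(tps, function(tp) {
    t(vapply(seq_along(matrices), function(s) {
      global_metrics(subnetwork(matrices[[s]][[tp]], parcellation, scope,
                                retained_labels = retained_labels),
                     small_world = small_world, n_null = n_null,
                     n_rewires_per_edge = n_rewires_per_edge,
                     seed = derive_seed(seed, paste("sw", scope, tp, s)))
    }, numeric(6)))
  })
  measures <- colnames(gm[[1]])
  out <- lapply(measures, function(ms) {
    o1 <- gm[[1]][, ms]; o2 <- gm[[2]][, ms]
    if (anyNA(o1) || anyNA(o2))
      return(data.frame(measure = ms, scope = scope, interval = interval,
                        t = NA_real_, p = NA_real_,
                        direction = NA_character_))
    res <- .perm_core(o2 - o1, n_perm,
                      derive_seed(seed, paste("global", scope, interval, ms)),
                      exhaustive)
    md <- mean(o2 - o1)
    data.frame(measure = ms, scope = scope, interval = interval,
               t = res$t, p = res$p,
               direction = if (md > 0) "increase"
                           else if (md < 0) "decrease" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Early-vs-late comparison of absolute connectivity changes
#'
#' For each supported edge (i < j), computes per-subject absolute CW
#' differences for the early (|CW_t1 - CW_t0|) and late (|CW_t2 - CW_t1|)
#' intervals, their cohort averages, and a permutation paired t-test
#' contrasting the two intervals. \code{greater_interval} reports which
#' interval shows the larger cohort-average change.
#'
#' @param matrices Canonical per-subject matrices.
#' @param support Logical edge support mask.
#' @param n_perm,seed,exhaustive,add_one Permutation settings (see
#'   [paired_perm_ttest()]).
#' @return data.frame: i, j, label_i, label_j, mean_abs_early,
#'   mean_abs_late, t, p, q, greater_interval.
#' @export
interval_abs_diff <- function(matrices, support, n_perm = 1000L, seed = 1L,
                              exhaustive = FALSE, add_one = TRUE) {
  ut <- upper.tri(support) & support
  edge_idx <- which(ut, arr.ind = TRUE)
  nm <- rownames(support)
  n_e <- nrow(edge_idx)
  if (!n_e)
    return(data.frame(i = integer(0), j = integer(0),
                      label_i = character(0), label_j = character(0),
                      mean_abs_early = numeric(0), mean_abs_late = numeric(0),
                      t = numeric(0), p = numeric(0), q = numeric(0),
                      greater_interval = character(0)))
  E <- abs(edge_observations(matrices, "t1", edge_idx) -
             edge_observations(matrices, "t0", edge_idx))
  L <- abs(edge_observations(matrices, "t2", edge_idx) -
             edge_observations(matrices, "t1", edge_idx))
  t_v <- p_v <- numeric(n_e)
  for (e in seq_len(n_e)) {
    res <- .perm_core(L[, e] - E[, e], n_perm,
                      derive_seed(seed, paste("absdiff", edge_idx[e, 1],
                                              edge_idx[e, 2])),
                      exhaustive, add_one)
    t_v[e] <- res$t; p_v[e] <- res$p
  }
  me <- colMeans(E); ml <- colMeans(L)
  data.frame(i = edge_idx[, 1], j = edge_idx[, 2],
             label_i = nm[edge_idx[, 1]], label_j = nm[edge_idx[, 2]],
             mean_abs_early = me, mean_abs_late = ml,
             t = t_v, p = p_v, q = bh_fdr(p_v),
             greater_interval = ifelse(me > ml, "early",
                                       ifelse(ml > me, "late", "equal")),
             stringsAsFactors = FALSE)
}

#' Classify an edge by hemisphere
#'
#' @param i,j Label names or matrix indices (vectors).
#' @param parcellation Parcellation with side tags.
#' @param focus_side Canonical surgical side (default "right").
#' @return Character vector in \{ipsilateral, contralateral, commissural,
#'   unclassified\}; any midline endpoint yields "unclassified".
#' @export
classify_edge <- function(i, j, parcellation, focus_side = "right") {
  labs <- parcellation$labels
  side_of <- function(x) {
    if (is.character(x)) labs$side[match(x, labs$name)]
    else labs$side[x]
  }
  si <- side_of(i); sj <- side_of(j)
  other <- if (focus_side == "right") "left" else "right"
  out <- rep("unclassified", length(si))
  both <- si != "midline" & sj != "midline"
  out[both & si == focus_side & sj == focus_side] <- "ipsilateral"
  out[both & si == other & sj == other] <- "contralateral"
  out[both & si != sj] <- "commissural"
  out
}

#' Cohort-level edge directions for one interval
#'
#' Direction of change (sign of the cohort-mean paired difference) for
#' every supported edge, significant or not.
#'
#' @param matrices Canonical per-subject matrices.
#' @param interval "early" or "late".
#' @param support Logical edge support mask.
#' @return data.frame: i, j, direction.
#' @export
edge_directions <- function(matrices, interval, support) {
  tps <- interval_timepoints(interval)
  ut <- upper.tri(support) & support
  edge_idx <- which(ut, arr.ind = TRUE)
  O1 <- edge_observations(matrices, tps[1], edge_idx)
  O2 <- edge_observations(matrices, tps[2], edge_idx)
  md <- colMeans(O2 - O1)
  data.frame(i = edge_idx[, 1], j = edge_idx[, 2],
             direction = ifelse(md > 0, "increase", "decrease"),
             stringsAsFactors = FALSE)
}

#' Lateralization chi-square analyses
#'
#' Two tests on the hemisphere-wise distribution of early connectivity
#' increases: (1) a chi-square test of independence (no continuity
#' correction) on the 2x2 hemisphere-by-direction table of all classified
#' intrahemispheric edges, and (2) a chi-square goodness-of-fit test of the
#' increase counts against an even 50/50 split between hemispheres.
#' Expected counts below 5 trigger a warning, not a failure.
#'
#' @param directions Character vector ("increase"/"decrease") per edge.
#' @param classes Character vector of edge classes from [classify_edge()];
#'   only "ipsilateral" and "contralateral" edges enter the tests.
#' @return List of class \code{"lateralization_result"}: the 2x2 table,
#'   both chi-square statistics with p-values, and the increase
#'   proportions per hemisphere.
#' @export
lateralization_tests <- function(directions, classes) {
  keep <- classes %in% c("ipsilateral", "contralateral")
  cls <- factor(classes[keep], levels = c("contralateral", "ipsilateral"))
  dir <- factor(directions[keep], levels = c("increase", "decrease"))
  tab <- table(cls, dir)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("lateralization tests undefined: empty hemisphere or direction ",
         "class", call. = FALSE)
  ind <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ind$expected < 5))
    warning("chi-square expected counts below 5", call. = FALSE)
  inc <- tab[, "increase"]
  gof <- suppressWarnings(stats::chisq.test(as.vector(inc),
                                            p = c(0.5, 0.5)))
  structure(list(
    table = tab,
    chi2_independence = unname(ind$statistic),
    p_independence = ind$p.value,
    chi2_gof = unname(gof$statistic),
    p_gof = gof$p.value,
    prop_increase = prop.table(tab, 1)[, "increase"],
    prop_increase_contra = unname(inc["contralateral"] / sum(inc))),
    class = "lateralization_result")
}

#' @export
print.lateralization_result <- function(x, ...) {
  cat("lateralization of early connectivity increases\n")
  print(x$table)
  cat(sprintf("  increase: %.0f%% contralateral vs %.0f%% ipsilateral\n",
              100 * x$prop_increase[["contralateral"]],
              100 * x$prop_increase[["ipsilateral"]]))
  cat(sprintf("  independence: chi2 = %.2f, p = %.3g\n",
              x$chi2_independence, x$p_independence))
  cat(sprintf("  goodness of fit (50/50): chi2 = %.2f, p = %.3g ",
              x$chi2_gof, x$p_gof))
  cat(sprintf("(%.0f%% of increases contralateral)\n",
              100 * x$prop_increase_contra))
  invisible(x)
}
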
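#' Synthetic cohort configuration
#'
#' Bundles every tunable of the synthetic-cohort generator: a lateralized
#' parcellation (\code{regions_per_hemisphere} per side plus
#' \code{n_midline} midline labels, the brainstem analogue) carved as
#' contiguous voxel patches on a small 3D grid, log-normal baseline
#' connection weights with a fixed fraction of structural zeros,
#' multiplicative planted effects concentrated in the early (t0 to t1)
#' interval (widespread ipsilateral decreases; contralateral and
#' peri-resection increases) and multiplicative log-normal within-subject
#' noise. Defaults mirror the study design this generator emulates: 10
#' subjects, 3 timepoints, 4/10 left-sided foci, six insular subregions per
#' hemisphere. Effect sizes are free parameters of the generator (the study
#' reports none); the defaults are chosen so that recovery is neither
#' trivial nor hopeless and are documented in the methods vignette.
#'
#' @param n_subjects Number of subjects.
#' @param regions_per_hemisphere Labels per hemisphere.
#' @param n_midline Midline labels (brainstem analogue).
#' @param n_insular_subregions Insular labels per hemisphere (must not
#'   exceed \code{regions_per_hemisphere}).
#' @param volume_shape 3D voxel grid dimensions.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline CW
#'   parameters (natural-log scale).
#' @param noise_log_sd Within-subject log-scale noise sd per timepoint
#'   transition.
#' @param effect_decrease_ipsi Multiplicative factor (< 1) planted on
#'   ipsilateral affected edges.
#' @param effect_increase_contra,effect_increase_periresection
#'   Multiplicative factors (> 1) planted on contralateral and
#'   peri-resection affected edges.
#' @param frac_edges_affected_early,frac_edges_affected_late Proportion of
#'   supported edges planted per interval.
#' @param frac_structural_zeros Proportion of edges absent from the shared
#'   anatomical support.
#' @param frac_left_focus Proportion of left-sided foci.
#' @param seed Master RNG seed (all randomness derives from it through
#'   per-subject substreams).
#' @return A validated list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_subjects = 10L,
                             regions_per_hemisphere = 20L,
                             n_midline = 1L,
                             n_insular_subregions = 6L,
                             volume_shape = c(24L, 24L, 24L),
                             baseline_log_mean = 0,
                             baseline_log_sd = 0.5,
                             noise_log_sd = 0.15,
                             effect_decrease_ipsi = 0.6,
                             effect_increase_contra = 1.5,
                             effect_increase_periresection = 1.5,
                             frac_edges_affected_early = 0.05,
                             frac_edges_affected_late = 0.02,
                             frac_structural_zeros = 0.15,
                             frac_left_focus = 0.4,
                             seed = 42L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              regions_per_hemisphere = as.integer(regions_per_hemisphere),
              n_midline = as.integer(n_midline),
              n_insular_subregions = as.integer(n_insular_subregions),
              volume_shape = as.integer(volume_shape),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              noise_log_sd = noise_log_sd,
              effect_decrease_ipsi = effect_decrease_ipsi,
              effect_increase_contra = effect_increase_contra,
              effect_increase_periresection = effect_increase_periresection,
              frac_edges_affected_early = frac_edges_affected_early,
              frac_edges_affected_late = frac_edges_affected_late,
              frac_structural_zeros = frac_structural_zeros,
              frac_left_focus = frac_left_focus,
              seed = as.integer(seed))
  fracs <- cfg[c("frac_edges_affected_early", "frac_edges_affected_late",
                 "frac_structural_zeros", "frac_left_focus")]
  if (any(unlist(fracs) < 0 | unlist(fracs) > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  eff <- cfg[c("effect_decrease_ipsi", "effect_increase_contra",
               "effect_increase_periresection")]
  if (any(unlist(eff) <= 0))
    stop("multiplicative effect factors must be > 0", call. = FALSE)
  if (cfg$n_insular_subregions > cfg$regions_per_hemisphere)
    stop("n_insular_subregions must be <= regions_per_hemisphere",
         call. = FALSE)
  if (cfg$n_subjects < 1 || cfg$regions_per_hemisphere < 1 ||
      cfg$n_midline < 0 || length(cfg$volume_shape) != 3L)
    stop("invalid synthetic configuration", call. = FALSE)
  if (cfg$noise_log_sd < 0 || cfg$baseline_log_sd < 0)
    stop("log-scale sds must be >= 0", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

split_ranges <- function(n, k) {
  # k nearly-equal consecutive 1..n chunks
  cuts <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Generate a lateralized synthetic parcellation
#'
#' Carves the voxel grid into contiguous label patches: a basal midline slab
#' (split into \code{n_midline} strips) and, above it, two mirrored
#' hemispheres (x-halves) each partitioned into a (y, z) grid of blocks.
#' The \code{n_insular_subregions} blocks nearest the hemisphere's center
#' are tagged \code{"insular"}; left/right labels with equal block index are
#' homotopic partners (names \code{L###}/\code{R###}).
#'
#' @param config A [synthetic_config()].
#' @return A \code{parcellation} (label table + label volume).
#' @export
generate_parcellation <- function(config) {
  d <- config$volume_shape
  R <- config$regions_per_hemisphere
  M <- config$n_midline
  halfx <- floor(d[1] / 2)
  mz <- if (M > 0) max(1L, ceiling(8 * M / (d[1] * d[2]))) else 0L
  hz <- d[3] - mz
  ny <- ceiling(sqrt(R))
  nz <- ceiling(R / ny)
  if (ny > d[2] || nz > hz || halfx < 1)
    stop("volume too small for the requested label count", call. = FALSE)
  yr <- split_ranges(d[2], ny)
  zr <- split_ranges(hz, nz)
  min_block <- halfx * min(lengths(yr)) * min(lengths(zr))
  if (min_block < 8)
    stop("volume too small: smallest label patch would have ", min_block,
         " voxels (< 8)", call. = FALSE)
  vol <- array(0L, dim = d)
  # block k -> (iy, iz); identical layout in both hemispheres
  block_iy <- ((seq_len(R) - 1L) %% ny) + 1L
  block_iz <- ((seq_len(R) - 1L) %/% ny) + 1L
  for (k in seq_len(R)) {
    ys <- yr[[block_iy[k]]]
    zs <- zr[[block_iz[k]]] + mz
    vol[1:halfx, ys, zs] <- k                      # left
    vol[(d[1] - halfx + 1):d[1], ys, zs] <- k + R  # right
  }
  if (M > 0) {
    ystrips <- split_ranges(d[2], M)
    for (m in seq_len(M)) vol[, ystrips[[m]], 1:mz] <- 2L * R + m
  }
  # insular tag: blocks nearest the hemisphere center (y, z)
  cy <- (d[2] + 1) / 2
  cz <- mz + (hz + 1) / 2
  bc_y <- vapply(yr[block_iy], function(v) mean(v), numeric(1))
  bc_z <- vapply(zr[block_iz], function(v) mean(v), numeric(1)) + mz
  dist2 <- (bc_y - cy)^2 + (bc_z - cz)^2
  insular_blocks <- order(dist2, seq_len(R))[seq_len(config$n_insular_subregions)]
  groups <- rep("", R)
  groups[insular_blocks] <- "insular"
  labels <- data.frame(
    id = c(seq_len(R), seq_len(R) + R, if (M > 0) 2L * R + seq_len(M)),
    name = c(sprintf("L%03d", seq_len(R)), sprintf("R%03d", seq_len(R)),
             if (M > 0) sprintf("M%03d", seq_len(M))),
    side = c(rep("left", R), rep("right", R),
             if (M > 0) rep("midline", M)),
    groups = c(groups, groups, if (M > 0) rep("", M)),
    stringsAsFactors = FALSE)
  new_parcellation(labels, vol)
}

# Labels with a voxel 6-adjacent to `region` (binary array) but not inside it.
adjacent_labels <- function(volume, region) {
  d <- dim(volume)
  idx <- which(region == 1)
  if (!length(idx)) return(integer(0))
  coords <- arrayInd(idx, d)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  found <- integer(0)
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(coords, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    out <- lin[region[lin] == 0]
    found <- union(found, setdiff(unique(volume[out]), 0L))
  }
  sort(found)
}

#' Generate tailored resection masks for one subject
#'
#' Draws two overlapping but non-identical binary cavity masks (t1 and t2
#' scans) centered on the focus-side insular labels, emulating manually
#' delineated cavities that remodel between postoperative scans. Boxes are
#' random per subject (every resection is tailored) but always contain the
#' insular centroid, guaranteeing overlap, and are clipped to the focus-side
#' half of the grid.
#'
#' @param config A [synthetic_config()].
#' @param parcellation Output of [generate_parcellation()].
#' @param subject_id Integer id (selects the per-subject RNG substream).
#' @param focus_side "left" or "right".
#' @return List with binary arrays \code{t1} and \code{t2}.
#' @export
generate_resection_masks <- function(config, parcellation, subject_id,
                                     focus_side) {
  stopifnot(focus_side %in% c("left", "right"))
  vol <- parcellation$volume
  labs <- parcellation$labels
  ins_ids <- labs$id[labs$side == focus_side & label_has_group(labs, "insular")]
  idx <- which(array(vol %in% ins_ids, dim = dim(vol)))
  coords <- arrayInd(idx, dim(vol))
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  centroid <- round(colMeans(coords))
  d <- dim(vol)
  halfx <- floor(d[1] / 2)
  xlim <- if (focus_side == "left") c(1L, halfx) else c(d[1] - halfx + 1L, d[1])
  draw_box <- function() {
    b <- matrix(0L, 2, 3)
    for (a in 1:3) {
      b[1, a] <- sample(lo[a]:centroid[a], 1)
      b[2, a] <- sample(centroid[a]:hi[a], 1)
    }
    # let the cavity nibble one voxel into neighbouring labels
    grow <- sample(0:1, 3, replace = TRUE)
    b[1, ] <- pmax(b[1, ] - grow, 1L)
    b[2, ] <- pmin(b[2, ] + grow, d)
    b[1, 1] <- max(b[1, 1], xlim[1]); b[2, 1] <- min(b[2, 1], xlim[2])
    b
  }
  box_to_mask <- function(b) {
    m <- array(0L, dim = d)
    m[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- 1L
    m
  }
  with_seed(derive_seed(config$seed, paste0("mask", subject_id)), {
    m1 <- box_to_mask(draw_box())
    m2 <- box_to_mask(draw_box())
    if (identical(m1, m2)) {
      b <- draw_box()
      b[2, 2] <- min(b[2, 2] + 1L, d[2])
      m2 <- box_to_mask(b)
      if (identical(m1, m2)) m2[centroid[1], max(b[1, 2] - 1, 1), centroid[3]] <- 1L
    }
    list(t1 = m1, t2 = m2)
  })
}

canonical_side_perm <- function(labels) {
  # permutation exchanging homotopic left/right labels, midline fixed
  nm <- labels$name
  perm <- seq_len(nrow(labels))
  for (i in seq_along(nm)) {
    side <- labels$side[i]
    if (side == "midline") next
    partner <- if (side == "left") sub("^L", "R", nm[i]) else sub("^R", "L", nm[i])
    j <- match(partner, nm)
    if (is.na(j))
      stop("missing homotopic partner for label ", nm[i], call. = FALSE)
    perm[i] <- j
  }
  perm
}

edge_upper <- function(P) {
  # all i < j pairs as a 2-column matrix
  which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Builds a full toy cohort: a shared parcellation, per-subject focus sides
#' (exactly \code{round(frac_left_focus * n_subjects)} left-sided, order
#' randomized), tailored resection masks, and three symmetric non-negative
#' connection-weight matrices per subject. The t0 matrix has log-normal edge
#' weights on a cohort-level anatomical support (structural zeros shared
#' across subjects); t1 multiplies t0 by the planted early factors and
#' log-normal noise; t2 multiplies t1 by the late factors and fresh noise.
#' Structural zeros stay zero at every timepoint.
#'
#' Planted effects are defined once, in canonical (right-focus) orientation,
#' so the cohort-level paired tests can recover them after side-flipping:
#' decreases on ipsilateral (canonical right) edges, increases on
#' contralateral and peri-resection edges (labels 6-adjacent to the
#' canonical insular block). Left-focus subjects are generated by mirroring
#' the canonical matrix through the homotopic label permutation.
#'
#' @param config A [synthetic_config()].
#' @return List with elements \code{cohort} (class \code{"cohort"}) and
#'   \code{ground_truth} (data.frame of planted edges in canonical label
#'   space: label_i < label_j, interval, direction, factor).
#' @export
generate_cohort <- function(config) {
  parc <- generate_parcellation(config)
  labs <- parc$labels
  P <- nrow(labs)
  pairs <- edge_upper(P)
  n_edges <- nrow(pairs)

  # cohort-level anatomical support
  support_edges <- with_seed(derive_seed(config$seed, "support"), {
    nz <- round(config$frac_structural_zeros * n_edges)
    zero_idx <- if (nz > 0) sample.int(n_edges, nz) else integer(0)
    setdiff(seq_len(n_edges), zero_idx)
  })

  # canonical geometry: focus = right
  side_i <- labs$side[pairs[, 1]]
  side_j <- labs$side[pairs[, 2]]
  ipsi_edges <- which(side_i == "right" & side_j == "right")
  contra_edges <- which(side_i == "left" & side_j == "left")
  ins_right <- labs$id[labs$side == "right" & label_has_group(labs, "insular")]
  region <- array(as.integer(parc$volume %in% ins_right),
                  dim = dim(parc$volume))
  peri_ids <- setdiff(adjacent_labels(parc$volume, region), ins_right)
  peri_edges <- which((pairs[, 1] %in% peri_ids | pairs[, 2] %in% peri_ids) &
                        side_i == "right" & side_j == "right")

  plant <- function(n_aff, pool_used, sub_seed) {
    with_seed(derive_seed(config$seed, sub_seed), {
      pool_dec <- setdiff(intersect(ipsi_edges, support_edges), pool_used)
      pool_peri <- setdiff(intersect(peri_edges, support_edges),
                           c(pool_used, pool_dec))
      pool_con <- setdiff(intersect(contra_edges, support_edges), pool_used)
      n_dec <- min(round(0.7 * n_aff), length(pool_dec))
      n_inc <- n_aff - n_dec
      n_peri <- min(ceiling(n_inc / 2), length(pool_peri))
      n_con <- min(n_inc - n_peri, length(pool_con))
      dec <- if (n_dec) sample(pool_dec, n_dec) else integer(0)
      peri <- if (n_peri) sample(pool_peri, n_peri) else integer(0)
      con <- if (n_con) sample(pool_con, n_con) else integer(0)
      peri <- setdiff(peri, dec)
      data.frame(
        edge = c(dec, peri, con),
        direction = c(rep("decrease", length(dec)),
                      rep("increase", length(peri) + length(con))),
        factor = c(rep(config$effect_decrease_ipsi, length(dec)),
                   rep(config$effect_increase_periresection, length(peri)),
                   rep(config$effect_increase_contra, length(con))))
    })
  }
  n_support <- length(support_edges)
  early <- plant(round(config$frac_edges_affected_early * n_support),
                 integer(0), "plant_early")
  late <- plant(round(config$frac_edges_affected_late * n_support),
                early$edge, "plant_late")
  # a multiplicative factor of exactly 1 is no effect: not a planted edge
  early <- early[early$factor != 1, , drop = FALSE]
  late <- late[late$factor != 1, , drop = FALSE]

  f_early <- rep(1, n_edges); f_early[early$edge] <- early$factor
  f_late <- rep(1, n_edges); f_late[late$edge] <- late$factor

  # focus-side assignment: fixed count, randomized order
  n_left <- round(config$frac_left_focus * config$n_subjects)
  sides <- with_seed(derive_seed(config$seed, "sides"),
                     sample(c(rep("left", n_left),
                              rep("right", config$n_subjects - n_left))))

  perm <- canonical_side_perm(labs)
  mirror <- function(m) {
    out <- m[perm, perm, drop = FALSE]
    dimnames(out) <- dimnames(m)
    out
  }
  edge_mat <- function(vals) {
    m <- matrix(0, P, P, dimnames = list(labs$name, labs$name))
    m[pairs] <- vals
    m + t(m)
  }

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    mats <- with_seed(derive_seed(config$seed, paste0("subject", s)), {
      w0 <- numeric(n_edges)
      w0[support_edges] <- exp(stats::rnorm(n_support, config$baseline_log_mean,
                                            config$baseline_log_sd))
      noise <- function() {
        e <- numeric(n_edges)
        e[support_edges] <- exp(stats::rnorm(n_support, 0, config$noise_log_sd))
        e
      }
      w1 <- w0 * f_early * noise()
      w2 <- w1 * f_late * noise()
      list(t0 = edge_mat(w0), t1 = edge_mat(w1), t2 = edge_mat(w2))
    })
    if (sides[s] == "left") mats <- lapply(mats, mirror)
    masks <- generate_resection_masks(config, parc, s, sides[s])
    subjects[[s]] <- list(id = s, focus_side = sides[s],
                          matrices = mats, masks = masks)
  }

  clinical <- with_seed(derive_seed(config$seed, "clinical"),
                        synth_clinical(config$n_subjects, sides))

  gt <- rbind(
    if (nrow(early)) data.frame(label_i = pairs[early$edge, 1],
                                label_j = pairs[early$edge, 2],
                                interval = "early",
                                direction = early$direction,
                                factor = early$factor),
    if (nrow(late)) data.frame(label_i = pairs[late$edge, 1],
                               label_j = pairs[late$edge, 2],
                               interval = "late",
                               direction = late$direction,
                               factor = late$factor))
  if (is.null(gt)) gt <- data.frame(label_i = integer(0), label_j = integer(0),
                                    interval = character(0),
                                    direction = character(0),
                                    factor = numeric(0))
  cohort <- structure(list(config = config, parcellation = parc,
                           subjects = subjects, clinical = clinical),
                      class = "cohort")
  list(cohort = cohort, ground_truth = gt)
}

synth_clinical <- function(n, sides) {
  age <- pmin(pmax(round(stats::rnorm(n, 32, 8)), 18), 48)
  onset <- vapply(age, function(a) sample(3:(a - 1), 1), numeric(1))
  deficit_pool <- c("Aphasia", "Contralateral hemiparesis",
                    "Contralateral hemihypesthesia")
  has_def <- stats::runif(n) < 0.5
  data.frame(
    patient_id = seq_len(n),
    sex = ifelse(stats::runif(n) < 0.8, "F", "M"),
    age_at_surgery = age,
    age_of_onset = onset,
    duration_of_epilepsy = age - onset,
    resection = sample(c("Anterior insula + Fop", "Posterior insula + TPop",
                         "Superior insula + FPop", "Insula (subtotal) + FPop"),
                       n, replace = TRUE),
    side = ifelse(sides == "left", "L", "R"),
    mri_finding = ifelse(stats::runif(n) < 0.3, "FCD", "N"),
    delay_baseline_to_surgery_months = round(stats::runif(n, 0.5, 12), 1),
    delay_surgery_to_scan1_months = round(stats::runif(n, 5, 8), 1),
    delay_surgery_to_scan2_months = round(stats::runif(n, 10.5, 14.5), 1),
    follow_up_months = sample(c(24, 36, 48, 60), n, replace = TRUE),
    engel_class = sample(c("IA", "IA", "IA", "IB", "IIA", "IIB"), n,
                         replace = TRUE),
    postoperative_deficit = ifelse(has_def, sample(deficit_pool, n,
                                                   replace = TRUE), "None"),
    delay_to_recovery_months = ifelse(has_def, sample(1:6, n, replace = TRUE),
                                      NA_real_),
    stringsAsFactors = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects x 3 timepoints, %d labels\n",
              length(x$subjects), nrow(x$parcellation$labels)))
  cat(sprintf("  focus sides: %d left / %d right\n",
              sum(vapply(x$subjects, `[[`, "", "focus_side") == "left"),
              sum(vapply(x$subjects, `[[`, "", "focus_side") == "right")))
  invisible(x)
}

#' Decompose a connectivity matrix into synthetic streamline records
#'
#' Emulates the output of microstructure-informed streamline filtering: each
#' supported connection becomes a bundle of \code{per_connection} streamline
#' records with random lengths, equal signal contributions (so that
#' aggregation through [build_matrix()] reproduces the input matrix exactly,
#' by the equal-contribution identity) and endpoint voxels sampled inside
#' the endpoint labels' patches.
#'
#' @param config A [synthetic_config()].
#' @param parcellation A \code{parcellation} with a label volume.
#' @param matrix Symmetric CW matrix to decompose; defaults to a baseline
#'   matrix drawn from the generator's log-normal model.
#' @param per_connection Streamlines per supported connection.
#' @param stream_tag Substream tag (vary per subject/timepoint).
#' @return data.frame with columns label_a, label_b, length, contribution
#'   and endpoint voxel coordinates (ax, ay, az, bx, by, bz).
#' @export
generate_streamlines <- function(config, parcellation, matrix = NULL,
                                 per_connection = 3L,
                                 stream_tag = "streamlines") {
  labs <- parcellation$labels
  P <- nrow(labs)
  if (is.null(matrix)) {
    matrix <- with_seed(derive_seed(config$seed, paste0(stream_tag, "_base")), {
      pairs <- edge_upper(P)
      vals <- exp(stats::rnorm(nrow(pairs), config$baseline_log_mean,
                               config$baseline_log_sd))
      m <- base::matrix(0, P, P, dimnames = list(labs$name, labs$name))
      m[pairs] <- vals
      m + t(m)
    })
  }
  idx <- which(upper.tri(matrix) & matrix > 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      length = numeric(0), contribution = numeric(0),
                      ax = integer(0), ay = integer(0), az = integer(0),
                      bx = integer(0), by = integer(0), bz = integer(0)))
  vox_by_label <- lapply(labs$id, function(id)
    arrayInd(which(parcellation$volume == id), dim(parcellation$volume)))
  names(vox_by_label) <- as.character(labs$id)
  with_seed(derive_seed(config$seed, stream_tag), {
    k <- per_connection
    n_str <- nrow(idx) * k
    ia <- rep(labs$id[idx[, 1]], each = k)
    ib <- rep(labs$id[idx[, 2]], each = k)
    cw <- rep(matrix[idx], each = k)
    lens <- stats::runif(n_str, 20, 100)
    pick <- function(ids) {
      t(vapply(as.character(ids), function(id) {
        v <- vox_by_label[[id]]
        v[sample.int(nrow(v), 1), ]
      }, numeric(3)))
    }
    pa <- pick(ia); pb <- pick(ib)
    data.frame(label_a = ia, label_b = ib, length = lens,
               contribution = cw / k,
               ax = pa[, 1], ay = pa[, 2], az = pa[, 3],
               bx = pb[, 1], by = pb[, 2], bz = pb[, 3],
               row.names = NULL)
  })
}
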
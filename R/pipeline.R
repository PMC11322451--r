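#' Pipeline orchestration
#'
#' Four stages wrap the analysis modules into a reproducible directory
#' layout: \code{simulate} writes a synthetic cohort (label volume, masks,
#' streamline records, clinical table, ground truth), \code{build} turns
#' streamlines into side-flipped, prevalence-thresholded CW matrices under
#' the merged resection masks, \code{analyze} runs all longitudinal
#' statistics, and \code{report} renders a plain-text summary. A JSON
#' manifest records the config snapshot, master seed, package version and
#' stage completion; replaying a manifest reproduces the report
#' byte-for-byte.
#'
#' @name cli_pipeline
NULL

manifest_path <- function(dir) file.path(dir, "manifest.json")

update_manifest <- function(dir, stage, extra = list()) {
  mp <- manifest_path(dir)
  man <- if (file.exists(mp)) read_config(mp) else
    list(version = as.character(utils::packageVersion("connremod")),
         stages = list())
  man$stages[[stage]] <- TRUE
  for (k in names(extra)) man[[k]] <- extra[[k]]
  write_config(man, mp)
  invisible(man)
}

stage_done <- function(dir, stage) {
  mp <- manifest_path(dir)
  file.exists(mp) && isTRUE(read_config(mp)$stages[[stage]])
}

#' Simulate a synthetic cohort into a run directory
#'
#' @param config A [synthetic_config()] (or named list of overrides).
#' @param out Output directory (created if needed).
#' @param force Re-run even if the stage is already complete.
#' @param write_streamlines Also write per-subject/timepoint streamline
#'   records (needed by the build stage).
#' @return Invisibly, the run directory.
#' @export
cmd_simulate <- function(config = synthetic_config(), out, force = FALSE,
                         write_streamlines = TRUE) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (stage_done(out, "simulate") && !force) {
    message("simulate: already complete (use force = TRUE to redo)")
    return(invisible(out))
  }
  gen <- generate_cohort(config)
  cohort <- gen$cohort
  write_config(unclass(config), file.path(out, "config.json"))
  write_label_table(cohort$parcellation$labels,
                    file.path(out, "labels.tsv"))
  write_nifti_volume(cohort$parcellation$volume,
                     file.path(out, "labels.nii"))
  write_clinical_table(cohort$clinical, file.path(out, "clinical.tsv"))
  utils::write.table(gen$ground_truth, file.path(out, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sdir <- file.path(out, "subjects")
  dir.create(sdir, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(sdir, sprintf("sub-%02d", s$id))
    dir.create(sd, showWarnings = FALSE)
    write_nifti_volume(s$masks$t1, file.path(sd, "mask_t1.nii"))
    write_nifti_volume(s$masks$t2, file.path(sd, "mask_t2.nii"))
    if (write_streamlines) {
      for (tp in c("t0", "t1", "t2")) {
        str <- generate_streamlines(config, cohort$parcellation,
                                    matrix = s$matrices[[tp]],
                                    stream_tag = paste0("str_", s$id, "_", tp))
        utils::write.table(str, file.path(sd, paste0("streamlines_", tp,
                                                     ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  update_manifest(out, "simulate",
                  list(config = unclass(config), seed = config$seed))
  invisible(out)
}

#' Build CW matrices from a simulated run directory
#'
#' Per subject: merge the two cavity masks, exclude masked label portions
#' (verifying timepoint invariance), aggregate streamlines into CW
#' matrices on the retained labels, side-flip left-focus subjects, then
#' apply the group prevalence threshold computed on the t0 matrices.
#'
#' @param dir Run directory produced by [cmd_simulate()].
#' @param min_retained_voxels Label-retention threshold.
#' @param max_zero_fraction Group prevalence removal boundary.
#' @param force Re-run even if complete.
#' @return Invisibly, the run directory.
#' @export
cmd_build <- function(dir, min_retained_voxels = 1L,
                      max_zero_fraction = 0.10, force = FALSE) {
  if (stage_done(dir, "build") && !force) {
    message("build: already complete (use force = TRUE to redo)")
    return(invisible(dir))
  }
  labels <- read_label_table(file.path(dir, "labels.tsv"))
  volume <- read_nifti_volume(file.path(dir, "labels.nii"))
  parc <- new_parcellation(labels, volume)
  clinical <- read_clinical_table(file.path(dir, "clinical.tsv"))
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  subj_dirs <- sort(list.dirs(file.path(dir, "subjects"), recursive = FALSE))
  mats_t0 <- list()
  all_mats <- list()
  for (k in seq_along(subj_dirs)) {
    sd <- subj_dirs[k]
    m1 <- read_nifti_volume(file.path(sd, "mask_t1.nii"))
    m2 <- read_nifti_volume(file.path(sd, "mask_t2.nii"))
    merged <- merge_masks(m1, m2)
    filt <- apply_filter_to_timepoints(
      list(t0 = volume, t1 = volume, t2 = volume), merged,
      min_retained_voxels = min_retained_voxels)
    retained <- filt$t0$retained_labels
    side <- clinical$side[k]
    mats <- lapply(c(t0 = "t0", t1 = "t1", t2 = "t2"), function(tp) {
      str <- utils::read.delim(file.path(sd, paste0("streamlines_", tp,
                                                    ".tsv")))
      m <- build_matrix(str, labels, retained_labels = retained)
      if (side == "L") m <- side_flip(m, parc) else m
    })
    all_mats[[k]] <- mats
    mats_t0[[k]] <- mats$t0
  }
  support <- group_threshold(mats_t0, max_zero_fraction = max_zero_fraction)
  smat <- matrix(as.integer(support), nrow(support),
                 dimnames = dimnames(support))
  write_matrix(smat, file.path(dir, "support.tsv"))
  for (k in seq_along(all_mats)) {
    for (tp in c("t0", "t1", "t2")) {
      write_matrix(apply_support(all_mats[[k]][[tp]], support),
                   file.path(mdir, sprintf("sub-%02d_%s.tsv", k, tp)))
    }
  }
  update_manifest(dir, "build")
  invisible(dir)
}

read_built_matrices <- function(dir) {
  files <- list.files(file.path(dir, "matrices"), pattern = "^sub-",
                      full.names = TRUE)
  ids <- sort(unique(sub("_t[0-2]\\.tsv$", "", basename(files))))
  lapply(ids, function(id) {
    lapply(c(t0 = "t0", t1 = "t1", t2 = "t2"), function(tp)
      read_matrix(file.path(dir, "matrices", paste0(id, "_", tp, ".tsv"))))
  })
}

#' Run the longitudinal analyses on a built run directory
#'
#' Edgewise CW comparisons (whole brain) for both intervals; nodewise
#' comparisons of the four regional measures on every scope; global-measure
#' comparisons per scope; the early-vs-late absolute-difference analysis;
#' and the lateralization chi-square tests on early directions. Results are
#' written as tab-separated tables under \code{results/}.
#'
#' @param dir Run directory after [cmd_build()].
#' @param n_perm Permutation iterations (default 1000).
#' @param seed Master seed for all permutation substreams.
#' @param scopes Subnetwork scopes to analyze.
#' @param small_world,n_null,n_rewires_per_edge Small-worldness settings.
#' @param force Re-run even if complete.
#' @return Invisibly, the run directory.
#' @export
cmd_analyze <- function(dir, n_perm = 1000L, seed = 1L,
                        scopes = c("whole_brain", "ipsilateral",
                                   "contralateral", "contralateral_insular"),
                        small_world = TRUE, n_null = 100L,
                        n_rewires_per_edge = 10L, force = FALSE) {
  if (stage_done(dir, "analyze") && !force) {
    message("analyze: already complete (use force = TRUE to redo)")
    return(invisible(dir))
  }
  labels <- read_label_table(file.path(dir, "labels.tsv"))
  parc <- new_parcellation(labels)
  support <- read_matrix(file.path(dir, "support.tsv")) > 0
  matrices <- read_built_matrices(dir)
  rdir <- file.path(dir, "results")
  dir.create(rdir, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(rdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edge_res <- lapply(c("early", "late"), function(iv)
    edgewise_compare(matrices, iv, support, n_perm = n_perm, seed = seed))
  wt(do.call(rbind, edge_res), "edgewise.tsv")
  node_res <- list()
  for (sc in scopes)
    for (metric in c("betweenness_centrality", "clustering_coefficient",
                     "local_efficiency", "nodal_strength"))
      for (iv in c("early", "late"))
        node_res[[length(node_res) + 1L]] <-
          nodewise_compare(matrices, parc, metric, sc, iv,
                           n_perm = n_perm, seed = seed)
  wt(do.call(rbind, node_res), "nodewise.tsv")
  glob_res <- list()
  for (sc in scopes)
    for (iv in c("early", "late"))
      glob_res[[length(glob_res) + 1L]] <-
        global_compare(matrices, parc, sc, iv, n_perm = n_perm, seed = seed,
                       small_world = small_world, n_null = n_null,
                       n_rewires_per_edge = n_rewires_per_edge)
  wt(do.call(rbind, glob_res), "global.tsv")
  wt(interval_abs_diff(matrices, support, n_perm = n_perm, seed = seed),
     "interval_abs_diff.tsv")
  dirs <- edge_directions(matrices, "early", support)
  cls <- classify_edge(dirs$i, dirs$j, parc)
  lat <- tryCatch(lateralization_tests(dirs$direction, cls),
                  error = function(e) NULL)
  if (!is.null(lat)) {
    lat_df <- data.frame(
      class = rep(rownames(lat$table), 2),
      direction = rep(colnames(lat$table), each = 2),
      count = as.vector(lat$table))
    wt(lat_df, "lateralization_table.tsv")
    wt(data.frame(test = c("independence", "goodness_of_fit"),
                  chi2 = c(lat$chi2_independence, lat$chi2_gof),
                  p = c(lat$p_independence, lat$p_gof)),
       "lateralization_tests.tsv")
  }
  update_manifest(dir, "analyze",
                  list(analysis = list(n_perm = n_perm, seed = seed,
                                       scopes = scopes, n_null = n_null,
                                       thresholds = list(p_uncorrected = 0.001,
                                                         q_fdr = 0.05,
                                                         p_global = 0.05))))
  invisible(dir)
}

fmt <- function(x) formatC(x, digits = 6, format = "g")

#' Render a plain-text report for an analyzed run directory
#'
#' Lists edges, nodes and global measures significant at the study's
#' thresholds (p <= 0.001 uncorrected and q <= 0.05 for edges/nodes;
#' p <= 0.05 for globals), the early-vs-late interval comparison counts,
#' and the lateralization tables. Byte-identical across replays of the
#' same manifest.
#'
#' @param dir Run directory after [cmd_analyze()].
#' @param force Re-run even if complete.
#' @return Invisibly, the report path.
#' @export
cmd_report <- function(dir, force = FALSE) {
  rp <- file.path(dir, "report.txt")
  if (stage_done(dir, "report") && !force && file.exists(rp)) {
    message("report: already complete (use force = TRUE to redo)")
    return(invisible(rp))
  }
  rdir <- file.path(dir, "results")
  edge <- utils::read.delim(file.path(rdir, "edgewise.tsv"))
  node <- utils::read.delim(file.path(rdir, "nodewise.tsv"))
  glob <- utils::read.delim(file.path(rdir, "global.tsv"))
  iad <- utils::read.delim(file.path(rdir, "interval_abs_diff.tsv"))
  lines <- c("connremod pipeline report", "")
  for (iv in c("early", "late")) {
    e <- edge[edge$interval == iv, ]
    sig <- e[e$p <= 0.001, ]
    lines <- c(lines, sprintf(
      "edgewise (%s): %d/%d edges p<=0.001 (%d increase / %d decrease); %d with q<=0.05",
      iv, nrow(sig), nrow(e), sum(sig$direction == "increase"),
      sum(sig$direction == "decrease"), sum(e$q <= 0.05)))
    if (nrow(sig)) {
      top <- sig[order(sig$p, sig$label_i, sig$label_j), ]
      top <- utils::head(top, 20)
      lines <- c(lines, sprintf("  %s-%s %s t=%s p=%s q=%s", top$label_i,
                                top$label_j, top$direction, fmt(top$t),
                                fmt(top$p), fmt(top$q)))
    }
  }
  sig_n <- node[node$p <= 0.001, ]
  lines <- c(lines, "", sprintf(
    "nodewise: %d/%d tests p<=0.001; %d with q<=0.05",
    nrow(sig_n), nrow(node), sum(node$q <= 0.05)))
  if (nrow(sig_n)) {
    sig_n <- sig_n[order(sig_n$p, sig_n$node), ]
    lines <- c(lines, sprintf("  %s %s %s [%s/%s] p=%s", sig_n$node,
                              sig_n$metric, sig_n$direction, sig_n$scope,
                              sig_n$interval, fmt(sig_n$p)))
  }
  sig_g <- glob[!is.na(glob$p) & glob$p <= 0.05, ]
  lines <- c(lines, "", sprintf("global: %d/%d measure tests p<=0.05",
                                nrow(sig_g), sum(!is.na(glob$p))))
  if (nrow(sig_g))
    lines <- c(lines, sprintf("  %s %s [%s/%s] p=%s", sig_g$measure,
                              sig_g$direction, sig_g$scope, sig_g$interval,
                              fmt(sig_g$p)))
  sig_i <- iad[iad$p <= 0.001, ]
  lines <- c(lines, "", sprintf(
    "interval comparison: %d edges differ (p<=0.001); %d early-greater, %d late-greater",
    nrow(sig_i), sum(sig_i$greater_interval == "early"),
    sum(sig_i$greater_interval == "late")))
  lt <- file.path(rdir, "lateralization_tests.tsv")
  if (file.exists(lt)) {
    ltab <- utils::read.delim(file.path(rdir, "lateralization_table.tsv"))
    ltst <- utils::read.delim(lt)
    inc <- ltab[ltab$direction == "increase", ]
    tot <- stats::aggregate(count ~ class, ltab, sum)
    lines <- c(lines, "", "lateralization of early changes:")
    for (cl in inc$class) {
      n_inc <- inc$count[inc$class == cl]
      n_tot <- tot$count[tot$class == cl]
      lines <- c(lines, sprintf("  %s: %d/%d (%.0f%%) increases", cl,
                                n_inc, n_tot, 100 * n_inc / n_tot))
    }
    lines <- c(lines, sprintf("  independence chi2=%s p=%s",
                              fmt(ltst$chi2[1]), fmt(ltst$p[1])),
               sprintf("  goodness-of-fit chi2=%s p=%s",
                       fmt(ltst$chi2[2]), fmt(ltst$p[2])))
  }
  writeLines(lines, rp)
  update_manifest(dir, "report")
  invisible(rp)
}

parse_cli_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2
      } else {
        out[[key]] <- TRUE; i <- i + 1
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate | build | analyze | report | all} with flags
#' \code{--config <json>}, \code{--out <dir>}, \code{--seed <int>},
#' \code{--n-perm <int>}, \code{--n-null <int>}, \code{--force}.
#' See \code{inst/cli/connremod} for an executable wrapper.
#'
#' @param args Character vector of CLI arguments.
#' @return Invisibly, the run directory.
#' @export
connremod_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- parse_cli_args(args)
  cmd <- opts$positional[1] %||% "help"
  if (cmd == "help" || is.na(cmd)) {
    cat("usage: connremod <simulate|build|analyze|report|all>",
        "--out DIR [--config FILE] [--seed N] [--n-perm N]",
        "[--n-null N] [--force]\n")
    return(invisible(NULL))
  }
  out <- opts$out %||% stop("--out is required", call. = FALSE)
  force <- isTRUE(opts$force)
  cfg_list <- if (!is.null(opts$config)) read_config(opts$config) else list()
  if (!is.null(opts$seed)) cfg_list$seed <- as.integer(opts$seed)
  seed <- as.integer(opts$seed %||% cfg_list$seed %||% 1L)
  n_perm <- as.integer(opts$n_perm %||% 1000L)
  n_null <- as.integer(opts$n_null %||% 100L)
  cfg <- do.call(synthetic_config, cfg_list)
  if (cmd %in% c("simulate", "all"))
    cmd_simulate(cfg, out, force = force)
  if (cmd %in% c("build", "all"))
    cmd_build(out, force = force)
  if (cmd %in% c("analyze", "all"))
    cmd_analyze(out, n_perm = n_perm, seed = seed, n_null = n_null,
                force = force)
  if (cmd %in% c("report", "all"))
    cmd_report(out, force = force)
  invisible(out)
}
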
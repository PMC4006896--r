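# Full pipeline orchestration: filter -> dense connectome -> optimal N ->
# N x N networks -> metrics -> pair-wise alignment -> reference -> sum
# network -> (optional) edge-wise group statistics.

#' Run the full atlas-free connectome pipeline on a cohort
#'
#' Executes the six pipeline stages for a cohort of subjects, each given as
#' a surface plus a streamline set (objects or file paths). Stages:
#' streamline length filtering, dense connectome construction, optimal-N
#' selection over the configured candidates, downscaling to N-node binary
#' networks, normalised global metrics, pair-wise simulated-annealing
#' alignment, cohort reference selection, and the sum network. If `groups`
#' assigns each subject to one of two groups, edge-wise statistics (FDR and
#' NBS) are added, computed on the networks aligned to the reference.
#'
#' @param subjects List of subjects; each a list with `surface` (a
#'   [surface_cloud()] or file path) and `streamlines` (a
#'   [streamline_set()] or file path).
#' @param config A `run_config` list, see [default_run_config()].
#' @param out_dir Optional directory; when given, per-subject network CSVs,
#'   the sum network and a JSON manifest are written there.
#' @param groups Optional factor/vector of two group labels, one per
#'   subject (requires >= 2 subjects per group).
#' @param nbs_t_threshold Primary |t| threshold for [nbs()]; required when
#'   `groups` is given.
#' @param nbs_K Permutations for [nbs()].
#' @param verbose Log per-stage progress to stderr.
#' @return An object of class `pipeline_result`: `optimal_n`, `networks`,
#'   `metrics`, `group_alignment`, `reference_index`, `sum_network`,
#'   `filter_reports`, `group_stats` (or NULL), `manifest`.
#' @export
run_pipeline <- function(subjects, config = default_run_config(),
                         out_dir = NULL, groups = NULL,
                         nbs_t_threshold = NULL, nbs_K = 1000L,
                         verbose = TRUE) {
  config <- validate_run_config(config)
  if (!is.list(subjects) || length(subjects) < 2L)
    stopf("the pipeline needs a cohort of at least 2 subjects (alignment is pair-wise)")
  if (!is.null(groups)) {
    if (length(groups) != length(subjects))
      stopf("groups must label every subject")
    if (length(unique(groups)) != 2L || min(table(groups)) < 2L)
      stopf("groups must define two groups with >= 2 subjects each")
    if (is.null(nbs_t_threshold))
      stopf("group comparison requested: nbs_t_threshold must be given")
  }
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  ns <- length(subjects)

  surfaces <- vector("list", ns)
  dense <- vector("list", ns)
  reports <- vector("list", ns)
  for (s in seq_len(ns)) {
    sub <- subjects[[s]]
    surf <- if (is.character(sub$surface)) read_surface(sub$surface) else
      surface_cloud(unclass(sub$surface))
    stream <- if (is.character(sub$streamlines))
      read_streamlines(sub$streamlines) else
        streamline_set(unclass(sub$streamlines))
    flt <- filter_by_length(stream, config$min_streamline_length_mm)
    reports[[s]] <- flt$report
    say("subject %d: %d/%d streamlines kept (>= %g mm)", s,
        flt$report$n_kept, flt$report$n_input,
        config$min_streamline_length_mm)
    dense[[s]] <- build_dense_connectome(flt$streamlines, surf,
                                         config$endpoint_radius_mm)
    surfaces[[s]] <- surf
    say("subject %d: dense connectome with %d point pairs", s,
        nrow(dense[[s]]$pairs))
  }

  say("selecting optimal N over {%s}",
      paste(config$node_counts_to_try, collapse = ", "))
  opt <- find_optimal_n(dense, surfaces, config$node_counts_to_try)
  if (is.na(opt$optimal_n))
    stopf("no candidate N leaves every subject connected; networks cannot be aligned")
  n_opt <- opt$optimal_n
  say("optimal N = %d", n_opt)

  part <- equal_area_partition(n_opt)
  networks <- vector("list", ns)
  metrics <- vector("list", ns)
  for (s in seq_len(ns)) {
    refs <- scale_to_surface(part, surfaces[[s]])
    asg <- assign_nodes(surfaces[[s]], refs)
    networks[[s]] <- downscale(dense[[s]], asg, surfaces[[s]])
    metrics[[s]] <- global_metrics(networks[[s]],
                                   n_random = config$n_random_networks,
                                   rewires_per_edge = config$rewires_per_edge,
                                   seed = config$random_seed + s)
    say("subject %d: nnz = %d, Cr = %.3f, Lr = %.3f, Q = %.3f, swi = %.3f",
        s, nnz(networks[[s]]), metrics[[s]]$Cr, metrics[[s]]$Lr,
        metrics[[s]]$Q, metrics[[s]]$swi)
  }

  say("pair-wise alignment (%d restarts)", config$sa_restarts)
  group <- pairwise_align_group(networks, restarts = config$sa_restarts,
                                iterations = config$sa_iterations,
                                cooling = config$cooling_factor,
                                seed = config$random_seed)
  ref <- select_reference(group)
  say("reference network: subject %d", ref)
  sum_net <- sum_network(group, ref)

  gstats <- NULL
  if (!is.null(groups)) {
    aligned <- lapply(seq_len(ns), function(j) {
      p <- group$permutations[[ref]][[j]]
      binary_network(networks[[j]]$adjacency[p, p])
    })
    ga <- aligned[groups == unique(groups)[1]]
    gb <- aligned[groups == unique(groups)[2]]
    tt <- edgewise_ttest(ga, gb)
    gstats <- list(
      ttest = tt,
      fdr_discoveries = fdr_correct(tt$p_value, 0.05),
      nbs = nbs(ga, gb, t_threshold = nbs_t_threshold, K = nbs_K,
                seed = config$random_seed)
    )
  }

  manifest <- list(
    n_subjects = ns,
    optimal_n = n_opt,
    reference_index = ref,
    random_seed = config$random_seed,
    config = unclass(config),
    nnz = vapply(networks, nnz, numeric(1)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = list()
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (s in seq_len(ns)) {
      fa <- file.path(out_dir, sprintf("subject%02d_adjacency.csv", s))
      fw <- file.path(out_dir, sprintf("subject%02d_weights.csv", s))
      write_adjacency(networks[[s]], fa)
      write_adjacency(networks[[s]], fw, what = "weights")
      files <- c(files, fa, fw)
    }
    fs <- file.path(out_dir, "sum_network.csv")
    write.table(sum_net$counts, fs, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files <- c(files, fs)
    manifest$files <- as.list(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(optimal_n = opt, networks = networks, metrics = metrics,
                 group_alignment = group, reference_index = ref,
                 sum_network = sum_net, filter_reports = reports,
                 group_stats = gstats, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d subjects, N = %d nodes, reference subject %d\n",
              x$manifest$n_subjects, x$manifest$optimal_n,
              x$reference_index))
  cat(sprintf("  nnz per subject: %s\n",
              paste(x$manifest$nnz, collapse = ", ")))
  cat("  mean off-diagonal post-alignment correlation: ")
  r <- x$group_alignment$r_matrix
  cat(sprintf("%.4f\n", mean(r[row(r) != col(r)])))
  if (!is.null(x$group_stats))
    cat(sprintf("  group stats: %d FDR discoveries, %d NBS components\n",
                sum(x$group_stats$fdr_discoveries),
                length(x$group_stats$nbs$sizes)))
  invisible(x)
}
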